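test_that("signed similarity maps correlation into [0,1]", {
  t_ <- seq(0, 1, length.out = 50)
  x <- rbind(a = t_, b = 2 * t_ + 3, c = -t_, d = sin(20 * t_))
  s <- signed_similarity(x)
  expect_equal(s["a", "b"], 1)            # perfectly correlated
  expect_equal(s["a", "c"], 0)            # perfectly anti-correlated
  expect_true(isSymmetric(s))
  expect_equal(unname(diag(s)), rep(1, 4))

  set.seed(2)
  long <- matrix(rnorm(2 * 5000), 2, dimnames = list(c("x", "y"), NULL))
  sl <- signed_similarity(long)
  expect_equal(sl["x", "y"], 0.5, tolerance = 0.05)
})

test_that("zero-variance genes get similarity 0.5 and are flagged", {
  x <- rbind(a = rnorm(10), b = rep(1, 10), c = rnorm(10))
  s <- signed_similarity(x)
  expect_equal(attr(s, "flagged"), "b")
  expect_equal(unname(s["b", c("a", "c")]), c(0.5, 0.5))
})

test_that("adjacency is an elementwise power with unit diagonal", {
  s <- matrix(0.5, 3, 3); diag(s) <- 1
  a <- adjacency_matrix(s, 6)
  expect_equal(a[1, 2], 0.015625)
  expect_equal(adjacency_matrix(s, 1), s)
  a2 <- adjacency_matrix(s, 8)
  expect_true(all(a2[upper.tri(a2)] <= a[upper.tri(a)]))
})

test_that("TOM matches the hand example and the brute-force oracle", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  tom <- topological_overlap(a)
  expect_equal(tom[1, 2], 0.5)

  z <- diag(5)
  expect_equal(topological_overlap(z), diag(5))

  for (seed in 1:3) {
    n <- sample(20:30, 1)
    adj <- random_adjacency(n, seed)
    expect_equal(topological_overlap(adj), tom_oracle(adj),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("soft-threshold choice honours the fit target and gene order", {
  # block structure gives a broad degree distribution
  st <- small_study(seed = 31, tissues = "BLD", n_genes = 300)
  sim <- signed_similarity(logcpm(st$counts$BLD))
  pick <- pick_soft_threshold(sim, candidate_betas = c(2, 4, 6, 8, 10, 12),
                              r2_target = 0.8)
  expect_true(pick$beta %in% c(2, 4, 6, 8, 10, 12))
  expect_equal(nrow(pick$fit_table), 6)

  low <- pick_soft_threshold(sim, candidate_betas = c(3, 6), r2_target = 1e-9)
  expect_lte(low$fit_table$r2[1], 1)
  # r2_target effectively 0: smallest candidate wins if its fit is positive
  if (low$fit_table$r2[1] > 0) expect_equal(low$beta, 3)

  perm <- sample(nrow(sim))
  pick2 <- pick_soft_threshold(sim[perm, perm],
                               candidate_betas = c(2, 4, 6, 8, 10, 12),
                               r2_target = 0.8)
  expect_equal(pick2$beta, pick$beta)
  expect_error(pick_soft_threshold(matrix(1, 4, 4), c(2, 4), 0.8),
               "degenerate")
})

test_that("block-diagonal similarity recovers the blocks exactly", {
  n <- 90
  labs <- rep(1:3, each = 30)
  sim <- outer(labs, labs, function(a, b) ifelse(a == b, 0.9, 0.1))
  diag(sim) <- 1
  dimnames(sim) <- list(paste0("g", 1:n), paste0("g", 1:n))
  tom <- topological_overlap(adjacency_matrix(sim, 6))
  asg <- detect_modules(tom, network_params(min_module_size = 10))
  expect_equal(mclust::adjustedRandIndex(asg$labels, labs), 1)
})

test_that("planted correlation blocks are recovered with high ARI", {
  aris <- vapply(1:5, function(seed) {
    set.seed(seed)
    n_sub <- 20
    # unit-variance factors so every block realizes the planted strength
    f <- t(scale(t(matrix(rnorm(3 * n_sub), 3))))
    x <- do.call(rbind, lapply(1:3, function(k)
      matrix(rep(f[k, ], each = 150), 150) * 2 + rnorm(150 * n_sub)))
    x <- rbind(x, matrix(rnorm(200 * n_sub), 200))
    rownames(x) <- paste0("g", seq_len(nrow(x)))
    truth <- c(rep(1:3, each = 150), rep(0, 200))
    tom <- topological_overlap(
      adjacency_matrix(signed_similarity(x), 8))
    asg <- detect_modules(tom, network_params(min_module_size = 100))
    mclust::adjustedRandIndex(asg$labels, truth)
  }, 0)
  expect_true(all(aris >= 0.9))
})

test_that("module detection is deterministic and degrades gracefully", {
  adj <- random_adjacency(40, 5)
  tom <- topological_overlap(adj)
  p <- network_params(min_module_size = 100)
  expect_warning(a1 <- detect_modules(tom, p), "min_module_size")
  expect_true(all(a1$labels == "0"))
  p2 <- network_params(min_module_size = 10)
  a2 <- detect_modules(tom, p2)
  a3 <- detect_modules(tom, p2)
  expect_identical(a2$labels, a3$labels)
})

test_that("eigengenes satisfy the rank-1, sign and norm conventions", {
  n <- 12
  prof <- rnorm(n)
  x <- matrix(rep(prof, each = 5), 5, byrow = FALSE) +
    matrix(rnorm(5 * n, sd = 1e-8), 5)
  rownames(x) <- paste0("g", 1:5); colnames(x) <- paste0("s", 1:n)
  labels <- setNames(rep("1", 5), rownames(x))
  E <- module_eigengenes(x, labels)
  expect_equal(sum(E[, 1]^2), 1)
  zprof <- as.numeric(scale(prof))
  expect_equal(abs(cor(E[, 1], zprof)), 1, tolerance = 1e-6)
  expect_gte(cor(E[, 1], zprof), 0)   # sign-aligned with the module mean

  # flipping all genes leaves the aligned eigengene unchanged
  E2 <- module_eigengenes(-x, labels)
  expect_equal(E2, -E, tolerance = 1e-6)

  # eigengene-mean correlation is never negative
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rnorm(8 * 15), 8, 15,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:15)))
    lab <- setNames(rep("1", 8), rownames(m))
    Em <- module_eigengenes(m, lab)
    z <- t(scale(t(m)))
    expect_gte(cor(Em[, 1], colMeans(z)), 0)
  }
  expect_error(module_eigengenes(x, setNames(c("1", "1", "0", "0", "0"),
                                             rownames(x))), "fewer than 3")
})

test_that("modules driven by one factor merge; distinct factors do not", {
  set.seed(9)
  n <- 20
  f <- rnorm(n)
  x <- rbind(matrix(rep(f, each = 30), 30) * 2 + rnorm(30 * n, sd = 0.5),
             matrix(rep(f, each = 30), 30) * 2 + rnorm(30 * n, sd = 0.5))
  rownames(x) <- paste0("g", 1:60); colnames(x) <- paste0("s", 1:n)
  labels <- setNames(rep(c("1", "2"), each = 30), rownames(x))
  asg <- structure(list(labels = labels, sizes = c(`1` = 30, `2` = 30),
                        dendrogram = NULL, params = network_params()),
                   class = "module_assignment")
  merged <- merge_similar_modules(x, asg, 0.25)
  expect_length(merged$sizes, 1)

  # no merging at threshold 0
  none <- merge_similar_modules(x, asg, 0)
  expect_length(none$sizes, 2)

  # distinct factors stay separate
  g <- rnorm(n)
  x2 <- rbind(matrix(rep(f, each = 30), 30) * 2 + rnorm(30 * n, sd = 0.5),
              matrix(rep(g, each = 30), 30) * 2 + rnorm(30 * n, sd = 0.5))
  dimnames(x2) <- dimnames(x)
  merged2 <- merge_similar_modules(x2, asg, 0.25)
  expect_length(merged2$sizes, 2)
})

test_that("the network pipeline is equivariant to gene permutation", {
  st <- small_study(seed = 41, tissues = "BLD", n_genes = 200,
                    with_degs = FALSE)
  e <- logcpm(st$counts$BLD)
  p <- network_params(beta = 10, min_module_size = 30)
  net1 <- coexpression_network(e, p)
  set.seed(1)
  perm <- sample(nrow(e$values))
  net2 <- coexpression_network(e$values[perm, ], p)
  l1 <- net1$assignment$labels
  l2 <- net2$assignment$labels[names(l1)]
  # same partition up to label names
  expect_equal(mclust::adjustedRandIndex(l1, l2), 1)
})
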