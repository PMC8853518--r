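# a small blood study with a strong planted group signal
blood_fixture <- function(seed = 1, n_genes = 120, lfc = 3, n_deg = 20) {
  st <- generate_study(synth_config(
    n_subjects_per_group = 10, tissues = "BLD", n_genes = n_genes,
    deg_specs = if (n_deg > 0)
      list(list(tissue = "BLD", n_genes = n_deg, lfc = lfc,
                direction = "up")) else list(),
    seed = seed))
  list(counts = st$counts$BLD,
       metadata = st$metadata,
       truth = st$truth)
}

small_grids <- function(p) list(
  elastic_net_lr = list(alpha = c(0.1, 1),
                        lambda = 10^seq(-2, 0, length.out = 10)),
  random_forest = list(mtry = max(2, floor(sqrt(p)))),
  plsda = list(ncomp = 1:2))

test_that("stratified fold plans are balanced, exhaustive and seeded", {
  y <- rep(c("CIE", "Air"), each = 10)
  plan <- repeated_cv_split(y, k = 5, repeats = 3, seed = 2)
  expect_length(plan, 3)
  for (folds in plan) {
    expect_length(folds, 5)
    all_idx <- sort(unlist(folds))
    expect_equal(all_idx, 1:20)                       # exhaustive, disjoint
    for (f in folds) expect_equal(as.vector(table(y[f])), c(2L, 2L))
  }
  expect_identical(plan, repeated_cv_split(y, k = 5, repeats = 3, seed = 2))
  expect_error(repeated_cv_split(rep(c("a", "b"), c(3, 17)), k = 5), ">= k")
})

test_that("fold normalization is leakage-safe", {
  set.seed(3)
  m <- matrix(rpois(50 * 12, 200), 50, 12,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  nz <- fold_normalize(m[, 1:8], m[, 9:12])
  # a test sample identical to a training sample normalizes identically
  nz2 <- fold_normalize(m[, 1:8], m[, c(1, 9:12)])
  expect_equal(nz2$test[1, ], nz$train[1, ])

  # leakage canary: an extreme outlier in the test fold must not move the
  # training statistics
  te_out <- m[, 9:12]; te_out[, 1] <- te_out[, 1] * 1000L
  nz3 <- fold_normalize(m[, 1:8], te_out)
  expect_identical(nz3$center, nz$center)
  expect_identical(nz3$scale, nz$scale)
  expect_identical(nz3$train, nz$train)

  # 10x test counts only shift via their own library size: centered
  # (unscaled) values move only by the prior-count nonlinearity
  nz4 <- fold_normalize(m[, 1:8], m[, 9:12] * 10L)
  d4 <- sweep(nz4$test, 2, nz4$scale, "*") - sweep(nz$test, 2, nz$scale, "*")
  expect_lt(max(abs(d4)), 0.02)

  # zero-sd training genes (identical training profiles) flagged, scale 1
  m0 <- m[, c(1, 1, 1, 1)]
  colnames(m0) <- paste0("t", 1:4)
  nz5 <- fold_normalize(m0, m[, 9:12])
  expect_true("g1" %in% nz5$flagged)
  expect_equal(unname(nz5$scale["g1"]), 1)
})

test_that("elastic net behaves at the penalty limits", {
  set.seed(5)
  x <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(NULL, paste0("g", 1:5)))
  eta <- 2 * x[, 1] - 1.5 * x[, 2]
  y <- factor(ifelse(plogis(eta) > runif(40), "CIE", "Air"),
              levels = c("Air", "CIE"))
  big <- fit_elastic_net_lr(x, y, alpha = 1, lambda = 100)
  expect_true(all(big$coef == 0))
  expect_equal(big$nonzero, 0)

  # alpha = 0, lambda -> 0 approaches the unpenalized fit (Newton oracle)
  small <- fit_elastic_net_lr(x, y, alpha = 0, lambda = 1e-5)
  ref <- glm(y ~ x, family = binomial)
  expect_equal(unname(small$coef), unname(coef(ref)[-1]), tolerance = 0.05)

  # separable training data gives training AUROC 1
  ysep <- factor(ifelse(x[, 1] > 0, "CIE", "Air"), levels = c("Air", "CIE"))
  fit <- fit_elastic_net_lr(x, ysep, alpha = 0.5, lambda = 0.01)
  expect_equal(roc_auc(predict(fit, x), ysep == "CIE")$auc, 1)
})

test_that("random forest ranks informative genes highly and is seeded", {
  set.seed(6)
  x <- matrix(rnorm(60 * 50), 60, 50,
              dimnames = list(NULL, paste0("g", 1:50)))
  y <- factor(rep(c("Air", "CIE"), each = 30))
  x[y == "CIE", 1:10] <- x[y == "CIE", 1:10] + 2
  hits <- vapply(1:5, function(s) {
    fit <- fit_random_forest(x, y, mtry = 7, n_trees = 200, seed = s)
    gini <- fit$forest$importance[, "MeanDecreaseGini"]
    top10 <- names(sort(gini, decreasing = TRUE))[1:10]
    mean(top10 %in% paste0("g", 1:10))
  }, 0)
  expect_gte(mean(hits >= 0.8), 0.8)

  f1 <- fit_random_forest(x, y, mtry = 7, n_trees = 100, seed = 3)
  f2 <- fit_random_forest(x, y, mtry = 7, n_trees = 100, seed = 3)
  expect_identical(predict(f1, x), predict(f2, x))

  const <- matrix(1, 20, 1, dimnames = list(NULL, "g1"))
  yc <- factor(rep(c("Air", "CIE"), c(12, 8)))
  fc <- fit_random_forest(const, yc, mtry = 1, n_trees = 50, seed = 1)
  expect_true(all(predict(fc, const) == predict(fc, const)[1]))
})

test_that("PLS-DA matches least squares at full rank and finds single markers", {
  set.seed(7)
  x <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- factor(rep(c("Air", "CIE"), 15))
  y01 <- as.numeric(y) - 1
  fit <- fit_plsda(x, y, ncomp = 4)     # ncomp = rank(X)
  ols <- lm(y01 ~ x)
  expect_equal(unname(predict(fit, x)), unname(fitted(ols)),
               tolerance = 1e-8)

  # one gene equal to the label loads first (features on comparable scale,
  # as after fold normalization)
  x2 <- cbind(marker = y01, matrix(rnorm(30 * 5), 30, 5))
  colnames(x2) <- c("marker", paste0("g", 1:5))
  x2 <- scale(x2)
  f2 <- fit_plsda(x2, y, ncomp = 1)
  expect_equal(names(which.max(f2$importance)), "marker")
  expect_error(fit_plsda(x, y, ncomp = 40), "ncomp")
})

test_that("confusion metrics match the printed formulas", {
  perfect <- confusion_matrix(rep(TRUE, 10), rep(TRUE, 10))
  perfect$TN <- 10   # 10 TP + 10 TN, no errors
  m <- metrics(perfect)
  expect_equal(unname(m["mcc"]), 1)
  expect_equal(unname(m["accuracy"]), 1)

  wrong <- structure(list(TP = 0, FP = 10, TN = 0, FN = 10),
                     class = "confusion_matrix")
  expect_equal(unname(metrics(wrong)["mcc"]), -1)

  cm <- structure(list(TP = 9, FN = 1, TN = 8, FP = 2),
                  class = "confusion_matrix")
  m2 <- metrics(cm)
  expect_equal(unname(m2["accuracy"]), 0.85)
  expect_equal(unname(m2["sensitivity"]), 0.9)
  expect_equal(unname(m2["specificity"]), 0.8)
  expect_equal(unname(m2["fpr"]), 0.2)
  expect_equal(unname(m2["mcc"]), 70 / sqrt(9900))
  expect_equal(unname(m2["mcc"]), 0.7035, tolerance = 1e-4)

  degen <- structure(list(TP = 5, FP = 5, TN = 0, FN = 0),
                     class = "confusion_matrix")
  expect_equal(unname(metrics(degen)["mcc"]), 0)
  expect_error(metrics(structure(list(TP = 0, FP = 0, TN = 0, FN = 0),
                                 class = "confusion_matrix")), "empty")

  # label swap exchanges sensitivity and specificity, keeps MCC
  pred <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  tru <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
  m_a <- metrics(confusion_matrix(pred, tru))
  m_b <- metrics(confusion_matrix(!pred, !tru))
  expect_equal(unname(m_a["sensitivity"]), unname(m_b["specificity"]))
  expect_equal(unname(m_a["mcc"]), unname(m_b["mcc"]))
})

test_that("AUROC matches the concordant-pair oracle and is rank-invariant", {
  set.seed(8)
  labels <- rep(c(TRUE, FALSE), each = 20)
  sep <- c(runif(20, 0.6, 1), runif(20, 0, 0.4))
  expect_equal(roc_auc(sep, labels)$auc, 1)

  for (i in 1:5) {
    sc <- round(rnorm(40), 1)   # generate ties on purpose
    expect_equal(roc_auc(sc, labels)$auc, auc_oracle(sc, labels),
                 tolerance = 1e-12)
  }
  sc <- rnorm(40)
  expect_equal(roc_auc(sc, labels)$auc, roc_auc(exp(sc), labels)$auc,
               tolerance = 1e-12)
  expect_error(roc_auc(sc, rep(TRUE, 40)), "both classes")
})

test_that("strong planted signal gives high cross-validated AUROC", {
  fx <- blood_fixture(seed = 10)
  rep_ <- run_classification(fx$counts, fx$metadata,
                             models = c("elastic_net_lr", "random_forest",
                                        "plsda"),
                             k = 5, repeats = 2, seed = 4,
                             grids = small_grids(120), k_inner = 3,
                             n_trees = 100)
  for (r in rep_) {
    expect_gte(r$metrics["auroc"], 0.9)
    expect_lte(r$n_nonzero, 120)
    expect_true(all(r$metrics[c("accuracy", "sensitivity",
                                "specificity")] <= 1))
  }
})

test_that("label permutation drives AUROC to chance", {
  # no planted signal: with n = 20 a permutation of labels over a strong
  # planted effect can stay partially aligned with the true groups
  fx <- blood_fixture(seed = 11, n_deg = 0)
  md <- fx$metadata
  set.seed(99)
  md$group <- sample(md$group)
  rep_ <- run_classification(fx$counts, md,
                             models = c("elastic_net_lr", "random_forest",
                                        "plsda"),
                             k = 5, repeats = 10, seed = 5,
                             grids = small_grids(120), k_inner = 3,
                             n_trees = 100)
  for (r in rep_) {
    expect_gte(r$metrics["auroc"], 0.35)
    expect_lte(r$metrics["auroc"], 0.65)
  }
})

test_that("mixed tissues are rejected", {
  st <- generate_study(synth_config(
    n_subjects_per_group = 5, tissues = c("BLD", "PFC"), n_genes = 50,
    seed = 1))
  both <- count_matrix(cbind(st$counts$BLD$counts, st$counts$PFC$counts))
  expect_error(run_classification(both, st$metadata), "mixed tissues")
})
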