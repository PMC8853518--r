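test_that("hypergeometric tail matches exhaustive enumeration", {
  expect_equal(hypergeometric_tail(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeometric_tail(0, 5, 4, 10), 1)
  expect_equal(hypergeometric_tail(5, 5, 10, 10), 1)  # sizeB = universe
  set.seed(1)
  for (i in 1:25) {
    N <- sample(5:30, 1)
    a <- sample.int(N, 1); b <- sample.int(N, 1)
    ov <- sample(max(0, a + b - N):min(a, b), 1)
    expect_equal(hypergeometric_tail(ov, a, b, N), hyper_oracle(ov, a, b, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeometric_tail(6, 5, 10, 10), "impossible")
})

test_that("module DEG enrichment flags a module equal to the DEG set", {
  genes <- paste0("g", 1:500)
  labels <- setNames(rep("0", 500), genes)
  labels[1:50] <- "1"; labels[51:120] <- "2"
  degs <- gene_set("DEG", genes[1:50])
  tab <- module_deg_enrichment(labels, degs)
  expect_lt(tab$p[tab$module == "1"], 1e-6)
  expect_equal(tab$strength[tab$module == "1"], "strong")
  none <- module_deg_enrichment(labels, gene_set("DEG", character(0)))
  expect_true(all(none$p == 1))
})

test_that("random DEG draws give a roughly nominal module false-positive rate", {
  genes <- paste0("g", 1:400)
  labels <- setNames(rep("0", 400), genes)
  for (k in 1:4) labels[((k - 1) * 50 + 1):(k * 50)] <- as.character(k)
  set.seed(5)
  hits <- replicate(200, {
    degs <- gene_set("DEG", sample(genes, 40))
    tab <- module_deg_enrichment(labels, degs)
    mean(tab$p < 0.05)
  })
  # hypergeometric p is discrete, so the realized rate sits at or below ~5%
  expect_lt(mean(hits), 0.07)
  expect_gt(mean(hits), 0.005)
})

test_that("eigengene-trait association recovers planted and null signals", {
  md <- data.frame(sample_id = paste0("s", 1:20),
                   group = rep(c("Air", "CIE"), each = 10),
                   consumption = rnorm(20, rep(c(8, 12), each = 10)),
                   preference = runif(20))
  E <- cbind(mod1 = as.numeric(scale(md$consumption)))
  rownames(E) <- md$sample_id
  tab <- eigengene_trait_association(E, md)
  r1 <- tab[tab$trait == "consumption", ]
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_lt(r1$p, 1e-12)

  # constant trait flagged
  md2 <- md; md2$preference <- 0.5
  tab2 <- eigengene_trait_association(E, md2)
  expect_true(is.na(tab2$r[tab2$trait == "preference"]))

  # planted correlation 0.7 recovered within +-0.15 on average
  rs <- vapply(1:20, function(seed) {
    st <- generate_study(synth_config(
      n_subjects_per_group = 10, tissues = "BLD", n_genes = 150,
      module_specs = list(list(id = "M1", size = 60, tissues = "BLD",
                               strength = 0.8, trait_cor = 0.7)),
      seed = seed))
    gm <- st$truth$module_genes$M1
    labs <- setNames(ifelse(rownames(st$counts$BLD$counts) %in% gm,
                            "M1", "0"), rownames(st$counts$BLD$counts))
    E <- module_eigengenes(logcpm(st$counts$BLD), labs)
    a <- eigengene_trait_association(E, st$metadata)
    a$r[a$trait == "consumption"]
  }, 0)
  expect_lt(abs(mean(rs) - 0.7), 0.15)

  # permuted trait: p roughly uniform
  set.seed(11)
  ps <- replicate(200, {
    mdp <- md; mdp$consumption <- sample(mdp$consumption)
    a <- eigengene_trait_association(E, mdp, traits = "consumption")
    a$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("CIE module selection is the union of the two criteria", {
  enr <- data.frame(module = c("1", "2", "3"), size = 50, overlap = 1,
                    p = c(0.01, 0.5, 0.9), p_up = NA, p_down = NA,
                    direction = "none", strength = "ns")
  assoc <- data.frame(module = rep(c("1", "2", "3"), each = 1),
                      trait = "consumption",
                      r = c(0, 0.8, 0.1), p = c(0.9, 0.001, 0.7), n = 20)
  sel <- select_cie_modules(enr, assoc)
  expect_setequal(sel$module, c("1", "2"))
  expect_equal(sel$criterion[sel$module == "1"], "deg")
  expect_equal(sel$criterion[sel$module == "2"], "trait")
  none <- select_cie_modules(enr[enr$module == "3", ],
                             assoc[assoc$module == "3", ])
  expect_equal(nrow(none), 0)
})

test_that("over-representation ranks an exactly matching set first", {
  uni <- paste0("g", 1:300)
  coll <- list(setA = uni[1:30], setB = uni[31:90], setC = uni[91:120])
  res <- gene_set_overrepresentation(gene_set("q", uni[1:30]), coll, uni)
  expect_equal(res$set[1], "setA")
  expect_equal(res$p_adj, pmin(1, res$p * 3), tolerance = 1e-12)
  expect_true(all(res$p_adj >= res$p))
  expect_warning(
    gene_set_overrepresentation(gene_set("q", uni[1:5]),
                                list(bad = c("zz1", "zz2"), setA = coll$setA),
                                uni), "skipped")
})

test_that("cross-tissue overlap uses the shared universe and excludes label 0", {
  genes <- paste0("g", 1:200)
  la <- setNames(rep("0", 200), genes); la[1:60] <- "1"; la[61:120] <- "2"
  lb <- la
  res <- cross_tissue_overlap(la, lb)
  self <- res[res$moduleA == res$moduleB, ]
  expect_true(all(self$overlap == self$sizeA))
  expect_true(all(self$p < 1e-10))
  expect_error(cross_tissue_overlap(setNames(la, paste0("x", 1:200)), lb),
               "universe")

  # independent random assignments: p roughly uniform
  set.seed(3)
  ps <- unlist(lapply(1:100, function(i) {
    l1 <- setNames(sample(c("1", "2"), 200, TRUE), genes)
    l2 <- setNames(sample(c("1", "2"), 200, TRUE), genes)
    cross_tissue_overlap(l1, l2)$p
  }))
  expect_gt(mean(ps > 0.5), 0.35)
  expect_lt(mean(ps < 0.05), 0.10)
})

test_that("meta-network applies the two-brain-region rule", {
  mk_overlap <- function(pa, pb, p) data.frame(
    moduleA = pa, moduleB = pb, sizeA = 50, sizeB = 50, overlap = 25,
    universe = 500, p = p)
  cie <- list(BLD = "1", PFC = "1", AMY = "1", HYP = "1")
  # blood connects to two brain regions -> flagged
  ov <- list("BLD|PFC" = mk_overlap("1", "1", 1e-8),
             "BLD|AMY" = mk_overlap("1", "1", 1e-6),
             "BLD|HYP" = mk_overlap("1", "1", 0.9))
  mn <- build_meta_network(ov, cie)
  expect_true(any(mn$clusters$blood_brain))
  expect_equal(nrow(mn$edges), 2)

  # only one brain region -> not flagged
  ov1 <- list("BLD|PFC" = mk_overlap("1", "1", 1e-8))
  mn1 <- build_meta_network(ov1, cie)
  expect_false(any(mn1$clusters$blood_brain))

  # two modules of the same region count once
  ovs <- list("BLD|PFC" = rbind(mk_overlap("1", "1", 1e-8),
                                mk_overlap("1", "2", 1e-8)))
  mn2 <- build_meta_network(ovs, list(BLD = "1", PFC = c("1", "2")))
  expect_false(any(mn2$clusters$blood_brain))

  # edge set invariant to tissue pair order
  ov_r <- ov[c(3, 1, 2)]
  mn_r <- build_meta_network(ov_r, cie)
  expect_equal(mn_r$edges, mn$edges)
})

test_that("meta-network export writes SIF and GraphML", {
  ov <- list("BLD|PFC" = data.frame(moduleA = "1", moduleB = "1",
                                    sizeA = 10, sizeB = 10, overlap = 9,
                                    universe = 100, p = 1e-9))
  mn <- build_meta_network(ov, list(BLD = "1", PFC = "1"))
  dir <- withr::local_tempdir()
  export_meta_network(mn, file.path(dir, "mn.sif"),
                      file.path(dir, "mn.graphml"))
  sif <- readLines(file.path(dir, "mn.sif"))
  expect_equal(sif, "BLD:1\toverlap\tPFC:1")
  g <- igraph::read_graph(file.path(dir, "mn.graphml"), format = "graphml")
  expect_equal(igraph::gorder(g), 2)
})
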