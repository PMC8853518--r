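# Independent brute-force oracles used across tests.

# triple-loop TOM: TOM_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 - a_ij)
tom_oracle <- function(adj) {
  n <- nrow(adj)
  a <- adj; diag(a) <- 0
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

# exact hypergeometric upper tail by enumeration over the overlap support
hyper_oracle <- function(overlap, sizeA, sizeB, universe) {
  xs <- overlap:min(sizeA, sizeB)
  sum(choose(sizeA, xs) * choose(universe - sizeA, sizeB - xs)) /
    choose(universe, sizeB)
}

# AUROC as the fraction of concordant (positive, negative) score pairs,
# ties credited one half
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# symmetric random adjacency in [0,1] with unit diagonal
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# a small multi-tissue study shared by several tests
small_study <- function(seed = 1, tissues = c("BLD", "PFC", "AMY"),
                        n_genes = 420, strength = 0.8, trait_cor = 0.7,
                        with_degs = TRUE) {
  mods <- list(
    list(id = "M1", size = 60, tissues = tissues, strength = strength,
         trait_cor = trait_cor),
    list(id = "M2", size = 60, tissues = tissues[1], strength = strength,
         trait_cor = 0))
  degs <- if (with_degs)
    lapply(tissues, function(tt)
      list(tissue = tt, n_genes = 20, lfc = 2, direction = "up"))
  else list()
  generate_study(synth_config(
    n_subjects_per_group = 10, tissues = tissues, n_genes = n_genes,
    module_specs = mods, deg_specs = degs, seed = seed))
}
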