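#' Network construction parameters
#'
#' Defaults follow the signed-network convention used throughout the
#' analysis: minimum module size 100, dynamic tree cut at height 0.99 with
#' deep split, and eigengene merge height 0.25. The soft-threshold power is
#' tissue-specific and normally chosen by [pick_soft_threshold()].
#'
#' @param beta soft-threshold power (positive integer), or NULL to choose
#'   from `candidate_betas` at network build time.
#' @param candidate_betas candidate powers for the scale-free fit search.
#' @param scale_free_r2_target minimal signed R^2 of the scale-free fit.
#' @param min_module_size smallest branch kept as a module (>= 3).
#' @param detect_cut_height dendrogram cut height for module detection,
#'   in (0, 1].
#' @param deep_split split long branches at secondary merge-height gaps?
#' @param merge_cut_height eigengene-dissimilarity height below which
#'   modules merge, in \[0, 1\].
#' @return object of class `network_params`.
#' @export
network_params <- function(beta = NULL, candidate_betas = c(1:10, 12, 14, 16, 18, 20),
                           scale_free_r2_target = 0.8,
                           min_module_size = 100, detect_cut_height = 0.99,
                           deep_split = TRUE, merge_cut_height = 0.25) {
  stopifnot(is.null(beta) || beta >= 1,
            min_module_size >= 3,
            detect_cut_height > 0, detect_cut_height <= 1,
            merge_cut_height >= 0, merge_cut_height <= 1,
            scale_free_r2_target > 0, scale_free_r2_target < 1)
  structure(list(beta = beta, candidate_betas = candidate_betas,
                 scale_free_r2_target = scale_free_r2_target,
                 min_module_size = as.integer(min_module_size),
                 detect_cut_height = detect_cut_height,
                 deep_split = isTRUE(deep_split),
                 merge_cut_height = merge_cut_height),
            class = "network_params")
}

#' Signed coexpression similarity
#'
#' `S_ij = (1 + cor(x_i, x_j)) / 2`, mapping Pearson correlation from
#' \[-1, 1\] to \[0, 1\] so that anti-correlated genes are maximally
#' dissimilar (the "signed" network convention). Zero-variance genes get the
#' uninformative similarity 0.5 to every other gene and are flagged in the
#' `"flagged"` attribute.
#'
#' @param expr [expression_matrix()] or numeric matrix, genes x samples.
#' @return symmetric similarity matrix in \[0,1\] with unit diagonal.
#' @export
signed_similarity <- function(expr) {
  x <- .expr_values(expr)
  if (ncol(x) < 3) stop("need >= 3 samples")
  sds <- apply(x, 1, stats::sd)
  flagged <- rownames(x)[sds == 0]
  s <- matrix(0.5, nrow(x), nrow(x), dimnames = list(rownames(x), rownames(x)))
  ok <- sds > 0
  if (any(ok)) {
    cc <- stats::cor(t(x[ok, , drop = FALSE]))
    s[ok, ok] <- (1 + cc) / 2
  }
  diag(s) <- 1
  s[s < 0] <- 0; s[s > 1] <- 1   # guard fp round-off
  attr(s, "flagged") <- flagged
  s
}

#' Soft-threshold adjacency
#'
#' Raises the signed similarity elementwise to the power beta; the diagonal
#' is forced to 1.
#'
#' @param sim similarity matrix in \[0,1\].
#' @param beta positive integer power.
#' @return adjacency matrix.
#' @export
adjacency_matrix <- function(sim, beta) {
  stopifnot(beta >= 1)
  a <- sim^beta
  diag(a) <- 1
  a
}

#' Choose a soft-threshold power by scale-free topology fit
#'
#' For each candidate power the connectivity `k_i = sum_j a_ij (j != i)` is
#' computed, log10(k) is binned, and log10(bin frequency) is regressed on
#' log10(mean k per bin). The fit index is R^2, signed negative when the
#' slope is positive (a scale-free degree distribution has a negative
#' slope). The smallest power reaching `r2_target` is chosen; if none does,
#' the power with the maximal fit wins.
#'
#' @param sim similarity matrix.
#' @param candidate_betas candidate powers (>= 2 of them).
#' @param r2_target target signed R^2.
#' @param n_bins number of logarithmic connectivity bins (empty bins drop).
#' @return list with `beta` and a `fit_table` data.frame
#'   (beta, r2, slope, mean_k).
#' @export
pick_soft_threshold <- function(sim, candidate_betas = c(1:10, 12, 14, 16, 18, 20),
                                r2_target = 0.8, n_bins = 10) {
  if (length(candidate_betas) < 2) stop("need >= 2 candidate powers")
  candidate_betas <- sort(candidate_betas)
  rows <- lapply(candidate_betas, function(b) {
    a <- sim^b
    diag(a) <- 0
    k <- rowSums(a)
    if (max(k) - min(k) < 1e-12) stop("degenerate network: constant connectivity")
    br <- seq(min(k), max(k) + 1e-9, length.out = n_bins + 1)
    bin <- cut(k, br, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    kmean <- tapply(k, bin, mean)
    keep <- !is.na(freq) & freq > 0 & kmean > 0
    lx <- log10(kmean[keep]); ly <- log10(freq[keep])
    if (length(lx) < 2) return(data.frame(beta = b, r2 = NA, slope = NA,
                                          mean_k = mean(k)))
    fit <- stats::lm(ly ~ lx)
    r2 <- summary(fit)$r.squared
    slope <- stats::coef(fit)[2]
    data.frame(beta = b, r2 = if (slope > 0) -r2 else r2,
               slope = slope, mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  hit <- which(!is.na(tab$r2) & tab$r2 >= r2_target)
  beta <- if (length(hit)) tab$beta[hit[1]] else
    tab$beta[which.max(tab$r2)]
  list(beta = beta, fit_table = tab)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for i != j, where
#' `l_ij = sum_u a_iu a_uj` over u distinct from i and j, and `k_i` is the
#' connectivity. The diagonal is 1. Measures how strongly two genes share
#' network neighbours in addition to their direct connection.
#'
#' @param adj adjacency matrix in \[0,1\], unit diagonal.
#' @return TOM matrix.
#' @export
topological_overlap <- function(adj) {
  a <- adj
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect modules by dynamic tree cut
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' (1 - TOM); the dendrogram is cut at `detect_cut_height` and branches with
#' at least `min_module_size` members become modules. With `deep_split`,
#' each accepted branch is refined: its secondary cut heights are scanned
#' for the one revealing the most subbranches of at least half the module
#' size (the module cores, which must be coherent — mean topological
#' overlap at least twice the tree-wide background), fragment cores of one
#' module are unioned, and remaining branch members join their nearest core
#' when close enough to it. Coreless branches at the background level are
#' dropped; coherent ones are kept whole. Genes outside any finished module
#' get the unassigned label "0".
#'
#' @param tom TOM (or any dissimilarity-convertible similarity) matrix.
#' @param params a [network_params()].
#' @return object of class `module_assignment`: list with `labels` (named
#'   character vector, "0" = unassigned), `sizes`, `dendrogram` (hclust) and
#'   `params`.
#' @export
detect_modules <- function(tom, params = network_params()) {
  n <- nrow(tom)
  genes <- rownames(tom) %||% as.character(seq_len(n))
  d <- 1 - tom
  dimnames(d) <- list(genes, genes)
  hc <- .monotone_hclust(d)
  labels <- setNames(rep("0", n), genes)
  if (n < params$min_module_size) {
    warning("fewer genes than min_module_size: all genes unassigned")
    return(structure(list(labels = labels, sizes = integer(0),
                          dendrogram = hc, params = params),
                     class = "module_assignment"))
  }
  cut0 <- stats::cutree(hc, h = min(params$detect_cut_height, max(hc$height)))
  branches <- split(genes, cut0)
  branches <- branches[lengths(branches) >= params$min_module_size]
  if (params$deep_split && length(branches)) {
    global_bg <- mean(d[upper.tri(d)])
    branches <- do.call(c, lapply(branches, function(memb)
      .deep_split(d[memb, memb, drop = FALSE], memb,
                  params$min_module_size, global_bg)))
    branches <- branches[lengths(branches) >= params$min_module_size]
  }
  branches <- branches[order(-lengths(branches))]
  for (i in seq_along(branches)) labels[branches[[i]]] <- as.character(i)
  sizes <- table(labels[labels != "0"])
  structure(list(labels = labels,
                 sizes = setNames(as.integer(sizes), names(sizes)),
                 dendrogram = hc, params = params),
            class = "module_assignment")
}

# refinement of one accepted branch: scan secondary cut heights for the one
# revealing the most full-sized subbranches, take the lowest such height as
# the module cores, then assign each remaining branch member to its nearest
# core if its average dissimilarity to that core is below the halfway point
# between the core's internal average and the branch-wide background level.
# Genes passing no threshold fall back to the unassigned label; the branch
# is kept whole when no height reveals >= 2 full-sized subbranches.
# average-linkage clustering with floating-point merge-height inversions
# flattened (cutree requires non-decreasing heights; ties in exact
# similarities can produce eps-scale inversions)
.monotone_hclust <- function(d) {
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  if (is.unsorted(hc$height)) hc$height <- cummax(hc$height)
  hc
}

.deep_split <- function(d, members, min_size, bg) {
  n <- length(members)
  branch_mean <- if (n > 1) mean(d[upper.tri(d)]) else bg
  # tightness on the overlap (similarity) scale: TOM dissimilarities crowd
  # toward 1, so a cluster counts as coherent when its mean topological
  # overlap is at least twice the tree-wide background overlap
  tight <- function(m) (1 - m) > 2 * (1 - bg)
  if (n < 2 * min_size)
    return(if (tight(branch_mean)) list(members) else list())
  hc <- .monotone_hclust(d)
  hs <- sort(unique(hc$height))
  if (length(hs) < 3) return(list(members))
  cand <- (utils::head(hs, -1) + utils::tail(hs, -1)) / 2
  if (length(cand) > 60)
    cand <- cand[round(seq(1, length(cand), length.out = 60))]
  # cores form at half the module quorum so they stay low in the tree and
  # pure; stragglers are recruited afterwards and the full min_size filter
  # is applied to the finished modules
  quorum <- max(ceiling(min_size / 2), 10)
  ks <- vapply(cand, function(hh)
    sum(table(stats::cutree(hc, h = hh)) >= quorum), 0L)
  if (max(ks) < 2) {
    return(if (tight(branch_mean)) list(members) else list())
  }
  cl <- stats::cutree(hc, h = cand[min(which(ks == max(ks)))])
  tab <- table(cl)
  core_labels <- names(tab)[tab >= quorum]
  cores <- lapply(core_labels, function(ci) which(cl == as.integer(ci)))
  core_inner <- function(ix) mean(d[ix, ix][upper.tri(d[ix, ix])])
  # a branch with no coherent core is itself either one tight module (kept
  # whole) or background (dropped); diffuse clumps at the background level
  # must not seed modules, or they recruit half the branch
  cores <- cores[vapply(cores, function(ix) tight(core_inner(ix)), TRUE)]
  if (!length(cores)) {
    return(if (tight(branch_mean)) list(members) else list())
  }
  # validity: fragments of one module are nearly as close across cores as
  # within them; union any core pair whose cross-dissimilarity is closer to
  # the within-core level than to the background
  repeat {
    k <- length(cores)
    if (k < 2) break
    within <- vapply(cores, core_inner, 0)
    merged <- FALSE
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        cross <- mean(d[cores[[i]], cores[[j]]])
        if (cross < (max(within[i], within[j]) + bg) / 2) {
          cores[[i]] <- sort(c(cores[[i]], cores[[j]]))
          cores[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  core_mean <- vapply(cores, core_inner, 0)
  out <- cores
  for (g in setdiff(seq_len(n), unlist(cores))) {
    md <- vapply(cores, function(ix) mean(d[g, ix]), 0)
    k <- which.min(md)
    if (md[k] <= core_mean[k] + 0.25 * (bg - core_mean[k]))
      out[[k]] <- c(out[[k]], g)
  }
  lapply(out, function(ix) members[sort(ix)])
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("module_assignment:", sum(x$labels != "0"), "of", length(x$labels),
      "genes in", length(x$sizes), "modules\n")
  if (length(x$sizes)) print(x$sizes)
  invisible(x)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene-standardized expression submatrix: the first right singular vector
#' over samples, unit norm, sign-aligned so that its correlation with the
#' module's mean standardized expression is non-negative.
#'
#' @param expr [expression_matrix()] or matrix, genes x samples.
#' @param assignment a `module_assignment` (or named label vector).
#' @return samples x modules numeric matrix of unit-norm eigengenes.
#' @export
module_eigengenes <- function(expr, assignment) {
  x <- .expr_values(expr)
  labels <- if (inherits(assignment, "module_assignment"))
    assignment$labels else assignment
  mods <- setdiff(unique(labels), "0")
  if (!length(mods)) stop("no modules to summarize")
  E <- matrix(NA_real_, ncol(x), length(mods),
              dimnames = list(colnames(x), mods))
  for (m in mods) {
    g <- names(labels)[labels == m]
    if (length(g) < 3) stop("module ", m, " has fewer than 3 genes")
    z <- t(scale(t(x[g, , drop = FALSE])))
    z[!is.finite(z)] <- 0   # zero-variance genes contribute nothing
    sv <- svd(z, nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (stats::cor(v, colMeans(z)) < 0) v <- -v
    E[, m] <- v / sqrt(sum(v^2))
  }
  E
}

#' Merge modules with correlated eigengenes
#'
#' Average-linkage clustering of eigengene dissimilarity `1 - cor(E_a, E_b)`;
#' module groups merging below `merge_cut_height` are unioned, eigengenes are
#' recomputed, and the procedure iterates until stable.
#'
#' @param expr expression matrix used to recompute eigengenes.
#' @param assignment a `module_assignment`.
#' @param merge_cut_height height threshold; 0 disables merging.
#' @return updated `module_assignment`.
#' @export
merge_similar_modules <- function(expr, assignment,
                                  merge_cut_height = 0.25) {
  stopifnot(inherits(assignment, "module_assignment"))
  labels <- assignment$labels
  if (merge_cut_height <= 0) return(assignment)
  repeat {
    mods <- setdiff(unique(labels), "0")
    if (length(mods) < 2) break
    E <- module_eigengenes(expr, labels)
    dis <- 1 - stats::cor(E)
    hc <- .monotone_hclust(dis)
    grp <- stats::cutree(hc, h = merge_cut_height)
    if (max(grp) == length(mods)) break
    remap <- setNames(as.character(grp[colnames(E)]), colnames(E))
    labels[labels != "0"] <- remap[labels[labels != "0"]]
  }
  # relabel 1..K by decreasing size
  mods <- setdiff(unique(labels), "0")
  sz <- sort(table(labels[labels != "0"]), decreasing = TRUE)
  remap <- setNames(as.character(seq_along(sz)), names(sz))
  labels[labels != "0"] <- remap[labels[labels != "0"]]
  sizes <- table(labels[labels != "0"])
  structure(list(labels = labels,
                 sizes = setNames(as.integer(sizes), names(sizes)),
                 dendrogram = assignment$dendrogram,
                 params = assignment$params),
            class = "module_assignment")
}

#' Build a signed coexpression network for one tissue
#'
#' End-to-end wrapper: signed similarity, soft-threshold choice (unless
#' `params$beta` is fixed), adjacency, TOM, dynamic tree cut, eigengene
#' merging and final eigengenes.
#'
#' @param expr [expression_matrix()] or matrix, genes x samples.
#' @param params [network_params()].
#' @return object of class `coexpr_network` with the similarity-derived
#'   pieces, the final `assignment` and `eigengenes`.
#' @export
coexpression_network <- function(expr, params = network_params()) {
  sim <- signed_similarity(expr)
  beta <- params$beta
  fit_table <- NULL
  if (is.null(beta)) {
    pick <- pick_soft_threshold(sim, params$candidate_betas,
                                params$scale_free_r2_target)
    beta <- pick$beta
    fit_table <- pick$fit_table
  }
  adj <- adjacency_matrix(sim, beta)
  tom <- topological_overlap(adj)
  assign0 <- detect_modules(tom, params)
  assign1 <- if (length(assign0$sizes) > 1)
    merge_similar_modules(expr, assign0, params$merge_cut_height) else assign0
  eig <- if (length(assign1$sizes))
    module_eigengenes(expr, assign1) else NULL
  structure(list(beta = beta, fit_table = fit_table,
                 assignment = assign1, eigengenes = eig,
                 flagged = attr(sim, "flagged"), params = params,
                 dendrogram = assign0$dendrogram),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat("Signed coexpression network (beta =", x$beta, "):",
      length(x$assignment$sizes), "modules\n")
  print(x$assignment)
  invisible(x)
}

#' @export
plot.coexpr_network <- function(x, ...) {
  plot(x$dendrogram, labels = FALSE, hang = -1,
       main = "TOM dissimilarity dendrogram", xlab = "", sub = "", ...)
  invisible(x)
}

#' Export the module dendrogram as Newick
#'
#' @param network a `coexpr_network` (or an hclust).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dendrogram_newick <- function(network, path) {
  hc <- if (inherits(network, "coexpr_network")) network$dendrogram
        else network
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
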