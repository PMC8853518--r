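# Spearman rho with average ranks and two-sided t-approximation p-value.
# Vectorized over the rows of two matrices with matched columns.
.spearman_rows <- function(a, b) {
  n <- ncol(a)
  ra <- t(apply(a, 1, rank))
  rb <- t(apply(b, 1, rank))
  ra <- ra - rowMeans(ra); rb <- rb - rowMeans(rb)
  num <- rowSums(ra * rb)
  den <- sqrt(rowSums(ra^2) * rowSums(rb^2))
  rho <- ifelse(den > 0, num / den, NA_real_)
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-15))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1] <- 0
  data.frame(rho = rho, p = p, n = n)
}

#' Between-subject blood/brain expression correlation
#'
#' Averages each gene's normalized expression across all samples in each
#' tissue (irrespective of treatment) and reports the Spearman correlation
#' between the two mean vectors over the shared genes — the design used when
#' blood and brain come from different individuals.
#'
#' @param exprA,exprB [expression_matrix()] or matrix for the two tissues.
#' @return list: `rho`, `p`, `n_genes`, and `table` (gene, meanA, meanB) for
#'   scatterplots.
#' @export
between_subject_correlation <- function(exprA, exprB) {
  a <- .expr_values(exprA); b <- .expr_values(exprB)
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) < 10) stop("need >= 10 shared genes")
  ma <- rowMeans(a[shared, , drop = FALSE])
  mb <- rowMeans(b[shared, , drop = FALSE])
  res <- .spearman_rows(matrix(ma, 1), matrix(mb, 1))
  list(rho = res$rho, p = res$p, n_genes = length(shared),
       table = data.frame(gene = shared, meanA = ma, meanB = mb,
                          row.names = NULL))
}

#' Within-subject blood/brain correlation per gene
#'
#' For each shared gene, the Spearman correlation of its expression across
#' subjects measured in both tissues (each point one animal). P-values are
#' Holm-adjusted across all genes tested.
#'
#' @param exprA,exprB expression matrices for the two tissues (columns are
#'   sample ids present in `metadata`).
#' @param metadata data.frame with sample_id and subject_id mapping samples
#'   to animals.
#' @return data.frame of class `correlation_records`: gene, rho, p, p_holm,
#'   n.
#' @export
within_subject_correlation <- function(exprA, exprB, metadata) {
  a <- .expr_values(exprA); b <- .expr_values(exprB)
  subjA <- metadata$subject_id[match(colnames(a), metadata$sample_id)]
  subjB <- metadata$subject_id[match(colnames(b), metadata$sample_id)]
  if (anyNA(subjA) || anyNA(subjB)) stop("samples missing from metadata")
  shared_subj <- intersect(subjA, subjB)
  if (!length(shared_subj)) stop("no matched subjects across tissues")
  if (length(shared_subj) < 5) stop("need >= 5 matched subjects")
  a <- a[, match(shared_subj, subjA), drop = FALSE]
  b <- b[, match(shared_subj, subjB), drop = FALSE]
  shared <- intersect(rownames(a), rownames(b))
  if (!length(shared)) stop("no shared genes")
  res <- .spearman_rows(a[shared, , drop = FALSE], b[shared, , drop = FALSE])
  out <- data.frame(gene = shared, rho = res$rho, p = res$p,
                    p_holm = holm_adjust(res$p), n = res$n,
                    row.names = NULL)
  class(out) <- c("correlation_records", "data.frame")
  out
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorted ascending, `adj_(i) = max_{j <= i} min(1, (m - j + 1) p_(j))`,
#' restored to input order. NA/NaN p-values propagate and are excluded from
#' m.
#'
#' @param pvals numeric vector of p-values in \[0,1\] (NA allowed).
#' @return adjusted p-values.
#' @export
holm_adjust <- function(pvals) {
  out <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values outside [0,1]")
  out[ok] <- stats::p.adjust(pvals[ok], method = "holm")
  out
}

#' Compare two independent correlations (Fisher z)
#'
#' Tests whether correlations observed in two independent groups (e.g. males
#' vs females) differ: both are Fisher z-transformed and
#' `z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` is referred to the standard
#' normal, two-sided.
#'
#' @param r1,r2 sample correlations, |r| < 1.
#' @param n1,n2 group sizes, > 3.
#' @return list with `z` and `p`.
#' @export
compare_independent_correlations <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both groups")
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("need |r| < 1")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
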