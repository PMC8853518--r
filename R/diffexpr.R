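#' Moderated t-statistic differential expression
#'
#' Fits a (weighted) linear model per gene and shrinks the residual
#' variances toward a common prior via empirical Bayes, giving the moderated
#' t-statistic: the gene-wise variance s_g^2 on d_g residual df is replaced
#' by the posterior `s2_post = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`, and
#' the t-statistic for the contrast is referred to a t-distribution on
#' `d0 + d_g` df. The prior df d0 and prior variance s0^2 are estimated by
#' moment matching on the log residual variances (a scaled-F fit).
#'
#' @param expr an [expression_matrix()] (weights used if present) or numeric
#'   matrix of log2 expression values, genes x samples.
#' @param design design matrix (samples x coefficients).
#' @param contrast numeric contrast vector over the design columns; default
#'   picks the last column (e.g. a group indicator).
#' @param prior_df optional override for d0: 0 recovers the ordinary
#'   t-statistic, `Inf` (capped at 1e8) fully shrinks every variance to s0^2.
#' @return data.frame of class `de_table` with columns gene, logFC, AveExpr,
#'   s2, df, s2_post, t, p, p_adj_BH, and attributes `d0` and `s02`.
#' @export
fit_moderated <- function(expr, design, contrast = NULL, prior_df = NULL) {
  y <- .expr_values(expr)
  w <- if (inherits(expr, "expression_matrix")) expr$weights else NULL
  design <- as.matrix(design)
  n <- ncol(y)
  p <- ncol(design)
  if (nrow(design) != n) stop("design rows must match samples")
  if (is.null(contrast)) contrast <- c(rep(0, p - 1), 1)
  if (length(contrast) != p) stop("contrast length must match design columns")
  # contrast must be estimable
  if (qr(cbind(t(design), contrast))$rank > qr(t(design))$rank)
    stop("contrast not in the span of the design")

  G <- nrow(y)
  logFC <- s2 <- u <- numeric(G)
  dfree <- numeric(G)
  if (is.null(w)) {
    qr_x <- qr(design)
    if (qr_x$rank < p) stop("design is not full rank")
    xtxi <- chol2inv(qr.R(qr_x))
    beta <- t(qr.coef(qr_x, t(y)))
    res <- y - beta %*% t(design)
    dfree[] <- n - p
    if (any(dfree < 1)) stop("residual df < 1")
    s2 <- rowSums(res^2) / dfree
    logFC <- as.numeric(beta %*% contrast)
    u[] <- drop(t(contrast) %*% xtxi %*% contrast)
  } else {
    for (g in seq_len(G)) {
      wg <- w[g, ]
      use <- wg > 0
      xg <- design[use, , drop = FALSE] * sqrt(wg[use])
      yg <- y[g, use] * sqrt(wg[use])
      qr_g <- qr(xg)
      if (qr_g$rank < p) stop("weighted design rank-deficient for gene ", g)
      beta <- qr.coef(qr_g, yg)
      res <- yg - xg %*% beta
      dfree[g] <- sum(use) - p
      if (dfree[g] < 1) stop("residual df < 1 for gene ", g)
      s2[g] <- sum(res^2) / dfree[g]
      logFC[g] <- sum(beta * contrast)
      u[g] <- drop(t(contrast) %*% chol2inv(qr.R(qr_g)) %*% contrast)
    }
  }

  eb <- if (is.null(prior_df)) .fit_f_dist(s2, dfree) else {
    d0 <- min(prior_df, 1e8)
    s02 <- if (d0 > 0) .fit_f_dist(s2, dfree)$s02 else mean(s2)
    list(d0 = d0, s02 = s02)
  }
  d0 <- eb$d0
  s02 <- eb$s02
  s2_post <- if (is.infinite(d0)) rep(s02, G) else
    (d0 * s02 + dfree * s2) / (d0 + dfree)
  tstat <- logFC / sqrt(u * s2_post)
  df_total <- pmin(d0 + dfree, 1e8)
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(gene = rownames(y) %||% as.character(seq_len(G)),
                    logFC = logFC, AveExpr = rowMeans(y),
                    s2 = s2, df = dfree, s2_post = s2_post,
                    t = tstat, p = pval,
                    p_adj_BH = stats::p.adjust(pval, "BH"),
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  class(out) <- c("de_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.de_table <- function(x, ...) {
  cat("Moderated-t DE table:", nrow(x), "genes; prior df d0 =",
      format(attr(x, "d0"), digits = 4), "; prior variance s0^2 =",
      format(attr(x, "s02"), digits = 4), "\n")
  print.data.frame(utils::head(x[order(x$p), ], 6))
  invisible(x)
}

# Moment-matching fit of a scaled F distribution to gene-wise variances:
# log(s2) ~ log(s0^2) + log F(df, d0). Mean and variance of log F involve
# digamma/trigamma; d0 solves trigamma(d0/2) = var(log s2) - trigamma(df/2).
.fit_f_dist <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  dfo <- if (length(df) == 1) rep(df, sum(ok)) else df[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(dfo / 2))
  if (is.na(evar) || evar <= 0) return(list(d0 = Inf, s02 = exp(emean)))
  d0 <- 2 * .trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton solve of trigamma(y) = x; trigamma is convex decreasing on (0, Inf)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Extract a DEG set from a DE table
#'
#' Genes with nominal p below `alpha`, optionally restricted by fold-change
#' direction.
#'
#' @param table a `de_table` from [fit_moderated()].
#' @param alpha nominal p-value cutoff (the design uses unadjusted p).
#' @param direction "both", "up" (logFC > 0) or "down" (logFC < 0).
#' @return a [gene_set()].
#' @export
deg_set <- function(table, alpha = 0.05, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(alpha > 0, alpha < 1)
  keep <- table$p < alpha
  if (direction == "up") keep <- keep & table$logFC > 0
  if (direction == "down") keep <- keep & table$logFC < 0
  gene_set(paste0("DEG_", direction), table$gene[keep], direction = direction)
}

#' Construct a gene set
#'
#' @param name set name.
#' @param genes character vector of gene ids (deduplicated).
#' @param direction optional regulation direction tag ("up", "down", "both").
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes, direction = NULL) {
  structure(list(name = name, genes = unique(as.character(genes)),
                 direction = direction), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$genes), " genes",
      if (!is.null(x$direction)) paste0(" (", x$direction, ")"), "\n",
      sep = "")
  invisible(x)
}

#' Hypergeometric test for DEG-set overlap between tissues
#'
#' Upper-tail probability of observing at least the given overlap between
#' two gene sets drawn from a shared universe.
#'
#' @param setA,setB [gene_set()] objects (must be subsets of `universe`).
#' @param universe [gene_set()] or character vector of the shared universe.
#' @return list with `overlap` and one-sided hypergeometric `p`.
#' @export
deg_overlap_test <- function(setA, setB, universe) {
  uni <- if (inherits(universe, "gene_set")) universe$genes else universe
  if (!all(setA$genes %in% uni) || !all(setB$genes %in% uni))
    stop("sets must be subsets of the universe")
  ov <- length(intersect(setA$genes, setB$genes))
  list(overlap = ov,
       p = hypergeometric_tail(ov, length(setA$genes), length(setB$genes),
                               length(uni)))
}
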