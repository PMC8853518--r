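#' Construct a count matrix container
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @return object of class `count_matrix` with fields `genes`, `samples`,
#'   `counts` and `lib_size` (column sums).
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("negative counts")
  if (any(counts != round(counts))) stop("non-integer counts")
  storage.mode(counts) <- "double"  # avoid integer overflow in sums
  structure(list(genes = rownames(counts), samples = colnames(counts),
                 counts = counts, lib_size = colSums(counts)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", length(x$genes), "genes x", length(x$samples),
      "samples; median library size", format(stats::median(x$lib_size)), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a gene-by-sample counts TSV
#'
#' Expects a header row; the first column holds gene ids and the remaining
#' columns integer counts, one column per sample.
#'
#' @param path TSV file path.
#' @return a [count_matrix].
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c("character"), header = TRUE)
  if (ncol(df) < 2) stop("counts file needs a gene column and >= 1 sample")
  if (anyDuplicated(df[[1]]))
    stop("duplicated gene id in ", path, ": ",
         df[[1]][duplicated(df[[1]])][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = dimnames(m)))
  bad <- which(is.na(num) | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 df[[1]][bad[1, 1]], colnames(m)[bad[1, 2]]))
  rownames(num) <- df[[1]]
  count_matrix(num)
}

#' Read a sample metadata TSV
#'
#' Columns: sample_id, subject_id, tissue, sex, group, consumption,
#' preference. One row per sample; (subject_id, tissue) must be unique.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "tissue", "sex", "group")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(md[c("subject_id", "tissue")]))
    stop("duplicate (subject_id, tissue) in metadata")
  md
}

#' Construct an expression matrix container
#'
#' @param values real matrix (genes x samples), typically log2-CPM.
#' @param weights optional positive precision weight matrix, same shape.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, weights = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!identical(dim(weights), dim(values)))
      stop("weights must match value dimensions")
    if (any(weights <= 0)) stop("weights must be strictly positive")
  }
  structure(list(genes = rownames(values), samples = colnames(values),
                 values = values, weights = weights),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples", if (!is.null(x$weights)) "(with precision weights)", "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# accept either an expression_matrix or a bare numeric matrix
.expr_values <- function(x) {
  if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
}

#' Log2 counts-per-million normalization
#'
#' `log2((count + prior) / (library_size + 2 * prior) * 1e6)`. The default
#' prior of 0.5 gives the usual half-count offset with library size + 1 in
#' the denominator, so values match the voom-style log-CPM exactly.
#'
#' @param counts a [count_matrix].
#' @param prior prior count, > 0.
#' @return an [expression_matrix] (no weights).
#' @export
logcpm <- function(counts, prior = 0.5) {
  stopifnot(inherits(counts, "count_matrix"))
  if (prior <= 0) stop("prior must be > 0")
  if (any(counts$lib_size <= 0)) stop("library sizes must be > 0")
  v <- log2(sweep(counts$counts + prior, 2, counts$lib_size + 2 * prior,
                  "/") * 1e6)
  expression_matrix(v)
}

#' Log-CPM with voom-style precision weights
#'
#' Computes log2-CPM as in [logcpm()] and per-observation precision weights
#' from the empirical mean-variance trend: a linear model is fitted per gene
#' under `design`, the square-root residual standard deviations are smoothed
#' (lowess, span `span`) against average log2 count, and each observation's
#' weight is the inverse of the predicted variance at its fitted log-count.
#' This downweights low-count observations, whose log-CPM is noisier.
#'
#' @param counts a [count_matrix].
#' @param design design matrix (samples x coefficients), full rank.
#' @param span lowess span for the mean-variance trend.
#' @param prior prior count for the log-CPM values.
#' @return an [expression_matrix] carrying strictly positive weights.
#' @export
voom_weights <- function(counts, design, span = 0.5, prior = 0.5) {
  stopifnot(inherits(counts, "count_matrix"))
  design <- as.matrix(design)
  n <- ncol(counts$counts)
  if (nrow(design) != n) stop("design rows must match samples")
  if (n < ncol(design)) stop("fewer samples than design columns")
  if (qr(design)$rank < ncol(design)) stop("design is not full rank")
  if (n - ncol(design) < 2) stop("need >= 2 residual degrees of freedom")
  e <- logcpm(counts, prior = prior)
  y <- e$values
  fit <- stats::lm.fit(design, t(y))
  fitted <- t(design %*% fit$coefficients)
  res <- y - fitted
  sdev <- sqrt(rowSums(res^2) / (n - ncol(design)))
  # mean-variance trend on the log2-count scale
  mean_logcount <- rowMeans(y) + mean(log2(counts$lib_size + 1)) - log2(1e6)
  ok <- is.finite(sdev) & sdev > 0
  lo <- stats::lowess(mean_logcount[ok], sqrt(sdev[ok]), f = span)
  trend <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  fitted_logcount <- fitted +
    matrix(log2(counts$lib_size + 1), nrow(y), n, byrow = TRUE) - log2(1e6)
  w <- 1 / pmax(trend(fitted_logcount), 1e-6)^4
  dim(w) <- dim(y)
  dimnames(w) <- dimnames(y)
  expression_matrix(y, weights = w)
}
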