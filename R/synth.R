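#' Configure a synthetic multi-tissue CIE study
#'
#' Builds a validated configuration for [generate_study()]. The generator
#' emulates a chronic-intermittent-ethanol (CIE) vs air-control design: the
#' same subjects are profiled in every tissue, genes belonging to a planted
#' coexpression module share a per-subject latent factor (the future module
#' eigengene), planted differentially expressed genes (DEGs) have their CIE
#' group mean shifted on the log2 scale, and counts are drawn from a
#' negative-binomial (gamma-Poisson) model with per-sample library sizes.
#'
#' @param n_subjects_per_group subjects per group (CIE and Air each), per sex
#'   if `sexes` has two levels the subjects are split as evenly as possible.
#' @param tissues character vector of tissue names (default the four tissues
#'   of the design: blood, prefrontal cortex, amygdala, hypothalamus).
#' @param n_genes total genes per tissue.
#' @param module_specs list of module descriptions, each a list with elements
#'   `id` (character), `size` (>= 3 genes), `tissues` (subset of `tissues`),
#'   `strength` (target mean within-module Pearson correlation, in \[0,1\]),
#'   `trait_cor` (planted eigengene-consumption correlation, in \[-1,1\]),
#'   and optional `signs` (named +1/-1 per tissue, flips the shared factor to
#'   emulate opposite regulation directions across tissues).
#' @param deg_specs list of DEG descriptions, each a list with `tissue`,
#'   `n_genes`, `lfc` (log2 fold-change CIE vs Air, > 0) and `direction`
#'   ("up" or "down").
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param baseline_logmean_range range (log2 scale) for baseline relative
#'   expression of genes.
#' @param library_size_range range of per-sample library sizes; sizes are
#'   drawn log-uniformly so CPM normalization is genuinely exercised.
#' @param group_consumption_means mean ethanol consumption (g/kg) for the
#'   Air and CIE groups; the CIE shift is what makes group, consumption and
#'   preference mutually informative, as in the vapor-exposure paradigm.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return an object of class `synth_config`.
#' @seealso [generate_study()], [write_fixtures()]
#' @export
synth_config <- function(n_subjects_per_group = 10,
                         tissues = c("BLD", "PFC", "AMY", "HYP"),
                         n_genes = 1000,
                         module_specs = list(),
                         deg_specs = list(),
                         nb_dispersion = 0.05,
                         baseline_logmean_range = c(3, 9),
                         library_size_range = c(5e5, 2e6),
                         group_consumption_means = c(Air = 8, CIE = 12),
                         seed = 1L) {
  stopifnot(n_subjects_per_group >= 2, n_genes >= 1,
            length(tissues) >= 1, !anyDuplicated(tissues))
  if (nb_dispersion <= 0 || !is.finite(nb_dispersion))
    stop("nb_dispersion must be a positive real")
  if (length(baseline_logmean_range) != 2 || diff(baseline_logmean_range) < 0)
    stop("baseline_logmean_range must be an increasing pair")
  if (length(library_size_range) != 2 || any(library_size_range < 1))
    stop("library_size_range must be a pair of positive counts")
  total <- 0
  for (m in module_specs) {
    if (is.null(m$id) || is.null(m$size) || is.null(m$tissues) ||
        is.null(m$strength))
      stop("each module spec needs id, size, tissues, strength")
    if (m$size < 3)
      stop("module size < 3: eigengene undefined, rejected")
    if (!all(m$tissues %in% tissues))
      stop("module spec references unknown tissue")
    if (is.na(m$strength) || m$strength < 0 || m$strength > 1)
      stop("module correlation strength must be in [0,1] and not NaN")
    tc <- if (is.null(m$trait_cor)) 0 else m$trait_cor
    if (is.na(tc) || abs(tc) > 1)
      stop("trait_cor must be in [-1,1]")
    total <- total + m$size
  }
  if (total > n_genes)
    stop("module sizes sum to more than n_genes")
  for (d in deg_specs) {
    if (is.null(d$tissue) || is.null(d$n_genes) || is.null(d$lfc))
      stop("each DEG spec needs tissue, n_genes, lfc")
    if (!d$tissue %in% tissues) stop("DEG spec references unknown tissue")
    if (is.na(d$lfc) || !is.finite(d$lfc))
      stop("log2 fold-change must be finite and not NaN")
  }
  structure(list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    tissues = tissues, n_genes = as.integer(n_genes),
    module_specs = module_specs, deg_specs = deg_specs,
    nb_dispersion = nb_dispersion,
    baseline_logmean_range = baseline_logmean_range,
    library_size_range = library_size_range,
    group_consumption_means = group_consumption_means,
    seed = as.integer(seed)), class = "synth_config")
}

#' Generate a synthetic multi-tissue study with known ground truth
#'
#' Simulates one study per the configuration: per-subject latent module
#' factors shared across tissues (optionally sign-flipped per tissue),
#' planted group effects for DEGs, traits (consumption, preference) tied to
#' group and to selected module factors, and negative-binomial counts.
#'
#' The expression model on the log2 scale is
#' `x = mu_g + a * f_m + sigma0 * eps` for a gene in module m, where `f_m` is
#' the subject's latent factor and `a = sigma0 * sqrt(r / (1 - r))` so the
#' expected pairwise within-module correlation equals the configured
#' strength r. A module with planted trait correlation rho draws its factor
#' as `rho * z_consumption + sqrt(1 - rho^2) * noise`.
#'
#' @param config a [synth_config()] object.
#' @return a list of class `synth_study` with elements `counts` (named list
#'   of per-tissue [count_matrix] objects), `metadata` (data.frame, one row
#'   per sample), and `truth` (ground truth: per-tissue gene -> module map,
#'   per-tissue DEG tables, per-subject traits and latent factors).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_sub <- 2L * config$n_subjects_per_group
  subjects <- sprintf("S%02d", seq_len(n_sub))
  group <- rep(c("Air", "CIE"), each = config$n_subjects_per_group)
  sex <- rep_len(c("M", "F"), n_sub)

  # traits: consumption shifted by group; preference correlated with it
  mu_c <- config$group_consumption_means[group]
  consumption <- stats::rnorm(n_sub, mean = mu_c, sd = 2)
  z_c <- as.numeric(scale(consumption))
  preference <- pmin(1, pmax(0, 0.5 + 0.08 * z_c + stats::rnorm(n_sub, 0, 0.08)))

  genes <- sprintf("G%05d", seq_len(config$n_genes))
  base_mu <- stats::runif(config$n_genes,
                          config$baseline_logmean_range[1],
                          config$baseline_logmean_range[2])
  names(base_mu) <- genes

  # assign module gene blocks once (shared identity across tissues)
  free <- seq_len(config$n_genes)
  module_genes <- list()
  factors <- matrix(0, n_sub, length(config$module_specs),
                    dimnames = list(subjects, vapply(config$module_specs,
                                                     `[[`, "", "id")))
  for (i in seq_along(config$module_specs)) {
    m <- config$module_specs[[i]]
    idx <- free[seq_len(m$size)]
    free <- setdiff(free, idx)
    module_genes[[m$id]] <- genes[idx]
    rho <- if (is.null(m$trait_cor)) 0 else m$trait_cor
    # orthogonalize the noise against the trait so the sample correlation
    # of factor and consumption equals rho exactly, not just in expectation
    eps <- stats::rnorm(n_sub)
    eps <- stats::residuals(stats::lm(eps ~ z_c))
    eps <- as.numeric(scale(eps))
    factors[, i] <- rho * z_c + sqrt(max(0, 1 - rho^2)) * eps
  }

  # choose planted DEGs per tissue among genes outside modules
  deg_truth <- list()
  deg_pool <- free
  for (d in config$deg_specs) {
    if (length(deg_pool) < d$n_genes)
      stop("not enough non-module genes left for DEG spec")
    idx <- deg_pool[seq_len(d$n_genes)]
    deg_pool <- setdiff(deg_pool, idx)
    sgn <- if (identical(d$direction, "down")) -1 else 1
    deg_truth[[length(deg_truth) + 1L]] <- data.frame(
      tissue = d$tissue, gene = genes[idx],
      lfc = sgn * abs(d$lfc), stringsAsFactors = FALSE)
  }
  deg_truth <- if (length(deg_truth)) do.call(rbind, deg_truth) else
    data.frame(tissue = character(), gene = character(), lfc = numeric())

  sigma0 <- 0.5   # per-gene log2-scale noise sd
  counts <- list()
  module_map <- list()
  for (tt in config$tissues) {
    x <- matrix(stats::rnorm(config$n_genes * n_sub, sd = sigma0),
                config$n_genes, n_sub, dimnames = list(genes, NULL))
    x <- x + base_mu
    map <- setNames(rep("0", config$n_genes), genes)
    for (i in seq_along(config$module_specs)) {
      m <- config$module_specs[[i]]
      if (!tt %in% m$tissues) next
      sgn <- 1
      if (!is.null(m$signs) && !is.null(m$signs[[tt]])) sgn <- m$signs[[tt]]
      r <- m$strength
      a <- sigma0 * sqrt(r / max(1 - r, 1e-8))
      gm <- module_genes[[m$id]]
      x[gm, ] <- x[gm, ] + rep(sgn * a * factors[, i], each = length(gm))
      map[gm] <- m$id
    }
    dt <- deg_truth[deg_truth$tissue == tt, , drop = FALSE]
    if (nrow(dt)) {
      cie <- group == "CIE"
      x[dt$gene, cie] <- x[dt$gene, cie] + dt$lfc
    }
    rel <- 2^x
    prop <- sweep(rel, 2, colSums(rel), "/")
    lib <- exp(stats::runif(n_sub, log(config$library_size_range[1]),
                            log(config$library_size_range[2])))
    mu <- sweep(prop, 2, lib, "*")
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / config$nb_dispersion),
                  nrow(mu), ncol(mu),
                  dimnames = list(genes, paste0(subjects, "_", tt)))
    counts[[tt]] <- count_matrix(cnt)
    module_map[[tt]] <- map
  }

  metadata <- do.call(rbind, lapply(config$tissues, function(tt) data.frame(
    sample_id = paste0(subjects, "_", tt), subject_id = subjects,
    tissue = tt, sex = sex, group = group,
    consumption = consumption, preference = preference,
    stringsAsFactors = FALSE)))
  rownames(metadata) <- NULL

  truth <- list(
    module_genes = module_genes, module_map = module_map,
    degs = deg_truth,
    traits = data.frame(subject_id = subjects, group = group, sex = sex,
                        consumption = consumption, preference = preference,
                        stringsAsFactors = FALSE),
    factors = factors)
  stopifnot(all(is.finite(consumption)), all(is.finite(preference)))
  structure(list(counts = counts, metadata = metadata, truth = truth,
                 config = config), class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat("Synthetic CIE study:", length(x$counts), "tissue(s),",
      x$config$n_genes, "genes,",
      2 * x$config$n_subjects_per_group, "subjects\n")
  cat("  planted modules:", length(x$truth$module_genes),
      "| planted DEGs:", nrow(x$truth$degs), "\n")
  invisible(x)
}

#' Write a synthetic study to disk as plain-text fixtures
#'
#' Writes one counts TSV per tissue, one metadata TSV, one GMT file of the
#' planted module gene sets, and one JSON ground-truth file. Re-reading the
#' counts with [read_counts()] reproduces the in-memory matrices.
#'
#' @param study a `synth_study` from [generate_study()].
#' @param dir output directory (created if absent).
#' @param overwrite overwrite existing files? Default FALSE: collision is an
#'   error.
#' @return named character vector of the files written, invisibly.
#' @export
write_fixtures <- function(study, dir, overwrite = FALSE) {
  stopifnot(inherits(study, "synth_study"))
  if (length(study$counts) == 0) stop("study has no tissues")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    setNames(file.path(dir, paste0("counts_", names(study$counts), ".tsv")),
             paste0("counts_", names(study$counts))),
    metadata = file.path(dir, "metadata.tsv"),
    modules = file.path(dir, "planted_modules.gmt"),
    truth = file.path(dir, "ground_truth.json"))
  if (!overwrite && any(file.exists(paths)))
    stop("fixture files already exist in ", dir, " (use overwrite = TRUE)")
  for (tt in names(study$counts)) {
    cm <- study$counts[[tt]]
    df <- data.frame(gene = cm$genes, cm$counts, check.names = FALSE)
    utils::write.table(df, paths[[paste0("counts_", tt)]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(study$metadata, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(study$truth$module_genes, paths[["modules"]],
            description = "planted module")
  jsonlite::write_json(list(
    module_genes = study$truth$module_genes,
    degs = study$truth$degs,
    traits = study$truth$traits), paths[["truth"]],
    auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
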