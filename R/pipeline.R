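#' Assemble and validate a pipeline configuration
#'
#' Accepts a YAML file path or a list. Required fields: `counts` (named map
#' tissue -> counts TSV path), `metadata` (TSV path), `out_dir`. Optional:
#' `sexes` (default both), `blood_tissue` ("BLD"), `de_alpha` (0.05),
#' `edge_alpha` (0.05), `seed` (1), `network` (arguments for
#' [network_params()], optionally with a `beta` map per tissue), and
#' `classifier` (arguments for [run_classification()]).
#'
#' @param config list or YAML path.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (f in c("counts", "metadata", "out_dir"))
    if (is.null(config[[f]])) stop("config missing field: ", f)
  if (is.null(names(config$counts)) || any(!nzchar(names(config$counts))))
    stop("config$counts must be a named tissue -> path map")
  missing <- !vapply(unlist(config$counts), file.exists, TRUE)
  if (any(missing))
    stop("counts file(s) not found: ",
         paste(unlist(config$counts)[missing], collapse = ", "))
  if (!file.exists(config$metadata))
    stop("metadata file not found: ", config$metadata)
  defaults <- list(sexes = c("M", "F"), blood_tissue = "BLD",
                   de_alpha = 0.05, edge_alpha = 0.05, seed = 1L,
                   network = list(), classifier = list())
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  class(config) <- c("pipeline_config", "list")
  config
}

#' Run the full cross-tissue analysis pipeline
#'
#' Per sex: differential expression per tissue (voom weights + moderated t),
#' signed coexpression network per tissue, CIE-module selection (DEG
#' enrichment or eigengene-trait correlation), cross-tissue module-overlap
#' meta-network with blood-brain cluster calling, between-/within-subject
#' blood-brain correlations, and blood-based classifiers. All outputs are
#' written under `out_dir` with a manifest (inputs, parameters, seed, file
#' checksums); identical config + seed reproduces identical tables.
#'
#' @param config a [pipeline_config()] (list or YAML path accepted).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  tissues <- names(cfg$counts)
  counts_all <- lapply(cfg$counts, read_counts)
  metadata <- read_metadata(cfg$metadata)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
    path
  }
  np_args <- cfg$network
  beta_map <- np_args$beta
  np_args$beta <- NULL

  for (sx in cfg$sexes) {
    md_sx <- metadata[metadata$sex == sx, , drop = FALSE]
    if (!nrow(md_sx)) next
    stage <- function(label, expr) {
      tryCatch(expr, error = function(e)
        stop("pipeline stage '", label, "' (sex ", sx, ") failed: ",
             conditionMessage(e), call. = FALSE))
    }
    nets <- list(); degs <- list(); cie <- list(); enr <- list()
    expr_sx <- list()
    for (tt in tissues) {
      samp <- md_sx$sample_id[md_sx$tissue == tt]
      cm <- counts_all[[tt]]
      keep <- cm$samples %in% samp
      if (sum(keep) < 4) next
      cm_sx <- count_matrix(cm$counts[, keep, drop = FALSE])
      md_t <- md_sx[match(cm_sx$samples, md_sx$sample_id), ]
      design <- stats::model.matrix(~group, data = md_t)

      stage(paste0("de_", tt), {
        ve <- voom_weights(cm_sx, design)
        de <- fit_moderated(ve, design)
        emit(de[c("gene", "logFC", "t", "p", "p_adj_BH", "s2_post")],
             sprintf("de_%s_%s.tsv", sx, tt))
        degs[[tt]] <- list(up = deg_set(de, cfg$de_alpha, "up"),
                            down = deg_set(de, cfg$de_alpha, "down"))
      })
      stage(paste0("network_", tt), {
        expr <- logcpm(cm_sx)
        expr_sx[[tt]] <- expr
        params <- do.call(network_params, c(
          np_args, if (!is.null(beta_map[[tt]])) list(beta = beta_map[[tt]])))
        net <- coexpression_network(expr, params)
        nets[[tt]] <- net
        emit(data.frame(gene = names(net$assignment$labels),
                        module = net$assignment$labels),
             sprintf("modules_%s_%s.tsv", sx, tt))
        if (!is.null(net$eigengenes))
          emit(data.frame(sample = rownames(net$eigengenes),
                          net$eigengenes, check.names = FALSE),
               sprintf("eigengenes_%s_%s.tsv", sx, tt))
      })
      stage(paste0("cie_modules_", tt), {
        net <- nets[[tt]]
        if (length(net$assignment$sizes)) {
          en <- module_deg_enrichment(net$assignment, degs[[tt]])
          as <- eigengene_trait_association(net$eigengenes, md_sx)
          enr[[tt]] <- en
          cie[[tt]] <- select_cie_modules(en, as, cfg$de_alpha)
          emit(en, sprintf("module_deg_enrichment_%s_%s.tsv", sx, tt))
          emit(as, sprintf("module_trait_association_%s_%s.tsv", sx, tt))
        } else cie[[tt]] <- data.frame(module = character(0))
      })
    }
    done <- names(nets)
    stage("meta_network", {
      overlaps <- list()
      if (length(done) >= 2) {
        pairs <- utils::combn(done, 2, simplify = FALSE)
        for (pr in pairs)
          overlaps[[paste(pr, collapse = "|")]] <-
            cross_tissue_overlap(nets[[pr[1]]]$assignment,
                                 nets[[pr[2]]]$assignment)
      }
      mn <- build_meta_network(overlaps, cie[done], enrichment = enr,
                               edge_alpha = cfg$edge_alpha,
                               blood_tissue = cfg$blood_tissue)
      sif <- file.path(cfg$out_dir, sprintf("meta_network_%s.sif", sx))
      gml <- file.path(cfg$out_dir, sprintf("meta_network_%s.graphml", sx))
      export_meta_network(mn, sif, gml)
      files <- c(files, sif)
      emit(mn$clusters %||% data.frame(), sprintf("meta_clusters_%s.tsv", sx))
    })
    stage("blood_brain_correlation", {
      bld <- cfg$blood_tissue
      if (!is.null(expr_sx[[bld]])) {
        for (tt in setdiff(done, bld)) {
          bt <- between_subject_correlation(expr_sx[[bld]], expr_sx[[tt]])
          emit(data.frame(tissueA = bld, tissueB = tt, rho = bt$rho,
                          p = bt$p, n_genes = bt$n_genes),
               sprintf("between_subject_%s_%s.tsv", sx, tt))
          ws <- within_subject_correlation(expr_sx[[bld]], expr_sx[[tt]],
                                           md_sx)
          emit(ws, sprintf("within_subject_%s_%s.tsv", sx, tt))
        }
      }
    })
    stage("classification", {
      bld <- cfg$blood_tissue
      samp <- md_sx$sample_id[md_sx$tissue == bld]
      cm <- counts_all[[bld]]
      keep <- cm$samples %in% samp
      if (sum(keep) >= 10) {
        cm_sx <- count_matrix(cm$counts[, keep, drop = FALSE])
        args <- c(list(counts = cm_sx, metadata = md_sx,
                       seed = cfg$seed), cfg$classifier)
        reports <- do.call(run_classification, args)
        met <- do.call(rbind, lapply(reports, function(r)
          data.frame(model = r$model, t(r$metrics))))
        emit(met, sprintf("classifier_metrics_%s.tsv", sx))
        for (r in reports) {
          emit(r$roc, sprintf("roc_%s_%s.tsv", sx, r$model))
          emit(utils::head(r$importance, 50),
               sprintf("importance_%s_%s.tsv", sx, r$model))
        }
        hp <- file.path(cfg$out_dir,
                        sprintf("hyperparameters_%s.json", sx))
        jsonlite::write_json(lapply(reports, `[[`, "hyperparameters"),
                             hp, auto_unbox = TRUE, digits = NA)
        files <- c(files, hp)
      }
    })
  }
  manifest <- list(
    inputs = c(unlist(cfg$counts), metadata = cfg$metadata),
    seed = cfg$seed,
    parameters = cfg[c("sexes", "blood_tissue", "de_alpha", "edge_alpha",
                       "network", "classifier")],
    outputs = as.list(tools::md5sum(sort(unique(files)))),
    package_version = as.character(utils::packageVersion("bloodbrain")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a study and write its fixtures
#'
#' Convenience wrapper used by the command-line interface: builds a
#' [synth_config()] (optionally from a YAML file of arguments), generates
#' the study and writes the plain-text fixtures.
#'
#' @param config NULL (defaults), a YAML path, or a list of
#'   [synth_config()] arguments.
#' @param seed overrides the config seed when not NULL.
#' @param out_dir output directory.
#' @param overwrite passed to [write_fixtures()].
#' @return the written file paths, invisibly.
#' @export
simulate_study <- function(config = NULL, seed = NULL, out_dir = "fixtures",
                           overwrite = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.null(seed)) config$seed <- seed
  cfg <- do.call(synth_config, config)
  study <- generate_study(cfg)
  write_fixtures(study, out_dir, overwrite = overwrite)
}
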