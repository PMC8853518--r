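#' One-sided hypergeometric tail probability
#'
#' Probability of drawing at least `overlap` elements of a size-`sizeA`
#' subset when sampling `sizeB` elements without replacement from a universe
#' of size `universe`. Evaluated in log space via [stats::phyper()].
#'
#' @param overlap observed overlap (>= 0).
#' @param sizeA,sizeB set sizes.
#' @param universe universe size.
#' @return the upper-tail probability P(X >= overlap).
#' @export
hypergeometric_tail <- function(overlap, sizeA, sizeB, universe) {
  if (overlap < 0 || sizeA > universe || sizeB > universe ||
      overlap > min(sizeA, sizeB))
    stop("impossible hypergeometric configuration")
  if (overlap == 0) return(1)
  exp(stats::phyper(overlap - 1, sizeA, universe - sizeA, sizeB,
                    lower.tail = FALSE, log.p = TRUE))
}

#' DEG enrichment per module
#'
#' For every module, tests whether it contains more DEGs than expected by
#' chance (one-sided hypergeometric test against the network's gene
#' universe). Enrichment is also computed separately for up- and
#' down-regulated DEGs, and a regulation direction is assigned from the more
#' significant of the two, with a strength category mirroring the meta-network
#' color scale (strong: p < 1e-5; weak: p < 0.05; ns otherwise).
#'
#' @param assignment `module_assignment` or named label vector.
#' @param degs a [gene_set()] of all DEGs, or a list with elements `up`,
#'   `down` (gene_sets); when a single set is given the direction split is
#'   skipped.
#' @param universe character vector of the network's genes (defaults to the
#'   assignment's genes).
#' @return data.frame: module, size, overlap, p, p_up, p_down, direction,
#'   strength.
#' @export
module_deg_enrichment <- function(assignment, degs, universe = NULL) {
  labels <- if (inherits(assignment, "module_assignment"))
    assignment$labels else assignment
  if (is.null(universe)) universe <- names(labels)
  split_dir <- is.list(degs) && !inherits(degs, "gene_set")
  all_degs <- if (split_dir)
    unique(c(degs$up$genes, degs$down$genes)) else degs$genes
  if (!all(all_degs %in% universe))
    stop("DEGs must be a subset of the universe")
  mods <- setdiff(unique(labels), "0")
  if (!length(mods))
    return(data.frame(module = character(), size = integer(),
                      overlap = integer(), p = numeric(),
                      p_up = numeric(), p_down = numeric(),
                      direction = character(), strength = character()))
  N <- length(universe)
  out <- lapply(mods, function(m) {
    g <- names(labels)[labels == m]
    ov <- length(intersect(g, all_degs))
    p <- hypergeometric_tail(ov, length(g), length(all_degs), N)
    p_up <- p_down <- NA_real_
    if (split_dir) {
      p_up <- hypergeometric_tail(length(intersect(g, degs$up$genes)),
                                  length(g), length(degs$up$genes), N)
      p_down <- hypergeometric_tail(length(intersect(g, degs$down$genes)),
                                    length(g), length(degs$down$genes), N)
    }
    direction <- if (!split_dir || (is.na(p_up) && is.na(p_down))) "none"
      else if (min(p_up, p_down) >= 0.05) "none"
      else if (p_up <= p_down) "up" else "down"
    pbest <- if (split_dir) min(p, p_up, p_down, na.rm = TRUE) else p
    strength <- if (pbest < 1e-5) "strong" else if (pbest < 0.05) "weak"
      else "ns"
    data.frame(module = m, size = length(g), overlap = ov, p = p,
               p_up = p_up, p_down = p_down, direction = direction,
               strength = strength, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Eigengene-trait association
#'
#' Pearson correlation of each module eigengene with each trait, with the
#' two-sided p-value from the t-distribution on n - 2 df. The group label is
#' coded 0/1 (reference = first level alphabetically unless a factor).
#'
#' @param eigengenes samples x modules matrix (rownames = sample ids).
#' @param metadata data.frame with sample_id and trait columns.
#' @param traits trait column names to test.
#' @return data.frame: module, trait, r, p, n (constant traits are flagged
#'   with NA and excluded from testing).
#' @export
eigengene_trait_association <- function(eigengenes, metadata,
                                        traits = c("group", "consumption",
                                                   "preference")) {
  md <- metadata[match(rownames(eigengenes), metadata$sample_id), ,
                 drop = FALSE]
  if (anyNA(md$sample_id)) stop("eigengene samples missing from metadata")
  out <- list()
  for (tr in traits) {
    v <- md[[tr]]
    if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
    n <- sum(!is.na(v))
    constant <- stats::sd(v, na.rm = TRUE) == 0 || n < 3
    for (m in colnames(eigengenes)) {
      if (constant) {
        out[[length(out) + 1L]] <- data.frame(module = m, trait = tr,
                                              r = NA_real_, p = NA_real_,
                                              n = n)
        next
      }
      r <- stats::cor(eigengenes[, m], v, use = "complete.obs")
      tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-15))
      out[[length(out) + 1L]] <- data.frame(
        module = m, trait = tr, r = r,
        p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
    }
  }
  do.call(rbind, out)
}

#' Select CIE-related modules
#'
#' A module is CIE-related if it is enriched with DEGs (criterion 1) or its
#' eigengene correlates with dependence status, consumption or preference
#' (criterion 2); the union is returned with the triggering criterion.
#'
#' @param enrichment output of [module_deg_enrichment()].
#' @param association output of [eigengene_trait_association()].
#' @param alpha significance level for both criteria.
#' @return data.frame: module, by_deg, by_trait, criterion.
#' @export
select_cie_modules <- function(enrichment, association, alpha = 0.05) {
  mods <- union(enrichment$module, association$module)
  by_deg <- vapply(mods, function(m) {
    rows <- enrichment[enrichment$module == m, , drop = FALSE]
    nrow(rows) > 0 && any(stats::na.omit(unlist(
      rows[c("p", "p_up", "p_down")])) < alpha)
  }, logical(1))
  by_trait <- vapply(mods, function(m) {
    p <- association$p[association$module == m]
    any(!is.na(p) & p < alpha)
  }, logical(1))
  keep <- by_deg | by_trait
  data.frame(module = mods[keep], by_deg = by_deg[keep],
             by_trait = by_trait[keep],
             criterion = ifelse(by_deg[keep] & by_trait[keep], "both",
                                ifelse(by_deg[keep], "deg", "trait")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read / write GMT gene-set collections
#'
#' Standard GMT: one set per line, tab-separated — name, description, then
#' gene ids.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors.
#' @param description description field written for every set.
#' @export
write_gmt <- function(sets, path, description = "") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set over-representation analysis
#'
#' One-sided hypergeometric test of each query set against each collection
#' set, restricted to the expressed-gene universe, with Bonferroni
#' correction over all (query, set) tests.
#'
#' @param queries a [gene_set()] or list of gene_sets (e.g. up/down DEG
#'   sets).
#' @param collections named list of gene-id vectors (e.g. from
#'   [read_gmt()]), such as cell-type marker sets.
#' @param universe character vector of expressed genes (the background).
#' @param correction "bonferroni" (default) or any [stats::p.adjust()]
#'   method.
#' @return data.frame: query, set, overlap, query_size, set_size, p, p_adj.
#' @export
gene_set_overrepresentation <- function(queries, collections, universe,
                                        correction = "bonferroni") {
  if (inherits(queries, "gene_set")) queries <- list(queries)
  if (!length(collections)) stop("empty collection")
  N <- length(universe)
  rows <- list()
  for (q in queries) {
    qg <- intersect(q$genes, universe)
    for (nm in names(collections)) {
      sg <- intersect(collections[[nm]], universe)
      if (!length(sg)) {
        warning("set '", nm, "' has no genes in the universe; skipped")
        next
      }
      ov <- length(intersect(qg, sg))
      rows[[length(rows) + 1L]] <- data.frame(
        query = q$name, set = nm, overlap = ov,
        query_size = length(qg), set_size = length(sg),
        p = hypergeometric_tail(ov, length(qg), length(sg), N),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = correction)
  out[order(out$p), ]
}

#' Cross-tissue module overlap tests
#'
#' For every pair of modules (one from each tissue), counts the gene overlap
#' within the shared measured-gene universe (the intersection of the two
#' assignments' genes) and reports the one-sided hypergeometric p.
#' Unassigned genes (label "0") never form a module.
#'
#' @param assignA,assignB `module_assignment` objects (or label vectors).
#' @return data.frame: moduleA, moduleB, sizeA, sizeB, overlap, universe, p.
#' @export
cross_tissue_overlap <- function(assignA, assignB) {
  la <- if (inherits(assignA, "module_assignment")) assignA$labels else assignA
  lb <- if (inherits(assignB, "module_assignment")) assignB$labels else assignB
  shared <- intersect(names(la), names(lb))
  if (!length(shared)) stop("no shared gene universe between assignments")
  la <- la[shared]; lb <- lb[shared]
  N <- length(shared)
  rows <- list()
  for (ma in setdiff(unique(la), "0")) {
    ga <- shared[la == ma]
    for (mb in setdiff(unique(lb), "0")) {
      gb <- shared[lb == mb]
      ov <- length(intersect(ga, gb))
      rows[[length(rows) + 1L]] <- data.frame(
        moduleA = ma, moduleB = mb, sizeA = length(ga), sizeB = length(gb),
        overlap = ov, universe = N,
        p = hypergeometric_tail(ov, length(ga), length(gb), N),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(moduleA = character(), moduleB = character(),
                      sizeA = integer(), sizeB = integer(),
                      overlap = integer(), universe = integer(),
                      p = numeric()))
  do.call(rbind, rows)
}

#' Build the cross-tissue module overlap meta-network
#'
#' Nodes are the CIE-related modules of each tissue; an edge connects two
#' modules of different tissues whose gene overlap is significant at
#' `edge_alpha`, weighted by -log10(p). Connected components containing a
#' blood module with significant edges to modules from at least two distinct
#' brain regions are flagged as blood-brain module clusters.
#'
#' @param overlaps named list of [cross_tissue_overlap()] tables; names are
#'   "tissueA|tissueB".
#' @param cie_modules named list (per tissue) of [select_cie_modules()]
#'   tables, or character vectors of module ids.
#' @param enrichment optional named list (per tissue) of
#'   [module_deg_enrichment()] tables used to annotate node regulation
#'   direction.
#' @param edge_alpha edge significance threshold.
#' @param blood_tissue name of the blood tissue.
#' @return object of class `meta_network`: `nodes`, `edges`, `clusters`
#'   data.frames and the underlying igraph in `graph`.
#' @export
build_meta_network <- function(overlaps, cie_modules, enrichment = NULL,
                               edge_alpha = 0.05, blood_tissue = "BLD") {
  mods_of <- lapply(cie_modules, function(x)
    if (is.data.frame(x)) x$module else as.character(x))
  node_id <- function(tissue, module) paste0(tissue, ":", module)
  nodes <- do.call(rbind, lapply(names(mods_of), function(tt) {
    if (!length(mods_of[[tt]])) return(NULL)
    dir <- rep("none", length(mods_of[[tt]]))
    pdeg <- rep(NA_real_, length(mods_of[[tt]]))
    if (!is.null(enrichment[[tt]])) {
      i <- match(mods_of[[tt]], enrichment[[tt]]$module)
      dir <- ifelse(is.na(i), "none", enrichment[[tt]]$direction[i])
      pdeg <- enrichment[[tt]]$p[i]
    }
    data.frame(id = node_id(tt, mods_of[[tt]]), tissue = tt,
               module = mods_of[[tt]], direction = dir, deg_p = pdeg,
               stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(names(overlaps), function(pair) {
    ts <- strsplit(pair, "|", fixed = TRUE)[[1]]
    if (ts[1] == ts[2]) stop("overlap pair within one tissue: ", pair)
    ov <- overlaps[[pair]]
    keep <- ov$p < edge_alpha &
      ov$moduleA %in% mods_of[[ts[1]]] & ov$moduleB %in% mods_of[[ts[2]]]
    if (!any(keep)) return(NULL)
    ov <- ov[keep, , drop = FALSE]
    data.frame(from = node_id(ts[1], ov$moduleA),
               to = node_id(ts[2], ov$moduleB),
               overlap = ov$overlap, p = ov$p,
               weight = -log10(pmax(ov$p, 1e-300)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(nodes)) nodes <- data.frame(id = character(),
                                          tissue = character(),
                                          module = character(),
                                          direction = character(),
                                          deg_p = numeric())
  if (is.null(edges)) edges <- data.frame(from = character(),
                                          to = character(),
                                          overlap = integer(), p = numeric(),
                                          weight = numeric())
  # canonical ordering: edge set invariant to tissue processing order
  if (nrow(edges)) {
    flip <- edges$from > edges$to
    tmp <- edges$from[flip]; edges$from[flip] <- edges$to[flip]
    edges$to[flip] <- tmp
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)
  brain_tissues <- setdiff(unique(nodes$tissue), blood_tissue)
  clusters <- lapply(seq_len(comp$no), function(ci) {
    ids <- names(comp$membership)[comp$membership == ci]
    sub <- nodes[nodes$id %in% ids, , drop = FALSE]
    blood_ids <- sub$id[sub$tissue == blood_tissue]
    bb <- FALSE
    for (b in blood_ids) {
      inc <- edges[edges$from == b | edges$to == b, , drop = FALSE]
      nb <- setdiff(c(inc$from, inc$to), b)
      regions <- unique(nodes$tissue[match(nb, nodes$id)])
      if (length(intersect(regions, brain_tissues)) >= 2) { bb <- TRUE; break }
    }
    data.frame(cluster = ci, n_nodes = length(ids),
               tissues = paste(sort(unique(sub$tissue)), collapse = ","),
               blood_brain = bb, members = paste(sort(ids), collapse = ","),
               stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, clusters)
  structure(list(nodes = nodes, edges = edges, clusters = clusters,
                 graph = g, edge_alpha = edge_alpha,
                 blood_tissue = blood_tissue), class = "meta_network")
}

#' @export
print.meta_network <- function(x, ...) {
  nbb <- if (is.null(x$clusters)) 0 else sum(x$clusters$blood_brain)
  cat("meta_network:", nrow(x$nodes), "module nodes,", nrow(x$edges),
      "overlap edges;", nbb, "blood-brain cluster(s)\n")
  invisible(x)
}

#' Export a meta-network for Cytoscape
#'
#' Writes a SIF file (`from overlap to`) and a GraphML file.
#'
#' @param mn a `meta_network`.
#' @param sif_path,graphml_path output paths (NULL skips either).
#' @return invisible NULL.
#' @export
export_meta_network <- function(mn, sif_path = NULL, graphml_path = NULL) {
  stopifnot(inherits(mn, "meta_network"))
  if (!is.null(sif_path)) {
    lines <- if (nrow(mn$edges))
      sprintf("%s\toverlap\t%s", mn$edges$from, mn$edges$to) else character(0)
    iso <- setdiff(mn$nodes$id, c(mn$edges$from, mn$edges$to))
    writeLines(c(lines, iso), sif_path)
  }
  if (!is.null(graphml_path))
    igraph::write_graph(mn$graph, graphml_path, format = "graphml")
  invisible(NULL)
}
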