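# Module merging, network export, and end-to-end pipeline orchestration.

# Coerce the various subnetwork containers to a named list of gene sets.
as_gene_sets <- function(x) {
  if (inherits(x, "subnetwork_search")) x <- x$subnetworks
  if (is.data.frame(x)) {
    stopifnot("genes" %in% names(x))
    labels <- if ("rank" %in% names(x)) as.character(x$rank) else
      as.character(seq_len(nrow(x)))
    sets <- lapply(strsplit(x$genes, ",", fixed = TRUE), normalize_symbols)
    return(setNames(sets, labels))
  }
  if (inherits(x, "subnetwork")) x <- list(x)
  stopifnot(is.list(x))
  sets <- lapply(x, function(el) {
    if (inherits(el, "subnetwork")) el$genes else normalize_symbols(el)
  })
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- as.character(seq_along(sets))
  }
  sets
}

#' Merge overlapping subnetworks into functional modules
#'
#' Two subnetworks belong to the same module when they share at least one
#' gene (or, with `min_jaccard > 0`, when their Jaccard index reaches the
#' threshold); modules are the connected components of this overlap
#' relation, and each module's gene set is the union over its member
#' subnetworks.  This mirrors how genes carrying several subnetwork colours
#' in a results figure tie their subnetworks into one larger module.
#'
#' @param subnets A `subnetwork_search` object, a list of `subnetwork`
#'   objects or gene-set character vectors, or a results tibble with a
#'   comma-joined `genes` column (and optionally `rank`).
#' @param min_jaccard Overlap threshold; 0 (default) merges on any shared
#'   gene.
#' @return Tibble with one row per module: `module`, `n_subnetworks`,
#'   `subnetworks` (comma-joined labels/ranks), `n_genes`, `genes`
#'   (comma-joined sorted union).
#' @export
merge_modules <- function(subnets, min_jaccard = 0) {
  sets <- as_gene_sets(subnets)
  if (length(sets) == 0L) {
    return(tibble::tibble(module = integer(), n_subnetworks = integer(),
                          subnetworks = character(), n_genes = integer(),
                          genes = character()))
  }
  n <- length(sets)
  overlap <- function(i, j) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    if (min_jaccard <= 0) return(inter >= 1L)
    inter / length(union(sets[[i]], sets[[j]])) >= min_jaccard
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (n > 1L) {
    pairs <- utils::combn(n, 2L)
    hit <- apply(pairs, 2L, function(pr) overlap(pr[1L], pr[2L]))
    if (any(hit)) g <- igraph::add_edges(g, as.vector(pairs[, hit, drop = FALSE]))
  }
  membership <- igraph::components(g)$membership
  purrr::map_dfr(sort(unique(membership)), function(mod) {
    idx <- which(membership == mod)
    tibble::tibble(
      module = mod,
      n_subnetworks = length(idx),
      subnetworks = paste(names(sets)[idx], collapse = ","),
      n_genes = length(unique(unlist(sets[idx]))),
      genes = paste(sort(unique(unlist(sets[idx]))), collapse = ","))
  })
}

#' Export subnetworks as a SIF or GraphML network
#'
#' Writes the union of the subnetworks' induced PPI edges; every node
#' carries a `membership` attribute listing the subnetworks it belongs to
#' (comma-joined), so genes shared between subnetworks are visible in a
#' viewer.  SIF rows use the `nodeA pp nodeB` dialect, with isolated nodes
#' written as single-column rows.
#'
#' @param subnets A `subnetwork_search` object or a list of `subnetwork`
#'   objects.
#' @param path Output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(subnets, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (inherits(subnets, "subnetwork_search")) subnets <- subnets$subnetworks
  if (inherits(subnets, "subnetwork")) subnets <- list(subnets)
  if (length(subnets) == 0L) abort("No subnetworks to export.")
  stopifnot(all(vapply(subnets, inherits, TRUE, "subnetwork")))
  labels <- vapply(seq_along(subnets), function(i) {
    sn <- subnets[[i]]
    if (!is.null(sn$seed)) sn$seed else as.character(i)
  }, "")

  nodes <- sort(unique(unlist(lapply(subnets, `[[`, "genes"))))
  membership <- vapply(nodes, function(gn) {
    paste(labels[vapply(subnets, function(sn) gn %in% sn$genes, TRUE)],
          collapse = ",")
  }, "")
  edges <- dplyr::distinct(dplyr::bind_rows(lapply(subnets, `[[`, "edges")))

  if (format == "sif") {
    rows <- sprintf("%s\tpp\t%s", edges$from, edges$to)
    isolated <- setdiff(nodes, unique(c(edges$from, edges$to)))
    readr::write_lines(c(rows, isolated), path)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    igraph::V(g)$membership <- membership[nodes]
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects input paths, preprocessing flags and search settings for
#' [run_pipeline()].  Input files are checked for existence immediately.
#'
#' @param edge_list Path to the PPI edge list (TSV or SIF).
#' @param expression Path to the expression TSV (features x samples).
#' @param survival Path to the survival TSV (sample, time, event).
#' @param out_dir Output directory (created if missing).
#' @param probe_map Optional probe-to-gene mapping TSV.
#' @param gmt Optional GMT gene-set collection for enrichment.
#' @param edge_format Edge-list dialect, `"tsv"` or `"sif"`.
#' @param log2 Apply `log2(x + 1)` before standardization.
#' @param standardize Z-score each gene row before model fitting
#'   (default TRUE: hazard ratios are then per expression SD).
#' @param missing Missing-value policy for expression rows.
#' @param alpha_univariate Threshold for the univariate survival-gene
#'   screen (default 0.05).
#' @param ... Passed to [search_config()] (`k`, `max_size`,
#'   `alpha_adjusted`, `min_improvement`, `ties`, `random_seed`).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(edge_list, expression, survival, out_dir,
                            probe_map = NULL, gmt = NULL,
                            edge_format = c("tsv", "sif"), log2 = FALSE,
                            standardize = TRUE, missing = c("drop", "impute"),
                            alpha_univariate = 0.05, ...) {
  edge_format <- match.arg(edge_format)
  missing <- match.arg(missing)
  for (p in c(edge_list, expression, survival, probe_map, gmt)) {
    if (!file.exists(p)) abort(sprintf("Input file not found: %s", p))
  }
  structure(list(edge_list = edge_list, expression = expression,
                 survival = survival, out_dir = out_dir,
                 probe_map = probe_map, gmt = gmt,
                 edge_format = edge_format, log2 = log2,
                 standardize = standardize, missing = missing,
                 alpha_univariate = alpha_univariate,
                 search = search_config(...)),
            class = "pipeline_config")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full discovery pipeline and write results to disk
#'
#' Loads the network, expression and survival inputs, applies the
#' configured preprocessing, runs the subnetwork search and the univariate
#' screen (plus enrichment when a GMT collection is configured), merges
#' overlapping subnetworks into modules, and writes
#' `subnetworks.tsv`, `seed_table.tsv`, `univariate.tsv`, `modules.tsv`,
#' optional `enrichment.tsv`, `network.sif`/`network.graphml`, and
#' `run_log.txt` into the output directory.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`search`,
#'   `univariate`, `modules`, `enrichment`, `files`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  net <- pipeline_stage("load_network", read_edge_list(cfg$edge_list, cfg$edge_format))
  expr <- pipeline_stage("load_expression",
                         read_expression(cfg$expression, missing = cfg$missing))
  if (!is.null(cfg$probe_map)) {
    pm <- pipeline_stage("load_probe_map",
                         readr::read_tsv(cfg$probe_map, show_col_types = FALSE))
    expr <- pipeline_stage("collapse_probes", collapse_probes(expr, pm))
  }
  if (isTRUE(cfg$log2)) expr <- pipeline_stage("log2", log2_transform(expr))
  if (isTRUE(cfg$standardize)) {
    expr <- pipeline_stage("standardize", standardize_expression(expr))
  }
  surv <- pipeline_stage("load_survival", read_survival(cfg$survival))
  aligned <- pipeline_stage("align_samples", align_samples(expr, surv))
  expr <- aligned$expression
  surv <- aligned$survival

  res <- pipeline_stage("subnetwork_search",
                        search_subnetworks(net, expr, surv, cfg$search))
  uni <- pipeline_stage("univariate_cox",
                        univariate_cox(expr, surv, ties = cfg$search$ties))
  modules <- pipeline_stage("merge_modules", merge_modules(res))
  enr <- NULL
  if (!is.null(cfg$gmt)) {
    collection <- pipeline_stage("load_gmt", read_gmt(cfg$gmt))
    hits <- select_survival_genes(uni, cfg$alpha_univariate)
    enr <- pipeline_stage("enrichment",
                          hypergeom_enrich(hits, collection, universe = expr$gene))
  }

  files <- c(subnetworks = file.path(cfg$out_dir, "subnetworks.tsv"),
             seed_table = file.path(cfg$out_dir, "seed_table.tsv"),
             univariate = file.path(cfg$out_dir, "univariate.tsv"),
             modules = file.path(cfg$out_dir, "modules.tsv"),
             log = file.path(cfg$out_dir, "run_log.txt"))
  readr::write_tsv(res$results, files[["subnetworks"]])
  readr::write_tsv(res$seed_table, files[["seed_table"]])
  readr::write_tsv(uni, files[["univariate"]])
  readr::write_tsv(modules, files[["modules"]])
  if (!is.null(enr)) {
    files[["enrichment"]] <- file.path(cfg$out_dir, "enrichment.tsv")
    readr::write_tsv(enr, files[["enrichment"]])
  }
  if (nrow(res$results) > 0L) {
    files[["sif"]] <- file.path(cfg$out_dir, "network.sif")
    files[["graphml"]] <- file.path(cfg$out_dir, "network.graphml")
    export_network(res, files[["sif"]], "sif")
    export_network(res, files[["graphml"]], "graphml")
  }

  log_lines <- c(
    sprintf("netsurv %s", as.character(utils::packageVersion("netsurv"))),
    sprintf("R %s", as.character(getRversion())),
    "-- config --",
    sprintf("%s: %s", names(unclass(cfg))[1:10],
            vapply(unclass(cfg)[1:10], function(v) paste(format(v), collapse = ","), "")),
    sprintf("search: k=%d max_size=%d alpha_adjusted=%g min_improvement=%g ties=%s",
            cfg$search$k, cfg$search$max_size, cfg$search$alpha_adjusted,
            cfg$search$min_improvement, cfg$search$ties),
    "-- run --",
    sprintf("seeds searched: %d", res$n_seeds),
    sprintf("candidate fits skipped (guard or non-convergence): %d", res$n_skipped_fits),
    sprintf("subnetworks reported at adjusted P <= %g: %d",
            cfg$search$alpha_adjusted, nrow(res$results)),
    sprintf("univariate survival genes at P < %g: %d",
            cfg$alpha_univariate,
            length(select_survival_genes(uni, cfg$alpha_univariate))))
  readr::write_lines(log_lines, files[["log"]])

  invisible(list(search = res, univariate = uni, modules = modules,
                 enrichment = enr, files = files))
}
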