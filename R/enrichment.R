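#' Read a GMT gene-set collection
#'
#' GMT lines are tab-separated: set id, description, then member gene
#' symbols.  Members are uppercased and deduplicated within each set.
#'
#' @param path Path to the GMT file.
#' @return Tibble with columns `set_id`, `name`, and `genes` (list column of
#'   character vectors).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("Empty GMT file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("Malformed GMT line %d: expected >= 3 tab-separated fields.", bad[1L]))
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) abort("Duplicate set ids in GMT file.")
  tibble::tibble(
    set_id = ids,
    name = vapply(fields, `[[`, "", 2L),
    genes = lapply(fields, function(f) unique(normalize_symbols(f[-(1:2)])))
  )
}

#' Select survival-associated genes from a univariate Cox screen
#'
#' @param univariate Tibble from [univariate_cox()] (columns `gene`, `p`).
#' @param alpha Significance threshold on the unadjusted P value
#'   (default 0.05).
#' @return Character vector of gene symbols with `p < alpha`, sorted by P
#'   ascending.
#' @export
select_survival_genes <- function(univariate, alpha = 0.05) {
  stopifnot(is.data.frame(univariate), all(c("gene", "p") %in% names(univariate)))
  if (nrow(univariate) == 0L) return(character(0))
  if (any(univariate$p < 0 | univariate$p > 1, na.rm = TRUE)) {
    abort("P values must lie in [0, 1].")
  }
  hit <- univariate[!is.na(univariate$p) & univariate$p < alpha, ]
  hit$gene[order(hit$p)]
}

#' Hypergeometric over-representation test against a gene-set collection
#'
#' For each set, the one-sided hypergeometric (Fisher) P value
#' \eqn{P(X \ge \mathrm{overlap})} of the observed overlap between the
#' selected genes and the set, drawing `length(selected)` genes without
#' replacement from the universe.  P values are FDR-adjusted across the
#' collection with [bh_adjust()].
#'
#' @param selected Character vector of selected gene symbols.
#' @param collection Gene sets as returned by [read_gmt()] (tibble with
#'   `set_id`, `name`, `genes` list column).
#' @param universe Optional explicit gene universe (recommended: all assayed
#'   genes).  Defaults to the union of all collection members and the
#'   selected genes.  Selected genes and set members outside the universe
#'   are dropped with a message.
#' @return Tibble with columns `set_id`, `name`, `set_size`, `overlap`,
#'   `p`, `fdr`, sorted by `p`.
#' @export
hypergeom_enrich <- function(selected, collection, universe = NULL) {
  stopifnot(is.data.frame(collection),
            all(c("set_id", "genes") %in% names(collection)))
  selected <- unique(normalize_symbols(selected))
  sets <- lapply(collection$genes, normalize_symbols)
  if (is.null(universe)) {
    universe <- union(unique(unlist(sets)), selected)
  } else {
    universe <- unique(normalize_symbols(universe))
  }
  if (length(universe) == 0L) abort("The gene universe is empty.")
  n_out <- sum(!selected %in% universe)
  if (n_out > 0L) {
    inform(sprintf("Dropped %d selected gene(s) outside the universe.", n_out))
    selected <- intersect(selected, universe)
  }
  N <- length(universe)
  n_sel <- length(selected)
  res <- purrr::map2_dfr(collection$set_id, seq_along(sets), function(id, i) {
    members <- intersect(sets[[i]], universe)
    K <- length(members)
    ov <- length(intersect(members, selected))
    # P(X >= ov), X ~ Hypergeom(N, K, n_sel)
    p <- if (ov == 0L) 1 else
      stats::phyper(ov - 1L, K, N - K, n_sel, lower.tail = FALSE)
    tibble::tibble(set_id = id,
                   name = if ("name" %in% names(collection)) collection$name[i] else id,
                   set_size = K, overlap = ov, p = min(1, p))
  })
  res$fdr <- bh_adjust(res$p)
  dplyr::arrange(res, .data$p, .data$set_id)
}
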