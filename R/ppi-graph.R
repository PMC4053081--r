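#' Build a protein-protein interaction network from an edge table
#'
#' Constructs an undirected, simple (no self-loops, no duplicate edges) PPI
#' network over gene symbols.  Symbols are whitespace-trimmed and uppercased
#' so that expression rows and network nodes match case-insensitively.
#' Duplicate edges (including reversed duplicates) and self-loops are dropped
#' with a message stating how many were removed.
#'
#' @param edges A data frame whose first two columns are interacting gene
#'   symbols; extra columns are ignored.
#' @return A `ppi_network` object: a list with `nodes` (character vector),
#'   `edges` (tibble with columns `from`, `to`, each edge stored once with
#'   `from` < `to`), and the underlying `igraph` graph used for queries.
#' @examples
#' net <- ppi_network(data.frame(a = c("ccr7", "CCL21"), b = c("CCL21", "FBLN2")))
#' net$nodes
#' @export
ppi_network <- function(edges) {
  if (!is.data.frame(edges) || ncol(edges) < 2L) {
    abort("`edges` must be a data frame with at least two columns.")
  }
  from <- normalize_symbols(edges[[1L]])
  to <- normalize_symbols(edges[[2L]])
  keep <- from != "" & to != ""
  from <- from[keep]
  to <- to[keep]
  if (length(from) == 0L) abort("No edges supplied.")

  n_self <- sum(from == to)
  ok <- from != to
  a <- pmin(from[ok], to[ok])
  b <- pmax(from[ok], to[ok])
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  edge_tbl <- tibble::tibble(from = a[!dup], to = b[!dup]) |>
    dplyr::arrange(.data$from, .data$to)
  if (n_self > 0L || n_dup > 0L) {
    inform(sprintf("Removed %d self-loop(s) and %d duplicate edge(s).", n_self, n_dup))
  }
  if (nrow(edge_tbl) == 0L) abort("All rows were self-loops; the network has no edges.")

  nodes <- sort(unique(c(edge_tbl$from, edge_tbl$to)))
  g <- igraph::graph_from_data_frame(edge_tbl, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(nodes = nodes, edges = edge_tbl, graph = g),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a PPI edge list from a TSV or SIF file
#'
#' TSV rows carry two tab- or whitespace-separated gene symbols (a leading
#' `#` marks a comment/header line); SIF rows use the three-column
#' `nodeA relation nodeB` dialect.  The result is deduplicated and
#' self-loop-free, with symbols uppercased.
#'
#' @param path Path to the edge-list file.
#' @param format `"tsv"` (two symbol columns) or `"sif"`.
#' @return A [ppi_network()] object.
#' @export
read_edge_list <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path)
  lines_kept <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(lines_kept) == 0L) abort(sprintf("Empty edge-list file: %s", path))
  fields <- strsplit(trimws(lines[lines_kept]), "[\t ]+")
  want <- if (format == "sif") 3L else 2L
  bad <- which(vapply(fields, length, 1L) < want)
  if (length(bad) > 0L) {
    abort(sprintf("Malformed row at line %d of %s: expected >= %d columns.",
                  lines_kept[bad[1L]], path, want))
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", if (format == "sif") 3L else 2L)
  ppi_network(data.frame(from = from, to = to))
}

as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  net$graph
}

check_genes_known <- function(net, genes, what = "gene") {
  missing <- setdiff(genes, net$nodes)
  if (length(missing) > 0L) {
    abort(sprintf("Unknown %s(s) not in network: %s", what,
                  paste(head(missing, 5L), collapse = ", ")))
  }
  invisible(TRUE)
}

#' k-hop neighbourhood of a seed gene
#'
#' All nodes whose unweighted shortest-path distance from `seed` is at most
#' `k`, including the seed itself.  Distances are hop counts on the full
#' network.
#'
#' @param net A [ppi_network()].
#' @param seed A gene symbol present in the network.
#' @param k Maximum shortest-path distance (positive integer).
#' @return Character vector of gene symbols (sorted; always contains `seed`).
#' @export
neighborhood <- function(net, seed, k) {
  seed <- normalize_symbols(seed)
  check_genes_known(net, seed, "seed")
  assert_scalar_number(k, "k", min = 1)
  d <- igraph::distances(net$graph, v = seed, mode = "all")[1L, ]
  sort(names(d)[is.finite(d) & d <= k])
}

#' Edges induced by a gene set
#'
#' @param net A [ppi_network()].
#' @param genes Character vector of gene symbols, all present in the network.
#' @return Tibble with columns `from`, `to`: exactly the network edges with
#'   both endpoints in `genes`.
#' @export
induced_edges <- function(net, genes) {
  genes <- unique(normalize_symbols(genes))
  check_genes_known(net, genes)
  dplyr::filter(net$edges, .data$from %in% genes & .data$to %in% genes)
}

#' Is the induced subgraph over a gene set connected?
#'
#' @inheritParams induced_edges
#' @return `TRUE` iff the subgraph of `net` induced by `genes` is connected.
#'   A single gene is connected by definition.
#' @export
is_connected_genes <- function(net, genes) {
  genes <- unique(normalize_symbols(genes))
  if (length(genes) == 0L) abort("`genes` must be non-empty.")
  check_genes_known(net, genes)
  sub <- igraph::induced_subgraph(net$graph, genes)
  igraph::is_connected(sub)
}
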