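#' Configuration for the subnetwork search
#'
#' @param k Maximum shortest-path distance from the seed defining the
#'   candidate pool (default 3).
#' @param max_size Maximum number of genes per subnetwork (default 10).
#' @param alpha_adjusted Reporting threshold on the FDR-adjusted
#'   subnetwork P value (default 0.001).
#' @param min_improvement Minimum decrease in the global Wald P value
#'   required to keep growing (default 0: any strict decrease).
#' @param ties Cox tie-handling approximation, `"breslow"` or `"efron"`.
#' @param max_covariate_frac Saturation guard: a candidate model with `p`
#'   covariates is only fitted when `p < max_covariate_frac * n_events`
#'   (default 1/3).
#' @param random_seed Optional integer recorded for provenance; the search
#'   itself is deterministic (ties in P are broken by gene symbol).
#' @return A `search_config` object (a validated list).
#' @export
search_config <- function(k = 3L, max_size = 10L, alpha_adjusted = 0.001,
                          min_improvement = 0, ties = c("breslow", "efron"),
                          max_covariate_frac = 1 / 3, random_seed = NULL) {
  ties <- match.arg(ties)
  assert_scalar_number(k, "k", min = 1)
  assert_scalar_number(max_size, "max_size", min = 1)
  assert_scalar_number(alpha_adjusted, "alpha_adjusted", min = 1e-300, max = 1)
  assert_scalar_number(min_improvement, "min_improvement", min = 0, max = 1)
  assert_scalar_number(max_covariate_frac, "max_covariate_frac", min = 0, max = 1)
  structure(list(k = as.integer(k), max_size = as.integer(max_size),
                 alpha_adjusted = alpha_adjusted,
                 min_improvement = min_improvement, ties = ties,
                 max_covariate_frac = max_covariate_frac,
                 random_seed = random_seed),
            class = "search_config")
}

#' Candidate gene pool for one seed
#'
#' Genes within shortest-path distance `k` of the seed on the full network
#' that also have an expression row.  Distances are computed on the complete
#' network; expression availability only filters membership, so genes
#' reachable through an unmeasured intermediate stay in the pool.
#'
#' @param net A [ppi_network()].
#' @param expr Expression tibble.
#' @param seed Seed gene symbol (must be in both the network and `expr`).
#' @param k Maximum shortest-path distance.
#' @return Sorted character vector of gene symbols, always containing `seed`.
#' @export
candidate_pool <- function(net, expr, seed, k = 3L) {
  seed <- normalize_symbols(seed)
  check_genes_known(net, seed, "seed")
  if (!seed %in% expr$gene) abort(sprintf("Seed %s has no expression row.", seed))
  hood <- neighborhood(net, seed, k)
  sort(union(seed, intersect(hood, expr$gene)))
}

# Shared precomputation for a search run.
search_context <- function(net, expr, surv, cfg) {
  aligned <- align_samples(expr, surv)
  m <- expr_matrix(aligned$expression)
  surv <- aligned$survival
  n_events <- sum(surv$event)
  if (n_events < 1L) abort("At least one observed event is required.")
  g <- net$graph
  adj <- igraph::adjacent_vertices(g, v = igraph::V(g))
  adj <- lapply(adj, function(v) v$name)
  names(adj) <- net$nodes
  list(net = net, E = t(m), expr_genes = rownames(m),
       time = as.numeric(surv$time), status = as.integer(surv$event),
       n_events = n_events, adj = adj,
       efron = identical(cfg$ties, "efron"))
}

# Greedy adjacency-constrained forward growth from one seed.  Returns the
# growth path and the member set attaining the minimum global Wald P.
grow_core <- function(seed, pool, ctx, cfg) {
  E <- ctx$E
  max_p_cov <- ctx$n_events * cfg$max_covariate_frac

  seed_fit <- cox_nr_fit_cpp(E[, seed, drop = FALSE], ctx$time, ctx$status,
                             efron = ctx$efron, maxit = 50L, tol = 1e-8)
  if (!isTRUE(seed_fit$converged)) {
    return(list(genes = seed, p = 1, converged = FALSE, n_skipped = 0L,
                path = tibble::tibble(step = 0L, gene = seed, p = 1)))
  }
  seed_p <- pchisq(as.numeric(seed_fit$wald), df = 1, lower.tail = FALSE)
  current <- seed
  current_p <- seed_p
  best <- seed
  best_p <- seed_p
  n_skipped <- 0L
  path_gene <- seed
  path_p <- seed_p

  while (length(current) < cfg$max_size) {
    cands <- setdiff(intersect(unique(unlist(ctx$adj[current], use.names = FALSE)),
                               pool), current)
    if (length(cands) == 0L) break
    if (length(current) + 1L >= max_p_cov) {
      n_skipped <- n_skipped + length(cands)
      break
    }
    cands <- sort(cands)
    batch <- cox_batch_wald_cpp(E[, current, drop = FALSE],
                                E[, cands, drop = FALSE],
                                ctx$time, ctx$status,
                                efron = ctx$efron, maxit = 50L, tol = 1e-8)
    conv <- batch[, 2L] == 1
    n_skipped <- n_skipped + sum(!conv)
    if (!any(conv)) break
    df <- length(current) + 1L
    p_cand <- rep(NA_real_, length(cands))
    p_cand[conv] <- pchisq(batch[conv, 1L], df = df, lower.tail = FALSE)
    p_round <- signif(p_cand, 12L)
    sel <- which(conv)[which.min(p_round[conv])]  # ties: first in symbol order
    p_sel <- p_cand[sel]

    improve <- current_p - p_sel
    if (!(improve > 0 && improve >= cfg$min_improvement)) break
    current <- c(current, cands[sel])
    current_p <- p_sel
    path_gene <- c(path_gene, cands[sel])
    path_p <- c(path_p, p_sel)
    if (p_sel < best_p) {
      best <- current
      best_p <- p_sel
    }
  }
  list(genes = best, p = best_p, converged = TRUE, n_skipped = n_skipped,
       path = tibble::tibble(step = seq_along(path_gene) - 1L,
                             gene = path_gene, p = path_p))
}

# Exhaustive enumeration of connected member sets containing the seed
# (feasible only for small max_size); used as an oracle for the greedy path.
exhaustive_core <- function(seed, pool, ctx, cfg) {
  E <- ctx$E
  max_p_cov <- ctx$n_events * cfg$max_covariate_frac
  best <- NULL
  best_p <- Inf
  seen <- new.env(hash = TRUE)
  eval_set <- function(genes) {
    fit <- cox_nr_fit_cpp(E[, genes, drop = FALSE], ctx$time, ctx$status,
                          efron = ctx$efron, maxit = 50L, tol = 1e-8)
    if (!isTRUE(fit$converged)) return(NA_real_)
    pchisq(as.numeric(fit$wald), df = length(genes), lower.tail = FALSE)
  }
  recurse <- function(genes) {
    key <- paste(sort(genes), collapse = "\r")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    p <- eval_set(genes)
    if (!is.na(p) && (p < best_p ||
                      (p == best_p && !is.null(best) &&
                       paste(sort(genes), collapse = ",") <
                       paste(sort(best), collapse = ",")))) {
      best <<- genes
      best_p <<- p
    }
    if (length(genes) >= cfg$max_size || length(genes) + 1L >= max_p_cov) {
      return(invisible())
    }
    cands <- setdiff(intersect(unique(unlist(ctx$adj[genes], use.names = FALSE)),
                               pool), genes)
    for (cand in sort(cands)) recurse(c(genes, cand))
    invisible()
  }
  recurse(seed)
  if (is.null(best)) {
    return(list(genes = seed, p = 1, converged = FALSE, n_skipped = 0L,
                path = tibble::tibble(step = 0L, gene = seed, p = 1)))
  }
  list(genes = best, p = best_p, converged = TRUE, n_skipped = 0L,
       path = tibble::tibble(step = seq_along(best) - 1L, gene = best, p = best_p))
}

build_subnetwork <- function(core, seed, net, ctx, cfg) {
  genes <- core$genes
  edges <- induced_edges(net, genes)
  fit <- NULL
  uni <- setNames(rep(NA_real_, length(genes)), genes)
  if (core$converged) {
    fit <- cox_fit(ctx$E[, genes, drop = FALSE],
                   data.frame(time = ctx$time, event = ctx$status),
                   ties = if (ctx$efron) "efron" else "breslow")
    for (g in genes) {
      f <- cox_nr_fit_cpp(ctx$E[, g, drop = FALSE], ctx$time, ctx$status,
                          efron = ctx$efron, maxit = 50L, tol = 1e-8)
      uni[g] <- if (isTRUE(f$converged)) {
        pchisq(as.numeric(f$wald), df = 1, lower.tail = FALSE)
      } else 1
    }
  }
  structure(list(seed = seed, genes = genes, n_genes = length(genes),
                 edges = edges, n_edges = nrow(edges),
                 p_multivariate = core$p, p_adjusted = NA_real_,
                 univariate_p = uni, fit = fit, converged = core$converged,
                 path = core$path, n_skipped = core$n_skipped,
                 k = cfg$k, max_size = cfg$max_size),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork> seed %s: %d gene(s), %d edge(s), P = %.3g",
              x$seed, x$n_genes, x$n_edges, x$p_multivariate))
  if (!is.na(x$p_adjusted)) cat(sprintf(", adjusted P = %.3g", x$p_adjusted))
  cat("\n  genes:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Grow the best-scoring subnetwork around one seed
#'
#' Greedy forward growth: starting from the seed alone, each step fits a
#' multivariate Cox model for every pool gene adjacent to the current member
#' set and adopts the candidate with the smallest global Wald P value;
#' growth stops when no candidate lowers P (by at least
#' `min_improvement`), the pool is exhausted, the size cap is reached, or
#' the saturation guard trips.  The member set attaining the minimum P
#' anywhere along the growth path is reported, so the reported P never
#' exceeds the seed-only P.  Connectivity is guaranteed because genes are
#' only added adjacent to the current set.
#'
#' @param seed Seed gene symbol.
#' @param pool Candidate gene pool (see [candidate_pool()]); defaults to the
#'   pool at distance `config$k`.
#' @param net A [ppi_network()].
#' @param expr Expression tibble (samples aligned with `surv` or alignable).
#' @param surv Survival tibble.
#' @param config A [search_config()].
#' @param method `"greedy"` (default) or `"exhaustive"`, which enumerates
#'   every connected member set containing the seed and is feasible only
#'   for small `max_size` (<= 4 or so).
#' @return A `subnetwork` object: member genes, induced edges, multivariate
#'   Wald P, per-gene univariate P values, the underlying [cox_fit()], and
#'   the growth path.
#' @export
grow_subnetwork <- function(seed, pool = NULL, net, expr, surv,
                            config = search_config(),
                            method = c("greedy", "exhaustive")) {
  method <- match.arg(method)
  seed <- normalize_symbols(seed)
  ctx <- search_context(net, expr, surv, config)
  if (is.null(pool)) pool <- candidate_pool(net, expr, seed, config$k)
  pool <- normalize_symbols(pool)
  if (!seed %in% pool) abort("`seed` must be a member of `pool`.")
  pool <- intersect(pool, ctx$expr_genes)
  core <- if (method == "greedy") grow_core(seed, pool, ctx, config) else
    exhaustive_core(seed, pool, ctx, config)
  build_subnetwork(core, seed, net, ctx, config)
}

#' Search every mappable seed for survival-related subnetworks
#'
#' Runs [grow_subnetwork()] from every network node with an expression row,
#' collects the per-seed minimum multivariate Cox Wald P values, adjusts
#' them across seeds by Benjamini-Hochberg false discovery rate, and
#' reports the subnetworks whose adjusted P passes
#' `config$alpha_adjusted`, ranked by adjusted then raw P.
#'
#' @param net A [ppi_network()].
#' @param expr Expression tibble.
#' @param surv Survival tibble.
#' @param config A [search_config()].
#' @return A `subnetwork_search` object with:
#'   \describe{
#'     \item{results}{tibble of reported subnetworks (rank, seed, genes,
#'       n_genes, n_edges, p_multivariate, p_adjusted, univariate_p)}
#'     \item{seed_table}{per-seed tibble over all seeds (unfiltered)}
#'     \item{subnetworks}{list of `subnetwork` objects for the reported rows}
#'     \item{config, n_seeds, n_skipped_fits}{run metadata}
#'   }
#'   Use [tidy()][generics::tidy] / [glance()][generics::glance] to extract
#'   tables.
#' @export
search_subnetworks <- function(net, expr, surv, config = search_config()) {
  stopifnot(inherits(net, "ppi_network"))
  ctx <- search_context(net, expr, surv, config)
  seeds <- sort(intersect(net$nodes, ctx$expr_genes))
  if (length(seeds) == 0L) abort("No network node has an expression row; nothing to seed.")

  g <- net$graph
  hoods <- igraph::ego(g, order = config$k, nodes = seeds, mode = "all")
  cores <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    pool <- intersect(hoods[[i]]$name, ctx$expr_genes)
    cores[[i]] <- grow_core(seeds[i], pool, ctx, config)
  }
  p_seed <- vapply(cores, `[[`, 0, "p")
  p_adj <- bh_adjust(p_seed)

  seed_table <- tibble::tibble(
    seed = seeds,
    n_genes = vapply(cores, function(cr) length(cr$genes), 0L),
    p_multivariate = p_seed,
    p_adjusted = p_adj,
    converged = vapply(cores, `[[`, TRUE, "converged")
  )

  keep <- which(p_adj <= config$alpha_adjusted)
  keep <- keep[order(p_adj[keep], p_seed[keep], seeds[keep])]
  subnets <- vector("list", length(keep))
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    sn <- build_subnetwork(cores[[i]], seeds[i], net, ctx, config)
    sn$p_adjusted <- p_adj[i]
    subnets[[j]] <- sn
    rows[[j]] <- tibble::tibble(
      rank = j, seed = sn$seed,
      genes = paste(sn$genes, collapse = ","),
      n_genes = sn$n_genes, n_edges = sn$n_edges,
      p_multivariate = sn$p_multivariate, p_adjusted = sn$p_adjusted,
      univariate_p = paste(sprintf("%s=%.6g", names(sn$univariate_p),
                                   sn$univariate_p), collapse = ";"))
  }
  results <- if (length(rows) > 0L) dplyr::bind_rows(rows) else
    tibble::tibble(rank = integer(), seed = character(), genes = character(),
                   n_genes = integer(), n_edges = integer(),
                   p_multivariate = double(), p_adjusted = double(),
                   univariate_p = character())

  structure(list(results = results, seed_table = seed_table,
                 subnetworks = subnets, config = config,
                 n_seeds = length(seeds),
                 n_skipped_fits = sum(vapply(cores, `[[`, 0L, "n_skipped"))),
            class = "subnetwork_search")
}

#' @export
print.subnetwork_search <- function(x, ...) {
  cat(sprintf("<subnetwork_search> %d seed(s) searched, %d subnetwork(s) at adjusted P <= %g\n",
              x$n_seeds, nrow(x$results), x$config$alpha_adjusted))
  if (nrow(x$results) > 0L) print(x$results, n = 10)
  invisible(x)
}

#' Summary statistics over reported subnetworks
#'
#' @param x A `subnetwork_search` object, a list of `subnetwork` objects, or
#'   a results tibble with `n_genes` and `n_edges` columns.
#' @return One-row tibble: `n_subnetworks`, `mean_genes`, `mean_edges`
#'   (zeros for an empty input).
#' @export
subnetwork_stats <- function(x) {
  tbl <- if (inherits(x, "subnetwork_search")) {
    x$results
  } else if (is.data.frame(x)) {
    x
  } else {
    tibble::tibble(n_genes = vapply(x, `[[`, 0L, "n_genes"),
                   n_edges = vapply(x, `[[`, 0L, "n_edges"))
  }
  if (nrow(tbl) == 0L) {
    return(tibble::tibble(n_subnetworks = 0L, mean_genes = 0, mean_edges = 0))
  }
  tibble::tibble(n_subnetworks = nrow(tbl),
                 mean_genes = mean(tbl$n_genes),
                 mean_edges = mean(tbl$n_edges))
}
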