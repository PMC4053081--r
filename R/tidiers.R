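#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-coefficient summary of a Cox fit
#'
#' @param x A [cox_fit()] object.
#' @param ... Unused.
#' @return Tibble with one row per covariate: `term`, `estimate` (log hazard
#'   ratio), `std.error`, `statistic` (per-coefficient Wald chi-squared),
#'   `p.value`.
#' @export
tidy.netsurv_cox <- function(x, ...) {
  se <- if (x$converged) sqrt(diag(x$vcov)) else rep(NA_real_, x$df)
  stat <- (x$beta / se)^2
  tibble::tibble(term = x$gene_ids,
                 estimate = unname(x$beta),
                 std.error = unname(se),
                 statistic = unname(stat),
                 p.value = pchisq(unname(stat), df = 1, lower.tail = FALSE))
}

#' One-row summary of a Cox fit
#'
#' @param x A [cox_fit()] object.
#' @param ... Unused.
#' @return Tibble: global Wald `statistic`, `df`, `p.value`, `logLik`,
#'   `logLik0`, `n`, `n_events`, `converged`.
#' @export
glance.netsurv_cox <- function(x, ...) {
  tibble::tibble(statistic = x$wald_stat, df = x$df, p.value = x$p_value,
                 logLik = x$loglik, logLik0 = x$loglik0,
                 n = x$n, n_events = x$n_events, converged = x$converged)
}

#' Tidy table of one subnetwork's member genes
#'
#' @param x A `subnetwork` object from [grow_subnetwork()].
#' @param ... Unused.
#' @return Tibble with one row per member gene: `seed`, `gene`,
#'   `univariate_p`, `p_multivariate`, `p_adjusted`.
#' @export
tidy.subnetwork <- function(x, ...) {
  tibble::tibble(seed = x$seed, gene = x$genes,
                 univariate_p = unname(x$univariate_p[x$genes]),
                 p_multivariate = x$p_multivariate,
                 p_adjusted = x$p_adjusted)
}

#' One-row summary of a subnetwork
#'
#' @inheritParams tidy.subnetwork
#' @return Tibble: `seed`, `n_genes`, `n_edges`, `p_multivariate`,
#'   `p_adjusted`, `converged`.
#' @export
glance.subnetwork <- function(x, ...) {
  tibble::tibble(seed = x$seed, n_genes = x$n_genes, n_edges = x$n_edges,
                 p_multivariate = x$p_multivariate, p_adjusted = x$p_adjusted,
                 converged = x$converged)
}

#' Tidy results table of a subnetwork search
#'
#' @param x A `subnetwork_search` object.
#' @param ... Unused.
#' @return The reported-subnetworks tibble (rank, seed, genes, sizes,
#'   P values).
#' @export
tidy.subnetwork_search <- function(x, ...) {
  x$results
}

#' One-row summary of a subnetwork search
#'
#' @inheritParams tidy.subnetwork_search
#' @return Tibble: `n_seeds`, `n_subnetworks`, `mean_genes`, `mean_edges`,
#'   `n_skipped_fits`, `alpha_adjusted`.
#' @export
glance.subnetwork_search <- function(x, ...) {
  stats <- subnetwork_stats(x)
  tibble::tibble(n_seeds = x$n_seeds,
                 n_subnetworks = stats$n_subnetworks,
                 mean_genes = stats$mean_genes,
                 mean_edges = stats$mean_edges,
                 n_skipped_fits = x$n_skipped_fits,
                 alpha_adjusted = x$config$alpha_adjusted)
}

#' Plot the significance of reported subnetworks
#'
#' Bar chart of `-log10` adjusted P per reported subnetwork, labelled by
#' seed, with the reporting threshold drawn as a dashed line.
#'
#' @param object A `subnetwork_search` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subnetwork_search <- function(object, ...) {
  tbl <- object$results
  if (nrow(tbl) == 0L) abort("No reported subnetworks to plot.")
  tbl$seed <- factor(tbl$seed, levels = rev(tbl$seed))
  ggplot2::ggplot(tbl, ggplot2::aes(x = -log10(.data$p_adjusted), y = .data$seed)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = -log10(object$config$alpha_adjusted),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted P"), y = "seed gene",
                  title = "Survival-related subnetworks") +
    ggplot2::theme_minimal()
}

#' Plot the greedy growth path of one subnetwork
#'
#' Shows how the global Wald P value evolves as genes are added, marking
#' the reported (minimum-P) step.
#'
#' @param subnet A `subnetwork` object.
#' @return A ggplot object.
#' @export
plot_growth_path <- function(subnet) {
  stopifnot(inherits(subnet, "subnetwork"))
  path <- subnet$path
  path$reported <- path$p == min(path$p)
  ggplot2::ggplot(path, ggplot2::aes(x = .data$step, y = -log10(.data$p))) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$reported), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene), vjust = -0.8, size = 3) +
    ggplot2::labs(x = "growth step", y = expression(-log[10] ~ P),
                  title = sprintf("Growth path for seed %s", subnet$seed)) +
    ggplot2::theme_minimal()
}
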