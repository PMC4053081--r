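#' Fit a Cox proportional-hazards model by Newton-Raphson
#'
#' Maximizes the log partial likelihood of a multivariate Cox
#' proportional-hazards model over the supplied covariates, with Breslow
#' (default) or Efron handling of tied event times.  Iteration stops when
#' the score vector's max-norm falls below `tol` (with step-halving when a
#' Newton step would decrease the likelihood) or after `max_iter`
#' iterations.  The coefficient covariance is the inverse observed
#' information at the optimum, and the global Wald statistic is
#' \eqn{\hat\beta^\top I(\hat\beta)\, \hat\beta} with one degree of freedom
#' per covariate.
#'
#' An ill-conditioned information matrix (constant or collinear covariates,
#' separation) is not an error: the fit is returned with
#' `converged = FALSE` and downstream code treats it as uninformative.
#'
#' @param x Covariate matrix or data frame, samples in rows, covariates in
#'   columns (column names become coefficient names).
#' @param surv Data frame with columns `time` (positive, months) and `event`
#'   (0/1), one row per row of `x`, in the same order.
#' @param ties Tie-handling approximation: `"breslow"` or `"efron"`.
#' @param max_iter Maximum Newton-Raphson iterations.
#' @param tol Convergence tolerance on the score max-norm.
#' @return An object of class `netsurv_cox`: coefficients, covariance,
#'   log partial likelihood at the optimum and at zero, global Wald
#'   statistic with its degrees of freedom and P value, convergence flag,
#'   and sample/event counts.  Use [tidy()][generics::tidy] for
#'   per-coefficient output and [glance()][generics::glance] for the global
#'   test.
#' @examples
#' x <- matrix(rnorm(40), ncol = 2, dimnames = list(NULL, c("G1", "G2")))
#' surv <- data.frame(time = rexp(20, 0.1), event = rbinom(20, 1, 0.8))
#' fit <- cox_fit(x, surv)
#' glance(fit)
#' @export
cox_fit <- function(x, surv, ties = c("breslow", "efron"),
                    max_iter = 50L, tol = 1e-8) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (ncol(x) < 1L) abort("At least one covariate is required.")
  if (!is.data.frame(surv) || !all(c("time", "event") %in% names(surv))) {
    abort("`surv` must be a data frame with `time` and `event` columns.")
  }
  if (nrow(surv) != nrow(x)) abort("`x` and `surv` must have the same number of rows.")
  if (any(is.na(x))) abort("Missing values in the covariate matrix.")
  if (any(surv$time <= 0)) abort("All follow-up times must be positive.")
  if (!all(surv$event %in% c(0, 1))) abort("`event` must be 0/1.")
  n_events <- sum(surv$event == 1)
  if (n_events < 1L) abort("At least one observed event is required to fit a Cox model.")

  res <- cox_nr_fit_cpp(x, as.numeric(surv$time), as.integer(surv$event),
                        efron = identical(ties, "efron"),
                        maxit = as.integer(max_iter), tol = tol)
  beta <- as.numeric(res$beta)
  names(beta) <- colnames(x)
  df <- ncol(x)
  wald <- if (isTRUE(res$converged)) as.numeric(res$wald) else NA_real_
  vcov <- res$vcov
  dimnames(vcov) <- list(colnames(x), colnames(x))
  structure(list(
    gene_ids = colnames(x),
    beta = beta,
    vcov = vcov,
    information = res$information,
    loglik = as.numeric(res$loglik),
    loglik0 = as.numeric(res$loglik0),
    wald_stat = wald,
    df = df,
    p_value = if (is.na(wald)) NA_real_ else pchisq(wald, df = df, lower.tail = FALSE),
    converged = isTRUE(res$converged),
    iter = res$iter,
    n = nrow(x),
    n_events = n_events,
    ties = ties
  ), class = "netsurv_cox")
}

#' @export
print.netsurv_cox <- function(x, ...) {
  cat(sprintf("<netsurv_cox> %d covariate(s), n = %d (%d events), ties = %s\n",
              x$df, x$n, x$n_events, x$ties))
  if (x$converged) {
    cat(sprintf("  Wald chi-squared = %.4g on %d df, P = %.3g\n",
                x$wald_stat, x$df, x$p_value))
  } else {
    cat("  fit did not converge (ill-conditioned information)\n")
  }
  invisible(x)
}

#' Global Wald test P value of a fitted Cox model
#'
#' Upper-tail probability of a chi-squared distribution with `df = p`
#' degrees of freedom at the global Wald statistic, testing all coefficients
#' jointly against zero.
#'
#' @param fit A converged [cox_fit()] object.
#' @return P value in `[0, 1]`.
#' @export
wald_p <- function(fit) {
  stopifnot(inherits(fit, "netsurv_cox"))
  if (!fit$converged) abort("Wald test requires a converged fit.")
  fit$p_value
}

#' Log partial likelihood at a fixed coefficient vector
#'
#' Evaluates the ties-adjusted Cox log partial likelihood at `beta` without
#' fitting.  At `beta = 0` with no tied event times this equals
#' \eqn{-\sum_{\mathrm{events}} \log |R_i|}, the negative sum of
#' log risk-set sizes.
#'
#' @inheritParams cox_fit
#' @param beta Numeric coefficient vector, one entry per column of `x`.
#' @return The log partial likelihood (a single number).
#' @export
cox_partial_loglik <- function(x, surv, beta, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (length(beta) != ncol(x)) abort("`beta` must have one entry per covariate.")
  cox_loglik_cpp(x, as.numeric(surv$time), as.integer(surv$event),
                 as.numeric(beta), efron = identical(ties, "efron"))
}

#' Univariate Cox screen over all genes
#'
#' Fits a single-covariate Cox proportional-hazards model per gene and
#' reports the coefficient and Wald P value.  Genes whose fit does not
#' converge are kept with `p = 1` and `converged = FALSE`.
#'
#' @param expr Expression tibble (`gene` column + sample columns) whose
#'   samples match `surv$sample` (see [align_samples()]).
#' @param surv Survival tibble (`sample`, `time`, `event`).
#' @param ties Tie-handling approximation.
#' @return Tibble with columns `gene`, `beta`, `se`, `p`, `converged`.
#' @export
univariate_cox <- function(expr, surv, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  surv <- validate_survival(surv)
  m <- expr_matrix(expr)
  if (nrow(m) == 0L) abort("Empty expression matrix.")
  if (!identical(colnames(m), surv$sample)) {
    aligned <- align_samples(expr, surv)
    m <- expr_matrix(aligned$expression)
    surv <- aligned$survival
  }
  if (sum(surv$event) < 1L) abort("At least one observed event is required.")
  time <- as.numeric(surv$time)
  status <- as.integer(surv$event)
  efron <- identical(ties, "efron")

  res <- lapply(seq_len(nrow(m)), function(i) {
    f <- cox_nr_fit_cpp(m[i, , drop = FALSE] |> t(), time, status,
                        efron = efron, maxit = 50L, tol = 1e-8)
    if (isTRUE(f$converged)) {
      c(beta = as.numeric(f$beta), se = sqrt(as.numeric(f$vcov)),
        p = pchisq(as.numeric(f$wald), df = 1, lower.tail = FALSE), conv = 1)
    } else {
      c(beta = NA_real_, se = NA_real_, p = 1, conv = 0)
    }
  })
  out <- do.call(rbind, res)
  tibble::tibble(gene = rownames(m),
                 beta = out[, "beta"],
                 se = out[, "se"],
                 p = out[, "p"],
                 converged = out[, "conv"] == 1)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted P values: with P values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, n\,p_{(j)}/j)}, returned in the
#' original order.
#'
#' @param pvalues Numeric vector of P values in `[0, 1]`.
#' @return Adjusted P values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("All P values must lie in [0, 1].")
  }
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(n / seq(n, 1) * p[o]))
  q[order(o)]
}
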