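test_that("single-covariate fit matches a 1-D numeric maximization oracle", {
  # fixed example: binary covariate interleaved with the death order so the
  # partial-likelihood maximum is interior
  x <- c(1, 0, 1, 0, 1, 0)
  surv <- data.frame(time = 1:6, event = 1)
  fit <- cox_fit(cbind(g = x), surv)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), oracle_fit_1d(x, surv$time, surv$event),
               tolerance = 1e-4)

  withr::local_seed(42)
  checked <- 0
  while (checked < 15) {
    d <- random_cox_data(sample(6:12, 1))
    ref <- oracle_fit_1d(d$x[, 1], d$surv$time, d$surv$event)
    if (abs(ref) > 8) next  # monotone likelihood: no finite optimum to compare
    fit <- cox_fit(d$x, d$surv)
    expect_true(fit$converged)
    expect_equal(unname(fit$beta), ref, tolerance = 1e-4)
    checked <- checked + 1
  }
})

test_that("log partial likelihood at beta = 0 equals -sum(log risk-set size)", {
  withr::local_seed(7)
  d <- random_cox_data(20)
  closed <- -sum(vapply(which(d$surv$event == 1),
                        function(i) log(sum(d$surv$time >= d$surv$time[i])), 0))
  expect_equal(cox_partial_loglik(d$x, d$surv, beta = 0), closed)
  # and the fitted optimum never falls below the null likelihood
  fit <- cox_fit(d$x, d$surv)
  expect_gte(fit$loglik, fit$loglik0)
  expect_equal(fit$loglik0, closed)
})

test_that("multivariate fit agrees with survival::coxph for both tie methods", {
  skip_if_not_installed("survival")
  withr::local_seed(13)
  for (tied in c(FALSE, TRUE)) {
    d <- random_cox_data(40, p = 3, tied = tied)
    for (ties in c("breslow", "efron")) {
      fit <- cox_fit(d$x, d$surv, ties = ties)
      ref <- survival::coxph(survival::Surv(d$surv$time, d$surv$event) ~ d$x,
                             ties = ties)
      expect_true(fit$converged)
      expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
      expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
      expect_equal(unname(diag(fit$vcov)), unname(diag(ref$var)),
                   tolerance = 1e-6)
    }
  }
})

test_that("degenerate covariates yield a non-convergence flag, not an error", {
  surv <- data.frame(time = c(1, 2, 3, 4, 5), event = c(1, 1, 0, 1, 1))
  fit <- cox_fit(cbind(k = rep(2, 5)), surv)
  expect_false(fit$converged)
  expect_error(wald_p(fit), "converged")

  # collinear pair
  x <- rnorm(5)
  fit2 <- cox_fit(cbind(a = x, b = 2 * x), surv)
  expect_false(fit2$converged)

  expect_error(cox_fit(cbind(x), data.frame(time = 1:5, event = 0)),
               "event")
})

test_that("global Wald P value behaves like a chi-squared upper tail", {
  withr::local_seed(5)
  d <- random_cox_data(30)
  fit <- cox_fit(d$x, d$surv)
  expect_equal(fit$p_value,
               pchisq(fit$wald_stat, df = 1, lower.tail = FALSE))
  expect_equal(wald_p(fit), fit$p_value)
  # reference quantile: chi2(1) 95th percentile
  expect_equal(pchisq(3.841459, df = 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-6)
  # monotone: larger statistic, smaller P
  expect_lt(pchisq(10, 1, lower.tail = FALSE), pchisq(2, 1, lower.tail = FALSE))
})

test_that("fit is invariant to sample reordering", {
  withr::local_seed(31)
  d <- random_cox_data(25, p = 2)
  fit1 <- cox_fit(d$x, d$surv)
  perm <- sample(25)
  fit2 <- cox_fit(d$x[perm, ], d$surv[perm, ])
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-8)
  expect_equal(fit1$p_value, fit2$p_value, tolerance = 1e-8)
})

test_that("univariate screen is deterministic, exchangeable and calibrated", {
  withr::local_seed(99)
  n <- 100
  expr <- dplyr::bind_cols(
    tibble::tibble(gene = paste0("G", 1:30)),
    tibble::as_tibble(as.data.frame(matrix(rnorm(30 * n), nrow = 30,
      dimnames = list(NULL, paste0("S", 1:n))))))
  expr[2, -1] <- expr[1, -1]  # duplicate gene content
  surv <- tibble::tibble(sample = paste0("S", 1:n),
                         time = rexp(n, 0.05) + 0.01,
                         event = rbinom(n, 1, 0.8))
  uni <- univariate_cox(expr, surv)
  expect_equal(uni$beta[1], uni$beta[2])
  expect_equal(uni$p[1], uni$p[2])

  perm <- sample(n)
  uni2 <- univariate_cox(expr[c("gene", paste0("S", perm))],
                         surv[perm, ])
  expect_equal(uni$p, uni2$p, tolerance = 1e-8)
})

test_that("univariate type-I error is near nominal on null genes", {
  withr::local_seed(123)
  n <- 100
  n_genes <- 1000
  m <- matrix(rnorm(n_genes * n), nrow = n_genes,
              dimnames = list(paste0("G", seq_len(n_genes)), paste0("S", 1:n)))
  expr <- dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                           tibble::as_tibble(as.data.frame(m)))
  surv <- tibble::tibble(sample = paste0("S", 1:n),
                         time = rexp(n, 0.05) + 0.01, event = 1)
  uni <- univariate_cox(expr, surv)
  frac <- mean(uni$p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("BH adjustment matches the step-up oracle and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::local_seed(8)
  for (rep in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p))
    expect_equal(q, stats::p.adjust(p, "BH"))
    expect_true(all(q >= p & q <= 1))
  }
})
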