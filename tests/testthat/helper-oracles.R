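# Independent oracles used across the suite.  These are deliberately naive
# (double loops, enumeration) and share no code with the package internals.

# Breslow log partial likelihood, straight from the definition:
# sum over events of [eta_i - log(sum_{j: t_j >= t_i} exp(eta_j))].
naive_breslow_loglik <- function(X, time, status, beta) {
  X <- as.matrix(X)
  eta <- as.numeric(X %*% beta)
  ll <- 0
  for (i in seq_along(time)) {
    if (status[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + eta[i] - log(sum(exp(eta[risk])))
    }
  }
  ll
}

# 1-D maximizer of the Breslow log partial likelihood by golden-section /
# grid search through stats::optimize.
oracle_fit_1d <- function(x, time, status, lower = -15, upper = 15) {
  stats::optimize(function(b) naive_breslow_loglik(cbind(x), time, status, b),
                  interval = c(lower, upper), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Benjamini-Hochberg step-up, computed per element from the textbook
# formula q_(i) = min_{j >= i} min(1, n p_(j) / j).
brute_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (rank_i in seq_len(n)) {
    vals <- vapply(rank_i:n, function(j) min(1, n * p[ord[j]] / j), 0)
    q[ord[rank_i]] <- min(vals)
  }
  q
}

# Hypergeometric upper tail P(X >= k) by direct enumeration of overlaps.
brute_hyper_tail <- function(N, K, n, k) {
  ks <- max(0, k):min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# All-pairs shortest-path hop counts by repeated relaxation (Floyd-Warshall).
brute_distances <- function(nodes, edge_df) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (r in seq_len(nrow(edge_df))) {
    a <- edge_df$from[r]; b <- edge_df$to[r]
    d[a, b] <- 1; d[b, a] <- 1
  }
  for (k in nodes) d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

# Random connected-ish simple graph as an edge data frame.
random_edge_df <- function(n_nodes, p_edge = 0.12) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  # ensure no isolated graph-breaking degenerate case: chain backbone
  backbone <- cbind(nodes[-n_nodes], nodes[-1])
  edges <- rbind(pairs[keep, , drop = FALSE], backbone)
  data.frame(from = edges[, 1], to = edges[, 2])
}

# Small random survival dataset for Cox oracle checks.
random_cox_data <- function(n, p = 1, tied = FALSE) {
  x <- matrix(rnorm(n * p), ncol = p,
              dimnames = list(NULL, paste0("V", seq_len(p))))
  time <- if (tied) sample(1:4, n, replace = TRUE) + 0.5 else rexp(n, 0.2) + 0.01
  event <- rbinom(n, 1, 0.8)
  if (sum(event) == 0) event[sample(n, 1)] <- 1
  list(x = x, surv = data.frame(time = time, event = event))
}

# Union-find merge of gene sets on the shares-a-gene relation.
brute_merge <- function(sets) {
  n <- length(sets)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && length(intersect(sets[[i]], sets[[j]])) > 0) {
      parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  unname(split(seq_len(n), roots))
}

# Write a small expression tibble + survival for IO tests.
write_expr_tsv <- function(df, path) {
  readr::write_tsv(df, path)
  path
}
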