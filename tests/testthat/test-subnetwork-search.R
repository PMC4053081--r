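# Small labelled dataset builders ------------------------------------------

path_net <- function(labels) {
  ppi_network(data.frame(from = labels[-length(labels)], to = labels[-1]))
}

expr_for <- function(genes, n, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                dimnames = list(genes, sprintf("S%03d", seq_len(n))))
    dplyr::bind_cols(tibble::tibble(gene = genes),
                     tibble::as_tibble(as.data.frame(m)))
  })
}

surv_for <- function(expr, coef = numeric(0), seed = 2) {
  generate_survival(expr, coef, censoring_rate = 0.01, random_seed = seed)
}

test_that("candidate pools honour graph distance computed on the full network", {
  net <- path_net(c("A", "B", "C", "D", "E"))
  expr <- expr_for(c("A", "B", "C", "D", "E"), 10)
  expect_setequal(candidate_pool(net, expr, "A", 3), c("A", "B", "C", "D"))

  # C unmeasured: still a conduit, so D (distance 3 via C) stays in the pool
  expr2 <- expr[expr$gene != "C", ]
  expect_setequal(candidate_pool(net, expr2, "A", 3), c("A", "B", "D"))

  expr3 <- expr[expr$gene == "A", ]
  expect_setequal(candidate_pool(net, expr3, "A", 3), "A")
  expect_error(candidate_pool(net, expr3, "E", 3), "expression")
})

test_that("a degenerate pool returns the seed alone at its univariate P", {
  net <- path_net(c("A", "B"))
  expr <- expr_for(c("A", "B"), 40)
  surv <- surv_for(expr)
  sn <- grow_subnetwork("A", pool = "A", net = net, expr = expr, surv = surv)
  expect_equal(sn$genes, "A")
  uni <- univariate_cox(expr, surv)
  expect_equal(sn$p_multivariate, uni$p[uni$gene == "A"], tolerance = 1e-10)
})

test_that("reported subnetworks satisfy their structural invariants", {
  d <- generate_dataset(n_nodes = 120, n_samples = 100, random_seed = 5)
  expr <- suppressWarnings(standardize_expression(d$expression))
  cfg <- search_config(alpha_adjusted = 1)  # report everything
  res <- suppressMessages(search_subnetworks(d$network, expr, d$survival, cfg))
  expect_gt(nrow(res$results), 0)
  uni <- univariate_cox(expr, d$survival)
  for (sn in res$subnetworks[seq_len(min(25, length(res$subnetworks)))]) {
    expect_true(sn$seed %in% sn$genes)
    expect_true(is_connected_genes(d$network, sn$genes))
    expect_lte(sn$n_genes, cfg$max_size)
    hood <- neighborhood(d$network, sn$seed, cfg$k)
    expect_true(all(sn$genes %in% hood))
    expect_lte(sn$p_multivariate,
               uni$p[uni$gene == sn$seed] + 1e-12)
    expect_gte(sn$p_adjusted, sn$p_multivariate - 1e-12)
    # reported P is the minimum over the growth path
    expect_equal(sn$p_multivariate, min(sn$path$p))
  }
})

test_that("exhaustive enumeration never scores worse than the greedy path", {
  withr::local_seed(17)
  for (rep in 1:5) {
    d <- generate_dataset(n_nodes = 30, mean_degree = 3, n_samples = 60,
                          module_size = 3, beta = 0.6,
                          random_seed = 100 + rep)
    expr <- suppressWarnings(standardize_expression(d$expression))
    cfg <- search_config(max_size = 3, alpha_adjusted = 1)
    seed_gene <- d$planted_genes[1]
    greedy <- suppressMessages(grow_subnetwork(seed_gene, net = d$network,
      expr = expr, surv = d$survival, config = cfg, method = "greedy"))
    exhaust <- suppressMessages(grow_subnetwork(seed_gene, net = d$network,
      expr = expr, surv = d$survival, config = cfg, method = "exhaustive"))
    expect_lte(exhaust$p_multivariate, greedy$p_multivariate + 1e-12)
    expect_true(is_connected_genes(d$network, exhaust$genes))
  }
})

test_that("the search is deterministic for a fixed configuration", {
  d <- generate_dataset(n_nodes = 80, n_samples = 80, random_seed = 9)
  expr <- suppressWarnings(standardize_expression(d$expression))
  r1 <- suppressMessages(search_subnetworks(d$network, expr, d$survival))
  r2 <- suppressMessages(search_subnetworks(d$network, expr, d$survival))
  expect_identical(r1$results, r2$results)
  expect_identical(r1$seed_table, r2$seed_table)
})

test_that("twin seeds in duplicated disconnected components score identically", {
  labels1 <- c("A1", "B1", "C1")
  labels2 <- c("A2", "B2", "C2")
  net <- ppi_network(data.frame(from = c("A1", "B1", "A2", "B2"),
                                to = c("B1", "C1", "B2", "C2")))
  base <- expr_for(labels1, 50, seed = 3)
  twin <- base
  twin$gene <- labels2
  expr <- dplyr::bind_rows(base, twin)
  surv <- surv_for(expr, seed = 4)
  cfg <- search_config(alpha_adjusted = 1)
  res <- suppressMessages(search_subnetworks(net, expr, surv, cfg))
  tab <- res$seed_table
  for (i in 1:3) {
    expect_equal(tab$p_multivariate[tab$seed == labels1[i]],
                 tab$p_multivariate[tab$seed == labels2[i]],
                 tolerance = 1e-10)
  }
})

test_that("a planted prognostic module is found with P below the seed-only P", {
  d <- generate_dataset(random_seed = 7)
  expr <- suppressWarnings(standardize_expression(d$expression))
  seed_gene <- d$planted_genes[1]
  sn <- suppressMessages(grow_subnetwork(seed_gene, net = d$network,
                                         expr = expr, surv = d$survival))
  overlap <- length(intersect(sn$genes, d$planted_genes))
  expect_gt(overlap, 0)
  expect_lt(sn$p_multivariate, sn$univariate_p[[seed_gene]])
})

test_that("subnetwork statistics summarise counts and means, handling empties", {
  tbl <- tibble::tibble(n_genes = c(4L, 6L), n_edges = c(3L, 5L))
  expect_equal(subnetwork_stats(tbl),
               tibble::tibble(n_subnetworks = 2L, mean_genes = 5, mean_edges = 4))
  empty <- subnetwork_stats(tbl[0, ])
  expect_equal(empty$n_subnetworks, 0L)
  expect_equal(empty$mean_genes, 0)
  one <- subnetwork_stats(tbl[1, ])
  expect_equal(one$mean_genes, 4)
})
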