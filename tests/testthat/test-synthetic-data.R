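test_that("network generation is reproducible and hits the degree target", {
  n1 <- generate_network(100, 4, random_seed = 3)
  n2 <- generate_network(100, 4, random_seed = 3)
  expect_identical(n1$edges, n2$edges)

  realized <- 2 * nrow(n1$edges) / length(n1$nodes)
  expect_lt(abs(realized - 4) / 4, 0.2)

  er <- sapply(1:10, function(s)
    nrow(generate_network(50, 2, "erdos_renyi", random_seed = s)$edges))
  expect_lt(abs(mean(er) - 50), 8)
})

test_that("preferential attachment yields heavy-tailed degrees", {
  ratios <- sapply(1:20, function(s) {
    net <- generate_network(120, 4, "preferential_attachment", random_seed = s)
    deg <- igraph::degree(net$graph)
    max(deg) / mean(deg)
  })
  expect_true(all(ratios >= 2))
})

test_that("planted modules are connected subgraphs of the requested size", {
  net <- generate_network(60, 3, random_seed = 12)
  for (s in 1:25) {
    mod <- plant_module(net, 5, random_seed = s)
    expect_length(mod, 5)
    expect_true(is_connected_genes(net, mod))
  }
  expect_length(plant_module(net, 1, random_seed = 1), 1)

  path5 <- ppi_network(data.frame(from = paste0("P", 1:4), to = paste0("P", 2:5)))
  expect_setequal(plant_module(path5, 5, random_seed = 2), paste0("P", 1:5))
  expect_error(plant_module(path5, 9), "component")
})

test_that("module expression has the requested correlation structure", {
  net <- generate_network(40, 3, random_seed = 6)
  mod <- plant_module(net, 5, random_seed = 6)
  e <- generate_expression(net, 2000, mod, within_module_corr = 0.5,
                           random_seed = 6)
  m <- as.matrix(e[-1])
  rownames(m) <- e$gene
  cors <- cor(t(m[mod, ]))
  mean_pair <- mean(cors[upper.tri(cors)])
  expect_gt(mean_pair, 0.4)
  expect_lt(mean_pair, 0.6)

  # marginals stay standard normal
  expect_lt(max(abs(rowMeans(m))), 0.1)
  expect_lt(max(abs(apply(m, 1, sd) - 1)), 0.1)

  e0 <- generate_expression(net, 500, mod, within_module_corr = 0,
                            random_seed = 7)
  m0 <- as.matrix(e0[-1]); rownames(m0) <- e0$gene
  c0 <- cor(t(m0[mod, ]))
  expect_lt(max(abs(c0[upper.tri(c0)])), 0.2)
})

test_that("survival times follow the proportional-hazards generator", {
  net <- generate_network(20, 3, random_seed = 8)
  e <- generate_expression(net, 2000, random_seed = 8)

  s0 <- generate_survival(e, baseline_hazard = 0.05, censoring_rate = 0,
                          max_followup = 1e6, random_seed = 9)
  expect_true(all(s0$event == 1))
  expect_lt(abs(median(s0$time) - log(2) / 0.05) / (log(2) / 0.05), 0.15)

  g <- e$gene[1]
  s1 <- generate_survival(e, setNames(1, g), censoring_rate = 0,
                          max_followup = 1e6, random_seed = 10)
  x <- as.numeric(e[e$gene == g, -1])
  hi <- s1$time[x >= quantile(x, 0.75)]
  lo <- s1$time[x <= quantile(x, 0.25)]
  expect_lt(mean(hi), mean(lo))
})

test_that("recovery metrics implement precision/recall/F1", {
  expect_equal(recovery_metrics(c("A", "B"), c("A", "B")),
               tibble::tibble(precision = 1, recall = 1, f1 = 1))
  expect_equal(recovery_metrics(c("X"), c("A", "B"))$f1, 0)
  r <- recovery_metrics(c("A", "B", "C", "X"), c("A", "B", "C", "D", "E"))
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.6)
  expect_equal(r$f1, 2 * 0.75 * 0.6 / 1.35)
})

test_that("full datasets are deterministic in every component", {
  d1 <- generate_dataset(n_nodes = 50, n_samples = 30, random_seed = 4)
  d2 <- generate_dataset(n_nodes = 50, n_samples = 30, random_seed = 4)
  expect_identical(d1$network$edges, d2$network$edges)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$survival, d2$survival)
  expect_identical(d1$planted_genes, d2$planted_genes)
  expect_true(is_connected_genes(d1$network, d1$planted_genes))
  expect_identical(names(d1$coefficients), d1$planted_genes)
})

test_that("fitting the true module covariates recovers the coefficients", {
  d <- generate_dataset(n_nodes = 50, n_samples = 1000, beta = 0.5,
                        random_seed = 21)
  m <- as.matrix(d$expression[-1])
  rownames(m) <- d$expression$gene
  fit <- cox_fit(t(m[d$planted_genes, ]),
                 data.frame(time = d$survival$time, event = d$survival$event))
  expect_true(fit$converged)
  bias <- mean(abs(fit$beta - 0.5))
  expect_lte(bias, 0.1)
})
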