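make_expr <- function(genes, m) {
  dplyr::bind_cols(tibble::tibble(gene = genes),
                   tibble::as_tibble(as.data.frame(m)))
}

test_that("expression TSV loads with labels, missing-value policy and id checks", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tS1\tS2", "g1\t1\t2", "g2\t3\t4", "g3\t5\t6"), f)
  e <- read_expression(f)
  expect_equal(e$gene, c("G1", "G2", "G3"))
  expect_equal(names(e), c("gene", "S1", "S2"))
  expect_equal(e$S2, c(2, 4, 6))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tS1\tS2", "g1\t1\tNA", "g2\t3\t4"), f2)
  expect_message(e2 <- read_expression(f2), "Dropped 1")
  expect_equal(e2$gene, "G2")
  e3 <- read_expression(f2, missing = "impute")
  expect_equal(e3$S2[1], 1)  # row mean of remaining value

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tS1\tS1", "g1\t1\t2"), f3)
  expect_error(read_expression(f3), "Duplicate sample")
})

test_that("GEO series-matrix style metadata lines are skipped", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("!Series_title\tfoo", "id\tS1\tS2", "g1\t1\t2"), f)
  e <- read_expression(f)
  expect_equal(dim(e), c(1L, 3L))
})

test_that("probe collapsing averages probes per gene and keeps sample order", {
  e <- make_expr(c("P1", "P2", "P3"),
                 matrix(c(1, 3, 10, 2, 4, 20), ncol = 2,
                        dimnames = list(NULL, c("S1", "S2"))))
  map <- data.frame(probe = c("P1", "P2", "P3"), gene = c("G", "G", "H"))
  out <- collapse_probes(e, map)
  expect_equal(out$gene, c("G", "H"))
  expect_equal(out$S1, c(2, 10))
  expect_equal(out$S2, c(3, 20))
  expect_equal(names(out), c("gene", "S1", "S2"))

  # unmapped probes dropped with a message; identity pass-through otherwise
  map2 <- data.frame(probe = c("P1", "P2"), gene = c("G1", "G2"))
  expect_message(out2 <- collapse_probes(e, map2), "Dropped 1 probe")
  expect_equal(out2$S1, c(1, 3))
  expect_error(collapse_probes(e, data.frame(probe = "QQ", gene = "G")),
               "No probe")
})

test_that("standardization gives mean 0 / sd 1 rows and is idempotent", {
  e <- make_expr(c("A", "B"),
                 matrix(c(1, 5, 2, 5, 3, 5), ncol = 3,
                        dimnames = list(NULL, c("S1", "S2", "S3"))))
  expect_warning(z <- standardize_expression(e), "zero-variance")
  expect_equal(z$gene, "A")
  expect_equal(as.numeric(z[1, -1]), c(-1, 0, 1))
  z2 <- standardize_expression(z)
  expect_equal(as.numeric(z2[1, -1]), as.numeric(z[1, -1]), tolerance = 1e-12)
  expect_error(standardize_expression(make_expr("A", matrix(1, 1, 1,
    dimnames = list(NULL, "S1")))), "at least 2")
})

test_that("survival table validation catches bad times and events", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\ttime\tevent", "S1\t12.5\t1", "S2\t3\t0"), f)
  s <- read_survival(f)
  expect_equal(s$time, c(12.5, 3))
  expect_equal(s$event, c(1, 0))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("S1\t-1\t0"), f2)
  expect_error(read_survival(f2), "S1")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("S1\t5\t2"), f3)
  expect_error(read_survival(f3), "0 or 1")
})

test_that("sample alignment restricts both sources to shared samples in one order", {
  e <- make_expr("G1", matrix(1:3, 1, dimnames = list(NULL, c("S1", "S2", "S3"))))
  s <- tibble::tibble(sample = c("S4", "S3", "S2"), time = c(1, 2, 3),
                      event = c(1, 0, 1))
  al <- suppressMessages(align_samples(e, s))
  expect_equal(setdiff(names(al$expression), "gene"), al$survival$sample)
  expect_equal(al$survival$sample, c("S2", "S3"))
  expect_equal(al$survival$time, c(3, 2))
  expect_equal(as.numeric(al$expression[1, -1]), c(2, 3))

  s_disjoint <- tibble::tibble(sample = c("X1", "X2"), time = c(1, 2),
                               event = c(1, 1))
  expect_error(align_samples(e, s_disjoint), "Fewer than 2")
})
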