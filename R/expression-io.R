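#' Read an expression matrix from TSV
#'
#' Expects a tab-separated table with a header row of sample identifiers and
#' a first column of feature identifiers (probes or gene symbols), i.e.
#' features x samples.  Lines starting with `!` (GEO series-matrix metadata)
#' are skipped, so the table body of a series-matrix file loads directly.
#' Rows containing any missing or non-numeric value are handled by
#' `missing`: dropped (default, with a message) or mean-imputed within the
#' row.
#'
#' @param path Path to the TSV file.
#' @param missing Policy for rows with missing values: `"drop"` or `"impute"`.
#' @return A tibble with first column `gene` (character feature ids,
#'   uppercased) followed by one numeric column per sample.
#' @export
read_expression <- function(path, missing = c("drop", "impute")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tbl <- readr::read_tsv(path, comment = "!", show_col_types = FALSE,
                         na = c("", "NA", "null", "NULL"),
                         name_repair = "minimal")
  if (ncol(tbl) < 2L) abort("Expression table needs a feature column and >= 1 sample column.")
  sample_ids <- names(tbl)[-1L]
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("Duplicate sample id(s): %s",
                  paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  vals <- suppressWarnings(
    lapply(tbl[-1L], function(col) as.numeric(as.character(col)))
  )
  m <- do.call(cbind, vals)
  gene <- normalize_symbols(tbl[[1L]])
  if (anyDuplicated(gene)) {
    abort(sprintf("Duplicate feature id(s): %s",
                  paste(unique(gene[duplicated(gene)])[1:3], collapse = ", ")))
  }
  bad <- !stats::complete.cases(m)
  if (any(bad)) {
    if (missing == "drop") {
      inform(sprintf("Dropped %d row(s) with missing values.", sum(bad)))
      m <- m[!bad, , drop = FALSE]
      gene <- gene[!bad]
    } else {
      m[bad, ] <- t(apply(m[bad, , drop = FALSE], 1L, function(r) {
        r[is.na(r)] <- mean(r, na.rm = TRUE)
        r
      }))
    }
  }
  if (nrow(m) == 0L) abort("No complete expression rows after applying the missing-value policy.")
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- sample_ids
  dplyr::bind_cols(tibble::tibble(gene = gene), out)
}

# Convert an expression tibble (gene column + numeric sample columns) to a
# genes x samples numeric matrix with dimnames.
expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), "gene" %in% names(expr))
  m <- as.matrix(expr[setdiff(names(expr), "gene")])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene
  m
}

expr_from_matrix <- function(m) {
  dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                   tibble::as_tibble(as.data.frame(m)))
}

#' Collapse probe-level rows to gene level by averaging
#'
#' Each gene's value in each sample is the arithmetic mean of all of its
#' probes' intensities in that sample.  Probes without a mapping are dropped
#' with a message.
#'
#' @param expr Probe-level expression tibble (`gene` column holds probe ids).
#' @param probe_map Data frame with columns `probe` and `gene` (or first two
#'   columns in that order).
#' @return Gene-level expression tibble, genes sorted alphabetically.
#' @export
collapse_probes <- function(expr, probe_map) {
  if (!is.data.frame(probe_map) || ncol(probe_map) < 2L) {
    abort("`probe_map` must be a data frame with probe and gene columns.")
  }
  map <- tibble::tibble(probe = normalize_symbols(probe_map[[1L]]),
                        gene = normalize_symbols(probe_map[[2L]]))
  m <- expr_matrix(expr)
  idx <- match(rownames(m), map$probe)
  unmapped <- is.na(idx)
  if (all(unmapped)) abort("No probe in the expression table has a gene mapping.")
  if (any(unmapped)) {
    inform(sprintf("Dropped %d probe(s) without a gene mapping.", sum(unmapped)))
  }
  m <- m[!unmapped, , drop = FALSE]
  gene <- map$gene[idx[!unmapped]]
  collapsed <- rowsum(m, group = gene) / as.vector(table(gene)[sort(unique(gene))])
  expr_from_matrix(collapsed[sort(rownames(collapsed)), , drop = FALSE])
}

#' Standardize each gene row to mean 0, sd 1
#'
#' Uses the sample standard deviation (denominator n - 1).  Zero-variance
#' rows carry no information for a proportional-hazards fit and are dropped
#' with a warning.
#'
#' @param expr Expression tibble.
#' @return Expression tibble with each remaining row standardized.
#' @export
standardize_expression <- function(expr) {
  m <- expr_matrix(expr)
  if (ncol(m) < 2L) abort("Standardization needs at least 2 samples.")
  sds <- apply(m, 1L, sd)
  zero <- sds == 0 | is.na(sds)
  if (any(zero)) {
    warn(sprintf("Dropped %d zero-variance row(s): %s", sum(zero),
                 paste(head(rownames(m)[zero], 5L), collapse = ", ")))
    m <- m[!zero, , drop = FALSE]
    sds <- sds[!zero]
  }
  if (nrow(m) == 0L) abort("All rows had zero variance.")
  expr_from_matrix((m - rowMeans(m)) / sds)
}

#' Apply log2 transformation to expression values
#'
#' Convenience preprocessing step for intensity-scale data: `log2(x + offset)`.
#'
#' @param expr Expression tibble.
#' @param offset Pseudo-value added before taking logs (default 1).
#' @return Transformed expression tibble.
#' @export
log2_transform <- function(expr, offset = 1) {
  m <- expr_matrix(expr)
  if (any(m + offset <= 0)) abort("log2 transform requires all values + offset > 0.")
  expr_from_matrix(log2(m + offset))
}

#' Read a clinical survival table
#'
#' Expects three tab-separated columns: sample id, follow-up time in months,
#' and event indicator (1 = death observed, 0 = right-censored).  A header
#' row is detected when the time field of the first line is non-numeric.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `sample`, `time`, `event`.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 3L) abort("Survival table needs 3 columns: sample, time, event.")
  if (is.na(suppressWarnings(as.numeric(raw[[2L]][1L])))) raw <- raw[-1L, ]
  out <- tibble::tibble(sample = as.character(raw[[1L]]),
                        time = as.numeric(raw[[2L]]),
                        event = as.numeric(raw[[3L]]))
  validate_survival(out)
}

validate_survival <- function(surv) {
  if (!all(c("sample", "time", "event") %in% names(surv))) {
    abort("Survival data must have columns `sample`, `time`, `event`.")
  }
  if (anyDuplicated(surv$sample)) abort("Duplicate sample ids in survival data.")
  if (any(is.na(surv$time)) || any(surv$time <= 0)) {
    bad <- surv$sample[is.na(surv$time) | surv$time <= 0]
    abort(sprintf("Non-positive or missing follow-up time for sample(s): %s",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  if (!all(surv$event %in% c(0, 1))) {
    bad <- surv$sample[!surv$event %in% c(0, 1)]
    abort(sprintf("Event indicator must be 0 or 1; offending sample(s): %s",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  tibble::as_tibble(surv)
}

#' Restrict expression and survival data to their shared samples
#'
#' Both objects are subset to the samples present in each and reordered to a
#' single canonical (sorted) sample order.  Numbers of dropped samples are
#' reported.
#'
#' @param expr Expression tibble.
#' @param surv Survival tibble (`sample`, `time`, `event`).
#' @return List with elements `expression` and `survival`.
#' @export
align_samples <- function(expr, surv) {
  surv <- validate_survival(surv)
  expr_samples <- setdiff(names(expr), "gene")
  shared <- sort(intersect(expr_samples, surv$sample))
  if (length(shared) < 2L) abort("Fewer than 2 samples are shared between expression and survival data.")
  d_expr <- length(expr_samples) - length(shared)
  d_surv <- nrow(surv) - length(shared)
  if (d_expr > 0L || d_surv > 0L) {
    inform(sprintf("align_samples: dropped %d expression and %d survival sample(s) without a match.",
                   d_expr, d_surv))
  }
  list(expression = expr[c("gene", shared)],
       survival = surv[match(shared, surv$sample), ])
}
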