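#' Example: top survival-related subnetworks from an HCC cohort
#'
#' The five top-ranked survival-related subnetworks identified by a
#' published network analysis of an 80-patient hepatocellular carcinoma
#' expression cohort, bundled as a worked example for [merge_modules()]:
#' chemokine-receptor subnetworks (seeds CCR7 and CCR6) and a BAT3
#' subnetwork overlap through FBLN2 and related extracellular-matrix genes,
#' while the BSG and SCP2 subnetworks share a CAV1-centred signalling core,
#' so merging yields two larger functional modules.
#'
#' @return Tibble with one row per member gene: `rank` (subnetwork rank),
#'   `gene`, `univariate_p` (single-gene Cox P value), and
#'   `subnetwork_adjusted_p` (the subnetwork's FDR-adjusted multivariate
#'   Cox P value).
#' @examples
#' subnets <- hcc_example_subnetworks()
#' sets <- split(subnets$gene, subnets$rank)
#' merge_modules(sets)
#' @export
hcc_example_subnetworks <- function() {
  path <- system.file("extdata", "hcc_top5_subnetworks.tsv", package = "netsurv")
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(rank = "i", gene = "c",
                                          univariate_p = "d",
                                          subnetwork_adjusted_p = "d"))
}
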