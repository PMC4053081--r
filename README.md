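# netsurv

Network-based discovery of survival-related subnetworks in
protein–protein interaction (PPI) graphs.

Tumour expression cohorts screened gene-by-gene against survival produce
hundreds of isolated hits with no mechanistic structure.  `netsurv`
implements the network alternative: every PPI node with matched
expression becomes a *seed*, a candidate gene set is grown outward from
the seed under two topological constraints — every member within
shortest-path distance *k* of the seed, and the member set connected in
the PPI graph — and each candidate set is scored as a whole by a
multivariate Cox proportional-hazards model,

  h(t | x) = h0(t) · exp(βᵀx),

via the global Wald statistic W = β̂ᵀ I(β̂) β̂ ~ χ²_p.  Growth is greedy:
each step fits every adjacency-eligible candidate and adopts the one with
the smallest Wald P, and the member set with the minimum P along the
growth path is reported for that seed.  Per-seed minimum P values are
Benjamini–Hochberg adjusted across seeds and subnetworks passing adjusted
P ≤ 0.001 are reported, ranked.  The Cox machinery (Newton–Raphson on the
Breslow/Efron partial likelihood, observed information, Wald testing) is
implemented from scratch in a C++ core and cross-checked against
independent oracles in the test suite.

The package also provides the conventional comparator (univariate Cox
screen + hypergeometric gene-set over-representation on user-supplied GMT
collections), merging of overlapping subnetworks into functional modules,
SIF/GraphML export, broom-style `tidy()`/`glance()` methods,
ggplot2-based plots, and a synthetic-data generator that plants a
prognostic connected module so the entire pipeline is testable without
any downloads.

## Worked example

A synthetic 300-gene interaction network with a planted 5-gene prognostic
module (log hazard ratio 0.8 per gene, 200 samples, ~30% censoring):

```r
library(netsurv)

d <- generate_dataset(random_seed = 42)
d$planted_genes
#> [1] "G019" "G044" "G051" "G081" "G147"

expr <- standardize_expression(d$expression)
res  <- search_subnetworks(d$network, expr, d$survival)
glance(res)
#> # A tibble: 1 × 6
#>   n_seeds n_subnetworks mean_genes mean_edges n_skipped_fits alpha_adjusted
#>     <int>         <int>      <dbl>      <dbl>          <int>          <dbl>
#> 1     300           177       7.45       6.47              0          0.001

head(tidy(res)[, c("rank", "seed", "genes", "n_genes", "p_multivariate", "p_adjusted")], 5)
#> # A tibble: 5 × 6
#>    rank seed  genes                    n_genes p_multivariate p_adjusted
#>   <int> <chr> <chr>                      <int>          <dbl>      <dbl>
#> 1     1 G147  G147,G044,G081,G051,G019       5       1.39e-38   8.32e-37
#> 2     2 G051  G051,G044,G019,G081,G147       5       1.39e-38   8.32e-37
#> 3     3 G044  G044,G019,G081,G051,G147       5       1.39e-38   8.32e-37
#> 4     4 G081  G081,G044,G019,G051,G147       5       1.39e-38   8.32e-37
#> 5     5 G019  G019,G044,G081,G051,G147       5       1.39e-38   8.32e-37

recovery_metrics(res$subnetworks[[1]]$genes, d$planted_genes)
#> # A tibble: 1 × 3
#>   precision recall    f1
#>       <dbl>  <dbl> <dbl>
#> 1         1      1     1
```

Every seed lying inside the planted module recovers exactly the planted
gene set (all five report the identical minimum-P model, hence the tied
ranks); 300 seeds were searched and the per-seed minima FDR-adjusted.
`autoplot(res)` draws the significance ranking, `plot_growth_path()` the
P-value trajectory of one subnetwork, and `merge_modules(res)` collapses
overlapping subnetworks into functional modules.  For file-based work,
`run_pipeline(pipeline_config(...))` reads edge-list/expression/survival
TSVs and writes `subnetworks.tsv`, `univariate.tsv`, `modules.tsv`,
optional `enrichment.tsv`, and SIF/GraphML exports;
`inst/cli/netsurv.R` wraps the same calls for shell use.

A worked module-merging example on real published data is bundled: the
five top-ranked survival subnetworks from a hepatocellular-carcinoma
cohort (`hcc_example_subnetworks()`) merge into exactly two functional
modules — an extracellular-matrix/chemokine module (subnetworks 1, 2, 4
share FBLN2) and a CAV1-centred cell-death module (3 and 5).

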