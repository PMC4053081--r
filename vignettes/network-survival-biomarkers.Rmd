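---
title: "Network-based survival biomarker discovery with netsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based survival biomarker discovery with netsurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsurv)
```

## The problem

Univariate survival screens of tumour expression data produce long, flat
gene lists: hundreds of genes pass `P < 0.05`, with no indication of how
they work together, and gene-set enrichment on such lists names broad
categories rather than concrete, testable signalling routes.  `netsurv`
implements the complementary network strategy: restrict attention to gene
groups that form *connected subnetworks* of a protein–protein interaction
(PPI) graph, score each candidate group as a whole with a multivariate Cox
proportional-hazards model, and report, per seed protein, the
connectivity-constrained group most strongly associated with survival.
The output is a short ranked list of compact subnetworks — a handful of
interacting genes each — rather than hundreds of isolated hits.

## The model

For sample $s$ with covariate row $x_s$ (the expression of the current
gene set), the Cox model assumes a hazard

$$h(t \mid x_s) = h_0(t)\, e^{\beta^\top x_s},$$

with $h_0$ unspecified.  Coefficients are estimated by maximizing the log
partial likelihood; tied event times use the Breslow approximation by
default (Efron available via `ties = "efron"`).  Writing $I(\hat\beta)$
for the observed information at the optimum, the **global Wald statistic**

$$W = \hat\beta^\top I(\hat\beta)\, \hat\beta \sim \chi^2_p
\quad \text{under } H_0 : \beta = 0$$

gives one P value for the whole gene set — exactly what a subnetwork
ranking needs.  The fitter is a from-scratch Newton–Raphson on the partial
likelihood (C++ core), cross-checked in the test suite against
`survival::coxph` and against a naive 1-D likelihood maximization.

The "significance of each predictor's hazard" is genuinely ambiguous
between per-coefficient and joint testing; `netsurv` takes the **global**
test as the subnetwork score because ranking and FDR adjustment need a
single P value per subnetwork, and exposes per-coefficient Wald P values
through `tidy()` for reporting.

## The search

For every network node with an expression row (a *seed*):

1. **Candidate pool** — all genes within shortest-path distance
   `k` (default 3) of the seed *on the full network*, filtered to those
   with expression.  Distances are unweighted hop counts (PPI edges carry
   no weights); an unmeasured gene still acts as a conduit, it just cannot
   become a member.
2. **Greedy growth** — start from the seed alone; at each step fit the
   multivariate Cox model for every pool gene *adjacent to the current
   member set* and adopt the candidate with the smallest global Wald P.
   Stop when no candidate strictly lowers P (by at least
   `min_improvement`, default 0), the pool is exhausted, `max_size`
   (default 10) is reached, or the saturation guard trips.  Because genes
   are only ever added adjacent to the current set, connectivity is
   guaranteed by construction.
3. **Min-P reporting** — the member set attaining the minimum P anywhere
   along the growth path is reported, so the reported P never exceeds the
   seed-only P.
4. **FDR across seeds** — the per-seed minimum P values are adjusted by
   Benjamini–Hochberg across all seeds, and subnetworks with adjusted
   P at most `alpha_adjusted` (default 0.001) are reported, ranked by
   adjusted then raw P.

Exhaustively enumerating every connected subset is exponential; greedy
forward growth is the tractable reading of "stepwise variable selection"
and an exhaustive mode (`method = "exhaustive"`, practical for
`max_size <= 4`) exists purely as a test oracle — the suite checks it
never scores worse than the greedy path.

```{r search-example}
d <- generate_dataset(random_seed = 7)
expr <- suppressWarnings(standardize_expression(d$expression))
res <- search_subnetworks(d$network, expr, d$survival)
glance(res)
head(tidy(res), 3)
```

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `k` | 3 | maximum hop distance from seed defining the pool |
| `max_size` | 10 | genes per subnetwork; with ~80-sample cohorts larger multivariate fits are not supportable |
| `alpha_adjusted` | 0.001 | reporting threshold on BH-adjusted subnetwork P |
| `min_improvement` | 0 | required P decrease per growth step (0 = any strict decrease) |
| `ties` | breslow | partial-likelihood tie handling |
| `max_covariate_frac` | 1/3 | saturation guard: fit only while `p < n_events/3` |

Per-gene z-scoring (`standardize_expression()`) is recommended before
fitting: hazard ratios then read per expression SD and Newton–Raphson is
better conditioned.  Time is in months throughout; no unit conversion is
attempted.

## What the synthetic generator emulates

`generate_dataset()` produces the benchmark condition used throughout the
validation suite:

* **network** — a 300-gene preferential-attachment graph with mean degree
  4 (PPI degree distributions are heavy-tailed; an Erdős–Rényi option
  exists for contrast);
* **planted module** — a uniformly seeded random *connected* 5-gene
  subgraph;
* **expression** — all genes marginally standard normal; module genes
  share a latent factor giving pairwise correlation
  `within_module_corr = 0.3`, a typical co-expression level for
  interacting proteins;
* **survival** — event times with hazard
  $h_0 \exp(\sum_g \beta_g x_{gs})$, $\beta_g = 0.8$ per module gene,
  exponential baseline $h_0 = 0.05$/month (≈14-month baseline median,
  a plausible advanced-HCC scale; Weibull shape available), independent
  exponential censoring at 0.008/month truncated at 120 months of
  follow-up.  The censoring rate was fixed once so that roughly 30% of
  samples are censored under this condition.

It deliberately does **not** model microarray probe effects, batch
structure, missingness patterns, or hazard non-proportionality.  Passing
the recovery benchmark therefore shows the search machinery works when
the modelling assumptions hold; it does not certify behaviour on real
cohort data, where effect sizes are smaller and the proportional-hazards
assumption is itself in question.

## Numerical choices

* **Convergence** — Newton–Raphson with step-halving stops when the score
  max-norm falls below `1e-8` *or* the relative log-likelihood change
  falls below `1e-9` (the `coxph` criterion).  The second criterion is
  needed because for some datasets the absolute gradient tolerance sits
  below the floating-point noise floor of the likelihood even though the
  coefficients are correct to seven digits.  A step that cannot improve
  the likelihood at floating-point resolution, with a well-conditioned
  information matrix, is likewise treated as converged.
* **Non-convergence is data, not error** — constant or collinear
  covariates and ill-conditioned information (reciprocal condition number
  below `1e-10`) flag the fit `converged = FALSE`; such seeds score
  P = 1 and such candidates are skipped (never treated as P = 1
  additions).
* **Monotone likelihood** — a covariate whose ordering aligns perfectly
  with the death order has its partial-likelihood maximum at infinity;
  the fitter then stalls at a large finite coefficient exactly as
  `coxph` does.
* **Tie-breaking** — when two candidates give equal P after rounding to
  12 *significant* digits, the lexicographically smallest gene symbol is
  adopted, making the whole search deterministic.  (Rounding to 12
  *decimal places* would collapse every P below 1e-12 to zero and derail
  growth precisely where the signal is strongest.)
* **Degenerate inputs** — zero-variance expression rows are dropped before
  standardization; an all-censored cohort is loadable but refuses to fit;
  empty result lists produce zero-valued summaries rather than errors.

## The null behaviour of min-P selection

The per-seed minimum P is a minimum over many correlated candidate
models, and no correction for that selection is applied — the reported
subnetwork P is the P of the *selected* model, exactly as in the original
procedure.  Under a pure null this makes the per-seed minima
stochastically much smaller than uniform: each greedy step adopts the
best of several adjacent candidates, so the global Wald statistic grows
faster than its degrees of freedom.  Two practical consequences, both
visible in the validation suite:

* at the benchmark null condition (300 genes, 200 samples, all
  coefficients zero) growth usually stalls after a few steps and the
  BH gate at 0.001 admits nothing — but the outcome is knife-edge: once a
  few seeds' minima cross the step-up line the BH cascade can admit tens
  of seeds at once, so null discovery counts vary wildly between seeds;
* in smaller cohorts (e.g. 80 samples) the per-step Wald
  anti-conservatism compounds and the selection effect is *stronger*,
  routinely driving per-seed minima below 1e-6.

Interpret reported subnetwork P values as ranking scores, not calibrated
error rates; `min_improvement > 0` blunts (but does not remove) the
effect.  The FDR adjustment controls selection *across seeds* only, not
the within-seed search.

## Enrichment comparator and module merging

`univariate_cox()` + `select_survival_genes()` reproduce the conventional
screen (default `P < 0.05`), and `hypergeom_enrich()` tests any GMT
collection by the one-sided hypergeometric over-representation test with
BH FDR.  No gene-set database ships with the package: term membership is
database-version-dependent, so the collection and, ideally, the explicit
universe (all assayed genes) are user inputs.  `merge_modules()` joins
subnetworks that share at least one gene into larger functional modules
(connected components of the overlap relation), mirroring how genes
belonging to several subnetworks knit them together; a Jaccard threshold
is available for stricter merging.  On the bundled example of five
published HCC subnetworks this yields exactly two modules — an
extracellular-matrix/chemokine module and a CAV1-centred cell-death
module:

```{r merge-example}
subnets <- hcc_example_subnetworks()
merge_modules(split(subnets$gene, subnets$rank))
```

## Validation problem sizes

The test suite and `scripts/acceptance.R` work at deliberately modest
scales chosen to exercise every code path while keeping the whole suite
fast: 50 small datasets (n ≤ 12) for the 1-D likelihood oracle, 2000
null replicates at n = 80 for Wald calibration, 100 random graphs
(≤ 50 nodes) for the neighbourhood oracle, 20 benchmark simulations for
planted-module recovery, 5 null runs for specificity, and n = 1000 for
coefficient recovery.  All expected values are computed by independent
oracles (naive likelihood code, brute-force enumeration, closed forms),
never copied from the implementation under test.

## Known limitations

* Greedy growth can miss a better non-nested subnetwork (the exhaustive
  oracle exists only for tiny sizes).
* Subnetwork P values are selection-biased (see above); permutation-based
  calibration is out of scope.
* No penalized or stratified Cox, no time-varying covariates, no
  proportional-hazards diagnostics.
* Probe-level preprocessing is limited to mean-collapsing plus optional
  log2/z-scoring; raw-intensity normalization (e.g. RMA) must happen
  upstream.
* Overlapping subnetworks from different seeds are reported as-is; no
  deduplication before the FDR step.
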