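---
title: "Signal mining for FAERS-style spontaneous report data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal mining for FAERS-style spontaneous report data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous reporting systems such as FAERS collect safety reports in which a
reporter names one or more suspect drugs and one or more adverse-event
preferred terms (PTs). Disproportionality analysis asks whether a drug-event
pair is reported more often than the rest of the database would predict.
`pvsignal` implements the pipeline used in statin hepatotoxicity
pharmacovigilance: ingest the quarterly ASCII extracts, keep one record per
case, restrict to reports where a statin is the Primary Suspect (PS), flag
reports whose reactions fall in an SMQ-style hepatic-disorder PT set, and
score drug-event pairs with two statistics - the reporting odds ratio (ROR)
and the Multi-item Gamma Poisson Shrinker (MGPS) empirical-Bayes geometric
mean (EBGM).

## Data model and ingestion

The package fixes the post-2012Q4 FAERS dialect: `$`-delimited, unquoted,
header-first ASCII tables (DEMO, DRUG, REAC, OUTC), joined on `primaryid`.
Legacy LAERS layouts are out of scope; two decades of the study window are
dominated by the current schema. Parsing never silently drops data: rows
violating a table invariant (unparseable receipt date, empty PT, outcome
code outside the seven FAERS codes) are quarantined and counted in an audit
attribute, and satellite rows whose `primaryid` has no DEMO entry are counted
as orphans. PT strings are upper-cased and trimmed before any comparison
because FAERS mixes cases across quarters.

## Deduplication

FAERS cases are resubmitted as new versions under one `caseid`.
`deduplicate_cases()` keeps, per case, the version with the latest FDA
receipt date, breaking ties by the numerically largest `primaryid` - the
FDA-recommended convention. The output is sorted by `caseid`, making the
result independent of input order; the operation is idempotent and conserves
counts (`input = kept + removed + quarantined`). Cross-`caseid` probabilistic
record linkage (the same patient reported under two caseids) is deliberately
not attempted.

## Cohort and event set

Drug names are matched against a synonym lexicon (generic names, brands,
salt forms) by exact lookup after trimming and case-folding - no substring
matching, since verbatims like "LIPITOR 10MG" need curation, not guessing.
Synonym sets must be pairwise disjoint; violations abort at load.
Cerivastatin, withdrawn in 2001, is excluded by omission from the lexicon.

A case with two distinct PS statins is counted under each statin in per-drug
tables and once in class-level tables; both choices are visible in the
annotation table so neither is hidden in aggregation.

The hepatic event set is the deduplicated union of a narrow and a broad
PT list, with all four sizes (narrow, broad, intersection, union) logged at
construction - a union can never be smaller than either input list, so
logging the sizes makes the set's provenance auditable. MedDRA is licensed;
the packaged list is a synthetic stand-in (`hepatic_smq_synthetic.csv`)
covering drug-induced liver injury, hepatitis variants, cholestatic
syndromes and liver laboratory abnormalities. A real SMQ export drops in as
the same two-column CSV.

## Contingency counting

The counting unit is the case, not the reaction row: a report listing three
matching PTs contributes one to `a` and one to each cell count `N`. The
comparator is the full remaining database (all non-target reports in the
ingested universe). Expected counts assume row/column independence,
`E = (row margin * column margin) / grand total`, computed over the complete
drug-by-PT grid so that `sum(E) = sum(N)` exactly. Stratified expectation
(summing E within strata) is available but off by default, matching the
unstratified construction of the published drug-level tables.

## Reporting odds ratio

For a 2x2 table, `ROR = (a d)/(b c)`, with the Woolf log-scale standard
error `sqrt(1/a + 1/b + 1/c + 1/d)` and `CI = exp(log ROR +/- z se)`. The
interval is log-symmetric, so the geometric mean of the bounds reproduces
the point estimate - a property the package exposes as `ror_from_ci()` and
uses to check published tables for internal consistency. Zero cells make
the estimate undefined; the result is flagged invalid rather than
continuity-corrected, because the positivity rule already requires at least
three co-reports. A Haldane 0.5 correction is available behind a flag for
exploratory work.

## MGPS / EBGM

The observed count of a cell is modelled as `N ~ Poisson(lambda E)` with a
two-component gamma prior (shape/rate) on the relative reporting rate
`lambda`:

```
lambda ~ P Gamma(alpha1, beta1) + (1 - P) Gamma(alpha2, beta2)
```

Marginally `N` follows a mixture of negative binomials; the five
hyperparameters are estimated by maximizing the summed marginal
log-likelihood over all cells of the grid. The posterior for a cell is again
a gamma mixture with updated parameters `(alpha_j + N, beta_j + E)` and
weight `Q` given by the posterior odds of the two negative-binomial terms.

* `EBGM = exp(E[log lambda])`, evaluated in closed form with the digamma
  function.
* `EBGM05`/`EBGM95` are the posterior 5th/95th percentiles, found by
  bracketed root finding on the mixture CDF. The root is solved on the
  log-lambda scale: with a posterior shape below 1 the 5th percentile can be
  orders of magnitude below 1, and an absolute-x tolerance would lose all
  relative precision there. The component quantiles bracket the root.

Numerical choices: the optimizer is multi-start L-BFGS-B on log-transformed
parameters (logit for `P`), starting from the classic `(0.2, 0.1, 2, 4,
1/3)` initialization plus deterministically jittered variants, because the
mixture likelihood is multimodal; convergence tolerance is below 1e-8
relative. Likelihood terms are combined in log space. Optional cell
squashing aggregates identical `(N, binned E)` cells with multiplicity
weights - the same likelihood with fewer terms - and reproduces the
unsquashed optimum (verified in the tests); it is off by default. A
degenerate input (a single cell) returns a diffuse prior flagged
`converged = FALSE` rather than crashing.

The test suite validates the closed forms against an independent adaptive
quadrature oracle that integrates the unnormalized posterior density
(prior times Poisson likelihood) on the log-lambda scale, sharing none of
the negative-binomial/digamma/root-finding code paths, with agreement to
1e-6 on a 200-point grid of `(N, E, theta)`.

## Positivity rules

A drug-event pair is ROR-positive when the co-report count is at least 3
and the 95% CI lower bound exceeds 1; EBGM-positive when EBGM05 exceeds 2.
The three-report minimum is read as `a >= 3` (the conventional reading of
the rule); a strict `a > 3` variant sits behind a configuration switch. The
two flags are always reported side by side rather than merged.

## The synthetic generator

`simulate_faers()` emulates the study population so every stage is testable
without the 21-million-record corpus: one PS drug per case (a statin with
probability `statin_share = 0.25` by default, uniform over the seven),
Poisson-distributed extra reactions (mean 1.2 beyond the guaranteed first),
mixed sex/age/reporter/outcome categories at realistic FAERS-like
proportions, receipt dates uniform over 2004-01-01 to 2024-03-31, and
versioned duplicates (`duplicate_rate = 0.08`) with strictly later receipt
dates and occasionally mutated sex, which is what makes the deduplication
rule observable. Ages are emitted under mixed unit codes (70% years, 15%
months, 10% decades, 5% days) to force the unit-conversion path.

Baseline PT probabilities are a long-tailed Dirichlet draw (concentration
0.5), mimicking spontaneous-report sparsity - most PTs are rare, which is
the regime where EBGM shrinkage matters. Named PTs can be pinned to fixed
baseline probabilities via `pt_weights`; planted pairs `(drug, pt, lambda)`
multiply the pinned weight by `lambda` inside the cases whose PS is that
drug. Pinning is what makes the expected planted cell count a controlled
study condition (the recovery experiments pin the planted PT at 0.008 so
that a lambda of 5 yields an expected count comfortably above 20 at 12,000
cases).

Determinism: a single `set.seed()` at the top of generation plus a fixed
draw order makes identical `(config, seed)` produce byte-identical files
and truth manifests on any platform running the same R version.

What the generator does **not** emulate: co-medication structure beyond
random concomitant rows, verbatim free-text noise beyond the lexicon's
synonym list, MedDRA hierarchy above PT level, reporting-rate drift over
calendar time, and correlated demographics. Passing recovery tests
therefore demonstrate the pipeline's correctness on clean FAERS-shaped
data, not robustness to real-world coding noise.

## Problem sizes used in the checks

The packaged experiments run at desk scale, chosen to keep each suite deep
but quick: recovery uses 20 seeds of 12,000 cases with the planted pair at
`lambda = 5` (accepting a point estimate within +/-40% of truth in at least
90% of seeds); null calibration uses 20 seeds of 3,000 cases and requires
under 10% of drug-PT cells flagged; hyperparameter recovery refits on
50,000 simulated cells and must reach the generating parameters' marginal
log-likelihood within 1.0 (a likelihood criterion rather than a parameter
criterion, since the mixture is only weakly identified). The headline counts
of the full-corpus study (14,511 hepatic cases, 148 positive PT signals,
the published drug-level RORs) are functions of the complete 21M-record
database and the licensed MedDRA dictionary, and are therefore validated
through the published-table arithmetic instead: yearly totals, percentage
shares, fatality proportions, Woolf log-symmetry of printed intervals, and
the dual positivity classification of the printed drug rows.

## Known limitations

* The dedup key is `caseid` with the latest-date/largest-id rule; fuzzy
  duplicate detection across caseids is out of scope.
* The full-database comparator includes the other statins in `c`/`d`; an
  active-comparator design is not implemented.
* EBGM at desk scale shrinks hard: with only a few thousand cells the
  fitted prior concentrates near the null, so EBGM05 rarely exceeds 2
  unless a signal is strong - the planted-recovery criteria use ROR for
  point-estimate accuracy for exactly this reason.
* PRR, IC/BCPNN and regression-based signal methods are intentionally not
  provided.

## A worked example

```{r example, eval = FALSE}
pt <- "DRUG-INDUCED LIVER INJURY"
cfg <- sim_config(
  n_cases = 12000, seed = 1, duplicate_rate = 0.05,
  planted_rr = data.frame(drug = "atorvastatin", pt = pt, lambda = 5),
  pt_weights = c("DRUG-INDUCED LIVER INJURY" = 0.008)
)
sim <- simulate_faers(cfg)
run <- run_pipeline(data = sim$data, config = pipeline_config(squash = TRUE))
run
top_signals(run$signals, k = 5)
heatmap_matrix(run$signals, "ror")[, 1:5]
```
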