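---
title: "Combined embryo-recipient metabolite biomarkers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined embryo-recipient metabolite biomarkers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After in vitro production, a bovine embryo is cultured singly for 24 h
(Day-6 to Day-7), vitrified, and transferred to a recipient heifer. Whether
the pregnancy holds to Day-40, Day-62 and birth depends on both partners:
the embryo (whose secretions accumulate in the spent culture medium, CM)
and the recipient (whose plasma reflects her metabolic readiness). This
package implements a discovery-and-validation workflow for metabolite
biomarkers measured by GC-MS in both compartments, and in particular a
rule-based *combined* biomarker: one embryo metabolite OR-combined with one
recipient metabolite, scored by F1 against the pregnancy outcome.

The workflow operates on quantified tables (samples x metabolites, either
internal-standard response ratios or absolute concentrations) plus a
per-transfer metadata table. Because studies of this design are small
(tens of transfers) and their raw data typically non-public, the package
ships a synthetic cohort generator with the same structure, so every stage
is testable end to end.

## The synthetic cohort generator

`cohort_config()` / `generate_cohort()` emulate a discovery cohort of 36
embryo transfers: a 36 x 37 CM matrix, 35 x 71 Day-0 plasma (one sample
uncollected) and 36 x 71 Day-7 plasma, recipient breeds AV 13 / Holstein
17 / crossbred 6, a Day-6 stage per embryo (morula or early blastocyst),
and nested binary outcomes at three endpoints.
`generate_validation_cohort()` produces the independent 19-transfer
Holstein cohort in absolute units.

Modelling choices, each made once:

* **Concentrations are lognormal, parameterised on the log2 scale.**
  A metabolite's log2-concentration is a per-metabolite baseline (drawn
  uniformly over `baseline_log2_range`, default 6-14, spanning response
  ratios of ~100 to ~16,000) plus group shifts plus Gaussian noise with
  `noise_sdlog` (default 1, log2 units). Group effects are log2 fold
  changes (open/pregnant), applied to the open group. Keeping effects and
  noise on the same log scale gives the clean closed form
  AUC = pnorm(effect / (sd * sqrt(2))): a planted log2FC of 2 with unit
  noise yields a theoretical AUC of 0.921, which the generator reproduces
  empirically (a property test checks it within +/- 0.03).
* **Outcomes follow a Markov chain** over endpoints (Day-40, then Day-62
  given Day-40, then birth given Day-62; defaults 0.65 / 0.9 / 0.9), so the
  nesting birth => Day-62 => Day-40 holds by construction and the default
  marginal group sizes land near the published-style denominators
  (roughly 23/21/19 pregnancies of 36). `fixed_outcome_counts` instead
  fixes the exact counts per endpoint (still nested), which is how the
  recovery benchmarks reproduce a known 17-open / 19-pregnant split at
  birth: with binomially drawn outcomes the occasional unbalanced cohort
  dominates the failure modes of downstream power measurements.
* **Named random substreams.** Every matrix column draws from a substream
  keyed by (root seed, stream, compartment, metabolite), via a small
  32-bit FNV-1a hash kept below 2^31. Identical configuration and seed
  give bitwise-identical cohorts; adding metabolites never perturbs
  existing columns; the validation cohort uses a disjoint stream of the
  same root seed.
* **Breed effects** can be injected into Day-0 plasma only
  (`breed_effect_d0`), mirroring the observation that recipient breed
  separates Day-0 plasma but not CM or Day-7 plasma.
* **Missingness** is limited to dropping `missing_day0` whole Day-0 rows
  (uncollected samples), chosen uniformly and recorded in the cohort log.

What the generator does **not** emulate: correlation among metabolites
(columns are independent; real panels are strongly correlated, so the
effective number of independent tests in real data is smaller than the
panel size), batch/run-order effects, censoring at the detection limit,
heteroscedastic instrument noise, and any association between Day-6 stage
or breed and the outcome. Passing tests on these cohorts therefore
demonstrate correctness of the *procedures*, not expected performance on
real data.

## Univariate candidate screen

`screen_matrix()` tests each metabolite against the open/pregnant outcome
at one endpoint. The parametric/nonparametric choice is gated per
metabolite: Shapiro-Wilk on the within-group residuals of both groups at
alpha = 0.05; one-way ANOVA only if neither group rejects normality,
otherwise Kruskal-Wallis (`choose_test()`). The same test is applied to
the bull-breed and Day-6-stage factors separately (one-way per factor; no
multi-factor model is fitted, matching the per-factor reporting style of
this literature). Multiplicity control is Bonferroni by default (the
stricter choice), Benjamini-Hochberg by option; a metabolite is a
*candidate* when both raw and adjusted p fall below alpha.

The fold change is defined as `log2(mean(open) / mean(pregnant))` —
positive when concentrations are higher in recipients that failed the
endpoint. Gross outliers are removed by a leave-one-out rule: a value
exceeding `threshold_fold` (default 100) times the mean of the others is
dropped and logged, never silently. Metabolites that are constant,
all-missing, or leave a group under 3 observations are skipped with a
logged warning.

## Single-biomarker ROC evaluation

`roc_auc()` uses the rank (Mann-Whitney) formulation with ties counted
one half; orientation is auto-detected (some biomarkers rise, others fall
in pregnant animals) and the reported AUC is always >= 0.5 with the
direction recorded. `optimal_cutoff()` scans midpoints of adjacent
distinct values plus the infinities and picks the threshold closest (in
Euclidean distance) to the perfect-classification corner; ties break by
maximal Youden J, then by the lower threshold. `bootstrap_ci()` is a
stratified percentile bootstrap (default B = 1000, seeded) with the
orientation fixed by the full sample, so small overlapping groups produce
intervals that straddle 0.5 rather than being folded above it. The
selection rule for a single biomarker is AUC > 0.650 together with a
Welch t-test p < 0.05 on the untransformed concentrations (pooled-variance
by option).

## The combined-biomarker F1 procedure

For each metabolite, the *pregnant range* is the inclusive [min, max] of
the pregnant group's concentrations in the cohort being scored (a
percentile-trimmed variant is available via `trim`). `boolean_calls()`
marks samples inside the range; `combine_or()` joins an embryo call
vector with a recipient call vector by logical OR — a sample is predicted
pregnant when *either* compartment places it in its pregnant range.
Missing member calls remove the sample from scoring. With pregnancy as
the positive class, `f1_score()` is 2TP / (2TP + FP + FN), printed to
three decimals with half-up rounding.

Significance comes from a Mantel-Haenszel chi-square over calls x outcome
tables (`mh_chi_square()`), with a 0.5 continuity correction (toggleable).
Two variance conventions exist for this statistic; the package defaults to
the Cochran form (margins product / N^3), under which the single-stratum
statistic reduces *exactly* to the Yates-corrected 2x2 chi-square — a
property the test suite verifies to 1e-12 — while the classical
hypergeometric form (/ N^2 (N-1), as in `stats::mantelhaen.test`) is
available via `variance = "hypergeometric"` and is cross-checked against
`mantelhaen.test` in the tests. Strata with a zero margin carry no
information and are dropped with a record.

`score_pair()` supports two modes. *Aggregate* derives one range per
member over the pooled cohort and tests a single stratum. *Stratified*
(`stratified_b_m`) re-derives ranges, calls and confusion within each
Day-6 embryonic stage, pools the confusions for F1 and the correct-call
count, and tests across the stage strata; re-deriving per-stage ranges
(rather than sharing pooled ones, available via `shared_range`) is the
point of stratifying — morulae and blastocysts occupy different
concentration regimes. Stage strata with fewer than 2 pregnant samples
cannot support a range and are dropped with a record.

The *ND rule*: a pair is "not determined" when its combined correct-call
count (TP + TN) falls below the best of its members taken singly; ND rows
withhold F1 and p from the primary report (the audit keeps the numbers).

One structural consequence deserves emphasis. When ranges are refit in
the cohort being scored and data are complete, every pregnant sample lies
inside its own group's min/max range, so FN = 0 for each member and for
the pair; the pair's correct calls are then n_pregnant plus the open
samples outside *both* ranges — never more than either member alone. Under
the refit policy the ND rule therefore withholds a pair unless both
members exclude exactly the same open samples. Pairs can genuinely beat
their members only where FN > 0 arises: frozen ranges carried into an
independent cohort, missing member values, or trimmed ranges. The
benchmark and validation reports make this visible rather than hiding it.

`score_all_pairs()` scans the Cartesian product of candidate CM and
plasma metabolites over the requested plasma days, ranked by F1 then p.
The scan is vectorised (matrix cross-products of complemented call
matrices) and verified against the per-pair route by a property test; a
full 37 x 71 x 2-day scan takes milliseconds, which is what makes the
null benchmarks cheap.

## Validation in an independent cohort

`validate_pairs()` re-scores selected pairs in a second cohort, reporting
the stratified and aggregate modes side by side, each with its own ND
flag. The default range policy refits pregnant ranges within the
validation cohort: the discovery data are semi-quantitative response
ratios while targeted validation is absolute, so numeric cutoffs cannot
transfer across units — refitting is the unit-coherent reading, and it is
invariant to affine rescaling of the validation matrix (a tested
property). The frozen policy (`frozen_from_discovery`) carries discovery
ranges over, refuses to run across a unit mismatch, and is the setting in
which the OR-combination can genuinely recover pregnant samples missed by
one member. Metabolites absent from the validation panel are flagged
`not_measured`; a configurable below-LOD filter (exclude when more than
half the values sit under a declared detection limit) guards members
measured near the limit.

## Pipeline and benchmarks

`run_discovery()` applies the breed-block strategy: CM screened as one
aggregate cohort, plasma within the AV and Holstein blocks, crossbred
recipients excluded from plasma analyses with the count logged; pair
members qualify via the Bonferroni screen, the single-biomarker rule, or
either (default). Stage-stratified pair scoring runs only in the Holstein
block — the smaller AV block's stage strata are too thin to support
per-stage pregnant ranges. Every exclusion (uncollected sample, crossbred,
outlier, below-LOD) appears in a log with counts; outputs carry the
configuration hash.

`run_benchmark()` characterises the procedure by simulation. The null
scenario measures the screen's per-metabolite type-I error (the gated
rank test is slightly conservative at these group sizes), the family-wise
error after Bonferroni, and — deliberately — the *selection inflation* of
the pair scan: the distribution of the maximum F1 over all pairs and how
often the best pair's MH p falls under 0.05, which materially exceeds the
nominal 5% because ~2,600 pairs were searched. The planted scenario
measures recovery of a known CM x plasma pair. Replicate counts used by
the shipped tests and the acceptance script (200 null, 100 planted, 100
generalization-gap replicates) were chosen to keep Monte-Carlo error
small relative to the bands being checked while the whole suite stays in
the low minutes on one CPU.

## Numerical and degenerate-input conventions

* Range membership is inclusive at both ends; a constant pregnant group
  gives a degenerate [c, c] range where only exact matches call true.
* Cutoff and corner-distance ties break deterministically (Youden J, then
  lower threshold); floating-point ties use a 1e-12 tolerance.
* The continuity-corrected MH deviation is clamped at zero (as
  `chisq.test` does; `mantelhaen.test` does not clamp — the conventions
  differ only where the statistic is uninformative).
* F1 with TP + FP + FN = 0 is undefined and reported as an ND-style null.
* Errors are classed (`bovipreg_config_error`, `bovipreg_data_error`) so
  callers and the pipeline can distinguish configuration mistakes from
  statistical degeneracy.

## Known limitations

* Independence across metabolites in the generator overstates the
  multiplicity burden relative to correlated real panels.
* The printed fold-change convention of published tables in this area is
  not always recoverable from printed group means; this package defines
  FCh as log2 of the open/pregnant mean ratio and reports it alongside
  any externally supplied value rather than guessing a provenance.
* Per-class correct counts are computed at the closest-to-corner cutoff;
  a Youden-optimal convention would differ on some data sets.
* The refit range policy's ND behaviour (above) means combined pairs
  rarely out-count their members within a single cohort; conclusions
  about "combination beats singles" should rest on frozen-range
  validation or on metrics other than the correct-call count.
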