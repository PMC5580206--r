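---
title: "Methods: concept-mapping development and validation of a referral decision tool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concept-mapping development and validation of a referral decision tool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(dtpd)
```

`dtpd` implements the full statistical pipeline behind a seven-criterion
referral decision tool for patients with personality disorders: the group
concept-mapping analytics by which the criteria were derived from expert
card sorts, the sum-score-plus-gate scoring rule itself, and the
multi-centre validation analytics. No raw study data are deposited anywhere,
so the package ships seeded generators that emulate both the expert sorting
study and the patient cohort; every analysis stage can therefore be
exercised, tested and benchmarked end to end on data whose ground truth is
known.

## 1. Concept mapping

### Similarity and dissimilarity

Each of the $S$ sorters partitions the full set of $N$ items (candidate
criteria) into piles of their own design. The co-sort count $c_{ij}$ is the
number of sorters who put items $i$ and $j$ in the same pile
(`build_similarity()`). Sorts that carry no pairwise information — all items
in one pile, or every item alone — are flagged invalid by
`sorter_validity()` and excluded by default, mirroring the practice of
dropping incorrectly executed sorts.

The mapping stage needs dissimilarities. The concept-mapping literature the
procedure descends from does not fix a transform, so the package uses

$$\delta_{ij} = \frac{S - c_{ij}}{S},$$

the share of sorters who did *not* co-pile the pair: bounded in $[0,1]$,
zero for always-co-piled pairs, and linear in the only quantity the sorts
measure. Only the rank order of $\delta$ matters downstream, so any strictly
monotone alternative would give the same embedding.

### Nonmetric scaling and stress

`embed_map()` places the items in the plane so that the rank order of map
distances matches the rank order of $\delta$ as well as possible. Fit is
measured by Kruskal's stress-1,

$$\sigma_1 = \sqrt{\frac{\sum_{i<j} (d_{ij} - \hat d_{ij})^2}
                        {\sum_{i<j} d_{ij}^2}},$$

where $\hat d$ are disparities from least-squares monotone regression of
the distances on the order of $\delta$ (pool-adjacent-violators, via
`stats::isoreg`). Ties in $\delta$ are handled by the primary approach: tied
dissimilarities are free to receive unequal disparities, implemented by
pre-sorting tie blocks by current distance. In concept mapping, stress
between roughly 0.20 and 0.35 is conventionally read as a reasonable fit;
`stress1()` is exported so any configuration can be re-scored.

Optimisation is SMACOF-style iterative majorization: alternate the monotone
regression (optimal disparities given distances) with a Guttman transform
(optimal coordinates given disparities). Each half step is an exact
minimiser, so the recorded stress trace is non-increasing; the iteration
stops when the decrease falls below `tol` ($10^{-10}$) or at the first
numerical non-decrease, whichever comes first. The stress surface is
multimodal, so the optimiser restarts from `n_starts = 8` random
configurations derived from one seed and keeps the lowest-stress solution.
Eight starts is a compromise: on simulated sorting studies of the default
scale the best of 8 starts is stable to the third decimal, while the cost
stays a few seconds.

Degenerate inputs are refused rather than guessed at: fewer than 3 items,
or a constant dissimilarity matrix (every pair equally dissimilar carries
no ordinal information).

### Cluster ladder

`cluster_ladder()` applies agglomerative hierarchical clustering with Ward
linkage (`ward.D2`) to the 2-D coordinates — not to the raw similarities —
because the cluster step of the concept-mapping tradition operates on the
map. It reports the whole ladder from `k_max = 15` down to `k_min = 2`, one
merge per step, so each coarser partition nests the finer one. The package
deliberately does **not** choose "the" number of clusters: in the original
procedure that is a judgement call by the expert panel, informed by
diagnostics the package does provide (`pile_count_summary()`, bridging per
solution).

### Bridging values

For item $i$,

$$b_i = \frac{\sum_{j \ne i} c_{ij} d_{ij}}{\sum_{j \ne i} c_{ij}},$$

the co-sort-weighted mean map distance: low when the sorters who grouped
the item did so with items that landed nearby (a coherent cluster member),
high when the item "bridges" distant map regions. Raw values are min–max
normalised to $[0,1]$ across items. Two edge cases are handled explicitly:
if every raw value is equal the normalisation is degenerate and all items
report 0; an item never co-piled with any other has no defined value and is
flagged (`defined = FALSE`) rather than silently zeroed. The original
software's exact formula is not published; this one is isolated behind
`bridging_values()` precisely so an alternative could be swapped in without
touching anything else.

### Ratings and sorter reliability

`rating_summary()` averages the 1–6 importance ratings to item level, then
to cluster level, and runs all $k(k-1)/2$ pairwise two-sample t-tests on
the item-level means with a Bonferroni-corrected threshold
$\alpha / \binom{k}{2}$ — for $k = 6$ clusters that is $0.05/15 \approx
0.0033$, the conventional "p < 0.003". Welch's unequal-variance test is the
default (`var_equal = FALSE`); the pooled test is available since the
historical analysis may have used either, and on item-level means the two
rarely disagree.

`sorter_reliability()` correlates each sorter's binary co-pile matrix
(vectorised upper triangle) with the group count matrix. The group matrix
is computed **leave-one-out** by default: correlating a sorter with a total
that includes their own sort inflates the correlation, and with ~20 sorters
the inflation is material. `include_self = TRUE` restores the
total-matrix variant for comparability with reports that used it. The
per-sorter correlations are averaged and optionally stepped up by
Spearman–Brown, $k r / (1 + (k-1) r)$, to the reliability of the whole
panel.

## 2. The decision rule

The instrument itself is deliberately simple (`score_patients()`): count
the YES answers over seven criteria; if the count reaches the cut-off
(default 4) a gate question — possibility and motivation to conform to
minimal treatment conditions — decides, with yes *and* not-applicable
leading to referral and no blocking it; below the cut-off the gate is never
consulted. Criteria 6 and 7 admit "not applicable", which under the default
`na_policy = "as_no"` contributes nothing to the score: the score counts
positive answers only. The policy is named in the configuration so that an
alternative (e.g. rescaling the cut-off to the answered items) could be
added without changing the rule's surface. Criterion 4 dichotomizes global
functioning (GAF) at $\le 50$ — revised upward from an initial
$< 45$ after piloting — and `gaf_criterion()` performs exactly that
dichotomization when raw GAF values are on hand.

Two properties of the rule are load-bearing and tested exhaustively over
all 864 answer combinations: flipping any answer from no to yes can never
revoke a referral, and recoding NA to no on criteria 6–7 never changes any
decision.

## 3. Validation analytics

### Marginal logistic model

Clinical judgement (the referral gold standard) is regressed on the seven
criteria coded 0/1 with `fit_marginal_logistic()`. Patients are clustered
within treatment centres, so the model is estimated by generalized
estimating equations with a binomial family, logit link and exchangeable
working correlation — the "any two patients of a centre are equally
correlated" assumption. The implementation is the classic Fisher-scoring
GEE with moment estimation of the correlation parameter and scale. Standard
errors are robust, with the Mancl–DeRouen leverage correction applied
because the plain sandwich is anti-conservative with a single-digit number
of clusters (seven centres). With working independence the estimating
equations reduce exactly to maximum-likelihood logistic regression, which
the tests exploit as an oracle. Complete separation is detected up front
and reported as an error naming the problem; a single-centre dataset falls
back to ordinary logistic regression with a classed warning. NA answers
enter the design matrix as 0 — the same NA-as-no policy the scoring rule
applies — so the model and the tool always see identical data.

### ROC, cut-off table, internal consistency

The ROC scores are the model's linear predictors (`validate_tool()` wires
this up). `roc_auc()` computes the area as the Mann–Whitney concordance
with half credit for ties and a DeLong 95% interval by default (a seeded
stratified bootstrap is available); both are delegated to pROC, while the
test suite checks the concordance against an exhaustive pair loop.
`cutoff_table()` evaluates sensitivity $P(\text{score} \ge k \mid
\text{judged yes})$ and specificity $P(\text{score} < k \mid \text{judged
no})$ at every $k = 1..7$; monotonicity in $k$ is guaranteed by
construction and still asserted. `cronbach_alpha()` uses the variance form
$\frac{k}{k-1}(1 - \sum s_i^2 / s_T^2)$ with $n-1$ divisors throughout,
and `pilot_agreement()` reports, per criterion, the percentage of records
whose answer agrees with the clinical judgement (the joint-positive share
is available behind a flag, since the historical "similarity" percentage
is ambiguous between the two readings). `welch_t()` reproduces
summary-statistic group comparisons (Welch statistic, Satterthwaite df);
published group summaries are usually rounded, so recomputed statistics
can differ from printed ones in the second decimal.

## 4. What the simulators emulate — and what they do not

`simulate_sorting()` generates sorters who share one latent partition
(default: 95 items in 6 clusters, 22 sorters, matching the scale of a real
expert exercise) but apply it imperfectly: with probability 0.3 a sorter
splits a pile, with probability 0.3 merges two (granularity disagreement —
real sorters produced anywhere from 5 to 23 piles), then each item is
reassigned to a random other pile with probability `noise = 0.25`. These
defaults were fixed once, on the reasoning that experts agree on broad
structure while disagreeing on granularity and on the placement of perhaps
a quarter of individual items; they produce stress and reliability values
in the range concept-mapping studies report.

`simulate_patients()` draws the seven criterion answers as correlated
binaries through a Gaussian copula with exchangeable correlation (0.2)
thresholded at fixed marginal prevalences, then draws the clinician's
judgement from a logistic model whose coefficients default to the published
multilevel-model estimates, with Normal centre-level intercept shifts
(sd 0.3) inducing within-centre correlation. The intercept is calibrated by
bisection (deterministic fixed-seed Monte Carlo integral) so the expected
referral prevalence matches the observed 110/378 split. Criterion
prevalences (0.50, 0.45, 0.35, 0.50, 0.40, 0.45, 0.40) are the package's
own choice of plausible intake prevalences — nothing in the public record
pins them down. NA is injected at 5% on criteria 6–7 and the gate;
therapists are generated nested in centres (88 across 7) but, like the
original analysis, the model clusters by centre only.

What passing tests on these simulators do **not** show: that the published
headline numbers are recovered. They depend on the original expert sorts
and the real 368-patient cohort, neither of which is deposited; the
simulators reproduce the *structure* of those data, not their realised
values. The tests therefore check properties — oracle equivalences, known
closed forms, parameter recovery within Monte-Carlo error, monotonicities —
rather than published point estimates. Nor do the simulators model
therapist-level effects on the judgement, item non-response outside
criteria 6–7, or any dependence of the gate answer on the criteria.

## 5. Numerical choices and degenerate inputs

* Stress optimisation: descent tolerance $10^{-10}$, at most 500
  iterations per start, first non-decrease stops the trace; all-coincident
  starting configurations are nudged apart deterministically.
* Monotone regression: primary tie approach; `isoreg` does the
  pool-adjacent-violators work.
* GEE: convergence at a maximum coefficient change of $10^{-10}$, at most
  100 scoring iterations, the exchangeable parameter clamped to
  $[0, 0.95]$; divergence of the initial logistic fit (|coefficient| > 30)
  is reported as separation.
* Intercept calibration: bisection on $[-20, 10]$ to $10^{-7}$ against a
  20 000-draw fixed-seed Monte Carlo estimate of prevalence.
* Degenerate inputs error loudly and early with classed conditions
  (`dtpd_input_error`, `dtpd_degenerate_error`): empty datasets, constant
  dissimilarities, all-invalid sorters, one-class outcomes, zero total
  variance in the alpha computation, NA where the instrument forbids it.
* Every stochastic function takes an explicit `seed` and restores the
  caller's RNG state; the pipeline splits one root seed into per-stage
  seeds.

Problem sizes in the test suite are scaled to what the properties need:
oracle equivalences run on 5–10 items and a handful of sorters where
brute force is exact and instant; recovery simulations use 20 replicates
of 15–24-item studies and 100 replicates of 368-patient cohorts, sizes at
which Monte-Carlo error bounds are tight enough to be meaningful.

## 6. A worked run

```{r, eval = FALSE}
out <- run_pipeline("dtpd_run", seed = 7)
out
#> <dtpd_run_report>
#>   items/sorters: 95 / 22, stress = 0.225
#>   reliability mean r = 0.433 (Spearman-Brown 0.944)
#>   patients: 368, AUC = 0.872 (0.835-0.910), alpha = 0.502
#>   sens/spec at cutoff 4: 0.727 / 0.733
```

The numbers above are what the pipeline computes on its own synthetic
defaults (root seed 7); they sit in the ranges the method is known for —
stress in the reasonable-fit band, a sum-score rule whose cut-off-4
sensitivity/specificity land in the 0.7–0.8 range, internal consistency
moderate because the criteria deliberately cover distinct aspects of
severity rather than one narrow construct.

## 7. Known limitations

* The bridging formula is a reasoned reconstruction, not a published one;
  it is isolated so it can be replaced.
* Whether the historical reliability correlated each sorter against a
  total matrix including themselves is ambiguous; leave-one-out is the
  default here and the inclusive variant an option, so the two readings
  bracket the published value.
* The GEE is a population-averaged model; a conditional (random-intercept)
  logistic model would estimate larger coefficients under strong centre
  effects. The package follows the marginal reading of "multilevel model
  with exchangeable correlation structure", which is GEE vocabulary.
* The cohort simulator's criterion prevalences and correlation are
  assumptions; conclusions that depend on them (e.g. the exact synthetic
  AUC) should be read as structural, not empirical.
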