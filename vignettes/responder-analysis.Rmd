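---
title: "Characterising inter-individual responses in crossover dietary trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising inter-individual responses in crossover dietary trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietresponder)
```

## The problem

Dietary intervention trials usually report group means, yet individual
responses to the same food can differ enormously: in a crossover
comparison of whole blueberries, blueberry powder and a cellulose
placebo, individual percent changes in plasma nitrite can span several
hundred percent while group effects stay non-significant. This package
implements the analysis used to characterise that variation: it turns
baseline/post measurement pairs into percent-change responses across a
fixed catalogue of 52 endpoints (9 vascular, 43 cognitive test
parameters in 7 domains), classifies participants into responders (RS),
non-responders (NRS) and average responders by direction-aware quartile
division, summarises consistency across arms and endpoints, tests
covariate associations, and searches urinary LC-MS feature tables for
metabolite signatures that discriminate RS from NRS.

## The response model

For each participant, arm and endpoint with both timepoints observed,
the response is

$$r = 100 \times \frac{\text{post} - \text{baseline}}{\text{baseline}}.$$

A zero baseline leaves the response undefined; the cell becomes
`missing` and drops out of every denominator. Each endpoint carries a
direction of benefit $d \in \{+1, -1\}$ (+1 when an increase is an
improvement, as for plasma nitrite or HDL-cholesterol; -1 when a
decrease is, as for blood pressure, arterial stiffness or mental
fatigue). The *folded* response $r \cdot d$ decides the category:
positive is `improved`, negative `worsened`, and exactly zero
`no_change`.

Two modelling choices deserve a note:

* **No-change tolerance.** The tolerance is 0 by default: only exact
  ties count as no change. Continuous assays (nitrite, lipids) then
  essentially never show "no change" while discrete cognitive scores
  do, which matches how such trials report their category tables. A
  nonzero band can be passed to `categorize_response()` or
  `build_response_table()`.
* **Folding happens only at categorisation and ranking.** Stored
  responses keep their raw sign, so exported tables read naturally
  ("SBP rose 10%") and the direction ledger can be edited without
  recomputing responses.

Because the published battery does not enumerate its 43 cognitive test
parameters per domain, `default_cognitive_spec()` ships an editable
assumption (working memory 10, episodic memory 12, attention 4, alert
9, content 5, calm 2, mental fatigue 1 — mood scales contributing
Bond–Lader-style item groups), constrained to sum to 43. Directions
default to +1 for accuracy-like scores and positive moods, and -1 for
mental fatigue and for parameters designated as reaction times. Both
the counts and the reaction-time designation are arguments of
`build_default_registry()`, and a registry round-trips through a
delimited file for manual editing.

## Quartile division and RS/NRS classification

Per endpoint (within one arm), participants are ranked by folded
response, best first. The top $\lfloor n/4 \rfloor$ form Q1, the bottom
$\lfloor n/4 \rfloor$ Q4, and the remainder splits at its median into
Q2/Q3; with $n = 37$ that gives 9 participants at each extreme. Ties
are broken by participant id, which makes the assignment deterministic;
a tie that straddles the Q1 or Q4 boundary is reported, because there
the cut is substantively arbitrary.

Each participant's `n_responded` is the number of endpoints where they
sat in Q1, and `n_nonresponded` the number where they sat in Q4.
Ranking by `n_responded` and taking the top quartile yields the RS
group; ranking by `n_nonresponded` yields the NRS group. The two
rankings are independent, so in principle a participant can top both
lists (imagine someone extreme in both directions). The package
resolves such a conflict toward the larger count, demotes exact ties to
`average`, and — a deliberate design choice — refills the vacated slot
from the same ranking, so both groups keep the quartile size
$\lfloor n/4 \rfloor$ whenever enough participants exist. `backfill =
FALSE` disables the refill if strict top-list semantics are wanted.
Classification is per arm; pooled analyses can simply be run on a
response table whose `arm` column was collapsed beforehand.

Endpoints with fewer than 4 non-missing participants cannot produce a
quartile and are skipped, leaving both counts untouched.

`consistency_matrix()` assembles the participant-by-(arm, endpoint)
category matrix behind a consistency heat map and scores, per
participant, the fraction of endpoints with the same category in two
chosen arms. Under independent uniform categories over three levels the
expected agreement is 1/3, which the test suite uses as a calibration
check.

`chi_square_association()` tests gender, BMI class or visit order
against the RS/NRS label over the classified participants
($N = |RS| + |NRS|$, 18 at the default size). The statistic is the
plain Pearson $\sum (O - E)^2 / E$ — no Yates continuity correction —
so it agrees with hand computation on 2x2 tables; `correct = TRUE` is
available since conventions differ. A table with a zero margin is
degenerate and returns `NA` with a warning rather than a spurious
statistic.

## The metabolomics biomarker stage

The LC-MS stage assumes an already aligned peak table (samples by
`mz@rt` features) with pooled-QC injections and blanks. Preprocessing
follows the standard untargeted workflow:

1. **QC-RSD filter** (`qc_rsd_filter()`, default 30%): a feature whose
   relative standard deviation across pooled QC injections exceeds the
   threshold is instrument-unstable and removed. RSD uses the sample SD
   (n-1 denominator). The filter is idempotent and threshold-monotone.
2. **MAD/median filter** (`mad_filter()`): a nonparametric
   relative-variability score — unscaled median absolute deviation over
   the median, across study samples — ranks features; the least
   variable are baseline noise. The default `"auto"` rule drops a
   size-dependent fraction (5% below 250 features, 10% below 500, 25%
   below 1000, 40% above), following common practice for large
   untargeted matrices. Note that any *fraction*-based rule is not
   idempotent by construction (a second pass drops another slice);
   when idempotence matters, use the absolute
   `list(threshold = x)` rule, which is.
3. **Log transform** (`log_transform()`): base-10 logs remove
   heteroscedasticity; the pseudo-value added to accommodate zeros
   defaults to half the smallest positive intensity in the table.
4. **Autoscaling** (`autoscale()`): per-feature centring and scaling to
   unit sample SD, computed over study samples and applied to all rows,
   removes the dependence of feature ranking on average intensity.
   Constant features are dropped.

Blanks are never used for removal — they only support a carryover
diagnostic — and only positive-mode data are expected, though the
container carries a polarity tag.

Univariate discrimination uses the rank-based AUC (Mann–Whitney
$U / (n_1 n_2)$, midranks for ties) with RS-high orientation, plus a
`higher_in` flag from the mean difference. The multivariate model
(`multivariate_roc()`) repeats, from a single seed: a stratified
2/3–1/3 split; a random forest on the training fold; feature ranking by
its Gini importance; refits on the top-$k$ features for each requested
subset size (default $k \in \{5, 10, 15, 25, 50, 100\}$, with the
largest feasible size as the headline model); and accumulation of
held-out RS probabilities. Fifty repeats is the default. Pooled
per-sample probabilities give the reported AUC and the majority-vote
predictive accuracy; the 95% CI is a 1000-resample percentile bootstrap
over per-repeat AUCs. The percentile interval is not forced to contain
the point estimate. Given the same seed and input, the whole procedure
is bit-identical across runs.

`rank_discriminating_features()` merges importance, univariate AUC,
direction and class means, and reports the fraction of features more
intense in NRS. Since a usable predictive biomarker of response should
be *elevated in responders*, the RS-high features form the
candidate-predictor subset.

A caution that the test suite makes explicit: with 9 + 9 samples, the
chance level of this model has substantial *dataset-level* variance.
Repeated splits of one null table share whatever spuriously separating
features that particular draw contains, so a single table's mean
held-out AUC can sit well away from 0.5 even with exchangeable labels;
averaging over independent label permutations is needed to see the
0.5 centre. This is exactly why a modest single-study AUC with a wide
bootstrap interval should not be over-read.

## The synthetic-data generator

Participant-level data from such trials are rarely shareable, so the
generator is a first-class module rather than a test fixture. For the
trial (`simulate_trial()`):

* baselines are Normal per endpoint (clinically plausible means/SDs:
  e.g. SBP 115 ± 10 mmHg, glucose 5 ± 0.5 mmol/L, PWV 8 ± 1.2 m/s,
  cognitive scores 50 ± 10), truncated away from zero so percent change
  is always defined;
* the post value is multiplicative,
  $\text{post} = \text{baseline}(1 + \text{pct}/100)$, where the
  percent response adds the arm's mean effect, a participant latent
  responsiveness aligned with each endpoint's direction of benefit
  (weight `consistency`, default 0.3, of the response SD; correlated
  `rho`, default 0.3, between arms), independent endpoint noise, and an
  optional planted responder boost (`planted_effect_sd` response-SDs,
  default 2.5, for the first `n_planted_responders` participants in the
  planted arm);
* per-endpoint response SDs are calibrated so simulated ranges are of
  the order real trials print — nitrite around ±(100–500)%, lipids tens
  of percent, blood pressure around ±(10–30)%, mental fatigue the most
  volatile cognitive endpoint;
* default arm effects are zero except nitrite (+68.66% / +4.34% /
  -9.10% for blueberry / powder / placebo), the one endpoint where such
  interventions show a marked mean shift;
* cognitive values are rounded to integers, which is what produces
  exact baseline/post ties — and hence nonzero `no_change` proportions
  for cognitive domains but not for continuous assays.

For the feature table (`simulate_feature_table()`): log-normal
intensities; planted discriminators shifted higher in RS by
`effect_size` log-SDs; all other features given a small background
drift whose direction is higher-in-NRS with probability 0.79 (the
asymmetry such RS/NRS contrasts tend to show); QC injections scattered
around each feature's grand mean at a 10% target RSD, with a designated
subset made unstable (target RSD drawn from 50–90%) to exercise the
30% filter; blanks at 1% of the mean. Ground truth (planted responders,
planted features, unstable features, per-feature direction) is returned
alongside, so recovery sensitivity and specificity are computable
without touching simulator internals.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: ceiling/floor effects tied to
baseline health status, realistic cross-endpoint biological correlation
beyond the single latent responsiveness factor, carryover between
crossover periods, LC-MS batch drift and correlated metabolite modules,
or missingness mechanisms other than missing-at-random cells.

## Numerical choices and degenerate inputs

* Negative Friedewald LDL estimates are returned flagged, never
  clamped, preserving linearity and making data problems visible.
* The nitrite calibration fit is unweighted least squares on the linear
  scale (a log-log option exists); a numerically flat or negative slope
  warns, and interpolation outside the calibrated signal range is
  flagged as extrapolation.
* Report rounding is half-up to whole percent (`rounded = TRUE`), so
  displayed category rows can deviate from 100 by at most 1.5 points
  while unrounded rows sum to 100 exactly.
* Zero-median features rank least variable in the MAD filter (logged);
  zero-SD features are dropped at autoscaling (warned).
* Quartile and waterfall orderings break ties by participant id;
  classification is invariant to input row order.

The examples and tests run at deliberately modest sizes — the default
37 x 3 x 52 trial, feature tables of 100–500 features with 18 study
samples, 30–50 forest repeats — which the package treats as its
reference problem sizes; all of them are arguments.

## Limitations

Quartile division always labels $\lfloor n/4 \rfloor$ participants RS
and NRS: it characterises *relative* extremes and says nothing about
whether anyone responded in an absolute, clinically meaningful sense.
The classification inherits the noise of single baseline/post pairs,
and with 52 correlated endpoints the responded-count is itself noisy.
The biomarker stage, at 9 + 9 samples, is exploratory by construction:
its confidence intervals are wide and its chance level scatters between
datasets, so its outputs are hypotheses for validation in larger
cohorts, not predictors.
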