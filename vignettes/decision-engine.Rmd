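---
title: "The prostaid decision engine: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The prostaid decision engine: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostaid)
```

## The decision problem

Localized prostate cancer offers several medically equivalent options whose
differences live almost entirely in side-effect risk and practical burden.
`prostaid` formalizes the preference side of that choice. The pipeline is:
clinical profile → NCCN risk group → eligible alternatives → per-alternative
expected dollar burden → ranking. Every stage is a pure function of its
inputs, so changing a single preference and re-evaluating reproduces the
"real-time toggle" behavior of an interactive aid exactly.

## Health states and ordinal scales

Four radiation-related side effects define the patient's health state, each
on an ordered ordinal scale (best level first, later = worse):

| side effect           | instrument item | levels |
|-----------------------|-----------------|--------|
| erectile function     | EPIC (percent of attempts achieving an erection) | 100%, 75%, 50%, 25%, 0% |
| urinary incontinence  | EPIC (leakage frequency) | rarely or never … more than once a day (5) |
| nocturia              | IPSS (awakenings per night) | 0, 1, 2, 3, 4, 5+ |
| bowel incontinence    | EPIC (leakage frequency) | rarely or never … more than once a day (5) |

Only the erectile-function levels and the nocturia phrasing are fixed by
published material; the two incontinence items use the standard five-point
EPIC frequency set. The registry is configurable
(`read_scale_registry()`/`write_scale_registry()`) for deployments with
different response sets, provided each scale stays a totally ordered list.

## NCCN risk classification

`classify_nccn()` implements the NCCN rule grid with explicit precedence,
most to least severe: very-high → high → unfavorable-intermediate →
favorable-intermediate → very-low → low. Precedence matters because the
high-risk rule reads "no very-high-risk features and exactly one high-risk
feature": it is only evaluated after very-high features (cT3b–T4, primary
Gleason pattern 5, two or three high-risk features, more than 4 cores with
Grade Group 4/5) are excluded. High-risk features are cT3a, Grade Group
4–5, and PSA > 20 ng/mL; intermediate risk factors (IRFs) are cT2b–cT2c,
Grade Group 2–3, and PSA 10–20 ng/mL.

One reading choice was genuinely open: the unfavorable-intermediate row
lists "≥ 50% biopsy cores positive" and "Grade Group 3" as free-standing
bullets, which read literally would drag otherwise low-risk patients (e.g.
cT1c, GG1, PSA 5, 6/12 cores) into the intermediate tier. We scope both
bullets to the intermediate tier — patients with at least one IRF and no
high or very-high feature — which matches clinical usage and makes the rule
grid total. The boundary cases are: PSA 10 and 20 are IRFs (the low-risk
rule requires PSA < 10, the high-risk rule PSA > 20); the broad
simplification is the fixed surjection {very-low, low} → LOW,
{favorable, unfavorable} → INTERMEDIATE, {high, very-high} → HIGH.

A missing `max_single_core_involvement` is a *classification gap*, not an
assumed value: it is raised as a typed condition only when it is decisive
(a profile meeting every other very-low criterion), and the CLI maps it to
its own exit code (3) distinct from validation errors (2).

## Toxicity transition matrices

For each treatment and side effect, the conditional probabilities
`P(post = j | pre = i)` are the frequentist counts over each starting
state: `p_ij = n_ij / n_i·`. Design conventions:

* **Empty rows.** A pre level with zero observations gets the identity row
  (the state persists) and is flagged in `empty_rows`. This is
  conservative, keeps every matrix row-stochastic and usable, and mirrors
  the active-surveillance convention. Add-alpha (Laplace) smoothing is
  available (`alpha`, default 0 — no smoothing) for users who prefer
  shrinkage toward uniform over the identity convention.
* **Active surveillance** attributes no side effects: identity matrix by
  convention, so its exceedance above any threshold is the indicator that
  the *current* state already exceeds it.
* **EBRT fractionation.** The standard and hypofractionated EBRT arms
  derive from one trial, so by default the hypofractionated arm reuses the
  standard-arm matrices; per-arm matrices are honored when supplied.
* **Counts travel with probabilities** in the JSON serialization so that
  resampling-based uncertainty work remains possible later; display
  rounding is two decimals on percentages (the worked-example cell prints
  as 17.39%).

`assess_pretreatment_predictiveness()` reports Spearman's rank correlation
between pre- and post-treatment levels per treatment × side effect,
reflecting the empirical observation that motivates conditioning on the
starting state: the pre-treatment level is the best predictor of the
post-treatment level. Degenerate cells (constant levels, n < 2) are
reported as `NA` — undefined, never zero.

## Preferences and the value function

Each patient states, per side effect *s*, a maximum-tolerance threshold
`τ_s` and a dollar amount `w_s` they would have to be *paid* to live
strictly worse than `τ_s` for the rest of their life; per alternative *a*,
a burden payment `b_a` for its non-medical attributes; and a payment `w_F`
to accept biochemical failure. Willingness to *accept* (get paid) rather
than willingness to pay avoids the patient's account balance acting as a
ceiling; consequently the amounts are unbounded burden magnitudes and the
engine imposes no cap. Amounts are normalized to whole dollars.

The exceedance probability is **strict**: tolerating waking 2 times a
night means the payment applies to *more than* 2 times; the threshold
level itself costs nothing. This makes exceedance monotone nonincreasing
as the threshold relaxes toward worse, which the suite checks by
enumeration.

The linear additive value function prices alternative *a* as

    V(a) = Σ_s  Pr(post_s worse than τ_s | pre_s, a) · w_s  +  b_a
         + (1 − P_FFBF(a, risk)) · w_F

and the engine ranks eligible alternatives by ascending `V` (expected
burden; the display layer may negate for "value" presentation — the
ranking contract is what matters). Treatment success enters as an expected
failure cost so that success is simply one more additive attribute.
Whether a lifetime discounting should apply to the dollar amounts is an
open modeling question; none is applied. Ties are broken by a fixed
documented order, least-intensive treatment first (`treatment_ids()`), so
ranking is deterministic and independent of input row order.

**Success probabilities.** Five-year FFBF values are not fixed by
published material at this granularity; the default catalog ships
clearly-labelled illustrative placeholders in `inst/extdata/catalog.json`
(0.80–0.95, ordered sensibly by risk and intensity). Every quantitative
test either fixes them explicitly or is invariant to them. The eligibility
map (surveillance for LOW only; ADT-containing courses for INTERMEDIATE
and HIGH) is configuration, not code.

## The preference-space search

`find_supporting_preferences()` asks whether an alternative can be the
*unique* cost minimizer for some preference profile. With the burden lever
on, the answer is immediate — load the maximum grid burden onto every
competitor — so the interesting configuration disables the lever and
searches the documented grid: every combination of per-side-effect
thresholds (750 combinations over the four scales), crossed with
structured dollar assignments from {0, 100, 1000, 10000} (each single
attribute carrying each nonzero value alone, plus 25 seeded random grid
draws). Exceedance probabilities are precomputed per (alternative, side
effect, threshold level), so each candidate is a dot product and the full
grid runs in well under a second; any hit is re-verified through the full
ranking path before being returned. Exhaustive failure is reported
honestly (`found = FALSE`) — for a component-wise dominated alternative
the additive form admits no supporting weights, and the suite constructs
exactly that case. Uniqueness is tested with a 1e-9 margin so exact ties
(e.g. two arms sharing a matrix and success value) are not spuriously
"supported".

With default synthetic matrices and catalog, a supporting profile exists
for all seven alternatives — the engine reproduces the qualitative
finding that no treatment deterministically dominates.

## The synthetic-cohort generator

Real institutional PRO datasets are unavailable, so the generator is
first-class, tested code rather than a fixture. It emulates:

* **Cohort scale** — 150 patients per treatment arm by default, the
  magnitude of the institutional series the engine targets; each patient
  contributes one paired record per side effect.
* **Decline structure** — ground-truth matrices in which the post state
  equals the pre state with probability `diagonal` (default 0.5) and the
  remaining mass decays geometrically (rate `decay = 0.5`) over strictly
  worse states, the worst state absorbing; `diagonal = 1` gives identity
  matrices. A deterministic per-arm jitter (±0.1 on the diagonal) makes
  arms distinguishable. These defaults qualitatively match the observed
  pattern that patients tend to decline after treatment; they are study
  conditions, not tuning knobs.
* **Pre-treatment marginals** — uniform over levels by default,
  configurable per side effect.

It does **not** emulate improvement after treatment, inter-institutional
heterogeneity, dropout, time-resolved toxicity (levels are taken as the
stabilized state ≥ 1 year out) or covariate effects. Passing tests
therefore demonstrate estimator and engine correctness under the stated
generative model — not the accuracy of any real institutional table. The
single externally anchored number is the worked-example retention cell
8/46 = 17.39%; the other 38 records of that fixture are spread
10/10/9/9 over the lower levels by documented convention and no claim
attaches to those cells.

## Numerical conventions and problem sizes

* Row-stochasticity tolerance 1e-9; additive decomposition checked to
  1e-12; strict-uniqueness margin 1e-9 on dollar totals.
* Currency is serialized as integer dollars in artifacts, and JSON output
  is key-ordered and pretty-printed, so identical inputs give
  byte-identical files.
* The suite's simulation sizes: counting-oracle equivalence on 1000 random
  cohorts of 5–40 records; parameter recovery at 5000 observations per
  pre-level row over 20 replicates (max cell error < 0.05 in ≥ 95% of
  replicates), with median error monotone over arm sizes
  {150, 1000, 5000}; predictiveness checks at n = 1000; marginal recovery
  at n = 10000. These sizes make the binomial standard errors small
  relative to the asserted tolerances.

## Limitations

The engine inherits the scope of its inputs: no surgery or brachytherapy
monotherapy arms (no toxicity input data), no ADT-specific side effects
(hot flashes are not among the four modeled states), no genomics, and no
sequential or concurrent therapy modeling. Active surveillance's identity
convention understates the natural accrual of urinary and erectile
symptoms with age. The linear additive form assumes preferential
independence between attributes and risk neutrality in dollars; patients
with strongly nonlinear risk attitudes are outside the model.
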