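# prostaid

A tested engine for personalized prostate-cancer shared decision making.

Men newly diagnosed with localized prostate cancer usually face several
medically reasonable options — active surveillance and a menu of radiation
courses — with similar cure rates but very different side-effect profiles
and practical burdens. `prostaid` turns the preference-elicitation side of
that decision into reproducible computation:

1. **Risk stratification** — classify a clinical profile (T stage, Grade
   Group, PSA, biopsy-core features) into the six NCCN risk groups and
   their three-way simplification (LOW / INTERMEDIATE / HIGH), which gates
   treatment eligibility.
2. **Toxicity transition matrices** — from paired pre/post
   patient-reported-outcome (PRO) records, estimate per treatment and side
   effect the row-stochastic matrix `P(post level | pre level)` by
   frequentist counting over each starting state. Four side effects are
   modeled on ordinal scales: erectile function, urinary incontinence,
   nocturia and bowel incontinence (EPIC/IPSS items). Active surveillance
   uses the identity matrix by convention.
3. **Preferences** — per side effect, a maximum-tolerance threshold `τ_s`
   and a willingness-to-accept dollar value `w_s`; per alternative `a`, a
   non-medical burden value `b_a`; plus a failure value `w_F`.
4. **Ranking** — a linear additive value function scores each eligible
   alternative as an expected dollar burden (lower is better):

   `V(a) = Σ_s P(post_s worse than τ_s | pre_s, a) · w_s + b_a + (1 − P_FFBF(a, risk)) · w_F`

   where "worse" is strict on each ordinal scale (the threshold level
   itself is tolerated) and `P_FFBF` is the 5-year freedom from
   biochemical failure. The best alternative is the unique minimizer.

Because the institutional PRO datasets behind such tools are not public,
the package includes a first-class synthetic-cohort generator with known
ground-truth transition structure, so every estimator and the full pipeline
are testable end to end. A preference-space search
(`find_supporting_preferences()`) demonstrates the engine's central
qualitative property: with realistic matrices, **no alternative
deterministically dominates** — every treatment can be the best choice for
some set of preferences.

## Worked example

The single published anchor for the estimator is a cohort of 46 patients
with 100% potency pre-treatment, of whom 8 retain 100% potency. The package
ships it as a deterministic fixture:

```r
library(prostaid)
mats <- estimate_toxicity_matrices(fixture_fig1_cohort())
print(mats$matrix[[1]])
#> Toxicity transition matrix — SBRT / erectile_function
#> Row totals: 46, 0, 0, 0, 0
#>       post
#> pre     100%    75%    50%    25%     0%
#>   100% 17.39  21.74  21.74  19.57  19.57
#>   ...
```

`P(100% → 100%) = 8/46 = 17.39%`: only 17.39% of patients starting with
perfect erectile function retain it. Unobserved rows are identity-filled
and flagged. (Only the first-row retention cell is data-anchored; the
spread of the other 38 patients is a documented fixture convention.)

A full evaluation runs from three JSON inputs (clinical profile, current
health state, preferences) through classification, eligibility and ranking:

```r
b <- system.file("extdata", package = "prostaid")
ev <- run_evaluate(
  file.path(b, "demo_profile.json"), file.path(b, "demo_health_state.json"),
  file.path(b, "demo_preferences.json"), "evaluation.json",
  catalog_path = file.path(b, "catalog.json")
)
print(ev)
#> Decision-aid evaluation — LOW risk
#>            alternative  se_cost burden_cost failure_cost    total rank is_best
#>    active_surveillance     0.00        5000         4000  9000.00    1    TRUE
#>                   SBRT 19388.23         500         2500 22388.23    2   FALSE
#>  EBRT_hypofractionated 20038.25        1500         3500 25038.25    3   FALSE
#>          EBRT_standard 20038.25        3000         3500 26538.25    4   FALSE
#> Ineligible for this risk group: EBRT_HDR, EBRT_ADT, EBRT_HDR_ADT
```

The demo patient is very-low-risk (cT1c, Grade Group 1, PSA 6.2, 2/12
cores); for this preference profile the expected side-effect burden of any
radiation course (about $19–20k against the demo's synthetic matrices)
outweighs surveillance's higher burden and failure values, so active
surveillance ranks first. `tidy()`, `glance()` and `autoplot()` give the
tabular and graphical views (best alternative in teal, others in red).

The shipped 5-year FFBF success probabilities in `catalog.json` are
clearly-labelled illustrative placeholders — supply institutional values
for real use.

A thin command-line wrapper (`inst/cli/prostaid.R`) exposes the same
pipeline as subcommands `classify`, `build-matrices`, `evaluate`,
`search-dominance`, `simulate` and `demo`.

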