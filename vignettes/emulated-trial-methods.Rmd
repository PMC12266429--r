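---
title: "Methods: emulating a trial of SEN provision in a clustered pupil cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulating a trial of SEN provision in a clustered pupil cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The causal question and the emulated trial

Children with special educational needs (SEN) provision in English schools
differ systematically from children without it: provision is assigned
*because* of health and developmental need, so raw comparisons of
hospitalisation, absence or attainment between provision groups are
confounded by indication. `emultrial` implements the analysis of an
emulated pragmatic trial in which the "intervention" is the SEN provision
category recorded in the January census of Year 1 (None, SEN Support, or
an Education and Health Care Plan, EHCP), assignment is treated as made at
that single time point, and outcomes accumulate to the end of primary
school (Year 6). The interpretation is intention-to-treat: the effect of
the recorded assignment, not of delivered support.

Two estimands are targeted for each pairwise contrast of provision
levels:

* **ATE** — the contrast of average potential outcomes over the whole
  eligible population;
* **ATT** — the same contrast restricted to pupils actually assigned the
  exposed level.

Outcomes and effect scales follow the field's conventions: unplanned
hospital days per 1000 follow-up years and absence sessions per 1000
possible half-day sessions (rate ratios, RaR); persistent absence — 10%
or more of possible sessions missed, boundary inclusive — as a risk ratio
(RiR; the crude row of reports is an odds ratio, as is conventional);
and year-standardised KS1/KS2 mathematics z-scores as mean differences
(Δ). Hospital days on which both an A&E attendance and an admission occur
count once (set union of day sets).

## Identification and the three estimators

All three causal estimators assume consistency, no interference and no
unmeasured confounding given the covariate set; they differ in which
nuisance model carries the burden:

* **IPW** re-weights arms by the inverse of the propensity score
  \(p(X)\); ATE weights are \(1/p\) (exposed) and \(1/(1-p)\)
  (reference), ATT weights 1 and \(p/(1-p)\). Count effects are ratios of
  weighted aggregate rates, binary effects ratios of weighted means
  (risk, not odds), score effects weighted mean differences.
* **G-computation** fits the outcome model on confounders plus
  treatment, predicts both potential outcomes for every pupil, and
  averages over the estimand population. For counts the marginal rate is
  exposure-weighted by default (total predicted events over total
  exposure): on aggregate data this convention reproduces the published
  crude rate ratio, whereas the printed per-arm rates in the source
  tables appear to follow a different (pupil-mean) convention that we
  also expose as an option.
* **AIPW** combines both:
  \(\hat\psi_a = n^{-1}\sum_i \big[\tfrac{I(A_i=a)}{p_a(X_i)}(Y_i -
  m_a(X_i)) + m_a(X_i)\big]\) on the rate scale for counts (observed
  count over exposure; predicted rate), probability scale for the flag,
  raw scale for scores. It is consistent if *either* the propensity or
  the outcome model is correct (double robustness). The ATT variant
  weights reference-arm residuals by \(p/(1-p)\) with normalisation; it
  is an extension flagged as such, since published reports leave that
  cell blank. Count outcome models for AIPW default to Poisson.

Crude and conditional (full-covariate) regression associations are
computed alongside, as the triangulation baseline.

## Propensity models and the positivity gate

Each pairwise contrast gets its own binary logistic propensity model fit
only on pupils observed in one of the two arms. Continuous confounders
(school-entry EYFSP z-score, relative age in months, prior hospital
contact rate, school-level SEN and FSM proportions) enter with linear and
quadratic terms; categorical confounders enter as full dummy sets with an
explicit `"Unknown"` level where values are masked. Whether school-level
covariates belong in the propensity model as well as the outcome model is
not settled; the default includes them in both, and the covariate list is
an argument.

Positivity is checked on the pooled-quantile decile table of the fitted
propensity score: a contrast **fails** when some decile holds at least
`min_per_cell` pupils of one arm and none of the other, and **warns**
when a decile is thinner than `min_per_cell` on one side. The published
analysis judged overlap visually; a cell-count rule is the closest
automatable surrogate, and `min_per_cell = 5` is the package default. In
the pipeline the gate — never an error — is the only mechanism by which a
contrast is dropped, reproducing the decision to analyse SEN Support
versus None only: under the default generating law the EHCP-versus-None
contrast fails the gate outright (reference-arm mass piles below 0.05)
and EHCP-versus-Support is flagged `warn`.

For AIPW, covariates of the outcome model can be selected by
cross-validated lasso (10 folds, penalty at minimum CV deviance, the
treatment indicator force-included, unpenalised refit on the selected
set). Selection is done once on the analysed data and kept fixed across
bootstrap replicates, the usual post-selection practice.

## Missing confounders

Missingness is handled by the missing-covariate indicator method (MCIM):
continuous covariates are zero-filled with a companion indicator column;
categorical covariates carry an explicit `"Unknown"` level (the
equivalent parameterisation, so no separate indicator is added — adding
one would be exactly collinear). Both the value and the indicator enter
the propensity and outcome models. MCIM is known to admit residual
confounding in principle; a complete-records filter is provided as the
corresponding sensitivity analysis.

## Uncertainty

Pupils cluster within home local authorities (LAs), and LA-level shocks
make observations within a cluster dependent. Intervals therefore come
from a cluster bootstrap: clusters are resampled with replacement (same
number as observed), repeated clusters are relabelled as distinct, and
the *entire* chain — propensity fit included — is re-run on each
replicate, the conservative choice that propagates nuisance-model
uncertainty. Intervals are percentile (bounds are order statistics of the
replicate set), since published intervals look asymmetric and no method
is stated; normal-theory intervals are available. `B = 1000` is the
reporting default; tests and the acceptance script use `B = 199`.
Cluster-robust (sandwich) standard errors with the `G/(G-1)` small-sample
factor are available for single model fits. Whether the source analysis
resampled clusters or pupils within clusters is not stated; "accounting
for clustering by home LA" is read as cluster resampling.

## The synthetic cohort generator

The real linked administrative data are access-restricted, so the package
ships a generator whose defaults emulate the published structure of the
cohort: 6,601 pupils in 150 clusters (England has about 150 upper-tier
LAs; the number is not stated in the source), three-level treatment with
shares near 66/30/4%, categorical and continuous confounders with
dependence induced by a few latent regressions (deprivation drives
free-school-meal eligibility; cleft severity drives chronic conditions
and school readiness), MAR missingness concentrated in birth
characteristics (~23% gestational age, ~17% birthweight, ~4% maternal
age, more common in earlier academic cohorts), and administrative
censoring by academic entry cohort — later cohorts are not followed to
Year 6, so KS2 scores are structurally absent for them.

Counts are generated per followed school year as Poisson draws sharing a
pupil-level gamma frailty, so yearly components sum to a negative
binomial total with the configured dispersion while remaining
decomposable for the Year-2 censoring sensitivity analysis. Absence
outcomes use possible half-day sessions (about 325 per followed year) as
the offset; hospital outcomes use follow-up years. A&E and admission days
overlap on the same day with probability 0.25 and are deduplicated into
the unplanned-days union. The persistent-absence flag is the
deterministic ≥10% functional of total simulated absence sessions
(medical, unauthorised and other authorised), matching its definition as
a derived outcome; a direct-logistic mode exists for power experiments.
Treatment is assigned by a single multinomial logit — one coherent law —
even though analysis-time propensity models are pairwise logistic fits on
arm-restricted subsets, mirroring the published design. Cluster random
intercepts (sd 0.2 on each outcome's link scale) make the cluster
bootstrap consequential.

Default coefficients were calibrated once so the generated margins match
the published descriptive tables: None-arm rates near 337 hospital days
per 1000 years, 31 medical and 9 unauthorised absence sessions per 1000,
persistent absence near 7% (None) and 15% (Support) with ~10% overall,
and crude associations near the published ones (crude hospitalisation
RaR ≈ 1.3, crude persistent-absence OR ≈ 2.2, crude KS1 Δ ≈ −0.6). True
treatment effects default to the published causal estimates (e.g. medical
absence RaR 1.09, KS1 Δ −0.21, A&E null with admissions RaR 1.30). The
EHCP arm's outcome margins are matched only roughly; that arm exists
mainly to exercise the positivity-failure path. The joint dependence
structure of confounders is invented — the source describes margins only
— so passing recovery tests demonstrates estimator correctness under this
law, not agreement with the inaccessible real data.

`true_marginal_effects()` is the generator's oracle: it simulates a large
Monte-Carlo population, evaluates each pupil's expected potential outcome
analytically where the family permits (the frailty has mean one) and by
simulation for the two genuinely derived outcomes (the deduplicated union
and the persistent flag), and averages on the reporting scale — ATE over
everyone, ATT over pupils whose realised assignment is the exposed level.
Score truths are rescaled by the per-academic-year population sd of the
realised scores, because the analysis standardises scores within year
(the source standardised against the whole national database, which is
unavailable here — a documented divergence).

## Numerical choices

GLM fits use tight IRLS tolerances (`epsilon` 1e-12; 1e-10 inside the
negative-binomial dispersion search) so that saturated-model identities
hold to near machine precision. If the NB dispersion estimate diverges
(no overdispersion), the fit falls back to Poisson with a warning — the
NB→Poisson limit. Propensity fits error on non-convergence (separation),
naming the largest coefficients; extreme-but-converged fits are allowed,
because near-zero propensities in the *reference* arm are a positivity
symptom handled by the gate, not a numerical failure. No propensity
truncation is applied by default (none is reported in the source);
winsorisation is available but off. Weights above 50 are recorded as a
diagnostic warning, not an error.

Simulation sizes in the test suite are chosen to keep the full suite in
the tens of minutes on one core: parameter recovery uses one 20,000-pupil
cohort with a 199-replicate cluster bootstrap, and the recovery chain
uses the Poisson count family throughout — it shares the negative
binomial's conditional mean, so every estimator remains consistent and
only efficiency is affected; the NB path is exercised separately at
smaller sizes and remains the pipeline default. Bootstrap coverage uses
50 repetitions of a 1,500-pupil, 75-cluster law whose assignment depends
on a small covariate subset, so the analysis model is exactly specified
and the check isolates the interval machinery.

## Known limitations

* The generator emulates the analysis-ready rectangle only: no hospital
  episode structure, diagnostic coding, or termly census files, and no
  eligibility phenotyping (eligibility is represented as flags consumed
  by a pass-through filter).
* MCIM is approximate under MAR; the complete-records sensitivity path is
  the check, not a fix.
* The ATT-AIPW cell is an extension beyond the published layout and is
  flagged as such in the estimate diagnostics.
* Positivity gating by decile cell counts is a surrogate for visual
  inspection; borderline contrasts receive `warn` and proceed.
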