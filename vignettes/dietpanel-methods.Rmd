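---
title: "Methods: production diversity, dietary diversity and panel estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: production diversity, dietary diversity and panel estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietpanel)
```

## The scientific question

Most rural households in sub-Saharan Africa farm, and many eat poorly.
A natural hypothesis is that diversifying a household's own farm
production improves its access to nutritious foods and hence its
dietary diversity. The counter-hypothesis is that markets matter more:
if local markets carry diverse foods, a specialised farm with cash
income can eat as diversely as a fully diversified one. Distinguishing
these requires (i) diversity scores measured consistently across
countries, (ii) panel estimators that do not mistake stable household
traits (skill, wealth, taste) for effects of diversification, and
(iii) diversity measured not only on one farm but across villages,
towns and districts. `dietpanel` implements all three, with a
synthetic data generator that reproduces the statistical structure of
the multi-country LSMS-type surveys such analyses use.

## Scores

**HDDS.** The household dietary diversity score counts distinct food
groups consumed over a 7-day recall. Of the 12 conventional groups,
the three with low nutrient density (spices/condiments/beverages,
sugar/sweets, oils/fats) are excluded, so the score runs 0–9. The
score is also computed per source: groups with at least one record
from own production, from market purchase, or from other sources
(gifts, aid). A group obtained from two sources counts once in the
total but once in each source component, so the components sum to at
least the total, and no single component can exceed it.

**FPD.** Farm production diversity is either the count of distinct
crop and livestock species produced in a wave, or the count of
distinct nutritious food groups those species yield. Species map to
groups by a registry (`food_taxonomy`): a crop maps to at most one
group; livestock may map to several (cattle to meat and milk, chicken
to meat and eggs) — the union semantics mean group diversity can
exceed species diversity for livestock keepers. Non-food cash crops
(cotton, coffee, tea, tobacco) count as species but contribute no food
group; `compute_fpd(include_cash_species = FALSE)` switches them out
of the species count, since survey practice varies on this point.

**Subsistence.** The own-production share of total consumption value
classifies a household as subsistence-oriented when it strictly
exceeds 0.5 ("more than half"), so a household at exactly one half is
not subsistence. Household-waves with zero recorded value have an
undefined share and are excluded from that classification.

**LPD.** Local production diversity at village, town or district scale
is the union of nutritious food groups produced by sampled farms in
the unit-wave, with the count of sampled farmers kept alongside.
Village-waves with at most one sampled farm are marked invalid —
with one farm, village and farm diversity coincide and the village
scale carries no signal. The exclusion is applied per village-wave
(sampling varies across waves) and only at village scale: town and
district unions legitimately include farms from singleton villages,
because the exclusion is about the identity of farm- and village-level
diversity, not about data quality. Spatial comparisons are run on one
common estimation sample valid at every scale, so coefficients are
comparable across scales.

## Estimators

The main model regresses the diet score on the focal diversity
measure, socio-economic controls, and country and wave dummies. With
observational panels the focal regressor is endogenous: stable
household traits drive both farm diversity and diet. Two estimators
address time-invariant heterogeneity:

* **CRE (Mundlak)** augments pooled OLS with household means, over the
  observed waves, of the potentially endogenous regressors. The
  coefficient on a time-varying regressor then equals the fixed-effects
  within estimate, while time-invariant regressors (head sex, literacy,
  distance to town) stay estimable — the reason CRE is the main
  estimator.
* **FE** demeans outcome and regressors within households and drops
  whatever the transform annihilates (time-invariant columns, country
  dummies).

The exact CRE–FE equality is algebra, not asymptotics, but it requires
means of *all* time-varying regressors. The default Mundlak set
(`mundlak = "paper"`) averages the focal regressor and the time-varying
controls, which matches common practice and is exactly equivalent on
balanced panels, where wave-dummy means are constant across households
and hence collinear with the intercept. On unbalanced panels exact
equivalence additionally needs wave-dummy means; `mundlak = "all"`
provides that, and the property tests use it.

**Covariance.** All fits report the CR1 cluster-robust sandwich
clustered on households: `c (X'X)^-1 (sum_g u_g u_g') (X'X)^-1` with
`u_g` the within-cluster score sum and small-sample factor
`c = G/(G-1) * (N-1)/(N-K)`. With singleton clusters this reduces
exactly to HC1. Confidence intervals use the normal approximation
(estimate ± 1.96 SE); with tens of thousands of household clusters the
degrees-of-freedom refinement is immaterial, and the surveys these
methods target are far above the small-G regime where CR1 is fragile.
The clustering level is a modelling choice the surveys do not settle;
household clustering matches the repeated-household structure, and any
other column (e.g. village) can be supplied via `model_spec(cluster=)`.

**Poisson CRE.** Because the diet score is a bounded count, a log-link
Poisson quasi-ML fit is available as a robustness check. It is fitted
by Newton–Raphson with analytic gradient and Hessian and step-halving,
declaring convergence when the maximum absolute score drops below
1e-8 relative to the outcome scale, capped at 100 iterations
(non-convergence is an error with the score trace). Only the
conditional mean must be correct: the cluster-robust sandwich makes no
equidispersion assumption. An all-zero outcome is rejected — the MLE
intercept would be minus infinity.

**Interactions and marginal effects.** A focal-by-distance interaction
gives the marginal effect `b_focal + b_int * d` at distance `d`, with
the delta-method SE `sqrt(v11 + d^2 v22 + 2 d v12)` — exact here
because the effect is linear in the coefficients.

**Attrition weights.** Retention after the first wave is modelled per
wave by a logistic regression on baseline covariates among households
still present; each observation is weighted by the inverse cumulative
predicted retention probability, normalised to mean one within wave.
Constant retention gives unit weights, so the weighted fit reduces to
the unweighted one without attrition. Fitted probabilities within
1e-8 of 0 or 1 are treated as separation and rejected. Note a design
honesty point: in the bundled generator attrition depends only on
baseline covariates that are also in the regression, so the unweighted
CRE fit is already consistent and the weights mainly demonstrate the
mechanics; real attrition on unobservables is exactly what such
weights cannot fix.

## The synthetic generator

The generator emulates the structure the estimators assume, not any
particular country: six countries with 2–7 waves, households nested in
villages (default 10 per village), towns and districts; village
distance to the nearest urban centre drawn from a gamma law with mean
31 km; lognormal landholdings with more than three quarters of farms
below 2 ha; about three quarters of households farming, so roughly
seven sampled farm households per village; species counts per
farm-wave one plus an overdispersed negative-binomial draw averaging
about 5.5 species, drawn from a registry weighted so cereal species
dominate (many species, few groups). The latent household effect
`c_i ~ N(0, sigma_c^2)` raises the species-count mean through `kappa`
(default 0.3), which is precisely the endogeneity the CRE and FE
estimators must absorb: with `kappa > 0`, pooled OLS overstates the
diversity–diet association severalfold while CRE recovers the truth.

Two outcome modes separate calibration from verification:

* **structural** builds consumption records mechanistically: produced
  nutritious groups are eaten from own production with probability
  0.75; each group is purchased with a group-specific probability
  whose odds rise with assets and income and fall with distance to
  town; other sources add groups at a low rate; the three low-nutrient
  groups are purchased frequently but never scored. Monetary values
  split a lognormal household total across sources so the pooled
  own-production value share centres on 33%, with the share falling in
  market access and rising in farm diversity — reproducing the survey
  pattern that subsistence households farm more diversely yet eat less
  diversely. The group-probability intercepts and the value-share law
  were calibrated once by simulation to the pooled survey descriptives
  (mean HDDS 5.66, mean species 5.55, share 33%) and then frozen.
* **linear** writes a continuous latent diet index that follows the
  estimating equation exactly — intercept 4, configurable focal
  coefficient on either FPD metric, optional focal-by-distance
  interaction, named covariate effects, country shifts, a wave trend,
  `c_i`, and Normal noise with SD 1.5 (chosen to mimic the survey
  HDDS dispersion of about 1.75). Coefficient-recovery tests use this
  mode because rounding and censoring a 0–9 count would attenuate
  estimates of the published coefficients for reasons unrelated to the
  estimator.

Attrition is permanent dropout from the second wave on, with a
logistic hazard in baseline covariates (literacy and phones retain,
distance attrites); a retention table over all scheduled waves is kept
for the weights. One root seed drives everything: each table draws
from a child stream derived deterministically from the seed and the
table name, so adding a table never perturbs the others and identical
configs reproduce panels bit for bit.

What the generator does **not** emulate: seasonality, prices and
currency, intra-household allocation, measurement error in recalls,
and real countries' idiosyncratic layouts. Passing tests therefore
show that the scores, aggregations and estimators are correct and that
the estimators recover known truths under realistic confounding and
attrition — not that any substantive conclusion transfers to a
particular survey.

## Numerical and data-handling choices

* Least squares via QR; rank deficiency is an error naming the
  collinear candidate columns, or (in the spatial battery, where
  degenerate aggregation such as a single district per country-wave
  makes the focal regressor collinear with the dummies) a recorded
  drop.
* Reference categories: first wave and alphabetically first country,
  so outputs are bit-for-bit reproducible.
* Rows with missing values in any used column are dropped and counted
  (`n_dropped_missing`); reported sample sizes always reconcile with
  the filter accounting.
* An optional consumption-value outlier trim (1st–99th percentile
  within country-wave, `trim_outliers()`) is available but off by
  default: synthetic data contain no recording errors, and any real
  trimming rule should be an explicit, logged analysis decision.
* Interchange CSVs are written in canonical sorted order, so
  `read_panel(write_panel(x))` is the identity and outputs diff
  cleanly.
* Problem sizes used by the bundled checks: coefficient recovery uses
  3,000 households over 3 waves per seed with five seeds; the bias
  comparison uses 50 replicates of about 2,100 households; the
  coverage study uses 200 replicates of about 190 households; the
  calibration checks use the full default panel (about 104,000
  households). These sizes give Monte-Carlo error comfortably below
  the tolerances being checked while keeping a full run in minutes.

## Known limitations

Estimates remain associations: CRE and FE absorb time-invariant
heterogeneity only, and time-varying confounders (a road paved, a
market opened) are untouched. The Poisson specification is a
robustness check, not a preferred model, since the score is bounded
above by 9. LPD from sampled farms is a lower bound on true local
diversity. Survey weights, instrumental variables and spatially
correlated errors are out of scope.
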