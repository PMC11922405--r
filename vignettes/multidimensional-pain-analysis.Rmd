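---
title: "Multidimensional analysis of acute postoperative pain registries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional analysis of acute postoperative pain registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

After total knee arthroplasty (TKA), pain in the first 24 hours is
routinely managed with combinations of general anesthesia (GA), spinal
anesthesia (SA) and peripheral nerve blocks, either as a single injection
(PNBs) or as a continuous catheter infusion (PNBc). Crossing technique
with block mode yields six anesthesia subgroups (GA-o, GA&PNBc, GA&PNBs,
SA-o, SA&PNBc, SA&PNBs; "-o" means no block). Whether continuous catheters
actually deliver better patient-reported outcomes than single injections
is contested, and unidimensional "worst pain" ratings are a poor basis for
answering it. `painpro` implements a multidimensional alternative on
registry data: composite patient-reported outcome (PRO) scores, morphine
equivalent (ME) accounting, and covariate-adjusted group comparisons.

Because the source registry of the motivating cohort is not public, the
package ships a synthetic registry generator with known ground truth; all
statistical machinery is validated against that ground truth.

## Composite scores

All questionnaire items are numeric rating scales (NRS), integers 0–10.
With `worst` and `least` pain and the fraction `t` of the first 24 hours
spent in severe pain, the pain composite score is the time-weighted mean

$$\mathrm{PCS} = \mathrm{worst}\cdot t + \mathrm{least}\cdot(1-t),$$

a convex combination that always lies between the least and worst rating.
Physical interference (PITS), emotional interference (EIS: anxiety,
helplessness) and adverse events (AES) are arithmetic means of their item
lists; the global PRO-Score is the unweighted mean of the four composites.
Item lists are configuration (`default_item_schema()`): three physical
interference items, two emotional items and four adverse-event items by
default, which reproduces the granularity visible in published tables
(thirds, halves and quarters grids). Missingness always propagates — a
composite is missing unless all of its items are present (`min_items`
relaxes this), and every model runs on complete cases for exactly the
variables it uses. No imputation is performed anywhere.

## The adjusted primary analysis

The PCS is bounded, skewed and heteroscedastic, so the adjusted analysis
uses a regression with a beta-distributed outcome in the mean–precision
parameterization: $y \sim \mathrm{Beta}(\mu\varphi, (1-\mu)\varphi)$ with
$\mathrm{logit}(\mu) = x^\top\beta$. Scores are mapped into the open unit
interval by $y = 0.1\cdot\mathrm{PCS}$ followed by the standard boundary
compression $y' = (y(n-1) + 0.5)/n$ with $n$ the complete-case sample
size (an epsilon-clamp strategy is available as an option). The default
covariate set is the anesthesia subgroup, sex, enrolment period,
preoperative/intraoperative and postoperative non-opioid analgesics, the
two postoperative opioid flags (recovery room and ward), preoperative
opioid/substance (O&S) status, age, weight, and a fixed income-stratum
intercept.

Two modelling choices deserve a note. First, the income stratum has only
two levels, and a two-level random intercept is weakly identified; the
package therefore fits the stratum as a fixed intercept, which is exactly
reproducible. Second, the O&S split is fitted as a single model with a
subgroup-by-O&S interaction (12 cells) rather than two separate fits;
`emmeans_by_oands()` returns the 12 marginal means and the 66 pairwise
contrasts over that grid.

Estimation is by maximum likelihood (BFGS with analytic gradients,
started from a linear fit of the logit-transformed outcome; convergence
requires a per-observation gradient norm below 1e-4, otherwise the fit
errors rather than returning a doubtful result). The covariance matrix is
the inverse observed information. On identical data the fit agrees with
an independent beta-family implementation to at least four decimals, and
the test suite verifies the optimum against 1000 random perturbations and
an independent optimizer.

Estimated marginal means (EMMs) are computed with the conventional
reference-grid semantics: every combination of the model's factor levels
weighted equally, continuous covariates at their complete-case means,
averaging on the link scale, then back-transforming through the inverse
logit and multiplying by 10 to return to the NRS scale. Pairwise
contrasts are reported on the NRS scale with delta-method standard
errors; p-values use the studentized-range (Tukey) distribution with
residual degrees of freedom $n - p$, and Tukey-matched critical values
are used for the adjusted confidence intervals. Subgroup levels are kept
in the fixed report order GA-o, GA&PNBc, GA&PNBs, SA-o, SA&PNBc, SA&PNBs.

## The opioid-use analysis

Opioid use (any postoperative administration; event-based, so a recorded
zero-dose administration counts) is analyzed by logistic regression with
the same covariates, GA-o as the reference category, and Wald
odds-ratio intervals. Because catheter subgroups use opioids at rates
above 99%, separation is a realistic hazard: when ordinary ML shows
separation the model automatically refits by Firth penalized likelihood
and tags every downstream report with `method = "firth"`.

Adjusted percentage-point differences come from g-computation (marginal
standardization): each record is counterfactually assigned to each
subgroup, predicted probabilities are averaged, and pairwise differences
of those averages are multiplied by 100. In a model with no covariates
this reproduces the raw group proportions exactly. Confidence intervals
are nonparametric bootstrap percentiles over patients (B = 1000 by
default, seeded); a delta-method alternative is available, and the
interval method is always tagged in the output. Multiplicity is not
adjusted for these secondary contrasts by default.

## Morphine equivalents

Administrations (long format: patient, drug, route, dose) are converted
with a versioned table (`painpro-me-1.0`): oral morphine 1.0 (anchor, by
definition), iv morphine 3.0, oral oxycodone 1.5, iv/sc piritramide 2.0
(chained through its iv-morphine equivalence), oral tramadol 0.1, oral
tapentadol 0.3, iv fentanyl 300 per mg, oral hydromorphone 5.0.
Subcutaneous routes fall back to the iv factor unless a dedicated entry
exists. Conversion references genuinely differ across the literature, so
the version tag travels with every report and users can supply their own
table. Unknown drug–route pairs convert to missing (never zero) and
poison the patient's 24-hour sum, keeping the complete-case logic honest.
Only recovery-room and ward administrations count toward the 24-hour
total by default; intraoperative dosing is out of scope.

## The synthetic registry

`generate_registry()` draws a latent composite score
$\mathrm{PCS}^* = 10\,b$, $b \sim \mathrm{Beta}(\mu\varphi,(1-\mu)\varphi)$,
with $\mathrm{logit}(\mu)$ built from subgroup intercepts, an O&S shift,
and sex/age/weight/income/period effects. Observable items are then
reverse-engineered: an integer pair `least <= PCS* <= worst` is drawn
uniformly among compatible pairs, the implied time fraction
`t = (PCS* - least)/(worst - least)` is snapped to the registry's 10%
grid (degenerate `worst = least` gets `t = 0`). The forward PCS then
reproduces the latent score up to discretization: absolute error at most
`0.05 * (worst - least) <= 0.5` NRS, median about 0.11 in practice.
Secondary items are correlated ordinal variables produced by a Gaussian
copula (latent correlation 0.5 with the standardized score logit, mapped
through binomial quantiles), so PITS/EIS/AES have a realistic joint
structure with the PCS. Opioid use is Bernoulli per subgroup; ME totals
among users are lognormal (meanlog log 15, sdlog 0.95, matching the
published median of about 15 mg with quartiles 8–29); missingness is
missing-completely-at-random per field.

The default configuration reproduces the published cohort structure:
4328 patients, 74.8% from high-income countries, stratum-specific
subgroup mixes taken from the printed income rows (catheters nearly
absent in the middle/low-income stratum), O&S prevalence 9.5%,
per-subgroup opioid-use probabilities (92.7/99.2/89.2/85.9/99.5/80.4%),
and subgroup intercepts chosen so the true adjusted marginal means are
exactly NRS (3.6, 3.7, 3.1, 3.0, 3.2, 3.0) — the published adjusted
range. Ground-truth EMMs are computed with the same reference-grid
convention as the analysis, so recovery experiments compare like with
like. All randomness derives from one seed via named per-stage
substreams, and generation is byte-identical across runs.

What the generator does *not* emulate: hospital-level clustering,
country-specific practice, informative missingness, and the unpublished
item-level correlation structure of the real questionnaire. Passing
recovery tests therefore validate the estimation machinery, not the
clinical realism of any particular simulated cohort.

## Numerical choices and degenerate inputs

* Quartiles use the linear-interpolation convention (R type 7); 2×2
  chi-square tests apply the Yates continuity correction, which
  reproduces the printed O&S-row p-value of 0.013 from the published
  counts.
* Factors with a single observed level (or levels with fewer than two
  records) after complete-case subsetting abort the fit with the stratum
  named; empty subgroup-by-O&S cells abort the 12-cell analysis naming
  the cell.
* A constant outcome has no finite beta MLE (the precision diverges);
  the fit reports non-convergence rather than a spurious result.
* Implausible single administrations (negative or above the configurable
  per-drug bound) are dropped while the patient is kept; patient-level
  exclusion applies only to age < 18 and weight < 34 kg. Exclusion logs
  are exhaustive: kept + excluded always equals the input count.

## Known limitations

Two properties of the method on discrete NRS-derived scores are measured
by the acceptance suite (50 replicate registries of n = 4328-scale data
at n = 4000, and 200 null simulations at n = 1500 — sizes chosen to make
the suite convenient to rerun) and should be understood by users:

1. **Boundary attenuation.** Roughly 6% of patients have an exact PCS of
   0 (least pain 0 and no time in severe pain). The compression rescale
   maps these to 0.5/n, where the beta log-likelihood is extremely
   sensitive; group means of low-scoring groups are attenuated by about
   0.1 NRS. This is not an optimizer artifact — an independent
   beta-family implementation produces identical estimates, and the same
   machinery run on the latent (undiscretized) score recovers the truth
   to better than 0.03 NRS.
2. **Anticonservative model-based errors.** Discretization noise
   concentrated at the compressed boundary makes information-matrix
   standard errors slightly too small: under equal true group effects the
   familywise rate of any Tukey-significant pair is about 0.11–0.15
   instead of 0.05, while the identical pipeline on the latent score
   holds its level (0.03). Robust (sandwich) standard errors would likely
   repair this but are not part of the reported method.

Neither composite score has been clinically validated as a measurement
instrument; the package computes them, it does not validate them. The
analyses are associational: no causal adjustment (propensity scores,
weighting) is attempted, matching the observational design of the
motivating registry study.

## Reproducing a full run

```r
library(painpro)
res <- run_pipeline(list(seed = 1, n = 4328), out_dir = "run")
res$emm          # six adjusted marginal means, NRS scale
res$contrasts    # 15 Tukey-adjusted pairwise contrasts
res$risk_contrasts  # opioid-use percentage-point contrasts
```

The run manifest (`manifest.json`) records the config hash, seed,
conversion-table version, exclusion counts and output hashes; rerunning
with the same config reproduces every output byte-identically.
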