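# painpro

Multidimensional analysis of acute postoperative pain after total knee
arthroplasty (TKA), for biostatisticians and outcomes researchers working
with patient-reported-outcome (PRO) registries. The package compares
anesthesia techniques — general (GA) or spinal (SA) anesthesia, with no
nerve block (-o), a single-injection peripheral nerve block (PNBs), or a
continuous catheter block (PNBc) — on composite pain scores and on
postoperative opioid use, adjusting for patient covariates.

## What it computes

**Composite scores** (all on the numeric rating scale, NRS 0–10):

- Pain composite score, a time-weighted intensity measure:
  `PCS = worst · t + least · (1 − t)`, where `t` is the fraction of the
  first 24 postoperative hours spent in severe pain;
- PITS, EIS and AES — mean-of-items composites for pain-related physical
  interference, emotional interference (anxiety, helplessness) and
  treatment-related adverse events;
- PRO-Score — the unweighted mean of the four composites, a global
  measure of pain severity.

**Adjusted models:**

- a beta-outcome regression for the PCS rescaled into (0, 1)
  (`y ~ Beta(μφ, (1−μ)φ)`, `logit(μ) = x'β`), with estimated marginal
  means over the reference grid and Tukey-adjusted pairwise contrasts on
  the NRS scale, optionally split by preoperative opioid/substance (O&S)
  status via a subgroup × O&S interaction;
- a logistic model for opioid use (reference GA-o) with Wald odds ratios
  and g-computation percentage-point treatment contrasts (bootstrap or
  delta-method intervals), with an automatic Firth penalized fallback
  under separation;
- morphine-equivalent (ME) accounting through a versioned drug × route
  conversion table;
- descriptive tables (median [Q1; Q3] / n (%)) with Mann–Whitney,
  Kruskal–Wallis and Yates-corrected chi-square tests.

Because the motivating registry is not public, the package includes a
synthetic registry generator (`generate_registry()`) that emulates the
published cohort structure — six anesthesia subgroups with an
income-dependent mix, integer NRS items, time in severe pain on a 10%
grid, 9.5% O&S prevalence, per-subgroup opioid-use rates, skewed ME
doses — with known ground truth for every downstream stage.

## Worked example

```r
library(painpro)
sim <- generate_registry(default_paperlike_config(n = 4328, seed = 1))
patients <- score_patients(sim$registry$patients)
patients$opioid_use <- opioid_use_flag(patients, sim$registry$administrations)

fit <- fit_beta(patients, default_model_spec("pcs"))
emm <- beta_emmeans(fit, "subgroup")
emm[, c("level", "estimate", "ci_low", "ci_high")]
#>    level estimate ci_low ci_high
#>     GA-o     3.44   3.19    3.71
#>  GA&PNBc     3.39   3.14    3.65
#>  GA&PNBs     2.76   2.52    3.00
#>     SA-o     2.46   2.28    2.66
#>  SA&PNBc     3.01   2.75    3.28
#>  SA&PNBs     2.80   2.59    3.02
```

These are covariate-adjusted marginal mean PCS values per anesthesia
subgroup on the NRS 0–10 scale with 95% confidence intervals: in this
simulated cohort the continuous-catheter groups do not show lower
adjusted pain scores than the single-injection groups. Pairwise
differences with Tukey-adjusted p-values:

```r
head(pairwise_contrasts(emm, adjust = "tukey"), 3)
#>  level1  level2  diff ci_low ci_high p_adjusted
#>    GA-o GA&PNBc 0.052  -0.33    0.44    1.0e+00
#>    GA-o GA&PNBs 0.688   0.29    1.08    9.7e-06
#>    GA-o    SA-o 0.981   0.64    1.32    4.1e-08
```

And adjusted percentage-point differences in opioid use by
g-computation (negative `diff_pp` for GA-o − GA&PNBc means the catheter
group received opioids *more* often):

```r
fit2 <- fit_logistic(patients, default_opioid_spec())
rc <- risk_difference_contrasts(fit2, ci_method = "delta")
head(rc, 3)
#>  level1  level2 diff_pp ci_low ci_high  p_value
#>    GA-o GA&PNBc   -5.59  -7.81   -3.38 7.09e-07
#>    GA-o GA&PNBs    6.25   2.71    9.79 5.39e-04
#>    GA-o    SA-o    7.16   4.22   10.10 1.77e-06
```

`run_pipeline(list(seed = 1, n = 4328), "out")` chains all stages
(simulate → filter → score → fit → report) and writes CSV artifacts plus
a manifest with config and output hashes for byte-identical reruns. See
the vignette (`vignettes/multidimensional-pain-analysis.Rmd`) for the
model details, generator assumptions and known limitations.

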