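test_that("a saturated two-group fit reproduces the closed-form odds ratio", {
  d <- data.frame(
    grp = factor(rep(c("ref", "other"), each = 100),
                 levels = c("ref", "other")),
    opioid_use = c(rep(c(TRUE, FALSE), c(90, 10)),
                   rep(c(TRUE, FALSE), c(80, 20))))
  spec <- model_spec("opioid_use", factors = "grp",
                     offset_stratum = NULL)
  fit <- fit_logistic(d, spec, reference = "ref", group_var = "grp")
  expect_equal(fit$method, "ml")
  ors <- odds_ratios(fit)
  # (0.8/0.2) / (0.9/0.1) = 4/9
  expect_equal(ors$or[ors$term == "grpother"], 4 / 9, tolerance = 1e-6)
  expect_equal(odds_ratios(fit)$method, rep("ml", 2))
})

test_that("a degenerate all-identical outcome is refused", {
  d <- data.frame(grp = factor(rep(c("a", "b"), 50)),
                  opioid_use = TRUE)
  spec <- model_spec("opioid_use", factors = "grp", offset_stratum = NULL)
  expect_error(fit_logistic(d, spec, reference = "a", group_var = "grp"),
               "degenerate outcome")
})

test_that("separation triggers the penalized-likelihood fallback with a tag", {
  set.seed(2)
  d <- data.frame(grp = factor(rep(c("a", "b"), each = 60)),
                  x = rnorm(120))
  d$opioid_use <- ifelse(d$grp == "b", TRUE, runif(120) < 0.5)
  spec <- model_spec("opioid_use", factors = "grp", continuous = "x",
                     offset_stratum = NULL)
  expect_warning(
    fit <- fit_logistic(d, spec, reference = "a", group_var = "grp"),
    "separation")
  expect_equal(fit$method, "firth")
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(abs(fit$coefficients) < 15))
  ors <- odds_ratios(fit)
  expect_equal(ors$method, rep("firth", nrow(ors)))
})

test_that("g-computation equals raw proportion differences in a no-covariate model", {
  cfg <- small_config(n = 1500, seed = 17)
  cfg$opioid_use_probs <- pmin(cfg$opioid_use_probs, 0.95)
  sim <- generate_registry(cfg)
  d <- sim$registry$patients
  d$opioid_use <- opioid_use_flag(d, sim$registry$administrations)
  spec <- model_spec("opioid_use", factors = "subgroup",
                     offset_stratum = NULL)
  fit <- fit_logistic(d, spec)
  expect_equal(fit$method, "ml")  # the exact identity holds for plain ML
  rc <- risk_difference_contrasts(fit, ci_method = "delta")
  raw <- tapply(d$opioid_use, d$subgroup, mean)
  raw_diff <- 100 * (raw[rc$level1] - raw[rc$level2])
  expect_equal(rc$diff_pp, as.numeric(raw_diff), tolerance = 1e-9)
  # cycle identity: (a-b) + (b-c) + (c-a) = 0 exactly
  idx <- function(a, b) {
    i <- which(rc$level1 == a & rc$level2 == b)
    if (length(i)) rc$diff_pp[i] else -rc$diff_pp[rc$level1 == b &
                                                    rc$level2 == a]
  }
  lv <- levels(d$subgroup)[1:3]
  expect_equal(idx(lv[1], lv[2]) + idx(lv[2], lv[3]) - idx(lv[1], lv[3]), 0,
               tolerance = 1e-12)
  # marginal probabilities live inside the span of individual predictions
  probs <- attr(rc, "marginal_probs")
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(attr(rc, "ci_method"), "delta")
})

test_that("adjusted and unadjusted contrasts agree when covariates are independent of groups", {
  sim <- generate_registry(default_paperlike_config(n = 12000, seed = 29))
  d <- sim$registry$patients
  d$opioid_use <- opioid_use_flag(d, sim$registry$administrations)
  spec_adj <- model_spec("opioid_use",
                         factors = c("subgroup", "sex", "oands_flag"),
                         continuous = c("age", "weight"),
                         offset_stratum = NULL)
  fit <- fit_logistic(d, spec_adj)
  rc <- risk_difference_contrasts(fit, ci_method = "delta")
  raw <- tapply(d$opioid_use, d$subgroup, mean)
  raw_diff <- 100 * (raw[rc$level1] - raw[rc$level2])
  expect_lt(max(abs(rc$diff_pp - as.numeric(raw_diff))), 1.5)
})

test_that("bootstrap intervals cover the point estimate and carry method tags", {
  cfg <- small_config(n = 1200, seed = 41)
  cfg$opioid_use_probs <- pmin(cfg$opioid_use_probs, 0.95)
  sim <- generate_registry(cfg)
  d <- sim$registry$patients
  d$opioid_use <- opioid_use_flag(d, sim$registry$administrations)
  spec <- model_spec("opioid_use", factors = c("subgroup", "sex"),
                     offset_stratum = NULL)
  fit <- fit_logistic(d, spec)
  rc <- risk_difference_contrasts(fit, B = 60, seed = 3)
  expect_equal(nrow(rc), choose(6, 2))
  expect_true(all(rc$ci_low <= rc$diff_pp + 1e-9))
  expect_true(all(rc$ci_high >= rc$diff_pp - 1e-9))
  expect_true(all(rc$diff_pp >= -100 & rc$diff_pp <= 100))
  expect_equal(attr(rc, "ci_method"), "bootstrap")
  expect_equal(attr(rc, "fit_method"), fit$method)
  # determinism under the seed
  rc2 <- risk_difference_contrasts(fit, B = 60, seed = 3)
  expect_equal(rc$ci_low, rc2$ci_low)
})
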