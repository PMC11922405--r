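# Independent prediction-averaging oracle: builds the full reference grid,
# computes per-row linear predictors directly from the formula and
# coefficient vector, and averages within each level of the target factor.
emm_link_oracle <- function(fit, factor_name, rhs) {
  grid <- expand.grid(fit$xlevels, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = TRUE)
  for (v in names(fit$cov_means)) grid[[v]] <- fit$cov_means[[v]]
  X <- model.matrix(stats::reformulate(rhs), grid)
  eta <- drop(X %*% fit$coefficients[colnames(X)])
  tapply(eta, grid[[factor_name]], mean)
}

test_that("beta fit recovers logit(0.5) = 0 for outcomes symmetric about NRS 5", {
  d <- data.frame(pcs = rep(c(4, 6), each = 60),
                  g = factor(rep(c("a", "b"), 60)))
  spec <- model_spec("pcs", factors = "g", offset_stratum = NULL)
  fit <- fit_beta(d, spec)
  eta0 <- unname(fit$coefficients[1] + 0.5 * fit$coefficients[2])
  expect_lt(abs(eta0), 0.02)
  expect_s3_class(fit, "beta_fit")
  expect_gt(fit$phi, 0)
})

test_that("likelihood weighting: duplicating every row keeps estimates, shrinks SE by sqrt(2)", {
  d <- make_beta_data(n = 250)
  spec <- model_spec("pcs", factors = "g", continuous = "x",
                     offset_stratum = NULL)
  f1 <- fit_beta(d, spec, rescale_method = "epsilon")
  f2 <- fit_beta(rbind(d, d), spec, rescale_method = "epsilon")
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-5)
  se1 <- sqrt(diag(f1$vcov)); se2 <- sqrt(diag(f2$vcov))
  expect_equal(unname(se1 / se2), rep(sqrt(2), length(se1)),
               tolerance = 1e-3)
})

test_that("the optimum is a local maximum and matches an independent optimizer", {
  d <- make_beta_data(n = 180, seed = 8)
  spec <- model_spec("pcs", factors = "g", continuous = "x",
                     offset_stratum = NULL)
  fit <- fit_beta(d, spec)
  y <- rescale_to_open_unit(d$pcs, nrow(d))
  X <- model.matrix(~ g + x, d)
  ll <- function(b, phi) {
    mu <- plogis(drop(X %*% b))
    sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  expect_equal(ll(fit$coefficients, fit$phi), fit$loglik, tolerance = 1e-8)
  set.seed(99)
  pert <- replicate(1000, ll(fit$coefficients + rnorm(3, 0, 0.05),
                             fit$phi * exp(rnorm(1, 0, 0.05))))
  expect_true(all(pert <= fit$loglik + 1e-9))
  # independent numerical-optimizer oracle, different start and routine
  oracle <- nlminb(c(0, 0, 0, 1),
                   function(p) -ll(p[1:3], exp(p[4])))
  expect_equal(-2 * fit$loglik, 2 * oracle$objective, tolerance = 1e-6)
})

test_that("beta ML agrees with an independent package implementation", {
  skip_if_not_installed("glmmTMB")
  d <- make_beta_data(n = 400, seed = 21)
  spec <- model_spec("pcs", factors = "g", continuous = "x",
                     offset_stratum = NULL)
  fit <- fit_beta(d, spec)
  d$y <- rescale_to_open_unit(d$pcs, nrow(d))
  g <- glmmTMB::glmmTMB(y ~ g + x, family = glmmTMB::beta_family(),
                        data = d)
  expect_equal(unname(fit$coefficients),
               unname(glmmTMB::fixef(g)$cond), tolerance = 1e-4)
  expect_equal(fit$phi, glmmTMB::sigma(g), tolerance = 1e-4)
})

test_that("coefficients are recovered within 3 SE on generator ground truth (latent outcome)", {
  cfg <- default_paperlike_config(n = 20000, seed = 314)
  sim <- generate_registry(cfg)
  d <- score_patients(sim$registry$patients)
  d$pcs_lat <- sim$truth$latent_pcs
  spec <- model_spec("pcs_lat",
                     factors = c("subgroup", "sex", "oands_flag",
                                 "enrolment_period"),
                     continuous = c("age", "weight"))
  fit <- fit_beta(d, spec)
  se <- sqrt(diag(fit$vcov))
  ge <- cfg$pcs_group_effects
  truth <- c(ge[-1] - ge[1],                   # subgroup contrasts vs GA-o
             cfg$covariate_effects[["sex_male"]],
             cfg$oands_effect,
             cfg$covariate_effects[["period_P2013_2017"]],
             cfg$covariate_effects[["period_P2017_2020"]],
             cfg$covariate_effects[["age_per10"]] / 10,
             cfg$covariate_effects[["weight_per10"]] / 10,
             cfg$covariate_effects[["income_middle_low"]])
  est <- fit$coefficients[-1]
  expect_equal(length(est), length(truth))
  expect_true(all(abs(unname(est) - unname(truth)) < 3 * se[-1]))
  expect_equal(fit$phi, cfg$phi, tolerance = 0.1)
  # vcov is symmetric positive definite
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("marginal means match the brute-force prediction-averaging oracle", {
  sim <- generate_registry(small_config(n = 400, seed = 55))
  d <- score_patients(sim$registry$patients)
  spec <- model_spec("pcs", factors = c("subgroup", "sex"),
                     continuous = "age")
  fit <- fit_beta(d, spec)
  emm <- beta_emmeans(fit, "subgroup")
  oracle_eta <- emm_link_oracle(fit, "subgroup",
                                c("subgroup", "sex", "age",
                                  "country_income"))
  expect_equal(unname(attr(emm, "eta")), as.numeric(oracle_eta),
               tolerance = 1e-10)
  expect_equal(emm$estimate, as.numeric(10 * plogis(oracle_eta)),
               tolerance = 1e-10)
  expect_true(all(emm$ci_low <= emm$estimate & emm$estimate <= emm$ci_high))
  expect_error(beta_emmeans(fit, "not_a_factor"), "not in the model")
})

test_that("marginal means are invariant to covariate location shifts and level relabeling", {
  d <- make_beta_data(n = 300, seed = 12)
  spec <- model_spec("pcs", factors = "g", continuous = "x",
                     offset_stratum = NULL)
  f1 <- fit_beta(d, spec)
  d2 <- d; d2$x <- d$x + 5
  f2 <- fit_beta(d2, spec)
  e1 <- beta_emmeans(f1, "g"); e2 <- beta_emmeans(f2, "g")
  expect_equal(e1$estimate, e2$estimate, tolerance = 1e-5)
  # relabel factor levels (reverse order): estimates follow the labels
  d3 <- d; d3$g <- factor(d$g, levels = rev(levels(d$g)))
  e3 <- beta_emmeans(fit_beta(d3, spec), "g")
  expect_equal(e1$estimate[match(e3$level, e1$level)], e3$estimate,
               tolerance = 1e-5)
})

test_that("pairwise contrasts enumerate all pairs with Tukey dominance over unadjusted", {
  sim <- generate_registry(small_config(n = 1200, seed = 23))
  d <- score_patients(sim$registry$patients)
  spec <- model_spec("pcs", factors = c("subgroup", "sex"),
                     continuous = "age")
  emm <- beta_emmeans(fit_beta(d, spec), "subgroup")
  tuk <- pairwise_contrasts(emm, adjust = "tukey")
  unadj <- pairwise_contrasts(emm, adjust = "none")
  expect_equal(nrow(tuk), choose(6, 2))
  expect_true(all(tuk$p_adjusted >= unadj$p_adjusted - 1e-12))
  expect_equal(tuk$diff, unadj$diff)
  # antisymmetry via the cycle identity on response-scale differences
  idx <- function(a, b) which(tuk$level1 == a & tuk$level2 == b)
  d_ab <- tuk$diff[idx("GA-o", "GA&PNBc")]
  d_bc <- tuk$diff[idx("GA&PNBc", "GA&PNBs")]
  d_ac <- tuk$diff[idx("GA-o", "GA&PNBs")]
  expect_equal(d_ab + d_bc, d_ac, tolerance = 1e-12)
})

test_that("two identically distributed levels give a null contrast", {
  base <- make_beta_data(n = 150, seed = 4)[, c("pcs", "x")]
  d <- rbind(cbind(base, g = "a"), cbind(base, g = "b"))
  d$g <- factor(d$g)
  spec <- model_spec("pcs", factors = "g", offset_stratum = NULL)
  emm <- beta_emmeans(fit_beta(d, spec), "g")
  ctr <- pairwise_contrasts(emm, adjust = "tukey")
  expect_equal(ctr$diff, 0, tolerance = 1e-5)
  expect_gt(ctr$p_adjusted, 0.99)
})

test_that("the O&S-split analysis yields 12 cells, 66 contrasts and a consistent shift", {
  cfg <- small_config(n = 6000, seed = 61)
  cfg$oands_prevalence <- 0.4
  sim <- generate_registry(cfg)
  d <- score_patients(sim$registry$patients)
  spec <- model_spec("pcs", factors = c("subgroup", "oands_flag", "sex"),
                     continuous = "age",
                     interactions = "subgroup:oands_flag")
  fit <- fit_beta(d, spec)
  res <- emmeans_by_oands(fit)
  expect_equal(nrow(res$emm), 12)
  expect_equal(nrow(res$contrasts), choose(12, 2))
  # within-subgroup O&S (yes - no) link-scale contrasts all share the
  # positive sign of the generating shift
  eta <- attr(res$emm, "eta")
  key <- res$emm[c("subgroup", "oands_flag")]
  shift <- vapply(subgroup_levels(), function(g) {
    eta[key$subgroup == g & key$oands_flag == "TRUE"] -
      eta[key$subgroup == g & key$oands_flag == "FALSE"]
  }, 0)
  expect_true(all(shift > 0))
  expect_lt(max(shift) - min(shift), 0.5)
  # guard rails
  spec0 <- model_spec("pcs", factors = c("subgroup", "oands_flag"),
                      continuous = "age")
  expect_error(emmeans_by_oands(fit_beta(d, spec0)), "interaction")
  fit_bad <- fit
  fit_bad$model_frame <- fit$model_frame[
    !(fit$model_frame$subgroup == "SA-o" &
        fit$model_frame$oands_flag == "TRUE"), ]
  expect_error(emmeans_by_oands(fit_bad), "empty cell")
})

test_that("degenerate single-level strata are refused by name", {
  d <- make_beta_data(n = 100)
  d$g <- factor("a", levels = c("a", "b"))
  spec <- model_spec("pcs", factors = "g", offset_stratum = NULL)
  expect_error(fit_beta(d, spec), "degenerate stratum.*'g'")
})
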