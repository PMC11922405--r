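#' Model specification for adjusted analyses
#'
#' Declares the outcome, the categorical and continuous covariates, the
#' income-stratum adjustment and optional interaction terms shared by the
#' beta-outcome model ([fit_beta()]) and the logistic opioid-use model
#' ([fit_logistic()]).
#'
#' @param outcome Name of the outcome column (a computed composite score
#'   for the beta model, a logical flag for the logistic model).
#' @param factors Character vector of categorical covariates (logical
#'   columns are treated as two-level factors).
#' @param continuous Character vector of continuous covariates.
#' @param offset_stratum Name of the income-stratum column entering as a
#'   fixed stratum intercept, or `NULL`.
#' @param interactions Optional character vector of interaction terms in
#'   formula notation, e.g. `"subgroup:oands_flag"`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(outcome, factors, continuous = character(0),
                       offset_stratum = "country_income",
                       interactions = NULL) {
  structure(list(outcome = outcome, factors = factors,
                 continuous = continuous, offset_stratum = offset_stratum,
                 interactions = interactions),
            class = "model_spec")
}

#' Default covariate set for the adjusted analyses
#'
#' Anesthesia subgroup, sex, enrolment period, preoperative/intraoperative
#' and postoperative non-opioid analgesics, opioid administration in the
#' postanesthesia care unit and on the ward (two separate flags),
#' preoperative opioid/substance status, age and weight, with a fixed
#' income-stratum intercept.
#'
#' @param outcome Outcome column name; default `"pcs"`.
#' @param interactions Optional interaction terms.
#' @return A [model_spec()].
#' @export
default_model_spec <- function(outcome = "pcs", interactions = NULL) {
  model_spec(outcome,
             factors = c("subgroup", "sex", "enrolment_period",
                         "nonopioid_pre_intra", "nonopioid_post",
                         "opioid_pacu", "opioid_ward", "oands_flag"),
             continuous = c("age", "weight"),
             offset_stratum = "country_income",
             interactions = interactions)
}

spec_variables <- function(spec) {
  ia_vars <- unique(unlist(strsplit(spec$interactions %||% character(0),
                                    ":", fixed = TRUE)))
  unique(c(spec$outcome, spec$factors, spec$continuous,
           spec$offset_stratum, ia_vars))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

spec_formula <- function(spec) {
  rhs <- c(spec$factors, spec$continuous, spec$offset_stratum,
           spec$interactions)
  if (!length(rhs)) rhs <- "1"
  stats::reformulate(rhs)
}

# Complete-case model frame with categorical covariates coerced to
# factors; errors on degenerate (single-level) factors, naming them.
prepare_model_frame <- function(data, spec) {
  vars <- spec_variables(spec)
  data <- complete_case_subset(data, vars)
  fac_vars <- intersect(c(spec$factors, spec$offset_stratum), vars)
  for (v in fac_vars) {
    data[[v]] <- droplevels(factor(data[[v]]))
    if (nlevels(data[[v]]) < 2)
      stop("degenerate stratum: covariate '", v,
           "' has a single level after complete-case subsetting")
    low <- table(data[[v]])
    if (any(low < 2))
      stop("degenerate stratum: level(s) ",
           paste(names(low)[low < 2], collapse = ", "),
           " of '", v, "' have fewer than 2 records")
  }
  list(data = data, fac_vars = fac_vars,
       cont_vars = intersect(spec$continuous, vars))
}

# Negative beta log-likelihood and analytic gradient in mean-precision
# parameterization; par = (beta, log phi).
beta_nll <- function(par, X, y) {
  p <- ncol(X)
  mu <- stats::plogis(drop(X %*% par[1:p]))
  phi <- exp(par[p + 1])
  -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

beta_grad <- function(par, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% par[1:p])
  mu <- stats::plogis(eta)
  phi <- exp(par[p + 1])
  ystar <- log(y / (1 - y))
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  gb <- -phi * drop(crossprod(X, (ystar - mustar) * mu * (1 - mu)))
  dphi <- digamma(phi) - mu * digamma(mu * phi) -
    (1 - mu) * digamma((1 - mu) * phi) + mu * log(y) + (1 - mu) * log(1 - y)
  c(gb, -sum(dphi) * phi)
}

#' Beta regression for a bounded composite-score outcome
#'
#' Fits a fixed-effects regression with a beta-distributed outcome by
#' maximum likelihood in the mean--precision parameterization
#' (`alpha = mu * phi`, `beta = (1 - mu) * phi`) with a logit link for the
#' mean. The composite score (NRS 0--10) is rescaled into the open unit
#' interval via [rescale_to_open_unit()] using the complete-case sample
#' size; the income stratum enters as a fixed stratum intercept. Only
#' complete cases for the model variables are used.
#'
#' Optimization uses BFGS with analytic gradients, started from a linear
#' fit on the logit scale; the fit errors (reporting the gradient norm)
#' rather than returning a non-converged result.
#'
#' @param data Scored patient data frame (see [score_patients()]).
#' @param spec A [model_spec()].
#' @param rescale_method Passed to [rescale_to_open_unit()].
#' @return A `beta_fit`: coefficients, `vcov` (observed-information),
#'   precision `phi`, residual degrees of freedom `df_residual
#'   = n_used - p`, log-likelihood, the model frame and grid metadata.
#' @export
fit_beta <- function(data, spec, rescale_method = "compression") {
  pf <- prepare_model_frame(data, spec)
  d <- pf$data
  n <- nrow(d)
  if (n < 10) stop("too few complete cases to fit (n = ", n, ")")
  y <- rescale_to_open_unit(d[[spec$outcome]], n_effective = n,
                            method = rescale_method)
  form <- spec_formula(spec)
  X <- stats::model.matrix(form, d)
  p <- ncol(X)
  start_beta <- stats::lm.fit(X, stats::qlogis(y))$coefficients
  start_beta[is.na(start_beta)] <- 0
  start <- c(start_beta, log_phi = log(5))
  opt <- stats::optim(start, beta_nll, beta_grad, X = X, y = y,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  gn <- sqrt(sum(beta_grad(opt$par, X, y)^2)) / n
  if (opt$convergence != 0 || !is.finite(gn) || gn > 1e-4)
    stop("beta regression did not converge (per-observation gradient ",
         "norm ", format(gn), ")")
  vc_all <- tryCatch(solve(opt$hessian), error = function(e)
    stop("singular information matrix in beta regression"))
  vc <- vc_all[1:p, 1:p, drop = FALSE]
  vc <- (vc + t(vc)) / 2
  coefs <- opt$par[1:p]
  names(coefs) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = coefs, vcov = vc, phi = unname(exp(opt$par[p + 1])),
    link = "logit", n_used = n, df_residual = n - p,
    loglik = -opt$value, grad_norm = gn,
    spec = spec, terms = stats::terms(form),
    xlevels = lapply(d[pf$fac_vars], levels),
    cov_means = vapply(d[pf$cont_vars], mean, 0),
    model_frame = d[spec_variables(spec)],
    rescale = list(method = rescale_method, n_effective = n)
  ), class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat("Beta-outcome regression (logit link), n =", x$n_used,
      " phi =", format(x$phi, digits = 4), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

# Linear predictor for new data on the link scale.
predict_eta <- function(fit, newdata) {
  tt <- stats::delete.response(fit$terms)
  mf <- stats::model.frame(tt, newdata, xlev = fit$xlevels,
                           na.action = stats::na.fail)
  X <- stats::model.matrix(tt, mf)
  drop(X %*% fit$coefficients[colnames(X)])
}

# Reference grid: all combinations of the model's factor levels with
# continuous covariates fixed at their complete-case means.
reference_grid <- function(fit) {
  grid <- expand.grid(fit$xlevels, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = TRUE)
  for (v in names(fit$cov_means)) grid[[v]] <- fit$cov_means[[v]]
  grid
}

# Averaging matrix L: one row per cell of the target factor(s), averaging
# model-matrix rows over the rest of the reference grid on the link scale.
emm_engine <- function(fit, target_vars) {
  absent <- setdiff(target_vars, names(fit$xlevels))
  if (length(absent))
    stop("factor(s) not in the model: ", paste(absent, collapse = ", "))
  grid <- reference_grid(fit)
  tt <- stats::delete.response(fit$terms)
  X <- stats::model.matrix(tt, stats::model.frame(tt, grid,
                                                  xlev = fit$xlevels))
  cell <- interaction(grid[target_vars], drop = FALSE, lex.order = TRUE,
                      sep = " | ")
  levs <- levels(cell)
  L <- t(vapply(levs, function(l) colMeans(X[cell == l, , drop = FALSE]),
                numeric(ncol(X))))
  key <- unique(grid[target_vars])
  key <- key[order(interaction(key, lex.order = TRUE, sep = " | ")), ,
             drop = FALSE]
  rownames(key) <- NULL
  list(L = L, levels = levs, key = key)
}

#' Estimated marginal means on the NRS scale
#'
#' Builds the reference grid (all combinations of the model's factor
#' levels, continuous covariates at their means), averages the linear
#' predictor over the grid within each level of the target factor(s),
#' back-transforms through the inverse logit and rescales to the 0--10
#' NRS scale. Confidence intervals are computed on the link scale with
#' t quantiles at the fit's residual degrees of freedom and then
#' back-transformed; standard errors on the response scale use the delta
#' method.
#'
#' @param fit A `beta_fit`.
#' @param factor Name of the target factor, or a character vector of
#'   several factors for a joint (cell-level) grid.
#' @param level Confidence level (default 0.95).
#' @return A `pain_emm` data frame: one row per level with `estimate`,
#'   `se`, `ci_low`, `ci_high` on the NRS scale, plus link-scale metadata
#'   used by [pairwise_contrasts()].
#' @export
beta_emmeans <- function(fit, factor, level = 0.95) {
  en <- emm_engine(fit, factor)
  eta <- drop(en$L %*% fit$coefficients)
  V <- en$L %*% fit$vcov %*% t(en$L)
  se_eta <- sqrt(pmax(diag(V), 0))
  mu <- stats::plogis(eta)
  tq <- stats::qt((1 + level) / 2, fit$df_residual)
  out <- data.frame(
    level = en$levels,
    estimate = 10 * mu,
    se = 10 * mu * (1 - mu) * se_eta,
    ci_low = 10 * stats::plogis(eta - tq * se_eta),
    ci_high = 10 * stats::plogis(eta + tq * se_eta),
    stringsAsFactors = FALSE)
  out <- cbind(en$key, out[-1])
  out$level <- en$levels
  attr(out, "eta") <- eta
  attr(out, "vcov_eta") <- V
  attr(out, "L") <- en$L
  attr(out, "vcov_coef") <- fit$vcov
  attr(out, "df") <- fit$df_residual
  attr(out, "conf_level") <- level
  class(out) <- c("pain_emm", "data.frame")
  out
}

#' Pairwise contrasts with Tukey multiplicity adjustment
#'
#' All pairwise differences between the marginal-mean levels, reported on
#' the response (NRS 0--10) scale with delta-method standard errors.
#' With `adjust = "tukey"`, p-values come from the studentized-range
#' distribution with the fit's residual degrees of freedom and the
#' confidence intervals use the matching studentized-range critical
#' value; `adjust = "none"` gives ordinary t-based tests and intervals.
#'
#' @param emm A `pain_emm` from [beta_emmeans()].
#' @param adjust `"tukey"` (default) or `"none"`.
#' @param level Confidence level.
#' @return A `data.frame` with one row per unordered pair: `level1`,
#'   `level2`, `diff` (level1 - level2, NRS), `se`, `ci_low`, `ci_high`,
#'   `p_adjusted`, and an `adjust` attribute.
#' @export
pairwise_contrasts <- function(emm, adjust = c("tukey", "none"),
                               level = 0.95) {
  adjust <- match.arg(adjust)
  eta <- attr(emm, "eta")
  L <- attr(emm, "L")
  Vc <- attr(emm, "vcov_coef")
  df <- attr(emm, "df")
  k <- length(eta)
  if (k < 2) stop("need at least 2 levels for pairwise contrasts")
  mu <- stats::plogis(eta)
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    g <- 10 * (mu[i] * (1 - mu[i]) * L[i, ] - mu[j] * (1 - mu[j]) * L[j, ])
    v <- drop(g %*% Vc %*% g)
    if (!is.finite(v) || v <= 1e-24)
      stop("singular contrast covariance for pair ", emm$level[i], " - ",
           emm$level[j])
    d <- 10 * (mu[i] - mu[j])
    c(d = unname(d), se = sqrt(v))
  })
  d <- res["d", ]; se <- res["se", ]
  tstat <- d / se
  if (adjust == "tukey") {
    p <- stats::ptukey(sqrt(2) * abs(tstat), k, df, lower.tail = FALSE)
    crit <- stats::qtukey(level, k, df) / sqrt(2)
  } else {
    p <- 2 * stats::pt(-abs(tstat), df)
    crit <- stats::qt((1 + level) / 2, df)
  }
  out <- data.frame(
    level1 = emm$level[pairs[1, ]],
    level2 = emm$level[pairs[2, ]],
    diff = d, se = se,
    ci_low = d - crit * se, ci_high = d + crit * se,
    t_ratio = tstat, p_adjusted = p,
    stringsAsFactors = FALSE)
  attr(out, "adjust") <- adjust
  attr(out, "df") <- df
  out
}

#' Marginal means split by preoperative opioid/substance status
#'
#' For a fit whose specification includes the subgroup-by-O&S interaction,
#' returns the 12 estimated marginal means (6 anesthesia subgroups crossed
#' with O&S yes/no) and the Tukey-adjusted pairwise contrasts over the
#' full 12-level grid.
#'
#' @param fit A `beta_fit` whose spec contains `"subgroup:oands_flag"`.
#' @param subgroup_var,oands_var Column names of the two factors.
#' @return A list: `emm` (12-row `pain_emm`) and `contrasts` (66-row
#'   contrast data frame).
#' @export
emmeans_by_oands <- function(fit, subgroup_var = "subgroup",
                             oands_var = "oands_flag") {
  ia <- paste(subgroup_var, oands_var, sep = ":")
  ia_rev <- paste(oands_var, subgroup_var, sep = ":")
  if (!any(c(ia, ia_rev) %in% (fit$spec$interactions %||% character(0))))
    stop("fit must include the ", ia, " interaction")
  tab <- table(fit$model_frame[[subgroup_var]], fit$model_frame[[oands_var]])
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("empty cell: subgroup ", rownames(tab)[bad[1]], ", ", oands_var,
         " = ", colnames(tab)[bad[2]])
  }
  emm <- beta_emmeans(fit, c(subgroup_var, oands_var))
  list(emm = emm, contrasts = pairwise_contrasts(emm, adjust = "tukey"))
}
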