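#' Default covariate set for the opioid-use model
#'
#' Same adjustment set as the primary composite-score analysis except the
#' postoperative opioid-administration flags, which define the outcome.
#'
#' @param outcome Outcome column name; default `"opioid_use"`.
#' @param interactions Optional interaction terms.
#' @return A [model_spec()].
#' @export
default_opioid_spec <- function(outcome = "opioid_use",
                                interactions = NULL) {
  model_spec(outcome,
             factors = c("subgroup", "sex", "enrolment_period",
                         "nonopioid_pre_intra", "nonopioid_post",
                         "oands_flag"),
             continuous = c("age", "weight"),
             offset_stratum = "country_income",
             interactions = interactions)
}

# Firth bias-reduced logistic regression (penalized likelihood with the
# Jeffreys prior), used when ordinary ML shows separation. Newton steps on
# the modified score U*(b) = X'(y - p + h (1/2 - p)).
firth_logistic <- function(X, y, maxit = 200, tol = 1e-8) {
  b <- numeric(ncol(X))
  I <- NULL
  for (it in seq_len(maxit)) {
    p <- stats::plogis(drop(X %*% b))
    W <- pmax(p * (1 - p), 1e-10)
    I <- crossprod(X * sqrt(W))
    Iinv <- tryCatch(solve(I), error = function(e)
      stop("singular information matrix in penalized logistic fit"))
    XW <- X * sqrt(W)
    h <- rowSums((XW %*% Iinv) * XW)
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    delta <- drop(Iinv %*% score)
    # step-halving to keep the update stable near separation
    while (max(abs(delta)) > 5) delta <- delta / 2
    b <- b + delta
    if (max(abs(delta)) < tol) break
  }
  if (max(abs(delta)) >= tol)
    warning("penalized logistic fit reached the iteration limit")
  list(coefficients = stats::setNames(b, colnames(X)), vcov = solve(I))
}

#' Logistic regression for postoperative opioid use
#'
#' Maximum-likelihood logistic regression of the dichotomous opioid-use
#' endpoint on the same covariates as the primary composite-score model,
#' with the reference anesthesia subgroup relevelled to general anesthesia
#' without a block (`GA-o`) so coefficients are log odds ratios against
#' that reference. Near-certain outcomes (opioid-use rates above 99\% in
#' the catheter subgroups) make separation plausible; when the ML fit
#' shows separation (non-convergence, boundary fitted probabilities or
#' runaway coefficients) the model is refitted by Firth penalized
#' likelihood with a warning, and the result carries `method = "firth"`.
#'
#' @param data Patient data frame including the outcome flag (see
#'   [opioid_use_flag()]).
#' @param spec A [model_spec()]; default [default_opioid_spec()].
#' @param reference Reference level for the subgroup factor.
#' @param group_var Name of the subgroup factor.
#' @return A `logit_fit`: coefficients, `vcov`, `method` (`"ml"` or
#'   `"firth"`), sample size, model frame and grid metadata.
#' @export
fit_logistic <- function(data, spec = default_opioid_spec(),
                         reference = "GA-o", group_var = "subgroup") {
  pf <- prepare_model_frame(data, spec)
  d <- pf$data
  if (group_var %in% names(d))
    d[[group_var]] <- stats::relevel(d[[group_var]], ref = reference)
  y <- d[[spec$outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("degenerate outcome: all opioid-use values identical")
  form <- spec_formula(spec)
  X <- stats::model.matrix(form, d)
  sep <- FALSE
  fit_ml <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit_ml$converged || any(abs(fit_ml$coefficients) > 15, na.rm = TRUE))
    sep <- TRUE
  if (sep) {
    warning("separation detected in the opioid-use model; ",
            "refitting with Firth penalized likelihood")
    ff <- firth_logistic(X, y)
    coefs <- ff$coefficients
    vc <- ff$vcov
    method <- "firth"
  } else {
    coefs <- fit_ml$coefficients
    w <- fit_ml$weights
    vc <- solve(crossprod(X * sqrt(w)))
    method <- "ml"
  }
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = coefs, vcov = vc, method = method,
    n_used = nrow(d), df_residual = nrow(d) - ncol(X),
    spec = spec, reference = reference, group_var = group_var,
    terms = stats::terms(form),
    xlevels = lapply(d[pf$fac_vars], levels),
    cov_means = vapply(d[pf$cont_vars], mean, 0),
    model_frame = d[spec_variables(spec)], outcome_values = y
  ), class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Logistic opioid-use model (", x$method, "), n = ", x$n_used,
      ", reference ", x$reference, "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Odds ratios with Wald confidence intervals
#'
#' @param fit A `logit_fit`.
#' @param level Confidence level.
#' @return Data frame with `term`, `or`, `ci_low`, `ci_high` and a
#'   `method` column echoing the fitting method (`ml` or `firth`).
#' @export
odds_ratios <- function(fit, level = 0.95) {
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm((1 + level) / 2)
  data.frame(term = names(fit$coefficients),
             or = exp(fit$coefficients),
             ci_low = exp(fit$coefficients - z * se),
             ci_high = exp(fit$coefficients + z * se),
             method = fit$method,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Marginal (g-computation) probability per subgroup level: set every
# record's subgroup to the level, average predicted probabilities.
gcomp_probs <- function(coefs, fit, data) {
  tt <- stats::delete.response(fit$terms)
  vapply(fit$xlevels[[fit$group_var]], function(lv) {
    nd <- data
    nd[[fit$group_var]][] <- lv
    X <- stats::model.matrix(tt, stats::model.frame(tt, nd,
                                                    xlev = fit$xlevels))
    mean(stats::plogis(drop(X %*% coefs[colnames(X)])))
  }, 0)
}

refit_coefs <- function(fit, X, y) {
  sep <- FALSE
  fm <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fm$converged || any(abs(fm$coefficients) > 15, na.rm = TRUE))
    sep <- TRUE
  if (sep || fit$method == "firth") firth_logistic(X, y)$coefficients
  else fm$coefficients
}

#' Percentage-point treatment contrasts by g-computation
#'
#' Adjusted differences in the percentage of patients receiving
#' postoperative opioids, obtained by marginal standardization
#' (g-computation): for each anesthesia subgroup the model predicts every
#' record's probability under counterfactual assignment to that subgroup,
#' the predictions are averaged, and pairwise differences of the averaged
#' probabilities are reported in percentage points. Confidence intervals
#' are nonparametric bootstrap percentiles over patients (default), or
#' delta-method (model-based) intervals; the method tag is always carried
#' in the result.
#'
#' @param fit A `logit_fit`.
#' @param B Number of bootstrap replicates (ignored for
#'   `ci_method = "delta"`).
#' @param seed RNG seed for the bootstrap.
#' @param ci_method `"bootstrap"` (default) or `"delta"`.
#' @param level Confidence level.
#' @return A `risk_contrast_set` data frame: one row per unordered pair
#'   with `diff_pp` (percentage points), `ci_low`, `ci_high`, `p_value`,
#'   plus attributes `marginal_probs`, `ci_method` and the fit method.
#' @export
risk_difference_contrasts <- function(fit, B = 1000, seed = 1,
                                      ci_method = c("bootstrap", "delta"),
                                      level = 0.95) {
  ci_method <- match.arg(ci_method)
  d <- fit$model_frame
  probs <- gcomp_probs(fit$coefficients, fit, d)
  levs <- names(probs)
  k <- length(levs)
  pairs <- utils::combn(k, 2)
  diff_pp <- 100 * (probs[pairs[1, ]] - probs[pairs[2, ]])

  if (ci_method == "delta") {
    tt <- stats::delete.response(fit$terms)
    G <- vapply(levs, function(lv) {
      nd <- d
      nd[[fit$group_var]][] <- lv
      X <- stats::model.matrix(tt, stats::model.frame(tt, nd,
                                                      xlev = fit$xlevels))
      p <- stats::plogis(drop(X %*% fit$coefficients[colnames(X)]))
      colMeans(X * (p * (1 - p)))
    }, numeric(length(fit$coefficients)))
    se <- apply(pairs, 2, function(ij) {
      g <- G[, ij[1]] - G[, ij[2]]
      100 * sqrt(drop(g %*% fit$vcov %*% g))
    })
    z <- stats::qnorm((1 + level) / 2)
    ci_low <- diff_pp - z * se
    ci_high <- diff_pp + z * se
    p_value <- 2 * stats::pnorm(-abs(diff_pp) / se)
  } else {
    tt <- stats::delete.response(fit$terms)
    mfX <- stats::model.matrix(tt, stats::model.frame(tt, d,
                                                      xlev = fit$xlevels))
    y <- fit$outcome_values
    n <- nrow(d)
    set.seed(seed)
    boot <- matrix(NA_real_, B, ncol(pairs))
    failures <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      pb <- tryCatch({
        cb <- refit_coefs(fit, mfX[idx, , drop = FALSE], y[idx])
        gcomp_probs(cb, fit, d[idx, , drop = FALSE])
      }, error = function(e) NULL)
      if (is.null(pb)) { failures <- failures + 1L; next }
      boot[b, ] <- 100 * (pb[pairs[1, ]] - pb[pairs[2, ]])
    }
    if (failures > 0.05 * B)
      stop("bootstrap failure rate above 5% (", failures, "/", B, ")")
    a <- (1 - level) / 2
    ci_low <- apply(boot, 2, stats::quantile, a, na.rm = TRUE)
    ci_high <- apply(boot, 2, stats::quantile, 1 - a, na.rm = TRUE)
    se <- apply(boot, 2, stats::sd, na.rm = TRUE)
    p_value <- 2 * stats::pnorm(-abs(diff_pp) / se)
  }

  out <- data.frame(level1 = levs[pairs[1, ]], level2 = levs[pairs[2, ]],
                    diff_pp = unname(diff_pp), ci_low = unname(ci_low),
                    ci_high = unname(ci_high), p_value = unname(p_value),
                    stringsAsFactors = FALSE)
  attr(out, "marginal_probs") <- probs
  attr(out, "ci_method") <- ci_method
  attr(out, "fit_method") <- fit$method
  attr(out, "reference") <- fit$reference
  class(out) <- c("risk_contrast_set", "data.frame")
  out
}
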