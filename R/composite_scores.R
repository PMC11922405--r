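#' Pain composite score (PCS)
#'
#' Combines worst pain, least pain (both NRS 0--10) and the fraction of the
#' first 24 postoperative hours spent in severe pain into a single
#' time-weighted intensity score:
#' \deqn{PCS = worst \cdot t + least \cdot (1 - t)}
#' where \eqn{t} is the time fraction. The result is a convex combination,
#' so it always lies between the least and worst pain ratings.
#'
#' @param worst,least Numeric rating scale values in \[0, 10\].
#' @param time_fraction Proportion of time in severe pain, in \[0, 1\].
#'   Percentages must be divided by 100 by the caller; values above 1 raise
#'   an error rather than being rescaled silently.
#' @return Numeric vector of PCS values on the 0--10 scale.
#' @examples
#' pcs(6, 2, 0.30)  # 3.2
#' @export
pcs <- function(worst, least, time_fraction) {
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 10))
  if (!ok(worst) || !ok(least))
    stop("worst and least pain must be NRS values in [0, 10]")
  if (any(!is.na(time_fraction) & time_fraction > 1))
    stop("time_fraction must be a proportion in [0, 1]; ",
         "divide a percentage by 100 before calling pcs()")
  if (any(!is.na(time_fraction) & time_fraction < 0))
    stop("time_fraction must be non-negative")
  worst * time_fraction + least * (1 - time_fraction)
}

#' Mean-of-items composite score
#'
#' Arithmetic mean of the non-missing NRS items, used for the
#' physical-interference (PITS), emotional-interference (EIS, anxiety and
#' helplessness) and adverse-events (AES) composites. The score is missing
#' when fewer than `min_items` items are answered; the strict default
#' requires every item (complete case, no imputation).
#'
#' @param items Numeric vector of NRS items in \[0, 10\] (single patient) or
#'   a matrix/data frame with one row per patient.
#' @param min_items Minimum number of non-missing items required; defaults
#'   to all items.
#' @return Numeric score(s) on 0--10, `NA` where too few items are present.
#' @export
item_mean_score <- function(items, min_items = NULL) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (!is.matrix(items)) items <- matrix(items, nrow = 1)
  if (ncol(items) == 0) stop("empty item schema")
  if (any(!is.na(items) & (items < 0 | items > 10)))
    stop("items must be NRS values in [0, 10]")
  if (is.null(min_items)) min_items <- ncol(items)
  n_ok <- rowSums(!is.na(items))
  out <- rowMeans(items, na.rm = TRUE)
  out[n_ok < min_items] <- NA_real_
  out[n_ok == 0] <- NA_real_
  out
}

#' Global patient-reported-outcome score (PRO-Score)
#'
#' Unweighted mean of the four composite scores (PCS, PITS, EIS, AES),
#' summarizing pain intensity, physical and emotional interference and
#' treatment-related adverse events into one measure of pain severity.
#' Missing in any component propagates (complete-case behaviour); custom
#' non-negative weights may be supplied.
#'
#' @param pcs,pits,eis,aes Component scores on 0--10.
#' @param weights Optional numeric weights of length 4 (renormalized to
#'   sum to one).
#' @return Numeric PRO-Score(s) on 0--10, `NA` where any component is
#'   missing.
#' @export
pro_score <- function(pcs, pits, eis, aes, weights = NULL) {
  m <- cbind(pcs, pits, eis, aes)
  if (is.null(weights)) weights <- rep(1, 4)
  if (length(weights) != 4 || any(weights < 0) || sum(weights) == 0)
    stop("weights must be 4 non-negative values with positive sum")
  w <- weights / sum(weights)
  out <- as.numeric(m %*% w)
  out[rowSums(is.na(m)) > 0] <- NA_real_
  out
}

#' Rescale NRS scores into the open unit interval
#'
#' Beta-distributed outcome models require responses strictly inside
#' (0, 1). Scores on 0--10 are first multiplied by 0.1; exact boundary
#' values are then handled by the chosen strategy. The default
#' `"compression"` applies the standard proportion compression
#' \eqn{y' = (y (n - 1) + 0.5) / n} with \eqn{n} the effective sample size,
#' which is strictly monotone, maps \[0, 1\] into (0, 1) and vanishes as
#' \eqn{n \to \infty}. The alternative `"epsilon"` clamps to
#' \eqn{[\epsilon, 1 - \epsilon]}.
#'
#' @param values Numeric scores in \[0, 10\].
#' @param n_effective Effective sample size (>= 2) used by the compression.
#' @param method `"compression"` (default) or `"epsilon"`.
#' @param epsilon Clamp width for `method = "epsilon"`.
#' @return Numeric vector strictly inside (0, 1).
#' @seealso [inverse_rescale()]
#' @export
rescale_to_open_unit <- function(values, n_effective,
                                 method = c("compression", "epsilon"),
                                 epsilon = 1e-4) {
  method <- match.arg(method)
  if (any(!is.na(values) & (values < 0 | values > 10)))
    stop("values must lie in [0, 10]")
  if (n_effective < 2) stop("n_effective must be >= 2")
  y <- values * 0.1
  if (method == "compression") {
    (y * (n_effective - 1) + 0.5) / n_effective
  } else {
    pmin(pmax(y, epsilon), 1 - epsilon)
  }
}

#' Invert the open-unit-interval rescaling
#'
#' @param y Values in (0, 1) produced by [rescale_to_open_unit()] with
#'   `method = "compression"`.
#' @param n_effective The effective sample size used in the forward map.
#' @return Scores on the original 0--10 scale.
#' @export
inverse_rescale <- function(y, n_effective) {
  10 * (y * n_effective - 0.5) / (n_effective - 1)
}

#' Default item schema for the composite scores
#'
#' Names the registry columns feeding each mean-of-items composite:
#' three physical-interference items (PITS), the anxiety and helplessness
#' items (EIS), and four adverse-event items (AES). The schema is
#' configuration: registries with different questionnaire layouts supply
#' their own column lists.
#'
#' @return Named list of character vectors `pits`, `eis`, `aes`.
#' @export
default_item_schema <- function() {
  list(
    pits = c("interf_activity", "interf_sleep", "interf_breathing"),
    eis = c("anxiety", "helplessness"),
    aes = c("ae_nausea", "ae_drowsiness", "ae_itching", "ae_dizziness")
  )
}

#' Append composite scores to a registry patient table
#'
#' Computes PCS, PITS, EIS, AES and the PRO-Score for every patient and
#' appends them as columns. `time_severe_pct` is divided by 100 before
#' entering the PCS. Missingness propagates: a composite is `NA` whenever
#' its inputs are incomplete, and the PRO-Score is `NA` unless all four
#' composites are present.
#'
#' @param patients Data frame with the columns named by the dictionary and
#'   schema.
#' @param schema Item schema, see [default_item_schema()].
#' @param min_items Passed to [item_mean_score()]; default all items.
#' @return The input data frame with columns `pcs`, `pits`, `eis`, `aes`,
#'   `pro_score` appended.
#' @export
score_patients <- function(patients, schema = default_item_schema(),
                           min_items = NULL) {
  for (nm in names(schema)) {
    absent <- setdiff(schema[[nm]], names(patients))
    if (length(absent))
      stop("schema column(s) missing for ", nm, ": ",
           paste(absent, collapse = ", "))
  }
  patients$pcs <- pcs(patients$worst_pain, patients$least_pain,
                      patients$time_severe_pct / 100)
  patients$pits <- item_mean_score(patients[schema$pits], min_items)
  patients$eis <- item_mean_score(patients[schema$eis], min_items)
  patients$aes <- item_mean_score(patients[schema$aes], min_items)
  patients$pro_score <- pro_score(patients$pcs, patients$pits,
                                  patients$eis, patients$aes)
  patients
}
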