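#' Anesthesia subgroup labels, in report order
#'
#' The six anesthesia subgroups formed by crossing the primary technique
#' (general vs spinal anesthesia) with the peripheral-nerve-block mode
#' (none, single-injection, continuous catheter). The order is the fixed
#' report/table order used throughout the package.
#'
#' @return Character vector of the six subgroup labels.
#' @export
subgroup_levels <- function() {
  c("GA-o", "GA&PNBc", "GA&PNBs", "SA-o", "SA&PNBc", "SA&PNBs")
}

#' Registry data dictionary
#'
#' Returns the data dictionary for per-patient registry records: one row per
#' field with its type, allowed values and whether the column is mandatory
#' in an input CSV. Numeric rating scale (NRS) items are integers on 0--10;
#' `time_severe_pct` is the percentage of the first 24 postoperative hours
#' spent in severe pain, recorded on a 10\% grid.
#'
#' @return A data frame with columns `field`, `type`, `values`, `required`.
#' @export
registry_dictionary <- function() {
  f <- function(field, type, values = "", required = FALSE)
    data.frame(field = field, type = type, values = values,
               required = required, stringsAsFactors = FALSE)
  rbind(
    f("patient_id", "character", required = TRUE),
    f("sex", "factor", "female|male"),
    f("age", "integer", "years, >=18 after plausibility filtering"),
    f("weight", "numeric", "kg, >=34 after plausibility filtering"),
    f("anesthesia_primary", "factor", "GA|SA|GA+SA|GA+epidural", required = TRUE),
    f("pnb_mode", "factor", "none|single|continuous", required = TRUE),
    f("pnb_site", "factor", "femoral|adductor_canal|sciatic|combination"),
    f("country_income", "factor", "high|middle_low"),
    f("enrolment_period", "factor", "P2010_2012|P2013_2017|P2017_2020"),
    f("preexisting_pain", "logical"),
    f("preexisting_pain_intensity", "integer", "NRS 0-10"),
    f("preexisting_pain_location", "factor", "site_of_surgery|elsewhere|both"),
    f("oands_flag", "logical", "preoperative opioid medication and/or substance abuse"),
    f("preop_me_mg", "numeric", "mg/day oral morphine equivalent"),
    f("worst_pain", "integer", "NRS 0-10", required = TRUE),
    f("least_pain", "integer", "NRS 0-10", required = TRUE),
    f("time_severe_pct", "numeric", "0-100, 10% grid", required = TRUE),
    f("interf_activity", "integer", "NRS 0-10"),
    f("interf_sleep", "integer", "NRS 0-10"),
    f("interf_breathing", "integer", "NRS 0-10"),
    f("anxiety", "integer", "NRS 0-10"),
    f("helplessness", "integer", "NRS 0-10"),
    f("ae_nausea", "integer", "NRS 0-10"),
    f("ae_drowsiness", "integer", "NRS 0-10"),
    f("ae_itching", "integer", "NRS 0-10"),
    f("ae_dizziness", "integer", "NRS 0-10"),
    f("nonopioid_pre_intra", "logical"),
    f("nonopioid_post", "logical"),
    f("opioid_pacu", "logical"),
    f("opioid_ward", "logical"),
    f("desire_more_treatment", "logical"),
    f("satisfaction", "integer", "NRS 0-10"),
    f("allowed_participate", "integer", "NRS 0-10"),
    f("pain_relief_pct", "numeric", "0-100")
  )
}

# Columns of the long-format administrations table.
admin_columns <- function() c("patient_id", "drug", "route", "dose_mg")

coerce_field <- function(x, type, values) {
  x <- as.character(x)
  x[x == "" | x == "NA"] <- NA_character_
  switch(type,
    character = x,
    integer = suppressWarnings(as.integer(x)),
    numeric = suppressWarnings(as.numeric(x)),
    logical = {
      lx <- tolower(x)
      out <- rep(NA, length(x))
      out[lx %in% c("true", "t", "1", "yes")] <- TRUE
      out[lx %in% c("false", "f", "0", "no")] <- FALSE
      out
    },
    factor = {
      lev <- strsplit(values, "|", fixed = TRUE)[[1]]
      x[!is.na(x) & !(x %in% lev)] <- NA_character_
      factor(x, levels = lev)
    },
    x)
}

#' Read a registry CSV (plus optional administrations CSV)
#'
#' Reads a per-patient registry CSV against the shipped data dictionary
#' ([registry_dictionary()]). Unknown columns are dropped with a warning;
#' unparseable cells become missing (never silently coerced) and are counted
#' in the parse report. Missing values are encoded as empty cells or `"NA"`.
#' Postoperative analgesic administrations live in a companion long-format
#' CSV keyed by `patient_id` with columns `drug`, `route`, `dose_mg`.
#'
#' @param path Path to the patient-level CSV (UTF-8, comma separated, header).
#' @param admin_path Optional path to the administrations CSV.
#' @return A `pain_registry`: a list with elements `patients` (data frame),
#'   `administrations` (data frame), and `parse_report` (list with
#'   `n_rows`, `n_unparseable`, `missing_by_field`).
#' @export
read_registry <- function(path, admin_path = NULL) {
  dict <- registry_dictionary()
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- dict$field[dict$required]
  absent <- setdiff(need, names(raw))
  if (length(absent))
    stop("registry schema error: mandatory column(s) missing: ",
         paste(absent, collapse = ", "))
  unknown <- setdiff(names(raw), dict$field)
  if (length(unknown))
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))

  n_unparseable <- 0L
  patients <- data.frame(row.names = seq_len(nrow(raw)))
  for (i in seq_len(nrow(dict))) {
    fld <- dict$field[i]
    if (!fld %in% names(raw)) next
    raw_col <- as.character(raw[[fld]])
    was_filled <- !(is.na(raw_col) | raw_col == "" | raw_col == "NA")
    val <- coerce_field(raw_col, dict$type[i], dict$values[i])
    bad <- was_filled & is.na(val)
    if (any(bad)) {
      n_unparseable <- n_unparseable + sum(bad)
      warning(sum(bad), " unparseable value(s) in column '", fld,
              "' set to missing")
    }
    patients[[fld]] <- val
  }

  administrations <- empty_administrations()
  if (!is.null(admin_path)) {
    adm <- utils::read.csv(admin_path, colClasses = "character")
    miss <- setdiff(admin_columns(), names(adm))
    if (length(miss))
      stop("administrations schema error: missing column(s): ",
           paste(miss, collapse = ", "))
    administrations <- data.frame(
      patient_id = adm$patient_id,
      drug = tolower(adm$drug),
      route = adm$route,
      dose_mg = suppressWarnings(as.numeric(adm$dose_mg)),
      stringsAsFactors = FALSE)
  }

  structure(list(
    patients = patients,
    administrations = administrations,
    parse_report = list(
      n_rows = nrow(patients),
      n_unparseable = n_unparseable,
      missing_by_field = vapply(patients, function(x) sum(is.na(x)), 0L))
  ), class = "pain_registry")
}

empty_administrations <- function() {
  data.frame(patient_id = character(), drug = character(),
             route = character(), dose_mg = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a registry to CSV
#'
#' @param registry A `pain_registry`.
#' @param path Output CSV for the patient table.
#' @param admin_path Optional output CSV for administrations.
#' @return Invisibly, `path`.
#' @export
write_registry <- function(registry, path, admin_path = NULL) {
  utils::write.csv(registry$patients, path, row.names = FALSE, na = "")
  if (!is.null(admin_path))
    utils::write.csv(registry$administrations, admin_path,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.pain_registry <- function(x, ...) {
  cat("pain_registry:", nrow(x$patients), "patients,",
      nrow(x$administrations), "analgesic administrations\n")
  invisible(x)
}

#' Allocate anesthesia subgroups
#'
#' Deterministically maps the primary anesthesia technique crossed with the
#' peripheral-nerve-block mode onto the six anesthesia subgroups. Records
#' with a combined spinal + general technique are interpreted as failed
#' spinal anesthesia and excluded; combined general + epidural records are
#' excluded because the depth of anesthesia cannot be determined; records
#' with missing block mode are excluded as incomplete. Exclusion reasons are
#' assigned first-match in the order failed_SA, epidural, incomplete.
#'
#' @param anesthesia_primary Character/factor: `GA`, `SA`, `GA+SA`,
#'   `GA+epidural`.
#' @param pnb_mode Character/factor: `none`, `single`, `continuous`
#'   (may be `NA`).
#' @return Character vector: one of [subgroup_levels()] or an exclusion
#'   token `excluded:failed_SA`, `excluded:epidural`,
#'   `excluded:incomplete_anesthesia`.
#' @export
allocate_subgroup <- function(anesthesia_primary, pnb_mode) {
  ap <- as.character(anesthesia_primary)
  pm <- as.character(pnb_mode)
  if (length(pm) == 1L && length(ap) > 1L) pm <- rep(pm, length(ap))
  stopifnot(length(ap) == length(pm))
  out <- character(length(ap))
  out[is.na(ap)] <- "excluded:incomplete_anesthesia"
  out[!is.na(ap) & ap == "GA+SA"] <- "excluded:failed_SA"
  out[!is.na(ap) & ap == "GA+epidural" & out == ""] <- "excluded:epidural"
  todo <- out == ""
  out[todo & is.na(pm)] <- "excluded:incomplete_anesthesia"
  todo <- out == ""
  suffix <- c(none = "-o", single = "&PNBs", continuous = "&PNBc")
  out[todo] <- paste0(ap[todo], suffix[pm[todo]])
  out
}

#' Default per-drug dose plausibility bounds
#'
#' Permissive upper bounds (mg per single administration) used by
#' [plausibility_filter()] to drop clearly implausible analgesic
#' administration entries. The bounds are configuration, not clinical
#' guidance; a registry curator should tighten them per site.
#'
#' @return Named numeric vector: drug -> maximum plausible single dose (mg).
#' @export
default_dose_bounds <- function() {
  c(morphine = 1000, oxycodone = 1000, piritramide = 1000,
    tramadol = 2000, tapentadol = 2000, fentanyl = 10,
    hydromorphone = 200)
}

#' Plausibility filtering of registry records
#'
#' Removes patients failing basic plausibility (age below 18 years or body
#' weight below 34 kg; boundary values are kept). Analgesic administrations
#' with non-positive or implausibly large doses are dropped from the
#' administrations table while the patient record is kept; every removal is
#' counted in the exclusion log, so kept + excluded always equals the input
#' count.
#'
#' @param registry A `pain_registry`.
#' @param dose_bounds Named numeric vector of per-drug maximum plausible
#'   single doses in mg; see [default_dose_bounds()]. Drugs not listed are
#'   left untouched.
#' @return A list: `registry` (filtered `pain_registry`), `exclusion_log`
#'   (named integer vector reason -> patient count), and
#'   `dropped_administrations` (data frame of removed administration rows).
#' @export
plausibility_filter <- function(registry, dose_bounds = default_dose_bounds()) {
  p <- registry$patients
  drop_age <- !is.na(p$age) & p$age < 18
  drop_wt  <- !is.na(p$weight) & p$weight < 34 & !drop_age
  keep <- !(drop_age | (!is.na(p$weight) & p$weight < 34))
  log <- c("age<18" = sum(drop_age), "weight<34" = sum(drop_wt))

  adm <- registry$administrations
  dropped_adm <- adm[0, ]
  if (nrow(adm)) {
    bound <- dose_bounds[adm$drug]
    bad <- (!is.na(adm$dose_mg) & adm$dose_mg < 0) |
      (!is.na(bound) & !is.na(adm$dose_mg) & adm$dose_mg > bound)
    dropped_adm <- adm[bad, , drop = FALSE]
    adm <- adm[!bad, , drop = FALSE]
  }
  kept_ids <- p$patient_id[keep]
  adm <- adm[adm$patient_id %in% kept_ids, , drop = FALSE]

  out <- registry
  out$patients <- p[keep, , drop = FALSE]
  rownames(out$patients) <- NULL
  out$administrations <- adm
  list(registry = out, exclusion_log = log,
       dropped_administrations = dropped_adm)
}

#' Complete-case subsetting
#'
#' Retains only the records with non-missing values for every listed
#' variable. No imputation is performed anywhere in the package; every
#' analysis step is run on complete cases for the variables it uses.
#'
#' @param data Data frame of patient records.
#' @param variables Character vector of column names that must be
#'   non-missing. An empty vector keeps all records.
#' @return The subset data frame, with attribute `missingness` giving the
#'   per-variable count of missing values in the input.
#' @export
complete_case_subset <- function(data, variables) {
  unknown <- setdiff(variables, names(data))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  if (!length(variables)) {
    attr(data, "missingness") <- integer(0)
    return(data)
  }
  miss <- vapply(data[variables], function(x) sum(is.na(x)), 0L)
  keep <- rowSums(is.na(data[variables])) == 0
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missingness") <- miss
  out
}
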