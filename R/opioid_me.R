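#' Default opioid-to-oral-morphine conversion table
#'
#' A versioned table of (drug, route) conversion factors expressing each
#' dose as mg of oral morphine equivalent (ME). Oral morphine is the
#' anchor with factor exactly 1; parenteral morphine uses the conventional
#' 3:1 oral:iv potency ratio, and piritramide is chained through its
#' iv-morphine equivalence. Conversion references differ across sources,
#' so the table carries a version tag that is echoed in every report, and
#' users can supply their own table with the same columns.
#'
#' @return Data frame with columns `drug`, `route`, `factor` and attribute
#'   `version`.
#' @export
default_conversion_table <- function() {
  tab <- data.frame(
    drug = c("morphine", "morphine", "oxycodone", "piritramide",
             "piritramide", "tramadol", "tapentadol", "fentanyl",
             "hydromorphone"),
    route = c("oral", "iv", "oral", "iv", "sc", "oral", "oral", "iv",
              "oral"),
    factor = c(1, 3, 1.5, 2, 2, 0.1, 0.3, 300, 5),
    stringsAsFactors = FALSE)
  attr(tab, "version") <- "painpro-me-1.0"
  class(tab) <- c("conversion_table", "data.frame")
  tab
}

#' Convert an opioid dose to oral morphine equivalents
#'
#' Multiplies each dose by the (drug, route) factor from the conversion
#' table. Subcutaneous administrations fall back to the intravenous factor
#' when no dedicated `sc` entry exists (common ME practice). Unknown
#' (drug, route) pairs convert to `NA` with a warning -- never to zero.
#'
#' @param drug Character vector of drug names (case-insensitive).
#' @param route Character vector: `oral`, `iv`, `sc`, `other`.
#' @param dose_mg Non-negative doses in mg.
#' @param table Conversion table; see [default_conversion_table()].
#' @return Numeric vector of ME doses in mg (`NA` where unconvertible).
#' @export
to_me <- function(drug, route, dose_mg, table = default_conversion_table()) {
  if (any(!is.na(dose_mg) & dose_mg < 0)) stop("dose_mg must be >= 0")
  drug <- tolower(as.character(drug))
  route <- tolower(as.character(route))
  key <- paste(drug, route)
  fac <- table$factor[match(key, paste(table$drug, table$route))]
  # sc falls back to the iv factor where no sc-specific entry exists
  sc_miss <- is.na(fac) & route == "sc"
  if (any(sc_miss)) {
    key_iv <- paste(drug[sc_miss], "iv")
    fac[sc_miss] <- table$factor[match(key_iv, paste(table$drug, table$route))]
  }
  unknown <- is.na(fac) & !is.na(drug) & !is.na(dose_mg)
  if (any(unknown))
    warning("no conversion factor for: ",
            paste(unique(key[unknown]), collapse = "; "),
            " (dose set to missing)")
  fac * dose_mg
}

#' Total 24-hour morphine equivalent per patient
#'
#' Sums the oral morphine equivalents of all postoperative administrations
#' (postanesthesia care unit + ward) in the first 24 hours for each
#' patient. Patients with no recorded administration get 0 mg; a patient
#' with any unconvertible administration gets `NA` (complete-case
#' propagation rather than a silently truncated sum).
#'
#' @param patients Data frame with a `patient_id` column.
#' @param administrations Long-format data frame (`patient_id`, `drug`,
#'   `route`, `dose_mg`).
#' @param table Conversion table.
#' @return Numeric vector of ME mg aligned with `patients` rows.
#' @export
me_24h <- function(patients, administrations,
                   table = default_conversion_table()) {
  out <- numeric(nrow(patients))
  if (!nrow(administrations)) return(out)
  me <- suppressWarnings(
    to_me(administrations$drug, administrations$route,
          administrations$dose_mg, table))
  sums <- tapply(me, administrations$patient_id, sum)  # NA if any NA
  idx <- match(patients$patient_id, names(sums))
  got <- !is.na(idx)
  out[got] <- sums[idx[got]]
  out
}

#' Postoperative opioid use flag
#'
#' `TRUE` if the patient received any opioid postoperatively: either chart
#' flag (postanesthesia care unit or ward) is set, or at least one
#' administration is recorded -- the flag is event based, so a recorded
#' zero-dose administration still counts as use.
#'
#' @param patients Data frame with `patient_id` and optional logical
#'   columns `opioid_pacu`, `opioid_ward`.
#' @param administrations Long-format administrations data frame.
#' @return Logical vector aligned with `patients` rows.
#' @export
opioid_use_flag <- function(patients, administrations = NULL) {
  n <- nrow(patients)
  flag <- rep(FALSE, n)
  for (col in c("opioid_pacu", "opioid_ward"))
    if (col %in% names(patients))
      flag <- flag | (!is.na(patients[[col]]) & patients[[col]])
  if (!is.null(administrations) && nrow(administrations))
    flag <- flag | patients$patient_id %in% administrations$patient_id
  flag
}
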