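#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> filter -> score -> fit -> report on a single
#' configuration: generates (or reads) a registry, applies plausibility
#' filtering and subgroup allocation, computes the composite scores and
#' morphine equivalents, fits the adjusted beta-outcome model for the pain
#' composite score (marginal means + Tukey pairwise contrasts) and the
#' logistic opioid-use model (odds ratios + g-computation percentage-point
#' contrasts), and writes all artifacts plus a run manifest.
#'
#' The configuration is a named list (or a YAML file with the same
#' structure) with elements: `seed`, and optionally `n`, `registry_csv` /
#' `admin_csv` (to analyze an existing registry instead of simulating),
#' `bootstrap_B` (default 200), `emm_adjust` (default `"tukey"`).
#' All randomness derives from the single top-level seed.
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (list), invisibly written as
#'   `manifest.json`. Artifacts: `registry.csv`, `administrations.csv`,
#'   `scored.csv`, `exclusions.json`, `emm.csv`, `contrasts.csv`,
#'   `odds_ratios.csv`, `risk_contrasts.csv`, `summary_table.csv`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  problems <- character(0)
  if (is.null(config$seed)) problems <- c(problems, "missing 'seed'")
  if (is.null(config$registry_csv) && is.null(config$n))
    problems <- c(problems, "need either 'n' (simulate) or 'registry_csv'")
  if (length(problems))
    stop("config error(s): ", paste(problems, collapse = "; "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  manifest <- list(seed = config$seed, stages = list(), outputs = character(0))
  res <- tryCatch({
    if (!is.null(config$registry_csv)) {
      registry <- read_registry(config$registry_csv, config$admin_csv)
      truth <- NULL
    } else {
      sim <- generate_registry(default_paperlike_config(
        n = config$n, seed = config$seed))
      registry <- sim$registry
      truth <- sim$truth
    }
    manifest$stages$simulate <- list(n = nrow(registry$patients))

    stage <- "filter"
    flt <- plausibility_filter(registry)
    registry <- flt$registry
    pts <- registry$patients
    if (!"subgroup" %in% names(pts)) {
      alloc <- allocate_subgroup(pts$anesthesia_primary, pts$pnb_mode)
      excluded <- grepl("^excluded:", alloc)
      pts$subgroup <- factor(ifelse(excluded, NA, alloc),
                             levels = subgroup_levels())
      flt$exclusion_log <- c(flt$exclusion_log,
                             table(sub("^excluded:", "", alloc[excluded])))
      pts <- pts[!excluded, , drop = FALSE]
    }
    manifest$stages$filter <- list(
      kept = nrow(pts), exclusion_log = as.list(flt$exclusion_log))

    stage <- "score"
    pts <- score_patients(pts)
    pts$opioid_use <- opioid_use_flag(pts, registry$administrations)
    pts$me_mg <- me_24h(pts, registry$administrations)
    manifest$stages$score <- list(
      n_scored = sum(!is.na(pts$pro_score)),
      conversion_table = attr(default_conversion_table(), "version"))

    stage <- "fit_pcs"
    fit1 <- fit_beta(pts, default_model_spec("pcs"))
    emm <- beta_emmeans(fit1, "subgroup")
    ctr <- pairwise_contrasts(emm, adjust = config$emm_adjust %||% "tukey")
    manifest$stages$fit_pcs <- list(n_used = fit1$n_used,
                                    phi = fit1$phi)

    stage <- "fit_opioid_use"
    fit2 <- fit_logistic(pts, default_opioid_spec())
    ors <- odds_ratios(fit2)
    rsk <- risk_difference_contrasts(
      fit2, B = config$bootstrap_B %||% 200, seed = config$seed)
    manifest$stages$fit_opioid_use <- list(n_used = fit2$n_used,
                                           method = fit2$method)

    stage <- "report"
    tab <- summarize_groups(
      pts, c("age", "weight", "pcs", "pits", "eis", "aes", "pro_score"),
      "subgroup")
    list(registry = registry, patients = pts, truth = truth, fit_pcs = fit1,
         emm = emm, contrasts = ctr, fit_opioid = fit2, odds_ratios = ors,
         risk_contrasts = rsk, summary_table = tab,
         exclusion_log = flt$exclusion_log)
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e)))

  wr <- function(obj, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(obj, path, row.names = FALSE, na = "")
    manifest$outputs <<- c(manifest$outputs, file)
    path
  }
  wr(res$patients, "scored.csv")
  wr(res$registry$administrations, "administrations.csv")
  wr(as.data.frame(res$emm), "emm.csv")
  wr(res$contrasts, "contrasts.csv")
  wr(res$odds_ratios, "odds_ratios.csv")
  wr(as.data.frame(res$risk_contrasts), "risk_contrasts.csv")
  wr(as.data.frame(res$summary_table), "summary_table.csv")
  jsonlite::write_json(as.list(res$exclusion_log),
                       file.path(out_dir, "exclusions.json"),
                       auto_unbox = TRUE)
  manifest$outputs <- c(manifest$outputs, "exclusions.json")

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  manifest$output_hashes <- as.list(
    tools::md5sum(file.path(out_dir, manifest$outputs)))
  names(manifest$output_hashes) <- manifest$outputs
  manifest$package_version <- as.character(
    utils::packageVersion("painpro"))
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(res, list(manifest = manifest)))
}
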