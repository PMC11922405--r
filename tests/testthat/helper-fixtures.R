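# Shared fixtures, generated in code at test time.

# Minimal well-formed registry CSV with the mandatory columns plus a few
# optional ones; returns the file path.
write_fixture_csv <- function(path = tempfile(fileext = ".csv"),
                              rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      patient_id = c("A1", "A2", "A3"),
      sex = c("female", "male", "female"),
      age = c("64", "71", "58"),
      weight = c("80", "92", "67"),
      anesthesia_primary = c("GA", "SA", "SA"),
      pnb_mode = c("none", "continuous", "single"),
      country_income = c("high", "high", "middle_low"),
      worst_pain = c("6", "8", "4"),
      least_pain = c("2", "3", "0"),
      time_severe_pct = c("30", "50", "10"),
      stringsAsFactors = FALSE)
  }
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

# Small scored data set with a known two-level group and beta outcome,
# used by the model unit tests.
make_beta_data <- function(n = 300, mu = c(a = 0.30, b = 0.40), phi = 8,
                           seed = 42) {
  set.seed(seed)
  g <- factor(rep(names(mu), length.out = n))
  y <- rbeta(n, mu[g] * phi, (1 - mu[g]) * phi)
  data.frame(g = g, pcs = 10 * y, x = rnorm(n))
}

# Tiny config used when full paper-scale defaults are not needed.
small_config <- function(n = 800, seed = 1, ...) {
  cfg <- default_paperlike_config(n = n, seed = seed)
  mods <- list(...)
  for (nm in names(mods)) cfg[[nm]] <- mods[[nm]]
  cfg
}
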