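# Shared fixtures. The default n=400 cohort (seed 1) is expensive, so it is
# generated once per test run and reused across property tests.

.lprx_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.lprx_test_cache[[key]]))
    assign(key, expr, envir = .lprx_test_cache)
  get(key, envir = .lprx_test_cache)
}

default_cohort <- function() {
  cached("cohort400", generate_cohort(sim_params(n_patients = 400L, seed = 1L)))
}

default_clean <- function() {
  cached("clean400", lapply(default_cohort()$records, clean_record))
}

# per-patient grand mean LPRx over the full recording
default_means <- function(window = 10L, imputed = FALSE) {
  cached(sprintf("means_%d_%s", window, imputed),
         vapply(default_clean(), function(r) {
           mean(compute_lprx(r, window, use_imputation = imputed)$lprx,
                na.rm = TRUE)
         }, numeric(1)))
}

# independently coded textbook Pearson formula (the oracle; deliberately not
# the package's rolling implementation and not stats::cor)
naive_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  k <- length(x)
  num <- k * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(k * sum(x^2) - sum(x)^2) * sqrt(k * sum(y^2) - sum(y)^2)
  num / den
}

small_record <- function(rho = 0.5, days = 1, seed = 7, monitor = "IPD",
                         params = sim_params(), gos = 3L, drain = NULL) {
  ser <- generate_patient_series(rho, days * 1440, params, seed)
  patient_record(paste0("T", seed), monitor, ser$icp, ser$map, drain, gos)
}

# a constant-value index series covering `minutes` minutes
const_index <- function(value, minutes, window = 10L) {
  index_series(t = seq_len(minutes), lprx = rep(value, minutes),
               window_minutes = window)
}
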