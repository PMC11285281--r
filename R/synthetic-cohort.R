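#' Simulation parameters for a synthetic neuromonitoring cohort
#'
#' Captures the statistical world the downstream analysis assumes: sporadic
#' 0.5--5-min median sampling (1-min median inter-sample interval, IQR
#' 1--2 min), slow-wave MAP fluctuations coupled into ICP with a per-patient
#' latent reactivity coefficient `rho`, out-of-range artifact spikes, EVD
#' open-drain gaps, stays of roughly 1--16 days, and Glasgow Outcome Scale
#' outcomes statistically linked to reactivity.
#'
#' The ICP/MAP coupling uses a shared-component mixture: with `Z` the
#' standardized MAP fluctuation and `W` an independent standardized process
#' of the same spectral make-up, the ICP fluctuation is
#' `rho * Z + sqrt(1 - rho^2) * W`, so the population-expected Pearson
#' correlation of paired samples equals `rho` exactly. This makes the latent
#' reactivity a checkable ground truth.
#'
#' @param n_patients number of patients.
#' @param stay_range_days uniform range of monitored stay length (days).
#' @param map_baseline,icp_baseline baseline pressures (mmHg).
#' @param slow_wave_period_range per-patient slow-wave period range (min).
#' @param slow_wave_amplitude total slow-wave amplitude (mmHg); the slow wave
#'   is a sum of 1--3 sinusoids with random periods/phases whose squared
#'   amplitudes sum to `slow_wave_amplitude^2`.
#' @param noise_sd_map,noise_sd_icp independent white-noise SDs (mmHg).
#' @param icp_fluct_sd total SD of the ICP fluctuation component (mmHg).
#' @param reactivity_distribution per-patient latent reactivity: a list with
#'   `kind` one of `"truncnorm"` (fields `mean`, `sd`; normal truncated to
#'   \[-1, 1\]), `"uniform"` (`lo`, `hi`) or `"fixed"` (`value`).
#' @param outcome_model death model on `rho`: `list(kind = "step",
#'   theta_star=, p_below=, p_above=)` (probability of death below/above the
#'   reactivity break point) or `list(kind = "logistic", intercept=, slope=)`.
#' @param favorable_model logistic model for favorable outcome (GOS 4--5)
#'   among survivors: `list(intercept=, slope=)` on `rho`; deliberately
#'   weaker than the death model.
#' @param frac_evd fraction of patients monitored by EVD.
#' @param drainage_rate expected open-drain episodes per day (EVD only).
#' @param artifact_rate expected out-of-range spikes per day and signal.
#' @param sampling_interval_range admissible inter-sample intervals (min);
#'   intervals are drawn from \{0.5, 1, 2, 3, 5\} min with weights
#'   (.05, .55, .30, .05, .05), then clamped to this range, reproducing the
#'   1-min median / 1--2-min IQR sampling of bedside archives.
#' @param icp_wander slow MAP-independent ICP baseline variation (B-wave /
#'   CSF-dynamics stand-in): `list(amplitude =, period_range =)` in mmHg and
#'   minutes, added to ICP outside the coupling mixture. It moves little
#'   within a 10-min window but contributes real variance within 60--120-min
#'   windows, attenuating long-window LPRx values toward zero. Note that
#'   this rescales patient summaries roughly monotonically, so it does not
#'   (and cannot) reproduce the clinically observed chi-square degradation
#'   with window length; see the methods vignette.
#'   It is an independent noise source: the perfect-coupling limit
#'   (LPRx = +1 everywhere at `rho = 1`) requires `amplitude = 0` together
#'   with `noise_sd_icp = 0`.
#' @param reactivity_drift either `list(kind = "none")` (reactivity constant
#'   over the stay) or `list(kind = "redraw", day =)` (after `day` days the
#'   coupling switches to a fresh, outcome-independent draw, so late-stay
#'   physiology decouples from outcome).
#' @param seed integer RNG seed.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_patients = 400L,
                       stay_range_days = c(1, 16),
                       map_baseline = 78, icp_baseline = 12,
                       slow_wave_period_range = c(10, 60),
                       slow_wave_amplitude = 5,
                       noise_sd_map = 3, noise_sd_icp = 3,
                       icp_fluct_sd = 3,
                       reactivity_distribution = list(kind = "truncnorm",
                                                      mean = 0.1, sd = 0.3),
                       outcome_model = list(kind = "step", theta_star = 0.3,
                                            p_below = 0.05, p_above = 0.6),
                       favorable_model = list(intercept = 0.6, slope = -3),
                       frac_evd = 0.52,
                       drainage_rate = 2,
                       artifact_rate = 2,
                       sampling_interval_range = c(0.5, 5),
                       icp_wander = list(amplitude = 2,
                                         period_range = c(120, 480)),
                       reactivity_drift = list(kind = "none"),
                       seed = 1L) {
  p <- list(n_patients = as.integer(n_patients),
            stay_range_days = as.numeric(stay_range_days),
            map_baseline = map_baseline, icp_baseline = icp_baseline,
            slow_wave_period_range = as.numeric(slow_wave_period_range),
            slow_wave_amplitude = slow_wave_amplitude,
            noise_sd_map = noise_sd_map, noise_sd_icp = noise_sd_icp,
            icp_fluct_sd = icp_fluct_sd,
            reactivity_distribution = reactivity_distribution,
            outcome_model = outcome_model, favorable_model = favorable_model,
            frac_evd = frac_evd, drainage_rate = drainage_rate,
            artifact_rate = artifact_rate,
            sampling_interval_range = as.numeric(sampling_interval_range),
            icp_wander = icp_wander,
            reactivity_drift = reactivity_drift,
            seed = as.integer(seed))
  stopifnot(p$n_patients >= 0L,
            length(p$stay_range_days) == 2L, all(p$stay_range_days > 0),
            p$stay_range_days[1] <= p$stay_range_days[2],
            p$slow_wave_amplitude >= 0, p$noise_sd_map >= 0,
            p$noise_sd_icp >= 0, p$icp_fluct_sd >= 0,
            p$frac_evd >= 0, p$frac_evd <= 1,
            p$drainage_rate >= 0, p$artifact_rate >= 0,
            length(p$sampling_interval_range) == 2L,
            all(p$sampling_interval_range > 0),
            p$icp_wander$amplitude >= 0)
  if (identical(p$outcome_model$kind, "step")) {
    with(p$outcome_model, stopifnot(p_below >= 0, p_below <= 1,
                                    p_above >= 0, p_above <= 1,
                                    theta_star >= -1, theta_star <= 1))
  }
  class(p) <- "sim_params"
  p
}

draw_reactivity <- function(n, dist) {
  switch(dist$kind,
    truncnorm = {
      lo <- pnorm(-1, dist$mean, dist$sd); hi <- pnorm(1, dist$mean, dist$sd)
      qnorm(runif(n, lo, hi), dist$mean, dist$sd)
    },
    uniform = runif(n, dist$lo, dist$hi),
    fixed = rep(dist$value, n),
    stop("unknown reactivity distribution kind: ", dist$kind))
}

# probability of death as a function of latent reactivity
death_prob <- function(rho, model) {
  switch(model$kind,
    step = ifelse(rho > model$theta_star, model$p_above, model$p_below),
    logistic = plogis(model$intercept + model$slope * rho),
    stop("unknown outcome model kind: ", model$kind))
}

# sum of 1..3 sinusoids; squared component amplitudes sum to amplitude^2 so
# the theoretical variance is amplitude^2 / 2 irrespective of the number of
# components
slow_wave <- function(tt, period_range, amplitude) {
  k <- sample.int(3L, 1L)
  periods <- runif(k, period_range[1], period_range[2])
  phases <- runif(k, 0, 2 * pi)
  w <- runif(k, 0.5, 1)
  amps <- amplitude * w / sqrt(sum(w^2))
  out <- numeric(length(tt))
  for (j in seq_len(k))
    out <- out + amps[j] * sin(2 * pi * tt / periods[j] + phases[j])
  out
}

# draw sporadic inter-sample intervals (minutes)
draw_intervals <- function(total_minutes, range) {
  pool <- c(0.5, 1, 2, 3, 5)
  prob <- c(0.05, 0.55, 0.30, 0.05, 0.05)
  n_guess <- ceiling(total_minutes / 1.2) + 16L
  iv <- sample(pool, n_guess, replace = TRUE, prob = prob)
  iv <- pmin(pmax(iv, range[1]), range[2])
  tcum <- cumsum(iv)
  iv[tcum <= total_minutes]
}

#' Generate one patient's coupled MAP/ICP series
#'
#' Simulates latent MAP and ICP on a 0.5-min grid (slow sinusoidal waves plus
#' white noise, ICP coupled to MAP through the shared-component mixture so the
#' expected sample correlation equals `rho`), then median-aggregates both
#' signals onto a shared sporadic sampling grid, as bedside archives do.
#'
#' @param rho latent reactivity in \[-1, 1\]; with `rho = 1` and
#'   `noise_sd_icp = 0` the ICP is an increasing affine function of MAP, so
#'   every full-window correlation is exactly +1.
#' @param duration monitored span in minutes (must exceed 360, the 6-h
#'   inclusion rule).
#' @param params a [sim_params()] object.
#' @param seed integer seed (sets the RNG).
#' @param rho_late,drift_cutoff_min optional second coupling coefficient used
#'   after `drift_cutoff_min` minutes (see `reactivity_drift` in
#'   [sim_params()]); defaults reproduce a constant coupling.
#' @return `list(map = physio_series, icp = physio_series)`.
#' @export
generate_patient_series <- function(rho, duration, params, seed,
                                    rho_late = rho, drift_cutoff_min = Inf) {
  if (!is.finite(rho) || abs(rho) > 1) stop("rho must lie in [-1, 1]")
  if (!is.finite(rho_late) || abs(rho_late) > 1) stop("rho_late must lie in [-1, 1]")
  if (duration < 360)
    stop("inclusion violation: duration must be at least 360 minutes (6 h)")
  set.seed(as.integer(seed))
  dt <- 0.5
  tt <- seq(dt, duration, by = dt)

  sw_var <- params$slow_wave_amplitude^2 / 2
  z_raw <- slow_wave(tt, params$slow_wave_period_range, params$slow_wave_amplitude) +
    rnorm(length(tt), sd = params$noise_sd_map)
  sd_z <- sqrt(sw_var + params$noise_sd_map^2)
  z <- if (sd_z > 0) z_raw / sd_z else z_raw

  w_raw <- slow_wave(tt, params$slow_wave_period_range, params$slow_wave_amplitude) +
    rnorm(length(tt), sd = params$noise_sd_icp)
  sd_w <- sqrt(sw_var + params$noise_sd_icp^2)
  w <- if (sd_w > 0) w_raw / sd_w else w_raw

  # slow MAP-independent ICP baseline wander (B-wave / CSF-dynamics
  # stand-in), added outside the standardized mixture: nearly constant
  # within a 10-min window but a real variance source within 60-120-min
  # windows, so it attenuates long-window correlations toward zero
  wander <- if (params$icp_wander$amplitude > 0)
    slow_wave(tt, params$icp_wander$period_range, params$icp_wander$amplitude)
  else 0

  rho_t <- ifelse(tt <= drift_cutoff_min, rho, rho_late)
  map_lat <- params$map_baseline + z_raw
  icp_lat <- params$icp_baseline + wander +
    params$icp_fluct_sd * (rho_t * z + sqrt(1 - rho_t^2) * w)

  iv <- draw_intervals(duration, params$sampling_interval_range)
  tk <- cumsum(iv)
  # each latent point belongs to the sample window (t_{k-1}, t_k]
  grp <- findInterval(tt, c(0, tk), left.open = TRUE)
  keep <- grp >= 1L & grp <= length(tk)
  agg <- data.table::data.table(g = grp[keep], v_map = map_lat[keep],
                                v_icp = icp_lat[keep])
  agg <- agg[, .(v_map = median(v_map), v_icp = median(v_icp)), by = g]
  data.table::setorder(agg, g)
  list(map = physio_series(t = tk[agg$g], v = agg$v_map, agg = iv[agg$g]),
       icp = physio_series(t = tk[agg$g], v = agg$v_icp, agg = iv[agg$g]))
}

#' Inject out-of-range artifact spikes
#'
#' Replaces sample values at Poisson-distributed times with values outside
#' the validity limits used in cleaning (ICP outside (0, 80) mmHg, MAP
#' outside (0, 400) mmHg), emulating transducer flushes, disconnections and
#' zeroing events. Positions and count are recorded in attributes
#' `artifact_t` and `n_artifacts` for round-trip accounting.
#'
#' @param series a [physio_series()].
#' @param rate expected artifacts per day (>= 0).
#' @param seed integer seed.
#' @param signal_kind `"ICP"` or `"MAP"` (selects the out-of-range support).
#' @return The series with artifacts injected and bookkeeping attributes.
#' @export
inject_artifacts <- function(series, rate, seed, signal_kind = c("ICP", "MAP")) {
  signal_kind <- match.arg(signal_kind)
  stopifnot(rate >= 0)
  if (rate == 0 || !nrow(series)) {
    attr(series, "n_artifacts") <- 0L
    attr(series, "artifact_t") <- numeric()
    return(series)
  }
  set.seed(as.integer(seed))
  days <- span_minutes(series) / 1440
  n <- rpois(1L, rate * days)
  n <- min(n, nrow(series))
  idx <- sort(sample.int(nrow(series), n))
  if (n) {
    high <- runif(n) < 0.7
    series$v[idx] <- if (signal_kind == "ICP")
      ifelse(high, runif(n, 80, 130), runif(n, -5, 0))
    else
      ifelse(high, runif(n, 400, 450), runif(n, -10, 0))
  }
  attr(series, "n_artifacts") <- n
  attr(series, "artifact_t") <- series$t[idx]
  series
}

default_covariates <- function() {
  # marginal frequencies typical of a moderate-to-severe TBI NCCU cohort;
  # independent of outcome by design (only reactivity drives outcome)
  list(sex_male = 0.777, hypoxia = 0.31, hypotension = 0.324,
       epidural_hematoma = 0.156, tsah_ivh = 0.82, evacuation = 0.598,
       dc_primary = 0.08, dc_secondary = 0.021,
       pupils = c(bilat_reactive = 0.665, unilateral_unreactive = 0.14,
                  bilat_unreactive = 0.195),
       marshall = c(I = 0.005, II = 0.27, III = 0.17, IV = 0.035, `V-VI` = 0.52))
}

draw_covariates <- function() {
  cv <- default_covariates()
  data.frame(
    age = round(min(max(rnorm(1L, 48, 17), 16), 95)),
    sex = if (runif(1L) < cv$sex_male) "M" else "F",
    gcs_eye = sample(1:4, 1L, prob = c(0.6, 0.2, 0.15, 0.05)),
    gcs_motor = sample(1:6, 1L, prob = c(0.2, 0.15, 0.15, 0.2, 0.25, 0.05)),
    gcs_verbal = sample(1:5, 1L, prob = c(0.6, 0.2, 0.1, 0.07, 0.03)),
    pupils = sample(names(cv$pupils), 1L, prob = cv$pupils),
    hypoxia = runif(1L) < cv$hypoxia,
    hypotension = runif(1L) < cv$hypotension,
    marshall = sample(names(cv$marshall), 1L, prob = cv$marshall),
    tsah_ivh = runif(1L) < cv$tsah_ivh,
    epidural_hematoma = runif(1L) < cv$epidural_hematoma,
    evacuation = runif(1L) < cv$evacuation,
    dc_primary = runif(1L) < cv$dc_primary,
    dc_secondary = runif(1L) < cv$dc_secondary,
    stringsAsFactors = FALSE)
}

draw_drainage <- function(duration, rate_per_day) {
  if (rate_per_day <= 0) return(matrix(numeric(), ncol = 2L))
  starts <- numeric(); cur <- 0
  repeat {
    cur <- cur + rexp(1L, rate = rate_per_day / 1440)
    if (cur >= duration) break
    starts <- c(starts, cur)
  }
  if (!length(starts)) return(matrix(numeric(), ncol = 2L))
  ends <- pmin(starts + runif(length(starts), 5, 60), duration)
  cbind(starts, ends)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-patient latent reactivity, stay length, monitor type, drainage
#' intervals and covariates; simulates coupled MAP/ICP series; injects
#' artifacts; corrupts ICP during open-drain intervals (drainage lowers and
#' decouples ventricular pressure readings); and draws outcomes from the
#' configured outcome model. Deaths map to GOS 1; survivors are split into
#' favorable (GOS 4--5) and unfavorable-alive (GOS 2--3) by the weaker
#' `favorable_model`, mirroring the weaker discrimination of favorable
#' outcome seen clinically.
#'
#' @param params a [sim_params()] object.
#' @return `list(records = list of patient_record, truth = data.frame)` where
#'   `truth` has columns `patient_id`, `rho_true`, `outcome_gos`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_patients
  if (n == 0L)
    return(list(records = list(),
                truth = data.frame(patient_id = character(),
                                   rho_true = numeric(),
                                   outcome_gos = integer())))
  set.seed(params$seed)
  rho <- draw_reactivity(n, params$reactivity_distribution)
  stay_min <- round(runif(n, params$stay_range_days[1],
                          params$stay_range_days[2]) * 1440)
  is_evd <- runif(n) < params$frac_evd
  p_dead <- death_prob(rho, params$outcome_model)
  dead <- runif(n) < p_dead
  p_fav <- plogis(params$favorable_model$intercept +
                  params$favorable_model$slope * rho)
  fav <- runif(n) < p_fav
  gos <- ifelse(dead, 1L,
                ifelse(fav, sample(4:5, n, replace = TRUE),
                       sample(2:3, n, replace = TRUE)))
  drift <- params$reactivity_drift
  rho_late <- if (identical(drift$kind, "redraw"))
    draw_reactivity(n, params$reactivity_distribution) else rho
  cutoff <- if (identical(drift$kind, "redraw")) drift$day * 1440 else Inf
  seeds <- sample.int(.Machine$integer.max, 3L * n)
  covs <- lapply(seq_len(n), function(i) draw_covariates())
  drains <- lapply(seq_len(n), function(i) {
    if (is_evd[i]) draw_drainage(stay_min[i], params$drainage_rate)
    else matrix(numeric(), ncol = 2L)
  })

  records <- vector("list", n)
  for (i in seq_len(n)) {
    ser <- generate_patient_series(rho[i], stay_min[i], params, seeds[i],
                                   rho_late = rho_late[i],
                                   drift_cutoff_min = cutoff)
    icp <- ser$icp
    if (nrow(drains[[i]])) {
      # open drain: ICP reads low and decouples from MAP
      set.seed(seeds[n + i])
      in_drain <- in_intervals(icp$t, drains[[i]])
      icp$v[in_drain] <- pmax(params$icp_baseline - 6 +
                                rnorm(sum(in_drain), sd = 1), 0.5)
    }
    icp <- inject_artifacts(icp, params$artifact_rate, seeds[2L * n + i], "ICP")
    map <- inject_artifacts(ser$map, params$artifact_rate,
                            seeds[2L * n + i] %% .Machine$integer.max, "MAP")
    records[[i]] <- patient_record(
      patient_id = sprintf("P%04d", i),
      monitor_type = if (is_evd[i]) "EVD" else "IPD",
      icp = icp, map = map,
      drainage_intervals = if (nrow(drains[[i]])) drains[[i]] else NULL,
      gos = gos[i], covariates = covs[[i]])
    attr(records[[i]], "n_artifacts_icp") <- attr(icp, "n_artifacts")
    attr(records[[i]], "n_artifacts_map") <- attr(map, "n_artifacts")
  }
  list(records = records,
       truth = data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                          rho_true = rho, outcome_gos = as.integer(gos)))
}
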