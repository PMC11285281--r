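VALIDITY_LIMITS <- list(ICP = c(0, 80), MAP = c(0, 400))

#' Remove out-of-range artifact samples
#'
#' Applies the strict validity limits `0 < ICP < 80` mmHg and
#' `0 < MAP < 400` mmHg: samples at or beyond either bound are marked
#' missing (the time base is kept). The removal count is recorded in
#' attributes `n_removed` / `removed_t`.
#'
#' @param series a [physio_series()].
#' @param signal_kind `"ICP"` or `"MAP"`.
#' @return The series with offending values set to `NA`.
#' @export
filter_artifacts <- function(series, signal_kind) {
  if (!signal_kind %in% names(VALIDITY_LIMITS))
    stop("unknown signal_kind: ", signal_kind)
  lim <- VALIDITY_LIMITS[[signal_kind]]
  bad <- !is.na(series$v) & (series$v <= lim[1] | series$v >= lim[2])
  out <- series
  out$v[bad] <- NA_real_
  attr(out, "n_removed") <- sum(bad)
  attr(out, "removed_t") <- series$t[bad]
  out
}

# merge overlapping/touching half-open [start, end) intervals
merge_intervals <- function(intervals) {
  if (is.null(intervals) || !nrow(intervals)) return(matrix(numeric(), ncol = 2L))
  m <- intervals[order(intervals[, 1L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1L]) {
    j <- nrow(out)
    if (m[i, 1L] <= out[j, 2L]) out[j, 2L] <- max(out[j, 2L], m[i, 2L])
    else out <- rbind(out, m[i, ])
  }
  out
}

# membership of time points in a union of half-open [start, end) intervals
in_intervals <- function(t, intervals) {
  hit <- rep(FALSE, length(t))
  if (is.null(intervals) || !nrow(intervals)) return(hit)
  for (i in seq_len(nrow(intervals)))
    hit <- hit | (t >= intervals[i, 1L] & t < intervals[i, 2L])
  hit
}

#' Remove open-drain periods from a series
#'
#' All time during which an external ventricular drain was open is removed:
#' samples whose timestamp falls in any half-open `[start, end)` interval are
#' marked missing. Overlapping intervals are merged, not an error.
#'
#' @param series a [physio_series()].
#' @param intervals two-column matrix of `[start, end)` minute intervals.
#' @return The series with in-interval values set to `NA`; attributes
#'   `n_removed` / `removed_t` record the removal.
#' @export
remove_drainage <- function(series, intervals) {
  iv <- merge_intervals(intervals)
  bad <- in_intervals(series$t, iv) & !is.na(series$v)
  out <- series
  out$v[bad] <- NA_real_
  attr(out, "n_removed") <- sum(bad)
  attr(out, "removed_t") <- series$t[bad]
  out
}

#' Impute a sporadic series onto a regular grid
#'
#' Stand-in for regular-grid imputation of sporadically sampled archive
#' data: values are placed on a uniform grid (default 1 min); grid points
#' falling in an inter-sample gap no longer than `max_gap_minutes` are
#' filled by linear interpolation between the neighbouring present samples;
#' longer gaps stay missing. A series already on the grid is returned
#' value-identical.
#'
#' @param series a [physio_series()].
#' @param grid_minutes grid spacing (default 1).
#' @param max_gap_minutes largest gap (minutes) bridged by interpolation.
#' @return A [physio_series()] on the regular grid (`agg = grid_minutes`).
#' @export
regularize <- function(series, grid_minutes = 1, max_gap_minutes = 5) {
  stopifnot(grid_minutes > 0)
  pres <- !is.na(series$v)
  tp <- series$t[pres]; vp <- series$v[pres]
  if (!length(tp)) return(physio_series())
  lo <- grid_minutes * ceiling(tp[1L] / grid_minutes - 1e-9)
  hi <- grid_minutes * floor(tp[length(tp)] / grid_minutes + 1e-9)
  if (hi < lo) return(physio_series())
  out_t <- seq(lo, hi, by = grid_minutes)
  if (length(tp) == 1L) {
    v_out <- ifelse(abs(out_t - tp) < 1e-9, vp, NA_real_)
    return(physio_series(t = out_t, v = v_out, agg = grid_minutes))
  }
  v_out <- approx(tp, vp, xout = out_t, method = "linear", rule = 1L)$y
  idx <- findInterval(out_t, tp)
  gaps <- c(diff(tp), Inf)
  exact <- idx >= 1L & abs(out_t - tp[pmax(idx, 1L)]) < 1e-9
  filled <- idx >= 1L & idx < length(tp) & gaps[pmax(idx, 1L)] <= max_gap_minutes
  v_out[!(exact | filled)] <- NA_real_
  physio_series(t = out_t, v = v_out, agg = grid_minutes)
}

# place sporadic samples into 1-min bins (m-1, m]; bins with several present
# samples take their mean, empty bins are NA; returns a vector indexed by
# minute 1..ceiling(span)
align_minute_grid <- function(series, grid_minutes = 1) {
  if (!nrow(series)) return(numeric())
  m <- ceiling(max(series$t) / grid_minutes - 1e-9)
  pres <- !is.na(series$v)
  if (!any(pres)) return(rep(NA_real_, m))
  bin <- ceiling(series$t[pres] / grid_minutes - 1e-9)
  dtab <- data.table::data.table(g = bin, v = series$v[pres])
  dtab <- dtab[g >= 1L & g <= m, .(v = mean(v)), by = g]
  out <- rep(NA_real_, m)
  out[dtab$g] <- dtab$v
  out
}

#' Moving Pearson correlation over consecutive minute samples
#'
#' At each minute `t >= n` the Pearson correlation of the pairwise-complete
#' `(x, y)` samples in the right-aligned window `(t - n, t]` is emitted.
#' A window yields `NA` when fewer than `min_valid_fraction * n` complete
#' pairs are present or when either signal is constant within the window
#' (an undefined correlation must not masquerade as zero reactivity).
#' Rolling sums are computed on globally centered signals so the result
#' matches a naive per-window recomputation to well below 1e-12.
#'
#' @param x,y numeric vectors on a shared minute grid (`NA` = missing).
#' @param n window length in consecutive samples, `>= 3`.
#' @param min_valid_fraction minimum fraction of complete pairs per window.
#' @return Numeric vector the length of `x`; entry `t` holds the correlation
#'   of the window ending at minute `t` (all emitted values in \[-1, 1\]).
#' @export
moving_pearson <- function(x, y, n, min_valid_fraction = 0.8) {
  if (n < 3L) stop("window length n must be at least 3")
  if (length(x) != length(y)) stop("x and y must share a common grid")
  m <- length(x)
  out <- rep(NA_real_, m)
  if (m < n) return(out)
  ok <- is.finite(x) & is.finite(y)
  if (!any(ok)) return(out)
  # global centering keeps rolling cumulative sums small (shift-invariance
  # of the correlation makes this exact in infinite precision)
  xc <- ifelse(ok, x - mean(x[ok]), 0)
  yc <- ifelse(ok, y - mean(y[ok]), 0)
  cs <- function(z) c(0, cumsum(z))  # leading 0 so S[i+1]-S[i-n+1] is the window sum
  Sx <- cs(xc); Sy <- cs(yc); Sxx <- cs(xc^2); Syy <- cs(yc^2)
  Sxy <- cs(xc * yc); Sn <- cs(as.numeric(ok))
  win <- function(S, i) S[i + 1L] - S[i - n + 1L]
  i <- n:m
  k <- win(Sn, i)
  sx <- win(Sx, i); sy <- win(Sy, i)
  sxx <- win(Sxx, i) - sx^2 / pmax(k, 1)
  syy <- win(Syy, i) - sy^2 / pmax(k, 1)
  sxy <- win(Sxy, i) - sx * sy / pmax(k, 1)
  msd_x <- mean(xc[ok]^2); msd_y <- mean(yc[ok]^2)
  tol_x <- 1e-7 * pmax(k, 1) * msd_x
  tol_y <- 1e-7 * pmax(k, 1) * msd_y
  kmin <- max(3, ceiling(min_valid_fraction * n - 1e-9))
  good <- k >= kmin & sxx > tol_x & syy > tol_y
  r <- rep(NA_real_, length(i))
  r[good] <- pmin(1, pmax(-1, sxy[good] / sqrt(sxx[good] * syy[good])))
  out[i] <- r
  out
}

LPRX_WINDOWS <- c(10L, 15L, 20L, 30L, 60L, 90L, 120L)

#' Construct an LPRx index series
#'
#' @param t minute grid (window end times).
#' @param lprx index values in \[-1, 1\] or `NA`.
#' @param window_minutes one of 10, 15, 20, 30, 60, 90, 120.
#' @return An `index_series` data.frame with attribute `window_minutes`.
#' @export
index_series <- function(t, lprx, window_minutes) {
  window_minutes <- as.integer(window_minutes)
  if (!window_minutes %in% LPRX_WINDOWS)
    stop("window_minutes must be one of ", paste(LPRX_WINDOWS, collapse = ", "))
  if (any(!is.na(lprx) & (lprx < -1 | lprx > 1)))
    stop("LPRx values must lie in [-1, 1]")
  structure(data.frame(t = t, lprx = lprx),
            window_minutes = window_minutes,
            class = c("index_series", "data.frame"))
}

#' Compute LPRx for one patient
#'
#' Derives the long-pressure-reactivity index: the moving Pearson correlation
#' between minute-by-minute MAP and ICP samples over a window of
#' `window_minutes` consecutive samples, emitted every minute. The record is
#' expected to be cleaned already (see [clean_record()]). With
#' `use_imputation = TRUE` both signals are first passed through
#' [regularize()] (gap-limited linear interpolation) and windows are
#' `window_minutes` cells of the regular 1-min grid. Without imputation the
#' sporadic data are used as-is: each minute takes the correlation of the
#' last `window_minutes` consecutive archived samples (roughly
#' `window_minutes` minutes of time at the ~1-min median sampling, exactly
#' so on a regular grid); windows with too few complete pairs, or minutes
#' before the window length has elapsed, stay missing.
#'
#' @param record a [patient_record()].
#' @param window_minutes one of 10, 15, 20, 30, 60, 90, 120.
#' @param use_imputation logical; impute to a regular grid first.
#' @param min_valid_fraction minimum fraction of complete pairs per window.
#' @return An [index_series()]; empty (with a warning) when the monitored
#'   span is shorter than the window.
#' @export
compute_lprx <- function(record, window_minutes, use_imputation = FALSE,
                         min_valid_fraction = 0.8) {
  window_minutes <- as.integer(window_minutes)
  if (!window_minutes %in% LPRX_WINDOWS)
    stop("window_minutes must be one of ", paste(LPRX_WINDOWS, collapse = ", "))
  if (use_imputation) {
    rmap <- regularize(record$map); ricp <- regularize(record$icp)
    m <- max(0, if (nrow(rmap)) max(rmap$t) else 0,
             if (nrow(ricp)) max(ricp$t) else 0)
    if (m < window_minutes) {
      warning("monitored span shorter than the requested window; empty index")
      return(index_series(t = integer(), lprx = numeric(),
                          window_minutes = window_minutes))
    }
    x <- rep(NA_real_, m); y <- rep(NA_real_, m)
    if (nrow(rmap)) x[rmap$t] <- rmap$v
    if (nrow(ricp)) y[ricp$t] <- ricp$v
    vals <- moving_pearson(x, y, n = window_minutes,
                           min_valid_fraction = min_valid_fraction)
    return(index_series(t = seq_len(m), lprx = vals,
                        window_minutes = window_minutes))
  }
  # sporadic route: windows of consecutive archived samples, one value per
  # minute (the window ending at the latest sample at or before that minute)
  tt <- intersect(record$map$t, record$icp$t)
  m <- ceiling(max(span_minutes(record$map), span_minutes(record$icp)))
  if (m < window_minutes || length(tt) < window_minutes) {
    warning("monitored span shorter than the requested window; empty index")
    return(index_series(t = integer(), lprx = numeric(),
                        window_minutes = window_minutes))
  }
  xv <- record$map$v[match(tt, record$map$t)]
  yv <- record$icp$v[match(tt, record$icp$t)]
  r_sample <- moving_pearson(xv, yv, n = window_minutes,
                             min_valid_fraction = min_valid_fraction)
  minutes <- seq_len(m)
  j <- findInterval(minutes + 1e-9, tt)
  vals <- ifelse(j >= 1L, r_sample[pmax(j, 1L)], NA_real_)
  vals[minutes < window_minutes] <- NA_real_
  index_series(t = minutes, lprx = vals, window_minutes = window_minutes)
}

#' Clean a patient record
#'
#' Applies strict artifact limits to both signals and removes open-drain
#' periods from the ICP series (pairwise-complete correlation then excludes
#' the paired MAP minutes automatically). Loss counts are recorded in
#' attributes `loss_artifacts_icp`, `loss_artifacts_map`, `loss_drainage`.
#'
#' @param record a [patient_record()].
#' @return The cleaned record.
#' @export
clean_record <- function(record) {
  icp <- filter_artifacts(record$icp, "ICP")
  map <- filter_artifacts(record$map, "MAP")
  n_art_icp <- attr(icp, "n_removed")
  icp <- remove_drainage(icp, record$drainage_intervals)
  out <- record
  out$icp <- icp
  out$map <- map
  attr(out, "loss_artifacts_icp") <- n_art_icp
  attr(out, "loss_artifacts_map") <- attr(map, "n_removed")
  attr(out, "loss_drainage") <- attr(icp, "n_removed")
  out
}

#' Write / read an index series CSV
#'
#' Columns `t_min`, `lprx`, `window_min`; missing values as empty fields.
#'
#' @param series an [index_series()].
#' @param path file path.
#' @export
write_index_csv <- function(series, path) {
  dt <- data.table::data.table(t_min = series$t, lprx = series$lprx,
                               window_min = attr(series, "window_minutes"))
  data.table::fwrite(dt, path, na = "")
  invisible(path)
}

#' @rdname write_index_csv
#' @export
read_index_csv <- function(path) {
  dt <- data.table::fread(path, na.strings = "")
  index_series(t = dt$t_min, lprx = dt$lprx,
               window_minutes = dt$window_min[1L])
}
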