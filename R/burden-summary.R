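SEGMENT_LABELS <- c("full", "first_24h", "first_48h", "first_96h",
                    "first_144h", paste0("day_", 1:7))

#' Time-segment definitions
#'
#' Segments are half-open `[start, end)` windows of continuous monitoring
#' time: `first_Nh = [0, N*60)`, `day_k = [(k-1)*1440, k*1440)` and `full`
#' spans the whole recording. On the minute-indexed series (minute `t`
#' covers `(t-1, t]`), segment `[s, e)` holds minutes `s+1 .. e`, so no
#' minute is counted twice across daily segments.
#'
#' @param label one of `"full"`, `"first_24h"`, `"first_48h"`, `"first_96h"`,
#'   `"first_144h"`, `"day_1"` .. `"day_7"`.
#' @return `list(label, start, end)` in minutes (`end = Inf` for `"full"`).
#' @export
segment_def <- function(label) {
  if (!label %in% SEGMENT_LABELS)
    stop("unknown segment label: ", label)
  if (label == "full") return(list(label = label, start = 0, end = Inf))
  if (grepl("^first_", label)) {
    h <- as.numeric(sub("h$", "", sub("^first_", "", label)))
    return(list(label = label, start = 0, end = h * 60))
  }
  k <- as.integer(sub("^day_", "", label))
  list(label = label, start = (k - 1) * 1440, end = k * 1440)
}

#' @rdname segment_def
#' @export
all_segment_labels <- function() SEGMENT_LABELS

# extract (t, v) pairs from an index_series, a minute-indexed numeric
# vector, or a data.frame with columns t and v
series_tv <- function(series) {
  if (inherits(series, "index_series")) list(t = series$t, v = series$lprx)
  else if (is.numeric(series)) list(t = seq_along(series), v = as.numeric(series))
  else if (is.data.frame(series)) list(t = series$t, v = series$v)
  else stop("unsupported series type")
}

seg_slice <- function(tv, seg) {
  sel <- tv$t > seg$start & tv$t <= min(seg$end, max(tv$t))
  list(v = tv$v[sel],
       len = if (is.infinite(seg$end)) length(tv$t)
             else seg$end - seg$start)
}

#' Segment grand mean
#'
#' Arithmetic mean of the present values inside a time segment; the result
#' is missing when the patient's valid-minute coverage of the segment falls
#' below `min_coverage` (patients monitored for two days simply drop out of
#' the day-5 analysis). Coverage is taken against the nominal segment length
#' (against the monitored span for `"full"`).
#'
#' @param series an [index_series()], a minute-indexed numeric vector (e.g.
#'   minute-binned ICP), or a data.frame with columns `t`, `v`.
#' @param segment a [segment_def()] (or its label).
#' @param min_coverage minimum fraction of segment minutes with valid data.
#' @return One-row `data.frame`: `segment`, `metric`, `window_minutes`,
#'   `threshold`, `value`, `n_valid`.
#' @export
segment_mean <- function(series, segment, min_coverage = 0.25) {
  if (is.character(segment)) segment <- segment_def(segment)
  tv <- series_tv(series)
  sl <- seg_slice(tv, segment)
  n_valid <- sum(!is.na(sl$v))
  value <- if (n_valid == 0 || n_valid < min_coverage * sl$len) NA_real_
           else mean(sl$v, na.rm = TRUE)
  data.frame(segment = segment$label,
             metric = if (inherits(series, "index_series")) "mean_lprx" else "mean_icp",
             window_minutes = if (inherits(series, "index_series"))
               attr(series, "window_minutes") else NA_integer_,
             threshold = NA_real_, value = value, n_valid = n_valid)
}

#' Percent time above a threshold
#'
#' Fraction of present minutes in the segment whose index value is strictly
#' greater than `threshold` (a dose-above-threshold burden metric; strict
#' `>` matches the "> 0, > 0.2, > 0.3" key thresholds).
#'
#' @inheritParams segment_mean
#' @param threshold index threshold in \[-1, 1\].
#' @return One-row `data.frame` as in [segment_mean()] with
#'   `metric = "pct_above_thr"`; `value` is a fraction in \[0, 1\].
#' @export
pct_time_above <- function(series, threshold, segment, min_coverage = 0.25) {
  stopifnot(threshold >= -1, threshold <= 1)
  if (is.character(segment)) segment <- segment_def(segment)
  tv <- series_tv(series)
  sl <- seg_slice(tv, segment)
  pres <- sl$v[!is.na(sl$v)]
  n_valid <- length(pres)
  value <- if (n_valid == 0 || n_valid < min_coverage * sl$len) NA_real_
           else mean(pres > threshold)
  data.frame(segment = segment$label, metric = "pct_above_thr",
             window_minutes = if (inherits(series, "index_series"))
               attr(series, "window_minutes") else NA_integer_,
             threshold = threshold, value = value, n_valid = n_valid)
}

#' Per-patient burden summaries for a cohort
#'
#' Cleans each record, derives LPRx for the requested windows, bins ICP onto
#' the minute grid, and reduces everything to segment-level grand means and
#' percent-time-above-threshold values in one long table.
#'
#' @param records list of [patient_record()] objects (raw; cleaning is
#'   applied here).
#' @param windows LPRx windows to compute (subset of 10, 15, 20, 30, 60, 90,
#'   120).
#' @param segments character vector of segment labels.
#' @param pct_thresholds key LPRx thresholds for the percent-time metric.
#' @param use_imputation logical, passed to [compute_lprx()].
#' @param min_coverage per-segment minimum coverage (see [segment_mean()]).
#' @param min_valid_fraction per-window minimum pair fraction (see
#'   [moving_pearson()]).
#' @return A `data.table` with one row per patient x metric x segment
#'   (x window x threshold where applicable).
#' @export
summarize_cohort <- function(records, windows = c(10L, 20L),
                             segments = c("full", "first_24h"),
                             pct_thresholds = c(0, 0.2, 0.3),
                             use_imputation = FALSE, min_coverage = 0.25,
                             min_valid_fraction = 0.8) {
  segs <- lapply(segments, segment_def)
  rows <- lapply(records, function(rec) {
    cl <- clean_record(rec)
    icp_min <- align_minute_grid(cl$icp)
    per <- list()
    for (s in segs) per[[length(per) + 1L]] <- segment_mean(icp_min, s, min_coverage)
    for (w in windows) {
      idx <- compute_lprx(cl, w, use_imputation = use_imputation,
                          min_valid_fraction = min_valid_fraction)
      for (s in segs) {
        per[[length(per) + 1L]] <- segment_mean(idx, s, min_coverage)
        for (thr in pct_thresholds)
          per[[length(per) + 1L]] <- pct_time_above(idx, thr, s, min_coverage)
      }
    }
    out <- data.table::rbindlist(per)
    out[, patient_id := rec$patient_id]
    out
  })
  data.table::rbindlist(rows)[, .(patient_id, segment, metric, window_minutes,
                                  threshold, value, n_valid)]
}

#' Cohort metadata table
#'
#' @param records list of [patient_record()] objects.
#' @return A `data.table` with `patient_id`, `monitor_type`, `gos`, a
#'   `decompressive_craniectomy` flag, and any covariates.
#' @export
cohort_meta <- function(records) {
  rows <- lapply(records, function(r) {
    base <- data.table::data.table(patient_id = r$patient_id,
                                   monitor_type = r$monitor_type,
                                   gos = r$gos)
    cv <- r$covariates
    dc <- if (!is.null(cv) && all(c("dc_primary", "dc_secondary") %in% names(cv)))
      isTRUE(cv$dc_primary) || isTRUE(cv$dc_secondary) else FALSE
    base[, decompressive_craniectomy := dc]
    if (!is.null(cv)) base <- cbind(base, cv)
    base
  })
  data.table::rbindlist(rows, fill = TRUE)
}

#' Median (IQR) summary table per outcome group
#'
#' Reduces per-patient grand means to per-group medians with interquartile
#' ranges (linear-interpolation quantiles, `type = 7`).
#'
#' @param summaries long table from [summarize_cohort()].
#' @param groups `data.frame` with `patient_id` and `group` columns.
#' @return A `data.table` keyed by metric/segment/window/threshold/group
#'   with `n`, `median`, `q25`, `q75` (all `NA` for an empty group).
#' @export
cohort_summary_table <- function(summaries, groups) {
  dt <- data.table::as.data.table(summaries)
  g <- data.table::as.data.table(groups)
  merged <- merge(dt, g, by = "patient_id", all.y = FALSE)
  out <- merged[!is.na(value),
                .(n = .N,
                  median = median(value),
                  q25 = quantile(value, 0.25, type = 7, names = FALSE),
                  q75 = quantile(value, 0.75, type = 7, names = FALSE)),
                by = .(metric, segment, window_minutes, threshold, group)]
  # carry empty groups as NA rows
  shell <- unique(merged[, .(metric, segment, window_minutes, threshold)])
  shell <- shell[, .(group = unique(g$group)), by = names(shell)]
  out <- merge(shell, out,
               by = c("metric", "segment", "window_minutes", "threshold", "group"),
               all.x = TRUE)
  out
}
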