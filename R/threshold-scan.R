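#' Dichotomize Glasgow Outcome Scale
#'
#' Two schemes are used: `"survival"` (GOS 1 = dead vs GOS 2--5 = alive) and
#' `"favorable"` (GOS 1--3 = unfavorable vs GOS 4--5 = favorable).
#'
#' @param gos integer vector, values in 1..5.
#' @param scheme `"survival"` or `"favorable"`.
#' @return Logical vector, `TRUE` for the adverse class (dead /
#'   unfavorable).
#' @export
dichotomize_gos <- function(gos, scheme = c("survival", "favorable")) {
  scheme <- match.arg(scheme)
  gos <- as.integer(gos)
  if (any(is.na(gos) | gos < 1L | gos > 5L))
    stop("gos values must be integers in 1..5")
  if (scheme == "survival") gos == 1L else gos <= 3L
}

#' Pearson chi-square for a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson statistic with one
#' degree of freedom; this dialect reproduces published p-values computed
#' from printed 2x2 counts. A table with any zero marginal is flagged
#' invalid rather than raising an error.
#'
#' @param a,b,c,d cell counts: `a`,`b` = first row (e.g. exposed) split by
#'   outcome, `c`,`d` = second row.
#' @return `list(chi2, p, valid)`.
#' @export
chi2_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  if (n == 0) stop("empty table")
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) return(list(chi2 = NA_real_, p = NA_real_, valid = FALSE))
  chi2 <- n * (a * d - b * c)^2 / prod(marg)
  list(chi2 = chi2, p = pchisq(chi2, df = 1L, lower.tail = FALSE),
       valid = TRUE)
}

#' Threshold grid for the sequential chi-square scan
#'
#' @param metric_kind `"lprx"` (-0.5 to 0.7 by 0.05), `"icp"` (0 to 40 mmHg
#'   by 0.5) or `"pct_time"` (0 to 1 by 0.05).
#' @return `list(metric_kind, lo, hi, step, thresholds)`; grid values are
#'   rounded to remove floating-point drift from accumulation.
#' @export
threshold_grid <- function(metric_kind = c("lprx", "icp", "pct_time")) {
  metric_kind <- match.arg(metric_kind)
  spec <- switch(metric_kind,
                 lprx = c(-0.5, 0.7, 0.05),
                 icp = c(0, 40, 0.5),
                 pct_time = c(0, 1, 0.05))
  thr <- round(seq(spec[1], spec[2], by = spec[3]), 10L)
  list(metric_kind = metric_kind, lo = spec[1], hi = spec[2], step = spec[3],
       thresholds = thr)
}

#' Sequential chi-square threshold scan
#'
#' At each grid threshold, patients are split into `value > threshold` vs
#' `value <= threshold` (strict above, applied uniformly), a 2x2 table
#' against the binary outcome is formed, and the uncorrected Pearson
#' chi-square is computed. The full per-threshold trace is retained for
#' curve plotting; the threshold with the highest chi-square has the best
#' discriminative value.
#'
#' @param values per-patient summary values (missing values excluded with
#'   their patients).
#' @param classes logical per-patient adverse-outcome indicator, aligned
#'   with `values`.
#' @param grid a [threshold_grid()].
#' @param tie_rule passed to [select_best()].
#' @return A `threshold_scan` object: `$table` (threshold, a, b, c, d, chi2,
#'   p, valid), `$best_threshold`, `$best_chi2`, `$best_p`, `$n_patients`,
#'   `$usable`.
#' @export
scan_thresholds <- function(values, classes, grid = threshold_grid("lprx"),
                            tie_rule = "lowest") {
  stopifnot(length(values) == length(classes))
  keep <- !is.na(values) & !is.na(classes)
  values <- values[keep]; classes <- as.logical(classes[keep])
  n <- length(values)
  usable <- sum(classes) >= 2L && sum(!classes) >= 2L
  rows <- lapply(grid$thresholds, function(thr) {
    above <- values > thr
    a <- sum(above & classes); b <- sum(above & !classes)
    cc <- sum(!above & classes); d <- sum(!above & !classes)
    if (n > 0) {
      res <- chi2_2x2(a, b, cc, d)
    } else res <- list(chi2 = NA_real_, p = NA_real_, valid = FALSE)
    data.table::data.table(threshold = thr, a = a, b = b, c = cc, d = d,
                           chi2 = res$chi2, p = res$p, valid = res$valid)
  })
  out <- structure(list(table = data.table::rbindlist(rows),
                        grid = grid, n_patients = n, usable = usable,
                        best_threshold = NA_real_, best_chi2 = NA_real_,
                        best_p = NA_real_),
                   class = "threshold_scan")
  if (usable) {
    best <- select_best(out, tie_rule = tie_rule)
    out$best_threshold <- best$threshold
    out$best_chi2 <- best$chi2
    out$best_p <- best$p
  }
  out
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("<threshold_scan> %s grid, n=%d%s\n", x$grid$metric_kind,
              x$n_patients, if (!x$usable) " (unusable)" else ""))
  if (x$usable && !is.na(x$best_threshold))
    cat(sprintf("  best threshold %.3g (chi2=%.3f, p=%.3g)\n",
                x$best_threshold, x$best_chi2, x$best_p))
  invisible(x)
}

#' Select the maximal-chi-square threshold
#'
#' Argmax of the chi-square statistic over valid grid points; ties are
#' broken by the configured rule (`"lowest"` by default -- the conservative
#' choice for an impairment metric). The returned p-value is the unadjusted
#' chi-square p-value (no multiplicity correction).
#'
#' @param result a `threshold_scan`.
#' @param tie_rule `"lowest"` or `"highest"`.
#' @return `list(threshold, chi2, p)`; all `NA` when no grid point is valid.
#' @export
select_best <- function(result, tie_rule = c("lowest", "highest")) {
  tie_rule <- match.arg(tie_rule)
  tab <- result$table[valid == TRUE]
  if (!nrow(tab)) return(list(threshold = NA_real_, chi2 = NA_real_,
                              p = NA_real_))
  mx <- max(tab$chi2)
  cand <- tab[abs(chi2 - mx) < 1e-12]
  row <- if (tie_rule == "lowest") cand[which.min(cand$threshold)]
         else cand[which.max(cand$threshold)]
  list(threshold = row$threshold, chi2 = row$chi2, p = row$p)
}

#' Mann-Whitney U comparison of two groups
#'
#' Standard two-sided Mann-Whitney U test (exact for small tie-free samples,
#' normal approximation with tie correction otherwise), as used for
#' continuous demographic/physiologic comparisons between outcome groups.
#'
#' @param values_group_a,values_group_b numeric vectors (non-empty after
#'   `NA` removal).
#' @return `list(u, p)` where `u` is the U statistic for the first group.
#' @export
mann_whitney_compare <- function(values_group_a, values_group_b) {
  a <- values_group_a[!is.na(values_group_a)]
  b <- values_group_b[!is.na(values_group_b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Run the full threshold-scan battery
#'
#' Cross-product of outcome schemes x metrics (mean LPRx per window, mean
#' ICP, percent time LPRx above each key threshold) x time segments x
#' monitor subgroups (`all`, `EVD`, `IPD`, `no_dc` = no decompressive
#' craniectomy). Each cell is one [scan_thresholds()] call; empty or
#' degenerate strata are marked unusable and the battery continues.
#'
#' @param summaries long table from [summarize_cohort()].
#' @param meta cohort metadata from [cohort_meta()].
#' @param schemes outcome schemes to use.
#' @param subgroups subset of `c("all", "EVD", "IPD", "no_dc")`.
#' @param tie_rule passed to [select_best()].
#' @return `list(results = tidy data.table (one row per cell), scans = list
#'   of threshold_scan objects named by cell id)`.
#' @export
run_scan_battery <- function(summaries, meta,
                             schemes = c("survival", "favorable"),
                             subgroups = c("all", "EVD", "IPD", "no_dc"),
                             tie_rule = "lowest") {
  dt <- data.table::as.data.table(summaries)
  meta <- data.table::as.data.table(meta)
  cells <- unique(dt[, .(metric, segment, window_minutes, threshold)])
  scans <- list()
  res_rows <- list()
  for (scheme_name in schemes) {
    cls_all <- setNames(dichotomize_gos(meta$gos, scheme_name),
                        meta$patient_id)
    for (sg in subgroups) {
      ids <- switch(sg,
        all = meta$patient_id,
        EVD = meta[monitor_type == "EVD", patient_id],
        IPD = meta[monitor_type == "IPD", patient_id],
        no_dc = meta[decompressive_craniectomy == FALSE, patient_id],
        stop("unknown subgroup: ", sg))
      for (ci in seq_len(nrow(cells))) {
        cell <- cells[ci]
        sub <- dt[metric == cell$metric & segment == cell$segment &
                    (is.na(cell$window_minutes) | window_minutes == cell$window_minutes) &
                    (is.na(cell$threshold) | threshold == cell$threshold)]
        sub <- sub[patient_id %in% ids]
        grid <- threshold_grid(switch(cell$metric,
                                      mean_lprx = "lprx",
                                      mean_icp = "icp",
                                      pct_above_thr = "pct_time"))
        scan <- scan_thresholds(sub$value, cls_all[sub$patient_id], grid,
                                tie_rule = tie_rule)
        id <- paste(scheme_name, sg, cell$metric, cell$segment,
                    ifelse(is.na(cell$window_minutes), "", cell$window_minutes),
                    ifelse(is.na(cell$threshold), "", cell$threshold),
                    sep = "|")
        scans[[id]] <- scan
        res_rows[[id]] <- data.table::data.table(
          scheme = scheme_name, subgroup = sg, metric = cell$metric,
          segment = cell$segment, window_minutes = cell$window_minutes,
          key_threshold = cell$threshold, n = scan$n_patients,
          usable = scan$usable, best_threshold = scan$best_threshold,
          best_chi2 = scan$best_chi2, best_p = scan$best_p,
          n_grid = nrow(scan$table))
      }
    }
  }
  list(results = data.table::rbindlist(res_rows), scans = scans)
}

#' Plot a chi-square vs threshold curve
#'
#' @param scan a `threshold_scan`.
#' @param main plot title.
#' @return Invisibly, the scan.
#' @export
plot_scan <- function(scan, main = "") {
  tab <- scan$table
  plot(tab$threshold, tab$chi2, type = "b", pch = 16, cex = 0.6,
       xlab = "threshold", ylab = "chi-square", main = main)
  if (scan$usable && !is.na(scan$best_threshold))
    abline(v = scan$best_threshold, lty = 2)
  invisible(scan)
}
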