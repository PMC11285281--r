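#' Construct a patient record
#'
#' Bundles one patient's ICP and MAP series with monitoring metadata and
#' outcome. Inclusion requires more than 6 h (360 min) of monitored span.
#' Drainage intervals (periods with an open cerebrospinal-fluid drain, during
#' which ventricular ICP readings are invalid) are only meaningful for EVD
#' monitoring; for a patient monitored with both devices only the EVD data is
#' retained upstream, so a record carries exactly one monitor type.
#'
#' @param patient_id character scalar.
#' @param monitor_type `"EVD"` (external ventricular drain) or `"IPD"`
#'   (intraparenchymal device).
#' @param icp,map [physio_series()] objects (mmHg).
#' @param drainage_intervals two-column matrix of half-open `[start, end)`
#'   open-drain intervals in minutes; must be empty unless `monitor_type`
#'   is `"EVD"`.
#' @param gos integer Glasgow Outcome Scale, 1 (dead) to 5 (good recovery).
#' @param covariates one-row `data.frame` of demographics (age, sex, GCS
#'   components, pupils, hypoxia/hypotension flags, Marshall class, surgery
#'   flags); may be `NULL`.
#' @return A `patient_record` (S3 list).
#' @export
patient_record <- function(patient_id, monitor_type, icp, map,
                           drainage_intervals = NULL, gos,
                           covariates = NULL) {
  monitor_type <- match.arg(monitor_type, c("EVD", "IPD"))
  if (!inherits(icp, "physio_series") || !inherits(map, "physio_series"))
    stop("icp and map must be physio_series objects")
  span <- max(span_minutes(icp), span_minutes(map))
  if (span <= 360)
    stop("inclusion violation: monitored span must exceed 360 minutes (6 h)")
  if (is.null(drainage_intervals)) {
    drainage_intervals <- matrix(numeric(), ncol = 2L)
  } else {
    drainage_intervals <- as.matrix(drainage_intervals)
    if (ncol(drainage_intervals) != 2L)
      stop("drainage_intervals must be a two-column [start, end) matrix")
  }
  if (nrow(drainage_intervals) && monitor_type != "EVD")
    stop("drainage intervals are only valid for EVD monitoring")
  gos <- as.integer(gos)
  if (is.na(gos) || gos < 1L || gos > 5L) stop("gos must be an integer in 1..5")
  structure(list(patient_id = as.character(patient_id),
                 monitor_type = monitor_type, icp = icp, map = map,
                 drainage_intervals = drainage_intervals, gos = gos,
                 covariates = covariates),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s (%s) GOS=%d, span=%.0f min, %d drainage intervals\n",
              x$patient_id, x$monitor_type, x$gos,
              max(span_minutes(x$icp), span_minutes(x$map)),
              nrow(x$drainage_intervals)))
  invisible(x)
}

#' Write / read a cohort of patient records
#'
#' One CSV per patient signal (`<id>_icp.csv`, `<id>_map.csv`; columns
#' `t_min`, `value_mmHg`, `agg_min`), a cohort-level `cohort.csv` with
#' monitor type, outcome and demographics, and `drainage.json` mapping
#' patient ids to half-open open-drain intervals.
#'
#' @param records list of [patient_record()] objects.
#' @param dir output directory (created if absent).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   list of `patient_record`s.
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(records, function(r) {
    write_physio_csv(r$icp, file.path(dir, paste0(r$patient_id, "_icp.csv")))
    write_physio_csv(r$map, file.path(dir, paste0(r$patient_id, "_map.csv")))
    base <- data.table::data.table(patient_id = r$patient_id,
                                   monitor_type = r$monitor_type, gos = r$gos)
    if (!is.null(r$covariates)) base <- cbind(base, r$covariates)
    base
  })
  data.table::fwrite(data.table::rbindlist(rows, fill = TRUE),
                     file.path(dir, "cohort.csv"), na = "")
  drains <- lapply(records, function(r) unname(apply(r$drainage_intervals, 1L, as.list)))
  names(drains) <- vapply(records, `[[`, "", "patient_id")
  jsonlite::write_json(drains, file.path(dir, "drainage.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- data.table::fread(file.path(dir, "cohort.csv"), na.strings = "")
  drain_path <- file.path(dir, "drainage.json")
  drains <- if (file.exists(drain_path)) jsonlite::read_json(drain_path) else list()
  cov_cols <- setdiff(names(meta), c("patient_id", "monitor_type", "gos"))
  lapply(seq_len(nrow(meta)), function(i) {
    pid <- as.character(meta$patient_id[i])
    di <- drains[[pid]]
    di <- if (length(di)) do.call(rbind, lapply(di, function(p) as.numeric(unlist(p)))) else NULL
    patient_record(
      patient_id = pid, monitor_type = meta$monitor_type[i],
      icp = read_physio_csv(file.path(dir, paste0(pid, "_icp.csv"))),
      map = read_physio_csv(file.path(dir, paste0(pid, "_map.csv"))),
      drainage_intervals = di, gos = meta$gos[i],
      covariates = if (length(cov_cols)) as.data.frame(meta[i, cov_cols, with = FALSE]) else NULL)
  })
}
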