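#' Percentage label at three significant digits
#'
#' Formats `100 * count / n` the way cohort comparison tables print
#' percentages (three significant digits, trailing zeros trimmed).
#'
#' @param count numerator count.
#' @param n group size.
#' @param sig significant digits (default 3).
#' @return Character scalar, e.g. `"4.76"` for 4/84.
#' @export
percent_label <- function(count, n, sig = 3L) {
  if (n == 0) return(NA_character_)
  formatC(signif(100 * count / n, sig), format = "fg")
}

fmt_med_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  q <- quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  sprintf("%.3g (%.3g-%.3g)", q[1], q[2], q[3])
}

table1_categorical <- function(flag_adv, flag_oth) {
  a <- sum(flag_adv, na.rm = TRUE); b <- sum(flag_oth, na.rm = TRUE)
  na_ <- sum(!is.na(flag_adv)); nb <- sum(!is.na(flag_oth))
  res <- chi2_2x2(a, na_ - a, b, nb - b)
  list(adverse = sprintf("%d (%s%%)", a, percent_label(a, na_)),
       other = sprintf("%d (%s%%)", b, percent_label(b, nb)),
       p = res$p)
}

table1_continuous <- function(x_adv, x_oth) {
  p <- tryCatch(mann_whitney_compare(x_adv, x_oth)$p, error = function(e) NA_real_)
  list(adverse = fmt_med_iqr(x_adv), other = fmt_med_iqr(x_oth), p = p)
}

#' Demographic / physiologic comparison table
#'
#' Builds the cohort comparison table: per outcome group (dead vs alive and
#' unfavorable vs favorable), continuous variables as median (IQR) with a
#' Mann-Whitney p-value, categorical variables as n (%) with an uncorrected
#' Pearson chi-square p-value. Physiologic grand means (mean MAP/ICP and
#' mean LPRx per window over the full recording) are taken from the burden
#' summaries; a missing covariate flags the row but the table is still
#' produced.
#'
#' @param records list of [patient_record()] objects.
#' @param summaries long table from [summarize_cohort()] (needs the `full`
#'   segment); may be `NULL` to skip physiologic rows.
#' @return A `data.table`: `scheme`, `variable`, `type`, `adverse`, `other`,
#'   `p`.
#' @export
build_table1 <- function(records, summaries = NULL) {
  meta <- cohort_meta(records)
  # grand mean MAP from the cleaned series (sporadic samples as stored)
  map_mean <- vapply(records, function(r) {
    cl <- filter_artifacts(r$map, "MAP")
    mean(cl$v, na.rm = TRUE)
  }, numeric(1))
  stay_days <- vapply(records, function(r)
    max(span_minutes(r$icp), span_minutes(r$map)) / 1440, numeric(1))
  meta[, `:=`(map_mean = map_mean, stay_days = stay_days)]

  phys <- NULL
  if (!is.null(summaries)) {
    sdt <- data.table::as.data.table(summaries)[segment == "full"]
    phys <- list(icp = sdt[metric == "mean_icp", .(patient_id, value)])
    for (w in sort(unique(sdt[metric == "mean_lprx", window_minutes])))
      phys[[paste0("lprx_", w)]] <-
        sdt[metric == "mean_lprx" & window_minutes == w, .(patient_id, value)]
  }

  rows <- list()
  add <- function(scheme, variable, type, res)
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      scheme = scheme, variable = variable, type = type,
      adverse = res$adverse, other = res$other, p = res$p)

  for (scheme_name in c("survival", "favorable")) {
    adv <- dichotomize_gos(meta$gos, scheme_name)
    pick <- function(x) list(a = x[adv], o = x[!adv])
    add(scheme_name, "n_patients", "count",
        list(adverse = sprintf("%d (%s%%)", sum(adv),
                               percent_label(sum(adv), nrow(meta))),
             other = sprintf("%d (%s%%)", sum(!adv),
                             percent_label(sum(!adv), nrow(meta))),
             p = NA_real_))
    cont_vars <- list(age = meta$age, gcs_eye = meta$gcs_eye,
                      gcs_motor = meta$gcs_motor, gcs_verbal = meta$gcs_verbal,
                      stay_days = meta$stay_days, map = meta$map_mean)
    for (nm in names(cont_vars)) {
      x <- cont_vars[[nm]]
      if (is.null(x)) {
        add(scheme_name, nm, "missing_covariate",
            list(adverse = NA_character_, other = NA_character_, p = NA_real_))
        next
      }
      s <- pick(as.numeric(x))
      add(scheme_name, nm, "continuous", table1_continuous(s$a, s$o))
    }
    if (!is.null(phys)) {
      for (nm in names(phys)) {
        v <- phys[[nm]][match(meta$patient_id, patient_id), value]
        s <- pick(v)
        add(scheme_name, nm, "continuous", table1_continuous(s$a, s$o))
      }
    }
    cat_vars <- list(
      sex_male = if (!is.null(meta$sex)) meta$sex == "M" else NULL,
      hypoxia = meta$hypoxia, hypotension = meta$hypotension,
      tsah_ivh = meta$tsah_ivh, epidural_hematoma = meta$epidural_hematoma,
      evacuation = meta$evacuation, dc_primary = meta$dc_primary,
      dc_secondary = meta$dc_secondary)
    if (!is.null(meta$pupils))
      for (lev in unique(meta$pupils))
        cat_vars[[paste0("pupils_", lev)]] <- meta$pupils == lev
    if (!is.null(meta$marshall))
      for (lev in unique(meta$marshall))
        cat_vars[[paste0("marshall_", lev)]] <- meta$marshall == lev
    for (nm in names(cat_vars)) {
      x <- cat_vars[[nm]]
      if (is.null(x)) {
        add(scheme_name, nm, "missing_covariate",
            list(adverse = NA_character_, other = NA_character_, p = NA_real_))
        next
      }
      s <- pick(as.logical(x))
      add(scheme_name, nm, "categorical",
          tryCatch(table1_categorical(s$a, s$o),
                   error = function(e) list(adverse = NA_character_,
                                            other = NA_character_,
                                            p = NA_real_)))
    }
  }
  data.table::rbindlist(rows)
}

#' Analysis configuration
#'
#' A single configuration object governs every sweep of the pipeline; no
#' hidden defaults live outside it.
#'
#' @param sim a [sim_params()] object, or `NULL` to read a cohort from
#'   `input_dir`.
#' @param input_dir directory with cohort files (see [write_cohort()]).
#' @param windows LPRx windows to compute.
#' @param segments segment labels to materialize.
#' @param pct_thresholds key LPRx thresholds for the percent-time metric.
#' @param schemes outcome schemes.
#' @param subgroups monitor subgroups for the battery.
#' @param use_imputation impute to a regular grid before LPRx.
#' @param tie_rule tie rule for [select_best()].
#' @param min_coverage per-segment coverage floor.
#' @param min_valid_fraction per-window complete-pair floor.
#' @param out_dir output directory.
#' @param seed integer seed (overrides `sim$seed` when simulating).
#' @param make_plots write chi-square-vs-threshold curve PDFs.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(sim = sim_params(), input_dir = NULL,
                            windows = c(10L, 20L),
                            segments = c("full", "first_24h"),
                            pct_thresholds = c(0, 0.2, 0.3),
                            schemes = c("survival", "favorable"),
                            subgroups = c("all", "EVD", "IPD", "no_dc"),
                            use_imputation = FALSE, tie_rule = "lowest",
                            min_coverage = 0.25, min_valid_fraction = 0.8,
                            out_dir = "lprx_out", seed = 1L,
                            make_plots = FALSE) {
  stopifnot(all(windows %in% LPRX_WINDOWS),
            all(segments %in% SEGMENT_LABELS),
            is.null(sim) || inherits(sim, "sim_params"),
            !is.null(sim) || !is.null(input_dir))
  structure(list(sim = sim, input_dir = input_dir,
                 windows = as.integer(windows), segments = segments,
                 pct_thresholds = pct_thresholds, schemes = schemes,
                 subgroups = subgroups, use_imputation = use_imputation,
                 tie_rule = tie_rule, min_coverage = min_coverage,
                 min_valid_fraction = min_valid_fraction,
                 out_dir = out_dir, seed = as.integer(seed),
                 make_plots = make_plots),
            class = "analysis_config")
}

#' Read an analysis configuration from JSON
#'
#' @param path JSON file; fields mirror the arguments of
#'   [analysis_config()], with `sim` given as a list of [sim_params()]
#'   arguments.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_params, as.list(raw$sim))
  do.call(analysis_config, raw)
}

#' Run the full pipeline
#'
#' Simulate (or load) a cohort, clean it, derive LPRx, reduce to burden
#' summaries, build the comparison table, run the threshold-scan battery,
#' and write everything plus a run manifest (configuration, package version,
#' per-patient data-loss counts) to `out_dir`. Deterministic for a fixed
#' configuration and seed: identical runs produce byte-identical CSV/JSON
#' outputs.
#'
#' @param config an [analysis_config()].
#' @return Invisibly, `list(records, truth, summaries, meta, table1,
#'   battery, manifest)`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    gen <- generate_cohort(sim)
    records <- gen$records
    truth <- gen$truth
    write_cohort(records, file.path(config$out_dir, "cohort"))
    jsonlite::write_json(truth, file.path(config$out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    records <- read_cohort(config$input_dir)
    truth <- NULL
  }
  if (!length(records)) stop("pipeline failure [cohort]: no patients")

  losses <- lapply(records, function(r) {
    cl <- clean_record(r)
    list(patient_id = r$patient_id,
         artifacts_icp = attr(cl, "loss_artifacts_icp"),
         artifacts_map = attr(cl, "loss_artifacts_map"),
         drainage = attr(cl, "loss_drainage"))
  })

  summaries <- summarize_cohort(records, windows = config$windows,
                                segments = config$segments,
                                pct_thresholds = config$pct_thresholds,
                                use_imputation = config$use_imputation,
                                min_coverage = config$min_coverage,
                                min_valid_fraction = config$min_valid_fraction)
  data.table::fwrite(summaries, file.path(config$out_dir, "summaries.csv"), na = "")

  meta <- cohort_meta(records)
  tab1 <- build_table1(records, summaries)
  data.table::fwrite(tab1, file.path(config$out_dir, "table1.csv"), na = "")

  battery <- run_scan_battery(summaries, meta, schemes = config$schemes,
                              subgroups = config$subgroups,
                              tie_rule = config$tie_rule)
  data.table::fwrite(battery$results,
                     file.path(config$out_dir, "scan_battery.csv"), na = "")
  best <- battery$results[usable == TRUE]
  jsonlite::write_json(
    lapply(seq_len(nrow(best)), function(i) as.list(best[i])),
    file.path(config$out_dir, "scan_summary.json"),
    auto_unbox = TRUE, digits = NA, na = "null")

  if (isTRUE(config$make_plots)) {
    pdf(file.path(config$out_dir, "scan_curves.pdf"), width = 7, height = 5)
    for (id in names(battery$scans))
      if (battery$scans[[id]]$usable) plot_scan(battery$scans[[id]], main = id)
    dev.off()
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lprx")),
    seed = config$seed,
    n_patients = length(records),
    config = config[setdiff(names(config), "sim")],
    sim = if (!is.null(config$sim)) unclass(config$sim) else NULL,
    data_loss = losses)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(records = records, truth = truth, summaries = summaries,
                 meta = meta, table1 = tab1, battery = battery,
                 manifest = manifest))
}
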