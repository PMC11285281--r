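#' Construct a physiologic pressure series
#'
#' A `physio_series` holds one patient's sporadically sampled pressure signal:
#' sample timestamps in minutes since monitoring start, sample values in mmHg
#' (each value is the median of the monitor readings over the sample's
#' aggregation window), and the per-sample aggregation duration in minutes.
#' Missing values are `NA`; timestamps of removed samples are retained so the
#' time base stays intact through cleaning.
#'
#' @param t numeric, strictly increasing sample timestamps (minutes, > 0).
#' @param v numeric, sample values in mmHg (`NA` allowed).
#' @param agg numeric, per-sample aggregation duration in minutes; recycled if
#'   scalar. Must be positive (monitoring archives store 0.5--5 min medians).
#' @return A `physio_series`, a `data.frame` with columns `t`, `v`, `agg`.
#' @examples
#' physio_series(t = c(1, 2, 4), v = c(12, 13, 11), agg = c(1, 1, 2))
#' @export
physio_series <- function(t = numeric(), v = numeric(), agg = numeric()) {
  t <- as.numeric(t); v <- as.numeric(v)
  if (length(agg) == 1L) agg <- rep(as.numeric(agg), length(t))
  agg <- as.numeric(agg)
  if (length(t) != length(v) || length(t) != length(agg))
    stop("t, v and agg must have equal length")
  if (length(t) && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing")
  if (any(!is.finite(t)) || (length(agg) && any(!is.finite(agg) | agg <= 0)))
    stop("timestamps must be finite and aggregation durations positive")
  structure(data.frame(t = t, v = v, agg = agg),
            class = c("physio_series", "data.frame"))
}

#' @export
print.physio_series <- function(x, ...) {
  cat(sprintf("<physio_series> %d samples over %.1f min (%d missing)\n",
              nrow(x), if (nrow(x)) max(x$t) else 0, sum(is.na(x$v))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

span_minutes <- function(series) {
  if (!nrow(series)) return(0)
  max(series$t)
}

#' Read / write a physiologic series CSV
#'
#' Serialization uses columns `t_min`, `value_mmHg`, `agg_min`; missing values
#' are written as empty fields.
#'
#' @param series a [physio_series()].
#' @param path file path.
#' @return `write_physio_csv` returns `path` invisibly; `read_physio_csv`
#'   returns a `physio_series`.
#' @export
write_physio_csv <- function(series, path) {
  dt <- data.table::data.table(t_min = series$t, value_mmHg = series$v,
                               agg_min = series$agg)
  data.table::fwrite(dt, path, na = "")
  invisible(path)
}

#' @rdname write_physio_csv
#' @export
read_physio_csv <- function(path) {
  dt <- data.table::fread(path, na.strings = "")
  physio_series(t = dt$t_min, v = dt$value_mmHg, agg = dt$agg_min)
}
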