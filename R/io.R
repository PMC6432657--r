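#' Read an evenly sampled time series from delimited text
#'
#' Expects a header row, one time column in seconds and at least one value
#' column. The delimiter is auto-detected from the file extension
#' (`.csv` = comma, anything else = tab). The sampling rate is inferred from
#' the median time step; spacing that deviates from it by more than
#' `1e-6 * dt` anywhere is an error — the reader never resamples silently.
#'
#' @param path Path to a delimited text file.
#' @param time_col Name of the time column (seconds).
#' @param value_col Name of the value column; defaults to the first non-time
#'   column.
#' @param label Channel label for the returned series; defaults to `value_col`.
#' @return A [ppg_ts()].
#' @export
read_timeseries <- function(path, time_col = "time_s", value_col = NULL,
                            label = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!time_col %in% names(df))
    stop(sprintf("time column '%s' not found in %s", time_col, path))
  if (is.null(value_col)) {
    value_col <- setdiff(names(df), time_col)[1L]
    if (is.na(value_col)) stop("no value column found")
  }
  if (!value_col %in% names(df))
    stop(sprintf("value column '%s' not found in %s", value_col, path))
  tt <- as.numeric(df[[time_col]])
  if (length(tt) < 2L) stop("need at least 2 rows to infer a sampling rate")
  dts <- diff(tt)
  if (any(dts <= 0)) stop("time column must be strictly increasing")
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * dt))
    stop("time column is not evenly spaced (tolerance 1e-6 * dt); refusing to resample")
  ppg_ts(as.numeric(df[[value_col]]), rate = 1 / dt, t0 = tt[1L],
         label = if (is.null(label)) value_col else label)
}

#' Write a time series as delimited text
#'
#' Writes columns `time_s` and `value` with 17 significant digits so that a
#' write/read round trip reproduces the samples exactly.
#'
#' @param ts A [ppg_ts()].
#' @param path Output path; `.csv` writes comma-separated, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "ppg_ts"))
  df <- data.frame(time_s = ts_times(ts), value = ts$samples)
  write_table(df, path)
}

#' Write a tabular analysis product as delimited text
#'
#' Accepts any data frame (frequency tracks, bout tables, coherence and ramp
#' summaries, long-format spectrograms). Numeric columns are written with 17
#' significant digits so round trips are lossless to double precision; an empty
#' table yields a header-only file.
#'
#' @param product A data frame.
#' @param path Output path; `.csv` writes comma-separated, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_table <- function(product, path) {
  product <- as.data.frame(product)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- product
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a tabular analysis product written by [write_table()]
#'
#' @param path Path to a delimited text file with a header.
#' @return A data frame.
#' @export
read_table_product <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Long-format representation of a spectrogram
#'
#' @param spec A `ppg_spectrogram` (see [spectrogram()]).
#' @return Data frame with columns `time_s`, `freq_hz`, `power`.
#' @export
spectrogram_table <- function(spec) {
  stopifnot(inherits(spec, "ppg_spectrogram"))
  data.frame(
    time_s = rep(spec$window_times, each = length(spec$freqs)),
    freq_hz = rep(spec$freqs, times = length(spec$window_times)),
    power = as.vector(spec$power)
  )
}

#' Rebuild a spectrogram object from its long-format table
#'
#' @param df Data frame with columns `time_s`, `freq_hz`, `power` as written
#'   by [spectrogram_table()].
#' @return A `ppg_spectrogram`.
#' @export
spectrogram_from_table <- function(df) {
  freqs <- sort(unique(df$freq_hz))
  times <- sort(unique(df$time_s))
  df <- df[order(df$time_s, df$freq_hz), ]
  pw <- matrix(df$power, nrow = length(freqs), ncol = length(times))
  structure(list(window_times = times, freqs = freqs, power = pw),
            class = "ppg_spectrogram")
}
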