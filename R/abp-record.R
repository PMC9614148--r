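#' Construct an arterial blood pressure record
#'
#' An ABP record is a tibble with columns `time` (seconds) and `pressure`
#' (arbitrary pressure units, e.g. mmHg), carrying the sampling rate and
#' optional ground-truth beat annotations as attributes. It is the container
#' every filter and the peak detector consume.
#'
#' @param pressure Numeric vector of pressure samples (finite).
#' @param fs Sampling rate in Hz (> 0).
#' @param time Optional vector of sample times in seconds; defaults to
#'   `(0:(n-1))/fs`.
#' @param annotations Optional integer vector of ground-truth systolic peak
#'   positions (1-based sample indices into `pressure`).
#' @param transient Number of leading samples dominated by filter start-up
#'   transients (0 for a raw record). Downstream beat detection skips them.
#'
#' @return A tibble of class `abp_record` with columns `time`, `pressure`
#'   and attributes `fs`, `annotations`, `transient`.
#' @examples
#' rec <- abp_record(sin(2 * pi * 1.2 * seq(0, 4, by = 1 / 250)), fs = 250)
#' rec
#' @export
abp_record <- function(pressure, fs, time = NULL, annotations = NULL,
                       transient = 0L) {
  pressure <- as.numeric(pressure)
  if (length(pressure) < 1L) stop("an ABP record needs at least one sample")
  if (!all(is.finite(pressure))) stop("ABP samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz")
  }
  if (is.null(time)) time <- (seq_along(pressure) - 1) / fs
  if (length(time) != length(pressure)) {
    stop("`time` and `pressure` must have equal length")
  }
  if (!is.null(annotations)) {
    annotations <- as.integer(annotations)
    stopifnot(all(annotations >= 1L), all(annotations <= length(pressure)))
  }
  out <- tibble::tibble(time = as.numeric(time), pressure = pressure)
  class(out) <- c("abp_record", class(out))
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "annotations") <- annotations
  attr(out, "transient") <- as.integer(transient)
  out
}

#' Sampling rate of an ABP record
#' @param x An `abp_record`.
#' @return Sampling rate in Hz.
#' @export
abp_fs <- function(x) attr(x, "fs")

#' Ground-truth beat annotations of an ABP record
#' @param x An `abp_record`.
#' @return Integer sample indices, or `NULL`.
#' @export
abp_annotations <- function(x) attr(x, "annotations")

#' @export
print.abp_record <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "<abp_record: %d samples, fs = %g Hz, %.2f s%s%s>\n",
    n, abp_fs(x), n / abp_fs(x),
    if (!is.null(abp_annotations(x))) {
      sprintf(", %d annotated beats", length(abp_annotations(x)))
    } else "",
    if (isTRUE(attr(x, "transient") > 0L)) {
      sprintf(", %d transient samples", attr(x, "transient"))
    } else ""
  ))
  NextMethod()
}

#' Read an ABP record from a two-column CSV
#'
#' Expects columns `time` (seconds, uniformly sampled) and `pressure`. The
#' sampling rate is inferred from the median time step unless given.
#'
#' @param path Path to a CSV file.
#' @param fs Optional sampling rate override (Hz).
#' @return An [abp_record()].
#' @export
read_abp_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time", "pressure") %in% names(df))) {
    stop("CSV must have columns `time` and `pressure`")
  }
  if (is.null(fs)) {
    dt <- stats::median(diff(df$time))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate from `time`")
    fs <- 1 / dt
  }
  abp_record(df$pressure, fs = fs, time = df$time)
}

#' Write an ABP record to CSV
#' @param x An `abp_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abp_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x[, c("time", "pressure")]), path,
                   row.names = FALSE)
  invisible(path)
}

# rebuild a record with new samples but shared metadata
abp_like <- function(x, pressure, transient = attr(x, "transient")) {
  abp_record(pressure,
    fs = abp_fs(x), time = x$time,
    annotations = abp_annotations(x), transient = transient
  )
}
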