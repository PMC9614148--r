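#' Detect systolic pulse peaks in a preprocessed ABP record
#'
#' A frequency-domain-gated detector: (1) candidate regions are gated by
#' sliding-window spectral energy in the pulse band (default 0.5–10 Hz),
#' (2) candidates are refined to local maxima of the filtered waveform,
#' (3) an adaptive amplitude threshold (moving median + `k` times moving
#' MAD) rejects sub-threshold ripples, and (4) a refractory period (default
#' 0.2 s, i.e. no rate above 300 bpm) suppresses double detections, keeping
#' the larger peak. Samples flagged as filter transient are skipped.
#'
#' If the record carries ground-truth beat annotations and
#' `use_annotations = TRUE`, those positions override detection (the
#' programmatic stand-in for manual calibration of mis-detected peaks).
#'
#' @param x A preprocessed [abp_record()].
#' @param band Pulse band for the spectral-energy gate, Hz.
#' @param refractory Minimum peak spacing in seconds.
#' @param threshold_k Multiplier on the moving MAD for the amplitude
#'   threshold.
#' @param gate_frac Fraction of the peak band energy below which a region is
#'   considered pulseless.
#' @param dicrotic_frac Peaks smaller than this fraction of both
#'   neighbouring peak amplitudes (above the signal median) are removed as
#'   separated dicrotic waves.
#' @param use_annotations Use ground-truth annotations when present.
#'
#' @return A tibble of class `beat_series` with columns `peak_index`
#'   (1-based sample position), `peak_time` (s) and `peak_amplitude`
#'   (filtered signal value), and an `fs` attribute.
#' @export
detect_peaks <- function(x, band = c(0.5, 10), refractory = 0.2,
                         threshold_k = 1.0, gate_frac = 0.05,
                         dicrotic_frac = 0.45, use_annotations = FALSE) {
  stopifnot(inherits(x, "abp_record"))
  if (!all(is.finite(x$pressure))) stop("record contains non-finite samples")
  fs <- abp_fs(x)
  p <- x$pressure
  n <- length(p)

  if (use_annotations && !is.null(abp_annotations(x))) {
    idx <- abp_annotations(x)
    return(new_beat_series(idx, x$time[idx], p[idx], fs))
  }

  skip <- min(attr(x, "transient") %||% 0L, n)
  empty <- new_beat_series(integer(0), numeric(0), numeric(0), fs)
  if (n - skip < fs) {
    warning("record too short for peak detection")
    return(empty)
  }

  # (1) pulse-band energy gate
  nyq <- fs / 2
  bf <- signal::butter(2, pmin(band, nyq * 0.99) / nyq, type = "pass")
  bp <- signal::filtfilt(bf$b, bf$a, p - mean(p))
  win <- max(3L, round(fs)) # 1 s energy window
  energy <- stats::filter(bp^2, rep(1 / win, win), sides = 2)
  energy[is.na(energy)] <- 0
  if (max(energy) <= 0) {
    warning("no pulse energy found; returning empty beat series")
    return(empty)
  }
  gated <- energy > gate_frac * max(energy)

  # (2) candidate maxima of the band-limited waveform, subject to an
  # adaptive amplitude threshold: moving median + k * moving MAD (raw
  # median absolute deviation), computed on a coarse 0.1 s grid
  tail_skip <- max(round(0.5 * fs), attr(x, "tail_invalid") %||% 0L)
  cand <- which(diff(sign(diff(bp))) < 0) + 1L
  cand <- cand[cand > skip & cand <= n - tail_skip & gated[cand]]
  if (!length(cand)) {
    warning("no peaks found")
    return(empty)
  }
  thr_win <- 2 # seconds
  grid <- unique(pmin(n, pmax(1L, seq(1L, n, by = max(1L, round(fs / 10))))))
  half <- round(thr_win * fs / 2)
  thr_grid <- vapply(grid, function(i) {
    seg <- bp[max(1L, i - half):min(n, i + half)]
    med <- stats::median(seg)
    med + threshold_k * stats::median(abs(seg - med))
  }, numeric(1))
  thr <- stats::approx(grid, thr_grid, xout = cand, rule = 2)$y
  cand <- cand[bp[cand] > thr]
  if (!length(cand)) {
    warning("no peaks found above the adaptive threshold")
    return(empty)
  }

  # (3) refine each candidate to the local maximum of the filtered
  # waveform within a 0.1 s neighbourhood; a short moving average absorbs
  # residual high-frequency noise around the flat systolic apex
  halfw <- max(1L, as.integer(round(0.05 * fs)))
  ks <- max(1L, as.integer(round(fs / 50)) * 2L + 1L)
  ps <- as.numeric(stats::filter(p, rep(1 / ks, ks), sides = 2))
  ps[is.na(ps)] <- p[is.na(ps)]
  cand <- unique(vapply(cand, function(ci) {
    lo <- max(1L, as.integer(ci) - halfw)
    hi <- min(n, as.integer(ci) + halfw)
    lo + which.max(ps[lo:hi]) - 1L
  }, integer(1)))
  cand <- cand[cand > skip]

  # (4) refractory: keep the larger peak within the minimum spacing
  min_gap <- round(refractory * fs)
  keep <- logical(length(cand))
  taken <- rep(FALSE, n + min_gap + 1L)
  for (i in order(p[cand], decreasing = TRUE)) {
    ci <- cand[i]
    lo <- max(1L, ci - min_gap + 1L)
    if (!any(taken[lo:(ci + min_gap - 1L)])) {
      keep[i] <- TRUE
      taken[ci] <- TRUE
    }
  }
  idx <- sort(cand[keep])

  # (5) dicrotic suppression: a dicrotic wave that separates from the
  # systolic downslope (long beats) is far smaller than BOTH surrounding
  # systolic peaks; genuine low-amplitude runs (VT, VF) keep at least one
  # similar-sized neighbour and survive
  amp0 <- p[idx] - stats::median(p)
  repeat {
    m <- length(idx)
    if (m < 2L) break
    nb_min <- pmin(c(amp0[2], amp0[-m]), c(amp0[-1], amp0[m - 1L]))
    drop <- amp0 < dicrotic_frac * nb_min
    if (!any(drop)) break
    idx <- idx[!drop]
    amp0 <- amp0[!drop]
  }
  new_beat_series(idx, x$time[idx], p[idx], fs)
}

new_beat_series <- function(idx, time, amp, fs) {
  out <- tibble::tibble(
    peak_index = as.integer(idx),
    peak_time = as.numeric(time),
    peak_amplitude = as.numeric(amp)
  )
  class(out) <- c("beat_series", class(out))
  attr(out, "fs") <- fs
  out
}

#' Pulse rate variability series from detected beats
#'
#' Converts consecutive peak positions into the beat-to-beat series used by
#' the feature battery: instantaneous pulse rate
#' `prv(i) = 60 fs / (peak(i+1) - peak(i))` in bpm, pulse-to-pulse interval
#' `ppi(i) = 1000 (peak(i+1) - peak(i)) / fs` in ms, and the pulse amplitude
#' `apm(i)` of peak `i`.
#'
#' @param beats A `beat_series` from [detect_peaks()], with at least 2 peaks.
#' @param label Optional class label carried through to features.
#' @param source Optional provenance string (record id).
#' @return A tibble of class `prv_series` with columns `prv` (bpm), `ppi`
#'   (ms) and `apm`, of length `n_peaks - 1`, plus `label`/`source`/`fs`
#'   attributes.
#' @examples
#' b <- prvdetect:::new_beat_series(c(1, 251, 501), c(0, 1, 2), c(1, 1, 1), 250)
#' compute_prv(b)
#' @export
compute_prv <- function(beats, label = NA, source = NA_character_) {
  stopifnot(inherits(beats, "beat_series"))
  if (nrow(beats) < 2L) stop("at least 2 peaks are required to compute PRV")
  fs <- attr(beats, "fs")
  gaps <- diff(beats$peak_index)
  new_prv_series(
    prv = 60 * fs / gaps,
    ppi = 1000 * gaps / fs,
    apm = beats$peak_amplitude[-nrow(beats)],
    label = label, source = source, fs = fs
  )
}

new_prv_series <- function(prv, ppi, apm, label = NA, source = NA_character_,
                           fs = NA_real_) {
  stopifnot(length(prv) == length(ppi), length(ppi) == length(apm))
  out <- tibble::tibble(prv = prv, ppi = ppi, apm = apm)
  class(out) <- c("prv_series", class(out))
  attr(out, "label") <- label
  attr(out, "source") <- source
  attr(out, "fs") <- fs
  out
}

#' Build a PRV series directly from interval and amplitude vectors
#'
#' Convenience constructor used when the interval sequence is already known
#' (e.g. the ground truth of the synthetic generator).
#'
#' @param ppi Pulse-to-pulse intervals in ms (> 0).
#' @param apm Per-beat amplitudes (same length).
#' @param label,source Optional label and provenance.
#' @return A `prv_series` tibble.
#' @export
prv_series <- function(ppi, apm = rep(1, length(ppi)), label = NA,
                       source = NA_character_) {
  stopifnot(all(ppi > 0), length(apm) == length(ppi))
  new_prv_series(prv = 60000 / ppi, ppi = ppi, apm = apm,
                 label = label, source = source)
}

#' Window a PRV series into fixed-beat segments
#'
#' Slides a window of `window_beats` PRV samples with a step of
#' `step_beats`; the trailing partial window is dropped. Each segment
#' inherits the series label and provenance and records its starting beat.
#'
#' @param series A `prv_series`.
#' @param window_beats Window length in beats (>= 8, the smallest window on
#'   which all 19 features are defined).
#' @param step_beats Step between consecutive windows, in beats.
#' @return A tibble with one row per segment: `source`, `start_beat`,
#'   `label` and a `series` list-column of `prv_series` windows.
#' @examples
#' s <- prv_series(rep(800, 30))
#' nrow(segment_prv(s, window_beats = 16, step_beats = 1)) # 30 - 16 + 1
#' @export
segment_prv <- function(series, window_beats = 16, step_beats = 1) {
  stopifnot(inherits(series, "prv_series"))
  if (window_beats < 8) stop("`window_beats` must be at least 8")
  stopifnot(step_beats >= 1)
  n <- nrow(series)
  if (n < window_beats) {
    warning("series shorter than one window; returning no segments")
    return(tibble::tibble(
      source = character(0), start_beat = integer(0),
      label = attr(series, "label")[0], series = list()
    ))
  }
  starts <- seq(1L, n - window_beats + 1L, by = step_beats)
  tibble::tibble(
    source = attr(series, "source") %||% NA_character_,
    start_beat = as.integer(starts),
    label = attr(series, "label"),
    series = purrr::map(starts, function(s) {
      new_prv_series(
        prv = series$prv[s:(s + window_beats - 1L)],
        ppi = series$ppi[s:(s + window_beats - 1L)],
        apm = series$apm[s:(s + window_beats - 1L)],
        label = attr(series, "label"),
        source = attr(series, "source"),
        fs = attr(series, "fs")
      )
    })
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
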