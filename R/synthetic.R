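#' Rhythm specification for the synthetic ABP generator
#'
#' Encodes one of the five rhythm classes and its generation parameters.
#' The arrhythmic kinds embed an episode satisfying the defining rate and
#' duration rule inside a normal background:
#' \itemize{
#'   \item EB (extreme bradycardia): rate < 40 bpm for >= 5 consecutive beats;
#'   \item ET (extreme tachycardia): rate > 140 bpm for >= 17 beats;
#'   \item VT (ventricular tachycardia): >= 5 beats at rate > 100 bpm with
#'     reduced pulse amplitude;
#'   \item VF (ventricular flutter): a low-amplitude oscillation
#'     (default 4.5 Hz) lasting >= 4 s.
#' }
#'
#' @param kind One of `"healthy"`, `"EB"`, `"ET"`, `"VT"`, `"VF"`.
#' @param base_rate Background rate in bpm.
#' @param variability Standard deviation of the AR(1) beat-to-beat rate
#'   modulation, bpm.
#' @param episode_rate Range (length 2) of the in-episode rate, bpm
#'   (ignored for healthy; for VF this is the oscillation rate).
#' @param episode_beats Episode length in beats; `NULL` fills the record up
#'   to a short lead-in/out, the default, which emulates the burst segments
#'   used for classification.
#' @param episode_seconds Minimum episode duration in seconds (VF).
#' @param amplitude_mean,amplitude_jitter Mean and standard deviation of
#'   per-beat pulse amplitude, pressure units.
#' @param amplitude_factor Episode amplitude scaling (VT 0.6, VF 0.3).
#' @return A list of class `rhythm_spec`.
#' @export
rhythm_spec <- function(kind = c("healthy", "EB", "ET", "VT", "VF"),
                        base_rate = 75, variability = 3,
                        episode_rate = NULL, episode_beats = NULL,
                        episode_seconds = 4, amplitude_mean = 40,
                        amplitude_jitter = 2, amplitude_factor = NULL) {
  kind <- match.arg(kind)
  defaults <- list(
    healthy = list(rate = NULL, factor = 1),
    EB = list(rate = c(32, 38), factor = 1),
    ET = list(rate = c(150, 165), factor = 1),
    VT = list(rate = c(110, 135), factor = 0.6),
    VF = list(rate = c(270, 270), factor = 0.3) # 4.5 Hz oscillation
  )[[kind]]
  structure(
    list(
      kind = kind, base_rate = base_rate, variability = variability,
      episode_rate = episode_rate %||% defaults$rate,
      episode_beats = episode_beats, episode_seconds = episode_seconds,
      amplitude_mean = amplitude_mean, amplitude_jitter = amplitude_jitter,
      amplitude_factor = amplitude_factor %||% defaults$factor
    ),
    class = "rhythm_spec"
  )
}

# Table-style minimum episode length, in beats
min_episode_beats <- function(spec) {
  switch(spec$kind,
    healthy = 0L,
    EB = 5L,
    ET = 17L,
    VT = 5L,
    VF = {
      rate <- mean(spec$episode_rate)
      as.integer(ceiling(spec$episode_seconds / (60 / rate))) + 1L
    }
  )
}

#' Generate a ground-truth interval and amplitude sequence
#'
#' The background is an AR(1)-modulated normal rhythm (coefficient 0.8,
#' marginal standard deviation `variability` bpm). Arrhythmic kinds embed a
#' single episode meeting the class's defining minimum, centred between a
#' lead-in and lead-out of normal beats; by default the episode fills all
#' but `margin_beats` on each side. VF intervals are the (constant)
#' oscillation period.
#'
#' @param spec A [rhythm_spec()].
#' @param n_beats Total number of intervals to generate.
#' @param seed Optional RNG seed for reproducibility.
#' @param margin_beats Normal beats kept before and after the episode.
#' @return A tibble with one row per interval: `ppi` (ms), `rate` (bpm),
#'   `amplitude` (pressure units, amplitude of the beat opening the
#'   interval), `in_episode`, `vf` (oscillatory rendering flag). The
#'   episode interval range is attached as attribute `episode`.
#' @examples
#' g <- gen_ppi(rhythm_spec("EB"), 40, seed = 1)
#' sum(g$ppi[g$in_episode] > 1500) >= 5
#' @export
gen_ppi <- function(spec, n_beats, seed = NULL, margin_beats = 4L) {
  stopifnot(inherits(spec, "rhythm_spec"), n_beats >= 2)
  if (!is.null(seed)) set.seed(seed)
  need <- min_episode_beats(spec)
  ep_len <- if (spec$kind == "healthy") 0L else {
    len <- spec$episode_beats %||% max(need, n_beats - 2L * margin_beats)
    as.integer(len)
  }
  if (ep_len > 0 && ep_len < need) {
    stop(sprintf("episode of %d beats is below the %s minimum of %d",
                 ep_len, spec$kind, need))
  }
  if (n_beats < ep_len + 2L) {
    stop("`n_beats` too small to host the episode plus background")
  }

  # AR(1) background rate, marginal sd = variability
  phi <- 0.8
  innov <- stats::rnorm(n_beats, 0, spec$variability * sqrt(1 - phi^2))
  e <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  rate <- pmax(20, spec$base_rate + e)

  in_episode <- rep(FALSE, n_beats)
  vf <- rep(FALSE, n_beats)
  if (ep_len > 0) {
    start <- max(1L, (n_beats - ep_len) %/% 2L + 1L)
    idx <- start:(start + ep_len - 1L)
    in_episode[idx] <- TRUE
    rate[idx] <- if (spec$kind == "VF") {
      mean(spec$episode_rate)
    } else {
      stats::runif(ep_len, spec$episode_rate[1], spec$episode_rate[2])
    }
    if (spec$kind == "VF") vf[idx] <- TRUE
  }

  amp <- spec$amplitude_mean + stats::rnorm(n_beats, 0, spec$amplitude_jitter)
  amp <- pmax(0.2 * spec$amplitude_mean, amp)
  amp[in_episode] <- amp[in_episode] * spec$amplitude_factor

  out <- tibble::tibble(
    ppi = 60000 / rate, rate = rate, amplitude = amp,
    in_episode = in_episode, vf = vf
  )
  attr(out, "episode") <- if (ep_len > 0) range(which(in_episode)) else NULL
  attr(out, "kind") <- spec$kind
  out
}

#' Render an interval sequence as an ABP waveform
#'
#' Each normal beat becomes a two-Gaussian pulse: a systolic peak (width
#' 0.08 s) and a dicrotic wave at 40% amplitude offset by 0.3 of the beat
#' interval (width 0.12 s), scaled by the per-beat amplitude and superposed
#' on a constant baseline. At ordinary rates the dicrotic wave rides the
#' systolic downslope as a shoulder, as in real ABP; only at long intervals
#' does it separate into its own bump. Oscillatory (VF) beats are rendered
#' as raised-cosine cycles whose superposition forms a continuous
#' low-amplitude oscillation. Ground-truth systolic peak positions
#' (refined to the rendered local maxima) are attached as annotations.
#'
#' @param ppi_tbl A tibble from [gen_ppi()] (columns `ppi`, `amplitude`,
#'   `vf`), or a numeric vector of intervals in ms.
#' @param amplitudes Per-beat amplitudes when `ppi_tbl` is a bare vector.
#' @param fs Sampling rate, Hz.
#' @param baseline Constant baseline pressure.
#' @param lead_in Seconds of flat signal before the first beat (leaves room
#'   for the rendered pulse onset and filter transients).
#' @return An annotated [abp_record()].
#' @export
render_abp <- function(ppi_tbl, amplitudes = NULL, fs = 250, baseline = 80,
                       lead_in = 3) {
  if (is.data.frame(ppi_tbl)) {
    ppi <- ppi_tbl$ppi
    amp <- ppi_tbl$amplitude
    vf <- ppi_tbl$vf %||% rep(FALSE, length(ppi))
  } else {
    ppi <- as.numeric(ppi_tbl)
    amp <- amplitudes %||% rep(1, length(ppi))
    vf <- rep(FALSE, length(ppi))
  }
  stopifnot(all(ppi > 0), length(amp) == length(ppi))
  n_beat <- length(ppi) + 1L
  peak_t <- lead_in + c(0, cumsum(ppi)) / 1000
  amp <- c(amp, amp[length(amp)])
  vf <- c(vf, vf[length(vf)])
  dur <- peak_t[n_beat] + 1
  n <- as.integer(ceiling(dur * fs))
  t <- (seq_len(n) - 1) / fs
  p <- rep(0, n)

  sig_s <- 0.08 # systolic width (s)
  sig_d <- 0.12 # dicrotic width (s)
  for (k in seq_len(n_beat)) {
    tk <- peak_t[k]
    beat_ppi <- if (k <= length(ppi)) ppi[k] / 1000 else ppi[length(ppi)] / 1000
    if (vf[k]) {
      # one raised-cosine oscillation cycle centred on the peak
      half <- beat_ppi / 2
      sel <- which(t >= tk - half & t <= tk + half)
      p[sel] <- p[sel] + amp[k] * 0.5 * (1 + cos(2 * pi * (t[sel] - tk) / beat_ppi))
    } else {
      lo <- tk - 0.45 * beat_ppi
      hi <- tk + 0.95 * beat_ppi
      sel <- which(t >= lo & t <= hi)
      td <- t[sel] - tk
      p[sel] <- p[sel] + amp[k] * (exp(-td^2 / (2 * sig_s^2)) +
        0.4 * exp(-(td - 0.3 * beat_ppi)^2 / (2 * sig_d^2)))
    }
  }
  # annotations: the rendered local maximum nearest each nominal peak time
  # (superposed dicrotic/neighbour tails shift the true maximum slightly)
  idx <- vapply(seq_len(n_beat), function(k) {
    nominal <- as.integer(round(peak_t[k] * fs)) + 1L
    beat_ppi <- if (k <= length(ppi)) ppi[k] / 1000 else ppi[length(ppi)] / 1000
    w <- max(2L, as.integer(round(0.12 * beat_ppi * fs)))
    lo <- max(1L, nominal - w)
    hi <- min(n, nominal + w)
    lo + which.max(p[lo:hi]) - 1L
  }, integer(1))
  abp_record(baseline + p, fs = fs, annotations = pmin(n, pmax(1L, idx)))
}

#' Noise specification for synthetic records
#'
#' Three additive noise classes: mains (AC) interference — a sinusoid at
#' the powerline frequency —, slow baseline drift — a sum of sub-0.5 Hz
#' sinusoids —, and EMG-like high-frequency noise — white noise high-passed
#' above `emg_cutoff`.
#'
#' @param ac_amplitude AC sinusoid amplitude, pressure units.
#' @param ac_freq Mains frequency, Hz.
#' @param drift_amplitude Total drift amplitude, pressure units.
#' @param drift_freqs Drift frequencies, Hz (each < 0.5).
#' @param emg_amplitude Standard deviation of the EMG-like noise.
#' @param emg_cutoff High-pass cutoff for the EMG band, Hz.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(ac_amplitude = 5, ac_freq = 50, drift_amplitude = 8,
                       drift_freqs = c(0.05, 0.1), emg_amplitude = 2,
                       emg_cutoff = 70) {
  stopifnot(ac_amplitude >= 0, drift_amplitude >= 0, emg_amplitude >= 0,
            all(drift_freqs < 0.5))
  structure(
    list(ac_amplitude = ac_amplitude, ac_freq = ac_freq,
         drift_amplitude = drift_amplitude, drift_freqs = drift_freqs,
         emg_amplitude = emg_amplitude, emg_cutoff = emg_cutoff),
    class = "noise_spec"
  )
}

#' Add the three noise classes to a record
#'
#' @param x An [abp_record()].
#' @param spec A [noise_spec()].
#' @param seed Optional RNG seed (phases and EMG noise).
#' @return A noisy `abp_record`; ground-truth annotations are preserved.
#' @export
add_noise <- function(x, spec = noise_spec(), seed = NULL) {
  stopifnot(inherits(x, "abp_record"), inherits(spec, "noise_spec"))
  if (!is.null(seed)) set.seed(seed)
  fs <- abp_fs(x)
  t <- x$time
  p <- x$pressure
  if (spec$ac_amplitude > 0) {
    p <- p + spec$ac_amplitude * sin(2 * pi * spec$ac_freq * t +
                                       stats::runif(1, 0, 2 * pi))
  }
  if (spec$drift_amplitude > 0) {
    for (f in spec$drift_freqs) {
      p <- p + spec$drift_amplitude / length(spec$drift_freqs) *
        sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    }
  }
  if (spec$emg_amplitude > 0 && spec$emg_cutoff < fs / 2) {
    hf <- signal::butter(4, spec$emg_cutoff / (fs / 2), type = "high")
    w <- signal::filtfilt(hf$b, hf$a, stats::rnorm(length(p)))
    p <- p + spec$emg_amplitude * w / stats::sd(w)
  }
  abp_like(x, p)
}

#' Generate a labeled synthetic dataset end to end
#'
#' Runs the full pipeline over synthetic records of all requested rhythm
#' classes: interval generation, waveform rendering, noise, preprocessing,
#' peak detection, PRV computation, windowing and feature extraction. Class
#' labels follow the fixed mapping healthy = 1, EB = 2, ET = 3, VT = 4,
#' VF = 5.
#'
#' @param kinds Character vector of rhythm kinds.
#' @param n_segments_per_class Number of windowed segments retained per
#'   class.
#' @param n_beats Beats per synthetic record.
#' @param fs Sampling rate, Hz.
#' @param noise A [noise_spec()], or `NULL` for clean records.
#' @param window_beats,step_beats Windowing parameters (see
#'   [segment_prv()]).
#' @param cfg An [entropy_config()].
#' @param seed RNG seed; the run is deterministic given the seed.
#' @return A feature tibble (one row per segment) with `label` (factor with
#'   the five class levels), `class_id` (1–5), `source`, `start_beat` and
#'   the 19 feature columns.
#' @export
make_dataset <- function(kinds = c("healthy", "EB", "ET", "VT", "VF"),
                         n_segments_per_class = 100, n_beats = 120,
                         fs = 250, noise = noise_spec(),
                         window_beats = 16, step_beats = 1,
                         cfg = entropy_config(), seed = 1) {
  stopifnot(all(kinds %in% class_levels()))
  set.seed(seed)
  out <- purrr::map(kinds, function(kind) {
    rows <- list()
    got <- 0L
    rec_i <- 0L
    while (got < n_segments_per_class && rec_i < 100L) {
      rec_i <- rec_i + 1L
      rec_seed <- sample.int(.Machine$integer.max, 1L)
      g <- gen_ppi(rhythm_spec(kind), n_beats, seed = rec_seed)
      rec <- render_abp(g, fs = fs)
      if (!is.null(noise)) rec <- add_noise(rec, noise, seed = rec_seed)
      filt <- preprocess(rec)
      beats <- detect_peaks(filt)
      if (nrow(beats) < window_beats + 1L) next
      series <- compute_prv(beats, label = kind,
                            source = sprintf("%s-%03d", kind, rec_i))
      segs <- segment_prv(series, window_beats, step_beats)
      if (!nrow(segs)) next
      rows[[length(rows) + 1L]] <- extract_features(segs, cfg)
      got <- got + nrow(segs)
    }
    dplyr::slice_head(dplyr::bind_rows(rows), n = n_segments_per_class)
  })
  res <- dplyr::bind_rows(out)
  res$label <- factor(res$label, levels = class_levels())
  res$class_id <- as.integer(res$label)
  dplyr::relocate(res, "label", "class_id", .after = "start_beat")
}

#' The five rhythm class labels, in label order 1–5
#' @return Character vector.
#' @export
class_levels <- function() c("healthy", "EB", "ET", "VT", "VF")
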