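#' Configuration for the entropy and histogram features
#'
#' @param m_sampen Embedding dimension for sample entropy (default 2).
#' @param m_pe Ordinal pattern order for permutation entropy (default 5;
#'   with natural-log entropy the maximum is `ln(m!)`, about 4.79 nats).
#' @param r_frac Sample-entropy tolerance as a fraction of the segment
#'   standard deviation (default 0.25). Set `r_abs` for an absolute
#'   tolerance instead.
#' @param r_abs Optional absolute sample-entropy tolerance (same units as
#'   the series); overrides `r_frac` when not `NULL`.
#' @param she_bins Number of equal-width histogram bins for the normalized
#'   Shannon entropy (default 16).
#' @param pnn_thresholds Successive-difference thresholds in ms for the
#'   PNN fractions (default 40 and 70 ms).
#' @return A list of class `entropy_config`.
#' @export
entropy_config <- function(m_sampen = 2, m_pe = 5, r_frac = 0.25,
                           r_abs = NULL, she_bins = 16,
                           pnn_thresholds = c(40, 70)) {
  stopifnot(m_sampen >= 1, m_pe >= 2, r_frac > 0, she_bins >= 2,
            length(pnn_thresholds) == 2)
  structure(
    list(m_sampen = m_sampen, m_pe = m_pe, r_frac = r_frac, r_abs = r_abs,
         she_bins = she_bins, pnn_thresholds = pnn_thresholds),
    class = "entropy_config"
  )
}

#' Names of the 19 PRV features, in canonical order
#' @return Character vector of length 19.
#' @export
feature_names <- function() {
  c("Mean", "Std", "RMSD", "nRMSD", "PNN40", "PNN70", "Mid", "IQR",
    "LF_HF", "Sd1_Sd2", "Se", "TPR_PR", "ShE_PR", "SamE_PR", "CSampEn",
    "PE_PR", "RMSD_APM", "SamE_APM", "TPR_APM")
}

#' Time-domain PRV statistics
#'
#' Computes the nine time-domain features of a segment: `Mean` and `Std`
#' (bpm, sample standard deviation), `RMSD` — the root mean square of
#' successive PRV differences, `sqrt(sum(diff^2) / (n - 1))` —, the
#' normalized `nRMSD = RMSD / Mean`, the fractions `PNN40`/`PNN70` of
#' successive PPI differences exceeding 40/70 ms (denominator = number of
#' difference pairs), the median `Mid`, the quartile ratio `IQR = S75/S25`
#' (quartiles by linear interpolation), and `RMSD_APM`, the RMSD operator
#' applied to the pulse-amplitude series.
#'
#' @param seg A `prv_series` with at least 2 beats.
#' @param cfg An [entropy_config()] (for the PNN thresholds).
#' @return One-row tibble with the nine time-domain features.
#' @export
time_features <- function(seg, cfg = entropy_config()) {
  stopifnot(inherits(seg, "prv_series"))
  n <- nrow(seg)
  if (n < 2L) stop("at least 2 beats are required for time-domain features")
  s <- seg$prv
  m <- mean(s)
  dppi <- abs(diff(seg$ppi))
  q <- stats::quantile(s, c(0.25, 0.75), names = FALSE)
  tibble::tibble(
    Mean = m,
    Std = stats::sd(s),
    RMSD = rmsd(s),
    nRMSD = rmsd(s) / m,
    PNN40 = mean(dppi > cfg$pnn_thresholds[1]),
    PNN70 = mean(dppi > cfg$pnn_thresholds[2]),
    Mid = stats::median(s),
    IQR = if (q[1] == 0) NA_real_ else q[2] / q[1],
    RMSD_APM = rmsd(seg$apm)
  )
}

rmsd <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  sqrt(sum(diff(x)^2) / (n - 1))
}

#' LF/HF spectral power ratio of the interval series
#'
#' The PPI series is resampled evenly (default 4 Hz) by linear
#' interpolation over cumulative beat time, mean-centred, and its power
#' spectral density estimated with a Burg autoregressive model (default
#' order 16). LF is the integrated power on 0.04–0.15 Hz, HF on
#' 0.15–0.4 Hz; the ratio reflects sympathetic/parasympathetic balance.
#' Segments covering less than `min_seconds` of signal time (default 25 s,
#' one LF cycle) return `NA`, as does zero HF power.
#'
#' @param seg A `prv_series`.
#' @param resample_hz Even resampling rate, Hz.
#' @param ar_order Burg AR model order.
#' @param lf_band,hf_band Integration bands, Hz.
#' @param min_seconds Minimum segment coverage in seconds.
#' @return LF/HF ratio (unitless) or `NA`.
#' @export
lf_hf <- function(seg, resample_hz = 4, ar_order = 16,
                  lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4),
                  min_seconds = 25) {
  stopifnot(inherits(seg, "prv_series"))
  t <- cumsum(seg$ppi) / 1000
  if (t[length(t)] < min_seconds) return(NA_real_)
  grid <- seq(t[1], t[length(t)], by = 1 / resample_hz)
  x <- stats::spline(t, seg$ppi, xout = grid)$y
  x <- x - mean(x)
  if (stats::sd(x) == 0) return(NA_real_)
  ord <- min(ar_order, length(x) - 2L)
  fit <- stats::ar.burg(x, aic = FALSE, order.max = ord, demean = FALSE)
  # parametric AR PSD on a fine grid up to Nyquist
  freq <- seq(0, resample_hz / 2, length.out = 1024L)
  ar_psd <- function(f) {
    z <- exp(-2i * pi * outer(f / resample_hz, seq_len(fit$order)))
    denom <- abs(1 - as.vector(z %*% fit$ar))^2
    fit$var.pred / (resample_hz * denom)
  }
  psd <- ar_psd(freq)
  band_power <- function(band) {
    sel <- freq >= band[1] & freq <= band[2]
    if (sum(sel) < 2L) return(0)
    sum(diff(freq[sel]) * (psd[sel][-1] + psd[sel][-sum(sel)]) / 2)
  }
  lf <- band_power(lf_band)
  hf <- band_power(hf_band)
  if (hf <= 0) return(NA_real_)
  lf / hf
}

#' Poincare plot statistics
#'
#' Dispersion of the lag-1 return map: `Sd1 = sqrt(sum((S(i+1) - S(i))^2 / 2)
#' / (n - 1))`, `Sd2 = sqrt(sum((S(i+1) + S(i) - 2 Mean)^2 / 2) / (n - 1))`,
#' the axis ratio `Sd1_Sd2`, and the fitted ellipse area `Se = pi Sd1 Sd2`.
#' A zero `Sd2` (constant or perfectly alternating series) yields an `NA`
#' ratio.
#'
#' @param seg A `prv_series` (statistics computed on the `prv` column) or a
#'   plain numeric vector.
#' @return One-row tibble with `Sd1`, `Sd2`, `Sd1_Sd2`, `Se`.
#' @export
poincare <- function(seg) {
  x <- if (inherits(seg, "prv_series")) seg$prv else as.numeric(seg)
  n <- length(x)
  if (n < 2L) stop("at least 2 values are required for Poincare statistics")
  m <- mean(x)
  sd1 <- sqrt(sum((x[-1] - x[-n])^2 / 2) / (n - 1))
  sd2 <- sqrt(sum((x[-1] + x[-n] - 2 * m)^2 / 2) / (n - 1))
  tibble::tibble(
    Sd1 = sd1, Sd2 = sd2,
    Sd1_Sd2 = if (sd2 == 0) NA_real_ else sd1 / sd2,
    Se = pi * sd1 * sd2
  )
}

#' Turning point ratio
#'
#' The fraction of samples that are strict local extrema:
#' `count((S(i) - S(i-1)) (S(i) - S(i+1)) > 0) / n`. For a long i.i.d.
#' continuous series the expected count is `2 (n - 2) / 3`.
#'
#' @param x Numeric vector with at least 3 values.
#' @return Fraction in `[0, 1)`.
#' @export
turning_point_ratio <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("at least 3 values are required for the turning point ratio")
  i <- 2:(n - 1)
  sum((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > 0) / n
}

#' Normalized Shannon entropy of a histogram
#'
#' Values are binned into `bins` equal-width bins over `[min, max]`; the
#' entropy `-sum(p log2 p)` is normalized by `log2(bins)` so the result
#' lies in `[0, 1]`. A degenerate series (`min == max`) returns 0.
#'
#' @param x Numeric vector.
#' @param bins Number of bins (default 16).
#' @return Normalized entropy in `[0, 1]`.
#' @export
shannon_entropy <- function(x, bins = 16) {
  x <- as.numeric(x)
  stopifnot(length(x) >= 1, bins >= 2)
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  cuts <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  p <- counts[counts > 0] / length(x)
  -sum(p * log2(p)) / log2(bins)
}

#' Sample entropy
#'
#' `SampEn = -ln(B^{m+1}(r) / B^m(r))` where `B^m(r)` counts template pairs
#' of length `m` within Chebyshev distance `r`, self-matches excluded. A
#' zero match count at either length returns `NA`.
#'
#' @param x Numeric vector of length at least `m + 2`.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance, absolute units (typically `0.25 * sd(x)`).
#' @return Entropy in nats, 0 for a constant series, or `NA`.
#' @export
sample_entropy <- function(x, m = 2, r) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(m >= 1, n >= m + 2)
  if (!is.finite(r) || r <= 0) return(NA_real_)
  nt <- n - m # both template lengths use the same n - m start positions
  count_pairs <- function(mm) {
    cheb <- matrix(0, nt, nt)
    for (k in 0:(mm - 1)) {
      seg <- x[(1 + k):(nt + k)]
      cheb <- pmax(cheb, abs(outer(seg, seg, "-")))
    }
    (sum(cheb <= r) - nt) / 2
  }
  b <- count_pairs(m)
  a <- count_pairs(m + 1)
  if (b == 0 || a == 0) {
    if (b > 0 && a == 0) return(NA_real_)
    return(NA_real_)
  }
  -log(a / b)
}

#' Tolerance-corrected sample entropy
#'
#' `CSampEn = SampEn + ln(2 r) - ln(mean(x))`, which removes the dependence
#' of sample entropy on the tolerance and the series scale. Sentinels from
#' [sample_entropy()] propagate.
#'
#' @inheritParams sample_entropy
#' @return Corrected entropy in nats, or `NA`.
#' @export
csampen <- function(x, m = 2, r) {
  se <- sample_entropy(x, m, r)
  mu <- mean(x)
  if (is.na(se) || !is.finite(r) || r <= 0 || mu <= 0) return(NA_real_)
  se + log(2 * r) - log(mu)
}

#' Permutation entropy
#'
#' Shannon entropy (natural log) of the ordinal-pattern distribution over
#' sliding windows of length `m`; ties are broken by index order. A strictly
#' monotone series has a single pattern and entropy 0; a long i.i.d.
#' continuous series approaches `ln(m!)`.
#'
#' @param x Numeric vector with `length(x) > m`.
#' @param m Pattern order (default 5).
#' @return Entropy in nats.
#' @export
permutation_entropy <- function(x, m = 5) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(m >= 2)
  if (n <= m) stop("series must be longer than the pattern order `m`")
  patterns <- vapply(seq_len(n - m + 1L), function(i) {
    paste(order(x[i:(i + m - 1L)], method = "radix"), collapse = ".")
  }, character(1))
  p <- table(patterns) / length(patterns)
  -sum(p * log(p))
}

#' Extract the full 19-feature vector of a segment
#'
#' Computes, in canonical order: the nine time-domain statistics, the LF/HF
#' autoregressive spectral ratio, the Poincare ratio `Sd1_Sd2` and ellipse
#' area `Se`, the turning point ratio, normalized Shannon entropy, sample
#' entropy and its tolerance-corrected variant, permutation entropy (all on
#' the rate series), and the amplitude-series variants `RMSD_APM`,
#' `SamE_APM`, `TPR_APM`. Degenerate features yield `NA` sentinels (never
#' silent NaN); downstream learning imputes them with training-set medians.
#'
#' @param seg A `prv_series` segment (>= 8 beats recommended).
#' @param cfg An [entropy_config()].
#' @param ... Passed on to [lf_hf()].
#' @return A one-row tibble with 19 feature columns, in [feature_names()]
#'   order.
#' @export
extract_all <- function(seg, cfg = entropy_config(), ...) {
  stopifnot(inherits(seg, "prv_series"))
  td <- time_features(seg, cfg)
  pc <- poincare(seg)
  r_pr <- cfg$r_abs %||% (cfg$r_frac * stats::sd(seg$prv))
  r_apm <- cfg$r_abs %||% (cfg$r_frac * stats::sd(seg$apm))
  out <- tibble::tibble(
    Mean = td$Mean, Std = td$Std, RMSD = td$RMSD, nRMSD = td$nRMSD,
    PNN40 = td$PNN40, PNN70 = td$PNN70, Mid = td$Mid, IQR = td$IQR,
    LF_HF = lf_hf(seg, ...),
    Sd1_Sd2 = pc$Sd1_Sd2, Se = pc$Se,
    TPR_PR = turning_point_ratio(seg$prv),
    ShE_PR = shannon_entropy(seg$prv, cfg$she_bins),
    SamE_PR = sampen_or_zero(seg$prv, cfg$m_sampen, r_pr),
    CSampEn = csampen(seg$prv, cfg$m_sampen, r_pr),
    PE_PR = permutation_entropy(seg$prv, cfg$m_pe),
    RMSD_APM = td$RMSD_APM,
    SamE_APM = sampen_or_zero(seg$apm, cfg$m_sampen, r_apm),
    TPR_APM = turning_point_ratio(seg$apm)
  )
  out[feature_names()]
}

# constant series: all templates match at both lengths -> entropy 0
sampen_or_zero <- function(x, m, r) {
  if (stats::sd(x) == 0) return(0)
  sample_entropy(x, m, r)
}

#' Feature matrix of a segmented record set
#'
#' Maps [extract_all()] over the `series` list-column produced by
#' [segment_prv()] (or by [make_dataset()]'s internals), returning one row
#' per segment with the 19 features plus label and provenance.
#'
#' @param segments A tibble with a `series` list-column of `prv_series`.
#' @param cfg An [entropy_config()].
#' @param ... Passed on to [lf_hf()].
#' @return A tibble: `source`, `start_beat`, `label`, then 19 feature
#'   columns.
#' @export
extract_features <- function(segments, cfg = entropy_config(), ...) {
  stopifnot(is.data.frame(segments), "series" %in% names(segments))
  feats <- purrr::map(segments$series, extract_all, cfg = cfg, ...)
  dplyr::bind_cols(
    segments[setdiff(names(segments), "series")],
    dplyr::bind_rows(feats)
  )
}
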