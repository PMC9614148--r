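seg_from <- function(prv = NULL, ppi = NULL, apm = NULL) {
  if (is.null(ppi)) ppi <- 60000 / prv
  if (is.null(prv)) prv <- 60000 / ppi
  if (is.null(apm)) apm <- rep(1, length(ppi))
  prvdetect:::new_prv_series(prv = prv, ppi = ppi, apm = apm)
}

test_that("time-domain features match hand computations", {
  s <- seg_from(prv = c(60, 60, 60))
  td <- time_features(s)
  expect_equal(td$Mean, 60)
  expect_equal(td$Std, 0)
  expect_equal(td$RMSD, 0)
  expect_equal(td$nRMSD, 0)
  expect_equal(td$Mid, 60)

  s2 <- seg_from(prv = c(1, 2, 3, 4, 5))
  td2 <- time_features(s2)
  expect_equal(td2$Mean, 3)
  expect_equal(td2$Std, sqrt(2.5))
  expect_equal(td2$RMSD, 1) # sqrt(4 * 1 / 4)
  expect_equal(td2$Mid, 3)

  # successive PPI differences {50, 10, 90}: 2 of 3 exceed 40, 1 of 3 exceeds 70
  s3 <- seg_from(ppi = c(800, 850, 860, 950))
  td3 <- time_features(s3)
  expect_equal(td3$PNN40, 2 / 3)
  expect_equal(td3$PNN70, 1 / 3)

  expect_error(time_features(seg_from(prv = 60)), "2 beats")
})

test_that("IQR is the quartile ratio and RMSD_APM acts on amplitudes", {
  s <- seg_from(prv = c(50, 60, 70, 80), apm = c(10, 12, 9, 14))
  td <- time_features(s)
  q <- stats::quantile(c(50, 60, 70, 80), c(0.25, 0.75), names = FALSE)
  expect_equal(td$IQR, q[2] / q[1])
  expect_equal(td$RMSD_APM, sqrt(sum(diff(c(10, 12, 9, 14))^2) / 3))
})

test_that("Poincare statistics: degenerate, alternating and oracle cases", {
  const <- poincare(seg_from(prv = rep(70, 10)))
  expect_equal(const$Sd1, 0)
  expect_equal(const$Sd2, 0)
  expect_equal(const$Se, 0)
  expect_true(is.na(const$Sd1_Sd2))

  alt <- poincare(rep(c(4, 10), 8))
  expect_equal(alt$Sd2, 0)
  expect_equal(alt$Sd1, 6 / sqrt(2) * sqrt(15 / 15))
  set.seed(3)
  for (i in 1:50) {
    x <- rnorm(sample(8:30, 1), 80, 10)
    o <- oracle_poincare(x)
    got <- poincare(x)
    expect_equal(got$Sd1, o$Sd1, tolerance = 1e-12)
    expect_equal(got$Sd2, o$Sd2, tolerance = 1e-12)
    expect_equal(got$Se, pi * o$Sd1 * o$Sd2, tolerance = 1e-12)
  }
})

test_that("turning point ratio matches enumeration and the iid expectation", {
  expect_equal(turning_point_ratio(1:10), 0)
  expect_equal(turning_point_ratio(c(1, 3, 2, 4, 3)), 3 / 5)
  expect_error(turning_point_ratio(c(1, 2)), "3 values")
  set.seed(11)
  for (i in 1:50) {
    x <- runif(sample(8:30, 1))
    expect_equal(turning_point_ratio(x), oracle_tpr(x))
  }
  # E[turning points] = 2(n-2)/3 for iid continuous series
  n <- 20000
  x <- runif(n)
  expect_equal(turning_point_ratio(x) * n / (n - 2), 2 / 3, tolerance = 0.02)
})

test_that("Shannon entropy is normalized, zero when degenerate, oracle-exact", {
  expect_equal(shannon_entropy(rep(5, 20)), 0)
  # exactly uniform occupancy over all 4 bins
  expect_equal(shannon_entropy(c(0.5, 1.5, 2.5, 3.5), bins = 4), 1)
  # hand-built histogram {1/2, 1/4, 1/4}: entropy 1.5 bits over log2(4)
  expect_equal(shannon_entropy(c(0.1, 0.2, 1.1, 3.9), bins = 4), 1.5 / 2)
  set.seed(4)
  for (i in 1:50) {
    x <- rnorm(sample(8:40, 1))
    expect_equal(shannon_entropy(x, 16), oracle_shannon_entropy(x, 16),
                 tolerance = 1e-12)
  }
})

test_that("sample entropy equals the brute-force pair count exactly", {
  expect_equal(sample_entropy(rep(3, 10), m = 2, r = 0.1), 0)
  set.seed(5)
  for (i in 1:60) {
    x <- rnorm(sample(8:30, 1))
    r <- 0.25 * sd(x)
    expect_equal(sample_entropy(x, 2, r), oracle_sampen(x, 2, r),
                 tolerance = 1e-12)
  }
  # a periodic series is more regular than its shuffles
  x <- rep(c(1, 2, 3, 4), 8)
  se_x <- sample_entropy(x, 2, 0.2 * sd(x))
  set.seed(6)
  shuf <- replicate(20, sample_entropy(sample(x), 2, 0.2 * sd(x)))
  expect_lt(se_x, stats::median(shuf, na.rm = TRUE))
})

test_that("csampen is the documented arithmetic correction of sampen", {
  set.seed(7)
  x <- rnorm(20, 800, 40)
  r <- 0.25 * sd(x)
  expect_equal(csampen(x, 2, r),
               oracle_sampen(x, 2, r) + log(2 * r) - log(mean(x)),
               tolerance = 1e-12)
  expect_true(is.na(csampen(rep(800, 20), 2, 0))) # degenerate tolerance
})

test_that("permutation entropy: monotone, iid limit, brute-force equality", {
  expect_equal(permutation_entropy(1:20, m = 3), 0)
  set.seed(8)
  x <- runif(20000)
  expect_equal(permutation_entropy(x, 3), log(6), tolerance = 0.01)
  for (i in 1:50) {
    y <- rnorm(sample(8:30, 1))
    expect_equal(permutation_entropy(y, 3), oracle_permutation_entropy(y, 3),
                 tolerance = 1e-12)
  }
  expect_error(permutation_entropy(1:4, m = 5), "longer")
})

test_that("LF/HF separates low- and high-frequency interval modulation", {
  t <- seq(0, 60, by = 0.8)
  lf_seg <- seg_from(ppi = 800 + 50 * sin(2 * pi * 0.1 * t))
  hf_seg <- seg_from(ppi = 800 + 50 * sin(2 * pi * 0.3 * t))
  expect_gt(lf_hf(lf_seg), 5)
  expect_lt(lf_hf(hf_seg), 0.2)
  # equal-amplitude mixture lands near 1
  mix <- seg_from(ppi = 800 + 25 * sin(2 * pi * 0.1 * t) +
                    25 * sin(2 * pi * 0.3 * t))
  expect_equal(lf_hf(mix), 1, tolerance = 0.2)
  # too-short segment yields the missing-value sentinel
  expect_true(is.na(lf_hf(seg_from(ppi = rep(800, 16)))))
})

test_that("extract_all returns the 19 named features in canonical order", {
  set.seed(9)
  # a smoothly modulated rhythm, as beat-to-beat series are in practice
  ppi <- 800 + 25 * sin(2 * pi * (1:16) / 8) + rnorm(16, 0, 4)
  s <- seg_from(ppi = ppi, apm = 40 + 2 * sin(2 * pi * (1:16) / 6))
  v <- extract_all(s)
  expect_equal(names(v), feature_names())
  expect_equal(ncol(v), 19)
  expect_true(is.na(v$LF_HF)) # 16 beats at 75 bpm < 25 s
  expect_false(anyNA(v[setdiff(feature_names(), "LF_HF")]))
  # determinism
  expect_identical(extract_all(s), v)
})

test_that("features obey the expected scaling and shift laws", {
  set.seed(10)
  ppi <- rnorm(24, 800, 40)
  s <- seg_from(ppi = ppi, apm = rnorm(24, 40, 2))
  v <- extract_all(s)
  # positive scaling of the rate series: linear statistics scale,
  # dimensionless statistics are invariant
  s2 <- prvdetect:::new_prv_series(prv = 2 * s$prv, ppi = s$ppi / 2, apm = s$apm)
  v2 <- extract_all(s2)
  expect_equal(v2$Mean, 2 * v$Mean)
  expect_equal(v2$Std, 2 * v$Std)
  expect_equal(v2$RMSD, 2 * v$RMSD)
  expect_equal(v2$Mid, 2 * v$Mid)
  expect_equal(v2$nRMSD, v$nRMSD)
  expect_equal(v2$IQR, v$IQR)
  expect_equal(v2$Sd1_Sd2, v$Sd1_Sd2)
  expect_equal(v2$TPR_PR, v$TPR_PR)
  expect_equal(v2$PE_PR, v$PE_PR)
  expect_equal(v2$ShE_PR, v$ShE_PR)
  # additive shift: Mean shifts, dispersion statistics unchanged
  s3 <- prvdetect:::new_prv_series(prv = s$prv + 10, ppi = s$ppi, apm = s$apm)
  v3 <- extract_all(s3)
  expect_equal(v3$Mean, v$Mean + 10)
  expect_equal(v3$RMSD, v$RMSD)
  expect_equal(poincare(s3$prv)$Sd1, poincare(s$prv)$Sd1)
})

test_that("rate means separate extreme tachycardia from extreme bradycardia", {
  et <- gen_ppi(rhythm_spec("ET"), 40, seed = 12)
  eb <- gen_ppi(rhythm_spec("EB"), 40, seed = 13)
  v_et <- extract_all(seg_from(ppi = et$ppi[et$in_episode][1:17]))
  v_eb <- extract_all(seg_from(ppi = eb$ppi[eb$in_episode][1:8]))
  expect_gt(v_et$Mean, 140 * 0.9)
  expect_lt(v_eb$Mean, 40 * 1.1)
})
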