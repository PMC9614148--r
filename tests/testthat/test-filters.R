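test_that("notch design reproduces the published integers and rejects bad input", {
  s <- design_notch(250, 50, N = 2, Q = 64)
  expect_equal(s$P, 5L)
  expect_equal(s$R, 320L)
  expect_equal(s$delay, 315L)
  # exact published numerator integers at their lags
  nz <- which(s$b_int != 0)
  expect_equal(nz - 1L, c(0L, 315L, 320L, 325L, 640L))
  expect_equal(s$b_int[nz], c(-1, 4096, -8190, 4096, -1))
  expect_equal(s$scale, 4096)

  s2 <- design_notch(250, 125, N = 1, Q = 2)
  expect_equal(s2$P, 2L)
  expect_equal(s2$R, 4L)

  expect_error(design_notch(250, 60), "divisible")
  expect_error(design_notch(250, 50, Q = 48), "power of two")
})

test_that("lowpass design gives C = fs/f2 and rejects non-integer C", {
  s <- design_lowpass(250, 62.5, N = 2)
  expect_equal(s$C, 4L)
  expect_equal(s$delay, 3)
  expect_equal(design_lowpass(250, 125, N = 1)$C, 2L)
  expect_error(design_lowpass(250, 60), "integer")
})

test_that("difference equation equals transfer-function filtering", {
  notch <- design_notch(250, 50)
  lp <- design_lowpass(250, 62.5)
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(1500)
    rec <- abp_record(x, fs = 250)
    expect_lt(
      max(abs(apply_notch(rec, notch)$pressure - oracle_iir(notch$b, notch$a, x))),
      1e-9 * max(abs(x))
    )
    expect_lt(
      max(abs(apply_lowpass(rec, lp)$pressure - oracle_iir(lp$b, lp$a, x))),
      1e-9 * max(abs(x))
    )
  }
  # a non-default design exercises the general strand decomposition
  n3 <- design_notch(200, 50, N = 3, Q = 8)
  l3 <- design_lowpass(200, 25, N = 3)
  x <- rnorm(800)
  rec <- abp_record(x, fs = 200)
  expect_lt(max(abs(apply_notch(rec, n3)$pressure - oracle_iir(n3$b, n3$a, x))), 1e-8)
  expect_lt(max(abs(apply_lowpass(rec, l3)$pressure - oracle_iir(l3$b, l3$a, x))), 1e-8)
})

test_that("filters are linear and reject mismatched sampling rates", {
  notch <- design_notch(250, 50)
  set.seed(7)
  x <- rnorm(1200)
  y <- rnorm(1200)
  lhs <- apply_notch(abp_record(2 * x + 3 * y, 250), notch)$pressure
  rhs <- 2 * apply_notch(abp_record(x, 250), notch)$pressure +
    3 * apply_notch(abp_record(y, 250), notch)$pressure
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  expect_error(apply_notch(abp_record(x, 500), notch), "fs")
})

test_that("notch suppresses DC and the mains frequency in steady state", {
  notch <- design_notch(250, 50)
  n <- 2000
  dc <- apply_notch(abp_record(rep(5, n), 250), notch)$pressure
  expect_lt(max(abs(dc[1500:n])), 1e-9)
  t <- (0:(n - 1)) / 250
  ac <- apply_notch(abp_record(sin(2 * pi * 50 * t), 250), notch)$pressure
  expect_lt(max(abs(ac[1500:n])), 1e-9)
})

test_that("lowpass passes DC and kills the stop-band frequency", {
  lp <- design_lowpass(250, 62.5)
  n <- 500
  dc <- apply_lowpass(abp_record(rep(3, n), 250), lp)$pressure
  expect_equal(dc[n], 3, tolerance = 1e-12)
  t <- (0:(n - 1)) / 250
  sb <- apply_lowpass(abp_record(sin(2 * pi * 62.5 * t), 250), lp)$pressure
  expect_lt(max(abs(sb[100:n])), 1e-9)
})

test_that("impulse response equals the transfer-function expansion", {
  notch <- design_notch(250, 50)
  x <- c(1, rep(0, 699))
  h <- apply_notch(abp_record(x, 250), notch)$pressure
  expect_equal(h, oracle_iir(notch$b, notch$a, x), tolerance = 1e-12)
})

test_that("analytic responses match polynomial evaluation on the unit circle", {
  notch <- design_notch(250, 50)
  lp <- design_lowpass(250, 62.5)
  f <- c(3, 12.3, 25, 30, 47, 60, 88, 110, 124)
  expect_equal(notch_response(notch, f),
               oracle_response(notch$b, notch$a, f, 250), tolerance = 1e-9)
  expect_equal(lowpass_response(lp, f),
               oracle_response(lp$b, lp$a, f, 250), tolerance = 1e-9)
  expect_error(notch_response(notch, 130), "Nyquist")
  expect_error(lowpass_response(lp, -1), "Nyquist")
})

test_that("notch magnitude is zero exactly at harmonics of f1 including 0 Hz", {
  notch <- design_notch(250, 50)
  expect_equal(abs(notch_response(notch, c(0, 50, 100))), rep(0, 3))
  # and passes mid-band frequencies essentially unchanged
  expect_gt(abs(notch_response(notch, 25)), 0.99)
})

test_that("lowpass magnitude is 1 at DC, 0 at f2, bounded and monotone below f2", {
  lp <- design_lowpass(250, 62.5)
  expect_equal(abs(lowpass_response(lp, 0)), 1)
  expect_equal(abs(lowpass_response(lp, 62.5)), 0)
  f <- seq(0, 125, by = 0.5)
  mag <- abs(lowpass_response(lp, f))
  expect_true(all(mag <= 1 + 1e-12))
  below <- mag[f <= 62.5]
  expect_true(all(diff(below) <= 1e-12))
})

test_that("both responses have linear phase in the passband", {
  notch <- design_notch(250, 50)
  lp <- design_lowpass(250, 62.5)
  f <- seq(10, 20, by = 0.25) # well inside the passband, away from zeros
  ph_n <- unwrap_phase(Arg(notch_response(notch, f)))
  ph_l <- unwrap_phase(Arg(lowpass_response(lp, f)))
  expect_lt(diff(range(diff(ph_n))), 1e-6)
  expect_lt(diff(range(diff(ph_l))), 1e-6)
})

test_that("preprocess removes the three noise classes and aligns beats", {
  g <- gen_ppi(rhythm_spec("healthy"), 40, seed = 3)
  clean <- render_abp(g)
  noisy <- add_noise(clean, noise_spec(), seed = 4)
  fc <- preprocess(clean)
  fn <- preprocess(noisy)
  tr <- attr(fn, "transient")
  sel <- (tr + 1):(nrow(fn) - 400)
  pulse_amp <- mean(g$amplitude)
  # noise residual: filtered noisy vs filtered clean
  expect_lt(sqrt(mean((fn$pressure[sel] - fc$pressure[sel])^2)), 0.02 * pulse_amp)
  # passband fidelity: filtered clean vs clean with its slow component
  # removed (the 0 Hz notch also removes the sub-1 Hz envelope, so the fair
  # reference is the running-mean-detrended pulse train)
  w <- 401 # ~1.6 s, matching the width of the DC notch
  slow <- stats::filter(clean$pressure, rep(1 / w, w), sides = 2)
  ref <- clean$pressure - slow
  ok <- sel[!is.na(slow[sel])]
  expect_lt(sqrt(mean((fc$pressure[ok] - ref[ok])^2)), 0.05 * pulse_amp)
  expect_gt(stats::cor(fc$pressure[ok], ref[ok]), 0.99)
  # delay compensation keeps annotated peaks on local maxima of the output
  ann <- abp_annotations(clean)
  ann <- ann[ann > tr & ann < nrow(fn) - 400]
  for (a in ann[1:5]) {
    w <- fn$pressure[(a - 10):(a + 10)]
    expect_lt(abs(which.max(w) - 11), 3)
  }
})

test_that("preprocess maps zero to zero and warns on too-short records", {
  z <- preprocess(abp_record(rep(0, 1500), 250))
  expect_equal(max(abs(z$pressure)), 0)
  expect_warning(preprocess(abp_record(rnorm(300), 250)), "transient")
})
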