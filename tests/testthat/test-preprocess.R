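make_raw <- function(I1, fs = 8.7) {
  n <- length(I1)
  raw_recording(array(rep(I1, 2 * 21), dim = c(n, 21, 2)), fs)
}

test_that("optical density conversion matches the closed form", {
  # constant intensity -> OD identically 0
  od <- intensity_to_od(make_raw(rep(2, 100)))
  expect_equal(max(abs(od$od)), 0)
  # a sample at exactly half the mean -> OD = ln 2 there
  I <- rep(1, 100)
  I[50] <- 99 / 199  # solves I[50] = mean(I) / 2
  od <- intensity_to_od(make_raw(I))
  expect_equal(od$od[50, 1, 1], log(2), tolerance = 1e-12)
  # arbitrary 10-sample vector vs per-sample -ln(I/mean) oracle
  set.seed(1)
  I <- runif(10, 0.5, 2)
  od <- intensity_to_od(make_raw(I))
  expect_equal(od$od[, 1, 1], -log(I / mean(I)), tolerance = 1e-12)
})

test_that("non-positive intensity raises an error naming the channel", {
  I <- array(1, dim = c(20, 21, 2))
  rec <- raw_recording(I)
  rec$intensities[5, 7, 1] <- -1
  expect_error(intensity_to_od(rec), "7")
})

test_that("low-pass passes DC and low tones, rejects high tones", {
  fs <- 10
  t <- (0:2999) / fs
  dc <- vec_as_od(rep(1.5, length(t)), fs)
  expect_lt(max(abs(od_lowpass(dc, 3)$od - 1.5)), 1e-9)
  hi <- sin(2 * pi * 4 * t)
  out <- od_lowpass(vec_as_od(hi, fs), 3)$od[, 1, 1]
  expect_lt(rms(out), 0.1 * rms(hi))
  lo <- sin(2 * pi * 0.1 * t)
  out <- od_lowpass(vec_as_od(lo, fs), 3)$od[, 1, 1]
  expect_lt(abs(rms(out) - rms(lo)) / rms(lo), 0.05)
  expect_error(od_lowpass(dc, 6), "Nyquist")
})

test_that("band-pass rejects drift and cardiac tones, passes the Mayer band", {
  fs <- 8.7
  t <- (0:4999) / fs
  drift <- 0.01 * t
  out <- od_bandpass(vec_as_od(drift, fs))$od[, 1, 1]
  expect_lt(rms(out), 0.05 * rms(drift))
  mayer <- sin(2 * pi * 0.1 * t)
  out <- od_bandpass(vec_as_od(mayer, fs))$od[, 1, 1]
  expect_lt(abs(rms(out) - rms(mayer)) / rms(mayer), 0.1)
  cardiac <- sin(2 * pi * 1.1 * t)
  out <- od_bandpass(vec_as_od(cardiac, fs))$od[, 1, 1]
  expect_lt(rms(out), 0.1 * rms(cardiac))
  expect_error(od_bandpass(vec_as_od(drift, fs), low = 0.5, high = 0.016),
               "low < high")
})

test_that("motion correction leaves clean signals untouched", {
  fs <- 8.7
  t <- (0:999) / fs
  smooth <- vec_as_od(sin(2 * pi * 0.05 * t), fs)
  out <- correct_motion_spline(smooth)
  expect_equal(out$od, smooth$od)
  expect_equal(nrow(attr(out, "artifacts")), 0L)
  zeros <- vec_as_od(rep(0, 500), fs)
  expect_equal(correct_motion_spline(zeros)$od, zeros$od)
})

test_that("motion correction halves the variance of an injected 10-sigma step", {
  fs <- 8.7
  t <- (0:999) / fs
  set.seed(42)
  base <- sin(2 * pi * 0.05 * t) + rnorm(length(t), sd = 0.1)
  x <- base
  x[500:length(x)] <- x[500:length(x)] + 10 * sd(base)
  out <- correct_motion_spline(vec_as_od(x, fs))
  corrected <- out$od[, 1, 1]
  expect_gt(nrow(attr(out, "artifacts")), 0L)
  expect_lt(var(corrected), 0.5 * var(x))
})

test_that("Beer-Lambert inversion: zeros, identity system, and round trip", {
  fs <- 8.7
  zero_od <- structure(list(od = array(0, dim = c(50, 21, 2)), sampling_rate = fs),
                       class = "od_series")
  h <- od_to_hemoglobin(zero_od)
  expect_true(all(h$hbo == 0) && all(h$hbr == 0) && all(h$hbt == 0))

  # identity extinction with unit pathlength: concentrations equal OD
  ident <- beer_lambert_params(extinction = diag(2), dpf = c(1, 1), distance = 1)
  set.seed(2)
  od <- structure(list(od = array(rnorm(50 * 21 * 2), dim = c(50, 21, 2)),
                       sampling_rate = fs), class = "od_series")
  h <- od_to_hemoglobin(od, ident)
  expect_equal(h$hbo, od$od[, , 1], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(h$hbr, od$od[, , 2], tolerance = 1e-12, ignore_attr = TRUE)

  # random concentrations forward-projected then inverted: relative error < 1e-8
  bl <- beer_lambert_params()
  set.seed(3)
  hbo <- matrix(rnorm(50 * 21, sd = 1e-3), 50, 21)
  hbr <- matrix(rnorm(50 * 21, sd = 1e-3), 50, 21)
  E <- bl$extinction
  path <- bl$distance * bl$dpf
  fwd <- array(0, dim = c(50, 21, 2))
  for (w in 1:2) fwd[, , w] <- (E[w, 1] * hbo + E[w, 2] * hbr) * path[w]
  rec <- od_to_hemoglobin(structure(list(od = fwd, sampling_rate = fs),
                                    class = "od_series"), bl)
  expect_lt(sqrt(sum((rec$hbo - hbo)^2)) / sqrt(sum(hbo^2)), 1e-8)
  expect_lt(sqrt(sum((rec$hbr - hbr)^2)) / sqrt(sum(hbr^2)), 1e-8)
})

test_that("HbT equals HbO + HbR to within 1e-9 everywhere", {
  sess <- clean_session()
  hemo <- preprocess(sess$recording)
  expect_lt(max(abs(hemo$hbt - (hemo$hbo + hemo$hbr))), 1e-9)
})

test_that("full chain recovers the band-passed ground truth on a clean session", {
  sess <- clean_session()
  hemo <- preprocess(sess$recording)
  gt <- bandpass_matrix(sess$truth$hbo)
  cors <- vapply(1:21, function(ch) cor(hemo$hbo[, ch], gt[, ch]), 0)
  expect_true(all(cors > 0.95))
  rel <- sqrt(sum((hemo$hbo - gt)^2)) / sqrt(sum(gt^2))
  expect_lt(rel, 0.05)
})

test_that("preprocessing is deterministic and shape-preserving", {
  sess <- clean_session()
  a <- preprocess(sess$recording)
  b <- preprocess(sess$recording)
  expect_identical(a$hbo, b$hbo)
  expect_equal(dim(a$hbo), dim(sess$recording$intensities)[1:2])
})

test_that("the stage order is a fixed contract", {
  sess <- clean_session()
  expect_error(preprocess(sess$recording, stages = rev(preprocess_stages())),
               "fixed")
})

test_that("the filter-only sub-chain is linear in its input", {
  fs <- 8.7
  set.seed(9)
  x <- cumsum(rnorm(800, sd = 0.01)) + sin(2 * pi * 0.07 * (0:799) / fs)
  chain <- function(v) {
    od <- od_bandpass(od_lowpass(vec_as_od(v, fs), 3))
    od$od[, 1, 1]
  }
  expect_equal(chain(3.7 * x), 3.7 * chain(x), tolerance = 1e-8)
})
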