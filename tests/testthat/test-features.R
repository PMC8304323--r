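test_that("min-max scaling maps each channel/signal series to [0, 1]", {
  h <- hemo_series(cbind(c(2, 4, 6)), cbind(c(-1, 0, 1)), 8.7)
  s <- scale_participant(h)
  expect_equal(s$hbo[, 1], c(0, 0.5, 1))
  expect_equal(s$hbr[, 1], c(0, 0.5, 1))
  # constant series maps to zero with a warning
  hc <- hemo_series(cbind(rep(3, 5)), cbind(rep(0, 5)), 8.7)
  w <- capture_warnings(sc <- scale_participant(hc))
  expect_true(any(grepl("constant", w)))
  expect_true(all(sc$hbo == 0))
  # property: min 0 / max 1 for every non-constant channel
  set.seed(8)
  h <- hemo_series(matrix(rnorm(200), 50, 4), matrix(rnorm(200), 50, 4), 8.7)
  s <- scale_participant(h)
  for (m in list(s$hbo, s$hbr, s$hbt)) {
    expect_equal(unname(apply(m, 2, min)), rep(0, 4))
    expect_equal(unname(apply(m, 2, max)), rep(1, 4))
  }
})

test_that("window counts follow the floor arithmetic", {
  fs <- 8.7
  mk_hemo <- function(dur) {
    n <- ceiling(dur * fs) + 5
    hemo_series(matrix(rnorm(n * 21), n, 21), matrix(rnorm(n * 21), n, 21), fs)
  }
  sch60 <- trial_schedule(data.frame(segment = "evaluation",
                                     start = c(0, 70), end = c(60, 130),
                                     condition = c("S", "N"), outcome = "n/a"))
  wins <- make_windows(mk_hemo(135), sch60)
  # 522-sample trial, 130-sample window, 65-sample step -> 7 windows each
  expect_equal(sum(vapply(wins, `[[`, 0, "trial") == 1), 7L)
  expect_equal(length(wins), 14L)
  expect_equal(nrow(wins[[1]]$hbo), floor(15 * fs))

  sch15 <- trial_schedule(data.frame(segment = "evaluation",
                                     start = c(0, 20), end = c(15, 35),
                                     condition = c("S", "N"), outcome = "n/a"))
  wins <- make_windows(mk_hemo(40), sch15)
  expect_equal(length(wins), 2L)  # exactly one window per 15 s trial

  sch14 <- trial_schedule(data.frame(segment = "evaluation",
                                     start = c(0, 20), end = c(14, 34),
                                     condition = c("S", "N"), outcome = "n/a"))
  expect_error(make_windows(mk_hemo(40), sch14), "shorter than one")
})

test_that("temporal statistics match their closed forms on symmetric data", {
  w <- toy_window(c(1, 2, 3))
  f <- temporal_features(w)
  expect_equal(unname(f["ch01_hbo_mean"]), 2)
  expect_equal(unname(f["ch01_hbo_var"]), 2 / 3)
  expect_equal(unname(f["ch01_hbo_max"]), 3)
  expect_equal(unname(f["ch01_hbo_min"]), 1)
  expect_equal(unname(f["ch01_hbo_skewness"]), 0)
})

test_that("kurtosis of standard normal draws is near 3 (Monte-Carlo oracle)", {
  set.seed(11)
  x <- rnorm(1e4)
  w <- toy_window(x)
  expect_lt(abs(unname(temporal_features(w)["ch01_hbo_kurtosis"]) - 3), 0.2)
})

test_that("all 441 temporal values match a naive loop implementation", {
  set.seed(12)
  fs <- 8.7
  n <- 130
  w <- list(trial = 1L, window = 1L, start_sample = 1L, end_sample = n,
            start_s = 0, end_s = n / fs,
            hbo = matrix(rnorm(n * 21), n, 21),
            hbr = matrix(rnorm(n * 21), n, 21),
            hbt = matrix(rnorm(n * 21), n, 21),
            sampling_rate = fs)
  f <- temporal_features(w)
  expect_length(f, 441L)
  md <- feature_metadata()
  md <- md[md$kind == "temporal", ]
  for (i in sample(nrow(md), 40)) {  # spot-check a broad sample of cells
    x <- w[[md$signal[i]]][, md$channel_a[i]]
    expect_equal(unname(f[md$name[i]]),
                 unname(naive_stats(x, 1 / fs)[md$statistic[i]]),
                 tolerance = 1e-10)
  }
  expect_error(temporal_features(list(hbo = matrix(1, 1, 21))), "2 samples")
})

test_that("connectivity features reproduce the Pearson formula", {
  set.seed(13)
  n <- 130
  hbo <- matrix(rnorm(n * 21), n, 21)
  hbo[, 2] <- 2 * hbo[, 1]          # perfect positive
  hbo[, 3] <- -hbo[, 1]             # perfect negative
  w <- list(hbo = hbo, sampling_rate = 8.7)
  f <- connectivity_features(w)
  expect_length(f, 210L)
  expect_equal(unname(f["ch01_ch02_corr"]), 1)
  expect_equal(unname(f["ch01_ch03_corr"]), -1)
  expect_true(all(f >= -1 & f <= 1))
  # longhand oracle on arbitrary pairs
  for (pair in list(c(4, 9), c(5, 21), c(10, 11))) {
    nm <- sprintf("ch%02d_ch%02d_corr", pair[1], pair[2])
    expect_equal(unname(f[nm]), naive_pearson(hbo[, pair[1]], hbo[, pair[2]]),
                 tolerance = 1e-12)
  }
  # zero-variance member -> r = 0 with warning
  hbo[, 4] <- 1
  expect_warning(f0 <- connectivity_features(list(hbo = hbo)), "zero-variance")
  expect_equal(unname(f0["ch01_ch04_corr"]), 0)
})

test_that("feature vector layout is 441 + 210 = 651 with deterministic names", {
  md <- feature_metadata()
  expect_equal(nrow(md), 651L)
  expect_equal(sum(md$kind == "temporal"), 441L)
  expect_equal(sum(md$kind == "connectivity"), 210L)
  expect_identical(md$name, feature_metadata()$name)
  expect_false(anyDuplicated(md$name) > 0)
})

test_that("dataset rows follow the labeling rule (schedule-walk oracle)", {
  fs <- 8.7
  build_one <- function(error_prob, seed) {
    cfg <- synthetic_config(training_error_prob = error_prob,
                            cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
                            drift_slope = 0, noise_sd = 0.001, spike_rate = 0)
    sch <- build_protocol_schedule(cfg, "stress", seed = seed)
    sim <- simulate_session(cfg, sch, seed = seed)
    hemo <- hemo_series(sim$truth$hbo, sim$truth$hbr, fs, schedule = sch)
    list(tbl = suppressWarnings(build_dataset(list(list(
           hemo = hemo, schedule = sch, participant = 1, group = "stress")))),
         sch = sch)
  }
  r0 <- build_one(0, 21)
  expect_equal(sum(r0$tbl$label == "encoding"), 3L)
  expect_equal(sum(r0$tbl$label == "retrieval"), 8L)

  # seed chosen arbitrarily; count errors from the realized schedule
  r <- build_one(0.4, 22)
  n_err <- sum(r$sch$segment == "training" & r$sch$outcome == "error")
  expect_equal(sum(r$tbl$label == "encoding"), 3L + 2L * n_err)
  expect_equal(sum(r$tbl$label == "retrieval"), 8L)
  # no unlabeled trial leaks into the table
  lab <- trial_labels(r$sch)
  expect_setequal(r$tbl$trial, r$sch$trial[!is.na(lab)])
  # shape contract
  expect_length(feature_columns(r$tbl), 651L)
  expect_false(anyNA(r$tbl))
})

test_that("feature table CSV + metadata sidecar round-trips", {
  tbl <- toy_feature_table(n_participants = 2, n_features = 5)
  attr(tbl, "metadata") <- data.frame(name = sprintf("f%03d", 1:5),
                                      kind = "temporal")
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back)$f001, as.data.frame(tbl)$f001)
  expect_equal(attr(back, "metadata")$name, sprintf("f%03d", 1:5))
})
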