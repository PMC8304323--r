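.signals <- c("hbo", "hbr", "hbt")
.stats <- c("mean", "var", "max", "min", "kurtosis", "skewness", "auc")

#' Canonical feature names and metadata
#'
#' The 651-dimensional feature vector is laid out deterministically from the
#' layout's canonical 1..21 channel order: 441 temporal features (channel
#' major, then signal HbO/HbR/HbT, then statistic mean, var, max, min,
#' kurtosis, skewness, AUC), followed by the 210 HbO pairwise Pearson
#' correlations in lexicographic pair order.
#'
#' @param layout A `probe_layout`.
#' @return Data frame with one row per feature: `name`, `kind`
#'   (temporal/connectivity), `channel_a`, `channel_b`, `signal`,
#'   `statistic`, `roi_a`, `roi_b`.
#' @export
feature_metadata <- function(layout = default_layout()) {
  rois <- roi_of(layout)
  chs <- layout$channel
  tmp <- expand.grid(statistic = .stats, signal = .signals, channel_a = chs,
                     stringsAsFactors = FALSE)
  tmp <- tmp[, c("channel_a", "signal", "statistic")]
  tmp$name <- sprintf("ch%02d_%s_%s", tmp$channel_a, tmp$signal, tmp$statistic)
  tmp$kind <- "temporal"
  tmp$channel_b <- NA_integer_
  tmp$roi_a <- rois[as.character(tmp$channel_a)]
  tmp$roi_b <- NA_character_
  prs <- channel_pairs(layout)
  con <- data.frame(
    channel_a = prs[, "a"], signal = "hbo", statistic = "corr",
    name = sprintf("ch%02d_ch%02d_corr", prs[, "a"], prs[, "b"]),
    kind = "connectivity", channel_b = prs[, "b"],
    roi_a = rois[as.character(prs[, "a"])],
    roi_b = rois[as.character(prs[, "b"])],
    stringsAsFactors = FALSE)
  out <- rbind(tmp, con)[, c("name", "kind", "channel_a", "channel_b",
                             "signal", "statistic", "roi_a", "roi_b")]
  rownames(out) <- NULL
  out
}

#' Participant-level min-max scaling
#'
#' Maps each (channel, signal) series to [0, 1] using its minimum and
#' maximum over the participant's full session, applied before windowing so
#' that features are comparable across participants. A constant
#' (zero-range) series maps to all zeros with a warning.
#'
#' @param hemo A `hemo_series` covering one participant's session.
#' @return The scaled `hemo_series` (marked with `attr(, "scaled")`;
#'   the HbT = HbO + HbR identity intentionally no longer holds after
#'   independent per-signal scaling).
#' @export
scale_participant <- function(hemo) {
  scale_mat <- function(m, what) {
    for (j in seq_len(ncol(m))) {
      rng <- range(m[, j])
      if (diff(rng) == 0) {
        warning(sprintf("constant %s series in channel %d; scaled to 0", what, j))
        m[, j] <- 0
      } else {
        m[, j] <- (m[, j] - rng[1L]) / diff(rng)
      }
    }
    m
  }
  hemo$hbo <- scale_mat(hemo$hbo, "hbo")
  hemo$hbr <- scale_mat(hemo$hbr, "hbr")
  hemo$hbt <- scale_mat(hemo$hbt, "hbt")
  attr(hemo, "scaled") <- TRUE
  hemo
}

#' Cut a session into sliding windows
#'
#' Within each trial, windows of `window_s` seconds step by `step_s` (50%
#' overlap at the defaults); sample counts are floored and the first window
#' starts exactly at trial onset. Partial trailing windows are dropped. A
#' trial shorter than one window is an error.
#'
#' @param hemo A `hemo_series`.
#' @param schedule A `trial_schedule`.
#' @param config A [pipeline_config()].
#' @return List of windows; each holds the trial id, window index, sample
#'   range, and the `hbo`/`hbr`/`hbt` sample matrices.
#' @export
make_windows <- function(hemo, schedule, config = pipeline_config()) {
  fs <- hemo$sampling_rate
  n_win <- floor(config$window_s * fs)
  step <- floor(config$step_s * fs)
  n_total <- nrow(hemo$hbo)
  out <- list()
  for (k in seq_len(nrow(schedule))) {
    i0 <- floor(schedule$start[k] * fs) + 1L
    i1 <- min(floor(schedule$end[k] * fs), n_total)
    ns <- i1 - i0 + 1L
    if (ns < n_win) {
      stop_invalid("window",
                   sprintf("trial %d (%.1f s) is shorter than one %g s window",
                           schedule$trial[k], ns / fs, config$window_s))
    }
    n_w <- floor((ns - n_win) / step) + 1L
    for (w in seq_len(n_w)) {
      a <- i0 + (w - 1L) * step
      b <- a + n_win - 1L
      out[[length(out) + 1L]] <- list(
        trial = schedule$trial[k], window = w,
        start_sample = a, end_sample = b,
        start_s = (a - 1L) / fs, end_s = b / fs,
        hbo = hemo$hbo[a:b, , drop = FALSE],
        hbr = hemo$hbr[a:b, , drop = FALSE],
        hbt = hemo$hbt[a:b, , drop = FALSE],
        sampling_rate = fs)
    }
  }
  out
}

# Biased (population) moment statistics of one vector, in canonical order.
# Kurtosis is non-excess (normal -> 3); zero-variance windows get
# kurtosis = skewness = 0 by convention.
.temporal_stats_vec <- function(x, dt) {
  n <- length(x)
  mu <- sum(x) / n
  cx <- x - mu
  m2 <- sum(cx^2) / n
  kur <- if (m2 > 0) (sum(cx^4) / n) / m2^2 else 0
  skw <- if (m2 > 0) (sum(cx^3) / n) / m2^1.5 else 0
  auc <- sum((x[-1L] + x[-n]) / 2) * dt
  c(mu, m2, max(x), min(x), kur, skw, auc)
}

#' Temporal window features
#'
#' The 441 time-domain statistics of one window: for each of the 21 channels
#' and each signal (HbO, HbR, HbT), the mean, biased variance, maximum,
#' minimum, non-excess kurtosis, skewness, and trapezoidal area under the
#' curve (dt = 1/sampling rate).
#'
#' @param window One window from [make_windows()] (needs at least 2 samples).
#' @param layout A `probe_layout` (names the outputs).
#' @return Named numeric vector of length 441.
#' @export
temporal_features <- function(window, layout = default_layout()) {
  if (nrow(window$hbo) < 2L) stop_invalid("window", "need at least 2 samples")
  dt <- 1 / window$sampling_rate
  n_ch <- ncol(window$hbo)
  vals <- numeric(n_ch * 3L * 7L)
  i <- 0L
  for (ch in seq_len(n_ch)) {
    for (sig in .signals) {
      vals[i + 1:7] <- .temporal_stats_vec(window[[sig]][, ch], dt)
      i <- i + 7L
    }
  }
  names(vals) <- as.vector(vapply(seq_len(n_ch), function(ch) {
    as.vector(vapply(.signals, function(sig) sprintf("ch%02d_%s_%s", ch, sig, .stats),
                     character(7L)))
  }, character(21L)))
  vals
}

#' HbO connectivity features
#'
#' Pairwise Pearson correlations of the window's HbO signals for all 210
#' channel pairs, in the deterministic order of [channel_pairs()]. A pair
#' involving a zero-variance series gets r = 0 with a warning.
#'
#' @param window One window from [make_windows()].
#' @param layout A `probe_layout`.
#' @return Named numeric vector of length `C(n, 2)` (210 for 21 channels).
#' @export
connectivity_features <- function(window, layout = default_layout()) {
  hbo <- window$hbo
  prs <- channel_pairs(layout)
  sds <- apply(hbo, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("zero-variance HbO in channel(s) %s; correlations set to 0",
                    paste(which(sds == 0), collapse = ", ")))
  }
  C <- suppressWarnings(stats::cor(hbo))
  C[!is.finite(C)] <- 0
  vals <- C[cbind(prs[, "a"], prs[, "b"])]
  names(vals) <- sprintf("ch%02d_ch%02d_corr", prs[, "a"], prs[, "b"])
  vals
}

#' Build the labeled feature table
#'
#' For every labeled trial (familiarization and errored training trials ->
#' encoding; evaluation trials -> retrieval; successful training trials and
#' the buffer are excluded), extracts the 651 features from the trial's
#' first 15 s window of the participant-scaled series. One row per labeled
#' trial, with `participant`, `group`, `trial`, `label` and `condition`
#' columns ahead of the features.
#'
#' @param sessions List of per-participant entries, each a list with `hemo`
#'   (a preprocessed `hemo_series`), `schedule`, `participant`, `group`
#'   (stress/control).
#' @param layout A `probe_layout`.
#' @param config A [pipeline_config()].
#' @return A `feature_table` data frame.
#' @export
build_dataset <- function(sessions, layout = default_layout(),
                          config = pipeline_config()) {
  md <- feature_metadata(layout)
  rows <- vector("list", 0L)
  for (sess in sessions) {
    hemo <- scale_participant(sess$hemo)
    labels <- trial_labels(sess$schedule)
    keep <- which(!is.na(labels))
    wins <- make_windows(hemo, sess$schedule, config)
    first_win <- Filter(function(w) w$window == 1L, wins)
    win_by_trial <- stats::setNames(first_win,
                                    vapply(first_win, `[[`, 0, "trial"))
    for (k in keep) {
      w <- win_by_trial[[as.character(sess$schedule$trial[k])]]
      feats <- c(temporal_features(w, layout), connectivity_features(w, layout))
      rows[[length(rows) + 1L]] <- data.frame(
        participant = sess$participant,
        group = sess$group,
        trial = sess$schedule$trial[k],
        label = labels[k],
        condition = sess$schedule$condition[k],
        t(feats),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  if (anyNA(tbl)) stop_invalid("feature table", "missing values in feature rows")
  structure(tbl, class = c("feature_table", "data.frame"),
            metadata = md)
}

#' Feature columns of a feature table
#'
#' @param table A `feature_table`.
#' @return Character vector of the 651 feature column names (everything
#'   after the id/label columns).
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("participant", "group", "trial", "label", "condition"))
}

#' Write a feature table to CSV plus a JSON metadata sidecar
#'
#' @param table A `feature_table`.
#' @param path Output CSV path; the column metadata (channel, signal,
#'   statistic, ROI per feature) goes to `<path>.meta.json`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  md <- attr(table, "metadata")
  if (!is.null(md)) {
    jsonlite::write_json(md, paste0(path, ".meta.json"), dataframe = "rows")
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  md <- if (file.exists(meta_path)) {
    as.data.frame(jsonlite::read_json(meta_path, simplifyVector = TRUE))
  } else {
    NULL
  }
  structure(tbl, class = c("feature_table", "data.frame"), metadata = md)
}
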