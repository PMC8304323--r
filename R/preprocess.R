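#' Convert light intensity to optical density change
#'
#' `OD(t) = -ln(I(t) / mean(I))`, the reference being each channel's and
#' wavelength's mean intensity over the full recording, so a constant series
#' maps to zero OD.
#'
#' @param raw A `raw_recording`.
#' @return An `od_series` (list with `od` time x channel x wavelength array,
#'   `sampling_rate`, and the recording's schedule).
#' @export
intensity_to_od <- function(raw) {
  I <- raw$intensities
  bad <- which(apply(I <= 0, 2L, any))
  if (length(bad)) {
    stop_invalid("intensity", paste("non-positive value in channel(s):",
                                    paste(bad, collapse = ", ")))
  }
  od <- I
  for (w in seq_len(dim(I)[3L])) {
    mu <- colMeans(I[, , w, drop = FALSE][, , 1L, drop = FALSE])
    od[, , w] <- -log(sweep(I[, , w], 2L, mu, "/"))
  }
  structure(list(od = od, sampling_rate = raw$sampling_rate,
                 schedule = raw$schedule),
            class = "od_series")
}

# Zero-phase (forward-backward) Butterworth filtering of a matrix, columnwise,
# with reflective padding to suppress edge transients.
.filtfilt_cols <- function(x, filt, pad = NULL) {
  n <- nrow(x)
  pad <- min(pad %||% 300L, n - 1L)
  apply(x, 2L, function(col) {
    ext <- c(2 * col[1L] - rev(col[2:(pad + 1L)]),
             col,
             2 * col[n] - rev(col[(n - pad):(n - 1L)]))
    y <- signal::filtfilt(filt, ext)
    y[(pad + 1L):(pad + n)]
  })
}

.map_od <- function(od, f) {
  out <- od$od
  for (w in seq_len(dim(out)[3L])) {
    out[, , w] <- f(matrix(out[, , w], nrow = dim(out)[1L]))
  }
  od$od <- out
  od
}

#' Low-pass filter an optical-density series
#'
#' 4th-order Butterworth applied forward-backward (zero phase), reflective
#' padding at the edges.
#'
#' @param od An `od_series`.
#' @param cutoff Cutoff frequency in Hz; must be below Nyquist.
#' @return Filtered `od_series`, same shape.
#' @export
od_lowpass <- function(od, cutoff = 3) {
  nyq <- od$sampling_rate / 2
  if (cutoff >= nyq) stop_invalid("filter", "low-pass cutoff must be below Nyquist")
  b <- signal::butter(4, cutoff / nyq, type = "low")
  .map_od(od, function(m) .filtfilt_cols(m, b))
}

#' Band-pass filter an optical-density series
#'
#' Removes drift and DC below `low` and physiological noise above `high`.
#' Realised as a cascade of 4th-order Butterworth low-pass (at `high`) and
#' high-pass (at `low`) stages, each applied forward-backward.
#'
#' @param od An `od_series`.
#' @param low,high Band edges in Hz, `0 < low < high <` Nyquist.
#' @return Filtered `od_series`, same shape.
#' @export
od_bandpass <- function(od, low = 0.016, high = 0.5) {
  nyq <- od$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop_invalid("filter", "require 0 < low < high < Nyquist")
  }
  bl <- signal::butter(4, high / nyq, type = "low")
  bh <- signal::butter(4, low / nyq, type = "high")
  .map_od(od, function(m) .filtfilt_cols(.filtfilt_cols(m, bl), bh))
}

# Moving standard deviation with a centered window of w samples.
.moving_sd <- function(x, w) {
  n <- length(x)
  w <- max(3L, w)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cnt <- hi - lo + 1L
  mu <- (cs[hi + 1L] - cs[lo]) / cnt
  v <- (cs2[hi + 1L] - cs2[lo]) / cnt - mu^2
  sqrt(pmax(v, 0))
}

#' Spline-based motion-artifact correction
#'
#' Detects abrupt peaks and baseline changes per channel/wavelength: the
#' moving-window (1 s) dispersion of the sample-to-sample differences must
#' exceed `k` times the channel's median moving dispersion, and the local
#' jumps must also clear an amplitude floor (a fraction of the channel's
#' robust range) so that smooth hemodynamic transitions are never flagged.
#' Flagged stretches are expanded to a minimum duration of 0.5 s, a cubic
#' smoothing spline is fit to each segment, the spline trend is subtracted,
#' and the segment plus all subsequent samples are re-leveled so the series
#' stays continuous — removing transient spikes and persistent steps alike.
#' Artifact-free input is returned unchanged.
#'
#' @param od An `od_series`.
#' @param k Detection threshold multiplier (default 3.5).
#' @param window_s Moving-dispersion window (s), default 1.
#' @param min_seg_s Minimum artifact segment duration (s), default 0.5.
#' @param amp_floor Fraction of the channel's robust (1st-99th percentile)
#'   range that a jump must exceed to count as an artifact (default 0.1).
#' @return Corrected `od_series`; detected segments are recorded in
#'   `attr(, "artifacts")` as a data frame (channel, wavelength, start, end
#'   in samples).
#' @export
correct_motion_spline <- function(od, k = 3.5, window_s = 1, min_seg_s = 0.5,
                                  amp_floor = 0.1) {
  fs <- od$sampling_rate
  w <- max(3L, round(window_s * fs))
  min_len <- max(4L, round(min_seg_s * fs))
  log <- list()
  out <- od$od
  for (wl in seq_len(dim(out)[3L])) {
    for (ch in seq_len(dim(out)[2L])) {
      x <- out[, ch, wl]
      d <- c(0, diff(x))
      msd <- .moving_sd(d, w)
      thr <- k * stats::median(msd)
      rng <- diff(stats::quantile(x, c(0.01, 0.99), names = FALSE))
      floor_abs <- amp_floor * rng
      if (thr <= 0 || !any(msd > thr & abs(d) > floor_abs)) next
      flagged <- msd > thr & abs(d) > floor_abs
      # expand each flagged run to the minimum segment length
      r <- rle(flagged)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      segs <- cbind(starts[r$values], ends[r$values])
      segs[, 1L] <- pmax(1L, segs[, 1L] - (min_len %/% 2L))
      segs[, 2L] <- pmin(length(x), segs[, 2L] + (min_len %/% 2L))
      # merge overlapping segments
      if (nrow(segs) > 1L) {
        merged <- segs[1L, , drop = FALSE]
        for (i in 2:nrow(segs)) {
          if (segs[i, 1L] <= merged[nrow(merged), 2L] + 1L) {
            merged[nrow(merged), 2L] <- max(merged[nrow(merged), 2L], segs[i, 2L])
          } else {
            merged <- rbind(merged, segs[i, , drop = FALSE])
          }
        }
        segs <- merged
      }
      for (i in seq_len(nrow(segs))) {
        a <- segs[i, 1L]; b <- segs[i, 2L]
        seg <- x[a:b]
        m <- length(seg)
        trend <- if (m >= 8L) {
          stats::smooth.spline(seq_len(m), seg,
                               df = max(4, min(m - 1, ceiling(m / 4))))$y
        } else {
          stats::fitted(stats::lm(seg ~ seq_len(m)))
        }
        # subtract the trend, anchor the segment at its entry level, and
        # shift everything after it so the series stays continuous
        level <- if (a > 1L) x[a - 1L] else trend[1L]
        corrected <- seg - trend + level
        shift <- corrected[m] - x[b]
        x[a:b] <- corrected
        if (b < length(x)) x[(b + 1L):length(x)] <- x[(b + 1L):length(x)] + shift
        log[[length(log) + 1L]] <- data.frame(channel = ch, wavelength = wl,
                                              start = a, end = b)
      }
      out[, ch, wl] <- x
    }
  }
  od$od <- out
  attr(od, "artifacts") <- if (length(log)) do.call(rbind, log) else
    data.frame(channel = integer(), wavelength = integer(),
               start = integer(), end = integer())
  od
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Inverts the modified Beer-Lambert system per channel and time point:
#' `dOD(lambda) / (d * DPF(lambda)) = eps(lambda, ) %*% c(dHbO, dHbR)`,
#' then `dHbT = dHbO + dHbR`. Units are mM given extinction coefficients in
#' 1/(mM cm) and distance in cm.
#'
#' @param od An `od_series` (two wavelengths).
#' @param bl [beer_lambert_params()].
#' @return A `hemo_series`: list with `hbo`, `hbr`, `hbt` time x channel
#'   matrices and `sampling_rate`.
#' @export
od_to_hemoglobin <- function(od, bl = beer_lambert_params()) {
  E <- bl$extinction
  Einv <- solve(E)
  path <- bl$distance * bl$dpf
  d <- dim(od$od)
  od1 <- od$od[, , 1L] / path[1L]
  od2 <- od$od[, , 2L] / path[2L]
  hbo <- Einv[1L, 1L] * od1 + Einv[1L, 2L] * od2
  hbr <- Einv[2L, 1L] * od1 + Einv[2L, 2L] * od2
  hemo_series(hbo, hbr, od$sampling_rate, schedule = od$schedule)
}

#' Construct a hemoglobin concentration series
#'
#' @param hbo,hbr time x channel matrices of oxy-/deoxyhemoglobin change (mM).
#' @param sampling_rate Hz.
#' @param schedule Optional attached `trial_schedule`.
#' @return A `hemo_series` with `hbt = hbo + hbr`.
#' @export
hemo_series <- function(hbo, hbr, sampling_rate, schedule = NULL) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  stopifnot(identical(dim(hbo), dim(hbr)))
  structure(list(hbo = hbo, hbr = hbr, hbt = hbo + hbr,
                 sampling_rate = sampling_rate, schedule = schedule),
            class = "hemo_series")
}

#' Full preprocessing chain
#'
#' Composes the stages in their fixed order: intensity -> optical density ->
#' 3 Hz low-pass -> spline motion correction -> wavelet despiking ->
#' 0.016-0.5 Hz band-pass -> modified Beer-Lambert inversion. The stage
#' order is part of the pipeline's contract and cannot be permuted.
#'
#' @param raw A `raw_recording`.
#' @param config A [pipeline_config()].
#' @param bl [beer_lambert_params()].
#' @param stages Internal guard: must remain the canonical stage vector;
#'   passing anything else raises a configuration error.
#' @return A `hemo_series`; motion-artifact segments detected along the way
#'   are kept in `attr(, "artifacts")`.
#' @export
preprocess <- function(raw, config = pipeline_config(),
                       bl = beer_lambert_params(),
                       stages = preprocess_stages()) {
  if (!identical(stages, preprocess_stages())) {
    stop_invalid("config", "the preprocessing stage order is fixed and cannot be changed")
  }
  od <- intensity_to_od(raw)
  od <- od_lowpass(od, config$lowpass_hz)
  od <- correct_motion_spline(od)
  arts <- attr(od, "artifacts")
  od <- wavelet_smooth(od)
  od <- od_bandpass(od, config$bandpass_low_hz, config$bandpass_high_hz)
  hemo <- od_to_hemoglobin(od, bl)
  attr(hemo, "artifacts") <- arts
  hemo
}

#' @rdname preprocess
#' @export
preprocess_stages <- function() {
  c("intensity_to_od", "lowpass", "correct_motion_spline",
    "wavelet_smooth", "bandpass", "od_to_hemoglobin")
}
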