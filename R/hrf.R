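#' Canonical double-gamma hemodynamic response function
#'
#' The impulse response linking a neural event to the oxygenated-hemoglobin
#' response: a gamma density peaking at `peak_s` minus a scaled gamma density
#' peaking at `undershoot_s` (the post-stimulus undershoot). The response is
#' 0 at onset, peaks near `peak_s`, dips below zero afterwards and decays to
#' 0; it is normalized so the peak value is 1.
#'
#' @param t Time since onset, seconds (vectorized; all `t >= 0`).
#' @param peak_s Time-to-peak of the positive lobe (s).
#' @param undershoot_s Time-to-peak of the undershoot lobe (s).
#' @param undershoot_ratio Peak-to-undershoot amplitude ratio (default 6, the
#'   conventional value).
#' @return Numeric vector of unitless amplitudes.
#' @export
fnirs_hrf <- function(t, peak_s = 6, undershoot_s = 16, undershoot_ratio = 6) {
  if (any(t < 0)) stop_invalid("hrf", "t must be non-negative")
  # shape a = peak*rate + 1 puts the gamma mode exactly at the requested peak
  rate <- 1
  a1 <- peak_s * rate + 1
  a2 <- undershoot_s * rate + 1
  h <- stats::dgamma(t, shape = a1, rate = rate) -
    stats::dgamma(t, shape = a2, rate = rate) / undershoot_ratio
  peak <- stats::dgamma(peak_s, shape = a1, rate = rate) -
    stats::dgamma(peak_s, shape = a2, rate = rate) / undershoot_ratio
  h / peak
}
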