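#' Configuration of the synthetic fNIRS session generator
#'
#' Defines the study conditions the generator emulates: a two-group
#' (stress/control) protocol of familiarization, training (with error-driven
#' fallback), buffer, and counterbalanced stress/no-stress evaluation trials;
#' HRF-driven region-specific activation that differs between memory encoding
#' and retrieval; and the standard fNIRS nuisance structure (cardiac,
#' respiratory and Mayer-wave oscillations, slow drift, white measurement
#' noise, and motion spikes/steps in optical density).
#'
#' Activation amplitudes are in micromolar equivalents of oxygenated
#' hemoglobin change; deoxygenated hemoglobin is coupled as
#' `hbr_ratio * HbO`. Three presets are provided: `"default"` (overlapping
#' but distinct encoding/retrieval topographies across all six ROIs),
#' `"strong"` (encoding confined to LDLPFC, retrieval to RDLPFC, high SNR —
#' the planted-signal recovery scenario), and `"null"` (identical amplitudes
#' for both states — no class signal).
#'
#' @param scenario One of `"default"`, `"strong"`, `"null"`.
#' @param n_participants Number of participants in a simulated study.
#' @param stress_group_fraction Fraction of participants in the stress group.
#' @param sampling_rate Sampling rate in Hz.
#' @param hrf_peak_s,hrf_undershoot_s Double-gamma HRF parameters (s).
#' @param activation Optional 6 x 3 x 2 amplitude array
#'   (ROI x state(encoding, retrieval, rest) x condition(N, S), micromolar);
#'   built from the scenario preset when NULL.
#' @param stress_gain Multiplier applied to prefrontal-ROI amplitudes under
#'   condition S (the stress-recruitment model).
#' @param tonic_stress_uM Tonic HbO shift (micromolar) added to prefrontal
#'   ROIs during S trials.
#' @param hbr_ratio HbR/HbO coupling ratio (negative).
#' @param cardiac_hz,cardiac_amp,resp_hz,resp_amp,mayer_hz,mayer_amp
#'   Physiological oscillation frequencies (Hz) and optical-density
#'   amplitudes.
#' @param drift_slope Linear drift slope in OD per second.
#' @param noise_sd White measurement-noise standard deviation (OD).
#' @param spike_rate Motion artifacts per minute.
#' @param spike_amplitude Typical artifact amplitude (OD).
#' @param spike_step_fraction Fraction of artifacts that are persistent
#'   baseline steps rather than decaying spikes.
#' @param spike_tau_s Decay time constant of spike artifacts (s).
#' @param training_error_prob Per-trial probability of a training error.
#' @param stress_exposure_fraction Probability that a familiarization or
#'   training trial of a stress-group participant is under stressors.
#' @param trial_min_s,trial_max_s Task-trial duration bounds (s).
#' @param buffer_s Buffer (consolidation) block duration (s).
#' @param gap_s Inter-trial gap (s).
#' @param buffer_amplitude_uM Residual task-free activation during the buffer.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(scenario = c("default", "strong", "null"),
                             n_participants = 31L,
                             stress_group_fraction = 0.5,
                             sampling_rate = 8.7,
                             hrf_peak_s = 6, hrf_undershoot_s = 16,
                             activation = NULL,
                             stress_gain = 1.3,
                             tonic_stress_uM = 0.2,
                             hbr_ratio = -1/3,
                             cardiac_hz = 1.1, cardiac_amp = 0.008,
                             resp_hz = 0.3, resp_amp = 0.004,
                             mayer_hz = 0.1, mayer_amp = 0.006,
                             drift_slope = 3e-4,
                             noise_sd = 0.005,
                             spike_rate = 0.5,
                             spike_amplitude = 0.05,
                             spike_step_fraction = 0.3,
                             spike_tau_s = 0.5,
                             training_error_prob = 0.2,
                             stress_exposure_fraction = 1.0,
                             trial_min_s = 20, trial_max_s = 60,
                             buffer_s = 120, gap_s = 2,
                             buffer_amplitude_uM = 0.1) {
  scenario <- match.arg(scenario)
  if (is.null(activation)) {
    base <- switch(scenario,
      default = rbind(  # encoding, retrieval (micromolar)
        LDLPFC = c(1.0, 0.3), RDLPFC = c(0.3, 1.0), MPFC = c(0.6, 0.5),
        LPM = c(0.4, 0.4), RPM = c(0.3, 0.8), SMA = c(0.3, 0.3)),
      strong = rbind(
        LDLPFC = c(2.0, 0.1), RDLPFC = c(0.1, 2.0), MPFC = c(0.1, 0.1),
        LPM = c(0.1, 0.1), RPM = c(0.1, 0.1), SMA = c(0.1, 0.1)),
      null = matrix(0.5, 6, 2, dimnames = list(roi_labels(), NULL))
    )
    # scenario presets fill in only what the caller left at the default
    if (scenario == "strong") {
      if (missing(stress_gain)) stress_gain <- 1.0
      if (missing(tonic_stress_uM)) tonic_stress_uM <- 0.0
      if (missing(noise_sd)) noise_sd <- 0.003
    }
    if (scenario == "null") {
      if (missing(stress_gain)) stress_gain <- 1.0
      if (missing(tonic_stress_uM)) tonic_stress_uM <- 0.0
    }
    activation <- array(0, dim = c(6L, 3L, 2L),
                        dimnames = list(roi_labels(),
                                        c("encoding", "retrieval", "rest"),
                                        c("N", "S")))
    activation[, "encoding", "N"] <- base[, 1L]
    activation[, "retrieval", "N"] <- base[, 2L]
    activation[, "rest", ] <- buffer_amplitude_uM
    pfc <- c("LDLPFC", "RDLPFC", "MPFC")
    activation[, c("encoding", "retrieval"), "S"] <-
      activation[, c("encoding", "retrieval"), "N"]
    activation[pfc, c("encoding", "retrieval"), "S"] <-
      activation[pfc, c("encoding", "retrieval"), "N"] * stress_gain
  }
  stopifnot(all(activation >= 0))
  if (training_error_prob < 0 || training_error_prob > 1) {
    stop_invalid("synthetic config", "training_error_prob must lie in [0, 1]")
  }
  nyq <- sampling_rate / 2
  if (any(c(cardiac_hz, resp_hz, mayer_hz) >= nyq)) {
    stop_invalid("synthetic config", "physiological frequencies must be below Nyquist")
  }
  structure(list(
    scenario = scenario,
    n_participants = as.integer(n_participants),
    stress_group_fraction = stress_group_fraction,
    sampling_rate = sampling_rate,
    hrf_peak_s = hrf_peak_s, hrf_undershoot_s = hrf_undershoot_s,
    activation = activation,
    stress_gain = stress_gain, tonic_stress_uM = tonic_stress_uM,
    hbr_ratio = hbr_ratio,
    cardiac_hz = cardiac_hz, cardiac_amp = cardiac_amp,
    resp_hz = resp_hz, resp_amp = resp_amp,
    mayer_hz = mayer_hz, mayer_amp = mayer_amp,
    drift_slope = drift_slope, noise_sd = noise_sd,
    spike_rate = spike_rate, spike_amplitude = spike_amplitude,
    spike_step_fraction = spike_step_fraction, spike_tau_s = spike_tau_s,
    training_error_prob = training_error_prob,
    stress_exposure_fraction = stress_exposure_fraction,
    trial_min_s = trial_min_s, trial_max_s = trial_max_s,
    buffer_s = buffer_s, gap_s = gap_s,
    buffer_amplitude_uM = buffer_amplitude_uM
  ), class = "synthetic_config")
}

#' Construct a raw recording
#'
#' @param intensities time x channel x wavelength array of strictly positive
#'   light intensities.
#' @param sampling_rate Sampling rate (Hz).
#' @param wavelengths The two wavelengths (nm).
#' @param schedule The session's `trial_schedule`.
#' @return A `raw_recording`.
#' @export
raw_recording <- function(intensities, sampling_rate = 8.7,
                          wavelengths = c(760, 850), schedule = NULL) {
  if (length(dim(intensities)) != 3L || dim(intensities)[3L] != 2L) {
    stop_invalid("recording", "intensities must be time x channel x 2 wavelengths")
  }
  bad <- which(apply(intensities <= 0 | !is.finite(intensities), 2L, any))
  if (length(bad)) {
    stop_invalid("recording",
                 paste("non-positive intensity in channel(s):",
                       paste(bad, collapse = ", ")))
  }
  if (length(wavelengths) != 2L) stop_invalid("recording", "exactly 2 wavelengths")
  structure(list(intensities = intensities, sampling_rate = sampling_rate,
                 wavelengths = wavelengths, schedule = schedule),
            class = "raw_recording")
}

# Trial state used by the generator: fam/training drive the encoding
# topography, evaluation the retrieval topography, buffer the rest level.
.trial_state <- function(segment) {
  switch(segment,
         familiarization = "encoding",
         training = "encoding",
         evaluation = "retrieval",
         buffer = "rest")
}

#' Simulate one fNIRS session
#'
#' Builds ground-truth per-channel hemoglobin signals (HRF-convolved trial
#' boxcars with amplitudes per ROI/state/condition, plus the tonic stress
#' shift), forward-projects them through the modified Beer-Lambert model to
#' two-wavelength optical density, adds physiological oscillations, drift,
#' white noise and motion artifacts, and exponentiates to light intensity.
#' Identical seeds yield bit-identical output.
#'
#' @param config A [synthetic_config()].
#' @param schedule A `trial_schedule` (see [build_protocol_schedule()]).
#' @param seed Integer seed.
#' @param layout A `probe_layout`.
#' @param bl [beer_lambert_params()] used for the forward projection.
#' @return List with elements `recording` (a `raw_recording`) and `truth`
#'   (labels, clean hemoglobin matrices in mM, injected artifact log).
#' @export
simulate_session <- function(config, schedule, seed = 1L,
                             layout = default_layout(),
                             bl = beer_lambert_params()) {
  fs <- config$sampling_rate
  dur <- max(schedule$end) + 20
  n <- ceiling(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  n_ch <- nrow(layout)
  rois <- roi_of(layout)

  with_seed(seed, {
    # neural drive per ROI (micromolar boxcars), then HRF convolution
    drive <- matrix(0, n, 6L, dimnames = list(NULL, roi_labels()))
    for (k in seq_len(nrow(schedule))) {
      st <- .trial_state(schedule$segment[k])
      amp <- config$activation[, st, schedule$condition[k]]
      idx <- which(tt >= schedule$start[k] & tt < schedule$end[k])
      drive[idx, ] <- drive[idx, ] + matrix(amp, length(idx), 6L, byrow = TRUE)
      if (schedule$condition[k] == "S" && config$tonic_stress_uM > 0) {
        pfc <- c("LDLPFC", "RDLPFC", "MPFC")
        drive[idx, pfc] <- drive[idx, pfc] + config$tonic_stress_uM
      }
    }
    kern_t <- seq(0, 32, by = 1 / fs)
    kern <- fnirs_hrf(kern_t, config$hrf_peak_s, config$hrf_undershoot_s)
    kern <- kern / sum(kern[kern > 0])  # unit-gain on sustained drive
    conv_roi <- apply(drive, 2L, function(x) {
      y <- stats::convolve(x, rev(kern), type = "open")
      y[seq_len(n)]
    })

    gain_ch <- stats::runif(n_ch, 0.85, 1.15)  # evoked-amplitude variability
    hbo_uM <- conv_roi[, rois, drop = FALSE] *
      matrix(gain_ch, n, n_ch, byrow = TRUE)
    hbo <- hbo_uM / 1000  # mM
    hbr <- config$hbr_ratio * hbo

    # forward Beer-Lambert projection to OD at the two wavelengths
    E <- bl$extinction
    path <- bl$distance * bl$dpf
    od <- array(0, dim = c(n, n_ch, 2L))
    for (w in 1:2) {
      od[, , w] <- (E[w, "HbO"] * hbo + E[w, "HbR"] * hbr) * path[w]
    }

    # nuisance structure in OD: physio sinusoids, drift, white noise
    wl_scale <- c(1, 0.8)
    for (ch in seq_len(n_ch)) {
      physio <-
        config$cardiac_amp * sin(2 * pi * config$cardiac_hz * tt + stats::runif(1, 0, 2 * pi)) +
        config$resp_amp * sin(2 * pi * config$resp_hz * tt + stats::runif(1, 0, 2 * pi)) +
        config$mayer_amp * sin(2 * pi * config$mayer_hz * tt + stats::runif(1, 0, 2 * pi))
      drift <- config$drift_slope * sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.5) * tt
      for (w in 1:2) {
        od[, ch, w] <- od[, ch, w] + wl_scale[w] * (physio + drift)
      }
    }
    if (config$noise_sd > 0) {
      od <- od + array(stats::rnorm(length(od), sd = config$noise_sd), dim = dim(od))
    }

    # motion artifacts: decaying spikes and persistent baseline steps
    n_spk <- if (config$spike_rate > 0) stats::rpois(1, config$spike_rate * dur / 60) else 0L
    spikes <- NULL
    if (n_spk > 0) {
      spikes <- data.frame(
        time = stats::runif(n_spk, 0, dur),
        channel = sample.int(n_ch, n_spk, replace = TRUE),
        type = ifelse(stats::runif(n_spk) < config$spike_step_fraction, "step", "spike"),
        amplitude = config$spike_amplitude * stats::runif(n_spk, 0.5, 1.5) *
          sample(c(-1, 1), n_spk, replace = TRUE)
      )
      for (s in seq_len(n_spk)) {
        idx <- which(tt >= spikes$time[s])
        if (!length(idx)) next
        shape <- if (spikes$type[s] == "step") {
          rep(1, length(idx))
        } else {
          exp(-(tt[idx] - spikes$time[s]) / config$spike_tau_s)
        }
        for (w in 1:2) {
          od[idx, spikes$channel[s], w] <- od[idx, spikes$channel[s], w] +
            wl_scale[w] * spikes$amplitude[s] * shape
        }
      }
    }

    base_I <- stats::runif(n_ch, 0.8, 1.2)  # per-channel optical gain
    intens <- array(0, dim = dim(od))
    for (w in 1:2) {
      intens[, , w] <- exp(-od[, , w]) *
        matrix(base_I, n, n_ch, byrow = TRUE)
    }

    list(
      recording = raw_recording(intens, fs, bl$wavelengths, schedule),
      truth = list(
        labels = trial_labels(schedule),
        schedule = schedule,
        hbo = hbo, hbr = hbr,
        spikes = spikes,
        activation = config$activation
      )
    )
  })
}

#' Simulate a multi-participant study
#'
#' Assigns participants to stress/control groups (exact counts from
#' `stress_group_fraction`, seeded), builds each participant's protocol
#' schedule and simulates each session with an independent derived sub-seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Master seed; fully determines the study.
#' @param layout,bl Passed to [simulate_session()].
#' @return List of per-participant entries: `participant`, `group`,
#'   `schedule`, `recording`, `truth`.
#' @export
simulate_study <- function(config = synthetic_config(), seed = 1L,
                           layout = default_layout(),
                           bl = beer_lambert_params()) {
  np <- config$n_participants
  n_stress <- round(np * config$stress_group_fraction)
  groups <- with_seed(seed, {
    sample(c(rep("stress", n_stress), rep("control", np - n_stress)))
  })
  seeds <- derive_seeds(seed, 2L * np)
  lapply(seq_len(np), function(i) {
    sch <- build_protocol_schedule(config, groups[i], seed = seeds[2L * i - 1L])
    sim <- simulate_session(config, sch, seed = seeds[2L * i], layout, bl)
    list(participant = i, group = groups[i], schedule = sch,
         recording = sim$recording, truth = sim$truth)
  })
}

#' Write / read a raw recording as long-format CSV
#'
#' Plain-text interchange dialect: columns `time`, `channel`, `wavelength`,
#' `intensity`, one row per sample.
#'
#' @param recording A `raw_recording`.
#' @param path Output CSV path.
#' @export
write_recording_csv <- function(recording, path) {
  d <- dim(recording$intensities)
  tt <- (seq_len(d[1L]) - 1) / recording$sampling_rate
  df <- data.frame(
    time = rep(tt, times = d[2L] * d[3L]),
    channel = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    wavelength = rep(recording$wavelengths, each = d[1L] * d[2L]),
    intensity = as.vector(recording$intensities)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param sampling_rate Sampling rate of the stored series (Hz).
#' @param schedule Optional `trial_schedule` to attach.
#' @export
read_recording_csv <- function(path, sampling_rate = 8.7, schedule = NULL) {
  df <- utils::read.csv(path)
  wls <- sort(unique(df$wavelength))
  chs <- sort(unique(df$channel))
  nt <- length(unique(df$time))
  arr <- array(NA_real_, dim = c(nt, length(chs), length(wls)))
  for (w in seq_along(wls)) {
    sub <- df[df$wavelength == wls[w], ]
    arr[, , w] <- matrix(sub$intensity[order(sub$channel, sub$time)], nt, length(chs))
  }
  raw_recording(arr, sampling_rate, wls, schedule)
}
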