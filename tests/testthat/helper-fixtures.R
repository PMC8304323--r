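# Shared fixtures, memoized so expensive simulations run once per session.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A clean (noise- and artifact-free) strong-contrast session.
clean_session <- function(seed = 7) {
  memo(paste0("clean_", seed), {
    cfg <- synthetic_config("strong", cardiac_amp = 0, resp_amp = 0,
                            mayer_amp = 0, drift_slope = 0, noise_sd = 0,
                            spike_rate = 0)
    sch <- build_protocol_schedule(cfg, "stress", seed = seed)
    c(simulate_session(cfg, sch, seed = seed), list(config = cfg, schedule = sch))
  })
}

# Band-pass an arbitrary time x channel matrix with the pipeline's band-pass,
# by wrapping it as a two-wavelength od_series.
bandpass_matrix <- function(m, fs = 8.7, low = 0.016, high = 0.5) {
  od <- structure(list(od = array(rep(m, 2), dim = c(nrow(m), ncol(m), 2)),
                       sampling_rate = fs),
                  class = "od_series")
  od_bandpass(od, low, high)$od[, , 1]
}

# Wrap a single-channel vector as an od_series for filter unit tests.
vec_as_od <- function(x, fs = 8.7) {
  structure(list(od = array(x, dim = c(length(x), 1L, 2L)),
                 sampling_rate = fs),
            class = "od_series")
}

rms <- function(x) sqrt(mean(x^2))

# Naive loop implementation of the windowed statistics, kept deliberately
# separate from the package's vectorized path.
naive_stats <- function(x, dt) {
  n <- length(x)
  mu <- 0; for (v in x) mu <- mu + v / n
  m2 <- 0; m3 <- 0; m4 <- 0
  for (v in x) {
    m2 <- m2 + (v - mu)^2 / n
    m3 <- m3 + (v - mu)^3 / n
    m4 <- m4 + (v - mu)^4 / n
  }
  auc <- 0
  for (i in 2:n) auc <- auc + (x[i] + x[i - 1]) / 2 * dt
  c(mean = mu, var = m2, max = max(x), min = min(x),
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    auc = auc)
}

naive_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# A synthetic feature table built directly (no simulation): `n_signal`
# informative features shifted by label, the rest pure noise. Fast fixture
# for the model-selection and importance modules.
toy_feature_table <- function(n_participants = 10, trials_per_class = 4,
                              n_features = 30, n_signal = 5, shift = 2,
                              seed = 1) {
  withr::with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
      lab <- rep(c("encoding", "retrieval"), each = trials_per_class)
      cond <- rep(c("S", "N"), length.out = length(lab))
      X <- matrix(rnorm(length(lab) * n_features), length(lab), n_features)
      X[lab == "retrieval", seq_len(n_signal)] <-
        X[lab == "retrieval", seq_len(n_signal)] + shift
      df <- data.frame(participant = p,
                       group = if (p %% 2 == 0) "stress" else "control",
                       trial = seq_along(lab), label = lab, condition = cond,
                       X, check.names = FALSE)
      names(df)[-(1:5)] <- sprintf("f%03d", seq_len(n_features))
      df
    }))
    structure(rows, class = c("feature_table", "data.frame"))
  })
}

# Simulate a study and carry it through preprocessing into a feature table.
study_feature_table <- function(cfg, seed) {
  study <- simulate_study(cfg, seed = seed)
  sessions <- lapply(study, function(s) {
    list(hemo = preprocess(s$recording), schedule = s$schedule,
         participant = s$participant, group = s$group)
  })
  suppressWarnings(build_dataset(sessions))
}

# The 31-participant strong-contrast study used by the end-to-end checks
# (26 train / 5 test after the participant split).
acceptance_strong_table <- function() {
  memo("acc_strong", study_feature_table(
    synthetic_config("strong", n_participants = 31L), seed = 2026))
}

# Activation pattern with a single differential ROI: retrieval recruits
# RDLPFC above the common background, nothing else distinguishes the states.
planted_rdlpfc_activation <- function() {
  act <- array(0.5, dim = c(6, 3, 2),
               dimnames = list(roi_labels(),
                               c("encoding", "retrieval", "rest"),
                               c("N", "S")))
  act[, "rest", ] <- 0.1
  act["RDLPFC", "retrieval", ] <- 1.2
  act
}

# One 2-channel window with prescribed signals, for feature unit tests.
toy_window <- function(x, y = NULL, fs = 8.7) {
  m <- cbind(x, if (is.null(y)) x else y)
  list(trial = 1L, window = 1L, start_sample = 1L, end_sample = nrow(m),
       start_s = 0, end_s = nrow(m) / fs,
       hbo = m, hbr = -m / 3, hbt = m * 2 / 3, sampling_rate = fs)
}
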