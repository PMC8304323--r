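# Orthonormal Daubechies-5 filter bank (10 taps). Coefficients follow the
# standard tabulation used across wavelet toolboxes.
.db5_dec_lo <- c(
  0.0033357252854737712, -0.012580751999081999, -0.006241490212798274,
  0.07757149384004572, -0.032244869584638375, -0.24229488706638203,
  0.13842814590132074, 0.7243085284377729, 0.6038292697971896,
  0.16010239797419293)
.db5_dec_hi <- c(
  -0.16010239797419293, 0.6038292697971896, -0.7243085284377729,
  0.13842814590132074, 0.24229488706638203, -0.032244869584638375,
  -0.07757149384004572, -0.006241490212798274, 0.012580751999081999,
  0.0033357252854737712)

# One periodized analysis step: circular correlation with the two filters at
# stride 2. Orthonormality of the Daubechies bank makes the transpose the
# exact inverse.
.dwt_step <- function(x, h = .db5_dec_lo, g = .db5_dec_hi) {
  n <- length(x)
  k <- seq.int(0L, n / 2L - 1L)
  a <- numeric(n / 2L)
  d <- numeric(n / 2L)
  for (l in seq_along(h)) {
    idx <- ((2L * k + (l - 1L)) %% n) + 1L
    a <- a + h[l] * x[idx]
    d <- d + g[l] * x[idx]
  }
  list(a = a, d = d)
}

.idwt_step <- function(a, d, h = .db5_dec_lo, g = .db5_dec_hi) {
  n <- 2L * length(a)
  k <- seq.int(0L, length(a) - 1L)
  x <- numeric(n)
  for (l in seq_along(h)) {
    idx <- ((2L * k + (l - 1L)) %% n) + 1L
    x[idx] <- x[idx] + h[l] * a + g[l] * d
  }
  x
}

# Multi-level periodized DWT of a vector whose length is a multiple of 2^J.
.dwt <- function(x, J) {
  details <- vector("list", J)
  a <- x
  for (j in seq_len(J)) {
    s <- .dwt_step(a)
    a <- s$a
    details[[j]] <- s$d
  }
  list(approx = a, details = details)
}

.idwt <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    a <- .idwt_step(a, decomp$details[[j]])
  }
  a
}

# Denoise one series: reflect-pad to a multiple of 2^J, decompose, zero
# detail coefficients whose magnitude exceeds a robust (MAD-based) universal
# threshold — motion artifacts concentrate in outlier coefficients — then
# reconstruct and truncate to the original length.
.wavelet_denoise_vec <- function(x, J = 4L, amp_floor = 0.1) {
  n <- length(x)
  if (n < 2L) return(x)
  floor_abs <- amp_floor * stats::sd(x)
  J <- min(J, max(1L, floor(log2(n)) - 3L))
  block <- 2L^J
  n_pad <- ceiling(n / block) * block
  if (n_pad > n) {
    extra <- n_pad - n
    refl <- rev(x)[seq_len(min(extra, n))]
    while (length(refl) < extra) refl <- c(refl, rev(refl))[seq_len(extra)]
    xp <- c(x, refl[seq_len(extra)])
  } else {
    xp <- x
  }
  dec <- .dwt(xp, J)
  for (j in seq_along(dec$details)) {
    d <- dec$details[[j]]
    sigma <- stats::median(abs(d)) / 0.6745
    if (sigma <= 0) next
    # outlier coefficients carry the artifacts; the amplitude floor keeps
    # the thresholder off clean low-noise signals
    thr <- max(sigma * sqrt(2 * log(length(xp))), floor_abs)
    d[abs(d) > thr] <- 0
    dec$details[[j]] <- d
  }
  .idwt(dec)[seq_len(n)]
}

#' Wavelet despiking of an optical-density series
#'
#' Per channel and wavelength: periodized Daubechies-5 discrete wavelet
#' decomposition over `levels` scales; detail coefficients whose magnitude
#' exceeds a robust dispersion-based (MAD) universal threshold are set to
#' zero — isolated spikes concentrate into a few outlier coefficients while
#' the smooth hemodynamic content stays below threshold — and the series is
#' reconstructed at its original length. An amplitude floor (a fraction of
#' the channel's standard deviation) keeps the thresholder inactive on
#' clean signals; a constant series is returned unchanged.
#'
#' @param od An `od_series`.
#' @param levels Decomposition depth (default 4).
#' @param amp_floor Minimum coefficient magnitude, as a fraction of the
#'   channel standard deviation, below which nothing is zeroed.
#' @return Smoothed `od_series`, same shape.
#' @export
wavelet_smooth <- function(od, levels = 4L, amp_floor = 0.1) {
  .map_od(od, function(m) apply(m, 2L, .wavelet_denoise_vec, J = levels,
                                amp_floor = amp_floor))
}
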