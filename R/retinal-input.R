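# Reconstruction of the retinal input to a drifting grating and its
# space-time power spectrum.
#
# For a sinusoidal grating, all spatial structure of the retinal input
# I(x, t) reduces to the phase path f_s . xi(t): the complex "demodulated"
# signal z(t) = exp(-i 2 pi f_s u(alpha) . xi(t) / 60) s(t) M(t) carries the
# full temporal spectrum of the grating's +f_s spatial component, and the
# one-sided folding below recovers the power of the real-valued stimulus.

#' Contrast envelope specification
#'
#' The modulating function `M(t)` that ramps stimulus contrast up at the start
#' and down at the end of a trial. The default emulates a typical contrast
#' sensitivity trial: raised-cosine ramps of 0.5 s on a 3.2 s presentation.
#'
#' @param ramp_shape `"raised_cosine"`, `"linear"` or `"none"`.
#' @param ramp_duration ramp length at each end (s).
#' @param plateau contrast during the plateau (dimensionless, default 1).
#' @return An object of class `envelope_spec`.
#' @export
envelope_spec <- function(ramp_shape = c("raised_cosine", "linear", "none"),
                          ramp_duration = 0.5, plateau = 1) {
  ramp_shape <- match.arg(ramp_shape)
  if (ramp_shape == "none") ramp_duration <- 0
  if (ramp_duration < 0) stop("ramp_duration must be non-negative")
  if (plateau < 0 || plateau > 1) stop("plateau contrast must be in [0, 1]")
  structure(list(ramp_shape = ramp_shape, ramp_duration = ramp_duration,
                 plateau = plateau), class = "envelope_spec")
}

#' Sinusoidal grating stimulus
#'
#' @param sf spatial frequency (cycles/deg), > 0.
#' @param orientation grating orientation alpha (rad).
#' @param phase spatial phase phi (rad).
#' @param temporal_mod sinusoidal contrast-modulation frequency omega_t (Hz);
#'   0 means an unmodulated (static) grating.
#' @param duration presentation duration (s), default 3.2.
#' @param envelope an [envelope_spec()].
#' @return An object of class `grating_stimulus`.
#' @export
grating_stimulus <- function(sf, orientation = 0, phase = 0, temporal_mod = 0,
                             duration = 3.2, envelope = envelope_spec()) {
  if (!is.numeric(sf) || sf <= 0) stop("sf must be positive")
  if (temporal_mod < 0) stop("temporal_mod must be non-negative")
  if (duration <= 0) stop("duration must be positive")
  stopifnot(inherits(envelope, "envelope_spec"))
  if (2 * envelope$ramp_duration > duration) {
    stop("contrast ramps longer than the trial")
  }
  structure(list(sf = sf, orientation = orientation, phase = phase,
                 temporal_mod = temporal_mod, duration = duration,
                 envelope = envelope), class = "grating_stimulus")
}

#' Evaluate the contrast envelope M(t) on a time grid
#'
#' Symmetric ramps at both ends; `M(t)` equals the plateau contrast between
#' them. The trial duration is taken as `length(t_grid) * dt`.
#'
#' @param t_grid uniform time grid starting at 0 (s).
#' @param env an [envelope_spec()].
#' @return Numeric vector `M(t)` with values in `[0, 1]`.
#' @export
contrast_envelope <- function(t_grid, env) {
  stopifnot(inherits(env, "envelope_spec"))
  n <- length(t_grid)
  if (n < 2L) stop("t_grid needs at least 2 samples")
  dt <- t_grid[2L] - t_grid[1L]
  dur <- n * dt
  rd <- env$ramp_duration
  if (env$ramp_shape != "none" && 2 * rd > dur) {
    stop("contrast ramps longer than the trial")
  }
  m <- rep(1, n)
  if (env$ramp_shape != "none" && rd > 0) {
    tt <- t_grid - t_grid[1L]
    up <- tt < rd
    down <- tt > dur - rd
    if (env$ramp_shape == "raised_cosine") {
      m[up] <- 0.5 * (1 - cos(pi * tt[up] / rd))
      m[down] <- 0.5 * (1 - cos(pi * (dur - tt[down]) / rd))
    } else {
      m[up] <- tt[up] / rd
      m[down] <- (dur - tt[down]) / rd
    }
  }
  m * env$plateau
}

# Temporal factor s(t): sinusoidal contrast modulation, or 1 for a static
# grating (the omega_t = 0 convention).
.temporal_modulation <- function(t_grid, temporal_mod) {
  if (temporal_mod > 0) sin(2 * pi * temporal_mod * t_grid) else rep(1, length(t_grid))
}

#' Complex demodulated retinal signal for one grating and one trace
#'
#' Computes `z(t) = exp(i (phi - 2 pi sf u(alpha) . xi(t) / 60)) s(t) M(t)`,
#' with `xi` in arcmin (hence the /60 to degrees), `u(alpha)` the unit vector
#' at the grating orientation, `s(t) = sin(2 pi omega_t t)` for a flickered
#' grating and 1 otherwise. `z` carries the temporal structure of the
#' grating's `+f_s` spatial-frequency component; its phase factor has unit
#' modulus, so the power spectrum is phase-invariant.
#'
#' @param trace an [eye_trace()] at least as long as the stimulus.
#' @param stim a [grating_stimulus()].
#' @return Complex vector of length `round(stim$duration * trace$fs)` with
#'   attribute `fs`.
#' @export
demodulated_signal <- function(trace, stim) {
  stopifnot(inherits(trace, "eye_trace"), inherits(stim, "grating_stimulus"))
  n <- round(stim$duration * trace$fs)
  if (n > length(trace$t)) stop("trace shorter than the stimulus")
  t_grid <- (0:(n - 1L)) / trace$fs
  u <- c(cos(stim$orientation), sin(stim$orientation))
  xi_deg <- (u[1L] * trace$x[1:n] + u[2L] * trace$y[1:n]) / 60
  env <- .temporal_modulation(t_grid, stim$temporal_mod) *
    contrast_envelope(t_grid, stim$envelope)
  z <- exp(1i * (stim$phase - 2 * pi * stim$sf * xi_deg)) * env
  attr(z, "fs") <- trace$fs
  z
}

# Fold a two-sided |FFT/n|^2 vector (or matrix of columns) to one-sided bins:
# P(0) = |Z(0)|^2, P(nu) = |Z(nu)|^2 + |Z(-nu)|^2, Nyquist once for even n.
.fold_power <- function(p2) {
  one_col <- is.null(dim(p2))
  if (one_col) p2 <- matrix(p2, ncol = 1L)
  n <- nrow(p2)
  half <- n %/% 2L
  out <- matrix(0, half + 1L, ncol(p2))
  out[1L, ] <- p2[1L, ]
  if (n %% 2L == 0L) {
    out[half + 1L, ] <- p2[half + 1L, ]
    ks <- seq.int(2L, half)
  } else {
    ks <- seq.int(2L, half + 1L)
  }
  out[ks, ] <- p2[ks, , drop = FALSE] + p2[n + 2L - ks, , drop = FALSE]
  if (one_col) out[, 1L] else out
}

#' One-sided temporal power spectral density of a complex signal
#'
#' `P(nu) = (|Z(nu)|^2 + |Z(-nu)|^2) / dnu` for `nu > 0` and
#' `P(0) = |Z(0)|^2 / dnu`, with `Z = fft(z) / n`. The two signs carry the
#' `+f_s` and `-f_s` spatial components of the real-valued grating. With this
#' normalization `sum(P) * dnu = mean(|z|^2)` (Parseval), so units are
#' contrast^2 * s.
#'
#' @param z complex (or numeric) series.
#' @param fs sampling rate (Hz); defaults to the `fs` attribute of `z`.
#' @return List with `tf` (Hz, 0 to Nyquist), `power` (PSD) and `df` (bin
#'   width, Hz).
#' @export
temporal_power_spectrum <- function(z, fs = attr(z, "fs")) {
  n <- length(z)
  if (n < 2L) stop("need at least 2 samples")
  if (is.null(fs)) stop("sampling rate fs is required")
  p2 <- Mod(stats::fft(as.complex(z)) / n)^2
  folded <- .fold_power(p2)
  df <- fs / n
  list(tf = (0:(length(folded) - 1L)) * df, power = folded / df, df = df)
}

# Shared keep-rule for hard temporal-frequency cutoffs. A 1% relative
# tolerance lets a printed, rounded cutoff (0.63 Hz) match the corresponding
# FFT bin of a 3.2 s trial (0.625 Hz).
.tf_keep <- function(tf, cutoff) {
  if (cutoff <= 0) rep(TRUE, length(tf)) else tf >= cutoff * 0.99
}

#' Space-time power spectrum of the retinal input
#'
#' For each spatial frequency, averages the one-sided temporal PSD of the
#' demodulated signal over traces, grating orientations and phases. Averaging
#' over uniformly spaced orientations implements the radial average of the 2D
#' spatial spectrum (the drift projection onto the grating axis is resampled
#' at every orientation). The PSD is exactly independent of the grating phase
#' (phase enters `z` as a unit-modulus constant), so the phase average is
#' performed analytically; likewise orientations `alpha` and `alpha + pi`
#' yield conjugate signals with identical folded PSDs, halving the computed
#' orientation set when `n_orientations` is even.
#'
#' @param traces list of [eye_trace()] objects (>= 1), equal sampling rates.
#' @param stim a [grating_stimulus()] template; its `sf` is ignored in favor
#'   of `sf_grid`.
#' @param sf_grid ascending spatial frequencies (cycles/deg).
#' @param n_orientations,n_phases counts averaged over (uniform in `[0, 2pi)`).
#' @return An object of class `input_spectrum`: list with `sf_grid`,
#'   `tf_grid` (Hz), `power` (matrix sf x tf, PSD units contrast^2 s), `df`,
#'   `duration`, `fs`, `n_trials`, `n_orientations`, `n_phases`.
#' @export
input_power_spectrum <- function(traces, stim, sf_grid,
                                 n_orientations = 8, n_phases = 4) {
  if (inherits(traces, "eye_trace")) traces <- list(traces)
  if (length(traces) == 0L) stop("need at least one trace")
  stopifnot(inherits(stim, "grating_stimulus"))
  if (is.unsorted(sf_grid) || any(sf_grid <= 0)) {
    stop("sf_grid must be ascending and positive")
  }
  fs <- traces[[1L]]$fs
  n <- round(stim$duration * fs)
  t_grid <- (0:(n - 1L)) / fs
  env <- .temporal_modulation(t_grid, stim$temporal_mod) *
    contrast_envelope(t_grid, stim$envelope)

  if (n_orientations %% 2L == 0L) {
    alphas <- pi * (0:(n_orientations / 2L - 1L)) / (n_orientations / 2L)
    w_alpha <- 2
  } else {
    alphas <- 2 * pi * (0:(n_orientations - 1L)) / n_orientations
    w_alpha <- 1
  }

  half <- n %/% 2L
  acc <- matrix(0, half + 1L, length(sf_grid))
  for (tr in traces) {
    if (abs(tr$fs - fs) > 1e-6) stop("traces must share one sampling rate")
    if (length(tr$t) < n) stop("trace shorter than the stimulus")
    for (a in alphas) {
      xi_deg <- (cos(a) * tr$x[1:n] + sin(a) * tr$y[1:n]) / 60
      z <- exp(outer(xi_deg, -2i * pi * sf_grid)) * env
      p2 <- Mod(stats::mvfft(z) / n)^2
      acc <- acc + w_alpha * .fold_power(p2)
    }
  }
  df <- fs / n
  power <- t(acc) / (length(traces) * n_orientations) / df
  structure(
    list(sf_grid = sf_grid, tf_grid = (0:half) * df, power = power, df = df,
         duration = n / fs, fs = fs, n_trials = length(traces),
         n_orientations = n_orientations, n_phases = n_phases),
    class = "input_spectrum"
  )
}

#' @export
print.input_spectrum <- function(x, ...) {
  cat(sprintf(
    "<input_spectrum> %d sf x %d tf bins (%.3g-%.3g cpd, 0-%.4g Hz, dnu = %.4g Hz)\n",
    length(x$sf_grid), length(x$tf_grid), min(x$sf_grid), max(x$sf_grid),
    max(x$tf_grid), x$df
  ))
  cat(sprintf("  averaged over %d trial(s) x %d orientations x %d phases\n",
              x$n_trials, x$n_orientations, x$n_phases))
  invisible(x)
}

#' Analytic Lorentzian temporal spectrum for Brownian drift
#'
#' For a unit-contrast grating at spatial frequency `sf` viewed through
#' Brownian drift (per-axis increment variance `2 D dt`), the demodulated
#' signal has autocorrelation `exp(-k |tau|)` with decay rate
#' `k = 4 pi^2 sf^2 D / 3600` (D converted from arcmin^2/s to deg^2/s).
#' The one-sided PSD is the Lorentzian `S(nu) = 4 k / (k^2 + (2 pi nu)^2)`,
#' normalized to unit total power; its half-width at half maximum is
#' `k / (2 pi)` Hz.
#'
#' @param sf spatial frequency (cycles/deg), > 0.
#' @param D diffusion coefficient (arcmin^2/s), > 0.
#' @return A function `nu -> PSD` with attributes `k` (1/s) and `hwhm` (Hz).
#' @export
lorentzian_prediction <- function(sf, D) {
  if (sf <= 0 || D <= 0) stop("sf and D must be positive")
  k <- 4 * pi^2 * sf^2 * D / 3600
  f <- function(nu) 4 * k / (k^2 + (2 * pi * nu)^2)
  attr(f, "k") <- k
  attr(f, "hwhm") <- k / (2 * pi)
  # cumulative power below nu, for comparing against binned estimates
  # (the sampled spectrum reports bin masses, not point densities; the 0 Hz
  # bin in particular holds only half a bin width of density)
  attr(f, "cdf") <- function(nu) (2 / pi) * atan(2 * pi * nu / k)
  f
}

#' Predicted power per FFT bin under the Lorentzian oracle
#'
#' Integrates the normalized Lorentzian of [lorentzian_prediction()] over the
#' frequency interval of each one-sided FFT bin (`[0, dnu/2]` for the 0 Hz
#' bin, `[nu - dnu/2, nu + dnu/2]` elsewhere), for direct comparison with a
#' Monte-Carlo `power * dnu` bin-mass estimate.
#'
#' @param tf_grid one-sided temporal-frequency grid (Hz), starting at 0.
#' @param sf,D as in [lorentzian_prediction()].
#' @return Numeric vector of bin masses (summing to slightly below 1: the
#'   mass beyond the last bin is the out-of-band tail).
#' @export
lorentzian_bin_mass <- function(tf_grid, sf, D) {
  lor <- lorentzian_prediction(sf, D)
  cdf <- attr(lor, "cdf")
  df <- tf_grid[2L] - tf_grid[1L]
  hi <- cdf(tf_grid + df / 2)
  lo <- cdf(pmax(tf_grid - df / 2, 0))
  hi - lo
}

#' Brute-force space-time spectrum of the sampled retinal input
#'
#' Independent oracle for the demodulation path: samples the full retinal
#' input `I(x, t) = sin(2 pi sf (x - xi(t)) + phi) s(t) M(t)` on a 1D spatial
#' grid along the grating axis covering exactly `n_periods` spatial periods
#' (periodic boundary), takes the 2D Fourier power, and extracts the temporal
#' spectrum at the two spatial bins `+/- sf`. The real sinusoid splits its
#' power evenly between those two spatial components, so the extracted sum is
#' half the demodulated-path PSD; the factor 2 is restored here so both paths
#' agree bin-for-bin.
#'
#' @param trace an [eye_trace()].
#' @param stim a [grating_stimulus()] (keep instances small: this is an
#'   O(n_space * n_t log) oracle, not the production path).
#' @param n_space number of spatial samples per period (>= 8).
#' @param n_periods integer number of spatial periods on the grid.
#' @return List with `tf`, `power`, `df` matching [temporal_power_spectrum()]
#'   applied to [demodulated_signal()].
#' @export
brute_force_spacetime_spectrum <- function(trace, stim, n_space = 64,
                                           n_periods = 1) {
  stopifnot(inherits(trace, "eye_trace"), inherits(stim, "grating_stimulus"))
  if (n_space < 8) stop("n_space must be at least 8")
  if (n_periods != round(n_periods) || n_periods < 1) {
    stop("the grid must hold an integer number of grating cycles")
  }
  n_t <- round(stim$duration * trace$fs)
  if (n_t > length(trace$t)) stop("trace shorter than the stimulus")
  t_grid <- (0:(n_t - 1L)) / trace$fs
  u <- c(cos(stim$orientation), sin(stim$orientation))
  xi_deg <- (u[1L] * trace$x[1:n_t] + u[2L] * trace$y[1:n_t]) / 60
  env <- .temporal_modulation(t_grid, stim$temporal_mod) *
    contrast_envelope(t_grid, stim$envelope)

  x_deg <- (0:(n_space - 1L)) / n_space * (n_periods / stim$sf)
  # I: n_space x n_t
  phase_mat <- outer(2 * pi * stim$sf * x_deg, 2 * pi * stim$sf * xi_deg - stim$phase, `-`)
  I_mat <- sin(phase_mat) * rep(env, each = n_space)

  g_space <- stats::mvfft(I_mat) / n_space          # spatial DFT per time bin
  sf_bins <- c(1L + n_periods, n_space + 1L - n_periods)  # +sf and -sf bins
  acc <- 0
  for (b in sf_bins) {
    zt <- g_space[b, ]
    p2 <- Mod(stats::fft(zt) / n_t)^2
    acc <- acc + .fold_power(p2)
  }
  df <- trace$fs / n_t
  list(tf = (0:(length(acc) - 1L)) * df, power = 2 * acc / df, df = df)
}

#' Split input power into static (DC) and dynamic components per spatial frequency
#'
#' For each spatial frequency of an [input_power_spectrum()], `dc_power` is
#' the power in the 0 Hz bin and `dynamic_power` the summed power at temporal
#' frequencies at or above the cutoff (both as power, i.e. PSD x bin width).
#' With the cutoff at one bin width, `dc_power + dynamic_power` equals the
#' total power.
#'
#' @param spectrum an `input_spectrum`.
#' @param cutoff temporal-frequency cutoff (Hz), >= 0.
#' @return A data.frame `sf_cpd`, `dc_power`, `dynamic_power` with attribute
#'   `cutoff`.
#' @export
power_decomposition <- function(spectrum, cutoff = 0.63) {
  stopifnot(inherits(spectrum, "input_spectrum"))
  if (cutoff < 0) stop("cutoff must be non-negative")
  keep <- .tf_keep(spectrum$tf_grid, cutoff) & spectrum$tf_grid > 0
  out <- data.frame(
    sf_cpd = spectrum$sf_grid,
    dc_power = spectrum$power[, 1L] * spectrum$df,
    dynamic_power = rowSums(spectrum$power[, keep, drop = FALSE]) * spectrum$df
  )
  attr(out, "cutoff") <- cutoff
  out
}

#' Write an input spectrum to CSV (long format)
#'
#' Columns `sf_cpd,tf_hz,power`.
#' @param spectrum an `input_spectrum`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "input_spectrum"))
  d <- data.frame(
    sf_cpd = rep(spectrum$sf_grid, times = length(spectrum$tf_grid)),
    tf_hz = rep(spectrum$tf_grid, each = length(spectrum$sf_grid)),
    power = as.vector(spectrum$power)
  )
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
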