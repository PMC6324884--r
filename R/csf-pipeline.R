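# From input spectra and cell filters to predicted contrast sensitivity
# functions, shape descriptors, and gain fitting.

#' Viewing condition for a CSF prediction
#'
#' @param drift_source `"brownian"` (simulated fixational drift),
#'   `"none"` (retinal image perfectly still, `xi(t) = 0`), or `"traces"`
#'   (read recorded/stored traces from `trace_file`).
#' @param D Brownian diffusion coefficient (arcmin^2/s); 250 models normal
#'   fixation, 2 models retinal stabilization.
#' @param n_trials number of simulated traces (brownian source).
#' @param seed integer seed for the trace ensemble.
#' @param trace_file CSV path for `drift_source = "traces"`
#'   (see [read_trace_csv()]).
#' @param temporal_mod grating flicker frequency omega_t (Hz); 0 = static.
#' @param duration trial duration (s).
#' @param fs sampling rate (samples/s).
#' @param envelope an [envelope_spec()].
#' @return An object of class `csf_condition`.
#' @export
csf_condition <- function(drift_source = c("brownian", "none", "traces"),
                          D = 250, n_trials = 100, seed = NULL,
                          trace_file = NULL, temporal_mod = 0,
                          duration = 3.2, fs = 1000,
                          envelope = envelope_spec()) {
  drift_source <- match.arg(drift_source)
  if (drift_source == "traces" && is.null(trace_file)) {
    stop("drift_source = 'traces' requires trace_file")
  }
  structure(list(drift_source = drift_source, D = D, n_trials = n_trials,
                 seed = seed, trace_file = trace_file,
                 temporal_mod = temporal_mod, duration = duration, fs = fs,
                 envelope = envelope), class = "csf_condition")
}

#' M/P combination parameters
#'
#' The predicted CSF is `A (lam CSF_M + (1 - lam) CSF_P)`. Both parameters
#' only align predictions with measured data; they have no effect on curve
#' shape (A) or on the existence of the band-pass/low-pass transition (lam).
#'
#' @param A_gain global gain `A` (default 1).
#' @param lam M-population weight `lambda` in `[0, 1]` (default 0.57).
#' @return An object of class `combination_params`.
#' @export
combination_params <- function(A_gain = 1, lam = 0.57) {
  if (lam < 0 || lam > 1) stop("lam must be in [0, 1]")
  structure(list(A_gain = A_gain, lam = lam), class = "combination_params")
}

#' Default spatial-frequency grid
#'
#' 24 log-spaced points over 0.1-60 cycles/deg, the sensitivity range covered
#' by classical CSF measurements.
#'
#' @param n number of points.
#' @param from,to range (cycles/deg).
#' @return Numeric vector.
#' @export
default_sf_grid <- function(n = 24, from = 0.1, to = 60) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Response power spectrum of one cell class
#'
#' `O(f, w) = P_I(f, w) |RF(f, w)|^2`: the input power filtered through the
#' squared modulus of the space-time separable transfer function. The pure
#' response delay drops out here, so all downstream quantities are
#' delay-invariant.
#'
#' @param spectrum an `input_spectrum`.
#' @param cell a [cell_model()].
#' @return An object of class `response_spectrum` with the same grid fields
#'   as the input spectrum plus `cell_class`.
#' @export
response_power <- function(spectrum, cell) {
  stopifnot(inherits(spectrum, "input_spectrum"), inherits(cell, "cell_model"))
  gain2 <- outer(dog_amplitude(spectrum$sf_grid, cell$dog)^2,
                 Mod(temporal_transfer(spectrum$tf_grid, cell$temporal))^2)
  if (!all(dim(gain2) == dim(spectrum$power))) stop("grid mismatch")
  out <- spectrum
  out$power <- spectrum$power * gain2
  out$cell_class <- cell$cell_class
  class(out) <- c("response_spectrum", "input_spectrum")
  out
}

#' Per-class contrast sensitivity from a response spectrum
#'
#' `CSF(f) = sqrt( sum_w w(w) O(f, w) dw )`: the square root of the response
#' power integrated over temporal frequency (rectangle rule on the uniform
#' FFT grid, up to the Nyquist limit), after applying the low-frequency
#' policy. The default policy discards the first two temporal bins of a
#' 3.2 s trial so the integral starts at 0.63 Hz.
#'
#' @param response a `response_spectrum` (or any `input_spectrum`).
#' @param policy a [low_freq_policy()].
#' @return Numeric sensitivity vector over the spatial-frequency grid.
#' @export
cell_csf <- function(response, policy = low_freq_policy()) {
  stopifnot(inherits(response, "input_spectrum"))
  w <- low_freq_weight(response$tf_grid, policy)
  sqrt(as.vector(response$power %*% w) * response$df)
}

#' Combine M and P sensitivities into a predicted CSF
#'
#' `A (lam CSF_M + (1 - lam) CSF_P)`, elementwise on a shared grid.
#'
#' @param csf_M,csf_P numeric sensitivity vectors on the same grid.
#' @param cp a [combination_params()].
#' @param sf_grid the shared spatial-frequency grid.
#' @param condition optional [csf_condition()] recorded in the result.
#' @return An object of class `csf_curve`: list with `sf_grid`,
#'   `sensitivity`, `csf_M`, `csf_P`, `combination`, `condition`.
#' @export
combine_csf <- function(csf_M, csf_P, cp = combination_params(),
                        sf_grid = NULL, condition = NULL) {
  stopifnot(inherits(cp, "combination_params"))
  if (length(csf_M) != length(csf_P)) stop("grid mismatch between M and P components")
  if (!is.null(sf_grid) && length(sf_grid) != length(csf_M)) stop("grid mismatch")
  total <- cp$A_gain * (cp$lam * csf_M + (1 - cp$lam) * csf_P)
  structure(
    list(sf_grid = sf_grid, sensitivity = total, csf_M = csf_M, csf_P = csf_P,
         combination = cp, condition = condition),
    class = "csf_curve"
  )
}

#' @export
print.csf_curve <- function(x, ...) {
  desc <- tryCatch(shape_descriptors(x), error = function(e) NULL)
  cat(sprintf("<csf_curve> %d spatial frequencies", length(x$sensitivity)))
  if (!is.null(x$sf_grid)) {
    cat(sprintf(" (%.3g-%.3g cpd)", min(x$sf_grid), max(x$sf_grid)))
  }
  if (!is.null(desc) && isTRUE(desc$valid)) {
    cat(sprintf(", peak %.3g cpd, %s (low-freq ratio %.2f)",
                desc$peak_sf, desc$shape_class, desc$lowfreq_ratio))
  }
  cat("\n")
  invisible(x)
}

# Build the trace ensemble for a condition.
.condition_traces <- function(condition) {
  switch(condition$drift_source,
    brownian = simulate_drift_ensemble(condition$n_trials, condition$duration,
                                       condition$fs, condition$D,
                                       seed = condition$seed),
    none = {
      n <- round(condition$duration * condition$fs)
      list(eye_trace(t = (0:(n - 1L)) / condition$fs, x = numeric(n),
                     y = numeric(n), trial_id = "static"))
    },
    traces = read_trace_csv(condition$trace_file)
  )
}

#' Predict the contrast sensitivity function for a viewing condition
#'
#' End-to-end pipeline: simulate (or load) the eye-trace ensemble, compute
#' the space-time power spectrum of the retinal input per spatial frequency,
#' filter it through the M and P transfer functions, integrate over temporal
#' frequency under the low-frequency policy, and combine the two classes.
#' Deterministic given the condition seed.
#'
#' @param condition a [csf_condition()].
#' @param cells named list `list(M = , P = )` of [cell_model()]s.
#' @param cp a [combination_params()].
#' @param policy a [low_freq_policy()].
#' @param sf_grid spatial frequencies (cycles/deg).
#' @param n_orientations,n_phases sampling of grating orientation and phase.
#' @param keep_spectrum if `TRUE` the input spectrum is attached to the
#'   result (`$spectrum`), allowing descriptors to be recomputed under other
#'   policies without re-simulating.
#' @param normalize_components if `TRUE`, each per-class CSF is rescaled to
#'   unit peak before the lambda-combination, so that the mixing weight acts
#'   purely on curve shapes (the raw M-pathway magnitude exceeds the
#'   P-pathway magnitude several-fold, so the raw mix is M-dominated). The
#'   default `FALSE` combines the raw integrated-power sensitivities, which
#'   keeps absolute sensitivity comparable across viewing conditions
#'   (e.g. the sensitivity loss under retinal stabilization).
#' @return A `csf_curve` with `$spectrum` (optional), `$policy`, `$cells`,
#'   and the raw per-class sensitivities in `$csf_M_raw` / `$csf_P_raw`.
#' @export
predict_csf <- function(condition, cells = default_cell_models(),
                        cp = combination_params(),
                        policy = low_freq_policy(),
                        sf_grid = default_sf_grid(),
                        n_orientations = 8, n_phases = 4,
                        keep_spectrum = TRUE, normalize_components = FALSE) {
  stopifnot(inherits(condition, "csf_condition"))
  traces <- .condition_traces(condition)
  stim <- grating_stimulus(sf = 1, temporal_mod = condition$temporal_mod,
                           duration = condition$duration,
                           envelope = condition$envelope)
  spec <- input_power_spectrum(traces, stim, sf_grid,
                               n_orientations = n_orientations,
                               n_phases = n_phases)
  csf_m_raw <- cell_csf(response_power(spec, cells$M), policy)
  csf_p_raw <- cell_csf(response_power(spec, cells$P), policy)
  csf_m <- csf_m_raw
  csf_p <- csf_p_raw
  if (normalize_components) {
    if (max(csf_m) > 0) csf_m <- csf_m / max(csf_m)
    if (max(csf_p) > 0) csf_p <- csf_p / max(csf_p)
  }
  curve <- combine_csf(csf_m, csf_p, cp, sf_grid = sf_grid,
                       condition = condition)
  curve$csf_M_raw <- csf_m_raw
  curve$csf_P_raw <- csf_p_raw
  curve$policy <- policy
  curve$cells <- cells
  if (keep_spectrum) curve$spectrum <- spec
  curve
}

#' Shape descriptors of a predicted CSF
#'
#' `peak_sf` is the grid argmax refined by parabolic interpolation of log
#' sensitivity in log spatial frequency (decoupling the reported peak from
#' grid spacing; no refinement at the grid edges). `lowfreq_ratio` is the
#' sensitivity at the lowest sampled frequency divided by the maximum.
#' The curve is classified `low_pass` when `lowfreq_ratio >= threshold`
#' (ties count as low-pass), else `band_pass`.
#'
#' @param curve a `csf_curve`, or a data.frame with `sf_cpd`/`sensitivity`.
#' @param lowpass_threshold classification threshold on `lowfreq_ratio`
#'   (default 0.5).
#' @return List with `peak_sf`, `lowfreq_ratio`, `shape_class`, `valid`.
#'   An all-zero curve gives `valid = FALSE` and `NA` descriptors.
#' @export
shape_descriptors <- function(curve, lowpass_threshold = 0.5) {
  if (inherits(curve, "csf_curve")) {
    sf <- curve$sf_grid
    s <- curve$sensitivity
  } else {
    d <- as.data.frame(curve)
    sf <- d$sf_cpd
    s <- d$sensitivity
  }
  if (length(s) < 5L) stop("need at least 5 grid points")
  if (is.null(sf)) stop("curve has no spatial-frequency grid")
  if (all(s == 0) || !all(is.finite(s))) {
    return(list(peak_sf = NA_real_, lowfreq_ratio = NA_real_,
                shape_class = NA_character_, valid = FALSE))
  }
  i <- which.max(s)
  peak <- sf[i]
  if (i > 1L && i < length(s) && s[i - 1L] > 0 && s[i + 1L] > 0) {
    lx <- log10(sf[(i - 1L):(i + 1L)])
    ly <- log(s[(i - 1L):(i + 1L)])
    # vertex of the parabola through the three points (spacing need not be
    # uniform); only refine when the points are actually concave
    d1 <- lx[2L] - lx[1L]
    d2 <- lx[3L] - lx[2L]
    f12 <- (ly[2L] - ly[1L]) / d1
    f23 <- (ly[3L] - ly[2L]) / d2
    a <- (f23 - f12) / (d1 + d2)
    if (a < 0) {
      vx <- (lx[1L] + lx[2L]) / 2 - f12 / (2 * a)
      vx <- min(max(vx, lx[1L]), lx[3L])
      peak <- 10^vx
    }
  }
  ratio <- s[1L] / max(s)
  list(
    peak_sf = peak,
    lowfreq_ratio = ratio,
    shape_class = if (ratio >= lowpass_threshold) "low_pass" else "band_pass",
    valid = TRUE
  )
}

#' Predict a family of CSFs over a grid of flicker frequencies
#'
#' Runs [predict_csf()] with each `temporal_mod` in `omegas`, holding all
#' other settings (including the drift seed) fixed.
#'
#' @param omegas flicker frequencies (Hz).
#' @param condition a [csf_condition()] template.
#' @param ... passed to [predict_csf()].
#' @return A list of `csf_curve`, named by frequency.
#' @export
predict_csf_family <- function(omegas, condition, ...) {
  stopifnot(inherits(condition, "csf_condition"))
  out <- lapply(omegas, function(om) {
    cond <- condition
    cond$temporal_mod <- om
    predict_csf(cond, ...)
  })
  names(out) <- as.character(omegas)
  out
}

#' Band-pass to low-pass transition frequency
#'
#' The smallest flicker frequency whose predicted CSF is classified low-pass
#' (sensitivity at the lowest sampled spatial frequency at least `threshold`
#' times the peak). If the classification is not monotone along the grid, the
#' first crossing is returned with a warning. If no curve is low-pass the
#' sentinel `Inf` is returned with attribute `status = "above_grid"`.
#'
#' @param curves list of `csf_curve` (e.g. from [predict_csf_family()]).
#' @param omegas flicker frequencies (Hz) matching `curves`; defaults to
#'   their conditions' `temporal_mod`.
#' @param lowpass_threshold classification threshold (default 0.5).
#' @return The transition frequency (Hz), with attribute `classes`.
#' @export
transition_frequency <- function(curves, omegas = NULL,
                                 lowpass_threshold = 0.5) {
  if (is.null(omegas)) {
    omegas <- vapply(curves, function(cv) cv$condition$temporal_mod, numeric(1))
  }
  ord <- order(omegas)
  omegas <- omegas[ord]
  curves <- curves[ord]
  classes <- vapply(curves, function(cv) {
    shape_descriptors(cv, lowpass_threshold)$shape_class
  }, character(1))
  lp <- which(classes == "low_pass")
  if (length(lp) == 0L) {
    out <- Inf
    attr(out, "status") <- "above_grid"
    attr(out, "classes") <- stats::setNames(classes, omegas)
    return(out)
  }
  first <- min(lp)
  if (!all(classes[first:length(classes)] == "low_pass")) {
    warning("band-pass/low-pass classification is not monotone in flicker ",
            "frequency; returning the first crossing")
  }
  out <- omegas[first]
  attr(out, "classes") <- stats::setNames(classes, omegas)
  out
}

#' Fit the global gain (and optionally the M/P weight) to reference data
#'
#' Least squares in log sensitivity between the model curve and tabulated
#' `(sf, sensitivity)` reference samples, interpolating the model components
#' log-log at the reference frequencies. With `fit_lambda = FALSE` only the
#' gain `A` is fitted (closed form: the mean log ratio), which never alters
#' the curve shape; with `fit_lambda = TRUE` the weight `lambda` is also
#' optimized on `[0, 1]`.
#'
#' @param curve a `csf_curve` with M and P components.
#' @param reference data.frame with `sf_cpd` and `sensitivity` (>= 1 row for
#'   gain only, >= 3 to fit lambda), within the curve's frequency range.
#' @param fit_lambda also fit the M/P weight?
#' @return A [combination_params()] with the fitted values.
#' @export
fit_gain <- function(curve, reference, fit_lambda = FALSE) {
  stopifnot(inherits(curve, "csf_curve"))
  ref <- as.data.frame(reference)
  if (!all(c("sf_cpd", "sensitivity") %in% names(ref))) {
    stop("reference needs columns sf_cpd and sensitivity")
  }
  if (any(ref$sf_cpd < min(curve$sf_grid) | ref$sf_cpd > max(curve$sf_grid))) {
    stop("reference samples outside the curve's spatial-frequency range")
  }
  if (fit_lambda && nrow(ref) < 3L) stop("need at least 3 samples to fit lambda")
  interp <- function(v) {
    exp(stats::approx(log(curve$sf_grid), log(pmax(v, 1e-300)),
                      xout = log(ref$sf_cpd))$y)
  }
  m <- interp(curve$csf_M)
  p <- interp(curve$csf_P)
  logr <- log(ref$sensitivity)
  gain_for <- function(lam) {
    mix <- lam * m + (1 - lam) * p
    exp(mean(logr - log(pmax(mix, 1e-300))))
  }
  ss_for <- function(lam) {
    mix <- lam * m + (1 - lam) * p
    a <- gain_for(lam)
    sum((logr - log(pmax(a * mix, 1e-300)))^2)
  }
  lam <- curve$combination$lam
  if (fit_lambda) {
    lam <- stats::optimize(ss_for, interval = c(0, 1))$minimum
  }
  combination_params(A_gain = gain_for(lam), lam = lam)
}

#' Write a predicted CSF to CSV
#'
#' Columns `sf_cpd,csf_total,csf_M,csf_P`.
#' @param curve a `csf_curve`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_csf_csv <- function(curve, path) {
  stopifnot(inherits(curve, "csf_curve"))
  d <- data.frame(sf_cpd = curve$sf_grid, csf_total = curve$sensitivity,
                  csf_M = curve$csf_M, csf_P = curve$csf_P)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
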