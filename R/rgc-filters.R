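# Spatial (difference-of-Gaussians) and temporal (linear cascade) transfer
# functions of modeled magno- and parvocellular retinal ganglion cells,
# low-frequency sensitivity policies, and DoG fitting to a tabulated CSF.

#' Difference-of-Gaussians spatial kernel parameters
#'
#' Frequency-domain DoG:
#' `K(f) = C (Kc pi rc^2 exp(-(pi rc g f)^2) - Ks pi rs^2 exp(-(pi rs g f)^2))`
#' with `g = gamma` a foveal scaling factor; each Gaussian is the exact 2D
#' Fourier transform of a spatial Gaussian mechanism `exp(-(r / rc)^2)`, the
#' convention of the physiological receptive-field literature the parameter
#' tables come from. Radii are in deg, `f` in cycles/deg.
#'
#' @param Kc,rc center strength and radius (deg).
#' @param Ks,rs surround strength and radius (deg), `rs > rc`.
#' @param gamma spatial-frequency scaling (default 0.5, foveal receptive
#'   fields under cortical magnification).
#' @param C overall scale (default 1; absorbed by the global CSF gain).
#' @return An object of class `dog_params`.
#' @export
dog_params <- function(Kc, rc, Ks, rs, gamma = 0.5, C = 1) {
  if (rc >= rs) stop("center radius rc must be smaller than surround radius rs")
  if (Kc < 0 || Ks < 0) stop("Kc and Ks must be non-negative")
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(C = C, Kc = Kc, rc = rc, Ks = Ks, rs = rs, gamma = gamma),
            class = "dog_params")
}

#' Temporal transfer-function parameters (cascade model)
#'
#' `H(w) = A exp(-i r 2 pi w D) (1 - Hs / (1 + i r 2 pi w tauS))
#'         (1 / (1 + i r 2 pi w tauL))^N`
#' with `w` in Hz, time constants and the pure delay `D` in ms (converted to s
#' internally so the products are dimensionless), and `r = rho` a scaling for
#' large-stimulus effects. The delay factor has unit modulus and never affects
#' `|H|` or anything downstream.
#'
#' @param N number of low-pass stages (>= 1).
#' @param A gain.
#' @param t_delay pure delay (ms).
#' @param Hs high-pass strength in `[0, 1]`; `Hs = 1` gives exactly zero DC
#'   gain.
#' @param tauL,tauS low-pass and high-pass time constants (ms), > 0.
#' @param rho temporal-frequency scaling (default 1/1.6).
#' @return An object of class `temporal_params`.
#' @export
temporal_params <- function(N, A, t_delay, Hs, tauL, tauS, rho = 1 / 1.6) {
  if (N < 1 || N != round(N)) stop("N must be a positive integer")
  if (Hs < 0 || Hs > 1) stop("Hs must be in [0, 1]")
  if (tauL <= 0 || tauS <= 0) stop("time constants must be positive")
  structure(list(N = as.integer(N), A = A, t_delay = t_delay, Hs = Hs,
                 tauL = tauL, tauS = tauS, rho = rho),
            class = "temporal_params")
}

#' Modeled retinal ganglion cell (M or P class)
#'
#' Default parameters are the physiological values used throughout the model:
#'
#' Spatial (deg): M `rc = 0.10, Kc = 148, rs = 0.72, Ks = 1.1`;
#' P `rc = 0.03, Kc = 353.2, rs = 0.18, Ks = 4.4`; `gamma = 0.5`.
#'
#' Temporal (ms): M `N = 30, A = 499.77, D = 2, Hs = 1, tauL = 1.1,
#' tauS = 2.23`; P `N = 38, A = 67.59, D = 3.5, Hs = 0.69, tauL = 1.27,
#' tauS = 29.36`; `rho = 1/1.6`.
#'
#' @param cell_class `"M"` or `"P"`.
#' @param dog optional [dog_params()] override.
#' @param temporal optional [temporal_params()] override.
#' @return An object of class `cell_model`.
#' @export
cell_model <- function(cell_class = c("M", "P"), dog = NULL, temporal = NULL) {
  cell_class <- match.arg(cell_class)
  if (is.null(dog)) {
    dog <- if (cell_class == "M") {
      dog_params(Kc = 148, rc = 0.10, Ks = 1.1, rs = 0.72)
    } else {
      dog_params(Kc = 353.2, rc = 0.03, Ks = 4.4, rs = 0.18)
    }
  }
  if (is.null(temporal)) {
    temporal <- if (cell_class == "M") {
      temporal_params(N = 30, A = 499.77, t_delay = 2, Hs = 1,
                      tauL = 1.1, tauS = 2.23)
    } else {
      temporal_params(N = 38, A = 67.59, t_delay = 3.5, Hs = 0.69,
                      tauL = 1.27, tauS = 29.36)
    }
  }
  stopifnot(inherits(dog, "dog_params"), inherits(temporal, "temporal_params"))
  structure(list(cell_class = cell_class, dog = dog, temporal = temporal),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf(
    "<cell_model %s> DoG: Kc=%g rc=%g Ks=%g rs=%g gamma=%g | cascade: N=%d A=%g Hs=%g tauL=%g tauS=%g ms\n",
    x$cell_class, x$dog$Kc, x$dog$rc, x$dog$Ks, x$dog$rs, x$dog$gamma,
    x$temporal$N, x$temporal$A, x$temporal$Hs, x$temporal$tauL, x$temporal$tauS
  ))
  invisible(x)
}

#' Both default cell models
#' @return Named list `list(M = cell_model("M"), P = cell_model("P"))`.
#' @export
default_cell_models <- function() {
  list(M = cell_model("M"), P = cell_model("P"))
}

#' DoG spatial amplitude K(f)
#'
#' @param sf spatial frequency (cycles/deg), vectorized, >= 0.
#' @param p a [dog_params()].
#' @return Numeric vector `K(sf)`.
#' @export
dog_amplitude <- function(sf, p) {
  stopifnot(inherits(p, "dog_params"))
  if (any(sf < 0)) stop("sf must be non-negative")
  p$C * (p$Kc * pi * p$rc^2 * exp(-(pi * p$rc * p$gamma * sf)^2) -
           p$Ks * pi * p$rs^2 * exp(-(pi * p$rs * p$gamma * sf)^2))
}

#' Temporal transfer function H(omega)
#'
#' @param tf temporal frequency (Hz), vectorized, >= 0.
#' @param p a [temporal_params()].
#' @return Complex vector `H(tf)`.
#' @export
temporal_transfer <- function(tf, p) {
  stopifnot(inherits(p, "temporal_params"))
  if (any(tf < 0)) stop("tf must be non-negative")
  w <- p$rho * 2 * pi * tf  # rad/s after ms -> s conversion below
  delay <- exp(-1i * w * p$t_delay / 1000)
  hp <- 1 - p$Hs / (1 + 1i * w * p$tauS / 1000)
  lp <- (1 / (1 + 1i * w * p$tauL / 1000))^p$N
  p$A * delay * hp * lp
}

#' Space-time separable receptive-field transfer function RF(f, omega)
#'
#' `RF(f, w) = K(f) H(w)`. With vector arguments, returns the outer-product
#' matrix (`length(sf)` x `length(tf)`).
#'
#' @param sf spatial frequencies (cycles/deg).
#' @param tf temporal frequencies (Hz).
#' @param cell a [cell_model()].
#' @return Complex matrix `sf x tf` (dropped to a vector if either input is
#'   scalar... it stays a matrix; use `drop()` if needed).
#' @export
rf_transfer <- function(sf, tf, cell) {
  stopifnot(inherits(cell, "cell_model"))
  outer(dog_amplitude(sf, cell$dog), temporal_transfer(tf, cell$temporal))
}

#' Low-temporal-frequency sensitivity policy
#'
#' The model assumes no sensitivity to unchanging stimuli; responses below a
#' low temporal frequency are discarded (`hard_cutoff`) or attenuated as a
#' power law of frequency (`power_law`), reflecting adaptation-limited
#' low-frequency behavior of retinal neurons.
#'
#' @param mode `"hard_cutoff"` or `"power_law"`.
#' @param cutoff cutoff frequency (Hz), default 0.63 (discards the first two
#'   temporal bins of a 3.2 s trial).
#' @param exponent power-law slope on power (used when `mode = "power_law"`),
#'   default 1.
#' @return An object of class `low_freq_policy`.
#' @export
low_freq_policy <- function(mode = c("hard_cutoff", "power_law"),
                            cutoff = 0.63, exponent = 1) {
  mode <- match.arg(mode)
  if (cutoff < 0) stop("cutoff must be non-negative")
  structure(list(mode = mode, cutoff = cutoff, exponent = exponent),
            class = "low_freq_policy")
}

#' Per-bin weights implementing a low-frequency policy
#'
#' `hard_cutoff`: weight 0 below the cutoff, 1 at or above it. The comparison
#' carries a 1% relative tolerance so that a printed, rounded cutoff (0.63 Hz)
#' matches the 0.625 Hz bin of a 3.2 s trial: exactly the 0 and 0.3125 Hz bins
#' are discarded there. `power_law`: weight `min(1, (tf/cutoff)^exponent)`,
#' with the 0 Hz bin always zeroed. A zero cutoff gives identity weights.
#'
#' @param tf_grid uniform temporal-frequency grid (Hz).
#' @param policy a [low_freq_policy()].
#' @return Numeric weights in `[0, 1]`, one per bin.
#' @export
low_freq_weight <- function(tf_grid, policy) {
  stopifnot(inherits(policy, "low_freq_policy"))
  if (policy$cutoff <= 0) return(rep(1, length(tf_grid)))
  if (policy$mode == "hard_cutoff") {
    as.numeric(.tf_keep(tf_grid, policy$cutoff))
  } else {
    w <- pmin(1, (tf_grid / policy$cutoff)^policy$exponent)
    w[tf_grid == 0] <- 0
    w
  }
}

# DoG in the reduced (degeneracy-free) parameterization used by the fitter:
# K(f) = Gc exp(-pi (rc g f)^2) - Gs exp(-pi (rs g f)^2)
# with Gc = C Kc pi rc^2, Gs = C Ks pi rs^2.
.dog_reduced <- function(sf, gc, rc, gs, rs, gamma) {
  gc * exp(-(pi * rc * gamma * sf)^2) - gs * exp(-(pi * rs * gamma * sf)^2)
}

#' Fit a difference-of-Gaussians kernel to a tabulated CSF
#'
#' Least-squares fit in the log-sensitivity domain of `|K(f)|` to
#' `(sf, sensitivity)` samples, via Levenberg-Marquardt with multiple starts.
#' A free overall gain `C` is always profiled out analytically (in log units
#' it is an intercept). Because `C` trades off exactly against `Kc` and `Ks`,
#' individual strengths are identified only up to that gain: recovery is
#' meaningful for `rc`, `rs`, the products `C*Kc`, `C*Ks` and the
#' surround/center balance `Ks rs^2 / (Kc rc^2)`.
#'
#' @param csf_samples data.frame with columns `sf_cpd` and `sensitivity`
#'   (positive), >= 4 rows spanning at least one decade of spatial frequency.
#' @param fixed named list of parameters to hold fixed, a subset of
#'   `Kc, rc, Ks, rs` (values in the [dog_params()] convention).
#' @param start optional [dog_params()] giving starting values; defaults to
#'   the M-cell table values.
#' @param gamma spatial-frequency scaling used during the fit.
#' @return An object of class `dog_fit`: list with `params` (fitted
#'   [dog_params()]), `converged` (logical), `rss` (residual sum of squares in
#'   log units), `fitted` (model sensitivities at the sample frequencies),
#'   `message` (optimizer diagnostics). Non-convergence is flagged, not
#'   raised.
#' @export
fit_dog_to_csf <- function(csf_samples, fixed = list(), start = NULL,
                           gamma = 0.5) {
  d <- as.data.frame(csf_samples)
  if (!all(c("sf_cpd", "sensitivity") %in% names(d))) {
    stop("csf_samples needs columns sf_cpd and sensitivity")
  }
  d <- d[order(d$sf_cpd), ]
  if (nrow(d) < 4L) stop("need at least 4 samples")
  if (max(d$sf_cpd) / min(d$sf_cpd) < 10) {
    stop("samples must span at least one decade of spatial frequency")
  }
  if (any(d$sensitivity <= 0)) stop("sensitivities must be positive")
  bad <- setdiff(names(fixed), c("Kc", "rc", "Ks", "rs"))
  if (length(bad) > 0L) stop("cannot fix parameter(s): ", paste(bad, collapse = ", "))
  if (is.null(start)) start <- cell_model("M")$dog

  logs <- log(d$sensitivity)
  par_full <- function(theta, free) {
    p <- c(Kc = start$Kc, rc = start$rc, Ks = start$Ks, rs = start$rs)
    p[names(fixed)] <- unlist(fixed)
    p[free] <- exp(theta)
    p
  }
  free <- setdiff(c("Kc", "rc", "Ks", "rs"), names(fixed))
  resid_fn <- function(theta) {
    p <- par_full(theta, free)
    k <- .dog_reduced(d$sf_cpd,
                      gc = p[["Kc"]] * pi * p[["rc"]]^2, rc = p[["rc"]],
                      gs = p[["Ks"]] * pi * p[["rs"]]^2, rs = p[["rs"]],
                      gamma = gamma)
    log(pmax(abs(k), 1e-12)) - logs
  }

  # gain is profiled out by an extra intercept-like free log-gain
  resid_gain <- function(theta) {
    r <- resid_fn(theta)
    r - mean(r)
  }

  starts <- list(1, 0.5, 2, 0.25)
  best <- NULL
  for (scale in starts) {
    th0 <- log(c(Kc = start$Kc, rc = start$rc * scale,
                 Ks = start$Ks, rs = start$rs * scale)[free])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_gain,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    p_try <- par_full(fit$par, free)
    if (p_try[["rc"]] >= p_try[["rs"]]) next  # center/surround roles swapped
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }

  if (is.null(best)) {
    return(structure(list(params = NULL, converged = FALSE, rss = Inf,
                          fitted = NULL,
                          message = "no start converged to a valid center/surround ordering"),
                     class = "dog_fit"))
  }
  p <- par_full(best$fit$par, free)
  gain_resid <- resid_fn(best$fit$par)
  C <- exp(-mean(gain_resid))  # sensitivity = C * |K|
  params <- dog_params(Kc = p[["Kc"]], rc = p[["rc"]], Ks = p[["Ks"]],
                       rs = p[["rs"]], gamma = gamma, C = C)
  fitted <- abs(dog_amplitude(d$sf_cpd, params))
  structure(
    list(params = params, converged = best$fit$info %in% 1:3, rss = best$rss,
         fitted = fitted, message = best$fit$message),
    class = "dog_fit"
  )
}

#' @export
print.dog_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("<dog_fit> FAILED:", x$message, "\n")
    return(invisible(x))
  }
  p <- x$params
  bal <- p$Ks * p$rs^2 / (p$Kc * p$rc^2)
  cat(sprintf(
    "<dog_fit%s> Kc=%.4g rc=%.4g Ks=%.4g rs=%.4g C=%.4g (surround/center balance %.3f), log-RSS %.3g\n",
    if (x$converged) "" else " (not converged)",
    p$Kc, p$rc, p$Ks, p$rs, p$C, bal, x$rss
  ))
  invisible(x)
}

#' Integrated surround/center balance of a DoG kernel
#'
#' `Ks rs^2 / (Kc rc^2)`: the ratio of integrated surround to center
#' strength; 1 means exact excitation/inhibition balance (zero response at
#' f = 0).
#'
#' @param p a [dog_params()].
#' @return A number in `[0, Inf)`.
#' @export
dog_surround_balance <- function(p) {
  stopifnot(inherits(p, "dog_params"))
  p$Ks * p$rs^2 / (p$Kc * p$rc^2)
}
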