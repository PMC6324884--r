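# Fixational drift generation, segmentation and trace I/O.

#' Eye-position trace
#'
#' Container for one uniformly sampled 2D gaze trajectory. Positions are in
#' arcmin, time in seconds. This is the trajectory `xi(t)` that displaces the
#' stimulus on the retina.
#'
#' @param t numeric vector of sample times (s), uniformly spaced.
#' @param x,y numeric vectors of horizontal/vertical gaze offset (arcmin).
#' @param trial_id opaque label for the trial.
#'
#' @return An object of class `eye_trace`: a list with fields `t`, `x`, `y`,
#'   `trial_id` and the derived sampling rate `fs` (samples/s).
#' @export
eye_trace <- function(t, x, y, trial_id = "trace") {
  n <- length(t)
  if (n < 2L) stop("an eye trace needs at least 2 samples")
  if (length(x) != n || length(y) != n) stop("t, x and y must have equal length")
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y))) {
    stop("eye trace contains non-finite values")
  }
  dt <- diff(t)
  if (max(abs(dt - dt[1L])) >= 1e-9) {
    stop("eye trace must be uniformly sampled (max |dt - dt[1]| < 1e-9 s)")
  }
  structure(
    list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
         trial_id = as.character(trial_id)[1L], fs = 1 / dt[1L]),
    class = "eye_trace"
  )
}

#' @export
print.eye_trace <- function(x, ...) {
  cat(sprintf(
    "<eye_trace '%s'> %d samples @ %.6g Hz (%.4g s), rms excursion %.3g arcmin\n",
    x$trial_id, length(x$t), x$fs, length(x$t) / x$fs,
    sqrt(mean(x$x^2 + x$y^2))
  ))
  invisible(x)
}

#' Diffusion specification for Brownian drift
#'
#' The diffusion coefficient follows the per-axis convention: each axis takes
#' independent Gaussian increments of variance `2 * D * dt`, so the planar mean
#' squared displacement grows as `4 * D * t`. Units are arcmin^2/s, the scale
#' on which normal fixational drift is around D = 100-350 and simulated
#' retinal stabilization is D = 2.
#'
#' @param D diffusion coefficient (arcmin^2/s), `D >= 0`.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return An object of class `diffusion_spec`.
#' @export
diffusion_spec <- function(D, seed = NULL) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D < 0) {
    stop("D must be a single finite non-negative number")
  }
  structure(list(D = D, seed = seed), class = "diffusion_spec")
}

#' Simulate fixational ocular drift as 2D Brownian motion
#'
#' Generates a random-walk gaze trajectory starting at (0, 0): each axis is the
#' cumulative sum of i.i.d. zero-mean Gaussian increments with variance
#' `2 * spec$D * dt` (see [diffusion_spec()] for the convention).
#'
#' @param duration trace length (s), > 0.
#' @param fs sampling rate (samples/s), default 1000.
#' @param spec a [diffusion_spec()].
#' @param trial_id label for the trace.
#' @return An [eye_trace()] with `round(duration * fs)` samples.
#' @export
simulate_brownian_drift <- function(duration, fs = 1000, spec,
                                    trial_id = "brownian") {
  if (!is.numeric(duration) || duration <= 0) stop("duration must be positive")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  stopifnot(inherits(spec, "diffusion_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- round(duration * fs)
  if (n < 2L) stop("duration * fs must give at least 2 samples")
  sd_inc <- sqrt(2 * spec$D / fs)
  x <- c(0, cumsum(stats::rnorm(n - 1L, 0, sd_inc)))
  y <- c(0, cumsum(stats::rnorm(n - 1L, 0, sd_inc)))
  eye_trace(t = (0:(n - 1L)) / fs, x = x, y = y, trial_id = trial_id)
}

#' Simulate an ensemble of independent Brownian drift traces
#'
#' Seeds the RNG once and draws `n_trials` independent traces, so the ensemble
#' is reproducible as a whole.
#'
#' @param n_trials number of traces.
#' @param duration,fs as in [simulate_brownian_drift()].
#' @param D diffusion coefficient (arcmin^2/s).
#' @param seed optional integer seed applied once before the first trace.
#' @return A list of [eye_trace()] objects.
#' @export
simulate_drift_ensemble <- function(n_trials, duration, fs = 1000, D,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- diffusion_spec(D, seed = NULL)
  lapply(seq_len(n_trials), function(i) {
    simulate_brownian_drift(duration, fs, spec,
                            trial_id = sprintf("brownian_%03d", i))
  })
}

#' Segment a trace into drift and saccade periods by a speed threshold
#'
#' Instantaneous speed is estimated by central finite differences (one-sided at
#' the ends), converted to deg/s, and smoothed with a moving-average window.
#' Samples whose smoothed speed exceeds the threshold are labeled `saccade`;
#' all others `drift`. The default 2 deg/s threshold is the standard criterion
#' for separating fixational drift from (micro)saccades.
#'
#' @param trace an [eye_trace()].
#' @param threshold speed threshold (deg/s).
#' @param smooth_window moving-average window (s); default 15 ms.
#' @return An object of class `segment_labels`: list with `labels` (character,
#'   per sample), `events` (data.frame `type`, `start`, `end` of maximal runs),
#'   `speed` (smoothed speed, deg/s), `threshold`, `smooth_window`.
#' @export
segment_by_speed <- function(trace, threshold = 2, smooth_window = 0.015) {
  stopifnot(inherits(trace, "eye_trace"))
  n <- length(trace$t)
  dt <- 1 / trace$fs
  nw <- max(1L, round(smooth_window * trace$fs))
  if (nw %% 2L == 0L) nw <- nw + 1L
  if (nw > n) stop("trace shorter than smoothing window")

  vx <- numeric(n)
  vy <- numeric(n)
  vx[2:(n - 1L)] <- (trace$x[3:n] - trace$x[1:(n - 2L)]) / (2 * dt)
  vy[2:(n - 1L)] <- (trace$y[3:n] - trace$y[1:(n - 2L)]) / (2 * dt)
  vx[1L] <- (trace$x[2L] - trace$x[1L]) / dt
  vy[1L] <- (trace$y[2L] - trace$y[1L]) / dt
  vx[n] <- (trace$x[n] - trace$x[n - 1L]) / dt
  vy[n] <- (trace$y[n] - trace$y[n - 1L]) / dt
  speed <- sqrt(vx^2 + vy^2) / 60  # arcmin/s -> deg/s

  if (nw > 1L) {
    half <- (nw - 1L) %/% 2L
    padded <- c(rep(speed[1L], half), speed, rep(speed[n], half))
    sm <- as.numeric(stats::filter(padded, rep(1 / nw, nw), sides = 2))
    speed_sm <- sm[(half + 1L):(half + n)]
  } else {
    speed_sm <- speed
  }

  labels <- ifelse(speed_sm > threshold, "saccade", "drift")
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  events <- data.frame(type = r$values, start = starts, end = ends,
                       stringsAsFactors = FALSE)
  structure(
    list(labels = labels, events = events, speed = speed_sm,
         threshold = threshold, smooth_window = smooth_window),
    class = "segment_labels"
  )
}

#' @export
print.segment_labels <- function(x, ...) {
  n_sac <- sum(x$events$type == "saccade")
  cat(sprintf(
    "<segment_labels> %d samples, %.1f%% drift, %d saccade event(s), threshold %g deg/s\n",
    length(x$labels), 100 * mean(x$labels == "drift"), n_sac, x$threshold
  ))
  invisible(x)
}

#' Extract saccade-free drift epochs from a segmented trace
#'
#' Returns the maximal all-drift subtraces of at least `min_duration`. Epoch
#' duration is counted as `n_samples / fs`.
#'
#' @param trace an [eye_trace()].
#' @param labels the [segment_by_speed()] result for the same trace.
#' @param min_duration minimum epoch duration (s).
#' @return A list of [eye_trace()] objects (possibly empty).
#' @export
select_drift_epochs <- function(trace, labels, min_duration) {
  stopifnot(inherits(trace, "eye_trace"), inherits(labels, "segment_labels"))
  if (length(labels$labels) != length(trace$t)) {
    stop("labels do not match the trace length")
  }
  ev <- labels$events[labels$events$type == "drift", , drop = FALSE]
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(ev))) {
    len <- ev$end[i] - ev$start[i] + 1L
    if (len / trace$fs >= min_duration && len >= 2L) {
      k <- k + 1L
      idx <- ev$start[i]:ev$end[i]
      out[[k]] <- eye_trace(
        t = trace$t[idx], x = trace$x[idx], y = trace$y[idx],
        trial_id = sprintf("%s_epoch%d", trace$trial_id, k)
      )
    }
  }
  out
}

#' Read eye traces from CSV
#'
#' Expects header `trial_id,t_s,x_arcmin,y_arcmin`, one row per sample, samples
#' of a trial contiguous and time-ordered.
#'
#' @param path file path.
#' @return A list of [eye_trace()] objects (empty for a header-only file).
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("trial_id", "t_s", "x_arcmin", "y_arcmin")
  if (!identical(names(d), expected)) {
    stop(sprintf("malformed header: expected '%s', got '%s'",
                 paste(expected, collapse = ","),
                 paste(names(d), collapse = ",")))
  }
  if (nrow(d) == 0L) return(list())
  bad <- which(!is.finite(d$t_s) | !is.finite(d$x_arcmin) | !is.finite(d$y_arcmin))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite value at row %d", bad[1L] + 1L))  # +1 for header
  }
  ids <- unique(d$trial_id)
  lapply(ids, function(id) {
    rows <- which(d$trial_id == id)
    t <- d$t_s[rows]
    dt <- diff(t)
    if (length(dt) == 0L) stop(sprintf("trial '%s' has a single sample", id))
    gap <- which(abs(dt - dt[1L]) >= 1e-9)
    if (length(gap) > 0L) {
      stop(sprintf("non-uniform timestamps at row %d (trial '%s')",
                   rows[gap[1L] + 1L] + 1L, id))
    }
    eye_trace(t = t, x = d$x_arcmin[rows], y = d$y_arcmin[rows], trial_id = id)
  })
}

#' Write eye traces to CSV
#'
#' Inverse of [read_trace_csv()]; positions round-trip to better than
#' 1e-6 arcmin.
#'
#' @param traces a list of [eye_trace()] objects (or a single one).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "eye_trace")) traces <- list(traces)
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(trial_id = tr$trial_id, t_s = tr$t,
               x_arcmin = tr$x, y_arcmin = tr$y, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(trial_id = character(), t_s = numeric(),
                       x_arcmin = numeric(), y_arcmin = numeric())
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
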