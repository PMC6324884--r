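# Scripted, seeded model experiments with logged provenance, and fixture
# generation for the test suite.

# Default configurations per experiment. The `quick` profile trades trial
# count and grid resolution for runtime while preserving every qualitative
# property.
.experiment_defaults <- function(name, quick = FALSE) {
  base <- list(
    D = 250, n_trials = if (quick) 30 else 100,
    duration = 3.2, fs = 1000,
    sf_grid = if (quick) default_sf_grid(16) else default_sf_grid(),
    n_orientations = if (quick) 4 else 8, n_phases = 4,
    lam = 0.57, A_gain = 1, cutoff = 0.63
  )
  extra <- switch(name,
    fig2_power = list(sf_grid = if (quick) default_sf_grid(16) else
      default_sf_grid(24)),
    fig3_static = list(),
    fig4_modulated = list(omegas = if (quick) c(0, 2, 3, 4, 6) else 0:6),
    fig5_stabilized = list(D_values = c(250, 2)),
    dog_fit = list(),
    stop("unknown experiment: ", name)
  )
  utils::modifyList(base, extra)
}

#' Run one of the packaged model experiments
#'
#' Available experiments:
#' \describe{
#'   \item{`fig2_power`}{DC vs dynamic power of the retinal input across
#'     spatial frequency, with and without fixational drift.}
#'   \item{`fig3_static`}{Predicted CSF for static gratings with and without
#'     drift.}
#'   \item{`fig4_modulated`}{Predicted CSFs for flickered gratings over a
#'     grid of modulation frequencies, and the band-pass/low-pass transition
#'     frequency.}
#'   \item{`fig5_stabilized`}{Predicted CSFs under normal drift (D = 250) and
#'     simulated retinal stabilization (D = 2).}
#'   \item{`dog_fit`}{Fits a difference-of-Gaussians kernel to the model's
#'     own drift-condition CSF and reports the surround/center balance the
#'     fit requires, compared to the physiological value.}
#' }
#'
#' Per-condition CSVs, a descriptors/summary JSON (including seed and a
#' config hash) and a run log are written to `out_dir`. Deterministic given
#' `seed`.
#'
#' @param name experiment name (see above).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param quick reduced-size profile (fewer trials, coarser grids).
#' @param config named list of overrides merged into the defaults.
#' @return The summary list, invisibly.
#' @export
run_experiment <- function(name, out_dir, seed = 1, quick = FALSE,
                           config = list()) {
  cfg <- utils::modifyList(.experiment_defaults(name, quick), config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, paste0(name, ".log"))
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  cat(sprintf("run %s seed=%d quick=%s\n", name, seed, quick),
      file = log_path)

  cp <- combination_params(A_gain = cfg$A_gain, lam = cfg$lam)
  policy <- low_freq_policy(cutoff = cfg$cutoff)
  cond <- function(...) {
    csf_condition(D = cfg$D, n_trials = cfg$n_trials, seed = seed,
                  duration = cfg$duration, fs = cfg$fs, ...)
  }
  run_one <- function(condition) {
    predict_csf(condition, cp = cp, policy = policy, sf_grid = cfg$sf_grid,
                n_orientations = cfg$n_orientations, n_phases = cfg$n_phases)
  }

  summary <- list(experiment = name, seed = seed, quick = quick,
                  config_hash = rlang::hash(cfg))

  if (name == "fig2_power") {
    stim <- grating_stimulus(sf = 1, duration = cfg$duration)
    drift <- simulate_drift_ensemble(cfg$n_trials, cfg$duration, cfg$fs,
                                     cfg$D, seed = seed)
    spec_drift <- input_power_spectrum(drift, stim, cfg$sf_grid,
                                       cfg$n_orientations, cfg$n_phases)
    none <- .condition_traces(csf_condition("none", duration = cfg$duration,
                                            fs = cfg$fs))
    spec_none <- input_power_spectrum(none, stim, cfg$sf_grid,
                                      cfg$n_orientations, cfg$n_phases)
    dec_drift <- power_decomposition(spec_drift, cfg$cutoff)
    dec_none <- power_decomposition(spec_none, cfg$cutoff)
    utils::write.csv(dec_drift, file.path(out_dir, "decomposition_drift.csv"),
                     row.names = FALSE)
    utils::write.csv(dec_none, file.path(out_dir, "decomposition_nodrift.csv"),
                     row.names = FALSE)
    write_spectrum_csv(spec_drift, file.path(out_dir, "spectrum_drift.csv"))
    mono_range <- cfg$sf_grid <= 30
    summary$dynamic_power_increases_to_30cpd <-
      !is.unsorted(dec_drift$dynamic_power[mono_range])
    summary$dc_power_decreasing <- !is.unsorted(rev(dec_drift$dc_power))
    log_line("decompositions written; monotone dynamic power: %s",
             summary$dynamic_power_increases_to_30cpd)
  } else if (name == "fig3_static") {
    curves <- list(drift = run_one(cond("brownian")),
                   no_drift = run_one(cond("none")))
    summary$descriptors <- lapply(curves, shape_descriptors)
    for (nm in names(curves)) {
      write_csf_csv(curves[[nm]], file.path(out_dir, paste0("csf_", nm, ".csv")))
    }
    log_line("drift CSF classified %s, no-drift %s",
             summary$descriptors$drift$shape_class,
             summary$descriptors$no_drift$shape_class)
  } else if (name == "fig4_modulated") {
    curves <- predict_csf_family(cfg$omegas, cond("brownian"), cp = cp,
                                 policy = policy, sf_grid = cfg$sf_grid,
                                 n_orientations = cfg$n_orientations,
                                 n_phases = cfg$n_phases)
    tr <- transition_frequency(curves, cfg$omegas)
    summary$transition_hz <- as.numeric(tr)
    summary$classes <- as.list(attr(tr, "classes"))
    for (nm in names(curves)) {
      write_csf_csv(curves[[nm]],
                    file.path(out_dir, sprintf("csf_omega_%s.csv", nm)))
    }
    log_line("transition at %s Hz", format(summary$transition_hz))
  } else if (name == "fig5_stabilized") {
    curves <- lapply(cfg$D_values, function(D) {
      c2 <- cond("brownian")
      c2$D <- D
      run_one(c2)
    })
    names(curves) <- paste0("D", cfg$D_values)
    summary$descriptors <- lapply(curves, shape_descriptors)
    summary$peak_sensitivity <- lapply(curves, function(cv) max(cv$sensitivity))
    for (nm in names(curves)) {
      write_csf_csv(curves[[nm]], file.path(out_dir, paste0("csf_", nm, ".csv")))
    }
    log_line("peaks: %s", paste(sprintf("%s=%.3g cpd", names(curves),
      vapply(summary$descriptors, function(d) d$peak_sf, numeric(1))),
      collapse = ", "))
  } else if (name == "dog_fit") {
    curve <- run_one(cond("brownian"))
    keep <- curve$sensitivity > 0
    samples <- data.frame(sf_cpd = curve$sf_grid[keep],
                          sensitivity = curve$sensitivity[keep])
    fit <- fit_dog_to_csf(samples)
    utils::write.csv(samples, file.path(out_dir, "csf_target.csv"),
                     row.names = FALSE)
    summary$fit_converged <- fit$converged
    summary$fitted_balance <- if (!is.null(fit$params))
      dog_surround_balance(fit$params) else NA
    summary$physiological_balance_M <-
      dog_surround_balance(cell_model("M")$dog)
    log_line("fitted surround/center balance %.3f (physiological M: %.3f)",
             summary$fitted_balance, summary$physiological_balance_M)
  }

  jsonlite::write_json(summary, file.path(out_dir, paste0(name, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Generate the small file fixtures used by the test suite
#'
#' Writes, deterministically given `seed`:
#' \itemize{
#'   \item `traces.csv`: 5 Brownian traces (D = 250, 3.2 s at 1 kHz), one
#'     constant trace, and one constructed trace with a single 10 deg/s,
#'     20 ms saccade between two stationary segments.
#'   \item `spectrum.csv`: a tiny input spectrum in long format.
#'   \item `dog_csf.csv`: synthetic CSF samples generated from a known DoG
#'     kernel.
#' }
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return Named character vector of the written paths, invisibly.
#' @export
generate_fixtures <- function(out_dir, seed = 1) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  fs <- 1000

  traces <- simulate_drift_ensemble(5, 3.2, fs, D = 250)
  n <- round(3.2 * fs)
  constant <- eye_trace(t = (0:(n - 1)) / fs, x = numeric(n), y = numeric(n),
                        trial_id = "constant")
  # 1 s still, 20 ms ramp at 10 deg/s (600 arcmin/s), 1 s still
  n_still <- fs
  n_ramp <- round(0.02 * fs)
  x <- c(rep(0, n_still), 600 * (1:n_ramp) / fs,
         rep(600 * n_ramp / fs, n_still))
  nt <- length(x)
  saccade <- eye_trace(t = (0:(nt - 1)) / fs, x = x, y = numeric(nt),
                       trial_id = "saccade")
  trace_path <- file.path(out_dir, "traces.csv")
  write_trace_csv(c(traces, list(constant, saccade)), trace_path)

  stim <- grating_stimulus(sf = 1, duration = 0.5,
                           envelope = envelope_spec(ramp_duration = 0.1))
  spec <- input_power_spectrum(traces[1:2], stim, sf_grid = c(1, 4, 16),
                               n_orientations = 2, n_phases = 1)
  spec_path <- file.path(out_dir, "spectrum.csv")
  write_spectrum_csv(spec, spec_path)

  sf <- default_sf_grid(12, 0.2, 40)
  p <- cell_model("M")$dog
  dog_path <- file.path(out_dir, "dog_csf.csv")
  utils::write.csv(
    data.frame(sf_cpd = sf, sensitivity = abs(dog_amplitude(sf, p))),
    dog_path, row.names = FALSE
  )

  invisible(c(traces = trace_path, spectrum = spec_path, dog_csf = dog_path))
}
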