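# Response spectra, CSF integration, combination, descriptors, gain fitting.

# small, fast input spectrum shared by several blocks
make_spec <- function(D = 250, n_trials = 20, seed = 1, temporal_mod = 0,
                      sf_grid = default_sf_grid(12), envelope = envelope_spec()) {
  traces <- if (D == 0) list(constant_trace(3.2)) else
    simulate_drift_ensemble(n_trials, 3.2, 1000, D, seed = seed)
  input_power_spectrum(traces,
                       grating_stimulus(1, temporal_mod = temporal_mod,
                                        envelope = envelope),
                       sf_grid, n_orientations = 4)
}

# hand-built spectrum with a single occupied (sf, tf) bin
unit_bin_spec <- function(sf_grid, tf_max = 10, df = 0.5, i_sf, i_tf, value) {
  tf <- seq(0, tf_max, by = df)
  power <- matrix(0, length(sf_grid), length(tf))
  power[i_sf, i_tf] <- value
  structure(list(sf_grid = sf_grid, tf_grid = tf, power = power, df = df,
                 duration = 1 / df, fs = 2 * max(tf), n_trials = 1,
                 n_orientations = 1, n_phases = 1),
            class = "input_spectrum")
}

test_that("response power is the input power through |RF|^2", {
  spec <- unit_bin_spec(c(0.5, 1, 4), i_sf = 2, i_tf = 21, value = 3)  # 10 Hz
  cell <- cell_model("P")
  o <- response_power(spec, cell)
  expect_equal(o$power[2, 21],
               3 * Mod(dog_amplitude(1, cell$dog) *
                         temporal_transfer(10, cell$temporal))^2)
  expect_equal(sum(o$power[-2, ]) + sum(o$power[2, -21]), 0)

  zero <- unit_bin_spec(c(0.5, 1, 4), i_sf = 1, i_tf = 1, value = 0)
  expect_equal(max(response_power(zero, cell)$power), 0)

  # M cells never respond at DC, whatever the input
  dc <- unit_bin_spec(c(0.5, 1, 4), i_sf = 3, i_tf = 1, value = 100)
  expect_equal(max(response_power(dc, cell_model("M"))$power), 0)
})

test_that("a truly static input yields zero sensitivity everywhere", {
  spec <- make_spec(D = 0, envelope = envelope_spec("none"))
  for (cls in c("M", "P")) {
    csf <- cell_csf(response_power(spec, cell_model(cls)))
    expect_equal(csf, rep(0, 12))
  }
})

test_that("a single passing bin integrates to sqrt(v * dnu)", {
  spec <- unit_bin_spec(c(0.5, 1, 4), i_sf = 2, i_tf = 21, value = 1)
  spec$power[2, 21] <- 1 / Mod(rf_transfer(1, 10, cell_model("P"))[1, 1])^2
  csf <- cell_csf(response_power(spec, cell_model("P")))
  expect_equal(csf[2], sqrt(1 * spec$df))
})

test_that("combination follows Eq.-7 arithmetic and validates grids", {
  m <- c(2, 2, 2)
  p <- c(1, 1, 1)
  cv <- combine_csf(m, p, combination_params(A_gain = 1, lam = 0.57))
  expect_equal(cv$sensitivity, rep(0.57 * 2 + 0.43 * 1, 3))
  expect_equal(combine_csf(m, p, combination_params(lam = 1))$sensitivity, m)
  expect_equal(combine_csf(m, p, combination_params(A_gain = 2, lam = 0))$sensitivity,
               2 * p)
  expect_error(combine_csf(m, c(1, 1), combination_params()), "mismatch")
})

test_that("contrast scaling propagates linearly to the CSF (gain equivariance)", {
  spec <- make_spec(n_trials = 5)
  scaled <- spec
  scaled$power <- 9 * spec$power  # contrast x3 -> power x9
  for (cls in c("M", "P")) {
    expect_equal(cell_csf(response_power(scaled, cell_model(cls))),
                 3 * cell_csf(response_power(spec, cell_model(cls))))
  }
})

test_that("M-class sensitivity ignores power added to the DC bin", {
  spec <- make_spec(n_trials = 5)
  bumped <- spec
  bumped$power[, 1] <- bumped$power[, 1] + 50
  expect_equal(cell_csf(response_power(bumped, cell_model("M"))),
               cell_csf(response_power(spec, cell_model("M"))))
})

test_that("shape descriptors classify and locate peaks as documented", {
  sf <- default_sf_grid(12)
  falling <- list(sf_grid = sf, sensitivity = 10 * (1 - seq(0, 0.9, length.out = 12)))
  class(falling) <- "csf_curve"
  d <- shape_descriptors(falling)
  expect_identical(d$shape_class, "low_pass")
  expect_equal(d$peak_sf, sf[1])

  # exact log-parabola centered at 4 cpd
  para <- list(sf_grid = sf, sensitivity = exp(-(log10(sf) - log10(4))^2))
  class(para) <- "csf_curve"
  expect_equal(shape_descriptors(para)$peak_sf, 4, tolerance = 1e-6)

  # boundary ratio counts as low-pass
  tie <- list(sf_grid = sf, sensitivity = c(0.5, rep(0.4, 10), 1))
  class(tie) <- "csf_curve"
  expect_identical(shape_descriptors(tie)$shape_class, "low_pass")

  flat0 <- list(sf_grid = sf, sensitivity = rep(0, 12))
  class(flat0) <- "csf_curve"
  expect_false(shape_descriptors(flat0)$valid)

  expect_error(shape_descriptors(data.frame(sf_cpd = 1:3,
                                            sensitivity = 1:3)),
               "at least 5")
})

test_that("drift yields an interior band-pass peak; no drift tilts low-pass", {
  drift <- cached_predict("unit_drift", function() {
    predict_csf(csf_condition("brownian", D = 250, n_trials = 30, seed = 2),
                sf_grid = default_sf_grid(16), n_orientations = 4,
                keep_spectrum = FALSE)
  })
  none <- predict_csf(csf_condition("none"), sf_grid = default_sf_grid(16),
                      n_orientations = 4, keep_spectrum = FALSE)
  dd <- shape_descriptors(drift)
  dn <- shape_descriptors(none)
  expect_identical(dd$shape_class, "band_pass")
  expect_gt(dd$peak_sf, min(drift$sf_grid))
  expect_lt(dd$peak_sf, max(drift$sf_grid))
  expect_identical(dn$shape_class, "low_pass")
  expect_gt(dn$lowfreq_ratio, dd$lowfreq_ratio)
})

test_that("the same condition and seed reproduce the curve exactly", {
  cond <- csf_condition("brownian", D = 250, n_trials = 5, seed = 33)
  a <- predict_csf(cond, sf_grid = default_sf_grid(8), n_orientations = 2,
                   keep_spectrum = FALSE)
  b <- predict_csf(cond, sf_grid = default_sf_grid(8), n_orientations = 2,
                   keep_spectrum = FALSE)
  expect_identical(a$sensitivity, b$sensitivity)
})

test_that("flicker pushes the predicted CSF monotonically toward low-pass", {
  fam <- cached_predict("unit_family", function() {
    predict_csf_family(c(0, 2, 4, 6), csf_condition("brownian", D = 250,
                                                    n_trials = 30, seed = 2),
                       sf_grid = default_sf_grid(16), n_orientations = 4,
                       keep_spectrum = FALSE)
  })
  ratios <- vapply(fam, function(cv) shape_descriptors(cv)$lowfreq_ratio,
                   numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("the band-pass to low-pass transition exists for each cell class alone", {
  fam <- cached_predict("unit_family_wide", function() {
    predict_csf_family(c(0, 4, 8, 12, 16),
                       csf_condition("brownian", D = 250, n_trials = 30,
                                     seed = 2),
                       sf_grid = default_sf_grid(16), n_orientations = 4,
                       keep_spectrum = FALSE)
  })
  for (lam in c(0, 1)) {
    relabeled <- lapply(fam, function(cv) {
      combine_csf(cv$csf_M, cv$csf_P, combination_params(lam = lam),
                  sf_grid = cv$sf_grid, condition = cv$condition)
    })
    tr <- suppressWarnings(
      transition_frequency(relabeled, c(0, 4, 8, 12, 16)))
    expect_true(is.finite(tr))
    expect_gt(as.numeric(tr), 0)
  }
})

test_that("transition frequency handles degenerate families and sentinels", {
  sf <- default_sf_grid(8)
  fake <- function(ratio, om) {
    s <- c(ratio, rep(0.2, 6), 1)
    cv <- list(sf_grid = sf, sensitivity = s,
               condition = list(temporal_mod = om))
    class(cv) <- "csf_curve"
    cv
  }
  all_lp <- lapply(c(0, 2, 4), function(om) fake(0.9, om))
  expect_equal(as.numeric(transition_frequency(all_lp, c(0, 2, 4))), 0)
  all_bp <- lapply(c(0, 2, 4), function(om) fake(0.1, om))
  tr <- transition_frequency(all_bp, c(0, 2, 4))
  expect_identical(as.numeric(tr), Inf)
  expect_identical(attr(tr, "status"), "above_grid")
  mixed <- list(fake(0.1, 0), fake(0.9, 2), fake(0.1, 4))
  expect_warning(out <- transition_frequency(mixed, c(0, 2, 4)),
                 "not monotone")
  expect_equal(as.numeric(out), 2)
})

test_that("gain fitting recovers scale and mixture weight", {
  drift <- cached_predict("unit_drift_withspec", function() {
    predict_csf(csf_condition("brownian", D = 250, n_trials = 20, seed = 5),
                sf_grid = default_sf_grid(12), n_orientations = 4)
  })
  ref3 <- data.frame(sf_cpd = drift$sf_grid,
                     sensitivity = 3 * drift$sensitivity)
  fit <- fit_gain(drift, ref3)
  expect_equal(fit$A_gain, 3, tolerance = 1e-10)
  expect_equal(fit$lam, drift$combination$lam)

  # reference built from a known (A*, lambda*) mixture of the components
  mix <- 2.5 * (0.3 * drift$csf_M + 0.7 * drift$csf_P)
  ref <- data.frame(sf_cpd = drift$sf_grid, sensitivity = mix)
  fit2 <- fit_gain(drift, ref, fit_lambda = TRUE)
  expect_equal(fit2$lam, 0.3, tolerance = 0.02)
  expect_equal(fit2$A_gain, 2.5, tolerance = 0.05)

  one <- data.frame(sf_cpd = drift$sf_grid[6],
                    sensitivity = 5)
  fit3 <- fit_gain(drift, one)
  interp <- fit3$A_gain * (drift$combination$lam * drift$csf_M[6] +
                             (1 - drift$combination$lam) * drift$csf_P[6])
  expect_equal(interp, 5, tolerance = 1e-10)

  out <- data.frame(sf_cpd = 500, sensitivity = 1)
  expect_error(fit_gain(drift, out), "outside")
})

test_that("CSV export writes the documented per-condition schema", {
  drift <- cached_predict("unit_drift_withspec", function() {
    predict_csf(csf_condition("brownian", D = 250, n_trials = 20, seed = 5),
                sf_grid = default_sf_grid(12), n_orientations = 4)
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_csf_csv(drift, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("sf_cpd", "csf_total", "csf_M", "csf_P"))
  expect_equal(back$csf_total, drift$sensitivity, tolerance = 1e-6)
})
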