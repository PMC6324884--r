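# driftcsf

Model the primate contrast sensitivity function (CSF) as the product of
fixational ocular drift and the spatiotemporal filtering of retinal ganglion
cells (RGCs).

## The scientific problem

The CSF — the reciprocal of the contrast detection threshold as a function of
a grating's spatial frequency — is band-pass for static gratings, peaking
near 3–5 cycles/deg. Yet the spatial tuning of retinal ganglion cells,
measured with immobilized eyes, shows far less low-frequency attenuation than
the behavioral CSF: a difference-of-Gaussians (DoG) receptive field can only
mimic the CSF with an unrealistically strong surround. The missing ingredient
is that behaving observers are never still: fixational drift sweeps the
stimulus across the retina, converting the static (0 Hz) power of the grating
into temporal modulations. Because the temporal spread of those modulations
grows with spatial frequency (for Brownian drift, the temporal spectrum at
spatial frequency *f* is a Lorentzian of half-width ∝ *f*²·D), and because
RGCs respond only to temporal change, drift imposes a spatial-frequency
dependence that the receptive fields alone do not have.

`driftcsf` implements this model end to end for users in visual
psychophysics and computational neuroscience:

1. **Drift kinematics** — fixational drift as a 2D Brownian walk with
   diffusion coefficient D (arcmin²/s; per-axis increment variance 2·D·Δt),
   speed-threshold segmentation of traces into drift and saccade periods,
   drift-epoch selection, and a plain CSV trace format.
2. **Retinal input** — for a sinusoidal grating, the full space–time
   structure of the retinal input reduces to the complex demodulated signal
   `z(t) = exp(−i·2π·f·û(α)·ξ(t)/60)·s(t)·M(t)`; its one-sided power
   spectrum, averaged over trials, orientations and phases, gives the input
   power `P_I(f, ω)`. An analytic Lorentzian oracle and a brute-force
   space–time FFT validate the fast path.
3. **RGC filters** — space–time separable transfer functions
   `RF(f, ω) = K(f)·H(ω)`: a DoG spatial kernel
   `K(f) = C(Kc·π·rc²·e^{−(π·rc·γ·f)²} − Ks·π·rs²·e^{−(π·rs·γ·f)²})` and a
   temporal cascade
   `H(ω) = A·e^{−iρ2πωD}(1 − Hs/(1+iρ2πωτS))(1+iρ2πωτL)^{−N}`, with
   physiological magno (M) and parvo (P) parameter sets built in
   (γ = 0.5, ρ = 1/1.6).
4. **CSF pipeline** — response power `O(f, ω) = P_I·|RF|²`, per-class
   sensitivity `CSF(f) = √(∫ O dω)` integrated above a low-frequency cutoff
   (default 0.63 Hz, or a power-law attenuation), the combination
   `A·[λ·CSF_M + (1−λ)·CSF_P]` with λ = 0.57, shape descriptors
   (peak location, band-pass/low-pass classification), and the
   flicker-driven band-pass → low-pass transition.
5. **Experiments** — scripted, seeded runs reproducing the model analyses
   (input power decomposition, static drift vs. no drift, flickered
   gratings, retinal stabilization with D reduced from 250 to 2, and the
   DoG-surround fitting analysis), with CSV/JSON outputs and run logs.

## Worked example

```r
library(driftcsf)

# predicted CSF under normal fixational drift vs. a perfectly still eye
drift <- predict_csf(
  csf_condition("brownian", D = 250, n_trials = 50, seed = 1),
  sf_grid = default_sf_grid(16)
)
still <- predict_csf(csf_condition("none"), sf_grid = default_sf_grid(16))

drift
#> <csf_curve> 16 spatial frequencies (0.1-60 cpd), peak 3.9 cpd, band_pass (low-freq ratio 0.04)
still
#> <csf_curve> 16 spatial frequencies (0.1-60 cpd), peak 2.27 cpd, low_pass (low-freq ratio 0.75)

shape_descriptors(drift)$peak_sf
#> [1] 3.904264
round(power_decomposition(drift$spectrum)$dynamic_power[c(1, 8, 16)], 4)
#> [1] 0.0531 0.6687 0.8039
```

With drift, the predicted CSF is band-pass with its peak near 4 cycles/deg,
because the dynamic power delivered above the 0.63 Hz cutoff rises steeply
with spatial frequency (5% of total stimulus power at 0.1 cycles/deg, 80% at
60 cycles/deg). Remove the eye movements and only the contrast on/off ramps
modulate the input — the same amount at every spatial frequency — so the
prediction collapses onto the receptive-field profile and turns low-pass,
with sensitivity at 0.1 cycles/deg three quarters of the maximum.

Scripted versions of the full analyses live behind `run_experiment()`:

```r
run_experiment("fig5_stabilized", out_dir = "scratch/stab", seed = 1)
```

writes the predicted curves for normal (D = 250) and stabilized (D = 2)
viewing plus a summary JSON with peak locations and sensitivities.

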