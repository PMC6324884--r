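# Shared in-code fixtures and a cache for the expensive full-pipeline runs.

# constant-position trace
constant_trace <- function(duration = 1, fs = 1000, id = "constant") {
  n <- round(duration * fs)
  eye_trace(t = (0:(n - 1)) / fs, x = numeric(n), y = numeric(n), trial_id = id)
}

# 1 s still + linear ramp at `speed_deg_s` for `ramp_s` + 1 s still
ramp_trace <- function(speed_deg_s = 10, ramp_s = 0.02, fs = 1000,
                       still_s = 1) {
  n_still <- round(still_s * fs)
  n_ramp <- round(ramp_s * fs)
  v <- speed_deg_s * 60  # arcmin/s
  x <- c(rep(0, n_still), v * (1:n_ramp) / fs, rep(v * n_ramp / fs, n_still))
  n <- length(x)
  eye_trace(t = (0:(n - 1)) / fs, x = x, y = numeric(n), trial_id = "ramp")
}

# full-pipeline runs reused across acceptance blocks (deterministic per key)
.run_cache <- new.env(parent = emptyenv())
cached_predict <- function(key, fn) {
  if (is.null(.run_cache[[key]])) assign(key, fn(), envir = .run_cache)
  .run_cache[[key]]
}
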