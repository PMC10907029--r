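# Shared fixtures, all generated in code.

# A small, fast default subject for pipeline tests.
quick_params <- function(..., duration_s = 120, fs = 125, seed = 101) {
  subject_params(duration_s = duration_s, fs = fs, seed = seed, ...)
}

# Run the per-subject stages needed for phase metrics, returning the
# intermediates (cheaper than analyze_subject when hemodynamics are not
# needed).
run_phase_pipeline <- function(sub, expiration_pairing = "following") {
  r <- detect_r_waves(sub$record)
  ng <- normalize_neurogram(sub$record)
  b <- detect_bursts(ng, r)
  sh <- shift_neurogram(ng, mean_burst_latency(b))
  cyc <- detect_resp_cycles(sub$record)
  grid <- build_interval_grid(cyc)
  ph <- assemble_phases(grid, expiration_pairing = expiration_pairing)
  pm <- phase_metrics(ph, b, r, sh)
  list(r = r, ng = ng, bursts = b, shifted = sh, cycles = cyc,
       grid = grid, phases = ph, metrics = pm,
       change = modulation_change(pm))
}

# Constant-valued neurogram object for arithmetic tests.
const_neurogram <- function(value, duration_s, fs = 100) {
  structure(list(samples = rep(value, round(duration_s * fs)), fs = fs,
                 start_time = 0, shift_applied = 0, noise_sd_pct = 1,
                 smooth_s = 0.05),
            class = "neurogram")
}

# Regular breath table (no detection involved).
regular_cycles <- function(n_breaths, period = 4, insp_fraction = 0.4,
                           t0 = 0) {
  tr <- t0 + (seq_len(n_breaths) - 1) * period
  tibble::tibble(
    breath = seq_len(n_breaths),
    t_trough = tr,
    t_peak = tr + insp_fraction * period,
    t_trough_next = tr + period,
    insp_dur = insp_fraction * period,
    exp_dur = (1 - insp_fraction) * period,
    amp = 1,
    amp_norm = 100
  )
}
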