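# shared fixture builders (all fixtures are constructed in code)

# reference displacement model with all variances removed
zero_sd_amplitudes <- function() {
  a <- reference_amplitudes()
  a$sd <- 0
  a
}

# deterministic motion model: fixed helical fraction, no displacement noise
deterministic_params <- function(u = 0.5) {
  sim_params(displacements = zero_sd_amplitudes(),
             helical_mean = u, helical_sd = 0)
}

# hand-built two-cycle trace: phase-0 amplitudes 10 and 11, per-cycle
# peak-to-peak 10 and 10, so the phase-0 error is exactly 10%
hand_trace <- function(n_phases = 4L) {
  amp <- c(10, 5, 0, 5, 11, 6, 1, 6)
  breathing_trace(
    tibble::tibble(time = seq_along(amp) - 1, amplitude = amp),
    dt = 1, cycle_starts = c(1L, 5L), n_phases = n_phases
  )
}

# single-cycle trace (phase error undefined)
one_cycle_trace <- function() {
  amp <- c(10, 5, 0, 5)
  breathing_trace(
    tibble::tibble(time = 0:3, amplitude = amp),
    dt = 1, cycle_starts = 1L, n_phases = 4L
  )
}

# one-patient point table built by hand
point_obs <- function(patient_id = "P1", segment = "S1",
                      helical = c(0, 0, 0), phase0 = c(0, 0, 0),
                      phase50 = c(0, 0, 0)) {
  tibble::tibble(
    patient_id = patient_id, segment = segment,
    helical_lr = helical[1], helical_ap = helical[2], helical_si = helical[3],
    phase0_lr = phase0[1], phase0_ap = phase0[2], phase0_si = phase0[3],
    phase50_lr = phase50[1], phase50_ap = phase50[2], phase50_si = phase50[3]
  )
}
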