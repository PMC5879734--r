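#' Simulation parameters for the synthetic cohort generator
#'
#' Bundles every tunable of the synthetic motion model.  For each patient the
#' generator draws one total expiration displacement `d ~ Normal(mean, sd)`
#' per segment and axis (defaults from [reference_amplitudes()]), places the
#' end-inspiration position at the fixed [segment_layout()], sets the
#' end-expiration position to `phase0 + d`, and locates the free-breathing
#' helical snapshot at `phase0 + u * d`, where the helical fraction
#' `u ~ Normal(helical_mean, helical_sd)` truncated to `[0, 1]` is drawn once
#' per patient (one helical scan per patient).  Axes and segments are
#' independent by default; `shared_depth_sd > 0` adds a per-patient scaling
#' factor common to all of a patient's displacements, emulating breathing
#' depth correlation.
#'
#' The default helical fraction law, `u ~ TruncNormal(0.42, 0.15)`, encodes
#' that the snapshot falls at a random, roughly mid-cycle point of expiration;
#' 0.42 is the fraction at which the reference cohort's helical-to-phase mean
#' displacements split its total expiration amplitudes.
#'
#' @param displacements Tibble with columns `segment`, `axis`, `mean`, `sd`
#'   (mm) giving the phase 0 to phase 50 displacement distribution for all
#'   nine segments and three axes.  Default: [reference_amplitudes()].
#' @param helical_mean,helical_sd Mean and SD of the untruncated helical
#'   fraction law; the draw is truncated to `[0, 1]`.  `helical_sd = 0` fixes
#'   the fraction at `helical_mean`.
#' @param shared_depth_sd SD of the per-patient shared displacement scaling
#'   factor (factor = `1 + Normal(0, shared_depth_sd)`); 0 (default) disables
#'   it.
#' @param period_s Mean breathing period in seconds.
#' @param trace_amplitude Mean peak-to-peak surrogate amplitude (arbitrary
#'   units).
#' @param period_jitter,amplitude_jitter Cycle-to-cycle fractional jitter of
#'   period and amplitude (SD of a multiplicative `1 + Normal(0, jitter)`
#'   factor).
#' @param n_cycles Number of breathing cycles per simulated trace (>= 3).
#' @param n_phases Number of gated phase bins (default 10, phases 0%--90%).
#' @param sample_dt Surrogate sampling interval in seconds.
#' @param lung_phase0,lung_phase50 Named numeric vectors `c(left=, right=)` of
#'   mean lung volumes (ml) at end-inspiration and end-expiration.
#' @param lung_size_sd SD of the per-patient log-normal lung size factor.
#' @param lung_ratio_sd SD of the multiplicative jitter on the per-lung
#'   expiration volume ratio.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [generate_cohort()], [simulate_breathing_trace()]
#' @export
#' @examples
#' p <- sim_params(helical_sd = 0)   # helical snapshot always at 42%
#' p$helical_mean
sim_params <- function(displacements = reference_amplitudes(),
                       helical_mean = 0.42,
                       helical_sd = 0.15,
                       shared_depth_sd = 0,
                       period_s = 4,
                       trace_amplitude = 10,
                       period_jitter = 0.1,
                       amplitude_jitter = 0.1,
                       n_cycles = 20,
                       n_phases = 10,
                       sample_dt = 0.04,
                       lung_phase0 = c(left = 1167.0, right = 1529.8),
                       lung_phase50 = c(left = 1034.3, right = 1336.1),
                       lung_size_sd = 0.15,
                       lung_ratio_sd = 0.03) {
  p <- list(
    displacements = as_tibble(displacements),
    helical_mean = helical_mean, helical_sd = helical_sd,
    shared_depth_sd = shared_depth_sd,
    period_s = period_s, trace_amplitude = trace_amplitude,
    period_jitter = period_jitter, amplitude_jitter = amplitude_jitter,
    n_cycles = n_cycles, n_phases = n_phases, sample_dt = sample_dt,
    lung_phase0 = lung_phase0, lung_phase50 = lung_phase50,
    lung_size_sd = lung_size_sd, lung_ratio_sd = lung_ratio_sd
  )
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  d <- p$displacements
  need <- c("segment", "axis", "mean", "sd")
  if (!all(need %in% names(d))) {
    abort("`displacements` must have columns segment, axis, mean, sd")
  }
  grid <- paste(rep(liver_segments(), each = 3L), rep(motion_axes(), 9L))
  have <- paste(d$segment, d$axis)
  if (nrow(d) != 27L || !setequal(have, grid) || anyDuplicated(have)) {
    abort("`displacements` must hold exactly one row per segment (9) and axis (3)")
  }
  if (!all(is.finite(d$mean)) || !all(is.finite(d$sd))) {
    abort("displacement means and SDs must be finite")
  }
  if (any(d$sd < 0)) abort("displacement SDs must be >= 0")
  scal <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      abort(paste0("`", nm, "` must be a single finite number"))
    }
  }
  for (nm in c("helical_mean", "helical_sd", "shared_depth_sd", "period_s",
               "trace_amplitude", "period_jitter", "amplitude_jitter",
               "sample_dt", "lung_size_sd", "lung_ratio_sd")) {
    scal(p[[nm]], nm)
  }
  if (p$helical_mean < 0 || p$helical_mean > 1) {
    abort("`helical_mean` must lie in [0, 1]")
  }
  if (p$helical_sd < 0) abort("`helical_sd` must be >= 0")
  if (p$shared_depth_sd < 0) abort("`shared_depth_sd` must be >= 0")
  if (p$period_s <= 0) abort("`period_s` must be > 0")
  if (p$trace_amplitude <= 0) abort("`trace_amplitude` must be > 0")
  if (p$period_jitter < 0 || p$amplitude_jitter < 0) {
    abort("jitter fractions must be >= 0")
  }
  if (p$sample_dt <= 0) abort("`sample_dt` must be > 0")
  if (!is.numeric(p$n_cycles) || p$n_cycles < 3) {
    abort("`n_cycles` must be at least 3")
  }
  if (!is.numeric(p$n_phases) || p$n_phases < 2) {
    abort("`n_phases` must be at least 2")
  }
  for (nm in c("lung_phase0", "lung_phase50")) {
    v <- p[[nm]]
    if (!is.numeric(v) || !all(c("left", "right") %in% names(v)) ||
        any(v[c("left", "right")] <= 0)) {
      abort(paste0("`", nm, "` must be a named vector c(left=, right=) of positive volumes"))
    }
  }
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat("  displacement model : 9 segments x 3 axes, normal(mean, sd) per cell\n")
  cat(sprintf("  helical fraction   : TruncNormal(%.2f, %.2f) on [0, 1]\n",
              x$helical_mean, x$helical_sd))
  cat(sprintf("  shared depth sd    : %.2f\n", x$shared_depth_sd))
  cat(sprintf("  trace              : period %.1f s, amplitude %.1f a.u., jitter %d%%/%d%%, %d cycles, %d phases\n",
              x$period_s, x$trace_amplitude, round(100 * x$period_jitter),
              round(100 * x$amplitude_jitter), x$n_cycles, x$n_phases))
  invisible(x)
}

# mean of Normal(mu, sd) truncated to [lo, hi]
truncnorm_mean <- function(mu, sd, lo = 0, hi = 1) {
  if (sd == 0) return(min(max(mu, lo), hi))
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
}

# truncated-normal sampler (rejection; fine for the mild truncation used here)
rtruncnorm01 <- function(n, mu, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(min(max(mu, 0), 1), n))
  x <- rnorm(n, mu, sd)
  bad <- x < 0 | x > 1
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mu, sd)
    bad <- x < 0 | x > 1
  }
  x
}
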