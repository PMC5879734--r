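#' Simulate a quasi-periodic breathing surrogate trace
#'
#' Emulates an external respiratory surrogate (chest-marker amplitude versus
#' time) as a sequence of raised-cosine cycles: cycle `k` has period
#' `period_s * (1 + e_k)` and peak-to-peak amplitude
#' `trace_amplitude * (1 + a_k)`, with independent normal jitters `e_k`, `a_k`
#' scaled by `period_jitter` and `amplitude_jitter`.  Within a cycle the
#' amplitude is `A_k * (1 + cos(2*pi*f)) / 2` at cycle fraction `f`, so the
#' peak (end-inspiration, gating phase 0) opens each cycle and the trough
#' (end-expiration, phase 50) sits at mid-cycle.  This is a deliberately
#' simplified emulation of a gating surrogate, not a physiological model.
#'
#' @param params A [sim_params()] object (fields `period_s`,
#'   `trace_amplitude`, `period_jitter`, `amplitude_jitter`, `n_cycles`,
#'   `n_phases`, `sample_dt`).
#' @param seed Optional integer seed for reproducibility.
#' @return A `breathing_trace` object; see [breathing_trace()].
#' @export
#' @examples
#' tr <- simulate_breathing_trace(sim_params(), seed = 1)
#' max_phase_error(tr, phase_index = 0)
simulate_breathing_trace <- function(params = sim_params(), seed = NULL) {
  params <- validate_sim_params(unclass(params))
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(params$n_cycles)
  periods <- params$period_s * pmax(0.2, 1 + rnorm(k, 0, params$period_jitter))
  amps <- params$trace_amplitude * pmax(0.05, 1 + rnorm(k, 0, params$amplitude_jitter))

  dt <- params$sample_dt
  bounds <- cumsum(c(0, periods))
  t_all <- seq(0, bounds[k + 1L] - dt / 2, by = dt)
  cyc <- findInterval(t_all, bounds, rightmost.closed = FALSE)
  cyc[cyc > k] <- k
  frac <- (t_all - bounds[cyc]) / periods[cyc]
  amplitude <- amps[cyc] * (1 + cos(2 * pi * frac)) / 2
  cycle_starts <- vapply(seq_len(k), function(i) which(cyc == i)[1L], integer(1))

  breathing_trace(tibble(time = t_all, amplitude = amplitude),
                  dt = dt, cycle_starts = cycle_starts,
                  n_phases = as.integer(params$n_phases))
}

#' Construct a breathing trace from samples
#'
#' Low-level constructor used by [simulate_breathing_trace()] and by code that
#' reads or hand-builds surrogate traces.  A trace is a uniformly sampled
#' amplitude signal plus the indices at which each complete breathing cycle
#' starts; gated phase `p` of a cycle (for `p` in `0:(n_phases - 1)`) is the
#' sample at fraction `p / n_phases` of that cycle.
#'
#' @param samples Data frame with numeric columns `time` (s) and `amplitude`
#'   (arbitrary units), uniformly sampled.
#' @param dt Sampling interval in seconds (> 0).
#' @param cycle_starts Integer indices into `samples` marking the first sample
#'   of each complete cycle, strictly increasing.
#' @param n_phases Number of gated phase bins (default 10).
#' @return An object of class `breathing_trace`.
#' @export
breathing_trace <- function(samples, dt, cycle_starts, n_phases = 10L) {
  samples <- as_tibble(samples)
  if (!all(c("time", "amplitude") %in% names(samples))) {
    abort("`samples` must have columns time and amplitude")
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    abort("`dt` must be a single positive number")
  }
  cycle_starts <- as.integer(cycle_starts)
  if (length(cycle_starts) < 1L || is.unsorted(cycle_starts, strictly = TRUE) ||
      cycle_starts[1L] < 1L || max(cycle_starts) > nrow(samples)) {
    abort("`cycle_starts` must be strictly increasing indices into `samples`")
  }
  if (n_phases < 2L) abort("`n_phases` must be at least 2")
  structure(
    list(samples = samples, dt = dt, cycle_starts = cycle_starts,
         n_phases = as.integer(n_phases), n_cycles = length(cycle_starts)),
    class = "breathing_trace"
  )
}

#' @export
print.breathing_trace <- function(x, ...) {
  cat(sprintf("<breathing_trace> %d cycles, %d samples at dt = %g s, %d gated phases\n",
              x$n_cycles, nrow(x$samples), x$dt, x$n_phases))
  invisible(x)
}

# samples of one complete cycle (start index inclusive, next start exclusive)
cycle_samples <- function(trace, k) {
  from <- trace$cycle_starts[k]
  to <- if (k < trace$n_cycles) trace$cycle_starts[k + 1L] - 1L else nrow(trace$samples)
  trace$samples$amplitude[from:to]
}

#' Maximum gating phase error of a breathing trace
#'
#' Quantifies cycle-to-cycle variability of the surrogate at a gated phase:
#' for each complete cycle the surrogate amplitude at that phase (the sample
#' at cycle fraction `phase_index / n_phases`) is read off, and the error is
#' the range of these values over cycles, expressed as a percentage of the
#' mean peak-to-peak cycle amplitude.  Identical cycles give 0%; the measure
#' is invariant under positive rescaling of the whole trace.  With
#' `phase_index = NULL` the maximum over all phases is returned, summarizing
#' the trace by its worst gated phase.
#'
#' @param trace A [breathing_trace()].
#' @param phase_index Gated phase bin in `0:(n_phases - 1)`, or `NULL` for
#'   the maximum over all phases.
#' @return Phase error in percent (non-negative scalar).
#' @export
#' @examples
#' tr <- simulate_breathing_trace(sim_params(amplitude_jitter = 0), seed = 2)
#' max_phase_error(tr, 0)
max_phase_error <- function(trace, phase_index = NULL) {
  if (!inherits(trace, "breathing_trace")) abort("`trace` must be a breathing_trace")
  if (trace$n_cycles < 2L) {
    abort("phase error needs at least 2 complete cycles")
  }
  if (is.null(phase_index)) {
    errs <- vapply(seq_len(trace$n_phases) - 1L,
                   function(p) max_phase_error(trace, p), numeric(1))
    return(max(errs))
  }
  if (!is.numeric(phase_index) || length(phase_index) != 1L ||
      phase_index < 0 || phase_index >= trace$n_phases) {
    abort("`phase_index` must lie in [0, n_phases)")
  }
  cycles <- lapply(seq_len(trace$n_cycles), function(k) cycle_samples(trace, k))
  at_phase <- vapply(cycles, function(s) {
    idx <- 1L + floor(phase_index / trace$n_phases * length(s) + 0.5)
    s[min(idx, length(s))]
  }, numeric(1))
  p2p <- vapply(cycles, function(s) max(s) - min(s), numeric(1))
  mean_p2p <- mean(p2p)
  if (mean_p2p == 0) return(0)
  100 * (max(at_phase) - min(at_phase)) / mean_p2p
}

#' Phase-error profile over all gated phases
#'
#' @param trace A [breathing_trace()].
#' @return Tibble with columns `phase` (0-based bin index) and `error_pct`.
#' @seealso [max_phase_error()]
#' @export
phase_error_profile <- function(trace) {
  phases <- seq_len(trace$n_phases) - 1L
  tibble(
    phase = phases,
    error_pct = vapply(phases, function(p) max_phase_error(trace, p), numeric(1))
  )
}

#' @export
autoplot.breathing_trace <- function(object, ...) {
  starts <- object$samples$time[object$cycle_starts]
  ggplot2::ggplot(object$samples, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = starts, linetype = "dotted", colour = "grey60") +
    ggplot2::labs(x = "time (s)", y = "surrogate amplitude (a.u.)",
                  title = "Simulated breathing surrogate",
                  subtitle = "dotted lines mark cycle starts (end-inspiration)") +
    ggplot2::theme_minimal()
}
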