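#' Volume overlap index (Dice-type agreement)
#'
#' `voi = 2 * v_intersection / (v_a + v_b)`: 0 means no spatial overlap, 1
#' perfect agreement (identical, fully overlapping volumes).  In the
#' verification workflow `v_a` is a deformed contour volume and `v_b` the
#' manually drawn reference; the index is computed from pre-measured volumes
#' (contour rasterization is out of scope).
#'
#' @param v_a,v_b Volumes in ml (> 0; vectorized).
#' @param v_intersection Intersection volume in ml
#'   (`0 <= v_intersection <= min(v_a, v_b)`).
#' @return Overlap index in `[0, 1]`.
#' @export
#' @examples
#' voi(100, 100, 100)   # 1
#' voi(2, 2, 1)         # 0.5
voi <- function(v_a, v_b, v_intersection) {
  if (!is.numeric(v_a) || !is.numeric(v_b) || !is.numeric(v_intersection)) {
    abort("volumes must be numeric")
  }
  if (any(!is.finite(v_a)) || any(!is.finite(v_b)) || any(!is.finite(v_intersection))) {
    abort("volumes must be finite")
  }
  if (any(v_a <= 0) || any(v_b <= 0)) abort("`v_a` and `v_b` must be positive")
  if (any(v_intersection < 0)) abort("`v_intersection` must be >= 0")
  if (any(v_intersection > pmin(v_a, v_b) + 1e-9)) {
    abort("`v_intersection` cannot exceed either volume")
  }
  2 * v_intersection / (v_a + v_b)
}

#' Lung-volume bracketing check
#'
#' Respiratory-stability verification: because the helical snapshot is taken
#' at an uncontrolled mid-cycle moment, each patient's lung volume on the
#' helical scan should lie between the end-expiration (phase 50) and
#' end-inspiration (phase 0) volumes.  The check is
#' `phase50 <= helical <= phase0`, inclusive (ties pass), evaluated for the
#' left, right and total lung separately.
#'
#' @param lungs A `liver_cohort` or a lung-volume table with columns
#'   `patient_id`, `state`, `left_ml`, `right_ml`, `total_ml` containing all
#'   three imaging states per patient.
#' @return Tibble with columns `patient_id`, `lung`, `phase0_ml`,
#'   `helical_ml`, `phase50_ml`, `pass`.
#' @export
#' @examples
#' lv <- tibble::tibble(
#'   patient_id = "P1",
#'   state = c("helical", "phase0", "phase50"),
#'   left_ml = c(1104.6, 1167.0, 1034.3),
#'   right_ml = c(1444.7, 1529.8, 1336.1),
#'   total_ml = c(2549.36, 2696.8, 2370.4)
#' )
#' lung_bracket_check(lv)
lung_bracket_check <- function(lungs) {
  if (inherits(lungs, "liver_cohort")) lungs <- cohort_lungs(lungs)
  lungs <- validate_lungs(lungs)
  counts <- lungs %>%
    group_by(.data$patient_id) %>%
    summarise(k = dplyr::n_distinct(.data$state), .groups = "drop")
  if (any(counts$k != 3L)) {
    bad <- counts$patient_id[counts$k != 3L]
    abort(paste0("missing imaging state(s) for patient(s): ",
                 paste(bad, collapse = ", ")))
  }
  long <- tidyr::pivot_longer(
    lungs, c("left_ml", "right_ml", "total_ml"),
    names_to = "lung", values_to = "ml"
  ) %>%
    mutate(lung = sub("_ml$", "", .data$lung)) %>%
    tidyr::pivot_wider(names_from = "state", values_from = "ml")
  long %>%
    mutate(
      pass = .data$phase50 <= .data$helical & .data$helical <= .data$phase0
    ) %>%
    select("patient_id", "lung",
           phase0_ml = "phase0", helical_ml = "helical",
           phase50_ml = "phase50", "pass") %>%
    arrange(.data$patient_id, match(.data$lung, c("left", "right", "total")))
}

#' Monte-Carlo coverage of the margin rule
#'
#' Checks what the envelope-and-clamp margin rule actually guarantees: for
#' each replicate a fresh cohort of `n_patients` is generated from the motion
#' model, the margin table is derived from it, and each segment/axis cell
#' scores a success when the model's *true mean* helical-to-phase-0 and
#' helical-to-phase-50 displacements (`-E[u] * mu` and `(1 - E[u]) * mu`,
#' with `E[u]` the truncated-normal mean of the helical fraction) both lie
#' inside the derived `[neg, pos]` interval.  `coverage_pct` is the
#' percentage of successes over replicates x segments x axes.  Because the
#' construct "cover each tumor" is ambiguous, a per-tumor reading is reported
#' alongside: the percentage of individual simulated patients whose own
#' helical-to-phase displacements both fall inside the cell's margins.
#'
#' `pairs` and `clamp` expose the rule's ingredients for calibration checks:
#' with `clamp = FALSE` and a single pair the margin reduces to a plain
#' Student-t interval, whose empirical coverage can be compared with the 95%
#' closed form.
#'
#' @param params A [sim_params()] object (the motion model).
#' @param config A [margin_config()]; default `margin_config(n_patients)`.
#' @param n_patients Patients per replicate cohort.
#' @param n_reps Number of Monte-Carlo replicates (>= 1).
#' @param seed Optional integer seed.
#' @param pairs `"both"` (default), or one of the two helical state pairs.
#' @param clamp Keep the zero clamp of the margin rule (default `TRUE`).
#' @return An object of class `coverage_result`: list with `coverage_pct`,
#'   `tumor_coverage_pct`, `per_cell` (tibble: segment, axis, true means,
#'   success percentages), `per_axis`, `n_reps`, `n_patients`, `seed`,
#'   `pairs`, `clamp`, `config`.
#' @export
#' @examples
#' cov <- coverage_simulation(n_patients = 20, n_reps = 50, seed = 1)
#' cov$coverage_pct
coverage_simulation <- function(params = sim_params(), config = NULL,
                                n_patients = 20, n_reps = 1000, seed = NULL,
                                pairs = c("both", "helical_to_phase0",
                                          "helical_to_phase50"),
                                clamp = TRUE) {
  params <- validate_sim_params(unclass(params))
  pairs <- rlang::arg_match(pairs)
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1) {
    abort("`n_reps` must be >= 1")
  }
  n_reps <- as.integer(n_reps)
  if (is.null(config)) config <- margin_config(n_patients)
  stopifnot(inherits(config, "margin_config"))
  if (!is.null(seed)) set.seed(seed)

  eu <- truncnorm_mean(params$helical_mean, params$helical_sd, 0, 1)
  truth <- params$displacements %>%
    mutate(
      mu_h0 = -eu * .data$mean,
      mu_h50 = (1 - eu) * .data$mean
    ) %>%
    select("segment", "axis", "mu_h0", "mu_h50") %>%
    arrange(seg_order(.data$segment), match(.data$axis, motion_axes()))

  use_pairs <- if (pairs == "both") {
    c("helical_to_phase0", "helical_to_phase50")
  } else {
    pairs
  }

  n_cells <- nrow(truth)
  mean_hits <- matrix(0L, n_reps, n_cells)
  tumor_hit_sum <- rep(0, n_cells)
  tumor_n <- 0L
  seg_idx <- rep(seq_len(9L), times = n_patients)  # cohort rows are patient-major

  for (r in seq_len(n_reps)) {
    coh <- generate_cohort(params, n_patients)
    disp <- lapply(use_pairs, function(p) displacement(coh, p))
    stats_list <- lapply(use_pairs, function(p) amplitude_stats(coh, p))
    # per-pair t-intervals and their envelope, in canonical cell order
    # (vectorized equivalent of margin_bounds(); agreement is unit-tested)
    lo_list <- hi_list <- vector("list", length(stats_list))
    for (i in seq_along(stats_list)) {
      hw <- t_halfwidth(stats_list[[i]]$sd, config)
      lo_list[[i]] <- stats_list[[i]]$mean - hw
      hi_list[[i]] <- stats_list[[i]]$mean + hw
    }
    neg <- do.call(pmin, lo_list)
    pos <- do.call(pmax, hi_list)
    if (clamp) {
      neg <- pmin(0, neg)
      pos <- pmax(0, pos)
    }
    # inclusion at machine precision: a degenerate (zero-variance) model puts
    # the truth exactly on the bound, up to floating-point round-off
    tol <- 1e-9
    bounds <- list(neg = neg - tol, pos = pos + tol)
    ok <- rep(TRUE, n_cells)
    if ("helical_to_phase0" %in% use_pairs) {
      ok <- ok & truth$mu_h0 >= bounds$neg & truth$mu_h0 <= bounds$pos
    }
    if ("helical_to_phase50" %in% use_pairs) {
      ok <- ok & truth$mu_h50 >= bounds$neg & truth$mu_h50 <= bounds$pos
    }
    mean_hits[r, ] <- as.integer(ok)

    # per-tumor reading: individual patients' displacements inside the margins
    for (ai in seq_along(motion_axes())) {
      ci <- (seg_idx - 1L) * 3L + ai
      inside <- rep(TRUE, length(ci))
      for (dd in disp) {
        v <- dd[[motion_axes()[ai]]]
        inside <- inside & v >= bounds$neg[ci] & v <= bounds$pos[ci]
      }
      cell_of <- (seq_len(9L) - 1L) * 3L + ai
      tumor_hit_sum[cell_of] <- tumor_hit_sum[cell_of] +
        rowsum(as.numeric(inside), seg_idx)[, 1]
    }
    tumor_n <- tumor_n + n_patients
  }

  per_cell <- truth %>%
    mutate(
      mean_cov_pct = 100 * colMeans(mean_hits),
      tumor_cov_pct = 100 * tumor_hit_sum / tumor_n
    )
  per_axis <- per_cell %>%
    group_by(.data$axis) %>%
    summarise(
      mean_cov_pct = mean(.data$mean_cov_pct),
      tumor_cov_pct = mean(.data$tumor_cov_pct),
      .groups = "drop"
    )

  structure(
    list(
      coverage_pct = mean(per_cell$mean_cov_pct),
      tumor_coverage_pct = mean(per_cell$tumor_cov_pct),
      per_cell = per_cell,
      per_axis = per_axis,
      n_reps = n_reps, n_patients = as.integer(n_patients),
      seed = seed, pairs = pairs, clamp = clamp, config = config
    ),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf(
    "<coverage_result> %d replicates x %d patients (pairs: %s, clamp: %s)\n",
    x$n_reps, x$n_patients, x$pairs, x$clamp
  ))
  cat(sprintf("  true-mean coverage : %.1f%%\n", x$coverage_pct))
  cat(sprintf("  per-tumor coverage : %.1f%%\n", x$tumor_coverage_pct))
  cat(sprintf("  worst cell         : %.1f%% (%s %s)\n",
              min(x$per_cell$mean_cov_pct),
              x$per_cell$segment[which.min(x$per_cell$mean_cov_pct)],
              x$per_cell$axis[which.min(x$per_cell$mean_cov_pct)]))
  invisible(x)
}

#' @export
tidy.coverage_result <- function(x, ...) {
  x$per_cell
}

#' @export
glance.coverage_result <- function(x, ...) {
  tibble(
    coverage_pct = x$coverage_pct,
    tumor_coverage_pct = x$tumor_coverage_pct,
    min_cell_pct = min(x$per_cell$mean_cov_pct),
    n_reps = x$n_reps,
    n_patients = x$n_patients,
    pairs = x$pairs,
    clamp = x$clamp
  )
}

#' @export
autoplot.coverage_result <- function(object, ...) {
  df <- object$per_cell %>%
    mutate(
      segment = factor(.data$segment, levels = liver_segments()),
      axis = factor(toupper(.data$axis), levels = c("LR", "AP", "SI"))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$mean_cov_pct)) +
    ggplot2::geom_hline(yintercept = 95, linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::facet_wrap(~axis) +
    ggplot2::labs(
      x = NULL, y = "true-mean coverage (%)",
      title = "Monte-Carlo coverage of the margin rule per segment/axis",
      subtitle = sprintf("%d replicates of %d-patient cohorts; dashed line: nominal 95%%",
                         object$n_reps, object$n_patients)
    ) +
    ggplot2::theme_minimal()
}

#' Assemble a machine-readable validation report
#'
#' Bundles the verification outputs for one cohort into a list ready for JSON
#' serialization: per-patient lung bracket verdicts, per-patient maximum
#' gating phase errors (when traces are present), optional volume-overlap
#' values, and an optional coverage summary.
#'
#' @param cohort A `liver_cohort`.
#' @param coverage Optional [coverage_simulation()] result.
#' @param voi_volumes Optional tibble with columns `v_a`, `v_b`,
#'   `v_intersection` (and any id columns), for which `voi` is computed.
#' @return A named list.
#' @export
validation_report <- function(cohort, coverage = NULL, voi_volumes = NULL) {
  stopifnot(inherits(cohort, "liver_cohort"))
  rep <- list()
  if (nrow(cohort$lungs)) {
    verdicts <- lung_bracket_check(cohort)
    rep$lung_bracket <- list(
      all_pass = all(verdicts$pass),
      n_fail = sum(!verdicts$pass),
      verdicts = verdicts
    )
  }
  if (!is.null(cohort$traces)) {
    rep$max_phase_error_pct <- tibble(
      patient_id = names(cohort$traces),
      max_phase_error_pct = vapply(cohort$traces, max_phase_error, numeric(1))
    )
  }
  if (!is.null(voi_volumes)) {
    voi_volumes$voi <- voi(voi_volumes$v_a, voi_volumes$v_b,
                           voi_volumes$v_intersection)
    rep$voi <- voi_volumes
  }
  if (!is.null(coverage)) {
    stopifnot(inherits(coverage, "coverage_result"))
    rep$coverage <- list(
      coverage_pct = coverage$coverage_pct,
      tumor_coverage_pct = coverage$tumor_coverage_pct,
      n_reps = coverage$n_reps,
      n_patients = coverage$n_patients,
      seed = coverage$seed,
      per_axis = coverage$per_axis
    )
  }
  rep
}
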