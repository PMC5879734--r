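#' Generate a synthetic patient cohort
#'
#' Simulates a cohort of patients, each carrying one representative point per
#' Couinaud segment observed at three imaging states (helical snapshot,
#' end-inspiration phase 0, end-expiration phase 50), per-patient lung volumes
#' at the same three states, and optionally a breathing trace.  The motion
#' model is described in [sim_params()]: the phase 0 position sits at the
#' fixed [segment_layout()], the phase 50 position adds the drawn total
#' displacement, and the helical position interpolates at the patient's
#' helical fraction.  Lung volumes scale the reference state means by a
#' per-patient log-normal size factor and place the helical volume between
#' the two phase volumes at the same helical fraction, so the lung bracket
#' property holds by construction.
#'
#' @param params A [sim_params()] object.
#' @param n_patients Number of patients (>= 0).
#' @param seed Optional integer seed; a fixed seed makes the cohort
#'   bit-reproducible.
#' @param include_traces If `TRUE`, simulate one breathing trace per patient
#'   (slower; off by default).
#'
#' @return A `liver_cohort` object: a list with tibbles `points` (one row per
#'   patient x segment, columns `patient_id`, `segment`, then
#'   `{helical,phase0,phase50}_{lr,ap,si}` in mm) and `lungs` (one row per
#'   patient x state), a list `traces` (or `NULL`), the `params` used, `seed`
#'   and patient count `n`.
#' @seealso [cohort_points()], [amplitude_table()], [margin_table()]
#' @export
#' @examples
#' coh <- generate_cohort(n_patients = 5, seed = 1)
#' coh
#' cohort_points(coh)
generate_cohort <- function(params = sim_params(), n_patients = 20,
                            seed = NULL, include_traces = FALSE) {
  params <- validate_sim_params(unclass(params))
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients < 0 || n_patients != floor(n_patients)) {
    abort("`n_patients` must be a non-negative integer")
  }
  n_patients <- as.integer(n_patients)
  if (!is.null(seed)) set.seed(seed)

  if (n_patients == 0L) {
    return(new_liver_cohort(empty_points(), empty_lungs(), NULL, params, seed))
  }

  ids <- sprintf("P%03d", seq_len(n_patients))
  u <- rtruncnorm01(n_patients, params$helical_mean, params$helical_sd)
  depth <- if (params$shared_depth_sd > 0) {
    1 + rnorm(n_patients, 0, params$shared_depth_sd)
  } else {
    rep(1, n_patients)
  }

  # displacement draws: one per patient x segment x axis, cells in canonical
  # order (segment-major, axes lr/ap/si)
  d <- params$displacements
  canon_seg <- rep(liver_segments(), each = 3L)
  canon_ax <- rep(motion_axes(), times = 9L)
  if (!identical(d$segment, canon_seg) || !identical(d$axis, canon_ax)) {
    d <- d[order(seg_order(d$segment), match(d$axis, motion_axes())), ]
  }
  layout <- segment_layout()
  n_cell <- nrow(d)                       # 27
  draws <- matrix(
    rnorm(n_patients * n_cell, mean = rep(d$mean, each = n_patients),
          sd = rep(d$sd, each = n_patients)),
    nrow = n_patients, ncol = n_cell
  ) * depth

  # rows are patient-major with segments cycling inside each patient
  cols <- list(
    patient_id = rep(ids, each = 9L),
    segment    = rep(liver_segments(), times = n_patients)
  )
  for (state in imaging_states()) {
    for (ai in seq_along(motion_axes())) {
      ax <- motion_axes()[ai]
      dm <- draws[, (seq_len(9L) - 1L) * 3L + ai, drop = FALSE]  # n x 9
      ref <- layout[[ax]]
      val <- switch(state,
        phase0  = matrix(ref, n_patients, 9L, byrow = TRUE),
        phase50 = matrix(ref, n_patients, 9L, byrow = TRUE) + dm,
        helical = matrix(ref, n_patients, 9L, byrow = TRUE) + u * dm
      )
      cols[[paste0(state, "_", ax)]] <- as.vector(t(val))
    }
  }
  points <- as_tibble(cols)[cohort_point_cols()]

  lungs <- simulate_lungs(params, ids, u)

  traces <- NULL
  if (include_traces) {
    traces <- lapply(ids, function(id) simulate_breathing_trace(params))
    names(traces) <- ids
  }

  new_liver_cohort(points, lungs, traces, params, seed)
}

simulate_lungs <- function(params, ids, u) {
  n <- length(ids)
  size <- exp(rnorm(n, 0, params$lung_size_sd))
  out <- vector("list", 2L)
  names(out) <- c("left", "right")
  for (lung in c("left", "right")) {
    p0 <- params$lung_phase0[[lung]] * size
    ratio0 <- params$lung_phase50[[lung]] / params$lung_phase0[[lung]]
    ratio <- pmin(pmax(ratio0 * (1 + rnorm(n, 0, params$lung_ratio_sd)), 0.5), 1)
    p50 <- p0 * ratio
    hel <- p50 + u * (p0 - p50)
    out[[lung]] <- cbind(helical = hel, phase0 = p0, phase50 = p50)
  }
  left <- as.vector(t(out$left))
  right <- as.vector(t(out$right))
  tibble(
    patient_id = rep(ids, each = 3L),
    state      = rep(imaging_states(), times = n),
    left_ml    = left,
    right_ml   = right,
    total_ml   = left + right
  )
}

cohort_point_cols <- function() {
  c("patient_id", "segment",
    paste0("helical_", motion_axes()),
    paste0("phase0_", motion_axes()),
    paste0("phase50_", motion_axes()))
}

empty_points <- function() {
  cols <- cohort_point_cols()
  out <- c(list(character(0), character(0)),
           rep(list(numeric(0)), length(cols) - 2L))
  names(out) <- cols
  as_tibble(out)
}

empty_lungs <- function() {
  tibble(patient_id = character(0), state = character(0),
         left_ml = numeric(0), right_ml = numeric(0), total_ml = numeric(0))
}

seg_order <- function(segment) {
  match(segment, liver_segments())
}

new_liver_cohort <- function(points, lungs, traces, params, seed) {
  structure(
    list(points = points, lungs = lungs, traces = traces,
         params = params, seed = seed,
         n = length(unique(points$patient_id))),
    class = "liver_cohort"
  )
}

#' Assemble a cohort from tables
#'
#' Builds a `liver_cohort` from an existing point table (and optional lung
#' table), validating the cohort invariants: every patient must carry exactly
#' one observation for each of the nine segments, and all coordinates must be
#' finite.
#'
#' @param points Data frame following the cohort point schema (see
#'   [generate_cohort()]).
#' @param lungs Optional data frame with columns `patient_id`, `state`,
#'   `left_ml`, `right_ml`, `total_ml`.
#' @param traces Optional named list of [breathing_trace()] objects.
#' @return A `liver_cohort`.
#' @export
as_liver_cohort <- function(points, lungs = NULL, traces = NULL) {
  points <- validate_cohort_points(points)
  if (is.null(lungs)) {
    lungs <- empty_lungs()
  } else {
    lungs <- validate_lungs(lungs)
  }
  new_liver_cohort(points, lungs, traces, NULL, NULL)
}

validate_cohort_points <- function(points) {
  cols <- cohort_point_cols()
  if (!is.data.frame(points)) abort("cohort points must be a data frame")
  missing_cols <- setdiff(cols, names(points))
  if (length(missing_cols)) {
    abort(paste0("cohort points are missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  points <- as_tibble(points)[cols]
  bad_seg <- setdiff(unique(points$segment), liver_segments())
  if (length(bad_seg)) {
    abort(paste0("unknown segment label(s): ", paste(bad_seg, collapse = ", ")))
  }
  for (pid in unique(points$patient_id)) {
    segs <- points$segment[points$patient_id == pid]
    miss <- setdiff(liver_segments(), segs)
    if (length(miss)) {
      abort(paste0("patient ", pid, " is missing segment(s): ",
                   paste(miss, collapse = ", ")))
    }
    if (anyDuplicated(segs)) {
      abort(paste0("patient ", pid, " has duplicated segment(s): ",
                   paste(unique(segs[duplicated(segs)]), collapse = ", ")))
    }
  }
  num <- as.matrix(points[cols[-(1:2)]])
  if (!is.numeric(num) || !all(is.finite(num))) {
    abort("cohort coordinates must all be finite numbers")
  }
  arrange(points, .data$patient_id, seg_order(.data$segment))
}

validate_lungs <- function(lungs) {
  need <- c("patient_id", "state", "left_ml", "right_ml", "total_ml")
  missing_cols <- setdiff(need, names(lungs))
  if (length(missing_cols)) {
    abort(paste0("lung table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  lungs <- as_tibble(lungs)[need]
  bad <- setdiff(unique(lungs$state), imaging_states())
  if (length(bad)) {
    abort(paste0("unknown imaging state(s): ", paste(bad, collapse = ", ")))
  }
  vols <- as.matrix(lungs[c("left_ml", "right_ml", "total_ml")])
  if (!all(is.finite(vols)) || any(vols <= 0)) {
    abort("lung volumes must be finite and positive")
  }
  if (any(abs(lungs$total_ml - lungs$left_ml - lungs$right_ml) > 1)) {
    abort("total lung volume must equal left + right within 1 ml")
  }
  arrange(lungs, .data$patient_id, match(.data$state, imaging_states()))
}

#' @export
print.liver_cohort <- function(x, ...) {
  cat(sprintf("<liver_cohort> %d patient(s), %d point observation(s)\n",
              x$n, nrow(x$points)))
  if (nrow(x$lungs)) cat("  lung volumes: yes\n")
  if (!is.null(x$traces)) cat(sprintf("  breathing traces: %d\n", length(x$traces)))
  if (!is.null(x$seed)) cat(sprintf("  seed: %s\n", format(x$seed)))
  invisible(x)
}

#' Cohort accessors
#'
#' Extract the component tables of a `liver_cohort`.  `cohort_points()`
#' returns the point-observation tibble (also available through
#' [as_tibble()][tibble::as_tibble]), `cohort_lungs()` the per-patient lung
#' volumes, and `cohort_traces()` the list of breathing traces (possibly
#' `NULL`).
#'
#' @param cohort A `liver_cohort`.
#' @return A tibble (or list of traces).
#' @export
cohort_points <- function(cohort) {
  stopifnot(inherits(cohort, "liver_cohort"))
  cohort$points
}

#' @rdname cohort_points
#' @export
cohort_lungs <- function(cohort) {
  stopifnot(inherits(cohort, "liver_cohort"))
  cohort$lungs
}

#' @rdname cohort_points
#' @export
cohort_traces <- function(cohort) {
  stopifnot(inherits(cohort, "liver_cohort"))
  cohort$traces
}

#' @export
as_tibble.liver_cohort <- function(x, ...) {
  x$points
}

# accept either a liver_cohort or a bare point table
as_cohort_points <- function(x) {
  if (inherits(x, "liver_cohort")) return(x$points)
  if (is.data.frame(x)) {
    missing_cols <- setdiff(cohort_point_cols(), names(x))
    if (length(missing_cols)) {
      abort(paste0("point table is missing columns: ",
                   paste(missing_cols, collapse = ", ")))
    }
    return(as_tibble(x))
  }
  abort("expected a liver_cohort or a cohort point table")
}

n_patients_of <- function(x) {
  if (inherits(x, "liver_cohort")) return(x$n)
  length(unique(as_cohort_points(x)$patient_id))
}
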