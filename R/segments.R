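#' Couinaud liver segment labels
#'
#' The nine functional liver segments used throughout the package, in
#' canonical order: the caudate lobe (S1), the left-lateral segments (S2, S3),
#' the left-medial segments (S4a, S4b) and the right-lobe segments (S5--S8).
#' Every cohort carries exactly one representative point per segment per
#' patient.
#'
#' @return Character vector of the nine segment labels.
#' @export
#' @examples
#' liver_segments()
liver_segments <- function() {
  c("S1", "S2", "S3", "S4a", "S4b", "S5", "S6", "S7", "S8")
}

#' Patient motion axes
#'
#' The three patient axes along which displacements are measured, with the
#' fixed sign convention used everywhere in the package: positive values are
#' excursions toward the patient's left (`lr`), posterior (`ap`) and superior
#' (`si`); negative values toward right, anterior, inferior.
#'
#' @return Character vector `c("lr", "ap", "si")`.
#' @export
motion_axes <- function() {
  c("lr", "ap", "si")
}

#' Imaging-state pairs
#'
#' The three ordered pairs of imaging states between which displacements are
#' computed.  `phase0_to_phase50` is the full expiration excursion
#' (end-inspiration to end-expiration of the gated 4DCT);
#' the two `helical_to_*` pairs measure where the free-breathing helical
#' snapshot sits relative to the respiratory extremes and drive the ITV margin
#' derivation.  Displacements are always destination minus origin.
#'
#' @return Character vector of the three state-pair names.
#' @export
state_pairs <- function() {
  c("phase0_to_phase50", "helical_to_phase0", "helical_to_phase50")
}

imaging_states <- function() {
  c("helical", "phase0", "phase50")
}

# origin/destination columns per state pair
pair_states <- function(pair) {
  switch(pair,
    phase0_to_phase50  = c(origin = "phase0",  dest = "phase50"),
    helical_to_phase0  = c(origin = "helical", dest = "phase0"),
    helical_to_phase50 = c(origin = "helical", dest = "phase50"),
    abort(paste0("unknown state pair: ", pair))
  )
}

#' Fixed reference layout of the nine representative points
#'
#' A fixed 3D arrangement (mm, left/posterior/superior positive) of one
#' representative point per Couinaud segment, loosely following the anatomical
#' arrangement: left-lateral segments at positive `lr`, right-lobe segments at
#' negative `lr`, posterior segments (S1, S6, S7) at positive `ap`, and the
#' superior segments (S2, S4a, S7, S8) high on `si`.  The absolute coordinates
#' are arbitrary: every statistic in the package depends only on displacement
#' differences between imaging states, never on the reference positions.
#'
#' @return Tibble with columns `segment`, `lr`, `ap`, `si`.
#' @export
segment_layout <- function() {
  tibble(
    segment = liver_segments(),
    lr = c(5, 70, 60, 25, 25, -30, -55, -60, -30),
    ap = c(30, 20, -10, 0, -20, -25, 25, 35, -15),
    si = c(40, 70, 30, 65, 30, 25, 20, 65, 70)
  )
}

#' Reference per-segment expiration amplitudes (20-patient cohort)
#'
#' Signed mean and standard deviation (mm) of the phase 0 to phase 50
#' displacement of each liver segment's representative point, as reported for
#' the 20-patient free-breathing cohort that this package's simulator is
#' calibrated to.  Positive = left / posterior / superior.  These values are
#' the default displacement distributions of [sim_params()].
#'
#' @return Tibble with columns `segment`, `axis`, `mean`, `sd` (27 rows).
#' @seealso [reference_helical_stats()], [reference_margins()]
#' @export
#' @examples
#' reference_amplitudes() %>% dplyr::filter(segment == "S7")
reference_amplitudes <- function() {
  tibble(
    segment = rep(liver_segments(), each = 3L),
    axis    = rep(motion_axes(), times = 9L),
    mean = c(
      -2.0, 1.0, 5.5,
       0.3, 1.2, 6.3,
      -0.3, 2.4, 5.8,
      -1.4, 1.5, 3.0,
      -1.2, 2.0, 5.3,
      -0.2, 3.2, 5.5,
      -0.1, 2.2, 6.5,
      -1.4, 3.5, 8.6,
       1.0, 3.3, 5.0
    ),
    sd = c(
      2.6, 1.3, 2.6,
      2.2, 3.5, 4.2,
      1.9, 1.4, 2.8,
      3.3, 2.4, 2.6,
      1.6, 1.9, 3.4,
      2.1, 2.0, 2.4,
      4.6, 2.3, 3.5,
      3.8, 2.5, 3.4,
      2.6, 2.3, 3.3
    )
  )
}

#' Reference helical-to-phase displacement statistics (20-patient cohort)
#'
#' Signed mean and standard deviation (mm) of the displacement from the
#' free-breathing helical snapshot to the end-inspiration (phase 0) and
#' end-expiration (phase 50) 4DCT bins, per segment and axis, as reported for
#' the reference 20-patient cohort.  These are the direct inputs of the ITV
#' margin rule; feeding them to [itv_margin()] with the default
#' [margin_config()] reproduces the reference margins of
#' [reference_margins()] to within the 0.1 mm rounding of the inputs.
#'
#' @return Tibble with columns `segment`, `axis`, `pair`, `mean`, `sd`
#'   (54 rows; `pair` is `"helical_to_phase0"` or `"helical_to_phase50"`).
#' @export
reference_helical_stats <- function() {
  h0 <- tibble(
    segment = rep(liver_segments(), each = 3L),
    axis    = rep(motion_axes(), times = 9L),
    pair    = "helical_to_phase0",
    mean = c(
       0.8,  0.4, -2.5,
      -1.1, -0.6, -2.4,
      -0.3, -1.8, -2.9,
       0.4, -1.4, -0.6,
      -0.5, -1.7, -2.4,
      -2.2, -1.4, -1.9,
       0.2, -1.2, -3.2,
       0.3, -1.7, -3.6,
      -2.2, -1.5, -1.9
    ),
    sd = c(
      3.1, 1.6, 3.9,
      2.5, 3.7, 4.9,
      2.9, 3.1, 3.5,
      2.8, 2.1, 3.9,
      1.5, 2.2, 3.5,
      1.7, 2.1, 2.2,
      4.3, 2.3, 2.9,
      4.2, 2.8, 4.4,
      2.5, 2.6, 3.4
    )
  )
  h50 <- tibble(
    segment = rep(liver_segments(), each = 3L),
    axis    = rep(motion_axes(), times = 9L),
    pair    = "helical_to_phase50",
    mean = c(
      -1.1, 1.4, 3.0,
      -0.8, 0.6, 3.9,
      -0.7, 0.6, 2.9,
      -1.0, 0.1, 2.4,
      -1.8, 0.3, 2.9,
      -2.3, 1.7, 3.7,
       0.1, 1.0, 3.3,
      -1.1, 1.8, 5.0,
      -1.3, 1.8, 3.2
    ),
    sd = c(
      2.2, 1.8, 3.5,
      2.6, 2.1, 4.1,
      3.1, 3.0, 2.5,
      1.7, 2.4, 3.4,
      1.6, 2.2, 3.3,
      1.3, 2.4, 2.1,
      4.1, 2.3, 3.7,
      2.6, 2.1, 4.8,
      1.5, 2.5, 3.1
    )
  )
  bind_rows(h0, h50)
}

#' Reference ITV expansion margins (20-patient cohort)
#'
#' The published asymmetric ITV expansion margins (mm) per segment and axis
#' for the reference cohort: `neg` is the (non-positive) expansion toward
#' right / anterior / inferior and `pos` the (non-negative) expansion toward
#' left / posterior / superior.  Used as the comparison standard for
#' [itv_margin()] applied to [reference_helical_stats()].
#'
#' @return Tibble with columns `segment`, `axis`, `neg`, `pos` (27 rows).
#' @export
reference_margins <- function() {
  tibble(
    segment = rep(liver_segments(), each = 3L),
    axis    = rep(motion_axes(), times = 9L),
    neg = c(
      -2.2, -0.4, -4.4,
      -2.3, -2.4, -4.7,
      -2.2, -3.3, -4.6,
      -1.8, -2.4, -2.4,
      -2.6, -2.8, -4.1,
      -3.0, -2.4, -3.0,
      -1.9, -2.3, -4.6,
      -2.4, -3.1, -5.7,
      -3.4, -2.8, -3.5
    ),
    pos = c(
      2.3, 2.3, 4.7,
      0.5, 1.6, 5.9,
      1.1, 2.1, 4.1,
      1.8, 1.3, 4.0,
      0.3, 1.4, 4.5,
      0.0, 2.9, 4.7,
      2.3, 2.1, 5.1,
      2.3, 2.8, 7.3,
      0.0, 3.0, 4.7
    )
  )
}

#' Reference mean lung volumes (20-patient cohort)
#'
#' Mean left, right and total lung volumes (ml) at the three imaging states
#' for the reference cohort.  The strict ordering phase 50 < helical < phase 0
#' of these means is the respiratory-stability assumption that
#' [lung_bracket_check()] verifies per patient; the phase 0 and phase 50 means
#' also parameterize the lung-volume part of the cohort generator.
#'
#' @return Tibble with columns `state`, `left_ml`, `right_ml`, `total_ml`.
#' @export
reference_lung_volumes <- function() {
  tibble(
    state    = imaging_states(),
    left_ml  = c(1104.6, 1167.0, 1034.3),
    right_ml = c(1444.7, 1529.8, 1336.1),
    total_ml = c(2549.36, 2696.8, 2370.4)
  )
}

# round half away from zero, as used in all printed reports
round_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
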