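#' Signed displacement between two imaging states
#'
#' Computes, for every point observation, the signed displacement vector of
#' the chosen state pair: destination minus origin on each axis, under the
#' package-wide sign convention (positive = left / posterior / superior).
#' `phase0_to_phase50` measures the full expiration excursion;
#' `helical_to_phase0` and `helical_to_phase50` measure from the helical
#' snapshot to the respective 4DCT extreme.
#'
#' @param x A `liver_cohort` or a cohort point table (see
#'   [generate_cohort()] for the schema).
#' @param pair One of [state_pairs()].
#' @return Tibble with columns `patient_id`, `segment`, `pair`, `lr`, `ap`,
#'   `si` (mm, signed).
#' @export
#' @examples
#' obs <- tibble::tibble(
#'   patient_id = "P1", segment = "S7",
#'   helical_lr = 5, helical_ap = 5, helical_si = 5,
#'   phase0_lr = 0, phase0_ap = 0, phase0_si = 0,
#'   phase50_lr = 4, phase50_ap = 7, phase50_si = 10
#' )
#' displacement(obs, "helical_to_phase50")   # (-1, 2, 5)
displacement <- function(x, pair = state_pairs()) {
  pair <- rlang::arg_match(pair)
  points <- as_cohort_points(x)
  num <- as.matrix(points[setdiff(cohort_point_cols(), c("patient_id", "segment"))])
  if (anyNA(num) || !all(is.finite(num))) {
    abort("point observations must be complete (no missing coordinates)")
  }
  st <- pair_states(pair)
  out <- tibble(
    patient_id = points$patient_id,
    segment = points$segment,
    pair = pair
  )
  for (ax in motion_axes()) {
    out[[ax]] <- points[[paste0(st[["dest"]], "_", ax)]] -
      points[[paste0(st[["origin"]], "_", ax)]]
  }
  out
}

#' Per-segment displacement statistics over a cohort
#'
#' Mean and sample standard deviation (n - 1 denominator) of the signed
#' displacement component over patients, for every segment and axis, for one
#' state pair.  The n - 1 convention matches the Student-t interval the
#' margin rule builds on these statistics.
#'
#' @inheritParams displacement
#' @param segments Optional subset of [liver_segments()] to keep.
#' @return Tibble with columns `segment`, `axis`, `pair`, `mean`, `sd`, `n`
#'   (mm; one row per segment x axis).
#' @export
#' @examples
#' coh <- generate_cohort(n_patients = 20, seed = 1)
#' amplitude_stats(coh, "phase0_to_phase50") %>%
#'   dplyr::filter(segment == "S7", axis == "si")
amplitude_stats <- function(x, pair = state_pairs(), segments = NULL) {
  pair <- rlang::arg_match(pair)
  disp <- displacement(x, pair)
  if (!is.null(segments)) disp <- filter(disp, .data$segment %in% segments)
  if (length(unique(disp$patient_id)) < 2L) {
    abort("amplitude statistics need at least 2 patients (sample SD undefined)")
  }
  segs <- intersect(liver_segments(), unique(disp$segment))
  grp <- factor(disp$segment, levels = segs)
  n_seg <- as.vector(table(grp))
  k <- length(motion_axes())
  mean_mat <- sd_mat <- matrix(0, length(segs), k)
  for (ai in seq_len(k)) {
    v <- disp[[motion_axes()[ai]]]
    s1 <- rowsum(v, grp)[, 1]
    s2 <- rowsum(v * v, grp)[, 1]
    m <- s1 / n_seg
    mean_mat[, ai] <- m
    sd_mat[, ai] <- sqrt(pmax(s2 - n_seg * m^2, 0) / (n_seg - 1L))
  }
  # assemble directly in canonical order (segment-major, axes lr/ap/si)
  tibble(
    segment = rep(segs, each = k),
    axis = rep(motion_axes(), times = length(segs)),
    pair = pair,
    mean = as.vector(t(mean_mat)),
    sd = as.vector(t(sd_mat)),
    n = rep(n_seg, each = k)
  )
}

#' Cohort amplitude summary table
#'
#' The per-segment displacement statistics of [amplitude_stats()] plus an
#' overall row (`segment = "ALL"`) summarizing all segments together.  By
#' default the overall mean and SD are computed over the pooled
#' 9 x n per-patient values per axis (so the overall SD mixes within- and
#' between-segment variability); `overall_sd = "mean_of_sds"` instead reports
#' the unweighted mean of the nine per-segment SDs.  Since every segment
#' contributes the same number of patients, the pooled overall mean always
#' equals the unweighted mean of the nine segment means.
#'
#' @inheritParams displacement
#' @param overall_sd `"pooled"` (default) or `"mean_of_sds"`.
#' @return A tibble of class `amplitude_table` with columns `segment`
#'   (nine segments then `"ALL"`), `axis`, `pair`, `mean`, `sd`, `n`.
#' @seealso [format_amplitude_table()] for a report-style text rendering.
#' @export
#' @examples
#' coh <- generate_cohort(n_patients = 20, seed = 1)
#' amplitude_table(coh, "phase0_to_phase50")
amplitude_table <- function(x, pair = state_pairs(),
                            overall_sd = c("pooled", "mean_of_sds")) {
  pair <- rlang::arg_match(pair)
  overall_sd <- rlang::arg_match(overall_sd)
  per_seg <- amplitude_stats(x, pair)

  disp <- displacement(x, pair)
  long <- tidyr::pivot_longer(disp, all_of(motion_axes()),
                              names_to = "axis", values_to = "value")
  overall <- long %>%
    group_by(.data$axis) %>%
    summarise(
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(segment = "ALL", pair = !!pair)
  if (overall_sd == "mean_of_sds") {
    sds <- per_seg %>%
      group_by(.data$axis) %>%
      summarise(sd = mean(.data$sd), .groups = "drop")
    overall$sd <- sds$sd[match(overall$axis, sds$axis)]
  }
  out <- bind_rows(per_seg, overall[names(per_seg)]) %>%
    arrange(match(.data$axis, motion_axes())) %>%
    arrange(ifelse(.data$segment == "ALL", 10L, seg_order(.data$segment)))
  structure(out, class = c("amplitude_table", class(tibble())),
            pair = pair, overall_sd = overall_sd)
}

#' Render an amplitude table as aligned text
#'
#' Mirrors the layout of a published amplitude table: one row per segment
#' plus a mean row, one `mean +/- sd` column per axis (0.1 mm, half away from
#' zero), and the sign-convention footnote.
#'
#' @param x An [amplitude_table()].
#' @return Character vector of report lines (invisibly printable with
#'   `writeLines()`).
#' @export
format_amplitude_table <- function(x) {
  stopifnot(inherits(x, "amplitude_table"))
  wide <- x %>%
    mutate(cell = sprintf("%.1f ± %.1f", round_away(.data$mean, 1),
                          round_away(.data$sd, 1))) %>%
    select("segment", "axis", "cell") %>%
    tidyr::pivot_wider(names_from = "axis", values_from = "cell")
  seg_lab <- ifelse(wide$segment == "ALL", "mean", wide$segment)
  fmt <- "%-6s %14s %14s %14s"
  c(
    sprintf("Amplitude (mean ± SD, mm), state pair: %s", attr(x, "pair")),
    sprintf(fmt, "Seg", "LR", "AP", "SI"),
    sprintf(fmt, seg_lab, wide$lr, wide$ap, wide$si),
    "Positive = left / posterior / superior; negative = right / anterior / inferior."
  )
}

#' @export
tidy.amplitude_table <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.amplitude_table <- function(x, ...) {
  seg <- filter(as_tibble(x), .data$segment != "ALL")
  top <- seg[which.max(abs(seg$mean)), ]
  all_row <- filter(as_tibble(x), .data$segment == "ALL")
  tibble(
    pair = attr(x, "pair"),
    n_patients = x$n[x$segment != "ALL"][1],
    overall_mean_si = all_row$mean[all_row$axis == "si"],
    largest_segment = top$segment,
    largest_axis = top$axis,
    largest_mean = top$mean
  )
}

#' @export
autoplot.amplitude_table <- function(object, ...) {
  df <- as_tibble(object) %>%
    filter(.data$segment != "ALL") %>%
    mutate(
      segment = factor(.data$segment, levels = liver_segments()),
      axis = factor(toupper(.data$axis), levels = c("LR", "AP", "SI"))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      colour = "steelblue"
    ) +
    ggplot2::facet_wrap(~axis) +
    ggplot2::labs(
      x = NULL, y = "displacement (mm)",
      title = sprintf("Segment displacement, %s", attr(object, "pair")),
      subtitle = "mean ± SD over patients; positive = left/posterior/superior"
    ) +
    ggplot2::theme_minimal()
}
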