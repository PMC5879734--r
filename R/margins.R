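#' Margin derivation settings
#'
#' The ITV margin rule widens each cohort-mean displacement by a Student-t
#' half-width `coverage_t * sd / sqrt(n)`.  At the reference cohort size
#' n = 20 the multiplier is fixed at the published value 2.093
#' (the two-sided 95% Student-t quantile at 19 degrees of freedom, printed to
#' three decimals); for any other n it defaults to `qt(0.975, n - 1)`.
#'
#' @param n Cohort size (>= 2).
#' @param coverage_t Optional explicit t multiplier (> 0); overrides the
#'   default quantile.
#' @return An object of class `margin_config`.
#' @export
#' @examples
#' margin_config(20)$coverage_t        # 2.093
#' margin_config(10)$coverage_t        # qt(0.975, 9)
margin_config <- function(n = 20, coverage_t = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != floor(n)) {
    abort("`n` must be an integer >= 2")
  }
  if (is.null(coverage_t)) {
    coverage_t <- if (n == 20) 2.093 else qt(0.975, n - 1)
  }
  if (!is.numeric(coverage_t) || length(coverage_t) != 1L || coverage_t <= 0) {
    abort("`coverage_t` must be a single positive number")
  }
  structure(list(n = as.integer(n), coverage_t = coverage_t),
            class = "margin_config")
}

#' @export
print.margin_config <- function(x, ...) {
  cat(sprintf("<margin_config> n = %d, coverage_t = %.4g (halfwidth = t*sd/sqrt(n))\n",
              x$n, x$coverage_t))
  invisible(x)
}

#' Student-t half-width of a cohort-mean displacement
#'
#' `coverage_t * sd / sqrt(n)`: the half-width added on both sides of a mean
#' helical-to-phase displacement before enveloping and clamping.
#'
#' @param sd Standard deviation(s) in mm (>= 0; vectorized).
#' @param config A [margin_config()].
#' @return Half-width(s) in mm.
#' @export
#' @examples
#' t_halfwidth(4.4, margin_config(20))   # 2.059 mm
t_halfwidth <- function(sd, config = margin_config()) {
  stopifnot(inherits(config, "margin_config"))
  if (!is.numeric(sd) || any(!is.finite(sd)) || any(sd < 0)) {
    abort("`sd` must be finite and >= 0")
  }
  config$coverage_t * sd / sqrt(config$n)
}

#' Per-phase t-interval of the mean displacement
#'
#' Adds the interval `[mean - hw, mean + hw]` (with `hw = t_halfwidth(sd)`)
#' to each row of a displacement statistics table.  This is the interval the
#' margin rule builds for each of the two helical-to-phase state pairs before
#' taking their envelope.
#'
#' @param stats Tibble with at least columns `mean` and `sd` (typically an
#'   [amplitude_stats()] result).
#' @param config A [margin_config()].
#' @return The input tibble with columns `lo` and `hi` appended.
#' @export
#' @examples
#' phase_interval(tibble::tibble(mean = -3.6, sd = 4.4), margin_config(20))
phase_interval <- function(stats, config = margin_config()) {
  if (!is.data.frame(stats) || !all(c("mean", "sd") %in% names(stats))) {
    abort("`stats` must be a data frame with columns mean and sd")
  }
  hw <- t_halfwidth(stats$sd, config)
  mutate(as_tibble(stats), lo = .data$mean - hw, hi = .data$mean + hw)
}

# envelope of per-pair intervals per (segment, axis); optional zero clamp
margin_bounds <- function(stats, config, clamp = TRUE) {
  iv <- phase_interval(stats, config)
  out <- iv %>%
    group_by(.data$segment, .data$axis) %>%
    summarise(neg = min(.data$lo), pos = max(.data$hi), .groups = "drop")
  if (clamp) {
    out <- mutate(out, neg = pmin(0, .data$neg), pos = pmax(0, .data$pos))
  }
  arrange(out, seg_order(.data$segment), match(.data$axis, motion_axes()))
}

#' Asymmetric ITV margin from the two helical-to-phase statistics
#'
#' The margin rule: for each segment and axis, build the Student-t interval
#' `mean +/- coverage_t * sd / sqrt(n)` for the mean helical-to-phase-0 and
#' the mean helical-to-phase-50 displacement, take the envelope of the two
#' intervals, and clamp it to include zero, so the expansion never shrinks
#' the target in either direction.  The result is an asymmetric pair:
#' `neg <= 0` is the expansion toward right / anterior / inferior and
#' `pos >= 0` toward left / posterior / superior.
#'
#' @param stats Tibble with columns `segment`, `axis`, `pair`, `mean`, `sd`
#'   holding both rows `helical_to_phase0` and `helical_to_phase50` for every
#'   segment/axis cell (e.g. [reference_helical_stats()], or two bound
#'   [amplitude_stats()] results).
#' @param config A [margin_config()].
#' @return Tibble with columns `segment`, `axis`, `neg`, `pos` (mm).
#' @export
#' @examples
#' itv_margin(reference_helical_stats(), margin_config(20)) %>%
#'   dplyr::filter(segment == "S7", axis == "si")   # about (-5.66, 7.25)
itv_margin <- function(stats, config = margin_config()) {
  need <- c("segment", "axis", "pair", "mean", "sd")
  if (!is.data.frame(stats) || !all(need %in% names(stats))) {
    abort("`stats` must have columns segment, axis, pair, mean, sd")
  }
  helical <- c("helical_to_phase0", "helical_to_phase50")
  stats <- filter(as_tibble(stats), .data$pair %in% helical)
  counts <- stats %>%
    group_by(.data$segment, .data$axis) %>%
    summarise(k = dplyr::n_distinct(.data$pair), .groups = "drop")
  if (nrow(counts) == 0L || any(counts$k != 2L)) {
    bad <- counts$segment[counts$k != 2L]
    abort(paste0(
      "every segment/axis cell needs both helical_to_phase0 and ",
      "helical_to_phase50 statistics",
      if (length(bad)) paste0(" (incomplete: ", paste(unique(bad), collapse = ", "), ")")
    ))
  }
  margin_bounds(stats, config, clamp = TRUE)
}

#' Full ITV margin table for a cohort
#'
#' Computes the helical-to-phase-0 and helical-to-phase-50 displacement
#' statistics of a cohort, applies the envelope-and-clamp margin rule
#' ([itv_margin()]) to all 27 segment/axis cells, and appends an overall row
#' (`segment = "ALL"`) whose margins are the unweighted means of the nine
#' per-segment margins per axis and direction (and whose statistics pool all
#' per-patient values).
#'
#' @param x A `liver_cohort` or cohort point table.
#' @param config A [margin_config()]; if `NULL` (default) it is built for the
#'   cohort's patient count.
#' @return A tibble of class `margin_table` with columns `segment`, `axis`,
#'   `mean_h0`, `sd_h0`, `mean_h50`, `sd_h50`, `neg`, `pos`.
#' @seealso [format_margin_table()], [margins_as_directions()]
#' @export
#' @examples
#' coh <- generate_cohort(n_patients = 20, seed = 1)
#' margin_table(coh)
margin_table <- function(x, config = NULL) {
  points <- as_cohort_points(x)
  if (is.null(config)) config <- margin_config(n_patients_of(points))
  stopifnot(inherits(config, "margin_config"))

  s0 <- amplitude_stats(points, "helical_to_phase0")
  s50 <- amplitude_stats(points, "helical_to_phase50")
  stats <- bind_rows(s0, s50)
  margins <- itv_margin(stats, config)

  wide <- stats %>%
    select("segment", "axis", "pair", "mean", "sd") %>%
    tidyr::pivot_wider(names_from = "pair", values_from = c("mean", "sd")) %>%
    rename(
      mean_h0 = "mean_helical_to_phase0", sd_h0 = "sd_helical_to_phase0",
      mean_h50 = "mean_helical_to_phase50", sd_h50 = "sd_helical_to_phase50"
    )
  out <- left_join(wide, margins, by = c("segment", "axis"))

  t0 <- amplitude_table(points, "helical_to_phase0")
  t50 <- amplitude_table(points, "helical_to_phase50")
  all0 <- filter(as_tibble(t0), .data$segment == "ALL")
  all50 <- filter(as_tibble(t50), .data$segment == "ALL")
  overall <- out %>%
    group_by(.data$axis) %>%
    summarise(neg = mean(.data$neg), pos = mean(.data$pos), .groups = "drop") %>%
    mutate(
      segment = "ALL",
      mean_h0 = all0$mean[match(.data$axis, all0$axis)],
      sd_h0 = all0$sd[match(.data$axis, all0$axis)],
      mean_h50 = all50$mean[match(.data$axis, all50$axis)],
      sd_h50 = all50$sd[match(.data$axis, all50$axis)]
    )
  out <- bind_rows(out, overall[names(out)]) %>%
    arrange(ifelse(.data$segment == "ALL", 10L, seg_order(.data$segment)),
            match(.data$axis, motion_axes()))
  structure(out, class = c("margin_table", class(tibble())), config = config)
}

#' Render a margin table as aligned text
#'
#' One row per segment (plus the mean row): the two helical-to-phase
#' mean +/- SD statistics and the derived "neg and pos" margin per axis,
#' rounded to 0.1 mm half away from zero.
#'
#' @param x A [margin_table()].
#' @return Character vector of report lines.
#' @export
format_margin_table <- function(x) {
  stopifnot(inherits(x, "margin_table"))
  df <- as_tibble(x) %>%
    mutate(
      stat0 = sprintf("%.1f±%.1f", round_away(.data$mean_h0, 1), round_away(.data$sd_h0, 1)),
      stat50 = sprintf("%.1f±%.1f", round_away(.data$mean_h50, 1), round_away(.data$sd_h50, 1)),
      marg = sprintf("%.1f and %.1f", round_away(.data$neg, 1), round_away(.data$pos, 1))
    )
  wide <- function(col) {
    df %>%
      select("segment", "axis", all_of(col)) %>%
      tidyr::pivot_wider(names_from = "axis", values_from = all_of(col))
  }
  w0 <- wide("stat0"); w50 <- wide("stat50"); wm <- wide("marg")
  seg_lab <- ifelse(w0$segment == "ALL", "mean", w0$segment)
  fmt <- "%-6s | %11s %11s %11s | %11s %11s %11s | %15s %15s %15s"
  c(
    "ITV expansion margins from helical-to-4DCT displacement statistics",
    sprintf(fmt, "", "helical->ph0", "", "", "helical->ph50", "", "", "margin", "", ""),
    sprintf(fmt, "Seg", "LR", "AP", "SI", "LR", "AP", "SI", "LR", "AP", "SI"),
    sprintf(fmt, seg_lab, w0$lr, w0$ap, w0$si, w50$lr, w50$ap, w50$si,
            wm$lr, wm$ap, wm$si),
    "Positive margins expand toward left / posterior / superior; negative toward right / anterior / inferior."
  )
}

#' Margins as magnitudes with anatomical direction labels
#'
#' Re-expresses the signed margin pairs as non-negative expansion distances
#' labelled by anatomical direction (right/left, anterior/posterior,
#' inferior/superior).
#'
#' @param x A [margin_table()] or any tibble with `segment`, `axis`, `neg`,
#'   `pos`.
#' @return Tibble with columns `segment`, `axis`, `direction`, `margin_mm`.
#' @export
margins_as_directions <- function(x) {
  need <- c("segment", "axis", "neg", "pos")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort("`x` must have columns segment, axis, neg, pos")
  }
  dir_neg <- c(lr = "right", ap = "anterior", si = "inferior")
  dir_pos <- c(lr = "left", ap = "posterior", si = "superior")
  df <- as_tibble(x)[need]
  bind_rows(
    mutate(df, direction = dir_neg[.data$axis], margin_mm = -.data$neg),
    mutate(df, direction = dir_pos[.data$axis], margin_mm = .data$pos)
  ) %>%
    select("segment", "axis", "direction", "margin_mm") %>%
    arrange(ifelse(.data$segment == "ALL", 10L, seg_order(.data$segment)),
            match(.data$axis, motion_axes()), .data$direction)
}

#' @export
tidy.margin_table <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(c("neg", "pos"), names_to = "side", values_to = "margin_mm") %>%
    select("segment", "axis", "side", "margin_mm")
}

#' @export
glance.margin_table <- function(x, ...) {
  cfg <- attr(x, "config")
  seg <- filter(as_tibble(x), .data$segment != "ALL")
  widest <- seg[which.max(seg$pos - seg$neg), ]
  tibble(
    n = cfg$n,
    coverage_t = cfg$coverage_t,
    n_cells = nrow(seg),
    widest_segment = widest$segment,
    widest_axis = widest$axis,
    max_pos = max(seg$pos),
    min_neg = min(seg$neg)
  )
}

#' @export
autoplot.margin_table <- function(object, ...) {
  df <- as_tibble(object) %>%
    filter(.data$segment != "ALL") %>%
    mutate(
      segment = factor(.data$segment, levels = rev(liver_segments())),
      axis = factor(toupper(.data$axis), levels = c("LR", "AP", "SI"))
    )
  ggplot2::ggplot(df, ggplot2::aes(y = .data$segment)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_linerange(
      ggplot2::aes(xmin = .data$neg, xmax = .data$pos),
      linewidth = 3, colour = "steelblue", alpha = 0.7
    ) +
    ggplot2::facet_wrap(~axis) +
    ggplot2::labs(
      x = "ITV expansion (mm)", y = NULL,
      title = "Asymmetric ITV expansion margins per liver segment",
      subtitle = "positive = left/posterior/superior"
    ) +
    ggplot2::theme_minimal()
}
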