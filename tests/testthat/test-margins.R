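test_that("the t half-width matches direct arithmetic", {
  cfg <- margin_config(20)
  expect_equal(cfg$coverage_t, 2.093)
  expect_equal(t_halfwidth(0, cfg), 0)
  expect_equal(t_halfwidth(4.4, cfg), 2.093 * 4.4 / sqrt(20))
  expect_equal(t_halfwidth(4.4, cfg), 2.059, tolerance = 5e-4)
  expect_equal(t_halfwidth(3.4, cfg), 1.591, tolerance = 5e-4)
  expect_error(t_halfwidth(-1, cfg), ">= 0")
})

test_that("the t multiplier defaults to the Student quantile away from n = 20", {
  expect_equal(margin_config(10)$coverage_t, stats::qt(0.975, 9))
  expect_equal(margin_config(41)$coverage_t, stats::qt(0.975, 40))
  expect_error(margin_config(1), ">= 2")
})

test_that("phase intervals match hand arithmetic on the reference statistics", {
  cfg <- margin_config(20)
  iv <- phase_interval(tibble::tibble(mean = 0, sd = 0), cfg)
  expect_equal(c(iv$lo, iv$hi), c(0, 0))
  iv <- phase_interval(tibble::tibble(mean = -3.6, sd = 4.4), cfg)
  expect_equal(iv$lo, -5.66, tolerance = 0.01)
  expect_equal(iv$hi, -1.54, tolerance = 0.01)
  iv <- phase_interval(tibble::tibble(mean = 5.0, sd = 4.8), cfg)
  expect_equal(iv$lo, 2.75, tolerance = 0.01)
  expect_equal(iv$hi, 7.25, tolerance = 0.01)
})

ref_margin_cell <- function(seg, ax) {
  m <- itv_margin(reference_helical_stats(), margin_config(20))
  m[m$segment == seg & m$axis == ax, ]
}

test_that("the envelope-and-clamp rule reproduces the published margin cells", {
  s7 <- ref_margin_cell("S7", "si")
  expect_equal(round(s7$neg, 1), -5.7)
  expect_lt(abs(s7$pos - 7.3), 0.15)   # published 7.3, rounded inputs

  s5 <- ref_margin_cell("S5", "lr")     # both intervals entirely negative
  expect_equal(s5$pos, 0)
  expect_equal(round(s5$neg, 1), -3.0)

  s4a <- ref_margin_cell("S4a", "si")
  expect_equal(round(s4a$neg, 1), -2.4)
  expect_equal(round(s4a$pos, 1), 4.0)
})

test_that("zero statistics give a zero margin", {
  stats0 <- tidyr::crossing(
    segment = liver_segments(), axis = motion_axes(),
    pair = c("helical_to_phase0", "helical_to_phase50")
  )
  stats0$mean <- 0
  stats0$sd <- 0
  m <- itv_margin(stats0, margin_config(20))
  expect_equal(m$neg, rep(0, 27))
  expect_equal(m$pos, rep(0, 27))
})

test_that("all 54 reference margin bounds reproduce within input-rounding slack", {
  m <- itv_margin(reference_helical_stats(), margin_config(20))
  ref <- reference_margins()
  j <- merge(m, ref, by = c("segment", "axis"), suffixes = c("_hat", "_ref"))
  expect_equal(nrow(j), 27)
  expect_true(all(abs(j$neg_hat - j$neg_ref) <= 0.15))
  expect_true(all(abs(j$pos_hat - j$pos_ref) <= 0.15))
})

test_that("margins satisfy envelope, clamp, and monotonicity properties", {
  set.seed(101)
  cfg20 <- margin_config(20)
  for (i in 1:50) {
    st <- tibble::tibble(
      segment = "S1", axis = "si",
      pair = c("helical_to_phase0", "helical_to_phase50"),
      mean = stats::rnorm(2, 0, 5),
      sd = stats::rexp(2, 1 / 3)
    )
    full <- dplyr::bind_rows(lapply(liver_segments(), function(sg) {
      dplyr::mutate(tidyr::crossing(axis = motion_axes(),
                                    pair = st$pair),
                    segment = sg,
                    mean = rep(st$mean, 3), sd = rep(st$sd, 3))
    }))
    m <- itv_margin(full, cfg20)
    iv <- phase_interval(full, cfg20)
    j <- merge(iv, m, by = c("segment", "axis"))
    # every phase interval is inside [neg, pos]; zero always included
    expect_true(all(j$lo >= j$neg - 1e-12 & j$hi <= j$pos + 1e-12))
    expect_true(all(m$neg <= 0 & m$pos >= 0))
    # wider sd never shrinks the margin
    wider <- dplyr::mutate(full, sd = sd * 1.5)
    mw <- itv_margin(wider, cfg20)
    expect_true(all(mw$neg <= m$neg + 1e-12 & mw$pos >= m$pos - 1e-12))
    # larger n (holding means/sds) never widens it
    m40 <- itv_margin(full, margin_config(40))
    expect_true(all(m40$neg >= m$neg - 1e-12 & m40$pos <= m$pos + 1e-12))
  }
})

test_that("itv_margin rejects incomplete cells", {
  st <- reference_helical_stats()
  expect_error(itv_margin(st[st$pair == "helical_to_phase0", ]),
               "both helical_to_phase0 and")
  expect_error(itv_margin(st[-1, ]), "incomplete")
})

test_that("margin_table builds the full grid, includes zero, and matches itv_margin", {
  coh <- generate_cohort(n_patients = 20, seed = 14)
  mt <- margin_table(coh)
  seg <- mt[mt$segment != "ALL", ]
  expect_equal(nrow(seg), 27)
  expect_true(all(seg$neg <= 0 & seg$pos >= 0))

  stats <- dplyr::bind_rows(amplitude_stats(coh, "helical_to_phase0"),
                            amplitude_stats(coh, "helical_to_phase50"))
  m <- itv_margin(stats, margin_config(20))
  expect_equal(seg$neg, m$neg)
  expect_equal(seg$pos, m$pos)

  # overall row: mean of per-segment margins per axis/direction
  all_row <- mt[mt$segment == "ALL", ]
  for (ax in motion_axes()) {
    expect_equal(all_row$neg[all_row$axis == ax],
                 mean(seg$neg[seg$axis == ax]))
    expect_equal(all_row$pos[all_row$axis == ax],
                 mean(seg$pos[seg$axis == ax]))
  }
})

test_that("direction labelling flips signs into anatomical margins", {
  m <- ref_margin_cell("S7", "si")
  d <- margins_as_directions(m)
  expect_equal(d$margin_mm[d$direction == "inferior"], -m$neg)
  expect_equal(d$margin_mm[d$direction == "superior"], m$pos)
  expect_true(all(d$margin_mm >= 0))
})

test_that("tidiers and the plot method work on a margin table", {
  mt <- margin_table(generate_cohort(n_patients = 20, seed = 15))
  td <- tidy(mt)
  expect_true(all(c("segment", "axis", "side", "margin_mm") %in% names(td)))
  gl <- glance(mt)
  expect_equal(gl$n, 20L)
  expect_equal(gl$coverage_t, 2.093)
  p <- autoplot(mt)
  expect_s3_class(p, "ggplot")
})
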