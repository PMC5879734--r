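test_that("an empty cohort is valid, typed, and empty", {
  coh <- generate_cohort(n_patients = 0, seed = 1)
  expect_s3_class(coh, "liver_cohort")
  expect_equal(coh$n, 0)
  expect_equal(nrow(cohort_points(coh)), 0)
  expect_equal(nrow(cohort_lungs(coh)), 0)
})

test_that("degenerate variance gives exact totals and exact helical midpoints", {
  coh <- generate_cohort(deterministic_params(u = 0.5), n_patients = 3, seed = 1)
  ref <- reference_amplitudes()
  tot <- displacement(coh, "phase0_to_phase50")
  half <- displacement(coh, "helical_to_phase50")
  for (i in seq_len(nrow(tot))) {
    for (ax in motion_axes()) {
      mu <- ref$mean[ref$segment == tot$segment[i] & ref$axis == ax]
      expect_equal(tot[[ax]][i], mu, tolerance = 1e-12)
      expect_equal(half[[ax]][i], mu / 2, tolerance = 1e-12)
    }
  }
})

test_that("cohorts are bit-reproducible for a fixed seed and differ across seeds", {
  a <- generate_cohort(n_patients = 10, seed = 7)
  b <- generate_cohort(n_patients = 10, seed = 7)
  c <- generate_cohort(n_patients = 10, seed = 8)
  expect_identical(cohort_points(a), cohort_points(b))
  expect_identical(cohort_lungs(a), cohort_lungs(b))
  expect_false(isTRUE(all.equal(cohort_points(a), cohort_points(c))))
})

test_that("helical, phase-0 and phase-50 positions satisfy the state-pair identity", {
  coh <- generate_cohort(n_patients = 15, seed = 11)
  d_tot <- displacement(coh, "phase0_to_phase50")
  d_h0 <- displacement(coh, "helical_to_phase0")
  d_h50 <- displacement(coh, "helical_to_phase50")
  for (ax in motion_axes()) {
    expect_equal(d_h50[[ax]] - d_h0[[ax]], d_tot[[ax]], tolerance = 1e-9)
  }
})

test_that("a large cohort recovers every per-cell mean and SD of the model", {
  n <- 2000
  coh <- generate_cohort(sim_params(), n_patients = n, seed = 2025)
  got <- amplitude_stats(coh, "phase0_to_phase50")
  ref <- reference_amplitudes()
  joined <- merge(got, ref, by = c("segment", "axis"),
                  suffixes = c("_hat", "_true"))
  expect_equal(nrow(joined), 27)
  expect_true(all(abs(joined$mean_hat - joined$mean_true) <=
                    3 * joined$sd_true / sqrt(n)))
  expect_true(all(abs(joined$sd_hat / joined$sd_true - 1) <= 0.10))
})

test_that("lung volumes are positive, additive, and bracketed by construction", {
  lungs <- cohort_lungs(generate_cohort(n_patients = 30, seed = 5))
  expect_true(all(lungs$left_ml > 0 & lungs$right_ml > 0))
  expect_equal(lungs$total_ml, lungs$left_ml + lungs$right_ml)
  expect_true(all(lung_bracket_check(lungs)$pass))
})

test_that("invalid generator inputs are rejected", {
  expect_error(generate_cohort(n_patients = -1), "non-negative")
  expect_error(sim_params(helical_mean = 1.5), "helical_mean")
  expect_error(sim_params(period_s = 0), "period_s")
  bad <- reference_amplitudes()
  bad$sd[5] <- -1
  expect_error(sim_params(displacements = bad), "sd|SD")
  expect_error(sim_params(displacements = reference_amplitudes()[-1, ]),
               "segment")
})

test_that("a shared breathing-depth factor correlates a patient's displacements", {
  p <- sim_params(shared_depth_sd = 0.3)
  coh <- generate_cohort(p, n_patients = 400, seed = 9)
  d <- displacement(coh, "phase0_to_phase50")
  si_by_seg <- matrix(d$si, nrow = 9)   # segments x patients
  r <- stats::cor(si_by_seg["S7" == liver_segments(), ],
                  si_by_seg["S2" == liver_segments(), ])
  r_indep <- stats::cor(
    matrix(displacement(generate_cohort(n_patients = 400, seed = 9),
                        "phase0_to_phase50")$si, nrow = 9)[8, ],
    matrix(displacement(generate_cohort(n_patients = 400, seed = 9),
                        "phase0_to_phase50")$si, nrow = 9)[2, ]
  )
  # theoretical correlation for these segments at depth_sd = 0.3 is ~0.23
  expect_gt(r, 0.1)
  expect_lt(abs(r_indep), 0.15)
})
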