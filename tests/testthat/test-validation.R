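test_that("the overlap index matches its closed form and bounds", {
  expect_equal(voi(100, 100, 100), 1)
  expect_equal(voi(50, 80, 0), 0)
  expect_equal(voi(2, 2, 1), 0.5)

  set.seed(77)
  for (i in 1:100) {
    va <- stats::runif(1, 0.1, 500)
    vb <- stats::runif(1, 0.1, 500)
    vi <- stats::runif(1, 0, min(va, vb))
    v <- voi(va, vb, vi)
    expect_true(v >= 0 && v <= 1)
    expect_equal(v, voi(vb, va, vi))            # symmetry
    expect_lt(voi(va, vb, min(va, vb) * 0.999), 1)
  }
  expect_error(voi(0, 1, 0), "positive")
  expect_error(voi(2, 2, 3), "exceed")
  expect_error(voi(2, 2, -0.1), ">= 0")
})

test_that("lung bracketing passes the reference means and catches violations", {
  lv <- reference_lung_volumes()
  tab <- tibble::tibble(
    patient_id = "P1", state = lv$state,
    left_ml = lv$left_ml, right_ml = lv$right_ml, total_ml = lv$total_ml
  )
  res <- lung_bracket_check(tab)
  expect_equal(nrow(res), 3)
  expect_true(all(res$pass))

  # helical above end-inspiration: out of bracket
  bad <- tab
  bad$left_ml[bad$state == "helical"] <- bad$left_ml[bad$state == "phase0"] + 50
  bad$total_ml <- bad$left_ml + bad$right_ml
  expect_false(all(lung_bracket_check(bad)$pass))

  # exact ties pass (inclusive bounds)
  tie <- tab
  tie$left_ml <- 1000; tie$right_ml <- 1500; tie$total_ml <- 2500
  expect_true(all(lung_bracket_check(tie)$pass))

  expect_error(lung_bracket_check(tab[tab$state != "phase0", ]),
               "missing imaging state")
})

test_that("coverage is exact when the motion model is deterministic", {
  cov <- coverage_simulation(deterministic_params(u = 0.42),
                             n_patients = 20, n_reps = 20, seed = 1)
  expect_equal(cov$coverage_pct, 100)
  expect_equal(cov$tumor_coverage_pct, 100)
})

test_that("vacuously wide margins always cover", {
  cfg <- margin_config(20, coverage_t = 1e6)   # margins ~ +/- 1000 mm
  cov <- coverage_simulation(sim_params(), config = cfg,
                             n_patients = 20, n_reps = 20, seed = 2)
  expect_equal(cov$coverage_pct, 100)
  expect_equal(cov$tumor_coverage_pct, 100)
})

test_that("coverage is monotone in the margin width", {
  base <- coverage_simulation(sim_params(), config = margin_config(20),
                              n_patients = 20, n_reps = 120, seed = 5)
  wide <- coverage_simulation(sim_params(), config = margin_config(20, coverage_t = 4),
                              n_patients = 20, n_reps = 120, seed = 5)
  expect_gte(wide$coverage_pct, base$coverage_pct)
  expect_gte(wide$tumor_coverage_pct, base$tumor_coverage_pct)
  expect_true(all(wide$per_cell$mean_cov_pct >= base$per_cell$mean_cov_pct))
})

test_that("without clamp and with one phase the t-interval coverage is nominal", {
  # fixed helical fraction makes the helical->phase displacement exactly
  # normal, so the plain t-interval must cover its mean 95% of the time
  p <- sim_params(helical_sd = 0)
  cov <- coverage_simulation(p, config = margin_config(20),
                             n_patients = 20, n_reps = 600, seed = 8,
                             pairs = "helical_to_phase50", clamp = FALSE)
  expect_gt(cov$coverage_pct, 94)
  expect_lt(cov$coverage_pct, 96)
})

test_that("the validation report bundles lung, trace and coverage evidence", {
  coh <- generate_cohort(n_patients = 4, seed = 3, include_traces = TRUE)
  cov <- coverage_simulation(n_patients = 5, n_reps = 5, seed = 4)
  rep <- validation_report(coh, coverage = cov,
                           voi_volumes = tibble::tibble(
                             v_a = 2, v_b = 2, v_intersection = 1))
  expect_true(rep$lung_bracket$all_pass)
  expect_equal(nrow(rep$max_phase_error_pct), 4)
  expect_equal(rep$voi$voi, 0.5)
  expect_equal(rep$coverage$n_reps, 5)
})
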