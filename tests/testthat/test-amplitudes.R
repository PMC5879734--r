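test_that("displacement is destination minus origin under the sign convention", {
  obs <- point_obs(phase0 = c(0, 0, 0), phase50 = c(1, 2, 3))
  d <- displacement(obs, "phase0_to_phase50")
  expect_equal(unlist(d[motion_axes()]), c(lr = 1, ap = 2, si = 3))

  # 1 mm right, 2 mm posterior, 5 mm superior
  obs <- point_obs(helical = c(5, 5, 5), phase50 = c(4, 7, 10))
  d <- displacement(obs, "helical_to_phase50")
  expect_equal(unlist(d[motion_axes()]), c(lr = -1, ap = 2, si = 5))

  still <- point_obs(helical = c(3, 3, 3), phase0 = c(3, 3, 3),
                     phase50 = c(3, 3, 3))
  for (pr in state_pairs()) {
    expect_equal(unlist(displacement(still, pr)[motion_axes()]),
                 c(lr = 0, ap = 0, si = 0))
  }
})

test_that("incomplete observations are rejected", {
  obs <- point_obs()
  obs$phase50_si <- NA_real_
  expect_error(displacement(obs, "phase0_to_phase50"), "complete")
  expect_error(displacement(obs[, -3], "phase0_to_phase50"), "missing columns")
})

test_that("amplitude statistics match hand computation and use the n-1 SD", {
  two <- dplyr::bind_rows(
    point_obs("A", "S1", phase50 = c(0, 0, 4)),
    point_obs("B", "S1", phase50 = c(0, 0, 6))
  )
  # single-segment table: build remaining segments as zero motion
  s <- amplitude_stats(dplyr::bind_rows(lapply(liver_segments(), function(sg) {
    dplyr::bind_rows(point_obs("A", sg, phase50 = c(0, 0, 4)),
                     point_obs("B", sg, phase50 = c(0, 0, 6)))
  })), "phase0_to_phase50")
  si <- s[s$segment == "S1" & s$axis == "si", ]
  expect_equal(si$mean, 5)
  expect_equal(si$sd, sqrt(2))
  expect_equal(si$n, 2L)
  expect_equal(nrow(two), 2)  # hand fixture sanity
})

test_that("a zero-variance cohort reproduces its generating means exactly", {
  coh <- generate_cohort(deterministic_params(), n_patients = 4, seed = 2)
  s <- amplitude_stats(coh, "phase0_to_phase50", segments = "S7")
  expect_equal(s$mean[s$axis == "lr"], -1.4, tolerance = 1e-12)
  expect_equal(s$mean[s$axis == "ap"], 3.5, tolerance = 1e-12)
  expect_equal(s$mean[s$axis == "si"], 8.6, tolerance = 1e-12)
  expect_equal(s$sd, rep(0, 3), tolerance = 1e-5)
})

test_that("statistics need at least two patients", {
  one <- dplyr::bind_rows(lapply(liver_segments(), function(sg) {
    point_obs("solo", sg)
  }))
  expect_error(amplitude_stats(one, "phase0_to_phase50"), "at least 2")
})

test_that("the overall row pools all values and equals the mean of segment means", {
  coh <- generate_cohort(n_patients = 12, seed = 3)
  tab <- amplitude_table(coh, "phase0_to_phase50")
  seg <- tab[tab$segment != "ALL", ]
  all_row <- tab[tab$segment == "ALL", ]
  d <- displacement(coh, "phase0_to_phase50")
  for (ax in motion_axes()) {
    expect_equal(all_row$mean[all_row$axis == ax], mean(d[[ax]]))
    expect_equal(all_row$sd[all_row$axis == ax], stats::sd(d[[ax]]))
    # equal n per segment -> pooled mean == unweighted mean of segment means
    expect_equal(all_row$mean[all_row$axis == ax],
                 mean(seg$mean[seg$axis == ax]))
    expect_equal(all_row$n[all_row$axis == ax], 9L * 12L)
  }
  alt <- amplitude_table(coh, "phase0_to_phase50", overall_sd = "mean_of_sds")
  for (ax in motion_axes()) {
    expect_equal(alt$sd[alt$segment == "ALL" & alt$axis == ax],
                 mean(seg$sd[seg$axis == ax]))
  }
})

test_that("statistics are invariant under rigid per-patient translation", {
  coh <- generate_cohort(n_patients = 8, seed = 6)
  pts <- cohort_points(coh)
  shifted <- pts
  shift <- stats::setNames(seq_len(8) * 10, unique(pts$patient_id))
  for (st in c("helical", "phase0", "phase50")) {
    for (ax in motion_axes()) {
      col <- paste0(st, "_", ax)
      shifted[[col]] <- shifted[[col]] + shift[shifted$patient_id]
    }
  }
  for (pr in state_pairs()) {
    expect_equal(as.data.frame(amplitude_stats(shifted, pr)),
                 as.data.frame(amplitude_stats(pts, pr)),
                 tolerance = 1e-9)
  }
})

test_that("the text rendering carries segments, the mean row and the sign footnote", {
  tab <- amplitude_table(generate_cohort(n_patients = 5, seed = 1),
                         "phase0_to_phase50")
  txt <- format_amplitude_table(tab)
  expect_true(any(grepl("^S7 ", txt)))
  expect_true(any(grepl("^mean", txt)))
  expect_true(any(grepl("Positive = left / posterior / superior", txt)))
})
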