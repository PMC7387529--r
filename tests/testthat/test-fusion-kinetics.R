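test_that("fit recovers the generating time constant exactly on noiseless data", {
  for (tau in c(1, 7, 30, 100)) {
    s <- simulate_fusion_series(fusion_sim_config(
      tau = tau, radius_a = 100, radius_b = 100,
      time_points = fusion_time_grid() * tau / 10, noise_cv = 0, seed = 1
    ))
    f <- fit_liquid_drop(s, window = c(0, max(s$time_h)))
    expect_lt(abs(f$tau - tau) / tau, 1e-6)
    expect_equal(f$adj_r2, 1, tolerance = 1e-9)
    expect_false(f$flagged)
    expect_equal(f$vcv, 2^(2 / 3) * 100 / f$tau)   # exact by construction
  }
})

test_that("degenerate series (no neck growth, too few points) are flagged", {
  s0 <- neck_series(time_h = fusion_time_grid(),
                    neck_radius_um = rep(0, 9),
                    radius_a_um = 100, radius_b_um = 100, R0_um = 100)
  f0 <- fit_liquid_drop(s0, window = c(0, 48))
  expect_true(f0$flagged)
  s1 <- neck_series(time_h = c(1, 2), neck_radius_um = c(10, 20),
                    radius_a_um = 100, radius_b_um = 100, R0_um = 100)
  expect_true(fit_liquid_drop(s1, window = c(0, 48))$flagged)
})

test_that("visco-capillary velocity identities hold", {
  expect_equal(visco_capillary_velocity(2^(2 / 3), 1), 1)
  expect_equal(visco_capillary_velocity(10, 200),
               2 * visco_capillary_velocity(10, 100))
  # algebraic inversion: R0 = 125 um, G/eta = 3.8 um/h -> tau = 52.2 h
  tau <- 2^(2 / 3) * 125 / 3.8
  expect_equal(tau, 52.2, tolerance = 1e-3)
  expect_equal(visco_capillary_velocity(tau, 125), 3.8, tolerance = 1e-12)
  expect_error(visco_capillary_velocity(-1, 10))
})

test_that("early window selection follows spheroid age with override", {
  s <- noiseless_series()
  attr(s, "age_days") <- 3
  expect_equal(select_early_window(s), c(0, 6))
  attr(s, "age_days") <- 7
  expect_equal(select_early_window(s), c(0, 48))
  expect_equal(select_early_window(s, override = 12), c(0, 12))
})

test_that("time rescaling rescales tau by c and the velocity by 1/c", {
  s <- noiseless_series(tau = 10)
  f <- fit_liquid_drop(s, window = c(0, 48))
  s2 <- neck_series(time_h = s$time_h * 3, neck_radius_um = s$neck_radius_um,
                    radius_a_um = s$radius_a_um, radius_b_um = s$radius_b_um,
                    R0_um = attr(s, "R0_um"))
  f2 <- fit_liquid_drop(s2, window = c(0, 48 * 3))
  expect_equal(f2$tau, 3 * f$tau, tolerance = 1e-8)
  expect_equal(f2$vcv, f$vcv / 3, tolerance = 1e-8)
})

test_that("fitted tau is proportional to R0 under a common visco-capillary velocity", {
  spec <- cohort_spec(n_pairs = 12, radius_mean = 75, radius_sd = 22,
                      vcv_um_per_h = 8.4, seed = 21,
                      ground_truth = fusion_sim_config(
                        tau = 15, radius_a = 75, radius_b = 75, noise_cv = 0))
  fits <- fit_cohort(generate_cohort(spec), window = c(0, 48))
  expect_false(any(fits$flagged))
  slope <- coef(lm(tau_h ~ R0_um - 1, data = fits))[[1]]
  expect_equal(slope, 2^(2 / 3) / 8.4, tolerance = 0.05)
})

test_that("group aggregation reports spread and the velocity-radius correlation", {
  # identical fits -> zero SD
  one <- glance(fit_liquid_drop(noiseless_series(), window = c(0, 48)))
  same <- dplyr::bind_rows(replicate(12, one, simplify = FALSE))
  agg <- aggregate_group(same, "homogeneous")
  expect_equal(agg$vcv_sd, 0)
  expect_equal(agg$n, 12)

  # a cohort built with a COMMON tau makes G/eta proportional to R0,
  # which the Pearson test must detect at n = 12
  series <- purrr::map(1:12, function(i) {
    R <- 40 + 6 * i
    simulate_fusion_series(fusion_sim_config(
      tau = 15, radius_a = R, radius_b = R, noise_cv = 0.05, seed = 100 + i
    ))
  })
  fits <- fit_cohort(series, window = c(0, 48))
  agg2 <- aggregate_group(fits, "tau-fixed")
  expect_lt(agg2$cor_p, 0.05)
  expect_gt(agg2$cor_vcv_R0, 0)

  # all-flagged input -> empty summary with a warning
  flagged <- same
  flagged$flagged <- TRUE
  expect_warning(empty <- aggregate_group(flagged), "unflagged")
  expect_true(is.na(empty$vcv_mean))
})
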