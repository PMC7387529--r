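test_that("coalescence law limits: zero at t=0, 2^(2/3) plateau, 1 - 1/e point", {
  s <- simulate_fusion_series(fusion_sim_config(
    tau = 10, radius_a = 100, radius_b = 100,
    time_points = c(0, 10, 1000), noise_cv = 0, seed = 1
  ))
  y <- (s$neck_radius_um / 100)^2
  expect_equal(y[1], 0)
  expect_equal(y[2], 2^(2 / 3) * (1 - exp(-1)), tolerance = 1e-12) # 1.0035
  expect_equal(y[3], 2^(2 / 3), tolerance = 1e-10)                 # 1.5874
})

test_that("simulation is reproducible under a fixed seed and noise is mean-one", {
  cfg <- fusion_sim_config(tau = 12, radius_a = 80, radius_b = 90,
                           noise_cv = 0.05, seed = 99)
  s1 <- simulate_fusion_series(cfg)
  s2 <- simulate_fusion_series(cfg)
  expect_identical(s1$neck_radius_um, s2$neck_radius_um)

  # mean-one multiplicative noise: average ratio to the clean curve -> 1
  clean <- simulate_fusion_series(fusion_sim_config(
    tau = 12, radius_a = 80, radius_b = 90, noise_cv = 0, seed = 1
  ))
  ratios <- unlist(lapply(1:300, function(i) {
    si <- simulate_fusion_series(fusion_sim_config(
      tau = 12, radius_a = 80, radius_b = 90, noise_cv = 0.05, seed = i
    ))
    si$neck_radius_um / clean$neck_radius_um
  }))
  expect_equal(mean(ratios), 1, tolerance = 0.005)
})

test_that("compaction shrinks radii linearly with a 10% floor", {
  s <- simulate_fusion_series(fusion_sim_config(
    tau = 10, radius_a = 100, radius_b = 100,
    time_points = c(0, 1, 2, 48), noise_cv = 0,
    compaction_rate = 0.05, seed = 1
  ))
  expect_equal(s$radius_a_um[1:3], 100 * (1 - 0.05 * c(0, 1, 2)))
  expect_equal(s$radius_a_um[4], 10)    # 48 h at 5%/h clamps at 0.1 * initial
  expect_equal(attr(s, "R0_um"), 100)   # R0 stays the initial value
})

test_that("invalid fusion configs are rejected", {
  expect_error(fusion_sim_config(tau = -1, radius_a = 1, radius_b = 1))
  expect_error(fusion_sim_config(tau = 1, radius_a = 1, radius_b = 1,
                                 time_points = c(2, 1)))
  expect_error(fusion_sim_config(tau = 1, radius_a = 1, radius_b = 1,
                                 noise_cv = -0.1))
})

test_that("cohorts are element-wise reproducible and follow tau = 2^(2/3) R0 / (G/eta)", {
  spec <- cohort_spec(n_pairs = 12, radius_mean = 100, radius_sd = 0,
                      vcv_um_per_h = 8.4, seed = 5)
  coh1 <- generate_cohort(spec)
  coh2 <- generate_cohort(spec)
  expect_length(coh1, 12)
  expect_identical(purrr::map(coh1, "neck_radius_um"),
                   purrr::map(coh2, "neck_radius_um"))
  taus <- purrr::map_dbl(coh1, ~ attr(.x, "tau_true"))
  expect_equal(taus, rep(2^(2 / 3) * 100 / 8.4, 12))   # 18.9 h
  # varying radii: per-pair tau proportional to per-pair R0
  spec2 <- cohort_spec(n_pairs = 8, radius_mean = 75, radius_sd = 20,
                       vcv_um_per_h = 8.4, seed = 6)
  coh3 <- generate_cohort(spec2)
  R0s <- purrr::map_dbl(coh3, ~ attr(.x, "R0_um"))
  taus3 <- purrr::map_dbl(coh3, ~ attr(.x, "tau_true"))
  expect_equal(taus3, 2^(2 / 3) * R0s / 8.4, tolerance = 1e-12)
  expect_gt(stats::sd(R0s), 0)
})

test_that("neck series round-trips through CSV with metadata", {
  s <- noiseless_series()
  attr(s, "pair_type") <- "RPE-RPE"
  attr(s, "age_days") <- 7
  path <- withr::local_tempfile(fileext = ".csv")
  write_neck_series(s, path)
  s2 <- read_neck_series(path)
  expect_equal(s2$neck_radius_um, s$neck_radius_um, tolerance = 1e-8)
  expect_equal(attr(s2, "R0_um"), attr(s, "R0_um"))
  expect_equal(attr(s2, "pair_type"), "RPE-RPE")
})
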