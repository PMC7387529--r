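test_that("contact point is found within 2 samples of the true touch-down", {
  # elastic curve: the baseline + delta^(3/2) rise is the detector's model
  for (seed in 4:8) {
    cfg <- indent_sim_config(E1 = 2000, alpha = 0, baseline_distance = 1e-6,
                             force_noise_sd = 1e-10, seed = seed)
    cv <- simulate_indentation_curve(cfg)
    cp <- detect_contact_point(cv)
    expect_lte(abs(cp$index - attr(cv, "contact_index")), 2)
  }
  # viscoelastic rise is steeper than delta^(3/2) near contact, which can
  # shift the apparent contact slightly early; the shift must stay well
  # below a tenth of the peak depth
  cfg2 <- indent_sim_config(E1 = 2000, alpha = 0.16, baseline_distance = 1e-6,
                            force_noise_sd = 1e-10, seed = 9)
  cv2 <- simulate_indentation_curve(cfg2)
  cp2 <- detect_contact_point(cv2)
  true_pos <- cv2$depth_m[attr(cv2, "contact_index")]
  expect_lt(abs(cp2$offset_m - true_pos), 3.5e-7)
  rez <- apply_contact_point(cv2, cp2)
  expect_lt(abs(rez$depth_m[cp2$index]), 2e-8)
})

test_that("contact detection refuses pure noise and baseline-free curves", {
  cv <- simulate_indentation_curve(fast_indent_cfg(
    E1 = 2000, alpha = 0.1, baseline_distance = 1e-6, seed = 5,
    force_noise_sd = 2e-10))
  noise_only <- cv
  set.seed(1)
  noise_only$force_N <- rnorm(nrow(cv), sd = 2e-10)
  expect_error(detect_contact_point(noise_only), "no contact")
  no_baseline <- simulate_indentation_curve(fast_indent_cfg(
    E1 = 2000, alpha = 0.1, seed = 5))
  expect_error(detect_contact_point(no_baseline), "baseline")
})

test_that("Hertz fit is exact on noiseless elastic data and linear in E", {
  cv <- simulate_indentation_curve(fast_indent_cfg(E1 = 3920, alpha = 0,
                                                   seed = 1))
  # direct evaluation at the window edge: F(900 nm) = 17.9 nN
  expect_equal(hertz_force(9e-7, 3920) * 1e9, 17.9, tolerance = 3e-3)
  f1 <- fit_hertz(cv)
  expect_equal(f1$E, 3920, tolerance = 1e-9)
  expect_equal(f1$fit_depth_max_m, 9e-7)
  cv2 <- simulate_indentation_curve(fast_indent_cfg(E1 = 7840, alpha = 0,
                                                    seed = 1))
  expect_equal(max(cv2$force_N), 2 * max(cv$force_N), tolerance = 1e-12)
  expect_equal(fit_hertz(cv2)$E, 2 * f1$E, tolerance = 1e-9)
})

test_that("Hertz estimate stays within 2% under 1% force noise", {
  # 1% of the force at the fit-window edge (900 nm), the scale the
  # shallow-window fit actually sees
  fwin <- hertz_force(9e-7, 3920)
  errs <- vapply(1:100, function(i) {
    cv <- simulate_indentation_curve(fast_indent_cfg(
      E1 = 3920, alpha = 0, force_noise_sd = 0.01 * fwin, seed = 1000 + i))
    abs(fit_hertz(cv)$E - 3920) / 3920
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("PLR inversion recovers (E1, alpha) from a noiseless cycle", {
  cv <- simulate_indentation_curve(fast_indent_cfg(E1 = 3940, alpha = 0.17,
                                                   seed = 2))
  pf <- fit_plr(cv)
  expect_true(pf$converged)
  expect_lt(abs(pf$E1 - 3940) / 3940, 1e-3)
  expect_lt(abs(pf$alpha - 0.17), 1e-3)
})

test_that("elastic degenerate case: alpha at the boundary, E1 equals the Hertz modulus", {
  cv <- simulate_indentation_curve(fast_indent_cfg(E1 = 2000, alpha = 0,
                                                   seed = 3))
  pf <- fit_plr(cv)
  hf <- fit_hertz(cv)
  expect_equal(pf$alpha, 0, tolerance = 1e-6)
  expect_lt(abs(pf$E1 - hf$E) / hf$E, 0.005)
})

test_that("replicate summaries preserve the per-spheroid structure", {
  base <- tibble::tibble(
    spheroid_id = rep(1:3, each = 4), indent = rep(1:4, 3),
    E1_Pa = 1630, alpha = 0.16, converged = TRUE
  )
  s <- summarize_sample(base)
  expect_equal(s$E1_kPa_sd, 0)
  expect_equal(s$n_indents, 12)
  # one flagged replicate is dropped, not imputed
  base$converged[1] <- FALSE
  s2 <- summarize_sample(base)
  expect_equal(s2$n_indents, 11)
  expect_equal(s2$E1_kPa_mean, 1.63)
})

test_that("compliance correction converts piezo displacement to indentation", {
  cv <- simulate_indentation_curve(fast_indent_cfg(E1 = 2000, alpha = 0.1,
                                                   seed = 6))
  k <- 0.045
  piezo <- cv
  piezo$depth_m <- cv$depth_m + cv$force_N / k
  back <- compliance_correct(piezo, stiffness = k)
  expect_equal(back$depth_m, cv$depth_m, tolerance = 1e-12)
})

test_that("indentation curves round-trip through CSV", {
  cv <- simulate_indentation_curve(fast_indent_cfg(E1 = 1500, alpha = 0.12,
                                                   seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_indentation_curve(cv, path)
  cv2 <- read_indentation_curve(path)
  expect_equal(cv2$force_N, cv$force_N, tolerance = 1e-6)
  expect_equal(attr(cv2, "tip_radius"), 9e-6)
  expect_equal(cv2$phase, cv$phase)
})
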