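#' Configuration for a simulated spheroid fusion trajectory
#'
#' Bundles the ground-truth parameters of one fusing spheroid pair: the
#' coalescence time constant, the two initial radii, the imaging schedule,
#' the multiplicative measurement noise on the neck radius, and an optional
#' compaction (shrinkage) rate for young spheroids.
#'
#' @param tau Time constant of the coalescence law (hours).
#' @param radius_a,radius_b Initial spheroid radii (micrometres).
#' @param time_points Imaging times in hours, strictly increasing, first
#'   point at or after 0. Defaults to [fusion_time_grid()].
#' @param noise_cv Coefficient of variation of the mean-one lognormal
#'   multiplicative noise applied to the simulated neck radius.
#' @param compaction_rate Fractional radius shrinkage per hour (1/h); radii
#'   decay linearly and are clamped at 10 % of their initial value. Default 0
#'   models mature spheroids of constant size.
#' @param seed Integer RNG seed; mandatory so every trajectory is reproducible.
#'
#' @return An object of class `fusion_sim_config` (a named list).
#' @seealso [simulate_fusion_series()], [cohort_spec()]
#' @export
fusion_sim_config <- function(tau, radius_a, radius_b,
                              time_points = fusion_time_grid(),
                              noise_cv = 0.05, compaction_rate = 0,
                              seed = 1L) {
  check_positive(tau, "tau")
  check_positive(radius_a, "radius_a")
  check_positive(radius_b, "radius_b")
  check_nonneg(noise_cv, "noise_cv")
  check_nonneg(compaction_rate, "compaction_rate")
  if (length(time_points) < 1L || any(!is.finite(time_points)) ||
      time_points[1] < 0 || any(diff(time_points) <= 0)) {
    abort("`time_points` must be strictly increasing and start at >= 0")
  }
  structure(
    list(tau = tau, radius_a = radius_a, radius_b = radius_b,
         time_points = as.numeric(time_points), noise_cv = noise_cv,
         compaction_rate = compaction_rate, seed = as.integer(seed)),
    class = "fusion_sim_config"
  )
}

#' Construct a neck-radius time series
#'
#' A `neck_series` is the measured (or simulated) record of one fusing
#' spheroid pair: neck radius and lobe radii at each imaging time, with the
#' initial average radius R0 and pair metadata carried as attributes.
#'
#' @param time_h Imaging times (hours).
#' @param neck_radius_um Neck radius r0 at each time (micrometres); `NA`
#'   where the measurement failed.
#' @param radius_a_um,radius_b_um Lobe radii (micrometres), `NA` allowed.
#' @param R0_um Initial average radius of the pair (micrometres). Defaults to
#'   the mean of the first available lobe radii.
#' @param pair_type Label of the pair (e.g. `"RPE-RPE"`).
#' @param age_days Spheroid age at the start of fusion (days).
#'
#' @return A tibble of class `neck_series` with columns `time_h`,
#'   `neck_radius_um`, `radius_a_um`, `radius_b_um`, `missing`.
#' @export
neck_series <- function(time_h, neck_radius_um, radius_a_um = NA_real_,
                        radius_b_um = NA_real_, R0_um = NULL,
                        pair_type = "unknown", age_days = 7) {
  if (any(diff(time_h) <= 0)) abort("`time_h` must be strictly increasing")
  if (any(neck_radius_um < 0, na.rm = TRUE)) {
    abort("`neck_radius_um` must be non-negative where present")
  }
  out <- tibble::tibble(
    time_h = as.numeric(time_h),
    neck_radius_um = as.numeric(neck_radius_um),
    radius_a_um = as.numeric(rep_len(radius_a_um, length(time_h))),
    radius_b_um = as.numeric(rep_len(radius_b_um, length(time_h))),
    missing = is.na(neck_radius_um)
  )
  if (is.null(R0_um)) {
    first_ok <- which(!is.na(out$radius_a_um) & !is.na(out$radius_b_um))[1]
    if (is.na(first_ok)) abort("`R0_um` missing and no lobe radii available")
    R0_um <- mean(c(out$radius_a_um[first_ok], out$radius_b_um[first_ok]))
  }
  check_positive(R0_um, "R0_um")
  structure(out, R0_um = R0_um, pair_type = pair_type, age_days = age_days,
            class = c("neck_series", class(out)))
}

#' Simulate one fusion trajectory under the liquid-drop coalescence law
#'
#' Forward-simulates the neck radius of a fusing pair: the squared normalised
#' neck radius grows as \eqn{(r_0/R_0)^2 = 2^{2/3}(1 - e^{-t/\tau})}, where
#' R0 is the mean of the two (optionally compacting) lobe radii at each time.
#' The neck radius is then perturbed by mean-one lognormal multiplicative
#' noise with the configured coefficient of variation.
#'
#' @param config A [fusion_sim_config()].
#' @return A [neck_series()] whose `R0_um` attribute is the initial average
#'   radius; also carries `tau_true` for downstream calibration checks.
#' @export
simulate_fusion_series <- function(config) {
  stopifnot(inherits(config, "fusion_sim_config"))
  set.seed(config$seed)
  t <- config$time_points
  shrink <- pmax(1 - config$compaction_rate * t, 0.1)
  ra <- config$radius_a * shrink
  rb <- config$radius_b * shrink
  R0_t <- (ra + rb) / 2
  r0 <- R0_t * sqrt(COALESCENCE_PLATEAU * (1 - exp(-t / config$tau)))
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    r0 <- r0 * exp(rnorm(length(t), mean = -sdlog^2 / 2, sd = sdlog))
  }
  out <- neck_series(
    time_h = t, neck_radius_um = r0, radius_a_um = ra, radius_b_um = rb,
    R0_um = (config$radius_a + config$radius_b) / 2
  )
  attr(out, "tau_true") <- config$tau
  attr(out, "seed") <- config$seed
  out
}

#' Specification of a simulated fusion cohort
#'
#' Describes a group of fusion pairs sharing one ground-truth visco-capillary
#' velocity. Per-pair initial radii are drawn from a truncated normal
#' distribution and each pair's time constant follows from
#' \eqn{\tau = 2^{2/3} R_0 / (\Gamma/\eta)}.
#'
#' @param n_pairs Number of fusion pairs (default 12, the standard group
#'   size in the hanging-drop fusion assay).
#' @param radius_mean,radius_sd Mean and SD (micrometres) of the sampling
#'   distribution of per-spheroid initial radii, truncated at > 0.
#' @param vcv_um_per_h Common ground-truth visco-capillary velocity
#'   \eqn{\Gamma/\eta} in micrometres per hour.
#' @param group_label Group label carried into every series.
#' @param ground_truth A [fusion_sim_config()] template supplying the time
#'   grid, noise level and compaction rate (its `tau`, radii and seed are
#'   overridden per pair).
#' @param seed Master seed; per-pair seeds are derived deterministically.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pairs = 12, radius_mean = 100, radius_sd = 20,
                        vcv_um_per_h = 8.4, group_label = "group",
                        ground_truth = fusion_sim_config(
                          tau = 15, radius_a = radius_mean,
                          radius_b = radius_mean),
                        seed = 1L) {
  stopifnot(n_pairs >= 1, radius_sd >= 0)
  check_positive(radius_mean, "radius_mean")
  check_positive(vcv_um_per_h, "vcv_um_per_h")
  structure(
    list(n_pairs = as.integer(n_pairs), radius_mean = radius_mean,
         radius_sd = radius_sd, vcv_um_per_h = vcv_um_per_h,
         group_label = group_label, ground_truth = ground_truth,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

rtrunc_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate a cohort of fusion trajectories
#'
#' Draws per-pair radii, sets each pair's time constant from the cohort's
#' common visco-capillary velocity, and simulates every trajectory with a
#' seed derived deterministically from the master seed so cohorts are
#' reproducible element-wise.
#'
#' @param spec A [cohort_spec()].
#' @return A list of [neck_series()] of length `spec$n_pairs`; each carries
#'   `tau_true` and the group label in `pair_type`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  gt <- spec$ground_truth
  purrr::map(seq_len(spec$n_pairs), function(i) {
    set.seed(derive_seed(spec$seed, 2L * i))
    radii <- rtrunc_pos(2, spec$radius_mean, spec$radius_sd)
    R0 <- mean(radii)
    tau_i <- COALESCENCE_PLATEAU * R0 / spec$vcv_um_per_h
    cfg <- fusion_sim_config(
      tau = tau_i, radius_a = radii[1], radius_b = radii[2],
      time_points = gt$time_points, noise_cv = gt$noise_cv,
      compaction_rate = gt$compaction_rate,
      seed = derive_seed(spec$seed, 2L * i + 1L)
    )
    s <- simulate_fusion_series(cfg)
    attr(s, "pair_type") <- spec$group_label
    s
  })
}

#' Write / read a neck series as CSV
#'
#' Columns `time_h, neck_radius_um, radius_a_um, radius_b_um`; the initial
#' average radius, pair type and age travel in `#`-prefixed header lines so
#' the file round-trips.
#'
#' @param series A [neck_series()].
#' @param path File path.
#' @return `write_neck_series()` returns `path` invisibly;
#'   `read_neck_series()` returns a [neck_series()].
#' @export
write_neck_series <- function(series, path) {
  stopifnot(inherits(series, "neck_series"))
  hdr <- c(
    sprintf("# R0_um=%.10g", attr(series, "R0_um")),
    sprintf("# pair_type=%s", attr(series, "pair_type") %||% "unknown"),
    sprintf("# age_days=%g", attr(series, "age_days") %||% 7)
  )
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    series[, c("time_h", "neck_radius_um", "radius_a_um", "radius_b_um")],
    path, sep = ",", row.names = FALSE, quote = FALSE, append = TRUE
  ))
  invisible(path)
}

#' @rdname write_neck_series
#' @export
read_neck_series <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default) {
    hit <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(hit) == 0) return(default)
    sub(paste0("^# ", key, "="), "", hit[1])
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  neck_series(
    time_h = df$time_h, neck_radius_um = df$neck_radius_um,
    radius_a_um = df$radius_a_um, radius_b_um = df$radius_b_um,
    R0_um = as.numeric(get_meta("R0_um", NA)),
    pair_type = get_meta("pair_type", "unknown"),
    age_days = as.numeric(get_meta("age_days", "7"))
  )
}
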