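#' Configuration for a simulated nanoindentation cycle
#'
#' Parameters of one load-dwell-retract indentation of a power-law-rheology
#' half-space with a spherical tip. Defaults follow the standard spheroid
#' protocol: 9 µm tip, 3.5 µm peak depth, 1 s dwell, incompressible sample.
#'
#' @param E1 Relaxation scale factor, the relaxation modulus at t = 1 s (Pa).
#' @param alpha Power-law exponent in `[0, 0.95]`; 0 is purely elastic.
#' @param tip_radius Probe radius (m).
#' @param max_depth Peak indentation depth (m); must not exceed half the tip
#'   radius (parabolic contact validity).
#' @param approach_speed Loading rate (m/s).
#' @param dwell_time Hold at peak depth (s).
#' @param retract_speed Unloading rate (m/s).
#' @param nu Poisson ratio in `[0, 0.5]`.
#' @param force_noise_sd Additive Gaussian force noise SD (N).
#' @param baseline_distance Pre-contact travel (m) recorded before touch-down
#'   (zero force plus noise); needed for contact-point detection. Default 0.
#' @param dt Sampling interval (s).
#' @param seed RNG seed.
#' @return An object of class `indent_sim_config`.
#' @export
indent_sim_config <- function(E1 = 1630, alpha = 0.16, tip_radius = 9e-6,
                              max_depth = 3.5e-6, approach_speed = 3.5e-6,
                              dwell_time = 1, retract_speed = 3.5e-6,
                              nu = 0.5, force_noise_sd = 0,
                              baseline_distance = 0, dt = 0.005, seed = 1L) {
  check_positive(E1, "E1")
  if (alpha < 0 || alpha >= 1) abort("`alpha` must lie in [0, 1)")
  check_positive(tip_radius, "tip_radius")
  check_positive(max_depth, "max_depth")
  if (max_depth > 0.5 * tip_radius) {
    abort("`max_depth` must not exceed half the tip radius")
  }
  check_positive(approach_speed, "approach_speed")
  check_nonneg(dwell_time, "dwell_time")
  check_positive(retract_speed, "retract_speed")
  if (nu < 0 || nu > 0.5) abort("`nu` must lie in [0, 0.5]")
  check_nonneg(force_noise_sd, "force_noise_sd")
  check_nonneg(baseline_distance, "baseline_distance")
  check_positive(dt, "dt")
  structure(
    list(E1 = E1, alpha = alpha, tip_radius = tip_radius,
         max_depth = max_depth, approach_speed = approach_speed,
         dwell_time = dwell_time, retract_speed = retract_speed, nu = nu,
         force_noise_sd = force_noise_sd,
         baseline_distance = baseline_distance, dt = dt,
         seed = as.integer(seed)),
    class = "indent_sim_config"
  )
}

#' Construct an indentation curve
#'
#' A tidy record of one indentation cycle: time, depth (negative before
#' contact when a baseline is present), force and phase label, with the tip
#' radius and Poisson ratio as attributes.
#'
#' @param time_s,depth_m,force_N Equal-length numeric vectors.
#' @param phase Character vector of labels among `approach`, `load`, `dwell`,
#'   `retract`.
#' @param tip_radius,nu Probe radius (m) and Poisson ratio.
#' @return A tibble of class `indentation_curve`.
#' @export
indentation_curve <- function(time_s, depth_m, force_N, phase,
                              tip_radius = 9e-6, nu = 0.5) {
  if (any(diff(time_s) <= 0)) abort("`time_s` must be strictly increasing")
  if (!all(phase %in% c("approach", "load", "dwell", "retract"))) {
    abort("`phase` labels must be approach/load/dwell/retract")
  }
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        depth_m = as.numeric(depth_m),
                        force_N = as.numeric(force_N),
                        phase = as.character(phase))
  structure(out, tip_radius = tip_radius, nu = nu,
            class = c("indentation_curve", class(out)))
}

#' Simulate a load-dwell-retract indentation curve
#'
#' Builds the triangle-with-plateau depth history (optional pre-contact
#' baseline, ramp to peak depth at the approach speed, hold, ramp down at the
#' retract speed), computes the force with the Ting forward model
#' ([ting_forward()]), and adds Gaussian force noise last.
#'
#' @param config An [indent_sim_config()].
#' @return An [indentation_curve()] carrying `contact_index` (first
#'   post-contact sample) and the ground-truth parameters as attributes.
#' @export
simulate_indentation_curve <- function(config) {
  stopifnot(inherits(config, "indent_sim_config"))
  set.seed(config$seed)
  t_base <- config$baseline_distance / config$approach_speed
  t_load <- config$max_depth / config$approach_speed
  t_ret <- config$max_depth / config$retract_speed
  dt <- config$dt
  n_base <- if (t_base > 0) ceiling(t_base / dt) else 0L
  time <- seq(0, t_base + t_load + config$dwell_time + t_ret, by = dt)
  tc <- n_base * dt                    # contact time on the grid
  depth <- numeric(length(time))
  for (i in seq_along(time)) {
    tt <- time[i]
    depth[i] <- if (tt < tc) {
      -(tc - tt) * config$approach_speed
    } else if (tt < tc + t_load) {
      (tt - tc) * config$approach_speed
    } else if (tt < tc + t_load + config$dwell_time) {
      config$max_depth
    } else {
      max(config$max_depth - (tt - tc - t_load - config$dwell_time) *
            config$retract_speed, 0)
    }
  }
  phase <- dplyr::case_when(
    time < tc ~ "approach",
    time < tc + t_load ~ "load",
    time < tc + t_load + config$dwell_time + dt / 2 ~ "dwell",
    TRUE ~ "retract"
  )
  post <- time >= tc
  force <- numeric(length(time))
  force[post] <- ting_forward(depth[post], time[post], config$E1,
                              config$alpha, config$tip_radius, config$nu)
  if (config$force_noise_sd > 0) {
    force <- force + rnorm(length(force), sd = config$force_noise_sd)
  }
  out <- indentation_curve(time, depth, force, phase,
                           tip_radius = config$tip_radius, nu = config$nu)
  attr(out, "contact_index") <- n_base + 1L
  attr(out, "truth") <- list(E1 = config$E1, alpha = config$alpha)
  attr(out, "seed") <- config$seed
  out
}

#' Write / read an indentation curve as CSV
#'
#' Columns `time_s, depth_m, force_N, phase`; the tip radius and Poisson
#' ratio travel in `#`-prefixed header lines.
#'
#' @param curve An [indentation_curve()].
#' @param path File path.
#' @return `write_indentation_curve()` returns `path` invisibly;
#'   `read_indentation_curve()` an [indentation_curve()].
#' @export
write_indentation_curve <- function(curve, path) {
  stopifnot(inherits(curve, "indentation_curve"))
  writeLines(c(sprintf("# tip_radius_m=%.10g", attr(curve, "tip_radius")),
               sprintf("# nu=%.10g", attr(curve, "nu"))), path)
  suppressWarnings(utils::write.table(
    curve[, c("time_s", "depth_m", "force_N", "phase")], path, sep = ",",
    row.names = FALSE, quote = FALSE, append = TRUE
  ))
  invisible(path)
}

#' @rdname write_indentation_curve
#' @export
read_indentation_curve <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  grab <- function(key, default) {
    hit <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(hit) == 0) default else
      as.numeric(sub(paste0("^# ", key, "="), "", hit[1]))
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  indentation_curve(df$time_s, df$depth_m, df$force_N, df$phase,
                    tip_radius = grab("tip_radius_m", 9e-6),
                    nu = grab("nu", 0.5))
}

#' @export
autoplot.indentation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_m * 1e6,
                                       y = .data$force_N * 1e9,
                                       colour = .data$phase)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "indentation (µm)", y = "force (nN)")
}
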