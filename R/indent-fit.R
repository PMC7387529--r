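#' Detect the contact point of an indentation curve
#'
#' Two-segment piecewise fit: a flat baseline before the candidate contact
#' sample and a Hertzian \eqn{\delta^{3/2}} rise after it, choosing the split
#' that minimises the total squared error. The curve must include a
#' pre-contact baseline; detection fails with `"no contact"` when the force
#' rise after the best split is below three baseline noise SDs.
#'
#' @param curve An [indentation_curve()] whose `depth_m` is the probe
#'   position (negative before touch-down).
#' @param min_baseline Minimum number of baseline samples required.
#' @return A list of class `contact_point`: `offset_m` (position at contact),
#'   `index` (first in-contact sample), `baseline_N` (force offset),
#'   `baseline_sd_N`.
#' @export
detect_contact_point <- function(curve, min_baseline = 5) {
  stopifnot(inherits(curve, "indentation_curve"))
  up <- which(curve$phase %in% c("approach", "load"))
  pos <- curve$depth_m[up]
  f <- curve$force_N[up]
  n <- length(up)
  if (n < 2 * min_baseline) abort("curve too short for contact detection")
  cands <- seq(min_baseline, n - min_baseline)
  sse <- rep(Inf, length(cands))
  for (ci in seq_along(cands)) {
    k <- cands[ci]
    bl <- mean(f[1:k])
    x <- pmax(pos - pos[k], 0)[(k + 1):n]^1.5
    y <- f[(k + 1):n] - bl
    a <- max(sum(x * y) / sum(x^2), 0)
    sse[ci] <- sum((f[1:k] - bl)^2) + sum((y - a * x)^2)
  }
  k <- cands[which.min(sse)]
  bl <- mean(f[1:k])
  bl_sd <- stats::sd(f[1:k])
  rise <- max(f[(k + 1):n]) - bl
  if (bl_sd > 0 && rise < 3 * bl_sd) abort("no contact")
  if (k <= min_baseline && pos[1] >= 0) {
    abort("no pre-contact baseline in curve")
  }
  # sub-sample refinement: continuous contact offset around the best split
  sse_at <- function(p0) {
    base_sel <- pos <= p0
    if (sum(base_sel) < 2 || sum(!base_sel) < 2) return(Inf)
    b <- mean(f[base_sel])
    x <- pmax(pos[!base_sel] - p0, 0)^1.5
    y <- f[!base_sel] - b
    a <- max(sum(x * y) / sum(x^2), 0)
    sum((f[base_sel] - b)^2) + sum((y - a * x)^2)
  }
  lo <- pos[max(k - 2, 1)]
  hi <- pos[min(k + 2, n)]
  offset <- if (hi > lo) optimize(sse_at, c(lo, hi))$minimum else pos[k]
  index <- which(pos > offset)[1]
  if (is.na(index)) index <- k
  structure(list(offset_m = offset, index = up[index], baseline_N = bl,
                 baseline_sd_N = bl_sd),
            class = "contact_point")
}

#' Re-zero an indentation curve at a contact point
#'
#' Subtracts the contact offset from the position channel and the baseline
#' force, and relabels pre-contact samples as `approach`.
#'
#' @param curve An [indentation_curve()].
#' @param contact A `contact_point` from [detect_contact_point()].
#' @return The re-zeroed [indentation_curve()] with `contact_index` set.
#' @export
apply_contact_point <- function(curve, contact) {
  stopifnot(inherits(contact, "contact_point"))
  out <- curve
  out$depth_m <- curve$depth_m - contact$offset_m
  out$force_N <- curve$force_N - contact$baseline_N
  pre <- seq_len(nrow(out)) < contact$index
  out$phase[pre & out$phase == "load"] <- "approach"
  attr(out, "contact_index") <- contact$index
  out
}

#' Correct piezo displacement for cantilever compliance
#'
#' Optional pre-processing for recordings where the position channel is the
#' piezo displacement rather than the sample indentation: the cantilever
#' deflection F/k is subtracted so that depth = piezo - F/k.
#'
#' @param curve An [indentation_curve()] whose `depth_m` holds piezo
#'   displacement.
#' @param stiffness Cantilever spring constant (N/m), typically 0.041-0.05
#'   for soft-tissue probes.
#' @return An [indentation_curve()] in indentation coordinates.
#' @export
compliance_correct <- function(curve, stiffness) {
  check_positive(stiffness, "stiffness")
  out <- curve
  out$depth_m <- curve$depth_m - curve$force_N / stiffness
  out
}

curve_contact_index <- function(curve) {
  ci <- attr(curve, "contact_index")
  if (!is.null(ci)) return(ci)
  which(curve$phase != "approach")[1]
}

#' Fit the Hertz model to the loading segment
#'
#' Least squares of \eqn{F = \frac{4}{3}\frac{E}{1-\nu^2}\delta^{3/2}\sqrt R}
#' over the shallow-indentation window \eqn{\delta \in (0, f R]} (default
#' f = 0.1, i.e. 900 nm for a 9 µm tip), where the parabolic contact
#' approximation holds. Linear in E, so the estimate and its standard error
#' come from a regression through the origin on \eqn{\delta^{3/2}}.
#'
#' @param curve An [indentation_curve()] with the contact point set (depth
#'   zeroed at contact).
#' @param fit_fraction Fraction of the tip radius bounding the fit depth.
#' @return An object of class `hertz_fit`: `E` (Pa), `E_se`, `contact_index`,
#'   `fit_depth_max_m`, `residual_norm`, `n_points`.
#' @export
fit_hertz <- function(curve, fit_fraction = 0.1) {
  stopifnot(inherits(curve, "indentation_curve"))
  R <- attr(curve, "tip_radius")
  nu <- attr(curve, "nu")
  dmax <- fit_fraction * R
  sel <- curve$phase == "load" & curve$depth_m > 0 & curve$depth_m <= dmax
  if (sum(sel) < 3 || max(curve$depth_m[sel]) < 0.5 * dmax) {
    abort("insufficient depth range in the Hertz window")
  }
  x <- curve$depth_m[sel]^1.5
  y <- curve$force_N[sel]
  fit <- lm(y ~ x - 1)
  ce <- 4 / 3 / (1 - nu^2) * sqrt(R)
  E <- unname(coef(fit)[1]) / ce
  E_se <- suppressWarnings(summary(fit)$coefficients[1, 2]) / ce
  structure(
    list(E = E, E_se = E_se, contact_index = curve_contact_index(curve),
         fit_depth_max_m = dmax, residual_norm = sqrt(sum(stats::resid(fit)^2)),
         n_points = sum(sel)),
    class = "hertz_fit"
  )
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("Hertz fit: E = %.4g Pa (+/- %.2g), %d points to %.3g nm\n",
              x$E, x$E_se, x$n_points, x$fit_depth_max_m * 1e9))
  invisible(x)
}

#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble::tibble(term = "youngs_modulus", estimate = x$E,
                 std.error = x$E_se, unit = "Pa")
}

#' @export
glance.hertz_fit <- function(x, ...) {
  tibble::tibble(E_Pa = x$E, E_se_Pa = x$E_se,
                 fit_depth_max_m = x$fit_depth_max_m,
                 residual_norm = x$residual_norm, n_points = x$n_points)
}

plr_objective <- function(alpha, depth, time, force, R, nu) {
  f1 <- ting_force_cpp(time, depth, 1, alpha, R, nu)
  denom <- sum(f1^2)
  E1 <- if (denom > 0) max(sum(f1 * force) / denom, 1e-12) else 1e-12
  list(E1 = E1, rss = sum((force - E1 * f1)^2))
}

#' Invert a full indentation cycle for power-law rheology parameters
#'
#' Least-squares inversion of the complete post-contact curve (loading,
#' dwell and retraction) under Ting's solution with relaxation modulus
#' \eqn{E(t) = E_1 t^{-\alpha}}. The force is linear in \eqn{E_1}, which is
#' therefore profiled out in closed form; the remaining one-dimensional
#' search over \eqn{\alpha} is multi-started at 0.05, 0.2 and 0.4 and refined
#' by golden-section search within bounds `[0, 0.95]`.
#'
#' @param curve An [indentation_curve()] with contact set and all three
#'   phases present.
#' @param alpha_starts Multi-start values for the exponent.
#' @param alpha_max Upper bound for the exponent.
#' @return An object of class `plr_fit`: `E1` (Pa), `alpha`,
#'   `residual_norm`, `converged`.
#' @export
fit_plr <- function(curve, alpha_starts = c(0.05, 0.2, 0.4),
                    alpha_max = 0.95) {
  stopifnot(inherits(curve, "indentation_curve"))
  if (!all(c("load", "dwell", "retract") %in% curve$phase)) {
    abort("curve must contain load, dwell and retract phases")
  }
  R <- attr(curve, "tip_radius")
  nu <- attr(curve, "nu")
  ci <- curve_contact_index(curve)
  post <- curve[seq(ci, nrow(curve)), ]
  depth <- pmax(post$depth_m, 0)
  time <- post$time_s
  force <- post$force_N
  obj <- function(a) plr_objective(a, depth, time, force, R, nu)$rss
  # coarse multi-start, then local refinement around the best start
  starts <- sort(unique(pmin(pmax(alpha_starts, 0), alpha_max)))
  vals <- vapply(starts, function(a) tryCatch(obj(a), error = function(e) Inf),
                 numeric(1))
  if (all(!is.finite(vals))) {
    return(structure(list(E1 = NA_real_, alpha = NA_real_,
                          residual_norm = NA_real_, converged = FALSE),
                     class = "plr_fit"))
  }
  a0 <- starts[which.min(vals)]
  lo <- max(0, a0 - 0.2); hi <- min(alpha_max, a0 + 0.25)
  opt <- optimize(obj, c(lo, hi), tol = 1e-6)
  # expand if the optimum pinned an interior bracket edge
  while (opt$minimum - lo < 1e-4 && lo > 0) {
    lo <- max(0, lo - 0.2)
    opt <- optimize(obj, c(lo, hi), tol = 1e-6)
  }
  while (hi - opt$minimum < 1e-4 && hi < alpha_max) {
    hi <- min(alpha_max, hi + 0.2)
    opt <- optimize(obj, c(lo, hi), tol = 1e-6)
  }
  alpha <- opt$minimum
  # allow exact boundary solutions (elastic limit)
  if (obj(0) <= opt$objective) alpha <- 0
  sol <- plr_objective(alpha, depth, time, force, R, nu)
  structure(
    list(E1 = sol$E1, alpha = alpha, residual_norm = sqrt(sol$rss),
         converged = is.finite(sol$rss) && sol$E1 > 0),
    class = "plr_fit"
  )
}

#' @export
print.plr_fit <- function(x, ...) {
  if (!x$converged) cat("PLR fit: NOT CONVERGED\n") else
    cat(sprintf("PLR fit: E1 = %.4g Pa, alpha = %.3f\n", x$E1, x$alpha))
  invisible(x)
}

#' @export
tidy.plr_fit <- function(x, ...) {
  tibble::tibble(term = c("E1", "alpha"), estimate = c(x$E1, x$alpha),
                 unit = c("Pa", ""))
}

#' @export
glance.plr_fit <- function(x, ...) {
  tibble::tibble(E1_Pa = x$E1, alpha = x$alpha,
                 residual_norm = x$residual_norm, converged = x$converged)
}

#' Summarise replicate indentations into sample statistics
#'
#' Replicate indents (typically 3-4 per spheroid) are first averaged within
#' each spheroid, then the mean and SD across spheroids are reported, so the
#' between-spheroid variability — not the replicate count — sets the spread.
#' Flagged (non-converged) replicates are dropped.
#'
#' @param fits A tibble with one row per indent containing `spheroid_id` and
#'   any of `E_Pa`, `E1_Pa`, `alpha`, plus optionally `converged`.
#' @return A one-row tibble of means and SDs (kPa for moduli) with replicate
#'   counts; the per-spheroid means are attached as attribute
#'   `per_spheroid`.
#' @export
summarize_sample <- function(fits) {
  stopifnot("spheroid_id" %in% names(fits))
  if ("converged" %in% names(fits)) fits <- fits[fits$converged %in% TRUE, ]
  if (nrow(fits) < 2) abort("need at least 2 unflagged replicates")
  num_cols <- intersect(c("E_Pa", "E1_Pa", "alpha"), names(fits))
  per <- fits |>
    dplyr::group_by(.data$spheroid_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(num_cols),
                                   \(x) mean(x, na.rm = TRUE)),
                     n_indents = dplyr::n(), .groups = "drop")
  out <- tibble::tibble(n_spheroids = nrow(per), n_indents = sum(per$n_indents))
  for (cl in num_cols) {
    scale <- if (cl %in% c("E_Pa", "E1_Pa")) 1e-3 else 1
    nm <- sub("_Pa$", "_kPa", cl)
    out[[paste0(nm, "_mean")]] <- mean(per[[cl]]) * scale
    out[[paste0(nm, "_sd")]] <- stats::sd(per[[cl]]) * scale
  }
  attr(out, "per_spheroid") <- per
  out
}

#' @export
autoplot.plr_fit <- function(object, curve, ...) {
  stopifnot(inherits(curve, "indentation_curve"))
  ci <- curve_contact_index(curve)
  post <- curve[seq(ci, nrow(curve)), ]
  post$fitted_N <- ting_forward(pmax(post$depth_m, 0), post$time_s,
                                object$E1, object$alpha,
                                attr(curve, "tip_radius"), attr(curve, "nu"))
  ggplot2::ggplot(post, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$force_N * 1e9), size = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_N * 1e9),
                       colour = "steelblue") +
    ggplot2::labs(x = "time since contact (s)", y = "force (nN)")
}
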