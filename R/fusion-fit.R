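#' Visco-capillary velocity from the fusion time constant
#'
#' The coalescence time constant of two equal viscous drops is
#' \eqn{\tau = 2^{2/3} R_0 \eta / \Gamma}; inverting gives the
#' visco-capillary velocity \eqn{\Gamma/\eta = 2^{2/3} R_0 / \tau}, the
#' tissue-intrinsic speed scale of fusion.
#'
#' @param tau Time constant (hours).
#' @param R0 Initial average radius (micrometres).
#' @return Visco-capillary velocity in micrometres per hour.
#' @export
visco_capillary_velocity <- function(tau, R0) {
  if (any(tau <= 0) || any(R0 <= 0)) abort("`tau` and `R0` must be positive")
  COALESCENCE_PLATEAU * R0 / tau
}

#' Early-time fit window for a fusion series
#'
#' Young (3-day) spheroids compact during fusion, violating the
#' constant-radius assumption of the coalescence law; only the first 6 h of
#' their kinetics follow the model, so fits are restricted to that window.
#' Mature (7-day) spheroids use the full recorded range.
#'
#' @param series A [neck_series()].
#' @param age_days Spheroid age; defaults to the series attribute.
#' @param override Optional numeric window upper bound (hours).
#' @return Numeric `c(lower, upper)` in hours.
#' @export
select_early_window <- function(series, age_days = attr(series, "age_days"),
                                override = NULL) {
  if (!is.null(override)) return(c(0, override))
  if (!is.null(age_days) && age_days <= 3) c(0, 6) else c(0, max(series$time_h))
}

#' Fit the liquid-drop coalescence law to a neck series
#'
#' Nonlinear least squares of \eqn{y = (r_0/R_0)^2} against
#' \eqn{2^{2/3}(1 - e^{-t/\tau})} with the time constant \eqn{\tau} as the
#' sole free parameter (the plateau prefactor is fixed by the model). The
#' initial guess is the time at which y first exceeds half its final observed
#' value; on failure the fit restarts from three spread guesses before being
#' flagged. Missing points are dropped, never interpolated.
#'
#' @param series A [neck_series()].
#' @param window Fit window `c(lower, upper)` in hours; defaults to
#'   [select_early_window()].
#' @param free_amplitude If `TRUE` the plateau amplitude is also fitted
#'   (diagnostic mode, off by default).
#' @param weighting `"relative"` (default) minimises log-scale residuals,
#'   the variance-stabilising choice for multiplicative measurement error
#'   whose spread grows with the neck size (points with `y = 0` are
#'   excluded); `"none"` minimises raw residuals.
#' @return An object of class `fusion_fit` with elements `tau`, `tau_se`,
#'   `vcv` (visco-capillary velocity, µm/h), `adj_r2`, `n_points`, `window`,
#'   `flagged`, `R0`, plus the data used. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
fit_liquid_drop <- function(series, window = select_early_window(series),
                            free_amplitude = FALSE,
                            weighting = c("relative", "none")) {
  stopifnot(inherits(series, "neck_series"))
  weighting <- match.arg(weighting)
  R0 <- attr(series, "R0_um")
  dat <- series[!series$missing &
                  series$time_h >= window[1] & series$time_h <= window[2], ]
  flagged <- FALSE
  tau <- tau_se <- adj_r2 <- amp <- NA_real_
  msg <- NULL
  if (nrow(dat) < 3) {
    flagged <- TRUE
    msg <- "fewer than 3 points in window"
  } else {
    t <- dat$time_h
    y <- (dat$neck_radius_um / R0)^2
    y_final <- max(y)
    if (y_final <= 0) {
      flagged <- TRUE
      msg <- "no neck growth (tau unresolved)"
    }
    tau0 <- t[which(y > y_final / 2)[1]]
    if (is.na(tau0) || y_final <= 0) tau0 <- median(t)
    pos <- y > 0
    model_y <- function(par) {
      A <- if (free_amplitude) par[2] else COALESCENCE_PLATEAU
      A * (1 - exp(-t / par[1]))
    }
    resid_fn <- function(par) {
      ym <- model_y(par)
      if (weighting == "relative") {
        log(y[pos]) - log(pmax(ym[pos], 1e-12))
      } else {
        y - ym
      }
    }
    if (weighting == "relative" && sum(pos) < 3 && !flagged) {
      flagged <- TRUE
      msg <- "fewer than 3 positive points in window"
    }
    fits <- list()
    starts <- if (flagged) numeric(0) else
      unique(c(tau0, tau0 * c(0.3, 3), median(t)))
    for (start in starts) {
      par0 <- if (free_amplitude) c(start, COALESCENCE_PLATEAU) else start
      lower <- if (free_amplitude) c(1e-6, 1e-6) else 1e-6
      f <- tryCatch(
        minpack.lm::nls.lm(par0, lower = lower, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL
      )
      if (!is.null(f) && f$info %in% 1:4) fits[[length(fits) + 1]] <- f
    }
    if (length(fits) == 0) {
      flagged <- TRUE
      msg <- msg %||% "non-convergence from all starts"
    } else {
      rss <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
      fit <- fits[[which.min(rss)]]
      co <- suppressWarnings(summary(fit)$coefficients)
      tau <- unname(co[1, "Estimate"])
      tau_se <- unname(co[1, "Std. Error"])
      amp <- if (free_amplitude) unname(co[2, "Estimate"]) else
        COALESCENCE_PLATEAU
      n <- length(y)
      p <- if (free_amplitude) 2 else 1
      ss_tot <- sum((y - mean(y))^2)
      raw_res <- y - model_y(coef(fit))
      r2 <- if (ss_tot > 0) 1 - sum(raw_res^2) / ss_tot else NA_real_
      adj_r2 <- if (!is.na(r2)) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
      # a time constant far beyond the data is indistinguishable from y == 0
      if (tau > 50 * max(t)) {
        flagged <- TRUE
        msg <- "tau unresolved (no saturation in window)"
      }
    }
  }
  structure(
    list(tau = tau, tau_se = tau_se,
         vcv = if (!flagged) visco_capillary_velocity(tau, R0) else NA_real_,
         amplitude = amp, adj_r2 = adj_r2,
         n_points = nrow(dat), window = window, flagged = flagged,
         flag_reason = msg, R0 = R0,
         pair_type = attr(series, "pair_type") %||% "unknown",
         age_days = attr(series, "age_days") %||% NA_real_,
         data = dat),
    class = "fusion_fit"
  )
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat("Liquid-drop coalescence fit\n")
  if (x$flagged) {
    cat("  FLAGGED:", x$flag_reason, "\n")
  } else {
    cat(sprintf("  tau   = %.3g +/- %.2g h\n", x$tau, x$tau_se))
    cat(sprintf("  G/eta = %.3g um/h   (R0 = %.3g um)\n", x$vcv, x$R0))
    cat(sprintf("  adj R2 = %.3f over %d points in [%g, %g] h\n",
                x$adj_r2, x$n_points, x$window[1], x$window[2]))
  }
  invisible(x)
}

#' @export
tidy.fusion_fit <- function(x, ...) {
  tibble::tibble(
    term = c("tau", "visco_capillary_velocity"),
    estimate = c(x$tau, x$vcv),
    std.error = c(x$tau_se, if (is.na(x$tau_se)) NA_real_ else
      x$vcv * x$tau_se / x$tau),
    unit = c("h", "um/h")
  )
}

#' @export
glance.fusion_fit <- function(x, ...) {
  tibble::tibble(
    tau_h = x$tau, vcv_um_per_h = x$vcv, adj.r.squared = x$adj_r2,
    n_points = x$n_points, window_lo_h = x$window[1],
    window_hi_h = x$window[2], flagged = x$flagged, R0_um = x$R0,
    pair_type = x$pair_type, age_days = x$age_days
  )
}

#' @export
autoplot.fusion_fit <- function(object, ...) {
  dat <- object$data
  dat$y <- (dat$neck_radius_um / object$R0)^2
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_h, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = expression((r[0] / R[0])^2))
  if (!object$flagged) {
    grid <- tibble::tibble(time_h = seq(0, max(dat$time_h), length.out = 200))
    grid$y <- object$amplitude * (1 - exp(-grid$time_h / object$tau))
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}

#' Fit every series of a cohort
#'
#' Convenience wrapper mapping [fit_liquid_drop()] over a list of series and
#' binding the [glance()] rows.
#'
#' @param series_list List of [neck_series()].
#' @param ... Passed to [fit_liquid_drop()].
#' @return A tibble with one row per pair.
#' @export
fit_cohort <- function(series_list, ...) {
  dplyr::bind_rows(purrr::map(series_list,
                              function(s) glance(fit_liquid_drop(s, ...))))
}

#' Summarise a group of coalescence fits
#'
#' Mean and SD of the visco-capillary velocity and time constant over
#' unflagged pairs, plus the Pearson correlation test of the velocity
#' against the initial radius (the coalescence model predicts no
#' correlation: tau is proportional to R0 so their ratio is radius-free).
#'
#' @param fits A tibble from [fit_cohort()] (or `bind_rows` of
#'   `glance`d [fusion_fit] objects).
#' @param group_label Optional label; defaults to the modal `pair_type`.
#' @return A one-row tibble: n, vcv mean/sd, tau mean/sd, Pearson r and
#'   two-sided p-value of vcv vs R0.
#' @export
aggregate_group <- function(fits, group_label = NULL) {
  ok <- fits[!fits$flagged, ]
  if (nrow(ok) < 2) {
    warn("fewer than 2 unflagged fits; returning empty summary")
    return(tibble::tibble(
      group = group_label %||% NA_character_, n = nrow(ok),
      vcv_mean = NA_real_, vcv_sd = NA_real_, tau_mean = NA_real_,
      tau_sd = NA_real_, cor_vcv_R0 = NA_real_, cor_p = NA_real_
    ))
  }
  ct <- if (stats::sd(ok$vcv_um_per_h) > 0 && stats::sd(ok$R0_um) > 0) {
    cor.test(ok$vcv_um_per_h, ok$R0_um, alternative = "two.sided")
  } else {
    list(estimate = NA_real_, p.value = NA_real_)
  }
  tibble::tibble(
    group = group_label %||% names(sort(table(ok$pair_type),
                                        decreasing = TRUE))[1],
    n = nrow(ok),
    vcv_mean = mean(ok$vcv_um_per_h), vcv_sd = stats::sd(ok$vcv_um_per_h),
    tau_mean = mean(ok$tau_h), tau_sd = stats::sd(ok$tau_h),
    cor_vcv_R0 = unname(ct$estimate), cor_p = ct$p.value
  )
}
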