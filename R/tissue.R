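#' Order-of-magnitude surface-tension estimate from stiffness
#'
#' For a spheroid whose surface layer is under tension, the effective surface
#' tension scales as \eqn{\Gamma \sim E R_0}: Young's modulus times the
#' spheroid radius. The result is an order-of-magnitude estimate and is
#' tagged as such in pipeline reports.
#'
#' @param E Young's modulus (Pa).
#' @param R0 Spheroid radius (m).
#' @return Surface tension estimate in N/m.
#' @export
surface_tension_estimate <- function(E, R0) {
  check_positive(E, "E")
  check_positive(R0, "R0")
  E * R0
}

#' Apparent viscosity from surface tension and visco-capillary velocity
#'
#' \eqn{\eta = \Gamma / (\Gamma/\eta)}: the independent surface-tension
#' estimate divided by the fusion-derived visco-capillary velocity, with the
#' µm/h velocity converted to m/h so the result is in Pa·h.
#'
#' @param gamma Surface tension (N/m).
#' @param vcv_um_per_h Visco-capillary velocity (µm/h).
#' @return Apparent viscosity in Pa·h.
#' @export
apparent_viscosity <- function(gamma, vcv_um_per_h) {
  check_positive(gamma, "gamma")
  check_positive(vcv_um_per_h, "vcv_um_per_h")
  gamma / (vcv_um_per_h * 1e-6)
}

#' Stiffness (or tension) fold ratio
#'
#' @param E_num,E_den Positive moduli (or tensions) to compare.
#' @param digits Decimal places used when reporting (default 1, matching the
#'   convention for fold changes).
#' @return The fold ratio, rounded to `digits`.
#' @export
stiffness_ratio <- function(E_num, E_den, digits = 1) {
  check_positive(E_num, "E_num")
  check_positive(E_den, "E_den")
  round(E_num / E_den, digits)
}

#' Combine fusion and indentation outputs into tissue-level mechanics
#'
#' Produces the derived quantities for one group: surface-tension estimate
#' \eqn{\Gamma \sim E R_0}, apparent viscosity
#' \eqn{\eta = \Gamma/(\Gamma/\eta)}, with provenance of each input.
#' By the algebra of the coalescence law this equals \eqn{E \tau / 2^{2/3}}
#' when all inputs come from the same group.
#'
#' @param E_Pa Group mean Young's modulus (Pa).
#' @param R0_um Group mean initial spheroid radius (micrometres).
#' @param vcv_um_per_h Group mean visco-capillary velocity (µm/h).
#' @param group Label.
#' @return A one-row tibble: group, inputs, `gamma_N_per_m`,
#'   `apparent_viscosity_Pa_h`, and a provenance note flagging the tension as
#'   an order-of-magnitude estimate.
#' @export
tissue_mechanics <- function(E_Pa, R0_um, vcv_um_per_h, group = "group") {
  gamma <- surface_tension_estimate(E_Pa, R0_um * 1e-6)
  eta <- apparent_viscosity(gamma, vcv_um_per_h)
  tibble::tibble(
    group = group, E_Pa = E_Pa, R0_um = R0_um,
    vcv_um_per_h = vcv_um_per_h, gamma_N_per_m = gamma,
    apparent_viscosity_Pa_h = eta,
    note = "gamma ~ E*R0 order-of-magnitude estimate; viscosity apparent"
  )
}

#' Compare groups: normality checks, one-way ANOVA, Bonferroni pairwise tests
#'
#' Per-group Shapiro-Wilk and Pearson chi-square normality tests, a one-way
#' analysis of variance across groups, and pairwise t tests with Bonferroni
#' correction (pooled SD). Pairwise p-values below 0.001 are flagged, the
#' conventional threshold for reporting a group as different from all others.
#'
#' @param data A data frame with the measurement and a grouping column.
#' @param value,group Column names (strings) of the measurement and group.
#' @param min_n Groups smaller than this are excluded with a warning.
#' @return A list of class `group_comparison`: `normality` (per-group
#'   tibble), `anova` (one-row tibble), `pairwise` (tibble with adjusted
#'   p-values and a `p_below_0.001` flag).
#' @export
group_compare <- function(data, value, group, min_n = 3) {
  stopifnot(value %in% names(data), group %in% names(data))
  x <- data[[value]]
  g <- as.factor(data[[group]])
  counts <- table(g)
  small <- names(counts)[counts < min_n]
  if (length(small) > 0) {
    warn(paste("excluding undersized group(s):", paste(small, collapse = ", ")))
    keep <- !(g %in% small)
    x <- x[keep]; g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2) abort("need at least 2 groups of sufficient size")
  normality <- purrr::map(levels(g), function(lv) {
    xi <- x[g == lv]
    sw <- tryCatch(shapiro.test(xi), error = function(e) NULL)
    pe <- tryCatch(nortest::pearson.test(xi), error = function(e) NULL)
    tibble::tibble(
      group = lv, n = length(xi), mean = mean(xi), sd = stats::sd(xi),
      shapiro_p = if (is.null(sw)) NA_real_ else sw$p.value,
      pearson_chisq_p = if (is.null(pe)) NA_real_ else pe$p.value
    )
  }) |> dplyr::bind_rows()
  fit <- aov(x ~ g)
  an <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(
    df_between = an$Df[1], df_within = an$Df[2],
    statistic = an$`F value`[1], p.value = an$`Pr(>F)`[1]
  )
  pw <- pairwise.t.test(x, g, p.adjust.method = "bonferroni", pool.sd = TRUE)
  pw_tbl <- as.data.frame(as.table(pw$p.value)) |>
    stats::na.omit() |>
    tibble::as_tibble() |>
    setNames(c("group1", "group2", "p.adjusted")) |>
    dplyr::mutate(group1 = as.character(.data$group1),
                  group2 = as.character(.data$group2),
                  p_below_0.001 = .data$p.adjusted < 0.001)
  structure(list(normality = normality, anova = anova_tbl, pairwise = pw_tbl),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison\n\nNormality:\n")
  print(as.data.frame(x$normality))
  cat(sprintf("\nOne-way ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
              x$anova$df_between, x$anova$df_within, x$anova$statistic,
              x$anova$p.value))
  cat("\nBonferroni pairwise:\n")
  print(as.data.frame(x$pairwise))
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @export
glance.group_comparison <- function(x, ...) x$anova
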