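# shared fixtures: small, fast synthetic objects built in code

noiseless_series <- function(tau = 10, R = 100,
                             times = fusion_time_grid()) {
  simulate_fusion_series(fusion_sim_config(
    tau = tau, radius_a = R, radius_b = R, time_points = times,
    noise_cv = 0, seed = 1L
  ))
}

# coarser sampling than the default keeps unit tests quick
fast_indent_cfg <- function(...) {
  indent_sim_config(dt = 0.01, ...)
}

lens_area <- function(Ra, Rb, d) {
  # area of intersection of two circles (standard lens formula)
  if (d >= Ra + Rb) return(0)
  if (d <= abs(Ra - Rb)) return(pi * min(Ra, Rb)^2)
  d1 <- (d^2 + Ra^2 - Rb^2) / (2 * d)
  d2 <- d - d1
  Ra^2 * acos(d1 / Ra) - d1 * sqrt(Ra^2 - d1^2) +
    Rb^2 * acos(d2 / Rb) - d2 * sqrt(Rb^2 - d2^2)
}
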