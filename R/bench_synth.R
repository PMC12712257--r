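#' Specification of a synthetic blower sweep
#'
#' Describes a synthetic bench measurement of a tube's pressure-flow
#' relationship: a blower slowly ramps the driving pressure from 0 up to
#' `+max_dp`, back through 0 down to `-max_dp`, and back to 0 (uniform steps
#' in driving pressure, mirroring a motor-speed ramp), the true flow follows
#' the Rohrer model, and both recorded channels carry additive zero-mean
#' Gaussian measurement noise.
#'
#' @param truth A [rohrer_model()]: the ground-truth tube.
#' @param max_dp Peak driving pressure of the ramp, mbar (default 80, the
#'   blower's rated zero-flow pressure).
#' @param n_samples Number of samples along the full up-down ramp
#'   (default 500, at least 10).
#' @param noise_sd_p SD of additive pressure noise, mbar (default 0).
#' @param noise_sd_f SD of additive flow noise, L/s (default 0).
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(truth, max_dp = 80, n_samples = 500,
                       noise_sd_p = 0, noise_sd_f = 0, seed = 1L) {
  stopifnot(inherits(truth, "rohrer_model"))
  if (max_dp <= 0) stop("`max_dp` must be positive", call. = FALSE)
  if (n_samples < 10L) stop("`n_samples` must be at least 10", call. = FALSE)
  if (noise_sd_p < 0 || noise_sd_f < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  structure(list(truth = truth, max_dp = max_dp,
                 n_samples = as.integer(n_samples),
                 noise_sd_p = noise_sd_p, noise_sd_f = noise_sd_f,
                 seed = as.integer(seed)),
            class = "sweep_spec")
}

#' Generate a synthetic bench pressure-flow sweep
#'
#' @param spec A [sweep_spec()].
#' @return A [pressure_flow_sweep()] with attribute `truth` (the generating
#'   model) retained for convenience in tests.
#' @examples
#' truth <- rohrer_model(k1 = 0.72, k2_insp = 2.88)
#' sw <- generate_sweep(sweep_spec(truth, noise_sd_p = 0.2, seed = 42))
#' fit_rohrer(sw)
#' @export
generate_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  # driving-pressure path 0 -> +max -> 0 -> -max -> 0, uniform in pressure
  u <- seq(0, 4, length.out = spec$n_samples)
  dp <- spec$max_dp * ifelse(u <= 2, 1 - abs(1 - u), -(1 - abs(3 - u)))
  flow <- flow_from_driving_pressure(spec$truth, 0, dp)
  noisy <- withr::with_seed(spec$seed, {
    list(flow = flow + stats::rnorm(length(flow), 0, spec$noise_sd_f),
         dp = dp + stats::rnorm(length(dp), 0, spec$noise_sd_p))
  })
  out <- pressure_flow_sweep(noisy$flow, noisy$dp, label = "synthetic bench")
  attr(out, "truth") <- spec$truth
  out
}

#' Generate a synthetic resistance-versus-diameter table
#'
#' Secant resistances at 1 L/s for a set of tube-bronchoscope geometries,
#' derived from the diameter scaling law and perturbed by multiplicative
#' log-normal noise — a synthetic stand-in for a bench-measured resistance
#' table, used to exercise [fit_power_law()] end to end.
#'
#' @param law A [scaling_law()].
#' @param geometries List of [tube_geometry()] objects, or a data.frame with
#'   columns `d_tube` and `d_scope` (as from [ett_scope_combinations()]).
#' @param rel_noise SD of the log-normal perturbation (fractional, default 0).
#' @param seed RNG seed.
#' @return data.frame: `d_tube, d_scope, d_eff, has_scope, r_1lps`.
#' @export
generate_resistance_table <- function(law, geometries, rel_noise = 0,
                                      seed = 1L) {
  stopifnot(inherits(law, "scaling_law"))
  if (is.data.frame(geometries)) {
    geometries <- lapply(seq_len(nrow(geometries)), function(i) {
      ds <- geometries$d_scope[i]
      tube_geometry(geometries$d_tube[i],
                    d_scope = if (is.na(ds)) NULL else ds)
    })
  }
  if (length(geometries) == 0L) {
    stop("`geometries` must be non-empty", call. = FALSE)
  }
  if (rel_noise < 0) stop("`rel_noise` must be non-negative", call. = FALSE)
  r_true <- vapply(geometries, function(g) {
    secant_resistance(scaling_law_model(g, law), 1)
  }, numeric(1))
  fac <- withr::with_seed(as.integer(seed),
                          exp(stats::rnorm(length(r_true), 0, rel_noise)))
  data.frame(
    d_tube = vapply(geometries, function(g) g$d_tube, numeric(1)),
    d_scope = vapply(geometries, function(g) g$d_scope, numeric(1)),
    d_eff = vapply(geometries, function(g) g$d_eff, numeric(1)),
    has_scope = vapply(geometries, function(g) g$has_scope, logical(1)),
    r_1lps = r_true * fac)
}
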