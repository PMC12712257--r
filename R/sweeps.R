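#' Sweep steady-state outcomes over the effective tube diameter
#'
#' Runs the selected ventilation mode for each effective diameter on the
#' grid, deriving the tube resistance from the diameter scaling law in the
#' bronchoscope regime (exponent -5, the situation of interest during
#' bronchoscopy) unless `beta` overrides it, and collects the steady-state
#' intrinsic PEEP and tidal volume.
#'
#' @param d_eff Ascending grid of effective diameters, mm.
#' @param settings A [ventilator_settings()].
#' @param system A [respiratory_system()].
#' @param law A [scaling_law()].
#' @param config A [sim_config()].
#' @param beta Optional scaling-exponent override.
#' @return data.frame with one row per grid point: `d_eff, r_1lps, ipeep,
#'   ipeep_alv, v_t, p_aw_peak, n_breaths, converged`.
#' @examples
#' \donttest{
#' sweep_deff(c(4, 6, 8), ventilator_settings("PC"))
#' }
#' @export
sweep_deff <- function(d_eff, settings, system = respiratory_system(),
                       law = scaling_law(), config = sim_config(),
                       beta = NULL) {
  if (length(d_eff) == 0L || any(d_eff <= 0)) {
    stop("`d_eff` must be a non-empty grid of positive diameters",
         call. = FALSE)
  }
  if (is.unsorted(d_eff, strictly = TRUE)) {
    stop("`d_eff` must be strictly ascending", call. = FALSE)
  }
  rows <- lapply(d_eff, function(d) {
    tube <- scaling_law_model(tube_geometry(d_eff = d, has_scope = TRUE),
                              law, beta = beta)
    sim <- simulate_ventilation(settings, system, tube, config)
    s <- sim$steady
    data.frame(d_eff = d, r_1lps = secant_resistance(tube, 1),
               ipeep = s$ipeep, ipeep_alv = s$ipeep_alv, v_t = s$v_t,
               p_aw_peak = s$p_aw_peak, n_breaths = s$n_breaths,
               converged = s$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scenario sweeps over patient mechanics and ventilator timing
#'
#' Sensitivity sweeps at a fixed tube geometry over one of three axes:
#' * `"compliance"`: respiratory-system compliance, ml/mbar. In PC mode the
#'   pressure support is co-adjusted to `ps = vt_target / C` (the clinical
#'   rule for holding the target tidal volume as compliance changes);
#' * `"rate"`: respiratory rate, breaths/min; the cycle time `60/rate` is
#'   split at the fixed I:E ratio of the base settings;
#' * `"ie_ratio"`: expiratory-to-inspiratory time ratio (e.g. 3 for I:E =
#'   1:3) at fixed total cycle time.
#'
#' @param axis `"compliance"`, `"rate"`, or `"ie_ratio"`.
#' @param grid Grid of axis values (positive).
#' @param d_eff Effective tube diameter, mm (scope regime).
#' @param settings Base [ventilator_settings()].
#' @param system Base [respiratory_system()].
#' @param law A [scaling_law()].
#' @param config A [sim_config()].
#' @param vt_target Target tidal volume for the PC compliance rule, ml
#'   (default `settings$vt`).
#' @return data.frame: `axis, value, d_eff, ipeep, v_t, converged`.
#' @export
sweep_scenarios <- function(axis = c("compliance", "rate", "ie_ratio"),
                            grid, d_eff, settings,
                            system = respiratory_system(),
                            law = scaling_law(), config = sim_config(),
                            vt_target = settings$vt) {
  axis <- match.arg(axis)
  if (length(grid) == 0L || any(grid <= 0)) {
    stop("`grid` must be non-empty and positive", call. = FALSE)
  }
  tube <- scaling_law_model(tube_geometry(d_eff = d_eff, has_scope = TRUE),
                            law)
  rows <- lapply(grid, function(g) {
    sys_g <- system
    set_g <- settings
    if (axis == "compliance") {
      sys_g <- respiratory_system(compliance = g, r_aw = system$r_aw,
                                  p_mus = system$p_mus,
                                  v_rest = system$v_rest)
      if (settings$mode == "PC") set_g$ps <- vt_target / g
    } else if (axis == "rate") {
      cycle <- 60 / g
      frac_in <- settings$t_in / (settings$t_in + settings$t_ex)
      set_g$t_in <- cycle * frac_in
      set_g$t_ex <- cycle * (1 - frac_in)
    } else { # ie_ratio: g = t_ex / t_in at fixed cycle time
      cycle <- settings$t_in + settings$t_ex
      set_g$t_in <- cycle / (1 + g)
      set_g$t_ex <- cycle * g / (1 + g)
    }
    sim <- simulate_ventilation(set_g, sys_g, tube, config)
    data.frame(axis = axis, value = g, d_eff = d_eff,
               ipeep = sim$steady$ipeep, v_t = sim$steady$v_t,
               converged = sim$steady$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
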