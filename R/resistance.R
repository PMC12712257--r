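#' Effective diameter of a tube-bronchoscope combination
#'
#' The effective diameter is the diameter of a circular tube whose
#' cross-sectional area equals the open (annular) lumen that remains when a
#' bronchoscope shaft of outer diameter `d_scope` occupies part of an
#' endotracheal tube of inner diameter `d_tube`:
#' \deqn{D_{eff} = \sqrt{D_{tube}^2 - D_{scope}^2}}
#' Without a scope the effective diameter is the tube diameter itself.
#'
#' @param d_tube Inner diameter of the endotracheal tube, mm.
#' @param d_scope Outer shaft diameter of the bronchoscope, mm, or `NULL`
#'   when no scope is inserted.
#' @return Effective diameter in mm.
#' @examples
#' effective_diameter(7.0, 5.0)  # 4.9 mm after rounding to one decimal
#' effective_diameter(8.0, 6.0)  # 5.3 mm
#' effective_diameter(7.5)       # no scope: 7.5 mm
#' @export
effective_diameter <- function(d_tube, d_scope = NULL) {
  if (!is.numeric(d_tube) || length(d_tube) != 1L || !is.finite(d_tube) ||
      d_tube <= 0) {
    stop("`d_tube` must be a single positive number (mm)", call. = FALSE)
  }
  if (is.null(d_scope)) {
    return(d_tube)
  }
  if (!is.numeric(d_scope) || length(d_scope) != 1L || !is.finite(d_scope) ||
      d_scope <= 0) {
    stop("`d_scope` must be a single positive number (mm)", call. = FALSE)
  }
  if (d_scope >= d_tube) {
    stop("bronchoscope shaft (", d_scope, " mm) leaves no open lumen in a ",
         d_tube, " mm tube", call. = FALSE)
  }
  sqrt(d_tube^2 - d_scope^2)
}

#' Tube-bronchoscope geometry
#'
#' Bundles the tube inner diameter, the optional bronchoscope shaft diameter,
#' and the derived effective diameter. Alternatively an effective diameter can
#' be given directly (with `has_scope` declaring which resistance-scaling
#' regime applies).
#'
#' @param d_tube Inner tube diameter, mm. May be `NULL` when `d_eff` is given.
#' @param d_scope Optional bronchoscope shaft diameter, mm.
#' @param d_eff Directly specified effective diameter, mm (mutually exclusive
#'   with the `d_tube`/`d_scope` pair).
#' @param has_scope Whether a bronchoscope is present; derived from `d_scope`
#'   when the geometry is given as a tube/scope pair, required information for
#'   picking the scaling exponent when only `d_eff` is supplied (default
#'   `TRUE` for a bare `d_eff`, matching the bronchoscopy use case).
#' @return An object of class `tube_geometry` with fields `d_tube`, `d_scope`,
#'   `d_eff`, `has_scope`.
#' @examples
#' tube_geometry(8.0, 3.8)
#' tube_geometry(d_eff = 5.0)
#' @export
tube_geometry <- function(d_tube = NULL, d_scope = NULL, d_eff = NULL,
                          has_scope = NULL) {
  if (!is.null(d_eff)) {
    if (!is.null(d_tube) || !is.null(d_scope)) {
      stop("give either `d_eff` or the `d_tube`/`d_scope` pair, not both",
           call. = FALSE)
    }
    if (!is.numeric(d_eff) || length(d_eff) != 1L || !is.finite(d_eff) ||
        d_eff <= 0) {
      stop("`d_eff` must be a single positive number (mm)", call. = FALSE)
    }
    if (is.null(has_scope)) has_scope <- TRUE
    geom <- list(d_tube = NA_real_, d_scope = NA_real_, d_eff = d_eff,
                 has_scope = isTRUE(has_scope))
  } else {
    if (is.null(d_tube)) {
      stop("either `d_tube` or `d_eff` is required", call. = FALSE)
    }
    deff <- effective_diameter(d_tube, d_scope)
    geom <- list(d_tube = d_tube,
                 d_scope = if (is.null(d_scope)) NA_real_ else d_scope,
                 d_eff = deff,
                 has_scope = !is.null(d_scope))
  }
  structure(geom, class = "tube_geometry")
}

#' @export
print.tube_geometry <- function(x, ...) {
  if (is.na(x$d_tube)) {
    cat(sprintf("Tube geometry: D_eff = %.1f mm (%s)\n", x$d_eff,
                if (x$has_scope) "scope regime" else "unobstructed regime"))
  } else if (x$has_scope) {
    cat(sprintf("Tube geometry: %.1f mm ETT + %.1f mm scope -> D_eff = %.1f mm\n",
                x$d_tube, x$d_scope, x$d_eff))
  } else {
    cat(sprintf("Tube geometry: %.1f mm ETT, no scope\n", x$d_tube))
  }
  invisible(x)
}

#' Rohrer pressure-flow model of an endotracheal tube
#'
#' The Rohrer equation describes the pressure drop across the tube as the sum
#' of a linear (laminar-like) and a quadratic (turbulent-like) term:
#' \deqn{\Delta p = k_1 \dot V + \mathrm{sign}(\dot V)\, k_2 (\dot V/\dot V_0)^2}
#' with flow positive toward the lung. `k1` is shared between inspiration and
#' expiration; the quadratic coefficient may differ between the two flow
#' directions (compression/expansion asymmetry at the tube tip).
#'
#' @param k1 Linear coefficient, mbar·s/L. Must be >= 0.
#' @param k2_insp Quadratic coefficient for inspiratory flow, mbar. Must be >= 0.
#' @param k2_exp Quadratic coefficient for expiratory flow, mbar; defaults to
#'   `k2_insp` (symmetric tube).
#' @param v_ref Reference flow, L/s (default 1, so `k1 + k2` is the pressure
#'   drop at 1 L/s).
#' @return An object of class `rohrer_model`.
#' @examples
#' m <- rohrer_model(k1 = 0.72, k2_insp = 2.88)
#' rohrer_dp(m, 1)  # 3.6 mbar
#' @export
rohrer_model <- function(k1, k2_insp, k2_exp = k2_insp, v_ref = 1) {
  vals <- c(k1 = k1, k2_insp = k2_insp, k2_exp = k2_exp, v_ref = v_ref)
  if (!all(is.finite(vals))) {
    stop("Rohrer coefficients must be finite numbers", call. = FALSE)
  }
  if (k1 < 0 || k2_insp < 0 || k2_exp < 0) {
    stop("Rohrer coefficients must be non-negative", call. = FALSE)
  }
  if (v_ref <= 0) stop("`v_ref` must be positive", call. = FALSE)
  structure(list(k1 = k1, k2_insp = k2_insp, k2_exp = k2_exp, v_ref = v_ref),
            class = "rohrer_model")
}

#' @export
print.rohrer_model <- function(x, ...) {
  cat(sprintf(
    "Rohrer model: k1 = %.3f mbar.s/L, k2 = %.3f (insp) / %.3f (exp) mbar at %.1f L/s\n",
    x$k1, x$k2_insp, x$k2_exp, x$v_ref))
  cat(sprintf("  secant resistance at 1 L/s: %.2f mbar.s/L\n",
              secant_resistance(x, 1)))
  invisible(x)
}

#' Pressure drop across the tube at a given flow (Rohrer equation)
#'
#' @param model A [rohrer_model()].
#' @param flow Gas flow, L/s; positive toward the lung (inspiration).
#'   Vectorized.
#' @return Pressure drop in mbar, same sign as the flow.
#' @export
rohrer_dp <- function(model, flow) {
  stopifnot(inherits(model, "rohrer_model"))
  k2 <- ifelse(flow >= 0, model$k2_insp, model$k2_exp)
  model$k1 * flow + sign(flow) * k2 * (flow / model$v_ref)^2
}

#' Secant resistance of the tube at a stated flow
#'
#' The pressure drop at the given flow divided by that flow. At the reference
#' flow of 1 L/s with symmetric coefficients this equals `k1 + k2`, the number
#' quoted as the tube resistance R.
#'
#' @inheritParams rohrer_dp
#' @param flow Flow at which the secant is taken, L/s (default 1). Must be
#'   nonzero.
#' @return Resistance in mbar·s/L.
#' @export
secant_resistance <- function(model, flow = 1) {
  if (any(flow == 0)) {
    stop("secant resistance is undefined at zero flow", call. = FALSE)
  }
  rohrer_dp(model, flow) / flow
}

#' Power-law scaling of tube resistance with effective diameter
#'
#' A one-parameter description of the Rohrer coefficients of any
#' tube-bronchoscope combination: the linear coefficient scales as a power law
#' of the effective diameter,
#' \deqn{k_1 = k_{1,ref}\,(D_{eff}/D_0)^{\beta},\qquad k_2 = 4\,k_1,}
#' with exponent \eqn{\beta = -3.6} for an unobstructed tube and
#' \eqn{\beta = -5} once a bronchoscope is inserted (frictional losses then
#' dominate, as for fully turbulent flow in a narrow lumen).
#'
#' @param k1_ref Linear coefficient at the reference diameter, mbar·s/L
#'   (default 0.72).
#' @param k2_over_k1 Ratio of quadratic to linear coefficient (default 4).
#' @param beta_tube Scaling exponent for an unobstructed tube (default -3.6).
#' @param beta_scope Scaling exponent with an inserted bronchoscope
#'   (default -5).
#' @param d_ref Reference diameter, mm (default 10).
#' @return An object of class `scaling_law`.
#' @export
scaling_law <- function(k1_ref = 0.72, k2_over_k1 = 4,
                        beta_tube = -3.6, beta_scope = -5, d_ref = 10) {
  if (k1_ref <= 0 || k2_over_k1 <= 0 || d_ref <= 0) {
    stop("`k1_ref`, `k2_over_k1` and `d_ref` must be positive", call. = FALSE)
  }
  if (beta_tube >= 0 || beta_scope >= 0) {
    stop("scaling exponents must be negative", call. = FALSE)
  }
  structure(list(k1_ref = k1_ref, k2_over_k1 = k2_over_k1,
                 beta_tube = beta_tube, beta_scope = beta_scope,
                 d_ref = d_ref),
            class = "scaling_law")
}

#' Rohrer model for a geometry via the diameter scaling law
#'
#' Evaluates the scaling law at the geometry's effective diameter, selecting
#' the exponent from the presence of a bronchoscope unless `beta` overrides
#' it, and returns the implied symmetric Rohrer model.
#'
#' @param geom A [tube_geometry()].
#' @param law A [scaling_law()] (defaults to the fitted bench values).
#' @param beta Optional exponent override (e.g. for sensitivity studies).
#' @return A [rohrer_model()] with `k2_insp = k2_exp = k2_over_k1 * k1`.
#' @examples
#' scaling_law_model(tube_geometry(d_eff = 10, has_scope = FALSE))
#' @export
scaling_law_model <- function(geom, law = scaling_law(), beta = NULL) {
  stopifnot(inherits(geom, "tube_geometry"), inherits(law, "scaling_law"))
  if (is.null(beta)) {
    beta <- if (geom$has_scope) law$beta_scope else law$beta_tube
  }
  k1 <- law$k1_ref * (geom$d_eff / law$d_ref)^beta
  rohrer_model(k1 = k1, k2_insp = law$k2_over_k1 * k1)
}

#' Flow through the tube for a given driving pressure
#'
#' Inverts the Rohrer relation, optionally with an additional linear
#' resistance in series (airway and valve resistance), i.e. solves
#' \deqn{\mathrm{sign}(\dot V)\,k_2 (\dot V/\dot V_0)^2 +
#'       (k_1 + r)\,\dot V = \Delta p}
#' for the unique flow with the sign of the driving pressure. The positive
#' root of the quadratic is taken in closed form; the forward map is strictly
#' monotone, so the solution is unique.
#'
#' @param model A [rohrer_model()].
#' @param r_linear Additional series linear resistance, mbar·s/L (>= 0).
#' @param dp Driving pressure across tube plus series resistance, mbar.
#'   Vectorized.
#' @return Flow in L/s with the sign of `dp`.
#' @export
flow_from_driving_pressure <- function(model, r_linear = 0, dp) {
  stopifnot(inherits(model, "rohrer_model"))
  if (!is.numeric(r_linear) || length(r_linear) != 1L || r_linear < 0) {
    stop("`r_linear` must be a single non-negative number", call. = FALSE)
  }
  a <- model$k1 + r_linear
  k2 <- ifelse(dp >= 0, model$k2_insp, model$k2_exp) / model$v_ref^2
  if (a == 0 && any(k2 == 0 & dp != 0)) {
    stop("zero total resistance: flow is undefined for nonzero driving pressure",
         call. = FALSE)
  }
  mag <- abs(dp)
  # branchless closed form; fall back to the linear solution where k2 == 0
  f <- ifelse(k2 > 0,
              (-a + sqrt(a^2 + 4 * k2 * mag)) / (2 * pmax(k2, .Machine$double.xmin)),
              mag / a)
  sign(dp) * f
}
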