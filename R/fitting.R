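#' Pressure-flow sweep container
#'
#' An ordered set of simultaneous flow and tube pressure-drop samples, as
#' produced by slowly ramping a blower up and down across the tube (or by
#' [generate_sweep()]). The pressure drop is the difference between airway
#' and tracheal pressure, `paw - ptrach`.
#'
#' @param flow Flows, L/s (positive toward the lung).
#' @param dp Pressure drops across the tube, mbar.
#' @param label Optional geometry label carried as metadata.
#' @return An object of class `pressure_flow_sweep` (a data.frame with
#'   columns `flow`, `dp`).
#' @export
pressure_flow_sweep <- function(flow, dp, label = NULL) {
  if (length(flow) != length(dp)) {
    stop("`flow` and `dp` must have the same length", call. = FALSE)
  }
  if (length(flow) < 10L) {
    stop("a sweep needs at least 10 samples", call. = FALSE)
  }
  if (!all(is.finite(flow)) || !all(is.finite(dp))) {
    stop("sweep samples must be finite", call. = FALSE)
  }
  structure(data.frame(flow = flow, dp = dp),
            label = label,
            class = c("pressure_flow_sweep", "data.frame"))
}

#' Least-squares Rohrer coefficients from a pressure-flow sweep
#'
#' Fits \eqn{\Delta p = k_1 \dot V + \mathrm{sign}(\dot V) k_2 \dot V^2}
#' (reference flow 1 L/s) as a linear least-squares problem in
#' \eqn{(k_1, k_{2,insp}, k_{2,exp})} with basis \eqn{\dot V}, the
#' inspiratory-masked and the expiratory-masked signed square. `k1` is shared
#' between the two flow directions; the quadratic coefficient is fitted per
#' direction unless `shared_k2` forces a single value. Negative estimates are
#' clipped to zero with a warning (the model class requires non-negative
#' coefficients).
#'
#' @param sweep A [pressure_flow_sweep()] or a data.frame with columns
#'   `flow` and `dp`.
#' @param shared_k2 Fit a single quadratic coefficient for both directions
#'   (required when the sweep covers only one flow sign).
#' @return A [rohrer_model()] with attribute `fit` holding the residual norm
#'   (`rss`, `sigma`) and the raw coefficients.
#' @export
fit_rohrer <- function(sweep, shared_k2 = FALSE) {
  if (!is.data.frame(sweep) || !all(c("flow", "dp") %in% names(sweep))) {
    stop("`sweep` must have columns `flow` and `dp`", call. = FALSE)
  }
  f <- sweep$flow
  dp <- sweep$dp
  if (length(f) < 10L) stop("a sweep needs at least 10 samples", call. = FALSE)
  has_insp <- any(f > 0)
  has_exp <- any(f < 0)
  if (!shared_k2 && !(has_insp && has_exp)) {
    stop("per-direction k2 requires flows of both signs; use `shared_k2 = TRUE`",
         call. = FALSE)
  }
  x <- if (shared_k2) {
    cbind(k1 = f, k2 = sign(f) * f^2)
  } else {
    cbind(k1 = f,
          k2_insp = ifelse(f >= 0, f^2, 0),
          k2_exp = ifelse(f < 0, -f^2, 0))
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    stop("degenerate sweep: pressure-flow samples do not identify the Rohrer ",
         "coefficients (rank-deficient design)", call. = FALSE)
  }
  beta <- qr.coef(qx, dp)
  if (any(beta < 0)) {
    warning("negative least-squares coefficient(s) clipped to zero: ",
            paste(names(beta)[beta < 0], collapse = ", "), call. = FALSE)
  }
  clipped <- pmax(beta, 0)
  model <- if (shared_k2) {
    rohrer_model(k1 = clipped[["k1"]], k2_insp = clipped[["k2"]])
  } else {
    rohrer_model(k1 = clipped[["k1"]], k2_insp = clipped[["k2_insp"]],
                 k2_exp = clipped[["k2_exp"]])
  }
  resid <- dp - rohrer_dp(model, f)
  attr(model, "fit") <- list(coefficients = beta,
                             rss = sum(resid^2),
                             sigma = sqrt(sum(resid^2) / max(1, length(f) - ncol(x))),
                             n = length(f))
  model
}

#' Power-law fit of resistance versus effective diameter
#'
#' Ordinary least squares of `log(R)` on `log(d_eff / d_ref)`, matching the
#' straight-line appearance of the resistance data on a double-logarithmic
#' plot. Returns the amplitude (the resistance at the reference diameter)
#' and the scaling exponent.
#'
#' @param d_eff Effective diameters, mm (all positive, at least 3 points).
#' @param r_1lps Secant resistances at 1 L/s, mbar·s/L (all positive).
#' @param d_ref Reference diameter, mm (default 10).
#' @return An object of class `power_law_fit`: list with `amplitude`
#'   (mbar·s/L at `d_ref`), `exponent`, `d_ref`, and `residuals` (log-space).
#' @examples
#' d <- c(4, 5, 6, 8, 10)
#' fit_power_law(d, 3.6 * (d / 10)^-5)  # recovers amplitude 3.6, exponent -5
#' @export
fit_power_law <- function(d_eff, r_1lps, d_ref = 10) {
  if (length(d_eff) != length(r_1lps)) {
    stop("`d_eff` and `r_1lps` must have the same length", call. = FALSE)
  }
  if (length(d_eff) < 3L) {
    stop("at least 3 points are needed for a power-law fit", call. = FALSE)
  }
  if (any(d_eff <= 0) || any(r_1lps <= 0) || d_ref <= 0) {
    stop("diameters and resistances must be positive", call. = FALSE)
  }
  fit <- stats::lm(log(r_1lps) ~ log(d_eff / d_ref))
  structure(list(amplitude = unname(exp(stats::coef(fit)[1L])),
                 exponent = unname(stats::coef(fit)[2L]),
                 d_ref = d_ref,
                 residuals = unname(stats::residuals(fit))),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: R = %.3f (D_eff/%g)^%.2f mbar.s/L\n",
              x$amplitude, x$d_ref, x$exponent))
  invisible(x)
}

#' Mean absolute percentage error
#'
#' @param measured Reference values (all nonzero).
#' @param predicted Model values, same length.
#' @return MAPE in percent: `mean(100 * |measured - predicted| / |measured|)`.
#' @export
mape <- function(measured, predicted) {
  if (length(measured) == 0L) stop("empty input", call. = FALSE)
  if (length(measured) != length(predicted)) {
    stop("`measured` and `predicted` must have the same length", call. = FALSE)
  }
  if (any(measured == 0)) {
    stop("`measured` must be nonzero everywhere", call. = FALSE)
  }
  mean(100 * abs(measured - predicted) / abs(measured))
}

#' Read a bench pressure-flow sweep from CSV
#'
#' Accepts either raw recordings with columns `time_s, flow_Lps, paw_mbar,
#' ptrach_mbar` (the tube pressure drop is computed as `paw - ptrach`) or a
#' pre-reduced table with columns `flow_Lps, dp_mbar`.
#'
#' @param path CSV file path.
#' @param label Optional geometry label.
#' @return A [pressure_flow_sweep()].
#' @export
read_sweep_csv <- function(path, label = NULL) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop("empty sweep file: ", path, call. = FALSE)
  if (all(c("flow_Lps", "dp_mbar") %in% names(df))) {
    pressure_flow_sweep(df$flow_Lps, df$dp_mbar, label = label)
  } else if (all(c("flow_Lps", "paw_mbar", "ptrach_mbar") %in% names(df))) {
    pressure_flow_sweep(df$flow_Lps, df$paw_mbar - df$ptrach_mbar,
                        label = label)
  } else {
    stop("sweep CSV needs columns `flow_Lps, dp_mbar` or ",
         "`time_s, flow_Lps, paw_mbar, ptrach_mbar`; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
}

#' Write a sweep to CSV in the reduced dialect
#'
#' @param sweep A [pressure_flow_sweep()].
#' @param path Output CSV path.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(data.frame(flow_Lps = sweep$flow, dp_mbar = sweep$dp),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a table of fitted Rohrer coefficients to CSV
#'
#' One row per tube-scope combination with columns
#' `tube, scope, k1, k2_insp, k2_exp` (supplementary-table layout).
#'
#' @param coefs data.frame with columns `tube`, `scope`, `k1`, `k2_insp`,
#'   `k2_exp`.
#' @param path Output CSV path.
#' @export
write_rohrer_csv <- function(coefs, path) {
  need <- c("tube", "scope", "k1", "k2_insp", "k2_exp")
  if (!all(need %in% names(coefs))) {
    stop("coefficient table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(coefs[need], path, row.names = FALSE)
  invisible(path)
}
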