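#' Predict ventilation impairments for a tube-bronchoscope combination
#'
#' Convenience front end tying the modules together: derives the effective
#' diameter and the tube's Rohrer model from the scaling law, runs the chosen
#' ventilation mode to steady state, and returns a one-row summary of the
#' quantities relevant at the bedside — effective diameter, secant resistance
#' at 1 L/s, steady intrinsic PEEP (end-expiratory tracheal pressure), steady
#' tidal volume and peak airway pressure. Effective diameters below 5 mm are
#' flagged: tube resistance, and with it intrinsic PEEP, rises sharply below
#' that lumen.
#'
#' @param d_tube Inner tube diameter, mm (with optional `d_scope`), or `NULL`
#'   when `d_eff` is given directly.
#' @param d_scope Optional bronchoscope shaft diameter, mm.
#' @param d_eff Effective diameter, mm (mutually exclusive with the pair).
#' @param settings A [ventilator_settings()] (default: pressure-controlled
#'   ventilation at the reference bench settings).
#' @param system A [respiratory_system()].
#' @param law A [scaling_law()].
#' @param config A [sim_config()].
#' @return An object of class `ventilation_prediction` (a one-row data.frame
#'   with columns `mode, d_eff, r_1lps, ipeep, v_t, p_aw_peak, narrow_lumen,
#'   converged`), with the full simulation attached as attribute `sim`.
#' @examples
#' \donttest{
#' predict_ventilation(7.0, 5.0, settings = ventilator_settings("PC"))
#' }
#' @export
predict_ventilation <- function(d_tube = NULL, d_scope = NULL, d_eff = NULL,
                                settings = ventilator_settings("PC"),
                                system = respiratory_system(),
                                law = scaling_law(),
                                config = sim_config()) {
  geom <- tube_geometry(d_tube, d_scope, d_eff)
  tube <- scaling_law_model(geom, law)
  sim <- simulate_ventilation(settings, system, tube, config)
  s <- sim$steady
  out <- data.frame(mode = settings$mode, d_eff = geom$d_eff,
                    r_1lps = secant_resistance(tube, 1),
                    ipeep = s$ipeep, v_t = s$v_t,
                    p_aw_peak = s$p_aw_peak,
                    narrow_lumen = geom$d_eff < 5,
                    converged = s$converged)
  structure(out, sim = sim, geometry = geom,
            class = c("ventilation_prediction", "data.frame"))
}

#' @export
print.ventilation_prediction <- function(x, ...) {
  cat(sprintf("Ventilation prediction (%s mode)\n", x$mode))
  cat(sprintf("  effective diameter : %.1f mm\n", x$d_eff))
  cat(sprintf("  tube resistance    : %.1f mbar.s/L at 1 L/s\n", x$r_1lps))
  cat(sprintf("  steady iPEEP       : %.2f mbar (end-expiratory tracheal)\n",
              x$ipeep))
  cat(sprintf("  steady tidal volume: %.0f ml\n", x$v_t))
  cat(sprintf("  peak airway press. : %.1f mbar\n", x$p_aw_peak))
  if (isTRUE(x$narrow_lumen)) {
    cat("  WARNING: effective diameter below 5 mm - expect sharply rising\n",
        "  intrinsic PEEP and/or falling tidal volume\n", sep = "")
  }
  if (!isTRUE(x$converged)) {
    cat("  note: simulation did not reach the steady-state tolerance\n")
  }
  invisible(x)
}

#' Run manifest for reproducible outputs
#'
#' Records the command, the fully resolved parameters (with units fixed
#' package-wide: pressure mbar, flow L/s, volume ml, time s, diameter mm),
#' package version, timestamp and file paths, so any output can be
#' regenerated from its manifest.
#'
#' @param command Name of the operation performed.
#' @param params Named list of resolved parameters.
#' @param inputs,outputs Character vectors of file paths.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(command, params, inputs = character(),
                         outputs = character()) {
  structure(list(command = command,
                 params = params,
                 package = "bronchosim",
                 version = as.character(utils::packageVersion("bronchosim")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 inputs = inputs, outputs = outputs),
            class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Plot ventilation waveforms
#'
#' Base-graphics panel of airway pressure, tracheal pressure and flow versus
#' time, in the layout used to compare ventilation modes across
#' tube-bronchoscope combinations.
#'
#' @param x A `ventilation_sim` result.
#' @param breaths Which breaths to show (default: the final two).
#' @param ... Unused.
#' @export
plot.ventilation_sim <- function(x, breaths = NULL, ...) {
  wf <- x$waveforms
  if (is.null(breaths)) {
    nb <- max(wf$breath)
    breaths <- unique(pmax(1L, c(nb - 1L, nb)))
  }
  wf <- wf[wf$breath %in% breaths, ]
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  ylim <- range(wf$paw, wf$ptrach)
  plot(wf$t, wf$paw, type = "l", col = "firebrick",
       xlab = "time (s)", ylab = "pressure (mbar)", ylim = ylim)
  graphics::lines(wf$t, wf$ptrach, col = "steelblue")
  graphics::legend("topright", c("airway", "tracheal"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  plot(wf$t, wf$flow, type = "l", xlab = "time (s)", ylab = "flow (L/s)")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
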