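#' Passive single-compartment respiratory system
#'
#' Linear one-compartment model: constant compliance, constant airway
#' resistance distal to the endotracheal tube, optional constant muscular
#' pressure (zero for a passive, sedated patient). Volume is tracked relative
#' to the elastic equilibrium at the set PEEP, so the alveolar pressure is
#' `PEEP + V/C`.
#'
#' @param compliance Respiratory-system compliance, ml/mbar (default 50).
#' @param r_aw Airway resistance, mbar·s/L (default 2).
#' @param p_mus Constant muscular pressure aiding inspiration, mbar
#'   (default 0: no spontaneous effort).
#' @param v_rest Volume offset at zero elastic recoil above the PEEP
#'   baseline, ml (default 0).
#' @return An object of class `respiratory_system`.
#' @export
respiratory_system <- function(compliance = 50, r_aw = 2, p_mus = 0,
                               v_rest = 0) {
  if (compliance <= 0) stop("`compliance` must be positive", call. = FALSE)
  if (r_aw < 0) stop("`r_aw` must be non-negative", call. = FALSE)
  structure(list(compliance = compliance, r_aw = r_aw, p_mus = p_mus,
                 v_rest = v_rest),
            class = "respiratory_system")
}

#' Ventilator settings
#'
#' @param mode One of `"VC"` (volume-controlled: square inspiratory flow),
#'   `"PC"` (pressure-controlled: constant inspiratory pressure above PEEP)
#'   or `"ATC"` (automatic tube compensation: the ventilator servo-controls
#'   the airway pressure so the *tracheal* pressure follows a triangular
#'   target ramp, cancelling the tube's resistive drop in both phases).
#' @param vt Set tidal volume, ml (VC mode; default 500).
#' @param peep Positive end-expiratory pressure, mbar (default 0).
#' @param ps Pressure support above PEEP, mbar (PC mode; default 10).
#' @param t_in Inspiratory time, s (default 1.8; no end-inspiratory pause).
#' @param t_ex Expiratory time, s (default 2.2).
#' @param ramp_time Inspiratory pressure ramp time, s (PC mode; default 0,
#'   i.e. a pressure step).
#' @param atc_target_peak Peak of the tracheal target-pressure ramp above
#'   PEEP, mbar (ATC mode; default 10).
#' @param p_max Maximum airway pressure the ventilator can deliver, mbar
#'   (default 80). Caps the ATC controller; VC mode back-computes the airway
#'   pressure of its flow source without a cap but flags samples above
#'   `p_max`.
#' @param allow_subatmospheric Permit airway pressure below 0 mbar (default
#'   `TRUE` only in ATC mode, where expiratory tube compensation requires it).
#' @param r_valve Linear resistance of the expiratory valve/circuit,
#'   mbar·s/L (default 0), in series with the tube during expiration.
#' @return An object of class `ventilator_settings`.
#' @export
ventilator_settings <- function(mode = c("VC", "PC", "ATC"), vt = 500,
                                peep = 0, ps = 10, t_in = 1.8, t_ex = 2.2,
                                ramp_time = 0, atc_target_peak = 10,
                                p_max = 80,
                                allow_subatmospheric = NULL, r_valve = 0) {
  mode <- match.arg(toupper(mode[1L]), c("VC", "PC", "ATC"))
  if (t_in <= 0 || t_ex <= 0) stop("`t_in` and `t_ex` must be positive",
                                   call. = FALSE)
  if (mode == "VC" && vt <= 0) stop("`vt` must be positive in VC mode",
                                    call. = FALSE)
  if (mode == "PC" && ps <= 0) stop("`ps` must be positive in PC mode",
                                    call. = FALSE)
  if (p_max <= peep) stop("`p_max` must exceed `peep`", call. = FALSE)
  if (r_valve < 0 || ramp_time < 0) {
    stop("`r_valve` and `ramp_time` must be non-negative", call. = FALSE)
  }
  if (is.null(allow_subatmospheric)) allow_subatmospheric <- mode == "ATC"
  structure(list(mode = mode, vt = vt, peep = peep, ps = ps, t_in = t_in,
                 t_ex = t_ex, ramp_time = ramp_time,
                 atc_target_peak = atc_target_peak, p_max = p_max,
                 allow_subatmospheric = isTRUE(allow_subatmospheric),
                 r_valve = r_valve),
            class = "ventilator_settings")
}

#' Simulation configuration
#'
#' @param dt Nominal time step, s (default 0.004, i.e. a 250 Hz update rate).
#'   Each breath phase uses `round(duration/dt)` equal steps so phase
#'   durations are represented exactly.
#' @param max_breaths Maximum number of simulated breaths (default 100).
#' @param steady_tol Breath-to-breath change in end-expiratory tracheal
#'   pressure below which the simulation is considered steady, mbar
#'   (default 0.01).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.004, max_breaths = 100, steady_tol = 0.01) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (max_breaths < 2) stop("`max_breaths` must be at least 2", call. = FALSE)
  if (steady_tol <= 0) stop("`steady_tol` must be positive", call. = FALSE)
  structure(list(dt = dt, max_breaths = max_breaths, steady_tol = steady_tol),
            class = "sim_config")
}

# trapezoidal integral of y over t
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1L] + y[-n]) / 2)
}

# One breath phase. The quadratic pressure balance is solved implicitly at
# the new time: folding the trapezoidal volume update into an augmented
# linear resistance r + 500*dt/C keeps the closed-form root exact, so the
# pressure balance and the trapezoidal volume trace hold to machine
# precision at every stored sample. The first sample (zero-width, duplicated
# time) carries the new boundary condition at the unchanged volume, so flow
# discontinuities at phase transitions never corrupt the volume trace.
#
# `phase` is a list: type "flow" (f_set), "pressure" (p_src(t_rel), r_extra)
# or "atc" (target(t_rel)); `state` carries t, v (ml above PEEP equilibrium)
# and f (L/s).
run_phase <- function(phase, duration, state, settings, system, tube, dt) {
  n <- max(1L, as.integer(round(duration / dt)))
  dtp <- duration / n
  cc <- system$compliance
  peep <- settings$peep
  pmus <- system$p_mus
  t <- state$t + c(0, seq_len(n) * dtp)
  flow <- vol <- paw <- numeric(n + 1L)
  v <- state$v

  solve_pressure <- function(p_src, r_lin, v_base, r_dyn) {
    # r_dyn = 500*dtp/C for implicit steps, 0 for the boundary sample
    dp <- p_src + pmus - peep - v_base / cc
    flow_from_driving_pressure(tube, r_lin + r_dyn, dp)
  }

  if (phase$type == "flow") {
    f_set <- phase$f_set
    flow[] <- f_set
    vol[1L] <- v
    vol[-1L] <- v + cumsum(rep(1000 * f_set * dtp, n))
    v <- vol[n + 1L]
  } else if (phase$type == "pressure") {
    r_lin <- system$r_aw + phase$r_extra
    f <- solve_pressure(phase$p_src(0), r_lin, v, 0)
    flow[1L] <- f
    vol[1L] <- v
    for (i in seq_len(n)) {
      f_new <- solve_pressure(phase$p_src(i * dtp), r_lin,
                              v + 500 * dtp * f, 500 * dtp / cc)
      v <- v + 500 * dtp * (f + f_new)
      f <- f_new
      flow[i + 1L] <- f
      vol[i + 1L] <- v
    }
  } else { # atc
    r_aw <- system$r_aw
    pmax_v <- settings$p_max
    sub_ok <- settings$allow_subatmospheric
    atc_flow <- function(target, v_base, r_dyn) {
      # ideal controller: p_trach tracks the target unless the required
      # airway pressure leaves [0 or -Inf, p_max]
      f <- (target + pmus - peep - v_base / cc) / (r_aw + r_dyn)
      p_aw <- target + rohrer_dp(tube, f)
      if (p_aw > pmax_v) {
        f <- solve_pressure(pmax_v, r_aw, v_base, r_dyn)
      } else if (!sub_ok && p_aw < 0) {
        f <- solve_pressure(0, r_aw, v_base, r_dyn)
      }
      f
    }
    f <- atc_flow(phase$target(0), v, 0)
    flow[1L] <- f
    vol[1L] <- v
    for (i in seq_len(n)) {
      f_new <- atc_flow(phase$target(i * dtp), v + 500 * dtp * f,
                        500 * dtp / cc)
      v <- v + 500 * dtp * (f + f_new)
      f <- f_new
      flow[i + 1L] <- f
      vol[i + 1L] <- v
    }
  }

  palv <- peep + vol / cc
  ptrach <- palv + system$r_aw * flow
  paw <- ptrach + rohrer_dp(tube, flow)
  list(t = t, flow = flow, vol = vol, paw = paw, ptrach = ptrach,
       palv = palv,
       state = list(t = t[n + 1L], v = v, f = flow[n + 1L]))
}

phase_plan <- function(settings, system) {
  peep <- settings$peep
  switch(settings$mode,
    VC = list(
      insp = list(type = "flow", f_set = settings$vt / 1000 / settings$t_in),
      exp = list(type = "pressure", p_src = function(t) peep,
                 r_extra = settings$r_valve)),
    PC = list(
      insp = {
        ps <- settings$ps
        ramp <- settings$ramp_time
        psrc <- if (ramp > 0) {
          function(t) peep + ps * min(1, t / ramp)
        } else {
          function(t) peep + ps
        }
        list(type = "pressure", p_src = psrc, r_extra = 0)
      },
      exp = list(type = "pressure", p_src = function(t) peep,
                 r_extra = settings$r_valve)),
    ATC = {
      peak <- settings$atc_target_peak
      t_in <- settings$t_in
      t_ex <- settings$t_ex
      list(
        insp = list(type = "atc",
                    target = function(t) peep + peak * t / t_in),
        exp = list(type = "atc",
                   target = function(t) peep + peak * (1 - t / t_ex)))
    })
}

summarize_breath <- function(wf) {
  insp <- wf$phase == "insp"
  last_exp <- max(which(!insp))
  data.frame(
    v_insp = 1000 * trapz(wf$t[insp], pmax(wf$flow[insp], 0)),
    v_exp = -1000 * trapz(wf$t[!insp], pmin(wf$flow[!insp], 0)),
    ipeep = wf$ptrach[last_exp],
    ipeep_alv = wf$palv[last_exp],
    p_aw_peak = max(wf$paw),
    p_alv_peak = max(wf$palv))
}

#' Simulate mechanical ventilation through an endotracheal tube
#'
#' Time-stepping simulation of a passive single-compartment respiratory
#' system ventilated through a nonlinear (Rohrer) tube resistance, in
#' volume-controlled, pressure-controlled, or automatic-tube-compensation
#' mode. Breathing starts from elastic equilibrium at the set PEEP with the
#' inspiratory phase, and repeats until the end-expiratory tracheal pressure
#' stabilises (breath-to-breath change below `config$steady_tol`) or
#' `config$max_breaths` is reached.
#'
#' @param settings A [ventilator_settings()].
#' @param system A [respiratory_system()].
#' @param tube A [rohrer_model()] (e.g. from [scaling_law_model()]).
#' @param config A [sim_config()].
#' @return An object of class `ventilation_sim`: list with
#'   * `waveforms`: data.frame `t, flow, vol, paw, ptrach, palv, phase,
#'     breath` (phase boundaries carry a duplicated time sample, one per
#'     boundary condition);
#'   * `breaths`: per-breath data.frame `breath, v_insp, v_exp, ipeep,
#'     ipeep_alv, p_aw_peak, p_alv_peak`;
#'   * `steady`: final-breath summary with `converged`, `n_breaths`, and
#'     `n_over_pmax` (samples whose airway pressure exceeded `p_max`).
#' @examples
#' tube <- scaling_law_model(tube_geometry(7.0, 5.0))
#' sim <- simulate_ventilation(ventilator_settings("PC"),
#'                             respiratory_system(), tube)
#' sim$steady$v_t
#' @export
simulate_ventilation <- function(settings, system = respiratory_system(),
                                 tube, config = sim_config()) {
  stopifnot(inherits(settings, "ventilator_settings"),
            inherits(system, "respiratory_system"),
            inherits(tube, "rohrer_model"),
            inherits(config, "sim_config"))
  if (config$dt > settings$t_in / 50 || config$dt > settings$t_ex / 50) {
    stop("`dt` must be at most 1/50 of each phase duration", call. = FALSE)
  }
  if (settings$mode == "ATC" && system$r_aw <= 0) {
    stop("ATC requires a positive airway resistance (the ideal controller ",
         "flow is otherwise undefined)", call. = FALSE)
  }
  plan <- phase_plan(settings, system)
  state <- list(t = 0, v = 0, f = 0)
  chunks <- vector("list", config$max_breaths)
  breaths <- vector("list", config$max_breaths)
  ipeep_prev <- NA_real_
  converged <- FALSE
  nb <- 0L
  for (b in seq_len(config$max_breaths)) {
    pi <- run_phase(plan$insp, settings$t_in, state, settings, system, tube,
                    config$dt)
    state <- pi$state
    pe <- run_phase(plan$exp, settings$t_ex, state, settings, system, tube,
                    config$dt)
    state <- pe$state
    wf <- data.frame(
      t = c(pi$t, pe$t), flow = c(pi$flow, pe$flow),
      vol = c(pi$vol, pe$vol), paw = c(pi$paw, pe$paw),
      ptrach = c(pi$ptrach, pe$ptrach), palv = c(pi$palv, pe$palv),
      phase = rep(c("insp", "exp"), c(length(pi$t), length(pe$t))),
      breath = b)
    chunks[[b]] <- wf
    sm <- summarize_breath(wf)
    breaths[[b]] <- cbind(breath = b, sm)
    nb <- b
    if (!is.na(ipeep_prev) &&
        abs(sm$ipeep - ipeep_prev) < config$steady_tol) {
      converged <- TRUE
      break
    }
    ipeep_prev <- sm$ipeep
  }
  waveforms <- do.call(rbind, chunks[seq_len(nb)])
  breaths <- do.call(rbind, breaths[seq_len(nb)])
  rownames(waveforms) <- rownames(breaths) <- NULL
  last <- breaths[nb, ]
  steady <- list(converged = converged, n_breaths = nb,
                 v_t = last$v_insp, v_exp = last$v_exp,
                 ipeep = last$ipeep, ipeep_alv = last$ipeep_alv,
                 p_aw_peak = last$p_aw_peak, p_alv_peak = last$p_alv_peak,
                 n_over_pmax = sum(waveforms$paw > settings$p_max))
  structure(list(waveforms = waveforms, breaths = breaths, steady = steady,
                 settings = settings, system = system, tube = tube,
                 config = config),
            class = "ventilation_sim")
}

#' @rdname simulate_ventilation
#' @export
run_vc <- function(settings, system = respiratory_system(), tube,
                   config = sim_config()) {
  if (settings$mode != "VC") stop("`settings$mode` must be \"VC\"",
                                  call. = FALSE)
  simulate_ventilation(settings, system, tube, config)
}

#' @rdname simulate_ventilation
#' @export
run_pc <- function(settings, system = respiratory_system(), tube,
                   config = sim_config()) {
  if (settings$mode != "PC") stop("`settings$mode` must be \"PC\"",
                                  call. = FALSE)
  simulate_ventilation(settings, system, tube, config)
}

#' @rdname simulate_ventilation
#' @export
run_atc <- function(settings, system = respiratory_system(), tube,
                    config = sim_config()) {
  if (settings$mode != "ATC") stop("`settings$mode` must be \"ATC\"",
                                   call. = FALSE)
  simulate_ventilation(settings, system, tube, config)
}

#' @export
print.ventilation_sim <- function(x, ...) {
  s <- x$steady
  cat(sprintf("%s ventilation: %d breaths (%s)\n", x$settings$mode,
              s$n_breaths,
              if (s$converged) "steady" else "NOT converged"))
  cat(sprintf("  steady V_T = %.1f ml, iPEEP = %.2f mbar (trach) / %.2f mbar (alv)\n",
              s$v_t, s$ipeep, s$ipeep_alv))
  cat(sprintf("  peak p_aw = %.1f mbar, peak p_alv = %.1f mbar\n",
              s$p_aw_peak, s$p_alv_peak))
  if (s$n_over_pmax > 0) {
    cat(sprintf("  note: airway pressure exceeded p_max = %g mbar in %d samples\n",
                x$settings$p_max, s$n_over_pmax))
  }
  invisible(x)
}

#' Per-breath metrics from ventilation waveforms
#'
#' Recomputes the per-breath summaries from a waveform table: inspired and
#' expired volume by trapezoidal integration of the (sign-restricted) flow
#' over each phase, intrinsic PEEP as the end-expiratory tracheal pressure
#' (the measured proxy for alveolar pressure), with the end-expiratory
#' alveolar pressure alongside.
#'
#' @param waveforms Waveform data.frame as in the `waveforms` element of a
#'   [simulate_ventilation()] result (columns `t, flow, vol, paw, ptrach,
#'   palv, phase, breath`).
#' @param steady_tol Breath-to-breath iPEEP tolerance for the `steady`
#'   indicator, mbar (default 0.01).
#' @return data.frame with one row per breath (`breath, v_insp, v_exp,
#'   ipeep, ipeep_alv, p_aw_peak, p_alv_peak, steady`).
#' @export
analyze_breaths <- function(waveforms, steady_tol = 0.01) {
  need <- c("t", "flow", "ptrach", "palv", "paw", "phase", "breath")
  if (!all(need %in% names(waveforms))) {
    stop("waveforms need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ids <- sort(unique(waveforms$breath))
  if (length(ids) < 2L) {
    stop("waveforms must cover at least 2 full breath cycles", call. = FALSE)
  }
  rows <- lapply(ids, function(b) {
    wf <- waveforms[waveforms$breath == b, ]
    if (!all(c("insp", "exp") %in% wf$phase)) {
      stop("breath ", b, " is truncated (missing a phase)", call. = FALSE)
    }
    cbind(breath = b, summarize_breath(wf))
  })
  out <- do.call(rbind, rows)
  out$steady <- c(NA, abs(diff(out$ipeep)) < steady_tol)
  rownames(out) <- NULL
  out
}

#' Write simulation waveforms to CSV
#'
#' Columns `t_s, flow_Lps, vol_ml, paw_mbar, ptrach_mbar, palv_mbar, phase`.
#'
#' @param sim A `ventilation_sim` result.
#' @param path Output CSV path.
#' @export
write_waveforms_csv <- function(sim, path) {
  wf <- sim$waveforms
  utils::write.csv(
    data.frame(t_s = wf$t, flow_Lps = wf$flow, vol_ml = wf$vol,
               paw_mbar = wf$paw, ptrach_mbar = wf$ptrach,
               palv_mbar = wf$palv, phase = wf$phase),
    path, row.names = FALSE)
  invisible(path)
}
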