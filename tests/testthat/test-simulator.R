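default_tube <- rohrer_model(0.72, 2.88)

test_that("constructors validate settings and mechanics", {
  expect_error(respiratory_system(compliance = 0), "positive")
  expect_error(respiratory_system(r_aw = -1), "non-negative")
  expect_error(ventilator_settings("VC", vt = 0), "vt")
  expect_error(ventilator_settings("PC", ps = 0), "ps")
  expect_error(ventilator_settings("VC", t_in = 0), "t_in")
  expect_error(ventilator_settings("VC", peep = 5, p_max = 5), "p_max")
  expect_error(sim_config(max_breaths = 1), "at least 2")
  expect_error(run_pc(ventilator_settings("VC"), tube = default_tube), "PC")
  expect_error(run_vc(ventilator_settings("PC"), tube = default_tube), "VC")
  expect_error(run_atc(ventilator_settings("PC"), tube = default_tube), "ATC")
  expect_error(
    run_atc(ventilator_settings("ATC"), respiratory_system(r_aw = 0),
            tube = default_tube),
    "airway resistance")
  expect_error(
    simulate_ventilation(ventilator_settings("VC"), respiratory_system(),
                         default_tube, sim_config(dt = 0.1)),
    "1/50")
})

test_that("a system at equilibrium under applied PEEP stays at rest", {
  sim <- run_pc(ventilator_settings("PC", ps = 1e-12), tube = default_tube,
                config = sim_config(max_breaths = 3))
  expect_lt(max(abs(sim$waveforms$flow)), 1e-9)
  expect_lt(max(abs(sim$waveforms$vol)), 1e-6)
})

test_that("the implicit step solves the stated quadratic pressure balance", {
  # p_aw = 10 mbar applied to an empty lung: 2.88 f^2 + 2.72 f = 10
  f <- flow_from_driving_pressure(default_tube, 2, 10)
  expect_equal(f, (-2.72 + sqrt(2.72^2 + 4 * 2.88 * 10)) / (2 * 2.88))
  expect_equal(f, bisect_flow(default_tube, 2, 10), tolerance = 1e-9)
  expect_equal(f, 1.45007, tolerance = 1e-4)
  # and the first PC inspiration sample reproduces it
  sim <- run_pc(ventilator_settings("PC", ps = 10), tube = default_tube,
                config = sim_config(max_breaths = 2))
  expect_equal(sim$waveforms$flow[1L], f)
})

test_that("pressure balance residual is at machine precision at every sample", {
  for (d in c(3.8, 7.5)) {
    sim <- run_pc(ventilator_settings("PC"), tube = tube_at(d),
                  config = sim_config(max_breaths = 5))
    wf <- sim$waveforms
    tube <- sim$tube
    resid <- pc_source_pressure(sim) - wf$palv -
      sim$system$r_aw * wf$flow - rohrer_dp(tube, wf$flow)
    expect_lt(max(abs(resid)), 1e-9)
  }
})

test_that("volume trace is the trapezoidal integral of the flow trace", {
  for (mode in c("VC", "PC", "ATC")) {
    sim <- simulate_ventilation(ventilator_settings(mode),
                                respiratory_system(), tube_at(5),
                                config = sim_config(max_breaths = 4))
    wf <- sim$waveforms
    dv <- diff(wf$vol)
    trap <- 500 * diff(wf$t) * (wf$flow[-1] + wf$flow[-nrow(wf)])
    expect_lt(max(abs(dv - trap)), 1e-9)
  }
})

test_that("VC delivers the set tidal volume regardless of the tube", {
  for (d in c(3.8, 5.4, 20)) {
    sim <- run_vc(ventilator_settings("VC", vt = 500), tube = tube_at(d))
    expect_lt(abs(sim$steady$v_t - 500), 1)
    expect_true(all(abs(sim$breaths$v_insp - 500) < 1))
  }
})

test_that("VC through a wide tube empties fully; a narrow lumen traps gas", {
  wide <- run_vc(ventilator_settings("VC"), tube = tube_at(20))
  expect_lt(wide$steady$ipeep, 0.2)
  narrow <- run_vc(ventilator_settings("VC"), tube = tube_at(3.8))
  expect_gt(narrow$steady$ipeep, 5)
  # the airway pressure needed to push the set flow exceeds the 80 mbar
  # sensor/delivery range through the narrow lumen, and is flagged
  expect_gt(narrow$steady$p_aw_peak, 80)
  expect_gt(narrow$steady$n_over_pmax, 0)
})

test_that("PC tidal volume is bounded by PS*C and reaches it for wide tubes", {
  st <- ventilator_settings("PC", ps = 10)
  sys <- respiratory_system(compliance = 50)
  wide <- run_pc(st, sys, tube = tube_at(50))
  expect_equal(wide$steady$v_t, 10 * 50, tolerance = 1e-3)
  for (d in c(4, 6, 7.5)) {
    sim <- run_pc(st, sys, tube = tube_at(d))
    expect_lte(sim$steady$v_t, 10 * 50 + 0.5)
    expect_lt(sim$steady$ipeep, st$ps + st$peep)
  }
})

test_that("steady state conserves volume and is approached monotonically", {
  for (mode in c("VC", "PC")) {
    sim <- simulate_ventilation(ventilator_settings(mode),
                                respiratory_system(), tube_at(4.3))
    s <- sim$steady
    expect_true(s$converged)
    expect_lt(abs(s$v_t - s$v_exp), 0.01 * s$v_t)
    # iPEEP rises monotonically from the empty-lung initial condition
    expect_true(all(diff(sim$breaths$ipeep) > -sim$config$steady_tol))
  }
})

test_that("ATC with an unbounded ceiling fully cancels the tube", {
  st <- ventilator_settings("ATC", p_max = Inf)
  a <- run_atc(st, tube = tube_at(3.8))
  b <- run_atc(st, tube = tube_at(8))
  n <- min(nrow(a$waveforms), nrow(b$waveforms))
  expect_lt(max(abs(a$waveforms$ptrach[1:n] - b$waveforms$ptrach[1:n])), 1e-6)
  expect_lt(max(abs(a$waveforms$flow[1:n] - b$waveforms$flow[1:n])), 1e-6)
  expect_lte(abs(a$steady$ipeep), 0.1)
  expect_lte(abs(b$steady$ipeep), 0.1)
  expect_equal(a$steady$v_t, b$steady$v_t, tolerance = 1e-6)
})

test_that("ATC drives expiratory airway pressure sub-atmospheric through a narrow lumen", {
  sim <- run_atc(ventilator_settings("ATC"), tube = tube_at(3.8))
  wf <- sim$waveforms
  expect_lt(min(wf$paw[wf$phase == "exp"]), 0)
  expect_gte(min(wf$ptrach), sim$settings$peep - 1e-9)
  expect_lte(abs(sim$steady$ipeep), 0.1)
})

test_that("the ATC pressure ceiling caps airway pressure and costs volume", {
  capped <- run_atc(ventilator_settings("ATC", p_max = 80), tube = tube_at(3))
  uncapped <- run_atc(ventilator_settings("ATC", p_max = Inf), tube = tube_at(3))
  expect_equal(max(capped$waveforms$paw), 80)
  expect_lt(capped$steady$v_t, uncapped$steady$v_t - 10)
})

test_that("halving the time step leaves steady outcomes unchanged within 1%", {
  st <- ventilator_settings("VC")
  a <- run_vc(st, tube = tube_at(3.8), config = sim_config(dt = 0.004))
  b <- run_vc(st, tube = tube_at(3.8), config = sim_config(dt = 0.002))
  expect_lt(abs(a$steady$ipeep - b$steady$ipeep) / b$steady$ipeep, 0.01)
  expect_lt(abs(a$steady$v_t - b$steady$v_t) / b$steady$v_t, 0.01)
})

test_that("breath analysis recovers volumes and end-expiratory pressures", {
  # synthetic square flow: 0.5 L/s for 1 s in, passive marker values out
  t_in <- seq(0, 1, by = 0.01)
  t_ex <- seq(1, 2, by = 0.01)
  mk <- function(b, off) data.frame(
    t = c(t_in, t_ex) + off, flow = c(rep(0.5, length(t_in)), rep(-0.5, length(t_ex))),
    vol = 0, paw = 1, ptrach = c(rep(1, length(t_in)), rep(0.25, length(t_ex))),
    palv = c(rep(1, length(t_in)), rep(0.2, length(t_ex))),
    phase = rep(c("insp", "exp"), c(length(t_in), length(t_ex))), breath = b)
  wf <- rbind(mk(1, 0), mk(2, 2))
  br <- analyze_breaths(wf)
  expect_equal(br$v_insp, c(500, 500))
  expect_equal(br$v_exp, c(500, 500))
  expect_equal(br$ipeep, c(0.25, 0.25))
  expect_equal(br$ipeep_alv, c(0.2, 0.2))
  expect_true(br$steady[2])
  # truncated or single-cycle input is refused
  expect_error(analyze_breaths(wf[wf$breath == 1, ]), "2 full")
  expect_error(analyze_breaths(wf[!(wf$breath == 2 & wf$phase == "exp"), ]),
               "truncated")
})

test_that("breath analysis agrees with the simulator's own summaries", {
  sim <- run_pc(ventilator_settings("PC"), tube = tube_at(5))
  br <- analyze_breaths(sim$waveforms, steady_tol = sim$config$steady_tol)
  expect_equal(br$v_insp, sim$breaths$v_insp)
  expect_equal(br$ipeep, sim$breaths$ipeep)
  # tracheal end-expiratory pressure is a close proxy for alveolar pressure
  wide <- run_pc(ventilator_settings("PC"), tube = tube_at(20))
  expect_lt(abs(wide$steady$ipeep - wide$steady$ipeep_alv), 0.1)
})

test_that("waveforms round-trip through the CSV writer", {
  dir <- withr::local_tempdir()
  sim <- run_pc(ventilator_settings("PC"), tube = tube_at(6),
                config = sim_config(max_breaths = 3))
  path <- file.path(dir, "wf.csv")
  write_waveforms_csv(sim, path)
  back <- utils::read.csv(path)
  expect_equal(back$flow_Lps, sim$waveforms$flow)
  expect_equal(back$ptrach_mbar, sim$waveforms$ptrach)
})
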