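# Independent oracles and small builders shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bisection root-finder for the flow that balances a driving pressure across
# the tube plus a series linear resistance. Deliberately independent of the
# closed-form inversion in the package: it only uses the forward Rohrer map,
# which is strictly monotone in flow.
bisect_flow <- function(model, r_linear, dp, tol = 1e-12) {
  forward <- function(f) rohrer_dp(model, f) + r_linear * f
  if (dp == 0) return(0)
  lo <- 0
  hi <- sign(dp)
  while (abs(forward(hi)) < abs(dp)) hi <- 2 * hi
  if (dp < 0) { tmp <- lo; lo <- hi; hi <- tmp }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (forward(mid) < dp) lo <- mid else hi <- mid
    if (abs(hi - lo) < tol) break
  }
  (lo + hi) / 2
}

# Tube model at a given effective diameter via the scaling law.
tube_at <- function(d_eff, has_scope = TRUE) {
  scaling_law_model(tube_geometry(d_eff = d_eff, has_scope = has_scope))
}

# Reconstruct the ventilator source pressure seen by each waveform sample of
# a VC/PC simulation (PEEP during expiration; PEEP + PS during PC
# inspiration), for pressure-balance residual checks.
pc_source_pressure <- function(sim) {
  st <- sim$settings
  ifelse(sim$waveforms$phase == "insp", st$peep + st$ps, st$peep)
}

random_rohrer <- function() {
  rohrer_model(k1 = runif(1, 0.1, 100), k2_insp = runif(1, 0.1, 400),
               k2_exp = runif(1, 0.1, 400))
}
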