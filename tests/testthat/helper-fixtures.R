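# Shared fixtures: the default parameter set and a tiny reference stepper
# written purely from the exported R-level operations, used to cross-check
# the compiled path.

bf_params <- default_parameters()

# One forward-Euler / three-level step using only the R-level operations.
# State is a list of ny x nx matrices (plus C fields); noise field p_ee is
# supplied explicitly.
r_reference_step <- function(st, p, ast, S0, p_ee, dt, dx, freeze_C = FALSE) {
  Phi <- list(ee = st$phi, ei = st$phi)
  A <- synaptic_input_rates(st$h_e, st$h_i, st$C_e, st$C_i, Phi, p_ee, p)
  S_e <- firing_rate(st$h_e, p, "e")
  S_i <- firing_rate(st$h_i, p, "i")
  new <- st
  new$h_e <- st$h_e + dt * membrane_rhs(st$h_e, st$I_ee, st$I_ie, p, "e")
  new$h_i <- st$h_i + dt * membrane_rhs(st$h_i, st$I_ei, st$I_ii, p, "i")
  for (cl in c("ee", "ei", "ie", "ii")) {
    Ik <- paste0("I_", cl); Jk <- paste0("J_", cl)
    d <- psp_rhs(st[[Ik]], st[[Jk]], A[[cl]], ast$gamma[cl], ast$gtilde[cl],
                 ast$gain[cl])
    new[[Ik]] <- st[[Ik]] + dt * d$dI
    new[[Jk]] <- st[[Jk]] + dt * d$dJ
  }
  new$phi <- wave_rhs_step(st$phi, st$phi_prev, st$C_e * S_e,
                           unname(p$lambda["ee"]), unname(p$v["ee"]), dx, dt)
  new$phi_prev <- st$phi
  if (!freeze_C) {
    new$C_e <- st$C_e + dt * synaptic_rhs(st$C_e, S_e, unname(p$f["e"]),
                                          unname(p$tau_rec["e"]), S0["e"])
    new$C_i <- st$C_i + dt * synaptic_rhs(st$C_i, S_i, unname(p$f["i"]),
                                          unname(p$tau_rec["i"]), S0["i"])
  }
  new
}

# field_state vectors -> list of matrices for the reference stepper
state_as_matrices <- function(st, grid) {
  out <- st
  for (nm in c("h_e", "h_i", "I_ee", "J_ee", "I_ei", "J_ei", "I_ie", "J_ie",
               "I_ii", "J_ii", "phi", "phi_prev", "C_e", "C_i"))
    out[[nm]] <- matrix(st[[nm]], grid$ny, grid$nx)
  out
}

# internal helpers exercised directly in tests
.welch_matrix <- burstfield:::.welch_matrix
.point_index_test <- burstfield:::.point_index
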