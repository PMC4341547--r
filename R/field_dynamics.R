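#' Population firing rate
#'
#' Sigmoidal rate function `S_k(h) = S_max_k / (1 + exp(-scale (h - mu_k) /
#' sigma_k))` with `scale = p$sigmoid_scale` (default `sqrt(2)`), strictly
#' increasing and bounded in `(0, S_max_k)`.
#'
#' @param h mean soma membrane potential (mV), vectorized.
#' @param p a `liley_params` object.
#' @param population `"e"` or `"i"`.
#' @return firing rate (1/ms).
#' @export
firing_rate <- function(h, p, population = "e") {
  k <- match.arg(population, c("e", "i"))
  unname(p$S_max[k]) /
    (1 + exp(-p$sigmoid_scale * (h - unname(p$mu[k])) / unname(p$sigma[k])))
}

#' Synaptic input rates
#'
#' Axonal pulse rates arriving at each synapse class:
#' `A_ek = N_beta_ek C_e S_e(h_e) + N_alpha_ek Phi_ek + p_ek` and
#' `A_ik = N_beta_ik C_i S_i(h_i)`. The cortico-cortical flux `Phi_ek`
#' already carries the pre-synaptic efficacy `C_e` through its wave-equation
#' source.
#'
#' @param h_e,h_i membrane potential fields (mV).
#' @param C_e,C_i synaptic efficacy fields.
#' @param Phi cortico-cortical flux field(s): a list with elements `ee` and
#'   `ei` (which may be the same vector when the classes share one wave
#'   field).
#' @param p_ee extracortical drive field for the ee class (1/ms); `p_ei` is
#'   taken constant from `p`.
#' @param p a `liley_params` object.
#' @return A list of fields `ee, ei, ie, ii` (1/ms).
#' @export
synaptic_input_rates <- function(h_e, h_i, C_e, C_i, Phi, p_ee, p) {
  S_e <- firing_rate(h_e, p, "e")
  S_i <- firing_rate(h_i, p, "i")
  list(
    ee = p$N_beta["ee"] * C_e * S_e + p$N_alpha["ee"] * Phi$ee + p_ee,
    ei = p$N_beta["ei"] * C_e * S_e + p$N_alpha["ei"] * Phi$ei + p$p_ext["ei"],
    ie = p$N_beta["ie"] * C_i * S_i,
    ii = p$N_beta["ii"] * C_i * S_i
  )
}

#' Membrane potential right-hand side
#'
#' `dh_k/dt = [h_r_k - h_k + sum_l psi_lk(h_k) I_lk] / tau_k` with the
#' reversal-potential weights `psi_lk(h) = (h_eq_lk - h) / |h_eq_lk -
#' h_r_k|`, which are +1 (excitatory) and -1 (inhibitory) at rest and vanish
#' at the reversal potentials.
#'
#' @param h membrane potential field (mV) of population `k`.
#' @param I_e,I_i PSP fields from the excitatory and inhibitory source onto
#'   population `k` (mV).
#' @param p a `liley_params` object.
#' @param population target population `"e"` or `"i"`.
#' @return dh/dt (mV/ms).
#' @export
membrane_rhs <- function(h, I_e, I_i, p, population = "e") {
  k <- match.arg(population, c("e", "i"))
  ecl <- paste0("e", k); icl <- paste0("i", k)
  psi_e <- (p$h_eq[ecl] - h) / abs(p$h_eq[ecl] - p$h_r[k])
  psi_i <- (p$h_eq[icl] - h) / abs(p$h_eq[icl] - p$h_r[k])
  (p$h_r[k] - h + psi_e * I_e + psi_i * I_i) / p$tau[k]
}

#' PSP cascade right-hand side
#'
#' The second-order PSP dynamics are integrated as two cascaded first-order
#' equations with one auxiliary field `J` per class:
#' `dI/dt = gtilde (J - I)`, `dJ/dt = gamma (gain * A - J)`, where `gain =
#' e^{gamma delta} Gamma(c) / gamma` uses the anesthesia-scaled amplitude
#' (synaptic depletion enters through `A`, not the gain). The impulse
#' response of this cascade is the bi-exponential kernel.
#'
#' @param I,J current PSP and auxiliary fields (mV).
#' @param A synaptic input rate field (1/ms).
#' @param gamma,gtilde rate constants (1/ms).
#' @param gain steady gain (mV ms).
#' @return list with `dI` and `dJ` (mV/ms).
#' @export
psp_rhs <- function(I, J, A, gamma, gtilde, gain) {
  list(dI = gtilde * (J - I), dJ = gamma * (gain * A - J))
}

#' Five-point toroidal Laplacian
#'
#' `(left + right + up + down - 4 center) / dx^2` with periodic wrap in both
#' dimensions.
#'
#' @param field numeric matrix (ny x nx).
#' @param dx grid spacing (mm).
#' @return matrix of the same shape (field units / mm^2).
#' @export
laplacian <- function(field, dx = 1) {
  ny <- nrow(field); nx <- ncol(field)
  up    <- field[c(ny, seq_len(ny - 1)), , drop = FALSE]
  down  <- field[c(seq_len(ny - 1) + 1, 1), , drop = FALSE]
  left  <- field[, c(nx, seq_len(nx - 1)), drop = FALSE]
  right <- field[, c(seq_len(nx - 1) + 1, 1), drop = FALSE]
  (up + down + left + right - 4 * field) / dx^2
}

#' One three-level step of the damped wave propagation
#'
#' Advances `[(1/v d/dt + 1/lambda)^2 - Lap] Phi = source / lambda^2` with
#' the second time derivative estimated from the previous, current and
#' future values and the future value solved for:
#' `(1/v^2)(Phi+ - 2 Phi + Phi-)/dt^2 + (2/(v lambda))(Phi+ - Phi-)/(2 dt)
#'  + Phi/lambda^2 - Lap(Phi) = source/lambda^2`.
#'
#' @param Phi_now,Phi_prev current and previous flux fields (1/ms), matrices.
#' @param source source field `C_e S_e` (1/ms).
#' @param lambda decay scale (mm); `v` conduction velocity (mm/ms).
#' @param v conduction velocity (mm/ms).
#' @param dx grid spacing (mm); `dt` time step (ms).
#' @param dt time step (ms).
#' @return the future field `Phi_next`.
#' @export
wave_rhs_step <- function(Phi_now, Phi_prev, source, lambda, v, dx, dt) {
  a <- 1 / (v^2 * dt^2)
  b <- 1 / (v * lambda * dt)
  rhs <- source / lambda^2 + laplacian(Phi_now, dx) - Phi_now / lambda^2 +
    a * (2 * Phi_now - Phi_prev) + b * Phi_prev
  rhs / (a + b)
}
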