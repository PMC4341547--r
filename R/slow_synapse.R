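#' Right-hand side of the slow synaptic efficacy dynamics
#'
#' Scaled depletion/recovery dynamics of the synaptic efficacy `C_l`:
#' `dC/dt = [1 + f_l - (1 + (S/S0_l) f_l) C] / tau_rec_l`. `C = 1` is the
#' constructed equilibrium (at `S = S0_l`); with no firing the fixed point is
#' `1 + f_l`, i.e. peak amplitudes recover to their resting values
#' `Gamma_r = Gamma0 (1 + f_l)`.
#'
#' @param C scaled synaptic efficacy (dimensionless), `> 0`. Vectorized.
#' @param S local population firing rate (1/ms), `>= 0`.
#' @param f depletion factor `f_l > 0`.
#' @param tau_rec recovery time (ms).
#' @param S0 reference firing rate at the constructed equilibrium (1/ms),
#'   `> 0`.
#' @return dC/dt (1/ms).
#' @export
synaptic_rhs <- function(C, S, f, tau_rec, S0) {
  if (any(S0 <= 0))
    stop("equilibrium firing rate S0 must be positive (configuration error)")
  stopifnot(all(f >= 0), all(tau_rec > 0), all(S >= 0))
  (1 + f - (1 + (S / S0) * f) * C) / tau_rec
}

#' Resting PSP peak amplitudes under anesthesia
#'
#' `Gamma_r_lk(c) = Gamma0_lk (1 + f_l) H_l(c)`: the no-activity fixed point
#' of the slow synaptic system, scaled by the anesthetic Hill factor of the
#' pre-synaptic source population. Per-class depletion-factor overrides
#' support spatially heterogeneous tissue (e.g. the circular-patch
#' experiment's raised `f_i`).
#'
#' @param p a `liley_params` object.
#' @param conc isoflurane concentration (mM).
#' @param f_e,f_i optional overrides of the depletion factors (scalars or
#'   per-grid-point vectors).
#' @return If the overrides are scalar, a named vector over the classes
#'   `ee, ei, ie, ii` (mV); otherwise a list of per-point vectors.
#' @export
resting_amplitudes <- function(p, conc, f_e = p$f["e"], f_i = p$f["i"]) {
  H <- c(e = hill_excitatory_amplitude(conc),
         i = hill_inhibitory_amplitude(conc))
  src <- c(ee = "e", ei = "e", ie = "i", ii = "i")
  fsrc <- list(e = f_e, i = f_i)
  if (length(f_e) == 1 && length(f_i) == 1) {
    f <- c(e = unname(f_e), i = unname(f_i))
    out <- p$Gamma0 * (1 + f[src]) * H[src]
    names(out) <- names(p$Gamma0)
    return(out)
  }
  out <- lapply(names(src), function(cl)
    p$Gamma0[cl] * (1 + fsrc[[src[cl]]]) * H[src[cl]])
  names(out) <- names(src)
  out
}

#' Effective PSP peak amplitude
#'
#' `Gamma0 * C * H`: the depletion-scaled, anesthesia-scaled amplitude used
#' by the stepper to scale PSP gains.
#'
#' @param Gamma0 zero-anesthesia equilibrium amplitude (mV).
#' @param C synaptic efficacy (dimensionless, `> 0`).
#' @param H amplitude Hill factor (dimensionless).
#' @export
effective_amplitude <- function(Gamma0, C, H) {
  stopifnot(all(is.finite(Gamma0)), all(is.finite(C)), all(is.finite(H)))
  Gamma0 * C * H
}
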