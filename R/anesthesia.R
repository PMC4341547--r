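#' @useDynLib burstfield, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Package-local cache (epsilon(kappa) spline, noise kernel cutoff constant).
.bf_cache <- new.env(parent = emptyenv())

.check_conc <- function(c) {
  if (any(!is.finite(c)) || any(c < 0))
    stop("isoflurane concentration must be finite and non-negative")
}

#' Hill factor for excitatory PSP amplitudes
#'
#' Dimensionless amplitude scaling `H_e(c)` of excitatory PSP peaks under
#' isoflurane: `0.707^2.22 / (0.707^2.22 + c^2.22)`. Strictly decreasing with
#' limit 0 as `c` grows.
#'
#' @param c aqueous isoflurane concentration (mM), vectorized.
#' @export
hill_excitatory_amplitude <- function(c) {
  .check_conc(c)
  0.707^2.22 / (0.707^2.22 + c^2.22)
}

#' Hill factor for inhibitory PSP amplitudes
#'
#' `H_i(c) = (0.79^2.6 + 0.56 c^2.6) / (0.79^2.6 + c^2.6)`; decreasing, with
#' asymptote 0.56.
#'
#' @inheritParams hill_excitatory_amplitude
#' @export
hill_inhibitory_amplitude <- function(c) {
  .check_conc(c)
  (0.79^2.6 + 0.56 * c^2.6) / (0.79^2.6 + c^2.6)
}

#' Prolongation factor of the inhibitory PSP decay time
#'
#' `kappa_i(c) = (0.32^2.7 + 4.7 c^2.7) / (0.32^2.7 + c^2.7)`; equals 1 at
#' `c = 0` and increases to the asymptote 4.7. Excitatory decay times are
#' unaffected (`kappa_e = 1`).
#'
#' @inheritParams hill_excitatory_amplitude
#' @export
inhibitory_decay_factor <- function(c) {
  .check_conc(c)
  (0.32^2.7 + 4.7 * c^2.7) / (0.32^2.7 + c^2.7)
}

# Decay time (to peak/e, measured from PSP onset) of the normalized
# bi-exponential with unit rise time, as a function of the shape parameter
# eps. Closed-form response; bracketed root solve. Used only to build the
# eps(kappa) inversion; the user-facing oracle lives in kinetics.
.zeta_unit <- function(eps) {
  g <- if (eps < 1e-8) 1 / (1 + eps / 2) else eps / (expm1(eps))
  gt <- exp(eps) * g
  resp <- function(t) {
    if (gt - g < 1e-10 * g) return(exp(g) * g * t * exp(-g * t) * exp(1 - 1))
    exp(g) * gt * (exp(-g * t) - exp(-gt * t)) / (gt - g)
  }
  # response is scaled so resp(1) = 1 (peak at the rise time)
  stats::uniroot(function(t) resp(t) - exp(-1),
                 lower = 1, upper = 10 * (1 + expm1(eps) / max(eps, 1e-8)),
                 tol = 1e-13)$root
}

# Reference decay time at eps = 0 (alpha kernel): -W_{-1}(-e^{-2}) times the
# rise time, via the -1 branch of the Lambert W function.
.zeta0_unit <- function() {
  arg <- -exp(-2)
  if (arg < -exp(-1) || arg >= 0) stop("Lambert W_{-1} argument out of domain")
  -pracma::lambertWn(arg)
}

.eps_solve_one <- function(kappa) {
  z0 <- .zeta0_unit()
  stats::uniroot(function(e) .zeta_unit(e) / z0 - kappa,
                 lower = 1e-9, upper = 12, tol = 1e-11)$root
}

.eps_spline <- function() {
  if (!is.null(.bf_cache$eps_spline)) return(.bf_cache$eps_spline)
  # interpolate in u = sqrt(kappa - 1): eps(kappa) has a square-root branch
  # point at kappa = 1, smooth in u
  kmax <- 4.7
  u <- seq(0, sqrt(kmax - 1 + 0.3), length.out = 160)
  k <- 1 + u^2
  e <- c(0, vapply(k[-1], .eps_solve_one, numeric(1)))
  .bf_cache$eps_spline <- stats::splinefun(u, e, method = "hyman")
  .bf_cache$eps_spline
}

#' Bi-exponential shape parameter from a target decay-time prolongation
#'
#' Computes the shape parameter `eps >= 0` such that the bi-exponential PSP
#' with fixed rise time has its decay time (back to peak/e, measured from PSP
#' onset) prolonged by the factor `kappa` relative to the `eps = 0` alpha
#' kernel. The defining relation is inverted numerically; the `eps = 0`
#' reference decay time is the closed form `-W_{-1}(-e^{-2})` rise times
#' (Lambert W, -1 branch, domain-checked). A monotone spline cache in
#' `sqrt(kappa - 1)` makes vectorized evaluation cheap during concentration
#' ramps.
#'
#' @param kappa decay-time prolongation factor(s), `kappa >= 1`.
#' @param exact if `TRUE`, bypass the spline cache and root-solve each value.
#' @return eps, same length as `kappa`; `eps = 0` at `kappa = 1` (continuous
#'   limit).
#' @export
epsilon_from_kappa <- function(kappa, exact = FALSE) {
  if (any(!is.finite(kappa)) || any(kappa < 1))
    stop("kappa must be finite and >= 1")
  if (any(kappa > 4.9))
    stop("kappa beyond the isoflurane parameterization range (max 4.7)")
  if (exact) {
    out <- vapply(kappa, function(k) if (k == 1) 0 else .eps_solve_one(k),
                  numeric(1))
    return(out)
  }
  pmax(0, .eps_spline()(sqrt(pmax(kappa - 1, 0))))
}

#' PSP rate constants from rise time and shape parameter
#'
#' `gamma = [eps / (e^eps - 1)] / delta` with the `eps -> 0` limit
#' `gamma = 1/delta` taken explicitly, and `gtilde = e^eps * gamma`.
#'
#' @param delta PSP rise time (ms), `> 0`.
#' @param eps shape parameter, `>= 0`. Recycled against `delta`.
#' @return A list with components `gamma` and `gtilde` (1/ms).
#' @export
rate_constants <- function(delta, eps) {
  stopifnot(all(delta > 0), all(eps >= 0))
  # eps/expm1(eps) is stable; series branch guards eps below 1e-8
  ratio <- ifelse(eps < 1e-8, 1 - eps / 2, eps / expm1(eps))
  gamma <- ratio / delta
  list(gamma = gamma, gtilde = exp(eps) * gamma)
}

#' Unit conversions for isoflurane level
#'
#' Linear conversions anchored at 1 MAC = 0.243 mM = 1.17% inspired
#' (adult, normal body temperature).
#'
#' @param mac concentration in multiples of the minimum alveolar concentration.
#' @export
concentration_from_mac <- function(mac) {
  stopifnot(all(mac >= 0))
  0.243 * mac
}

#' @rdname concentration_from_mac
#' @param c aqueous concentration (mM).
#' @export
percent_from_mM <- function(c) {
  .check_conc(c)
  c * 1.17 / 0.243
}

#' @rdname concentration_from_mac
#' @export
mac_from_concentration <- function(c) {
  .check_conc(c)
  c / 0.243
}

#' All concentration-derived model quantities at one isoflurane level
#'
#' Assembles the amplitude Hill factors, inhibitory decay prolongation and
#' shape parameters, PSP rate constants, anesthesia-scaled peak amplitudes
#' `Gamma_lk(c) = Gamma0_lk * H_l(c)` and the steady PSP gains
#' `g_lk = e^{gamma delta} Gamma_lk(c) / gamma_lk` for all four synapse
#' classes. Rise times are concentration-independent; excitatory decay times
#' are unaffected (`eps_ek = 0`).
#'
#' @param p a `liley_params` object.
#' @param conc aqueous isoflurane concentration (mM), scalar.
#' @return A list of class `anesthetic_state`.
#' @export
anesthetic_state <- function(p, conc) {
  .check_conc(conc)
  stopifnot(length(conc) == 1)
  H <- c(e = hill_excitatory_amplitude(conc),
         i = hill_inhibitory_amplitude(conc))
  kappa_i <- inhibitory_decay_factor(conc)
  eps_i <- epsilon_from_kappa(kappa_i)
  eps <- c(ee = 0, ei = 0, ie = eps_i, ii = eps_i)
  rc <- rate_constants(p$delta, eps)
  src <- c(ee = "e", ei = "e", ie = "i", ii = "i")
  Gamma_c <- p$Gamma0 * H[src]
  names(Gamma_c) <- names(p$Gamma0)
  gain <- exp(rc$gamma * p$delta) * Gamma_c / rc$gamma
  structure(list(conc = conc, H = H, kappa_i = kappa_i, eps = eps,
                 gamma = rc$gamma, gtilde = rc$gtilde,
                 Gamma_c = Gamma_c, gain = gain),
            class = "anesthetic_state")
}
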