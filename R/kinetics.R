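#' Construct a PSP kernel
#'
#' A post-synaptic potential impulse-response kernel with rate constants
#' `gamma <= gtilde`, peak amplitude `Gamma` (mV) reached at the rise time
#' `delta` (ms), and steady-state gain `g = e^{gamma delta} Gamma / gamma`
#' (mV ms). `delta` is derived from the rates: the response peaks at
#' `log(gtilde/gamma) / (gtilde - gamma)`.
#'
#' @param Gamma peak amplitude (mV).
#' @param gamma,gtilde rate constants (1/ms), `gtilde >= gamma > 0`.
#' @return An object of class `psp_kernel`.
#' @export
psp_kernel <- function(Gamma, gamma, gtilde = gamma) {
  Gamma <- unname(Gamma); gamma <- unname(gamma); gtilde <- unname(gtilde)
  stopifnot(gamma > 0, gtilde >= gamma, is.finite(Gamma))
  delta <- if ((gtilde - gamma) < 1e-12 * gamma) 1 / gamma
           else log(gtilde / gamma) / (gtilde - gamma)
  structure(list(Gamma = Gamma, gamma = gamma, gtilde = gtilde,
                 delta = delta,
                 gain = exp(gamma * delta) * Gamma / gamma),
            class = "psp_kernel")
}

#' PSP kernel for one synapse class at a given anesthetic state
#'
#' @param p a `liley_params` object.
#' @param class one of `"ee"`, `"ei"`, `"ie"`, `"ii"`.
#' @param conc isoflurane concentration (mM).
#' @return A `psp_kernel`.
#' @export
class_kernel <- function(p, class = "ee", conc = 0) {
  st <- anesthetic_state(p, conc)
  psp_kernel(st$Gamma_c[class], st$gamma[class], st$gtilde[class])
}

#' Bi-exponential impulse response
#'
#' Evaluates `I(t) = e^{gamma delta} (Gamma/gamma) * gamma gtilde
#' (e^{-gamma t} - e^{-gtilde t}) / (gtilde - gamma)` for `t >= 0` and 0
#' otherwise, with the degenerate `gtilde -> gamma` limit handled as the
#' alpha form through a stabilized difference quotient.
#'
#' @param t time (ms), vectorized.
#' @param kernel a `psp_kernel`.
#' @return response (mV).
#' @export
biexp_response <- function(t, kernel) {
  g <- kernel$gamma; gt <- kernel$gtilde
  pre <- exp(g * kernel$delta) * kernel$Gamma / g
  d <- gt - g
  if (d < 1e-7 * g) {
    # (e^{-g t} - e^{-gt t})/(gt - g) = t e^{-g t} * phi(d t),
    # phi(x) = (1 - e^{-x})/x evaluated stably
    x <- d * t
    phi <- ifelse(abs(x) < 1e-5, 1 - x / 2, -expm1(-x) / x)
    phi[t == 0] <- 1
    out <- pre * g * gt * t * exp(-g * t) * phi
  } else {
    out <- pre * g * gt * (exp(-g * t) - exp(-gt * t)) / d
  }
  out[t < 0] <- 0
  out
}

#' Alpha-function impulse response
#'
#' `I(t) = e (Gamma/gamma) gamma^2 t e^{-gamma t}` for `t >= 0`; the
#' `eps -> 0` limit of the bi-exponential. Peaks at `t = 1/gamma` with value
#' `Gamma`.
#'
#' @param t time (ms), vectorized.
#' @param Gamma peak amplitude (mV).
#' @param gamma rate constant (1/ms).
#' @export
alpha_response <- function(t, Gamma, gamma) {
  out <- exp(1) * (Gamma / gamma) * gamma^2 * t * exp(-gamma * t)
  out[t < 0] <- 0
  out
}

#' Decay time of a PSP kernel
#'
#' The unique time `zeta > delta` at which the response has fallen back to
#' `Gamma/e`, measured from PSP onset (t = 0), found by bracketed root
#' solving.
#'
#' @param kernel a `psp_kernel`.
#' @return zeta (ms).
#' @export
decay_time <- function(kernel) {
  target <- kernel$Gamma / exp(1)
  f <- function(t) biexp_response(t, kernel) - target
  hi <- kernel$delta * 2
  while (f(hi) > 0 && hi < kernel$delta * 1e9) hi <- hi * 2
  if (f(hi) > 0) stop("decay-time bracketing failed")
  stats::uniroot(f, lower = kernel$delta, upper = hi, tol = 1e-12)$root
}

#' Steady-state gain of a PSP kernel
#'
#' `e^{gamma delta} Gamma / gamma` (mV ms): the integral of the impulse
#' response, and the steady response level under unit constant drive.
#'
#' @param kernel a `psp_kernel`.
#' @export
steady_gain <- function(kernel) kernel$gain
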