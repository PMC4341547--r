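#' Spatially homogeneous fixed point of the fast subsystem
#'
#' Solves the reduced two-dimensional steady-state system in `(h_e, h_i)`
#' obtained by setting all time and space derivatives to zero with the
#' synaptic efficacies at their constructed equilibrium (`C_l = 1`): the
#' steady cortico-cortical flux is `Phi_ek = S_e(h_e)`, the steady PSP
#' levels are `I_ek = g_ek [(N_beta_ek + N_alpha_ek) S_e + p_ek]` and
#' `I_ik = g_ik N_beta_ik S_i` with the steady gains at `Gamma_lk(c)`, and
#' the membrane equations are set to zero. A damped Newton iteration with a
#' finite-difference Jacobian is started from the resting potentials; a
#' coarse grid scan reports (but does not resolve) any other candidate
#' roots.
#'
#' @param p a `liley_params` object.
#' @param conc isoflurane concentration (mM).
#' @param tol convergence tolerance on the membrane residual (mV/ms).
#' @return A list of class `equilibrium_result` with `h_star` (named e/i,
#'   mV), `S0` (1/ms), `I_star` (four classes, mV), `Phi_star` (1/ms),
#'   `residual_norm`, and `n_other_roots` from the scan.
#' @export
fixed_point <- function(p, conc = 0, tol = 1e-12) {
  st <- anesthetic_state(p, conc)
  Fm <- function(h) .membrane_residual(h, p, st)
  h <- unname(p$h_r)
  for (iter in 1:200) {
    r <- Fm(h)
    if (max(abs(r)) < tol) break
    eps <- 1e-6
    Jm <- matrix(0, 2, 2)
    for (j in 1:2) {
      hp <- h; hp[j] <- hp[j] + eps
      Jm[, j] <- (Fm(hp) - r) / eps
    }
    step <- tryCatch(solve(Jm, r), error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian in fixed-point solve")
    lam <- 1
    repeat {
      hn <- h - lam * step
      if (max(abs(Fm(hn))) < max(abs(r)) || lam < 1e-6) break
      lam <- lam / 2
    }
    h <- hn
  }
  r <- Fm(h)
  if (max(abs(r)) >= 1e-8)
    stop(sprintf("fixed-point iteration did not converge (residual %.3g)",
                 max(abs(r))))
  # coarse scan for other roots: sign changes of the diagonal residuals
  hs <- seq(-90, -40, by = 1)
  n_other <- 0L
  for (he0 in hs) {
    rr <- vapply(hs, function(hi0) Fm(c(he0, hi0))[2], numeric(1))
    sgn <- which(diff(sign(rr)) != 0)
    for (s in sgn) {
      cand <- c(he0, hs[s])
      if (sqrt(sum((cand - h)^2)) > 5 && abs(Fm(cand)[1]) < 0.05)
        n_other <- n_other + 1L
    }
  }
  S0 <- c(e = unname(firing_rate(h[1], p, "e")),
          i = unname(firing_rate(h[2], p, "i")))
  I_star <- .steady_psp(S0, p, st)
  structure(list(h_star = c(e = h[1], i = h[2]), S0 = S0, I_star = I_star,
                 Phi_star = unname(S0["e"]), residual_norm = max(abs(r)),
                 conc = conc, n_other_roots = n_other),
            class = "equilibrium_result")
}

.steady_psp <- function(S0, p, st) {
  A <- c(ee = unname((p$N_beta["ee"] + p$N_alpha["ee"]) * S0["e"] + p$p_ext["ee"]),
         ei = unname((p$N_beta["ei"] + p$N_alpha["ei"]) * S0["e"] + p$p_ext["ei"]),
         ie = unname(p$N_beta["ie"] * S0["i"]),
         ii = unname(p$N_beta["ii"] * S0["i"]))
  out <- st$gain * A
  names(out) <- names(st$gain)
  out
}

.membrane_residual <- function(h, p, st) {
  S_e <- firing_rate(h[1], p, "e")
  S_i <- firing_rate(h[2], p, "i")
  I <- .steady_psp(c(e = unname(S_e), i = unname(S_i)), p, st)
  c(unname(membrane_rhs(h[1], I["ee"], I["ie"], p, "e")),
    unname(membrane_rhs(h[2], I["ei"], I["ii"], p, "i")))
}

#' Construct the combined stationary initial state on a grid
#'
#' Builds the homogeneous field state at the `c = 0` fixed point with all
#' synaptic efficacies at 1, PSP auxiliaries consistent with steady drive,
#' and the wave history consistent with a static flux. The reference firing
#' rates `S0_l` recorded here are frozen thereafter (they define the slow
#' system's depletion couplings), which makes the initial state exactly
#' stationary.
#'
#' @param p a `liley_params` object.
#' @param grid a `grid_spec`.
#' @return A list of class `field_state`: per-point vectors `h_e, h_i`,
#'   `I_*`/`J_*` for the four classes, `phi, phi_prev`, `C_e, C_i`, plus the
#'   scalars `S0` and the `equilibrium_result`.
#' @export
construct_initial_state <- function(p, grid) {
  eq <- fixed_point(p, conc = 0)
  n <- grid$nx * grid$ny
  rep_f <- function(x) rep(unname(x), n)
  st <- list(
    h_e = rep_f(eq$h_star["e"]), h_i = rep_f(eq$h_star["i"]),
    I_ee = rep_f(eq$I_star["ee"]), J_ee = rep_f(eq$I_star["ee"]),
    I_ei = rep_f(eq$I_star["ei"]), J_ei = rep_f(eq$I_star["ei"]),
    I_ie = rep_f(eq$I_star["ie"]), J_ie = rep_f(eq$I_star["ie"]),
    I_ii = rep_f(eq$I_star["ii"]), J_ii = rep_f(eq$I_star["ii"]),
    phi = rep_f(eq$Phi_star), phi_prev = rep_f(eq$Phi_star),
    C_e = rep(1, n), C_i = rep(1, n),
    S0 = eq$S0, equilibrium = eq
  )
  class(st) <- "field_state"
  st
}
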