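test_that("firing rate sigmoid midpoint and saturation", {
  p <- bf_params
  expect_equal(firing_rate(p$mu["e"], p, "e"), p$S_max["e"] / 2,
               ignore_attr = TRUE)
  expect_equal(firing_rate(p$mu["i"], p, "i"), p$S_max["i"] / 2,
               ignore_attr = TRUE)
  expect_equal(firing_rate(-1e4, p, "e"), 0, ignore_attr = TRUE)
  expect_equal(firing_rate(1e4, p, "e"), unname(p$S_max["e"]))
  h <- seq(-100, -20, by = 0.5)
  expect_true(all(diff(firing_rate(h, p, "i")) > 0))
})

test_that("reversal-potential weights are +1/-1 at rest and vanish at reversal", {
  p <- bf_params
  # at rest, with only one input active, the rhs reduces to +-I/tau
  r_exc <- membrane_rhs(p$h_r["e"], I_e = 2, I_i = 0, p, "e")
  expect_equal(unname(r_exc), 2 / unname(p$tau["e"]))
  r_inh <- membrane_rhs(p$h_r["e"], I_e = 0, I_i = 2, p, "e")
  expect_equal(unname(r_inh), -2 / unname(p$tau["e"]))
  # at the excitatory reversal the excitatory term vanishes
  r_rev <- membrane_rhs(p$h_eq["ee"], I_e = 5, I_i = 0, p, "e")
  expect_equal(unname(r_rev),
               unname((p$h_r["e"] - p$h_eq["ee"]) / p$tau["e"]))
})

test_that("synaptic input rates at the constructed equilibrium", {
  p <- bf_params
  eq <- fixed_point(p, 0)
  A <- synaptic_input_rates(eq$h_star["e"], eq$h_star["i"], 1, 1,
                            Phi = list(ee = eq$Phi_star, ei = eq$Phi_star),
                            p_ee = p$p_ext["ee"], p)
  expect_equal(unname(A$ee),
               unname((p$N_beta["ee"] + p$N_alpha["ee"]) * eq$S0["e"] +
                        p$p_ext["ee"]))
  expect_equal(unname(A$ie), unname(p$N_beta["ie"] * eq$S0["i"]))
  # inhibitory input rates carry no flux or extracortical terms
  A2 <- synaptic_input_rates(eq$h_star["e"], eq$h_star["i"], 1, 1,
                             Phi = list(ee = 99, ei = 99), p_ee = 99, p)
  expect_equal(A2$ie, A$ie)
  expect_equal(A2$ii, A$ii)
})

test_that("toroidal five-point Laplacian", {
  expect_equal(laplacian(matrix(3.7, 9, 7)), matrix(0, 9, 7))
  m <- matrix(0, 8, 8); m[3, 5] <- 1
  lp <- laplacian(m, dx = 2)
  expect_equal(lp[3, 5], -4 / 4)
  expect_equal(lp[2, 5], 1 / 4)
  expect_equal(lp[3, 4], 1 / 4)
  expect_equal(sum(lp), 0)
  # periodic wrap
  m2 <- matrix(0, 8, 8); m2[1, 1] <- 1
  lp2 <- laplacian(m2)
  expect_equal(lp2[8, 1], 1)
  expect_equal(lp2[1, 8], 1)
  # plane-wave eigenvalue -(2 - 2 cos(2 pi n dx / L)) / dx^2
  n <- 3; L <- 32
  w <- cos(2 * pi * n * (0:(L - 1)) / L)
  M <- matrix(rep(w, each = L), L, L)
  lam <- -(2 - 2 * cos(2 * pi * n / L))
  expect_equal(laplacian(M), lam * M, tolerance = 1e-12)
})

test_that("damped wave relaxes to its source and decays without one", {
  lamb <- 14; v <- 2.1042; dt <- 0.05
  s <- 0.123
  ph <- matrix(0.05, 16, 16); php <- ph
  src <- matrix(s, 16, 16)
  for (i in 1:40000) {
    nxt <- wave_rhs_step(ph, php, src, lamb, v, 1, dt)
    php <- ph; ph <- nxt
  }
  expect_equal(ph, src, tolerance = 1e-9)
  # zero source: uniform field decays monotonically to 0
  ph <- matrix(1, 8, 8); php <- ph
  prev <- 1
  mono <- TRUE
  for (i in 1:4000) {
    nxt <- wave_rhs_step(ph, php, matrix(0, 8, 8), lamb, v, 1, dt)
    php <- ph; ph <- nxt
    if (ph[1, 1] > prev + 1e-14) mono <- FALSE
    prev <- ph[1, 1]
  }
  expect_true(mono)
  expect_lt(abs(ph[1, 1]), 1e-3)
})

test_that("steady point-source influence is below 2% at four decay scales", {
  lamb <- 3; v <- 2.1042; dt <- 0.05; L <- 64
  src <- matrix(0, L, L); src[1, 1] <- 1
  ph <- php <- matrix(0, L, L)
  for (i in 1:20000) {
    nxt <- wave_rhs_step(ph, php, src, lamb, v, 1, dt)
    php <- ph; ph <- nxt
  }
  expect_lt(ph[1, 1 + 4 * lamb] / ph[1, 1], 0.02)
  # decay scale sanity: ratio across one lambda close to exp(-1) within
  # the 2-D (Bessel) correction
  r1 <- ph[1, 1 + 3 * lamb] / ph[1, 1 + 2 * lamb]
  expect_lt(r1, exp(-1))
})

test_that("compiled stepper agrees with the R reference operations", {
  p <- bf_params
  g <- grid_spec(12)
  conc <- 0.2
  st0 <- construct_initial_state(p, g)
  # heterogeneous start so the comparison exercises all couplings
  set.seed(11)
  st0$h_e <- st0$h_e + rnorm(144, 0, 0.3)
  st0$h_i <- st0$h_i + rnorm(144, 0, 0.3)
  st0$C_e <- st0$C_e + runif(144, -0.05, 0.05)
  nst <- 200
  rec <- run_simulation(p, g, constant_protocol(conc, nst * 0.05 / 1000),
                        record = record_spec("h_e", 0, 1),
                        noise = noise_spec(mean = p$p_ext["ee"], rel_sd = 0),
                        seed = 1, state0 = st0)
  ast <- anesthetic_state(p, conc)
  sm <- state_as_matrices(st0, g)
  pee <- matrix(unname(p$p_ext["ee"]), g$ny, g$nx)
  for (i in seq_len(nst))
    sm <- r_reference_step(sm, p, ast, st0$S0, pee, 0.05, 1)
  expect_equal(rec$state$h_e, as.numeric(sm$h_e), tolerance = 1e-12)
  expect_equal(rec$state$C_e, as.numeric(sm$C_e), tolerance = 1e-12)
  expect_equal(rec$state$phi, as.numeric(sm$phi), tolerance = 1e-12)
  expect_equal(rec$state$I_ii, as.numeric(sm$I_ii), tolerance = 1e-12)
})

test_that("freezing the efficacies recovers the extended model", {
  p <- bf_params
  g <- grid_spec(12)
  st0 <- construct_initial_state(p, g)
  set.seed(12)
  st0$h_e <- st0$h_e + rnorm(144, 0, 0.3)
  rec <- run_simulation(p, g, constant_protocol(0.2, 0.01),
                        record = record_spec("h_e", 0, 1),
                        noise = noise_spec(mean = p$p_ext["ee"], rel_sd = 0),
                        seed = 1, state0 = st0, freeze_C = TRUE)
  expect_equal(rec$state$C_e, rep(1, 144))
  expect_equal(rec$state$C_i, rep(1, 144))
  ast <- anesthetic_state(p, 0.2)
  sm <- state_as_matrices(st0, g)
  pee <- matrix(unname(p$p_ext["ee"]), g$ny, g$nx)
  for (i in seq_len(200))
    sm <- r_reference_step(sm, p, ast, st0$S0, pee, 0.05, 1,
                           freeze_C = TRUE)
  expect_equal(rec$state$h_e, as.numeric(sm$h_e), tolerance = 1e-12)
})

test_that("solutions are equivariant under toroidal translation", {
  p <- bf_params
  g <- grid_spec(12)
  st0 <- construct_initial_state(p, g)
  set.seed(13)
  pert <- rnorm(144, 0, 0.2)
  shift <- function(v, dyx) {
    m <- matrix(v, g$ny, g$nx)
    m <- m[c((dyx[1] + 1):g$ny, seq_len(dyx[1])),
           c((dyx[2] + 1):g$nx, seq_len(dyx[2]))]
    as.numeric(m)
  }
  run_from <- function(pert_v) {
    s <- st0; s$h_e <- s$h_e + pert_v
    run_simulation(p, g, constant_protocol(0.2, 0.05),
                   record = record_spec("h_e", 0, 1),
                   noise = noise_spec(mean = p$p_ext["ee"], rel_sd = 0),
                   seed = 1, state0 = s)$state$h_e
  }
  a <- run_from(pert)
  b <- run_from(shift(pert, c(3, 5)))
  expect_equal(b, shift(a, c(3, 5)), tolerance = 1e-13)
})
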