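test_that("Hill amplitude and decay factors hit their anchors and limits", {
  expect_equal(hill_excitatory_amplitude(0), 1.0)
  expect_equal(hill_excitatory_amplitude(0.707), 0.5)
  expect_lt(hill_excitatory_amplitude(1e6), 1e-10)
  # inverting the printed resting amplitude Gamma_r_ee(0.25) = 0.37703 mV
  # with Gamma_r = Gamma0 (1 + f_e) H_e
  expect_equal(hill_excitatory_amplitude(0.25),
               0.37703 / (0.18424 * 2.25), tolerance = 2e-5)

  expect_equal(hill_inhibitory_amplitude(0), 1.0)
  expect_equal(hill_inhibitory_amplitude(0.79), (1 + 0.56) / 2)
  expect_equal(hill_inhibitory_amplitude(1e8), 0.56, tolerance = 1e-6)

  expect_equal(inhibitory_decay_factor(0), 1.0)
  expect_equal(inhibitory_decay_factor(0.32), (1 + 4.7) / 2)
  expect_equal(inhibitory_decay_factor(1e8), 4.7, tolerance = 1e-6)

  cc <- seq(0, 1, by = 0.005)
  expect_true(all(diff(hill_excitatory_amplitude(cc)) < 0))
  expect_true(all(diff(hill_inhibitory_amplitude(cc)) < 0))
  expect_true(all(diff(inhibitory_decay_factor(cc)) > 0))
  expect_error(hill_excitatory_amplitude(-0.1), "non-negative")
})

test_that("epsilon(kappa) reproduces decay-time prolongations within 1%", {
  expect_equal(epsilon_from_kappa(1), 0)
  expect_lt(epsilon_from_kappa(1 + 1e-8), 1e-3)
  expect_error(epsilon_from_kappa(0.9), "kappa")
  # oracle: bisection on the assembled kernel via decay_time(); the
  # eps = 0 reference is the alpha-kernel decay time
  for (kap in c(1.05, 1.2, 1.5, 2, 3, 4.5)) {
    for (delta in unname(bf_params$delta[c("ie", "ii")])) {
      eps <- epsilon_from_kappa(kap)
      rc <- rate_constants(delta, eps)
      z  <- decay_time(psp_kernel(1, rc$gamma, rc$gtilde))
      z0 <- decay_time(psp_kernel(1, 1 / delta))
      expect_equal(z / z0, kap, tolerance = 0.01)
    }
  }
  # spline cache agrees with direct root-solving
  kk <- c(1.01, 1.7, 2.9, 4.6)
  expect_equal(epsilon_from_kappa(kk), epsilon_from_kappa(kk, exact = TRUE),
               tolerance = 1e-6)
})

test_that("rate constants take the removable eps -> 0 limit", {
  rc <- rate_constants(9.1059, 0)
  expect_equal(rc$gamma, 1 / 9.1059)
  expect_equal(rc$gtilde, rc$gamma)
  rc1 <- rate_constants(1, 1)
  expect_equal(rc1$gamma, 1 / (exp(1) - 1))
  expect_equal(rc1$gtilde, exp(1) / (exp(1) - 1))
  # continuity across the series branch
  expect_equal(rate_constants(2, 1e-9)$gamma, rate_constants(2, 1e-7)$gamma,
               tolerance = 1e-6)
})

test_that("MAC / percent / mM conversions are anchored linearly", {
  expect_equal(concentration_from_mac(1), 0.243)
  expect_equal(concentration_from_mac(0.5), 0.1215)
  expect_equal(concentration_from_mac(0), 0)
  expect_equal(percent_from_mM(0.243), 1.17)
  expect_equal(percent_from_mM(0.27), 1.3)
  expect_equal(mac_from_concentration(0.3645), 1.5)
})

test_that("anesthetic state assembles consistently from its components", {
  p <- bf_params
  st0 <- anesthetic_state(p, 0)
  expect_equal(unname(st0$H), c(1, 1), ignore_attr = TRUE)
  expect_equal(unname(st0$eps), rep(0, 4), ignore_attr = TRUE)
  expect_equal(unname(st0$gamma), unname(1 / p$delta))
  expect_equal(unname(st0$gtilde), unname(st0$gamma))

  st <- anesthetic_state(p, 0.243)
  # independent high-precision evaluation of each component
  expect_equal(unname(st$kappa_i), inhibitory_decay_factor(0.243))
  expect_equal(unname(st$eps["ie"]),
               epsilon_from_kappa(inhibitory_decay_factor(0.243),
                                  exact = TRUE),
               tolerance = 1e-6)
  expect_equal(unname(st$eps["ee"]), 0)
  expect_equal(unname(st$Gamma_c["ei"]),
               unname(p$Gamma0["ei"]) * hill_excitatory_amplitude(0.243))
  expect_equal(unname(st$Gamma_c["ii"]),
               unname(p$Gamma0["ii"]) * hill_inhibitory_amplitude(0.243))
  expect_equal(unname(st$gtilde), unname(exp(st$eps) * st$gamma))
  # rise times unchanged: peak of every kernel sits at delta
  for (cl in c("ee", "ei", "ie", "ii")) {
    ker <- psp_kernel(st$Gamma_c[cl], st$gamma[cl], st$gtilde[cl])
    expect_equal(unname(ker$delta), unname(p$delta[cl]), tolerance = 1e-10)
    opt <- optimize(function(t) -biexp_response(t, ker),
                    c(0, 10 * ker$delta), tol = 1e-10)
    expect_equal(opt$minimum, unname(p$delta[cl]), tolerance = 1e-6)
  }
})
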