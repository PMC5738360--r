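test_that("dox steady state reproduces the saturation algebra", {
  p <- dox_induction_params(kappa1 = 10, kappa2 = 5, K_D = 7, n_hill = 2)
  expect_identical(dox_steady_state_gfp(0, p), 0)
  # half-saturation: D^n_hill == K_D
  expect_equal(dox_steady_state_gfp(sqrt(7), p), 10 * 5 / 2)
  # saturation limit converges to kappa1*kappa2
  p1 <- dox_induction_params(kappa1 = 10, kappa2 = 5, K_D = 7, n_hill = 1)
  expect_equal(dox_steady_state_gfp(1e9, p1), 50, tolerance = 1e-7)
  # general m raises the effector steady state before scaling
  pm <- dox_induction_params(kappa1 = 10, kappa2 = 5, K_D = 7, n_hill = 1,
                             m = 2)
  C_ss <- 10 * 3 / (7 + 3)
  expect_equal(dox_steady_state_gfp(3, pm), 5 * C_ss^2)
  expect_error(dox_steady_state_gfp(-1, p), "must be finite and >= 0")
})

test_that("ChaCha surface obeys its boundary and half-maximum algebra", {
  p <- steady_state_params(G_max = 8, K_L = 3, K_A = 5, n_stoich = 2)
  expect_identical(chacha_steady_state_gfp(0, 4, p), 0)
  expect_identical(chacha_steady_state_gfp(100, 0, p), 0)
  # L = K_L and A^n = K_A gives G_max/4
  expect_equal(chacha_steady_state_gfp(3, sqrt(5), p), 8 / 4)
  expect_error(chacha_steady_state_gfp(-1, 1, p), ">= 0")
  expect_error(chacha_steady_state_gfp(1, -1, p), ">= 0")
})

test_that("surface is monotone in both arguments and scales with G_max", {
  p <- steady_state_params(G_max = 2, K_L = 50, K_A = 1.7, n_stoich = 2.33)
  L <- 10^seq(-2, 5, length.out = 120)
  A <- 10^seq(-2, 2, length.out = 120)
  expect_true(all(diff(chacha_steady_state_gfp(L, 1.3, p)) >= 0))
  expect_true(all(diff(chacha_steady_state_gfp(40, A, p)) >= 0))
  p3 <- steady_state_params(G_max = 3 * p$G_max, K_L = p$K_L, K_A = p$K_A,
                            n_stoich = p$n_stoich)
  expect_equal(chacha_steady_state_gfp(L, 0.8, p3),
               3 * chacha_steady_state_gfp(L, 0.8, p))
})

test_that("rate constants lump into surface parameters as derived", {
  unit <- chacha_rate_params(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  s <- derive_steady_state_params(unit)
  expect_equal(s$G_max, 0.5)
  expect_equal(s$K_L, 1)
  expect_equal(s$K_A, 1)
  expect_equal(s$n_stoich, 1)
  # K_L = beta_R / alpha_Rstar is proportional to beta_R
  doubled <- chacha_rate_params(1, 1, 1, 2, 1, 1, 1, 1, 1, 1, 1)
  expect_equal(derive_steady_state_params(doubled)$K_L, 2 * s$K_L)
})

test_that("coupled steady state solves the fixed point exactly", {
  p <- rand_rate_params(7)
  # L = 0: no activation, adaptor at its production/degradation balance
  s0 <- solve_coupled_steady_state(p, 0)
  expect_equal(s0$Rstar_ss, 0)
  expect_equal(s0$C_ss, 0)
  expect_equal(s0$G_ss, 0)
  expect_equal(s0$A_ss, p$alpha_A / p$beta_A)
  expect_equal(s0$R_ss, p$alpha_R / p$beta_R)
  # residuals of all five rate equations vanish for random draws
  for (seed in 1:50) {
    pp <- rand_rate_params(seed)
    L <- 10^stats::runif(1, -1, 1)
    s <- solve_coupled_steady_state(pp, L)
    expect_lt(max(abs(s$residuals)), 1e-8)
    # the lumped surface evaluated at (L, A_ss) returns the same G_ss
    expect_equal(
      chacha_steady_state_gfp(L, s$A_ss, derive_steady_state_params(pp)),
      s$G_ss, tolerance = 1e-8)
  }
  expect_error(solve_coupled_steady_state(p, -1), ">= 0")
})

test_that("closed-form steady state matches long-time ODE integration", {
  for (seed in c(2, 11, 23, 34, 45)) {
    p <- rand_rate_params(seed)
    L <- 10^stats::runif(1, -0.5, 0.5)
    s <- solve_coupled_steady_state(p, L)
    tr <- simulate_chacha(p, schedule(0, L), c(0, relax_horizon(p)),
                          init = "zero", n_out = 51L,
                          rtol = 1e-10, atol = 1e-12)
    term <- tr$states[nrow(tr$states), ]
    expect_equal(term[["G"]], s$G_ss, tolerance = 1e-4)
    expect_equal(term[["A"]], s$A_ss, tolerance = 1e-4)
    # Eq 17 closed form with the numerically solved adaptor steady state
    expect_equal(
      chacha_steady_state_gfp(L, term[["A"]],
                              derive_steady_state_params(p)),
      term[["G"]], tolerance = 1e-4)
  }
})

test_that("parameter sets round-trip through flat JSON and reject typos", {
  for (p in list(chacha_rate_params(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 2.33),
                 dox_induction_params(10, 5, 7, 1.2, 1),
                 steady_state_params(1, 105, 1, 2.33),
                 dose_response_params(0.1, 1, 105, 1))) {
    q <- params_from_json(params_to_json(p))
    expect_identical(unclass(q), unclass(p))
    expect_s3_class(q, class(p)[1L])
  }
  bad <- '{".class":"steady_state_params","G_max":1,"K_L":2,"K_A":3,"n_stoich":1,"extra":9}'
  expect_error(params_from_json(bad), "unknown parameter key")
  expect_error(params_from_json('{"G_max":1}'), ".class")
})

test_that("parameter constructors enforce positivity invariants", {
  expect_error(steady_state_params(0, 1, 1, 1), "> 0")
  expect_error(chacha_rate_params(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, -2), "> 0")
  expect_error(dose_response_params(2, 1, 10, 1), "top")
  expect_error(dose_response_params(-1, 1, 10, 1), "bottom")
  # bottom = 0 is a legal baseline
  expect_s3_class(dose_response_params(0, 1, 10, 1),
                  "dose_response_params")
})
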