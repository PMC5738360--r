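test_that("schedules are validated and evaluate as right-open steps", {
  s <- schedule(c(0, 24, 48), c(5, 0, 2))
  expect_equal(schedule_level(s, c(-1, 0, 23.9, 24, 47, 48, 1000)),
               c(5, 5, 5, 0, 0, 2, 2))
  expect_error(schedule(c(0, 0), c(1, 1)), "strictly increasing")
  expect_error(schedule(0, -1), ">= 0")
})

test_that("a coupled steady state is a fixed point of the simulation", {
  p <- rand_rate_params(3)
  L <- 2
  s <- solve_coupled_steady_state(p, L)
  init <- c(R = s$R_ss, Rstar = s$Rstar_ss, A = s$A_ss, C = s$C_ss,
            G = s$G_ss)
  tr <- simulate_chacha(p, schedule(0, L), c(0, 100), init = init)
  drift <- abs(sweep(tr$states, 2, init, "/") - 1)
  expect_lt(max(drift), 1e-6)
})

test_that("without ligand no effector is released and G stays dark", {
  p <- rand_rate_params(5)
  init <- c(R = 0.3, Rstar = 0, A = 0.8, C = 0, G = 0)
  tr <- simulate_chacha(p, schedule(0, 0), c(0, 50), init = init)
  expect_true(all(tr$states[, "C"] == 0))
  expect_true(all(tr$states[, "G"] == 0))
})

test_that("dox simulation reaches the closed-form steady state", {
  p <- dox_induction_params(kappa1 = 12, kappa2 = 3, K_D = 50, n_hill = 1)
  tr <- simulate_dox(p, schedule(0, 20), c(0, 600), beta1 = 0.1,
                     beta2 = 0.1)
  expect_equal(unname(tr$states[nrow(tr$states), "G"]),
               dox_steady_state_gfp(20, p), tolerance = 1e-4)
  # zero dox, zero init stays identically zero
  tr0 <- simulate_dox(p, schedule(0, 0), c(0, 100))
  expect_true(all(tr0$states == 0))
  # doubling kappa1 (production) doubles the terminal effector level
  p2 <- dox_induction_params(kappa1 = 24, kappa2 = 3, K_D = 50, n_hill = 1)
  tr2 <- simulate_dox(p2, schedule(0, 20), c(0, 600))
  expect_equal(tr2$states[nrow(tr2$states), "C"],
               2 * tr$states[nrow(tr$states), "C"], tolerance = 1e-6)
})

test_that("states stay nonnegative across random parameters and inputs", {
  scheds <- list(schedule(0, 1), schedule(c(0, 24), c(8, 0)),
                 schedule(c(0, 10, 20), c(0, 3, 0.3)))
  for (seed in seq(1, 50, by = 7)) {
    p <- rand_rate_params(seed)
    for (s in scheds) {
      tr <- simulate_chacha(p, s, c(0, 60), init = "zero", n_out = 61L)
      expect_true(all(tr$states >= 0))
    }
  }
})

test_that("halving solver tolerances leaves trajectories unchanged", {
  p <- rand_rate_params(9)
  s <- schedule(c(0, 24), c(5, 0))
  coarse <- simulate_chacha(p, s, c(0, 96), init = "zero",
                            rtol = 1e-6, atol = 1e-9)
  fine <- simulate_chacha(p, s, c(0, 96), init = "zero",
                          rtol = 5e-7, atol = 5e-10)
  diff <- abs(coarse$states - fine$states)
  expect_true(all(diff < 1e-6 * pmax(abs(fine$states), 1) + 1e-8))
})

test_that("a one-day ligand pulse peaks after removal, then resets", {
  p <- chacha_demo_params()
  tr <- simulate_chacha(p, schedule(c(0, 24), c(10, 0)), c(0, 240),
                        n_out = 961L)
  G <- tr$states[, "G"]
  peak <- which.max(G)
  expect_gt(tr$times[peak], 24)            # keeps rising past pulse end
  i168 <- which.min(abs(tr$times - 168))   # pulse end + 6 days
  expect_lt(G[i168], 0.1 * G[peak])        # decays back toward baseline
})

test_that("time_to_fraction interpolates first crossings", {
  # exact exponential rise 1 - exp(-t): half-rise at ln 2
  t <- seq(0, 12, by = 0.01)
  tr <- chacha:::new_trajectory(t, cbind(G = 1 - exp(-t)))
  t50 <- time_to_fraction(tr, "G", 0.5)
  expect_equal(t50, -log(1 - 0.5 * (1 - exp(-12))), tolerance = 1e-3)
  # constant trajectory never crosses a fraction below 1
  trc <- chacha:::new_trajectory(t, cbind(G = rep(2, length(t))))
  res <- time_to_fraction(trc, "G", 0.5)
  expect_true(is.na(res))
  expect_true(isTRUE(attr(res, "no_crossing")))
  expect_error(time_to_fraction(tr, "G", 1.5), "\\(0, 1\\)")
  # faster reporter production shortens the half-rise time
  p <- chacha_demo_params()
  fast <- params_from_json(params_to_json(p)); fast$gamma_G <- 0.2
  fast <- do.call(chacha_rate_params, unclass(fast))
  t_slow <- time_to_fraction(
    simulate_chacha(p, schedule(0, 5), c(0, 500), init = "zero"), "G", 0.5)
  t_fast <- time_to_fraction(
    simulate_chacha(fast, schedule(0, 5), c(0, 500), init = "zero"),
    "G", 0.5)
  expect_lt(t_fast, t_slow)
})

test_that("trajectories export to tidy long CSV and back", {
  p <- chacha_demo_params()
  tr <- simulate_chacha(p, schedule(0, 2), c(0, 10), n_out = 11L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  tab <- utils::read.csv(path)
  expect_identical(names(tab), c("time", "symbol", "value"))
  expect_equal(nrow(tab), 11L * 5L)
  expect_equal(tab$value[tab$symbol == "G"], unname(tr$states[, "G"]))
})
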