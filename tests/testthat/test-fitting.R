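test_that("pearson_r matches the direct formula and its edge cases", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(-1, -2, -3)), -1)
  # hand computation: centred products 3, sums of squares 2 and 42/9
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84))
  expect_error(pearson_r(c(1, 2), c(1, 2)), ">= 3")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("noiseless surface data are recovered exactly, any free set", {
  truth <- steady_state_params(G_max = 2, K_L = 40, K_A = 3,
                               n_stoich = 2.33)
  tab <- generate_grid_dataset(truth, noise = noise_model(cv_or_sd = 0,
                                                          seed = 1))
  fit <- fit_steady_state_model(tab, adaptor = "true")
  expect_equal(coef(fit), unlist(unclass(truth)), tolerance = 1e-6)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$standard_errors)))
  # partial free sets with the rest fixed at truth
  for (free in list(c("G_max", "n_stoich"), c("K_L", "K_A"), "n_stoich")) {
    fixed <- unclass(truth)[setdiff(names(unclass(truth)), free)]
    f <- fit_steady_state_model(tab, free = free, fixed = fixed,
                                adaptor = "true")
    expect_equal(coef(f), unlist(unclass(truth))[free], tolerance = 1e-6)
  }
})

test_that("record order does not change surface estimates", {
  truth <- demo_grid_truth()
  tab <- generate_grid_dataset(truth, noise = noise_model(cv_or_sd = 0.1,
                                                          seed = 4))
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(coef(fit_steady_state_model(tab)),
               coef(fit_steady_state_model(perm)))
})

test_that("single-adaptor designs with free n are refused, not mis-fit", {
  truth <- demo_grid_truth()
  tab <- generate_grid_dataset(truth, adaptor_levels = c(1, 1),
                               noise = noise_model(cv_or_sd = 0, seed = 1))
  expect_error(fit_steady_state_model(tab, adaptor = "true"),
               "non-identifiable")
  # fixing n makes the same design fittable
  f <- fit_steady_state_model(tab, free = c("G_max", "K_L"),
                              fixed = list(K_A = 1, n_stoich = 2.33),
                              adaptor = "true")
  expect_true(f$converged)
})

test_that("noiseless Hill curves are recovered exactly", {
  truth <- dose_response_params(bottom = 5, top = 100, EC50 = 50,
                                hill_slope = 1.3)
  tab <- generate_dose_response(truth, doses = 10^seq(-1, 4,
                                                      length.out = 10),
                                replicates = 1L,
                                noise = noise_model(cv_or_sd = 0, seed = 1))
  fit <- fit_hill_dose_response(tab)
  expect_equal(coef(fit), unlist(unclass(truth)), tolerance = 1e-6)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_error(
    fit_hill_dose_response(data.frame(ligand_dose = rep(3, 6),
                                      gfp = rnorm(6, 10))),
    ">= 4 distinct doses")
})

test_that("noiseless dox saturation data recover a unit Hill coefficient", {
  p <- dox_induction_params(kappa1 = 20, kappa2 = 5, K_D = 100, n_hill = 1)
  D <- 10^seq(-1, 4, length.out = 9)
  tab <- data.frame(dox_level = D, gfp = dox_steady_state_gfp(D, p))
  fit <- fit_dox_hill(tab)
  expect_equal(coef(fit)[["n_hill"]], 1, tolerance = 1e-6)
  expect_equal(coef(fit)[["G_max_dox"]], 100, tolerance = 1e-6)
  expect_equal(coef(fit)[["K_D"]], 100, tolerance = 1e-5)
  # rescaling dose and K_D together is invisible to the cooperativity
  tab2 <- data.frame(dox_level = 2 * D, gfp = tab$gfp)
  expect_equal(coef(fit_dox_hill(tab2))[["n_hill"]], 1, tolerance = 1e-6)
  expect_equal(coef(fit_dox_hill(tab2))[["K_D"]], 200, tolerance = 1e-5)
})

test_that("reported r equals pearson_r of observed vs fitted", {
  tab <- generate_grid_dataset(demo_grid_truth(),
                               noise = noise_model(cv_or_sd = 0.15,
                                                   seed = 8))
  fit <- fit_steady_state_model(tab)
  expect_identical(fit$r, pearson_r(fit$observed, fit$fitted_values))
})

test_that("optimizer loss trace is monotone non-increasing", {
  tab <- generate_dose_response(dose_response_params(0, 1, 105, 1),
                                noise = noise_model(cv_or_sd = 0.1,
                                                    seed = 3))
  fit <- fit_hill_dose_response(tab)
  expect_true(all(diff(fit$loss_trace) <= 1e-12))
  # and the winning start achieves the minimum recorded loss
  expect_equal(fit$deviance, min(fit$starts$loss, na.rm = TRUE))
})

test_that("stoichiometry estimates are nearly unbiased at design scale", {
  truth <- demo_grid_truth()
  ns <- vapply(1:12, function(s) {
    tab <- generate_grid_dataset(truth,
                                 noise = noise_model(cv_or_sd = 0.1,
                                                     seed = 100 + s))
    coef(fit_steady_state_model(tab))[["n_stoich"]]
  }, numeric(1))
  expect_lt(abs(stats::median(ns) / truth$n_stoich - 1), 0.05)
})

test_that("fit objects behave like standard modelling results", {
  tab <- generate_grid_dataset(demo_grid_truth(),
                               noise = noise_model(cv_or_sd = 0.1,
                                                   seed = 6))
  fit <- fit_steady_state_model(tab)
  expect_equal(fitted(fit) + residuals(fit), fit$observed)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, tab[1:4, ]), fitted(fit)[1:4])
  s <- summary(fit)
  expect_s3_class(s, "summary.chacha_fit")
  expect_output(print(fit), "n_stoich")
  expect_output(print(s), "r = ")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1L]], "measurement_table")
  expect_false(identical(sims[[1L]]$gfp, sims[[2L]]$gfp))
})
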