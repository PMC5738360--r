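# Random positive rate-constant draws used across property tests.
# Rates span two decades (0.1-10 per hour) and the stoichiometry exponent
# cycles through representative values including the non-integer regime.
rand_rate_params <- function(seed) {
  set.seed(seed)
  r <- 10^stats::runif(10, -1, 1)
  n_set <- c(0.5, 1, 2, 2.33, 3)
  chacha_rate_params(
    alpha_R = r[1], alpha_Rstar = r[2], alpha_A = r[3],
    beta_R = r[4], beta_Rstar = r[5], beta_A = r[6],
    beta_C = r[7], beta_G = r[8],
    gamma_C = r[9], gamma_G = r[10],
    n_stoich = n_set[(seed %% length(n_set)) + 1L])
}

# Time horizon long enough for every first-order mode to relax.
relax_horizon <- function(p) {
  betas <- c(p$beta_R, p$beta_Rstar, p$beta_A, p$beta_C + p$gamma_G,
             p$beta_G)
  40 / min(betas)
}

demo_grid_truth <- function() steady_state_params(G_max = 1, K_L = 105,
                                                  K_A = 1, n_stoich = 2.33)
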