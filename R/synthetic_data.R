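#' Measurement noise model for synthetic well-level readouts
#'
#' Two noise laws are offered. The default for fluorescence readouts is
#' multiplicative lognormal, parameterized by its coefficient of variation
#' and mean-one (so the expected readout equals the noiseless model
#' prediction): log-sd `s = sqrt(log(1 + cv^2))`, log-mean `-s^2/2`.
#' Additive Gaussian noise (sd in AU) is available for instruments with
#' scale-independent error.
#'
#' @param kind `"multiplicative-lognormal"` or `"additive-gaussian"`.
#' @param cv_or_sd Coefficient of variation (multiplicative) or standard
#'   deviation in AU (additive); >= 0.
#' @param seed Integer seed; identical seed and parameters give identical
#'   synthetic tables.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative-lognormal",
                                 "additive-gaussian"),
                        cv_or_sd = 0.10, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(cv_or_sd) || cv_or_sd < 0)
    stop("cv_or_sd must be >= 0", call. = FALSE)
  structure(list(kind = kind, cv_or_sd = cv_or_sd, seed = as.integer(seed)),
            class = "noise_model")
}

# Apply a noise model to a vector of expected values. Caller is responsible
# for RNG state management.
apply_noise <- function(mu, noise) {
  if (noise$cv_or_sd == 0) return(mu)
  n <- length(mu)
  if (noise$kind == "multiplicative-lognormal") {
    s <- sqrt(log1p(noise$cv_or_sd^2))
    mu * stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
  } else {
    pmax(mu + stats::rnorm(n, 0, noise$cv_or_sd), 0)
  }
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic adaptor-by-ligand grid dataset
#'
#' Emulates the titration experiment in which the dox-inducible adaptor
#' fusion is expressed at several levels (read out as an mCherry-proxy
#' fluorescence) and crossed with a range of ligand doses, with the
#' reporter GFP measured per well. The expected GFP of each record is the
#' closed-form surface [chacha_steady_state_gfp()]; noise is applied
#' independently per record. The `adaptor_readout` column carries the true
#' adaptor level passed through the same noise model, mimicking a measured
#' rather than known covariate.
#'
#' @param truth A [steady_state_params()] object (the generating surface).
#' @param adaptor_levels >= 2 adaptor expression levels (AU).
#' @param ligand_doses >= 2 ligand doses (nM).
#' @param replicates Technical replicates per grid point (>= 1).
#' @param noise A [noise_model()]; its seed fixes the whole table.
#' @return A `data.frame` (class `measurement_table`) with columns
#'   `adaptor_level`, `ligand_dose`, `replicate`, `gfp`, `adaptor_readout`.
#' @export
generate_grid_dataset <- function(truth,
                                  adaptor_levels = default_adaptor_levels(),
                                  ligand_doses = default_ligand_doses(),
                                  replicates = 3L,
                                  noise = noise_model()) {
  stopifnot(inherits(truth, "steady_state_params"),
            inherits(noise, "noise_model"))
  if (length(adaptor_levels) < 2L || length(ligand_doses) < 2L ||
      replicates < 1L)
    stop("need >= 2 adaptor levels, >= 2 doses and >= 1 replicate",
         call. = FALSE)
  design <- expand.grid(replicate = seq_len(replicates),
                        ligand_dose = ligand_doses,
                        adaptor_level = adaptor_levels,
                        KEEP.OUT.ATTRS = FALSE)
  mu <- chacha_steady_state_gfp(design$ligand_dose, design$adaptor_level,
                                truth)
  tab <- with_seed(noise$seed, {
    gfp <- apply_noise(mu, noise)
    readout <- apply_noise(design$adaptor_level, noise)
    data.frame(adaptor_level = design$adaptor_level,
               ligand_dose = design$ligand_dose,
               replicate = design$replicate,
               gfp = gfp,
               adaptor_readout = readout)
  })
  class(tab) <- c("measurement_table", "data.frame")
  tab
}

#' Default adaptor levels: 6 log-spaced levels spanning 0.1-10 AU
#' @return Numeric vector of length 6.
#' @export
default_adaptor_levels <- function() 10^seq(-1, 1, length.out = 6)

#' Default ligand doses: 8 log-spaced doses spanning 1-10,000 nM
#' @return Numeric vector of length 8.
#' @export
default_ligand_doses <- function() 10^seq(0, 4, length.out = 8)

#' Generate a synthetic single-variable dose-response series
#'
#' Emulates a one-day ligand titration of the reporter line: GFP
#' expectation follows the four-parameter Hill curve
#' `bottom + (top - bottom) * dose^h / (EC50^h + dose^h)`, with per-well
#' noise.
#'
#' @param truth A [dose_response_params()] object.
#' @param doses Ligand doses (nM), >= 2 distinct values.
#' @param replicates Technical replicates per dose.
#' @param noise A [noise_model()].
#' @return A `measurement_table` data frame with columns `ligand_dose`,
#'   `replicate`, `gfp`.
#' @export
generate_dose_response <- function(truth,
                                   doses = default_ligand_doses(),
                                   replicates = 3L,
                                   noise = noise_model()) {
  stopifnot(inherits(truth, "dose_response_params"),
            inherits(noise, "noise_model"))
  if (length(unique(doses)) < 2L || replicates < 1L)
    stop("need >= 2 distinct doses and >= 1 replicate", call. = FALSE)
  design <- expand.grid(replicate = seq_len(replicates),
                        ligand_dose = doses, KEEP.OUT.ATTRS = FALSE)
  mu <- hill4(design$ligand_dose, truth$bottom, truth$top, truth$EC50,
              truth$hill_slope)
  tab <- with_seed(noise$seed, {
    data.frame(ligand_dose = design$ligand_dose,
               replicate = design$replicate,
               gfp = apply_noise(mu, noise))
  })
  class(tab) <- c("measurement_table", "data.frame")
  tab
}

# 4-parameter logistic response; dose = 0 returns bottom for any slope.
hill4 <- function(dose, bottom, top, EC50, h) {
  dh <- dose^h
  bottom + (top - bottom) * dh / (EC50^h + dh)
}

#' Generate a synthetic qPCR plate
#'
#' Emulates a Ct table with a housekeeping gene: each target gene has a
#' true expression factor relative to the housekeeping gene, and detected
#' Ct values follow `gapdh_ct - log2(factor) + N(0, noise_sd)` (one cycle
#' per two-fold change). Genes whose factor falls below
#' `dropout_rel_threshold` emit explicit undetected markers (`NA` Ct),
#' never silently dropped rows.
#'
#' @param true_rel_expression Named list/vector: per-sample named numeric
#'   vectors of per-gene expression factors (> 0) relative to the
#'   housekeeping gene. A plain named numeric vector is treated as a single
#'   sample called `"S1"`.
#' @param gapdh_ct Housekeeping baseline Ct (cycles), in (10, 35).
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param dropout_rel_threshold Factors below this emit undetected wells.
#' @param replicates Technical replicates per sample x gene.
#' @param seed Integer seed.
#' @param housekeeping Housekeeping gene label.
#' @return A `data.frame` (class `qpcr_plate`) with columns `sample`,
#'   `gene`, `replicate`, `ct` (`NA` = undetected).
#' @export
generate_qpcr_plate <- function(true_rel_expression, gapdh_ct = 20,
                                noise_sd = 0, dropout_rel_threshold = 0,
                                replicates = 3L, seed = 1L,
                                housekeeping = "GAPDH") {
  if (is.numeric(true_rel_expression) && !is.list(true_rel_expression))
    true_rel_expression <- list(S1 = true_rel_expression)
  if (!is.numeric(gapdh_ct) || gapdh_ct <= 10 || gapdh_ct >= 35)
    stop("gapdh_ct must lie in (10, 35)", call. = FALSE)
  if (any(unlist(true_rel_expression) <= 0))
    stop("expression factors must be > 0", call. = FALSE)
  rows <- with_seed(seed, {
    out <- list()
    for (smp in names(true_rel_expression)) {
      factors <- true_rel_expression[[smp]]
      genes <- c(housekeeping, names(factors))
      mu_ct <- c(gapdh_ct, gapdh_ct - log2(factors))
      dropped <- c(FALSE, factors < dropout_rel_threshold)
      for (i in seq_along(genes)) {
        ct <- mu_ct[i] + stats::rnorm(replicates, 0, noise_sd)
        if (dropped[i]) ct <- rep(NA_real_, replicates)
        out[[length(out) + 1L]] <- data.frame(
          sample = smp, gene = genes[i], replicate = seq_len(replicates),
          ct = ct)
      }
    }
    do.call(rbind, out)
  })
  class(rows) <- c("qpcr_plate", "data.frame")
  rows
}
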