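#' Parameter set for doxycycline-inducible dCas9-VPR reporter induction
#'
#' Lumped parameters of the two-species induction model
#' dC/dt = alpha1 * D^n / (K_D + D^n) - beta1 * C,
#' dG/dt = alpha2 * C^m - beta2 * G,
#' where only the ratios kappa1 = alpha1/beta1 and kappa2 = alpha2/beta2
#' enter the steady state. Note that K_D multiplies no exponent of its own:
#' it carries the units of D^n_hill.
#'
#' @param kappa1 Production/degradation ratio alpha1/beta1 for dCas9 (AU).
#' @param kappa2 Production/degradation ratio alpha2/beta2 for GFP
#'   (AU per AU of dCas9 when `m = 1`).
#' @param K_D Dox affinity constant, in units of `D^n_hill`.
#' @param n_hill Hill cooperativity of dox induction (dimensionless).
#' @param m Lumped dCas9-to-GFP exponent capturing target binding,
#'   transcription and translation in series. Defaults to 1, the
#'   non-cooperative case.
#' @return An object of class `dox_induction_params`.
#' @examples
#' p <- dox_induction_params(kappa1 = 10, kappa2 = 5, K_D = 2)
#' dox_steady_state_gfp(2, p)  # half-saturation when D^n_hill == K_D
#' @export
dox_induction_params <- function(kappa1, kappa2, K_D, n_hill = 1, m = 1) {
  p <- list(kappa1 = kappa1, kappa2 = kappa2, K_D = K_D,
            n_hill = n_hill, m = m)
  validate_positive(p, names(p), "dox_induction_params")
  structure(p, class = c("dox_induction_params", "chacha_params"))
}

#' Mass-action rate constants of the CRISPR ChaCha system
#'
#' The eleven constants of the four-process rate model: ligand binding
#' converts inactive receptor R to active R*, active receptor cleaves the
#' adaptor fusion A (beta-arrestin-2 fused to dCas9-VPR via a TEV cleavage
#' site) to release free effector C, and C drives reporter G.
#'
#' @param alpha_R Inactive-receptor production rate (conc/time).
#' @param alpha_Rstar Ligand-activation rate constant (1/(conc * time)).
#' @param alpha_A Adaptor-fusion production rate (conc/time).
#' @param beta_R,beta_Rstar,beta_A,beta_C,beta_G First-order degradation
#'   constants (1/time) for inactive receptor, active receptor, adaptor
#'   fusion, released effector and reporter.
#' @param gamma_C Cleavage rate constant (1/(conc^n_stoich * time)).
#' @param gamma_G Effector-driven reporter production constant (1/time).
#' @param n_stoich Adaptor molecules processed per active receptor
#'   (dimensionless exponent; may be non-integer).
#' @return An object of class `chacha_rate_params`.
#' @seealso [derive_steady_state_params()], [simulate_chacha()]
#' @export
chacha_rate_params <- function(alpha_R, alpha_Rstar, alpha_A,
                               beta_R, beta_Rstar, beta_A, beta_C, beta_G,
                               gamma_C, gamma_G, n_stoich) {
  p <- list(alpha_R = alpha_R, alpha_Rstar = alpha_Rstar, alpha_A = alpha_A,
            beta_R = beta_R, beta_Rstar = beta_Rstar, beta_A = beta_A,
            beta_C = beta_C, beta_G = beta_G,
            gamma_C = gamma_C, gamma_G = gamma_G, n_stoich = n_stoich)
  validate_positive(p, names(p), "chacha_rate_params")
  structure(p, class = c("chacha_rate_params", "chacha_params"))
}

#' Lumped steady-state surface parameters
#'
#' Parameters of the closed-form GFP surface
#' G = G_max * L/(L + K_L) * A^n/(K_A + A^n),
#' obtained by eliminating the fast species from the full rate model:
#' G_max = (gamma_G/beta_G) * alpha_R/(gamma_G + beta_C),
#' K_L = beta_R/alpha_Rstar, K_A = beta_Rstar/gamma_C.
#'
#' @param G_max Theoretical maximum reporter level at saturating ligand and
#'   adaptor (AU).
#' @param K_L Ligand set-point producing half-maximal response (conc).
#' @param K_A Adaptor half-maximal constant, in units of `A^n_stoich`.
#' @param n_stoich Stoichiometry exponent: effector molecules released per
#'   active receptor.
#' @return An object of class `steady_state_params`.
#' @export
steady_state_params <- function(G_max, K_L, K_A, n_stoich) {
  p <- list(G_max = G_max, K_L = K_L, K_A = K_A, n_stoich = n_stoich)
  validate_positive(p, names(p), "steady_state_params")
  structure(p, class = c("steady_state_params", "chacha_params"))
}

#' Four-parameter logistic (Hill) dose-response parameters
#'
#' @param bottom Baseline response at zero dose (AU, >= 0).
#' @param top Plateau response at saturating dose (AU, > bottom).
#' @param EC50 Half-maximal dose (same units as the dose axis).
#' @param hill_slope Hill coefficient (dimensionless, > 0).
#' @return An object of class `dose_response_params`.
#' @export
dose_response_params <- function(bottom, top, EC50, hill_slope = 1) {
  if (!is.numeric(bottom) || length(bottom) != 1L || !is.finite(bottom) ||
      bottom < 0)
    stop("dose_response_params: 'bottom' must be a finite number >= 0",
         call. = FALSE)
  if (!is.numeric(top) || length(top) != 1L || !is.finite(top) ||
      top <= bottom)
    stop("dose_response_params: 'top' must be finite and > bottom",
         call. = FALSE)
  validate_positive(list(EC50 = EC50, hill_slope = hill_slope),
                    c("EC50", "hill_slope"), "dose_response_params")
  structure(list(bottom = bottom, top = top, EC50 = EC50,
                 hill_slope = hill_slope),
            class = c("dose_response_params", "chacha_params"))
}

validate_positive <- function(p, fields, ctor) {
  for (f in fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("%s: '%s' must be a single finite number > 0", ctor, f),
           call. = FALSE)
  }
  invisible(p)
}

#' @export
print.chacha_params <- function(x, ...) {
  cat("<", class(x)[1L], ">\n", sep = "")
  vals <- unlist(x)
  print(format(vals, digits = 6), quote = FALSE)
  invisible(x)
}

#' Serialize a parameter set to flat JSON
#'
#' Writes a flat JSON object whose keys exactly match the parameter field
#' names, so parameter files round-trip losslessly.
#'
#' @param p A parameter object created by one of the `*_params()`
#'   constructors.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return The JSON string (invisibly when written to file).
#' @export
params_to_json <- function(p, path = NULL) {
  stopifnot(inherits(p, "chacha_params"))
  doc <- c(list(.class = class(p)[1L]), unclass(p))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Deserialize a parameter set from flat JSON
#'
#' Unknown keys are rejected rather than ignored, so a typo in a parameter
#' file fails loudly.
#'
#' @param json A JSON string or path to a JSON file written by
#'   [params_to_json()], or a flat JSON object with a `.class` key naming
#'   one of the parameter classes.
#' @return The reconstructed parameter object.
#' @export
params_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  cls <- doc[[".class"]]
  if (is.null(cls))
    stop("parameter JSON must carry a '.class' key", call. = FALSE)
  doc[[".class"]] <- NULL
  ctor <- switch(cls,
    dox_induction_params = dox_induction_params,
    chacha_rate_params   = chacha_rate_params,
    steady_state_params  = steady_state_params,
    dose_response_params = dose_response_params,
    stop(sprintf("unknown parameter class '%s'", cls), call. = FALSE))
  doc <- lapply(doc, function(v) if (is.numeric(v)) as.numeric(v) else v)
  known <- names(formals(ctor))
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop(sprintf("unknown parameter key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  do.call(ctor, doc)
}

#' Demonstration rate-constant set for pulse experiments
#'
#' A documented parameter set with receptor and adaptor turnover on the
#' scale of 1/h but slow effector and reporter turnover, so that reporter
#' fluorescence keeps rising after a one-day ligand pulse ends and then
#' relaxes back over several days -- the qualitative reversibility
#' behaviour of the system. Units: hours and AU.
#'
#' @return A `chacha_rate_params` object.
#' @export
chacha_demo_params <- function() {
  chacha_rate_params(
    alpha_R = 1, alpha_Rstar = 1, alpha_A = 1,
    beta_R = 1, beta_Rstar = 1, beta_A = 1,
    beta_C = 0.04, beta_G = 0.05,
    gamma_C = 1, gamma_G = 0.02,
    n_stoich = 1)
}
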