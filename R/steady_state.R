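#' Steady-state reporter level under dox induction
#'
#' Closed-form steady state of the dox-induction model. For `m = 1` this is
#' `kappa1 * kappa2 * D^n_hill / (K_D + D^n_hill)`; for general `m` the
#' effector steady state `C_ss = kappa1 * D^n_hill/(K_D + D^n_hill)` is
#' raised to `m` before scaling by `kappa2`.
#'
#' @param D Dox concentration(s), >= 0. Vectorized.
#' @param p A [dox_induction_params()] object.
#' @return Steady-state reporter level(s) (AU).
#' @export
dox_steady_state_gfp <- function(D, p) {
  stopifnot(inherits(p, "dox_induction_params"))
  if (any(!is.finite(D)) || any(D < 0))
    stop("dox concentration D must be finite and >= 0", call. = FALSE)
  Dn <- D^p$n_hill
  C_ss <- p$kappa1 * Dn / (p$K_D + Dn)
  p$kappa2 * C_ss^p$m
}

#' Steady-state reporter level of the ChaCha surface
#'
#' Evaluates G = G_max * L/(L + K_L) * A^n/(K_A + A^n): a hyperbolic
#' saturation in ligand multiplied by a Hill-type saturation in adaptor
#' level, with the stoichiometry exponent n setting the steepness of the
#' adaptor arm. Monotone nondecreasing in both arguments.
#'
#' @param L Ligand concentration(s), >= 0. Vectorized with `A_ss`.
#' @param A_ss Steady-state adaptor-fusion level(s), >= 0.
#' @param p A [steady_state_params()] object.
#' @return Reporter level(s) (AU).
#' @export
chacha_steady_state_gfp <- function(L, A_ss, p) {
  stopifnot(inherits(p, "steady_state_params"))
  if (any(!is.finite(L)) || any(L < 0))
    stop("ligand concentration L must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(A_ss)) || any(A_ss < 0))
    stop("adaptor level A_ss must be finite and >= 0", call. = FALSE)
  An <- A_ss^p$n_stoich
  p$G_max * (L / (L + p$K_L)) * (An / (p$K_A + An))
}

#' Lump rate constants into steady-state surface parameters
#'
#' Applies the steady-state elimination of the full rate model:
#' `G_max = (gamma_G/beta_G) * alpha_R/(gamma_G + beta_C)`,
#' `K_L = beta_R/alpha_Rstar`, `K_A = beta_Rstar/gamma_C`;
#' `n_stoich` carries over unchanged.
#'
#' @param p A [chacha_rate_params()] object.
#' @return A [steady_state_params()] object.
#' @export
derive_steady_state_params <- function(p) {
  stopifnot(inherits(p, "chacha_rate_params"))
  steady_state_params(
    G_max = (p$gamma_G / p$beta_G) * p$alpha_R / (p$gamma_G + p$beta_C),
    K_L = p$beta_R / p$alpha_Rstar,
    K_A = p$beta_Rstar / p$gamma_C,
    n_stoich = p$n_stoich)
}

#' Solve the coupled steady state of the full rate model
#'
#' At steady state the five species satisfy
#' R = alpha_R/(alpha_Rstar*L + beta_R),
#' R* = alpha_Rstar*R*L/(beta_Rstar + gamma_C*A^n),
#' 0 = alpha_A - beta_A*A - gamma_C*R**A^n,
#' C = gamma_C*R**A^n/(gamma_G + beta_C), G = (gamma_G/beta_G)*C.
#' The adaptor balance is implicit because A appears inside the active
#' receptor denominator; substituting R and R* reduces it to one scalar
#' equation in A, which is bracketed on (0, alpha_A/beta_A] -- cleavage can
#' only pull A below its no-ligand level -- and solved with
#' [stats::uniroot()].
#'
#' @param p A [chacha_rate_params()] object.
#' @param L Ligand concentration, a single value >= 0.
#' @param tol Relative residual tolerance demanded of the solution.
#' @return A named list with elements `R_ss`, `Rstar_ss`, `A_ss`, `C_ss`,
#'   `G_ss`, plus `residuals` (the five steady-state residuals, scaled by
#'   the production terms).
#' @export
solve_coupled_steady_state <- function(p, L, tol = 1e-10) {
  stopifnot(inherits(p, "chacha_rate_params"))
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L < 0)
    stop("ligand concentration L must be a single finite value >= 0",
         call. = FALSE)
  A0 <- p$alpha_A / p$beta_A
  R_ss <- p$alpha_R / (p$alpha_Rstar * L + p$beta_R)
  if (L == 0) {
    out <- list(R_ss = p$alpha_R / p$beta_R, Rstar_ss = 0,
                A_ss = A0, C_ss = 0, G_ss = 0)
    out$residuals <- steady_residuals(p, L, out)
    return(out)
  }
  rstar_of_A <- function(A)
    p$alpha_Rstar * R_ss * L / (p$beta_Rstar + p$gamma_C * A^p$n_stoich)
  # adaptor balance: f(A) = alpha_A - beta_A*A - gamma_C*R*(A)*A^n
  f <- function(A)
    p$alpha_A - p$beta_A * A - p$gamma_C * rstar_of_A(A) * A^p$n_stoich
  # f(A0) <= 0 (cleavage removes adaptor), f(0+) = alpha_A > 0
  lower <- A0 * 1e-12
  if (f(lower) <= 0 || f(A0) > 1e-12 * p$alpha_A) {
    stop("steady-state bracketing failed; residuals at bracket ends: ",
         paste(signif(c(f(lower), f(A0)), 4), collapse = ", "),
         call. = FALSE)
  }
  root <- stats::uniroot(f, c(lower, A0), tol = .Machine$double.eps^0.75,
                         maxiter = 2000L)
  A_ss <- root$root
  # polish with a few damped Newton-free fixed-point refinements via uniroot
  Rstar_ss <- rstar_of_A(A_ss)
  C_ss <- p$gamma_C * Rstar_ss * A_ss^p$n_stoich / (p$gamma_G + p$beta_C)
  G_ss <- (p$gamma_G / p$beta_G) * C_ss
  out <- list(R_ss = R_ss, Rstar_ss = Rstar_ss, A_ss = A_ss,
              C_ss = C_ss, G_ss = G_ss)
  out$residuals <- steady_residuals(p, L, out)
  if (max(abs(out$residuals)) > tol) {
    stop("coupled steady-state solve did not reach tolerance ", tol,
         "; scaled residuals: ",
         paste(signif(out$residuals, 4), collapse = ", "), call. = FALSE)
  }
  out
}

# Residuals of the five rate equations at a candidate steady state, each
# scaled by the magnitude of its largest flux term so the tolerance is
# relative.
steady_residuals <- function(p, L, s) {
  An <- s$A_ss^p$n_stoich
  cleave <- p$gamma_C * s$Rstar_ss * An
  r <- c(
    R = p$alpha_R - p$alpha_Rstar * s$R_ss * L - p$beta_R * s$R_ss,
    Rstar = p$alpha_Rstar * s$R_ss * L - p$beta_Rstar * s$Rstar_ss - cleave,
    A = p$alpha_A - p$beta_A * s$A_ss - cleave,
    C = cleave - p$gamma_G * s$C_ss - p$beta_C * s$C_ss,
    G = p$gamma_G * s$C_ss - p$beta_G * s$G_ss)
  scale <- c(
    R = max(p$alpha_R, p$beta_R * s$R_ss),
    Rstar = max(p$alpha_Rstar * s$R_ss * L, p$beta_Rstar * s$Rstar_ss,
                cleave, .Machine$double.xmin),
    A = max(p$alpha_A, p$beta_A * s$A_ss),
    C = max(cleave, (p$gamma_G + p$beta_C) * s$C_ss, .Machine$double.xmin),
    G = max(p$gamma_G * s$C_ss, p$beta_G * s$G_ss, .Machine$double.xmin))
  r / scale
}
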