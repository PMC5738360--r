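#' Pearson correlation between observed and fitted responses
#'
#' The goodness-of-fit statistic reported alongside every fit: the Pearson
#' correlation of fitted versus observed response values.
#'
#' @param observed,fitted Numeric vectors of equal length >= 3 with
#'   nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 3L)
    stop("need >= 3 observed/fitted pairs", call. = FALSE)
  if (stats::sd(observed) == 0 || stats::sd(fitted) == 0)
    stop("zero variance in observed or fitted values", call. = FALSE)
  stats::cor(observed, fitted)
}

# ---- shared bounded multi-start Levenberg-Marquardt driver -----------------
#
# All fits run in log-parameter space (positivity is structural), on linear
# response values with unweighted least squares. Starts form a log-grid
# around moment-based guesses; the best final loss wins. Standard errors
# come from the Gauss-Newton curvature at the optimum, mapped back to the
# natural scale by the delta method.

ls_multistart <- function(observed, mu_fn, starts, lower, upper,
                          maxiter = 200L) {
  p <- ncol(starts)
  best <- NULL
  start_log <- data.frame(matrix(NA_real_, nrow(starts), p))
  names(start_log) <- colnames(starts)
  start_log$loss <- NA_real_
  resid_fn <- function(theta) observed - mu_fn(exp(theta))
  for (k in seq_len(nrow(starts))) {
    th0 <- pmin(pmax(log(as.numeric(starts[k, ])), lower), upper)
    names(th0) <- colnames(starts)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    start_log[k, seq_len(p)] <- exp(th0)
    if (is.null(fit)) next
    start_log$loss[k] <- fit$deviance
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("nonlinear least squares failed to converge from every start",
         call. = FALSE)
  theta <- best$par
  est <- exp(theta)
  names(est) <- colnames(starts)
  # numerical Jacobian of residuals wrt log-parameters at the optimum
  J <- matrix(0, length(observed), p)
  h <- 1e-6
  for (j in seq_len(p)) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    J[, j] <- (resid_fn(tp) - resid_fn(tm)) / (2 * h)
  }
  dof <- length(observed) - p
  sigma2 <- if (dof > 0) best$deviance / dof else NA_real_
  se <- rep(NA_real_, p)
  vcov_log <- tryCatch(sigma2 * solve(crossprod(J)),
                       error = function(e) NULL)
  if (!is.null(vcov_log)) {
    d <- diag(vcov_log)
    se <- ifelse(d >= 0, sqrt(d) * est, NA_real_)  # delta method
  }
  names(se) <- colnames(starts)
  list(estimates = est, standard_errors = se,
       deviance = best$deviance, loss_trace = best$rsstrace,
       converged = best$info %in% 1:4, n_iter = best$niter,
       starts = start_log)
}

new_chacha_fit <- function(kind, ls, observed, fitted_vals, data, mu_fn,
                           fixed = list()) {
  structure(list(
    kind = kind,
    estimates = ls$estimates,
    standard_errors = ls$standard_errors,
    fixed = fixed,
    r = pearson_r(observed, fitted_vals),
    observed = observed,
    fitted_values = fitted_vals,
    residuals = observed - fitted_vals,
    deviance = ls$deviance,
    converged = ls$converged,
    n_iter = ls$n_iter,
    starts = ls$starts,
    loss_trace = ls$loss_trace,
    data = data,
    mu_fn = mu_fn),
    class = c(paste0("chacha_fit_", kind), "chacha_fit"))
}

# log-grid of starts: each free parameter takes guess * 10^(-2, 0, 2),
# clipped just inside its bounds.
start_grid <- function(guesses, lower, upper) {
  cols <- lapply(seq_along(guesses), function(j) {
    v <- guesses[j] * 10^c(-2, 0, 2)
    pmin(pmax(v, exp(lower[j]) * 1.0001), exp(upper[j]) * 0.9999)
  })
  g <- expand.grid(cols, KEEP.OUT.ATTRS = FALSE)
  names(g) <- names(guesses)
  g
}

#' Fit the steady-state GFP surface to a grid dataset
#'
#' Unweighted nonlinear least squares of the closed-form surface
#' `G = G_max * L/(L + K_L) * A^n/(K_A + A^n)` against well-level GFP
#' measurements over an adaptor-level-by-ligand-dose design. The
#' stoichiometry exponent `n_stoich` -- effector molecules released per
#' active receptor -- is the quantity of main scientific interest.
#' Optimization is bounded Levenberg-Marquardt in log-parameter space with
#' a deterministic multi-start log-grid (best final loss wins), so fits are
#' reproducible without a seed.
#'
#' @param data A `measurement_table` with columns `ligand_dose`, `gfp` and
#'   an adaptor covariate (see `adaptor`).
#' @param free Character subset of `c("G_max","K_L","K_A","n_stoich")` to
#'   estimate; the rest must be supplied in `fixed`.
#' @param fixed Named list of values for parameters not in `free`.
#' @param adaptor Which covariate carries the adaptor level:
#'   `"readout"` uses the measured `adaptor_readout` (the realistic choice,
#'   mirroring mCherry fluorescence); `"true"` uses the design column
#'   `adaptor_level` (for oracle checks).
#' @param basal If `TRUE`, adds an additive baseline parameter `G0` for
#'   leaky real data. Off by default so the fitted form is exactly the
#'   closed-form surface.
#' @param maxiter Maximum optimizer iterations per start.
#' @return A `chacha_fit` object; see [coef.chacha_fit()],
#'   [summary.chacha_fit()], [predict.chacha_fit()].
#' @examples
#' truth <- steady_state_params(G_max = 1, K_L = 105, K_A = 1,
#'                              n_stoich = 2.33)
#' tab <- generate_grid_dataset(truth, noise = noise_model(cv_or_sd = 0,
#'                                                         seed = 1))
#' fit <- fit_steady_state_model(tab, adaptor = "true")
#' coef(fit)["n_stoich"]
#' @export
fit_steady_state_model <- function(data,
                                   free = c("G_max", "K_L", "K_A",
                                            "n_stoich"),
                                   fixed = list(),
                                   adaptor = c("readout", "true"),
                                   basal = FALSE, maxiter = 200L) {
  adaptor <- match.arg(adaptor)
  free <- match.arg(free, several.ok = TRUE)
  need <- c("ligand_dose", "gfp")
  if (!all(need %in% names(data)))
    stop("data must have columns ligand_dose and gfp", call. = FALSE)
  acol <- if (adaptor == "readout" && "adaptor_readout" %in% names(data))
    "adaptor_readout" else "adaptor_level"
  if (!acol %in% names(data))
    stop("data lacks an adaptor covariate column (", acol, ")",
         call. = FALSE)
  A <- data[[acol]]; L <- data$ligand_dose; y <- data$gfp
  if ("n_stoich" %in% free &&
      (length(unique(data$adaptor_level %||% A)) < 2L ||
       length(unique(L)) < 2L))
    stop("non-identifiable design: freeing n_stoich requires >= 2 distinct ",
         "adaptor levels and >= 2 distinct ligand doses", call. = FALSE)
  all_par <- c("G_max", "K_L", "K_A", "n_stoich")
  miss <- setdiff(setdiff(all_par, free), names(fixed))
  if (length(miss))
    stop("parameters neither free nor fixed: ",
         paste(miss, collapse = ", "), call. = FALSE)

  guesses <- c(G_max = max(y), K_L = stats::median(L[L > 0]),
               K_A = stats::median(A[A > 0]), n_stoich = 1)
  if (basal) guesses <- c(guesses, G0 = max(min(y), 1e-4 * max(y)))
  free_all <- c(free, if (basal) "G0")
  guesses <- guesses[free_all]
  lower <- rep(-Inf, length(free_all)); upper <- rep(Inf, length(free_all))
  names(lower) <- names(upper) <- free_all
  lower["n_stoich"[("n_stoich" %in% free_all)]] <- log(0.1)
  upper["n_stoich"[("n_stoich" %in% free_all)]] <- log(10)
  lower[!is.finite(lower)] <- log(guesses[!is.finite(lower)]) - 23
  upper[!is.finite(upper)] <- log(guesses[!is.finite(upper)]) + 23

  mu_fn <- function(par) {
    th <- c(as.list(par), fixed)
    g <- steady_state_params(th$G_max, th$K_L, th$K_A, th$n_stoich)
    base <- if (basal) th$G0 else 0
    base + chacha_steady_state_gfp(L, A, g)
  }
  ls <- ls_multistart(y, mu_fn, start_grid(guesses, lower, upper),
                      lower, upper, maxiter)
  pred_fn <- function(est, newdata) {
    th <- c(as.list(est), fixed)
    g <- steady_state_params(th$G_max, th$K_L, th$K_A, th$n_stoich)
    base <- if (basal) th$G0 else 0
    acl <- if (acol %in% names(newdata)) acol else "adaptor_level"
    base + chacha_steady_state_gfp(newdata$ligand_dose, newdata[[acl]], g)
  }
  new_chacha_fit("surface", ls, y, mu_fn(ls$estimates), data, pred_fn,
                 fixed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a four-parameter Hill dose-response curve
#'
#' Fits `response = bottom + (top - bottom) * dose^h / (EC50^h + dose^h)`
#' to a ligand titration by bounded multi-start Levenberg-Marquardt in
#' log-parameter space, reporting the half-maximal dose EC50 with its
#' standard error from the regression curvature.
#'
#' @param data Data frame with columns `ligand_dose` (or `dose`) and `gfp`
#'   (or `response`); >= 4 distinct doses spanning the transition.
#' @param maxiter Maximum optimizer iterations per start.
#' @return A `chacha_fit` object whose estimates are
#'   `bottom`, `top`, `EC50`, `hill_slope`.
#' @export
fit_hill_dose_response <- function(data, maxiter = 200L) {
  dose <- data$ligand_dose %||% data$dose
  y <- data$gfp %||% data$response
  if (is.null(dose) || is.null(y))
    stop("data must have dose and response columns", call. = FALSE)
  if (length(unique(dose)) < 4L)
    stop("need >= 4 distinct doses to fit a 4-parameter Hill curve",
         call. = FALSE)
  agg <- tapply(y, dose, mean)
  dlev <- as.numeric(names(agg))
  half <- (min(agg) + max(agg)) / 2
  ec50_guess <- dlev[which.min(abs(agg - half))]
  if (ec50_guess <= 0) ec50_guess <- stats::median(dlev[dlev > 0])
  guesses <- c(bottom = max(min(y), 1e-4 * max(y)), top = max(y),
               EC50 = ec50_guess, hill_slope = 1)
  lower <- c(log(guesses["bottom"]) - 23, log(guesses["top"]) - 23,
             log(ec50_guess) - 23, log(0.1))
  upper <- c(log(guesses["bottom"]) + 23, log(guesses["top"]) + 23,
             log(ec50_guess) + 23, log(10))
  mu_fn <- function(par)
    hill4(dose, par[["bottom"]], par[["top"]], par[["EC50"]],
          par[["hill_slope"]])
  ls <- ls_multistart(y, mu_fn, start_grid(guesses, lower, upper),
                      lower, upper, maxiter)
  pred_fn <- function(est, newdata) {
    d <- newdata$ligand_dose %||% newdata$dose
    hill4(d, est[["bottom"]], est[["top"]], est[["EC50"]],
          est[["hill_slope"]])
  }
  new_chacha_fit("hill", ls, y, mu_fn(ls$estimates), data, pred_fn)
}

#' Fit the dox-induction saturation model with free Hill coefficient
#'
#' Fits `G = G_max_dox * D^n_hill / (K_D + D^n_hill)` to a dox titration,
#' with the cooperativity `n_hill` free, to check whether reporter
#' induction is cooperative (`n_hill > 1`) or not. `K_D` is treated
#' exactly as it enters the rate model: it carries the units of
#' `D^n_hill`, so doubling all dox levels together with `K_D` (at
#' `n_hill = 1`) leaves the fitted cooperativity unchanged.
#'
#' @param data Data frame with columns `dox_level` (or `ligand_dose` /
#'   `dose`) and `gfp` (or `response`); >= 4 distinct levels.
#' @param maxiter Maximum optimizer iterations per start.
#' @return A `chacha_fit` object with estimates `G_max_dox`, `K_D`,
#'   `n_hill`.
#' @export
fit_dox_hill <- function(data, maxiter = 200L) {
  D <- data$dox_level %||% data$ligand_dose %||% data$dose
  y <- data$gfp %||% data$response
  if (is.null(D) || is.null(y))
    stop("data must have dox and response columns", call. = FALSE)
  if (length(unique(D)) < 4L)
    stop("need >= 4 distinct dox levels", call. = FALSE)
  agg <- tapply(y, D, mean)
  dlev <- as.numeric(names(agg))
  half <- (min(agg) + max(agg)) / 2
  d_half <- dlev[which.min(abs(agg - half))]
  if (d_half <= 0) d_half <- stats::median(dlev[dlev > 0])
  guesses <- c(G_max_dox = max(y), K_D = d_half, n_hill = 1)
  lower <- c(log(guesses["G_max_dox"]) - 23, log(d_half) - 23, log(0.1))
  upper <- c(log(guesses["G_max_dox"]) + 23, log(d_half) + 23, log(10))
  mu_fn <- function(par) {
    Dn <- D^par[["n_hill"]]
    par[["G_max_dox"]] * Dn / (par[["K_D"]] + Dn)
  }
  ls <- ls_multistart(y, mu_fn, start_grid(guesses, lower, upper),
                      lower, upper, maxiter)
  pred_fn <- function(est, newdata) {
    d <- newdata$dox_level %||% newdata$ligand_dose %||% newdata$dose
    dn <- d^est[["n_hill"]]
    est[["G_max_dox"]] * dn / (est[["K_D"]] + dn)
  }
  new_chacha_fit("dox", ls, y, mu_fn(ls$estimates), data, pred_fn)
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.chacha_fit <- function(x, ...) {
  label <- switch(x$kind, surface = "steady-state GFP surface",
                  hill = "4-parameter Hill dose-response",
                  dox = "dox-induction saturation", x$kind)
  cat("ChaCha nonlinear least-squares fit:", label, "\n")
  est <- format(signif(x$estimates, 4))
  se <- format(signif(x$standard_errors, 3))
  cat(paste0("  ", names(x$estimates), " = ", est, " (se ", se, ")",
             collapse = "\n"), "\n")
  cat(sprintf("  r = %.4f over %d records; %s in %d iterations\n",
              x$r, length(x$observed),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @export
coef.chacha_fit <- function(object, ...) object$estimates

#' @export
fitted.chacha_fit <- function(object, ...) object$fitted_values

#' @export
residuals.chacha_fit <- function(object, ...) object$residuals

#' @export
deviance.chacha_fit <- function(object, ...) object$deviance

#' Predict responses from a fitted ChaCha model
#' @param object A `chacha_fit`.
#' @param newdata Data frame with the covariate columns the fit used;
#'   defaults to the training data.
#' @param ... Unused.
#' @return Predicted response values (AU).
#' @export
predict.chacha_fit <- function(object, newdata = object$data, ...) {
  object$mu_fn(object$estimates, newdata)
}

#' @export
summary.chacha_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$estimates,
                    std_error = object$standard_errors)
  structure(list(kind = object$kind, coefficients = tab, r = object$r,
                 deviance = object$deviance, n = length(object$observed),
                 converged = object$converged, n_iter = object$n_iter,
                 n_starts = nrow(object$starts),
                 residual_sd = stats::sd(object$residuals)),
            class = "summary.chacha_fit")
}

#' @export
print.summary.chacha_fit <- function(x, ...) {
  cat("Fit kind:", x$kind, "  records:", x$n, "\n")
  print(signif(x$coefficients, 5))
  cat(sprintf("r = %.5f   RSS = %.5g   residual sd = %.4g\n",
              x$r, x$deviance, x$residual_sd))
  cat(sprintf("%d starts; best %s after %d iterations\n", x$n_starts,
              if (x$converged) "converged" else "did not converge",
              x$n_iter))
  invisible(x)
}

#' @export
plot.chacha_fit <- function(x, ...) {
  if (x$kind %in% c("hill", "dox")) {
    d <- x$data$ligand_dose %||% x$data$dox_level %||% x$data$dose
    graphics::plot(d, x$observed, log = "x",
                   xlab = "dose", ylab = "response (AU)", ...)
    dd <- 10^seq(log10(min(d[d > 0])), log10(max(d)), length.out = 200)
    nd <- data.frame(ligand_dose = dd, dox_level = dd, dose = dd)
    graphics::lines(dd, x$mu_fn(x$estimates, nd), col = 2)
  } else {
    graphics::plot(x$fitted_values, x$observed,
                   xlab = "fitted (AU)", ylab = "observed (AU)", ...)
    graphics::abline(0, 1, col = 2)
  }
  invisible(x)
}

#' Simulate replicate synthetic datasets from a fitted model
#'
#' Draws new synthetic measurement tables at the fit's own design points,
#' using the fitted parameters as truth and a multiplicative lognormal
#' noise model whose coefficient of variation is estimated from the fit's
#' residuals.
#'
#' @param object A `chacha_fit` of kind `"surface"` or `"hill"`.
#' @param nsim Number of tables to draw.
#' @param seed Integer seed for the first table; table k uses `seed + k - 1`.
#' @param ... Unused.
#' @return A list of `measurement_table` data frames.
#' @export
simulate.chacha_fit <- function(object, nsim = 1, seed = 1L, ...) {
  ratio <- object$observed / pmax(object$fitted_values,
                                  .Machine$double.eps)
  cv <- stats::sd(ratio - 1)
  lapply(seq_len(nsim), function(k) {
    nm <- noise_model("multiplicative-lognormal", cv, seed + k - 1L)
    if (object$kind == "hill") {
      generate_dose_response(
        dose_response_params(max(object$estimates[["bottom"]], 1e-12),
                             object$estimates[["top"]],
                             object$estimates[["EC50"]],
                             object$estimates[["hill_slope"]]),
        doses = unique(object$data$ligand_dose %||% object$data$dose),
        replicates = 1L, noise = nm)
    } else if (object$kind == "surface") {
      est <- c(as.list(object$estimates), object$fixed)
      generate_grid_dataset(
        steady_state_params(est$G_max, est$K_L, est$K_A, est$n_stoich),
        adaptor_levels = sort(unique(object$data$adaptor_level)),
        ligand_doses = sort(unique(object$data$ligand_dose)),
        replicates = 1L, noise = nm)
    } else {
      stop("simulate() supports surface and hill fits", call. = FALSE)
    }
  })
}
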