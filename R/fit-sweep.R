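#' Fit the descriptive model to an amplitude sweep
#'
#' Least-squares fit of the descriptive strain-sweep model (see
#' [rheo_params()]) to measured storage and loss moduli.  Because the moduli
#' and strains span decades, the objective is the summed squared residual of
#' `log10(G')` and `log10(G'')` jointly over all points; fitting in linear
#' space would be dominated by the LVE plateau.  Parameters are
#' log-transformed internally so positivity is structural, and the
#' Levenberg-Marquardt minimizer is restarted from a deterministic list of
#' perturbed initial values, so the fit is reproducible for given data and
#' options.
#'
#' Initial values: `g0` and `tan_delta` from medians over the lowest decade
#' of strain; the critical strains from the first strain where G' drops below
#' 0.8 G0 (log-linear interpolation); thinning indices start at 0.3.  Five
#' multi-starts perturb the initial critical strain by x0.3/x1/x3 and the
#' indices by +/-0.1; the best final objective is kept.
#'
#' @param sweep a [strain_sweep()] (at least 8 points).
#' @param a shape exponent; fixed at 1.5 unless `free_a = TRUE`.
#' @param free_a if TRUE the shape exponent is fitted too.
#' @param equal_gamma if TRUE constrain `gamma_cr1 == gamma_cr2`.
#' @param control list passed to [minpack.lm::nls.lm.control()]; defaults are
#'   tight (`ftol = ptol = 1e-15`, `maxiter = 500`).
#' @return An object of class `sweep_fit` with elements `params`
#'   (a [rheo_params()], including `fit_r2_log`), `sweep`, `converged`,
#'   `degenerate` (TRUE when the data contain no usable thinning signal and
#'   the critical strain / index are unidentifiable), `ssr`, `niter`,
#'   `message`, `options`.  Methods: [coef.sweep_fit()], `print`, `summary`,
#'   [predict.sweep_fit()], `residuals` (log10 residuals), `plot`,
#'   [simulate.sweep_fit()].
#' @examples
#' truth <- rheo_params(5e4, 0.3, 0.003, 0.004, 0.35, 0.4)
#' g <- 10^seq(-5, 0, length.out = 33)
#' m <- eval_model(truth, g)
#' fit <- fit_sweep(strain_sweep(g, m$g_prime, m$g_double_prime))
#' coef(fit)
#' @export
fit_sweep <- function(sweep, a = 1.5, free_a = FALSE, equal_gamma = FALSE,
                      control = list()) {
  stopifnot(inherits(sweep, "strain_sweep"))
  if (nrow(sweep) < 8)
    stop("at least 8 sweep points are required for fitting")
  ctrl <- do.call(minpack.lm::nls.lm.control,
                  utils::modifyList(list(ftol = 1e-15, ptol = 1e-15,
                                         gtol = 0, maxiter = 500),
                                    control))
  g <- sweep$strain
  lgp <- log10(sweep$g_prime)
  lgpp <- log10(sweep$g_double_prime)

  ## --- initial values from the data ---------------------------------------
  low <- g <= min(g) * 10            # lowest decade of strain
  if (sum(low) < 2) low <- seq_along(g) <= 3
  g0_init <- stats::median(sweep$g_prime[low])
  td_init <- stats::median(sweep$g_double_prime[low] / sweep$g_prime[low])
  gcr_init <- .first_crossing(g, sweep$g_prime, 0.8 * g0_init)
  n_init <- 0.3

  unpack <- function(th) {
    i <- 3L
    gcr1 <- exp(th[i]); i <- i + 1L
    gcr2 <- if (equal_gamma) gcr1 else { v <- exp(th[i]); i <- i + 1L; v }
    n1 <- exp(th[i]); i <- i + 1L
    n2 <- exp(th[i]); i <- i + 1L
    a_val <- if (free_a) exp(th[i]) else a
    list(g0 = exp(th[1]), tan_delta = exp(th[2]),
         gamma_cr1 = gcr1, gamma_cr2 = gcr2, n1 = n1, n2 = n2, a = a_val)
  }
  resid_fn <- function(th) {
    p <- unpack(th)
    mp <- log10(p$g0) +
      ((p$n1 - 1) / p$a) * log10(1 + (g / p$gamma_cr1)^p$a)
    mpp <- log10(p$tan_delta * p$g0) +
      ((p$n2 - 1) / p$a) * log10(1 + (g / p$gamma_cr2)^p$a)
    r <- c(lgp - mp, lgpp - mpp)
    r[!is.finite(r)] <- 1e6
    r
  }
  make_start <- function(gcr_mult, n_shift) {
    th <- c(log(g0_init), log(td_init), log(gcr_init * gcr_mult))
    if (!equal_gamma) th <- c(th, log(gcr_init * gcr_mult))
    th <- c(th, log(n_init + n_shift), log(n_init + n_shift))
    if (free_a) th <- c(th, log(1.5))
    th
  }
  starts <- list(make_start(1, 0), make_start(0.3, 0), make_start(3, 0),
                 make_start(1, 0.1), make_start(1, -0.1))

  best <- NULL
  for (th0 in starts) {
    res <- tryCatch(minpack.lm::nls.lm(par = th0, fn = resid_fn,
                                       control = ctrl),
                    error = function(e) NULL)
    if (is.null(res)) next
    ssr <- sum(res$fvec^2)
    if (is.null(best) || ssr < best$ssr - 1e-14)
      best <- list(fit = res, ssr = ssr)
  }
  if (is.null(best))
    return(structure(list(params = NULL, sweep = sweep, converged = FALSE,
                          degenerate = NA, ssr = NA_real_, niter = NA_integer_,
                          message = "all multi-starts failed",
                          options = list(a = a, free_a = free_a,
                                         equal_gamma = equal_gamma)),
                     class = "sweep_fit"))

  fit <- best$fit
  p <- unpack(fit$par)
  ltot <- c(lgp, lgpp)
  r2 <- 1 - best$ssr / sum((ltot - mean(ltot))^2)
  if (!is.finite(r2)) r2 <- NA_real_

  ## unidentifiable thinning: critical strain beyond the measured range or
  ## an index ~1 means the sweep never left the LVE plateau
  degenerate <- (p$gamma_cr1 >= max(g)) || (p$gamma_cr2 >= max(g)) ||
    (p$n1 > 0.95 && p$n2 > 0.95)
  if (degenerate)
    warning("no strain-thinning signal: gamma_cr and n are unidentifiable")

  params <- suppressWarnings(
    rheo_params(p$g0, p$tan_delta, p$gamma_cr1, p$gamma_cr2, p$n1, p$n2,
                p$a, fit_r2_log = r2))
  if ((p$n1 <= 0 || p$n1 >= 1 || p$n2 <= 0 || p$n2 >= 1) && !degenerate)
    warning("fitted strain-thinning index outside (0, 1): n1 = ",
            signif(p$n1, 4), ", n2 = ", signif(p$n2, 4))

  structure(list(params = params, sweep = sweep,
                 converged = fit$info %in% 1:4, degenerate = degenerate,
                 ssr = best$ssr, niter = fit$niter, message = fit$message,
                 options = list(a = a, free_a = free_a,
                                equal_gamma = equal_gamma)),
            class = "sweep_fit")
}

## first strain where y drops below level, log-linear interpolation
.first_crossing <- function(g, y, level) {
  below <- which(y < level)
  if (length(below) == 0) return(sqrt(min(g) * max(g)))
  i <- below[1]
  if (i == 1) return(g[1])
  f <- (log(level) - log(y[i - 1])) / (log(y[i]) - log(y[i - 1]))
  exp(log(g[i - 1]) + f * (log(g[i]) - log(g[i - 1])))
}

#' @export
coef.sweep_fit <- function(object, ...) {
  if (is.null(object$params)) return(NULL)
  p <- object$params
  c(g0 = p$g0, tan_delta = p$tan_delta, gamma_cr1 = p$gamma_cr1,
    gamma_cr2 = p$gamma_cr2, n1 = p$n1, n2 = p$n2, a = p$a,
    sigma_y = p$sigma_y)
}

#' @export
print.sweep_fit <- function(x, ...) {
  cat("Amplitude-sweep model fit\n")
  if (is.null(x$params)) {
    cat("  FAILED:", x$message, "\n")
    return(invisible(x))
  }
  print(x$params)
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  if (isTRUE(x$degenerate))
    cat("  NOTE: degenerate fit (no thinning signal in the data)\n")
  invisible(x)
}

#' @export
summary.sweep_fit <- function(object, ...) {
  structure(list(fit = object,
                 coef = coef(object),
                 n_points = nrow(object$sweep),
                 ssr = object$ssr,
                 r2_log = if (!is.null(object$params))
                   object$params$fit_r2_log else NA_real_),
            class = "summary.sweep_fit")
}

#' @export
print.summary.sweep_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  points: %d   SSR(log10): %.4g   iter: %s\n",
              x$n_points, x$ssr, x$fit$niter))
  invisible(x)
}

#' Predicted moduli from a fitted sweep model
#'
#' @param object a [fit_sweep()] result.
#' @param newdata optional vector of strain amplitudes (fractions); defaults
#'   to the fitted sweep's strains.
#' @param ... unused.
#' @return data.frame with `strain`, `g_prime`, `g_double_prime`.
#' @export
predict.sweep_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$params)) stop("cannot predict from a failed fit")
  strain <- if (is.null(newdata)) object$sweep$strain else newdata
  eval_model(object$params, strain)
}

#' @export
residuals.sweep_fit <- function(object, ...) {
  if (is.null(object$params)) stop("failed fit has no residuals")
  pred <- predict(object)
  data.frame(strain = object$sweep$strain,
             g_prime = log10(object$sweep$g_prime) - log10(pred$g_prime),
             g_double_prime = log10(object$sweep$g_double_prime) -
               log10(pred$g_double_prime))
}

#' @export
plot.sweep_fit <- function(x, ...) {
  plot(x$sweep, ...)
  if (!is.null(x$params)) {
    gg <- 10^seq(log10(min(x$sweep$strain)), log10(max(x$sweep$strain)),
                 length.out = 200)
    pr <- eval_model(x$params, gg)
    graphics::lines(gg, pr$g_prime)
    graphics::lines(gg, pr$g_double_prime, lty = 2)
  }
  invisible(x)
}

#' Simulate noisy sweeps from a fitted model
#'
#' Draws replicate sweeps from the fitted parameters on the fitted strain
#' grid with multiplicative lognormal noise (see [simulate_sweep()]).
#'
#' @param object a converged [fit_sweep()] result.
#' @param nsim number of replicate sweeps.
#' @param seed integer seed (the session RNG state is preserved).
#' @param noise_cv multiplicative coefficient of variation (default 0.05).
#' @param ... unused.
#' @return A list of [strain_sweep()] objects.
#' @export
simulate.sweep_fit <- function(object, nsim = 1, seed = NULL,
                               noise_cv = 0.05, ...) {
  if (is.null(object$params)) stop("cannot simulate from a failed fit")
  lapply(seq_len(nsim), function(i)
    simulate_sweep(object$params, strain = object$sweep$strain,
                   noise_cv = noise_cv,
                   seed = if (is.null(seed)) NULL else child_seed(seed, i)))
}
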