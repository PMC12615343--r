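#' Validated table of per-ink records
#'
#' One row per ink: class label, fitted rheological parameters, optional
#' measured print force (N) and optional image-derived deviation metric.
#' The constructor validates the closed class set and basic invariants; all
#' statistics functions ([pairwise_regression()], [collapse_gamma_cr()],
#' [extract_window()], [correlation_report()]) operate on this table.
#'
#' @param df data.frame with at least `ink_id`, `ink_class`; recognised
#'   numeric columns: `g0`, `tan_delta`, `gamma_cr1`, `gamma_cr2`, `n1`,
#'   `n2`, `sigma_y`, `dev`, `print_force`.
#' @return `df` with class `ink_records`.
#' @export
ink_records <- function(df) {
  df <- as.data.frame(df)
  req <- c("ink_id", "ink_class")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "))
  classes <- c("carbohydrate", "protein", "fiber")
  bad <- setdiff(unique(df$ink_class), c(classes, NA))
  if (length(bad) > 0)
    stop("unknown ink class(es): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(classes, collapse = ", "), ")")
  if (!is.null(df$dev) && any(df$dev < 0, na.rm = TRUE))
    stop("dev must be non-negative")
  if (anyDuplicated(df$ink_id))
    stop("duplicated ink_id")
  if (!is.null(df$g0) && !is.null(df$gamma_cr1) && is.null(df$sigma_y))
    df$sigma_y <- df$g0 * df$gamma_cr1
  class(df) <- c("ink_records", "data.frame")
  df
}

#' Cohort-generation specification
#'
#' Study conditions for a synthetic multi-class ink cohort mirroring the
#' measured one: 18 carbohydrate-rich doughs, 10 protein-rich and 10
#' fiber-rich inks by default.  Per-class lognormal parameter distributions
#' carry imposed correlation structure: `gamma_cr1`/`gamma_cr2` correlated
#' on log scale (target 0.95), `n1` tied to `n2` with mean ratio 2, `G0`
#' anti-correlated with `n2` (higher-yield-stress inks thin more strongly),
#' print force proportional to the yield stress per class (fiber inks on
#' their own line), and a deviation response convex in `log(tan_delta)`
#' crossing `dev_threshold` exactly at the configured window bounds.
#'
#' Class medians for `gamma_cr1` are anchored at the characteristic
#' critical strains of the three classes, {0.3, 1.5, 4} x 10^-2.
#'
#' @param n_per_class named counts for carbohydrate / protein / fiber.
#' @param gamma_cr1_median,gamma_cr_sdlog,gamma_corr critical-strain
#'   lognormal medians (per class), log-sd and log-scale correlation
#'   between the two critical strains.
#' @param g0_median,g0_sdlog LVE modulus lognormal parameters, Pa.
#' @param tan_delta_median,tan_delta_sdlog loss-factor lognormal parameters.
#' @param n2_mean,n2_sd strain-thinning index (normal, clamped to
#'   (0.05, 0.95)).
#' @param n1_ratio,n1_sd `n1 = n1_ratio * n2 + noise`, same clamp.
#' @param g0_n2_corr correlation of `log(G0)` with `n2` (negative).
#' @param force_k per-class force/yield-stress slope, N/Pa.
#' @param force_noise_sd multiplicative force noise sd.
#' @param dev_window,dev_threshold,dev_b1,dev_b2,dev_noise_sd deviation
#'   response: `dev = max(0, thr + b1 * ((t - c)^2 - hw^2)) + b2 * n2 +
#'   noise` with `t = log(tan_delta)` and `(c, hw)` the log-center and
#'   log-half-width of `dev_window`; the defaults (`b2 = 0`, no noise) make
#'   `dev < dev_threshold` hold exactly inside the window.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(carbohydrate = 18, protein = 10,
                                        fiber = 10),
                        gamma_cr1_median = c(carbohydrate = 0.003,
                                             protein = 0.015, fiber = 0.04),
                        gamma_cr_sdlog = 0.4, gamma_corr = 0.95,
                        g0_median = c(carbohydrate = 3e4, protein = 8e3,
                                      fiber = 1.5e4),
                        g0_sdlog = 0.8,
                        tan_delta_median = c(carbohydrate = 0.25,
                                             protein = 0.30, fiber = 0.35),
                        tan_delta_sdlog = 0.45,
                        n2_mean = 0.35, n2_sd = 0.05,
                        n1_ratio = 2, n1_sd = 0.03,
                        g0_n2_corr = -0.6,
                        force_k = c(carbohydrate = 1.2e-4, protein = 1.2e-4,
                                    fiber = 2.4e-4),
                        force_noise_sd = 0.1,
                        dev_window = c(0.15, 0.5), dev_threshold = 0.1,
                        dev_b1 = 0.35, dev_b2 = 0, dev_noise_sd = 0,
                        seed = 1) {
  if (abs(gamma_corr) >= 1 || abs(g0_n2_corr) >= 1)
    stop("correlation targets must lie in (-1, 1)")
  if (dev_window[1] <= 0 || dev_window[2] <= dev_window[1])
    stop("dev_window must be increasing and positive")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a correlated multi-class ink cohort
#'
#' Samples one [ink_records()] table from a [cohort_spec()].  Correlations
#' are imposed by explicit Gaussian-latent construction on log scale
#' (a two-variable Cholesky factor for the critical strains, a shared
#' latent for `G0` vs `n2`).  Deterministic for a given spec (seed
#' included).
#'
#' Per-ink raw inputs for the upstream pipeline stages are produced on
#' demand by [cohort_sweeps()] (noisy amplitude sweeps from each ink's
#' parameters) and [cohort_images()] (rendered top views whose drawn
#' deviation matches each ink's `dev`).
#'
#' @param spec a [cohort_spec()].
#' @return An [ink_records()] table with attribute `"spec"`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  classes <- names(spec$n_per_class)
  with_seed(spec$seed, {
    rows <- lapply(classes, function(cl) {
      n <- spec$n_per_class[[cl]]
      z1 <- stats::rnorm(n)
      z2 <- spec$gamma_corr * z1 +
        sqrt(1 - spec$gamma_corr^2) * stats::rnorm(n)
      gamma_cr1 <- spec$gamma_cr1_median[[cl]] *
        exp(spec$gamma_cr_sdlog * z1)
      gamma_cr2 <- spec$gamma_cr1_median[[cl]] *
        exp(spec$gamma_cr_sdlog * z2)
      n2 <- pmin(pmax(stats::rnorm(n, spec$n2_mean, spec$n2_sd), 0.05), 0.95)
      zn <- (n2 - spec$n2_mean) / spec$n2_sd
      rho <- spec$g0_n2_corr
      g0 <- spec$g0_median[[cl]] *
        exp(spec$g0_sdlog * (rho * zn + sqrt(1 - rho^2) * stats::rnorm(n)))
      n1 <- pmin(pmax(spec$n1_ratio * n2 + stats::rnorm(n, 0, spec$n1_sd),
                      0.05), 0.95)
      tan_delta <- spec$tan_delta_median[[cl]] *
        exp(spec$tan_delta_sdlog * stats::rnorm(n))
      sigma_y <- g0 * gamma_cr1
      force <- spec$force_k[[cl]] * sigma_y *
        pmax(1 + stats::rnorm(n, 0, spec$force_noise_sd), 0.1)
      lw <- log(spec$dev_window)
      ctr <- mean(lw)
      hw <- diff(lw) / 2
      t <- log(tan_delta)
      dev <- pmax(0, spec$dev_threshold +
                    spec$dev_b1 * ((t - ctr)^2 - hw^2)) +
        spec$dev_b2 * n2
      if (spec$dev_noise_sd > 0)
        dev <- pmax(0, dev + stats::rnorm(n, 0, spec$dev_noise_sd))
      data.frame(ink_id = sprintf("%s%02d", substr(cl, 1, 4), seq_len(n)),
                 ink_class = cl, g0 = g0, tan_delta = tan_delta,
                 gamma_cr1 = gamma_cr1, gamma_cr2 = gamma_cr2,
                 n1 = n1, n2 = n2, sigma_y = sigma_y,
                 print_force = force, dev = dev)
    })
    out <- ink_records(do.call(rbind, rows))
    attr(out, "spec") <- spec
    out
  })
}

#' @rdname generate_cohort
#' @param records an [ink_records()] table from [generate_cohort()].
#' @param noise_cv multiplicative sweep noise (default 0.05).
#' @param strain strain grid for the sweeps.
#' @param seed integer seed (per-ink child seeds are derived from it).
#' @return `cohort_sweeps()`: named list of [strain_sweep()] objects.
#' @export
cohort_sweeps <- function(records, noise_cv = 0.05,
                          strain = 10^seq(-5, 0, length.out = 33),
                          seed = 1) {
  stopifnot(inherits(records, "ink_records"))
  out <- lapply(seq_len(nrow(records)), function(i) {
    p <- suppressWarnings(
      rheo_params(records$g0[i], records$tan_delta[i], records$gamma_cr1[i],
                  records$gamma_cr2[i], records$n1[i], records$n2[i]))
    simulate_sweep(p, strain = strain, noise_cv = noise_cv,
                   seed = child_seed(seed, i))
  })
  names(out) <- records$ink_id
  out
}

#' @rdname generate_cohort
#' @param base_spec [render_spec()] whose geometry is reused for every ink;
#'   the widening of each render is chosen so the analytic deviation of the
#'   drawn object equals the ink's `dev`.
#' @return `cohort_images()`: named list of [render_topview()] results.
#' @export
cohort_images <- function(records, base_spec = render_spec(), seed = 1) {
  stopifnot(inherits(records, "ink_records"))
  if (is.null(records$dev)) stop("records carry no dev column")
  out <- lapply(seq_len(nrow(records)), function(i) {
    s <- base_spec
    s$widening <- .widening_for_dev(records$dev[i], base_spec)
    s$seed <- child_seed(seed, i)
    render_topview(s)
  })
  names(out) <- records$ink_id
  out
}
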