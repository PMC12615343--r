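#' Descriptive amplitude-sweep model parameters
#'
#' Bundle the parameters of the descriptive strain-sweep model for a
#' yield-stress ink into a validated object.  The model describes the decay of
#' the storage and loss moduli with oscillatory strain amplitude:
#' \deqn{G'(\gamma) = G_0\,[1+(\gamma/\gamma_{cr,1})^a]^{(n_1-1)/a}}
#' \deqn{G''(\gamma) = \tan\delta\,G_0\,[1+(\gamma/\gamma_{cr,2})^a]^{(n_2-1)/a}}
#' At low strain the moduli plateau at the linear-viscoelastic (LVE) values
#' \eqn{G_0} and \eqn{\tan\delta\,G_0}; beyond the critical strains the
#' material strain-thins with power-law indices \eqn{n_1}, \eqn{n_2}.  The
#' yield stress is the derived quantity \eqn{\sigma_Y = G_0\,\gamma_{cr,1}}.
#'
#' Strains are dimensionless fractions (not percent) throughout: the product
#' \eqn{G_0\gamma_{cr,1}} only has units of Pa when the strain is a fraction.
#'
#' @param g0 LVE storage modulus, Pa (> 0).
#' @param tan_delta LVE loss factor G''/G' (> 0).
#' @param gamma_cr1,gamma_cr2 critical strains (fractions, > 0) marking the
#'   end of the LVE plateau for G' and G'' respectively.
#' @param n1,n2 strain-thinning indices.  Values outside (0, 1) are accepted
#'   with a warning (n = 1 means no thinning).
#' @param a shape exponent controlling the sharpness of the LVE-to-thinning
#'   crossover; 1.5 by default.
#' @param fit_r2_log optional goodness of fit (coefficient of determination of
#'   the joint log10-modulus fit); filled in by [fit_sweep()].
#' @return An object of class `rheo_params`: a named list with the fields
#'   above plus `sigma_y = g0 * gamma_cr1` (Pa).
#' @seealso [eval_model()], [fit_sweep()], [yield_stress()]
#' @examples
#' p <- rheo_params(g0 = 1000, tan_delta = 0.3, gamma_cr1 = 0.01,
#'                  gamma_cr2 = 0.012, n1 = 0.3, n2 = 0.35)
#' p$sigma_y  # 10 Pa
#' @export
rheo_params <- function(g0, tan_delta, gamma_cr1, gamma_cr2 = gamma_cr1,
                        n1, n2, a = 1.5, fit_r2_log = NA_real_) {
  vals <- c(g0 = g0, tan_delta = tan_delta, gamma_cr1 = gamma_cr1,
            gamma_cr2 = gamma_cr2, a = a)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("g0, tan_delta, gamma_cr1, gamma_cr2 and a must be positive and finite")
  if (!is.finite(n1) || !is.finite(n2))
    stop("n1 and n2 must be finite")
  if (n1 <= 0 || n1 >= 1 || n2 <= 0 || n2 >= 1)
    warning("strain-thinning index outside (0, 1): n1 = ",
            signif(n1, 4), ", n2 = ", signif(n2, 4))
  structure(list(g0 = g0, tan_delta = tan_delta,
                 gamma_cr1 = gamma_cr1, gamma_cr2 = gamma_cr2,
                 n1 = n1, n2 = n2, a = a,
                 sigma_y = g0 * gamma_cr1,
                 fit_r2_log = fit_r2_log),
            class = "rheo_params")
}

#' @export
print.rheo_params <- function(x, ...) {
  cat("Amplitude-sweep model parameters\n")
  cat(sprintf("  G0        = %.6g Pa\n", x$g0))
  cat(sprintf("  tan(delta)= %.4g\n", x$tan_delta))
  cat(sprintf("  gamma_cr1 = %.4g   gamma_cr2 = %.4g\n",
              x$gamma_cr1, x$gamma_cr2))
  cat(sprintf("  n1 = %.4g   n2 = %.4g   a = %.3g\n", x$n1, x$n2, x$a))
  cat(sprintf("  sigma_Y   = %.6g Pa (= G0 * gamma_cr1)\n", x$sigma_y))
  if (is.finite(x$fit_r2_log))
    cat(sprintf("  R2 (log fit) = %.4f\n", x$fit_r2_log))
  invisible(x)
}

#' Evaluate the amplitude-sweep model
#'
#' Storage and loss moduli of the descriptive model at given strain
#' amplitudes (see [rheo_params()] for the model equations).
#'
#' @param params a [rheo_params()] object.
#' @param strain strain amplitude(s), dimensionless fraction, > 0.
#' @return A data.frame with columns `strain`, `g_prime`, `g_double_prime`
#'   (Pa).
#' @examples
#' p <- rheo_params(1000, 0.3, 0.01, 0.01, 0.3, 0.3)
#' eval_model(p, c(1e-5, 0.01, 1))
#' @export
eval_model <- function(params, strain) {
  stopifnot(inherits(params, "rheo_params"))
  if (any(!is.finite(strain)) || any(strain <= 0))
    stop("strain must be positive and finite")
  gp <- params$g0 *
    (1 + (strain / params$gamma_cr1)^params$a)^((params$n1 - 1) / params$a)
  gpp <- params$tan_delta * params$g0 *
    (1 + (strain / params$gamma_cr2)^params$a)^((params$n2 - 1) / params$a)
  data.frame(strain = strain, g_prime = gp, g_double_prime = gpp)
}

#' Yield stress from the LVE modulus and critical strain
#'
#' \eqn{\sigma_Y = G_0 \gamma_{cr,1}}: the stress at the solid-to-liquid
#' transition marking the end of the linear-viscoelastic plateau.
#'
#' @param g0 LVE storage modulus, Pa (> 0).
#' @param gamma_cr1 critical strain (fraction, > 0).
#' @return Yield stress in Pa.
#' @examples
#' yield_stress(1000, 0.01)  # 10 Pa
#' @export
yield_stress <- function(g0, gamma_cr1) {
  if (any(!is.finite(g0)) || any(g0 <= 0) ||
      any(!is.finite(gamma_cr1)) || any(gamma_cr1 <= 0))
    stop("g0 and gamma_cr1 must be positive and finite")
  g0 * gamma_cr1
}

#' Nozzle geometry and flow specification
#'
#' @param radius nozzle radius R, m.
#' @param length nozzle length L, m.
#' @param gamma_dot_min minimum (process-required) shear rate, 1/s (>= 0).
#' @param gamma_dot_cr critical shear rate at the onset of shear thinning,
#'   1/s (> 0).
#' @param shear_index Herschel-Bulkley shear-thinning index n (0 < n <= 1).
#' @return An object of class `nozzle_spec`.
#' @export
nozzle_spec <- function(radius, length, gamma_dot_min, gamma_dot_cr,
                        shear_index) {
  if (radius <= 0 || length <= 0 || gamma_dot_cr <= 0)
    stop("radius, length and gamma_dot_cr must be positive")
  if (gamma_dot_min < 0) stop("gamma_dot_min must be non-negative")
  if (shear_index <= 0 || shear_index > 1)
    stop("shear_index must be in (0, 1]")
  structure(list(radius = radius, length = length,
                 gamma_dot_min = gamma_dot_min, gamma_dot_cr = gamma_dot_cr,
                 shear_index = shear_index),
            class = "nozzle_spec")
}

#' Maximum extrusion force for a Herschel-Bulkley ink
#'
#' Force needed to push a yield-stress ink through a straight cylindrical
#' nozzle at the minimum process shear rate:
#' \deqn{F_{max} = \sigma_Y\,[1 + (\dot\gamma_{min}/\dot\gamma_{cr})^{n}]\,
#'   2\pi R L}
#' The bracket interpolates between the yield-limited floor
#' (\eqn{\dot\gamma_{min} = 0}) and the shear-thinning regime.
#'
#' @param sigma_y yield stress, Pa (> 0).
#' @param nozzle a [nozzle_spec()].
#' @return Force in N.
#' @examples
#' nz <- nozzle_spec(5e-4, 0.01, gamma_dot_min = 10, gamma_dot_cr = 10,
#'                   shear_index = 0.3)
#' extrusion_force(100, nz)  # 2 * 100 * 2*pi*5e-4*0.01
#' @export
extrusion_force <- function(sigma_y, nozzle) {
  stopifnot(inherits(nozzle, "nozzle_spec"))
  if (any(sigma_y <= 0) || any(!is.finite(sigma_y)))
    stop("sigma_y must be positive and finite")
  ratio <- nozzle$gamma_dot_min / nozzle$gamma_dot_cr
  sigma_y * (1 + ratio^nozzle$shear_index) *
    2 * pi * nozzle$radius * nozzle$length
}

#' Self-support criterion for a printed column
#'
#' A printed object of height H supports its own weight when the yield stress
#' exceeds three times the hydrostatic pressure: \eqn{\sigma_Y > 3\rho g H}
#' (strict inequality).  The maximum self-supporting height is
#' \eqn{H_{max} = \sigma_Y / (3 \rho g)}.
#'
#' @param sigma_y yield stress, Pa (> 0).
#' @param density ink mass density, kg/m^3.
#' @param height object height, m (>= 0).
#' @param gravity gravitational acceleration, m/s^2 (default 9.81).
#' @return A list with `supported` (logical) and `h_max` (m).
#' @examples
#' self_support(300, density = 1000, height = 0.015)
#' @export
self_support <- function(sigma_y, density, height, gravity = 9.81) {
  if (sigma_y <= 0 || density <= 0 || gravity <= 0 || height < 0)
    stop("sigma_y, density, gravity must be positive; height non-negative")
  list(supported = sigma_y > 3 * density * gravity * height,
       h_max = sigma_y / (3 * density * gravity))
}

#' Critical-gel relation between tan(delta) and the frequency exponent
#'
#' For a critical gel whose moduli scale as \eqn{G' \sim G'' \sim \omega^m},
#' the loss factor is \eqn{\tan\delta = \tan(m\pi/2)}.  `critical_gel_tan`
#' maps the exponent to tan(delta); `critical_gel_m` inverts it.
#'
#' @param m power-law frequency exponent, 0 < m < 1.
#' @param tan_delta loss factor, > 0.
#' @return `critical_gel_tan`: tan(delta); `critical_gel_m`: m.
#' @examples
#' critical_gel_tan(0.5)  # 1
#' critical_gel_m(1)      # 0.5
#' @export
critical_gel_tan <- function(m) {
  if (any(m <= 0) || any(m >= 1)) stop("m must be in (0, 1)")
  tan(m * pi / 2)
}

#' @rdname critical_gel_tan
#' @export
critical_gel_m <- function(tan_delta) {
  if (any(tan_delta <= 0)) stop("tan_delta must be positive")
  (2 / pi) * atan(tan_delta)
}
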