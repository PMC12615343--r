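#' Simulate a noisy amplitude sweep from known parameters
#'
#' Forward-evaluates the descriptive model on a log-spaced strain grid and
#' applies multiplicative lognormal noise, the natural error model for a
#' rheometer whose uncertainty scales with the signal: each modulus is
#' multiplied by \eqn{\exp(\epsilon)}, \eqn{\epsilon \sim N(0, \sigma^2)}
#' with \eqn{\sigma = \sqrt{\log(1 + cv^2)}} so that the coefficient of
#' variation of the factor equals `noise_cv`.  Noise is independent per
#' point and per modulus.  Output is bit-reproducible for a given seed.
#'
#' @param truth a [rheo_params()] object.
#' @param strain strain grid (fractions); default 33 log-spaced points over
#'   `[1e-5, 1]`, i.e. 0.001 %-100 %.
#' @param noise_cv multiplicative coefficient of variation (>= 0).
#' @param frequency sweep frequency metadata, Hz.
#' @param seed integer seed; the session RNG state is preserved.
#' @return A [strain_sweep()].
#' @examples
#' p <- rheo_params(1e4, 0.3, 0.01, 0.01, 0.3, 0.35)
#' sw <- simulate_sweep(p, noise_cv = 0.05, seed = 1)
#' @export
simulate_sweep <- function(truth, strain = 10^seq(-5, 0, length.out = 33),
                           noise_cv = 0, frequency = 1, seed = NULL) {
  stopifnot(inherits(truth, "rheo_params"), noise_cv >= 0)
  m <- eval_model(truth, strain)
  if (noise_cv > 0) {
    sigma <- sqrt(log(1 + noise_cv^2))
    eps <- with_seed(seed, stats::rnorm(2 * length(strain), 0, sigma))
    n <- length(strain)
    m$g_prime <- m$g_prime * exp(eps[1:n])
    m$g_double_prime <- m$g_double_prime * exp(eps[(n + 1):(2 * n)])
  }
  strain_sweep(strain, m$g_prime, m$g_double_prime, frequency = frequency)
}
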