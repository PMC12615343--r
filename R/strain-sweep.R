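#' Amplitude-sweep data for one ink
#'
#' Container for one oscillatory amplitude sweep: storage and loss moduli
#' measured over a (log-spaced) grid of strain amplitudes at fixed frequency.
#' Strains are dimensionless fractions; use `percent = TRUE` if the input is
#' in percent (the usual rheometer export).
#'
#' @param strain strain amplitudes, strictly increasing and positive.
#' @param g_prime storage moduli G', Pa, > 0.
#' @param g_double_prime loss moduli G'', Pa, > 0.
#' @param frequency oscillation frequency, Hz (metadata; default 1).
#' @param percent if TRUE, `strain` is given in percent and divided by 100.
#' @return An object of class `strain_sweep`: a data.frame with columns
#'   `strain`, `g_prime`, `g_double_prime` and attribute `frequency`.
#' @examples
#' p <- rheo_params(1000, 0.3, 0.01, 0.01, 0.3, 0.3)
#' g <- 10^seq(-5, 0, length.out = 20)
#' m <- eval_model(p, g)
#' sw <- strain_sweep(g, m$g_prime, m$g_double_prime)
#' @export
strain_sweep <- function(strain, g_prime, g_double_prime, frequency = 1,
                         percent = FALSE) {
  if (percent) strain <- strain / 100
  n <- length(strain)
  if (length(g_prime) != n || length(g_double_prime) != n)
    stop("strain, g_prime and g_double_prime must have equal length")
  if (any(!is.finite(strain)) || any(strain <= 0))
    stop("strains must be positive and finite")
  if (any(diff(strain) <= 0))
    stop("strains must be strictly increasing")
  if (any(!is.finite(g_prime)) || any(g_prime <= 0) ||
      any(!is.finite(g_double_prime)) || any(g_double_prime <= 0))
    stop("moduli must be positive and finite")
  structure(data.frame(strain = strain, g_prime = g_prime,
                       g_double_prime = g_double_prime),
            frequency = frequency,
            class = c("strain_sweep", "data.frame"))
}

#' @export
print.strain_sweep <- function(x, ...) {
  cat(sprintf("Amplitude sweep: %d points, strain %.3g .. %.3g, %g Hz\n",
              nrow(x), min(x$strain), max(x$strain),
              attr(x, "frequency") %||% NA))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
plot.strain_sweep <- function(x, ...) {
  graphics::plot(x$strain, x$g_prime, log = "xy", pch = 16,
                 xlab = "strain amplitude (-)", ylab = "modulus (Pa)",
                 ylim = range(c(x$g_prime, x$g_double_prime)), ...)
  graphics::points(x$strain, x$g_double_prime, pch = 1)
  graphics::legend("bottomleft", legend = c("G'", "G''"), pch = c(16, 1),
                   bty = "n")
  invisible(x)
}
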