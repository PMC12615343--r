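## Shared fixtures, all generated in code.

## random but reproducible model parameters spanning realistic ink ranges
random_rheo_params <- function(seed) {
  withr::with_seed(seed, {
    rheo_params(g0 = 10^runif(1, 2, 5),
                tan_delta = 10^runif(1, -1.2, -0.1),
                gamma_cr1 = 10^runif(1, -3, -1.3),
                gamma_cr2 = 10^runif(1, -3, -1.3),
                n1 = runif(1, 0.15, 0.6),
                n2 = runif(1, 0.15, 0.6))
  })
}

default_grid <- function(n = 33) 10^seq(-5, 0, length.out = n)

noise_free_sweep <- function(params, n = 33) {
  g <- default_grid(n)
  m <- eval_model(params, g)
  strain_sweep(g, m$g_prime, m$g_double_prime)
}

## independent annulus rasterizer (oracle for the moments pipeline):
## plain subpixel sampling, no shared code with the package renderer
render_annulus_mask <- function(r1, r2, size, ss = 4) {
  mid <- size / 2 - 0.5
  off <- ((seq_len(ss) - 0.5) / ss) - 0.5
  cov <- matrix(0, size, size)
  for (ox in off) for (oy in off) {
    dx2 <- (0:(size - 1) + ox - mid)^2
    dy2 <- (0:(size - 1) + oy - mid)^2
    r <- sqrt(outer(dy2, dx2, "+"))
    cov <- cov + (r >= r1 & r <= r2)
  }
  (cov / ss^2 >= 0.5) * 1
}

## two ink classes sampled from one master curve dev = g(log10 gamma),
## class-2 critical strains multiplied by 5 (known collapse scale)
shifted_collapse_records <- function(noise_sd = 0.01, seed = 3) {
  withr::with_seed(seed, {
    g1 <- 10^runif(12, -3, -1)
    d1 <- pmax(0, 0.5 - 0.2 * (log10(g1) + 3)) + rnorm(12, 0, noise_sd)
    g2 <- 10^runif(12, -3, -1) * 5
    d2 <- pmax(0, 0.5 - 0.2 * (log10(g2 / 5) + 3)) + rnorm(12, 0, noise_sd)
    ink_records(data.frame(
      ink_id = sprintf("i%02d", 1:24),
      ink_class = rep(c("carbohydrate", "protein"), each = 12),
      gamma_cr1 = c(g1, g2), dev = pmax(0, c(d1, d2))))
  })
}

## small-image pipeline settings used across imaging tests (fast)
small_render_spec <- function(...) {
  render_spec(image_size = 560, outer_radius = 110, ...)
}
small_pipeline_config <- function(...) {
  pipeline_config(crop_size = 460, ...)
}
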