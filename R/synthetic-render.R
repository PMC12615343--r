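#' Rendering specification for synthetic top-view fixtures
#'
#' Describes a synthetic top-view photograph of the 4-connected-cylinder
#' print design: four annuli in a 2 x 2 layout touching at single points,
#' with controllable geometric defects.
#'
#' Widening models track thickening at a fixed print-path centerline: the
#' cylinder centers and the annulus centerline radius stay at their design
#' positions while the wall thickens so that the drawn ratio is exactly
#' `ratio_target + widening`.  The centroid consequently drifts toward the
#' neighbors relative to its target `(R2, R2)` (the outer radius grows while
#' the center stays put), reproducing the coupling between track widening
#' and center-of-mass displacement seen in real prints.  `asymmetry` scales
#' the vertical center positions by `1 + asymmetry`, driving `Cx/Cy != 1`.
#'
#' @param image_size square frame side, px.
#' @param outer_radius design outer radius R2 at zero widening, px.
#' @param ratio_target design R2/R1 (default 1.34).
#' @param widening w >= 0: drawn R2/R1 = ratio_target + w.
#' @param asymmetry vertical center-position scaling (0 = symmetric).
#' @param illum_gradient fractional horizontal shading across the frame.
#' @param blob_count,blob_size nuisance specks (wall-colored disks placed
#'   outside the object), count and radius in px.
#' @param colors list of OpenCV-convention HSV triplets `wall`, `interior`,
#'   `background` chosen to pass/fail the dough filter rules; the defaults
#'   place the rule-flipping channel of each boundary near the midpoint of
#'   the wall/neighbor blend, so edge pixels classify as wall at about half
#'   coverage and the segmented count tracks the rasterized one.
#' @param supersample subpixel grid factor for anti-aliased edges.
#' @param seed integer seed (blob placement).
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(image_size = 1080, outer_radius = 215,
                        ratio_target = 1.34, widening = 0, asymmetry = 0,
                        illum_gradient = 0, blob_count = 0, blob_size = 3,
                        colors = list(wall = c(100, 80, 180),
                                      interior = c(100, 180, 150),
                                      background = c(20, 15, 20)),
                        supersample = 8, seed = 1) {
  if (widening < 0) stop("widening must be non-negative")
  if (image_size %% 2 != 0) stop("image_size must be even")
  structure(list(image_size = image_size, outer_radius = outer_radius,
                 ratio_target = ratio_target, widening = widening,
                 asymmetry = asymmetry, illum_gradient = illum_gradient,
                 blob_count = blob_count, blob_size = blob_size,
                 colors = colors, supersample = supersample, seed = seed),
            class = "render_spec")
}

## anti-aliased coverage of a disk of radius R centered at (cx, cy)
## (0-based pixel-center coordinates, x = column); pixels within 1 px of the
## edge are resolved on an ss x ss subpixel grid
.disk_coverage <- function(nr, nc, cx, cy, R, ss = 8) {
  x <- 0:(nc - 1)
  y <- 0:(nr - 1)
  dx2 <- (x - cx)^2
  dy2 <- (y - cy)^2
  r <- sqrt(outer(dy2, dx2, "+"))
  cov <- (r < R) * 1
  band <- which(abs(r - R) < 1)
  if (length(band) > 0) {
    bi <- arrayInd(band, c(nr, nc))
    xb <- bi[, 2] - 1
    yb <- bi[, 1] - 1
    off <- ((seq_len(ss) - 0.5) / ss) - 0.5
    A <- (outer(xb, off, "+") - cx)^2   # n_band x ss
    B <- (outer(yb, off, "+") - cy)^2
    cnt <- numeric(length(band))
    for (j in seq_len(ss)) cnt <- cnt + rowSums(A + B[, j] < R^2)
    cov[band] <- cnt / ss^2
  }
  cov
}

#' Render a synthetic top-view image of the 4-cylinder design
#'
#' Draws four anti-aliased annuli per the [render_spec()] geometry, fills
#' interiors and background with class-specific HSV colors, applies an
#' optional horizontal illumination gradient and wall-colored nuisance
#' blobs, and records the exact drawn geometry as ground truth.
#'
#' @param spec a [render_spec()].
#' @return list with `image` (RGB array `[rows, cols, 3]` in `[0, 1]`) and
#'   `truth`: drawn `r1`, `r2`, centerline radius, center offsets
#'   `p_x`/`p_y`, the three deviation terms in the design frame, the
#'   analytic `dev` of the drawn geometry (equal weights), per-annulus
#'   analytic area, and `wall_px` (rasterized wall pixel count at half
#'   coverage).
#' @export
render_topview <- function(spec = render_spec()) {
  stopifnot(inherits(spec, "render_spec"))
  W <- spec$image_size
  rt <- spec$ratio_target
  r2t <- spec$outer_radius
  rc <- r2t * (1 + 1 / rt) / 2          # fixed print-path centerline radius
  rho <- rt + spec$widening
  r2 <- 2 * rc * rho / (1 + rho)
  r1 <- 2 * rc / (1 + rho)
  p_x <- r2t
  p_y <- r2t * (1 + spec$asymmetry)
  if (p_x + r2 + 2 > W / 2 || p_y + r2 + 2 > W / 2)
    stop("geometry does not fit in frame")

  mid <- W / 2 - 0.5                    # 0-based frame center (boundary)
  centers <- rbind(c(mid - p_x, mid - p_y), c(mid + p_x, mid - p_y),
                   c(mid - p_x, mid + p_y), c(mid + p_x, mid + p_y))

  wall_a <- matrix(0, W, W)
  int_a <- matrix(0, W, W)
  for (k in 1:4) {
    outer_cov <- .disk_coverage(W, W, centers[k, 1], centers[k, 2], r2,
                                spec$supersample)
    inner_cov <- .disk_coverage(W, W, centers[k, 1], centers[k, 2], r1,
                                spec$supersample)
    wall_a <- pmax(wall_a, outer_cov - inner_cov)
    int_a <- pmax(int_a, inner_cov)
  }

  if (spec$blob_count > 0) {
    pos <- with_seed(spec$seed, {
      out <- matrix(NA_real_, 0, 2)
      tries <- 0
      while (nrow(out) < spec$blob_count && tries < 1000) {
        tries <- tries + 1
        q <- stats::runif(2, spec$blob_size + 2, W - spec$blob_size - 3)
        d <- sqrt((q[1] - centers[, 1])^2 + (q[2] - centers[, 2])^2)
        if (all(d > r2 + 3 * spec$blob_size)) out <- rbind(out, q)
      }
      out
    })
    for (k in seq_len(nrow(pos)))
      wall_a <- pmax(wall_a, .disk_coverage(W, W, pos[k, 1], pos[k, 2],
                                            spec$blob_size,
                                            spec$supersample))
  }

  to_rgb <- function(hsv_cv) {
    hex <- grDevices::hsv(hsv_cv[1] / 180, hsv_cv[2] / 255, hsv_cv[3] / 255)
    as.numeric(grDevices::col2rgb(hex)) / 255
  }
  cw <- to_rgb(spec$colors$wall)
  ci <- to_rgb(spec$colors$interior)
  cb <- to_rgb(spec$colors$background)

  img <- array(0, c(W, W, 3))
  for (ch in 1:3) {
    base <- int_a * ci[ch] + (1 - int_a) * cb[ch]
    img[, , ch] <- wall_a * cw[ch] + (1 - wall_a) * base
  }
  if (spec$illum_gradient != 0) {
    ramp <- 1 + spec$illum_gradient * ((0:(W - 1)) / (W - 1) - 0.5)
    for (ch in 1:3)
      img[, , ch] <- sweep(img[, , ch], 2, ramp, "*")
  }
  img <- pmin(pmax(img, 0), 1)

  t1 <- spec$widening
  t2 <- p_x / p_y - 1
  t3 <- (p_x + p_y) / 2 / r2 - 1
  truth <- list(r1 = r1, r2 = r2, centerline = rc, p_x = p_x, p_y = p_y,
                ratio = rho, terms = c(ratio = t1, symmetry = t2,
                                       centering = t3),
                dev = sqrt(t1^2 + t2^2 + t3^2),
                annulus_area = pi * (r2^2 - r1^2),
                annulus_inertia = pi / 2 * (r2^4 - r1^4),
                wall_px = sum(wall_a > 0.5))
  list(image = img, truth = truth, spec = spec)
}

## invert the widening -> analytic Dev map of the renderer (asymmetry 0)
.widening_for_dev <- function(dev, spec = render_spec()) {
  if (dev <= 0) return(0)
  f <- function(w) {
    s <- spec; s$widening <- w
    rc <- s$outer_radius * (1 + 1 / s$ratio_target) / 2
    rho <- s$ratio_target + w
    r2 <- 2 * rc * rho / (1 + rho)
    sqrt(w^2 + (s$outer_radius / r2 - 1)^2) - dev
  }
  upper <- 2
  if (f(upper) < 0) return(upper)
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}
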