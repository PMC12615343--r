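#' Image-pipeline configuration
#'
#' @param crop_size side of the square crop around the object center, px
#'   (even; default 900, about the printed 40 x 40 mm design).
#' @param erosion_kernel side of the square structuring element, px.
#' @param erosion_iter erosion (and dilation) iterations.
#' @param binarize_factor threshold multiplier on the quarter-image mean
#'   (> 1; default 1.25).
#' @param quadrant which quarter of the averaged crop to analyze (after
#'   4-fold averaging all four are equivalent; one is fixed for
#'   determinism).
#' @param grayscale_moments if TRUE, moments are weighted by the grayscale
#'   quarter values instead of the binarized 0/1 mask.
#' @param mm_per_px optional scale for reporting radii in mm.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(crop_size = 900, erosion_kernel = 5,
                            erosion_iter = 2, binarize_factor = 1.25,
                            quadrant = c("topleft", "topright",
                                         "bottomleft", "bottomright"),
                            grayscale_moments = FALSE, mm_per_px = NULL) {
  quadrant <- match.arg(quadrant)
  if (crop_size %% 2 != 0) stop("crop_size must be even")
  if (binarize_factor <= 1) stop("binarize_factor must exceed 1")
  structure(list(crop_size = crop_size, erosion_kernel = erosion_kernel,
                 erosion_iter = erosion_iter,
                 binarize_factor = binarize_factor, quadrant = quadrant,
                 grayscale_moments = grayscale_moments,
                 mm_per_px = mm_per_px),
            class = "pipeline_config")
}

## crop a matrix to rows r0..r0+L-1, cols c0..c0+L-1 (1-based), zero-padding
## outside the source extent
.crop_pad <- function(m, r0, c0, L) {
  out <- matrix(0, L, L)
  rs <- max(1, r0):min(nrow(m), r0 + L - 1)
  cs <- max(1, c0):min(ncol(m), c0 + L - 1)
  if (length(rs) > 0 && length(cs) > 0)
    out[rs - r0 + 1, cs - c0 + 1] <- m[rs, cs]
  out
}

#' Crop, illumination-correct and symmetry-average around the object center
#'
#' Crops a square window of side `crop_size` centered on the measured object
#' center from the masked grayscale image, divides it by its own mean to
#' remove illumination gradients, averages the four 90-degree rotations
#' (an image of a 4-fold-symmetric object is invariant under this), and
#' returns the configured quarter.
#'
#' @param c_filter grayscale matrix (wall saturation values).
#' @param center 0-based `c(x, y)` center from [clean_and_center()].
#' @param s_mask binary shape mask applied before cropping.
#' @param config a [pipeline_config()].
#' @return The quarter matrix (`crop_size/2` square).  The full averaged
#'   crop is attached as attribute `"averaged_crop"`.
#' @export
crop_correct_average <- function(c_filter, center, s_mask,
                                 config = pipeline_config()) {
  L <- config$crop_size
  masked <- c_filter * s_mask
  ## place the object center on the central pixel boundary of the crop:
  ## 1-based window starts so that full-image x = round(cx) + 0.5 maps to
  ## crop coordinate L/2 - 0.5 (0-based)
  c0 <- round(center[["x"]]) + 1 - L / 2 + 1
  r0 <- round(center[["y"]]) + 1 - L / 2 + 1
  crop <- .crop_pad(masked, r0, c0, L)
  mu <- mean(crop)
  if (mu == 0) stop_stage("averaging", "crop has zero mean after masking")
  crop <- crop / mu
  avg <- (crop + rot90(crop) + rot90(rot90(crop)) +
            rot90(rot90(rot90(crop)))) / 4
  Lq <- L / 2
  q <- switch(config$quadrant,
              topleft = avg[1:Lq, 1:Lq],
              topright = avg[1:Lq, (Lq + 1):L],
              bottomleft = avg[(Lq + 1):L, 1:Lq],
              bottomright = avg[(Lq + 1):L, (Lq + 1):L])
  attr(q, "averaged_crop") <- avg
  q
}

#' Binarize a quarter image at a multiple of its mean
#'
#' @param quarter grayscale matrix.
#' @param factor threshold multiplier (default 1.25): a pixel is set when
#'   its value exceeds `factor * mean(quarter)`.
#' @return binary 0/1 matrix.
#' @export
binarize_quarter <- function(quarter, factor = 1.25) {
  if (length(quarter) == 0) stop_stage("binarization", "empty quarter image")
  (quarter > factor * mean(quarter)) * 1
}

#' Method-of-moments shape features of a binary mask
#'
#' Zeroth, first and second central moments of the pixel distribution
#' `f(x, y)`:
#' area \eqn{A = \sum f}, centroid \eqn{(C_x, C_y)}, second central moments
#' \eqn{M_{20}, M_{02}} and the polar moment of inertia
#' \eqn{I = M_{20} + M_{02}}.  Coordinates have the origin at the top-left,
#' x rightward (columns), y downward (rows), with pixel centers at integers
#' starting from 0.
#'
#' @param mask binary (or, with `grayscale = TRUE` semantics, non-negative
#'   grayscale) matrix with at least one positive pixel.
#' @return An object of class `geometry_features`: list with `area`, `cx`,
#'   `cy`, `m20`, `m02`, `inertia`, and `r1`/`r2` slots (`NA` until filled by
#'   [annulus_radii()] / [analyze_image()]).
#' @examples
#' m <- matrix(0, 5, 5); m[5, 4] <- 1   # pixel at x = 3, y = 4
#' image_moments(m)[c("area", "cx", "cy")]
#' @export
image_moments <- function(mask) {
  f <- as.matrix(mask)
  A <- sum(f)
  if (A <= 0) stop_stage("moments", "empty mask")
  x <- 0:(ncol(f) - 1)
  y <- 0:(nrow(f) - 1)
  mass_x <- colSums(f)
  mass_y <- rowSums(f)
  cx <- sum(mass_x * x) / A
  cy <- sum(mass_y * y) / A
  m20 <- sum(mass_x * (x - cx)^2)
  m02 <- sum(mass_y * (y - cy)^2)
  structure(list(area = A, cx = cx, cy = cy, m20 = m20, m02 = m02,
                 inertia = m20 + m02, r1 = NA_real_, r2 = NA_real_),
            class = "geometry_features")
}

#' @export
print.geometry_features <- function(x, ...) {
  cat(sprintf("Geometry: A = %.1f px^2, centroid = (%.2f, %.2f), I = %.4g px^4\n",
              x$area, x$cx, x$cy, x$inertia))
  if (is.finite(x$r1) || is.finite(x$r2))
    cat(sprintf("  annulus radii: R1 = %.2f px, R2 = %.2f px\n", x$r1, x$r2))
  invisible(x)
}

#' Annulus radii from area and moment of inertia
#'
#' For a full annulus, \eqn{A = \pi(R_2^2 - R_1^2)} and
#' \eqn{I = (\pi/2)(R_2^4 - R_1^4)}, which invert to
#' \deqn{R_2^2 = I/A + A/(2\pi), \qquad R_1^2 = I/A - A/(2\pi).}
#' When the measured pair is not realizable as an annulus
#' (\eqn{R_1^2 < 0}), the inner radius is clamped to 0 (solid disk) and
#' flagged.
#'
#' @param area mask area, px^2 (> 0).
#' @param inertia polar second central moment, px^4 (>= 0).
#' @return list with `r1`, `r2` (px) and logical `clamped`.
#' @examples
#' annulus_radii(pi * (60^2 - 30^2), pi / 2 * (60^4 - 30^4))  # 30, 60
#' @export
annulus_radii <- function(area, inertia) {
  if (!is.finite(area) || area <= 0) stop("area must be positive")
  if (!is.finite(inertia) || inertia < 0) stop("inertia must be non-negative")
  r2sq <- inertia / area + area / (2 * pi)
  r1sq <- inertia / area - area / (2 * pi)
  clamped <- r1sq < 0
  if (clamped) r1sq <- 0
  list(r1 = sqrt(r1sq), r2 = sqrt(r2sq), clamped = clamped)
}

#' Print-fidelity deviation metric
#'
#' Aggregates three dimensionless deviations of the measured quarter-image
#' geometry from the print design into a single accuracy number:
#' \deqn{Dev^2 = (R_2/R_1 - R_{ratio})^2 + (C_x/C_y - 1)^2 +
#'   (\bar C/R_2 - 1)^2,\quad \bar C = (C_x + C_y)/2,}
#' with the centroid expressed in the frame in which the design target is
#' \eqn{(C_x, C_y) = (R_2, R_2)} (origin at the quarter corner facing the
#' object center, axes pointing into the quarter).  Dev = 0 is a perfect
#' print.  A weight vector generalizes the three terms;
#' \eqn{Dev^2 = 3\sum_j w_j t_j^2} with \eqn{\sum w_j = 1}, so equal weights
#' reproduce the unweighted form.
#'
#' @param geom a [geometry_features()] with `r1`, `r2` filled and `cx`, `cy`
#'   in the target frame described above.
#' @param r_ratio_target design outer/inner radius ratio (default 1.34 for
#'   the 4-cylinder object).
#' @param weights non-negative 3-vector, normalized to sum 1.
#' @return An object of class `fidelity_metrics`: `r_ratio`, `c_sym`
#'   (`Cx/Cy`), `c_bar_rel` (`Cbar/R2 - 1`), `r_ratio_target`, `weights`,
#'   `dev` (`NA` with `undefined = TRUE` when `r1 = 0`).
#' @export
dev_metric <- function(geom, r_ratio_target = 1.34,
                       weights = rep(1, 3) / 3) {
  stopifnot(inherits(geom, "geometry_features"))
  if (length(weights) != 3 || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be 3 non-negative values")
  w <- weights / sum(weights)
  if (!is.finite(geom$r2) || geom$r2 <= 0)
    stop("geom$r2 must be positive; run annulus_radii first")
  if (!is.finite(geom$r1) || geom$r1 <= 0) {
    return(structure(list(r_ratio = NA_real_, c_sym = geom$cx / geom$cy,
                          c_bar_rel = (geom$cx + geom$cy) / 2 / geom$r2 - 1,
                          r_ratio_target = r_ratio_target, weights = w,
                          dev = NA_real_, undefined = TRUE),
                     class = "fidelity_metrics"))
  }
  t1 <- geom$r2 / geom$r1 - r_ratio_target
  t2 <- geom$cx / geom$cy - 1
  t3 <- (geom$cx + geom$cy) / 2 / geom$r2 - 1
  dev <- sqrt(3 * sum(w * c(t1, t2, t3)^2))
  structure(list(r_ratio = geom$r2 / geom$r1, c_sym = geom$cx / geom$cy,
                 c_bar_rel = t3, r_ratio_target = r_ratio_target,
                 weights = w, dev = dev, undefined = FALSE),
            class = "fidelity_metrics")
}

#' @export
print.fidelity_metrics <- function(x, ...) {
  cat(sprintf(
    "Fidelity: R2/R1 = %.3f (target %.2f), Cx/Cy = %.3f, Cbar/R2-1 = %+.3f\n",
    x$r_ratio, x$r_ratio_target, x$c_sym, x$c_bar_rel))
  cat(sprintf("  Dev = %s\n",
              if (isTRUE(x$undefined)) "undefined (R1 = 0)"
              else sprintf("%.4f", x$dev)))
  invisible(x)
}

#' Entropy weights for the deviation terms
#'
#' Objective criterion weighting by the entropy weight method: each column
#' of the ink x criterion matrix is normalized to proportions
#' \eqn{p_{ij}}, its Shannon entropy \eqn{e_j = -\frac{1}{\ln n}\sum_i
#' p_{ij}\ln p_{ij}} (with \eqn{0\ln 0 = 0}) is computed, and the weights
#' are the normalized information contents \eqn{w_j = (1-e_j)/\sum_k(1-e_k)}.
#' A constant column carries no information and receives weight 0; an
#' all-zero column is treated as fully entropic (weight 0).
#'
#' @param mat numeric matrix (>= 2 rows, non-negative) of per-ink deviation
#'   terms, one column per criterion.
#' @return weight vector summing to 1 (equal weights when no column carries
#'   information).
#' @export
entropy_weights <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2) stop("entropy weights need at least 2 rows")
  if (any(mat < 0)) stop("entries must be non-negative")
  e <- apply(mat, 2, function(col) {
    s <- sum(col)
    if (s == 0) return(1)
    p <- col / s
    p <- p[p > 0]
    -sum(p * log(p)) / log(n)
  })
  info <- 1 - e
  info[info < 0] <- 0   # guard tiny negative rounding
  if (sum(info) == 0) return(rep(1, ncol(mat)) / ncol(mat))
  info / sum(info)
}
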