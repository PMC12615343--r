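#' Analyze a top-view photograph of a printed object
#'
#' Runs the full image pipeline in order: HSV segmentation
#' ([hsv_segment()]), mask cleaning and centering ([clean_and_center()]),
#' crop / illumination correction / 4-fold symmetry averaging
#' ([crop_correct_average()]), quarter binarization ([binarize_quarter()]),
#' method-of-moments geometry ([image_moments()]), annulus-radius recovery
#' ([annulus_radii()]) and the deviation metric ([dev_metric()]).  A failure
#' in any stage raises an error naming that stage.
#'
#' The measured quarter centroid is re-expressed in the design frame whose
#' origin is the quarter corner adjacent to the object center, so that a
#' perfect print has centroid `(R2, R2)`.
#'
#' @param image RGB array `[rows, cols, 3]`, values in `[0, 1]`.
#' @param spec a [filter_spec()] for the ink class.
#' @param config a [pipeline_config()].
#' @param r_ratio_target design radius ratio (default 1.34).
#' @param weights weight vector for [dev_metric()].
#' @return list with `geometry` (a [image_moments()] record with `r1`, `r2`
#'   filled; centroid in the design frame, raw quarter centroid in
#'   `cx_px`/`cy_px`), `fidelity` (a [dev_metric()] record) and
#'   `diagnostics` (stage statistics: mask pixel counts, center, clamping).
#' @export
analyze_image <- function(image, spec, config = pipeline_config(),
                          r_ratio_target = 1.34, weights = rep(1, 3) / 3) {
  seg <- hsv_segment(image, spec)
  cen <- clean_and_center(seg$c_mask, config)
  quarter <- crop_correct_average(seg$c_filter, cen$center, seg$s_mask,
                                  config)
  bin <- binarize_quarter(quarter, config$binarize_factor)
  f <- if (config$grayscale_moments) quarter * bin else bin
  geom <- image_moments(f)
  rad <- annulus_radii(geom$area, geom$inertia)
  geom$r1 <- rad$r1
  geom$r2 <- rad$r2

  ## design frame: origin at the quarter corner facing the object center,
  ## axes pointing into the quarter; pixel centers at integers so the corner
  ## boundary sits at Lq - 0.5
  Lq <- config$crop_size / 2
  flip_x <- config$quadrant %in% c("topleft", "bottomleft")
  flip_y <- config$quadrant %in% c("topleft", "topright")
  geom$cx_px <- geom$cx
  geom$cy_px <- geom$cy
  geom$cx <- if (flip_x) (Lq - 0.5) - geom$cx_px else geom$cx_px + 0.5
  geom$cy <- if (flip_y) (Lq - 0.5) - geom$cy_px else geom$cy_px + 0.5

  fid <- dev_metric(geom, r_ratio_target = r_ratio_target, weights = weights)
  diagnostics <- list(mask_counts = seg$counts, center = cen$center,
                      quarter_mean = mean(quarter),
                      quarter_set_px = sum(bin), r1_clamped = rad$clamped)
  if (!is.null(config$mm_per_px)) {
    geom$r1_mm <- geom$r1 * config$mm_per_px
    geom$r2_mm <- geom$r2 * config$mm_per_px
  }
  list(geometry = geom, fidelity = fid, diagnostics = diagnostics)
}

#' Read / write raster images
#'
#' `read_image()` reads a PNG (via the png package) or other formats via
#' EBImage, returning an RGB array `[rows, cols, 3]` in `[0, 1]`.
#' `write_mask_png()` writes a binary or grayscale matrix as PNG.
#'
#' @param path file path.
#' @return `read_image()`: RGB array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else {
    eb <- EBImage::readImage(path)
    img <- aperm(EBImage::imageData(eb), c(2, 1, 3))
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image
#' @param mask numeric matrix in `[0, 1]` (values are clipped).
#' @export
write_mask_png <- function(mask, path) {
  m <- pmin(pmax(as.matrix(mask), 0), 1)
  png::writePNG(m, path)
  invisible(path)
}

#' Write an image-analysis record as JSON
#'
#' @param result an [analyze_image()] result.
#' @param path output path.
#' @export
write_features_json <- function(result, path) {
  rec <- list(geometry = unclass(result$geometry),
              fidelity = unclass(result$fidelity),
              diagnostics = result$diagnostics)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
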