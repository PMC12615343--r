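#' HSV filter specification for ink segmentation
#'
#' Two pure predicates over the HSV channels of a top-view photograph.  The
#' S-rule ("shape") selects the whole printed object (cylinder walls plus
#' interiors); the C-rule ("cylinder") selects only the cylinder walls.
#' Channels use the OpenCV convention by default: H in 0-180 half-degree
#' units, S and V in 0-255.  If `hue_convention = "degrees"` the rules are
#' written for H in 0-360 and hue is halved at ingest.
#'
#' The shipped default is the dough-class rule set:
#' S-rule `(80 < H & H < 120) | S > 25`;
#' C-rule `H > 90 & S < 130 & V > 100`.
#' Thresholds for other ink classes depend on the photographed material and
#' should be tuned per dataset (see [filter_spec_from_yaml()]).
#'
#' @param s_rule,c_rule functions of `(h, s, v)` (numeric vectors in the
#'   declared convention) returning a logical vector.
#' @param hue_convention `"opencv"` (0-180) or `"degrees"` (0-360).
#' @return An object of class `filter_spec`.
#' @examples
#' fs <- dough_filter_spec()
#' fs$c_rule(100, 80, 180)  # TRUE: wall-colored pixel
#' @export
filter_spec <- function(s_rule, c_rule, hue_convention = c("opencv", "degrees")) {
  hue_convention <- match.arg(hue_convention)
  stopifnot(is.function(s_rule), is.function(c_rule))
  structure(list(s_rule = s_rule, c_rule = c_rule,
                 hue_convention = hue_convention),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @export
dough_filter_spec <- function() {
  filter_spec(
    s_rule = function(h, s, v) (h > 80 & h < 120) | s > 25,
    c_rule = function(h, s, v) h > 90 & s < 130 & v > 100,
    hue_convention = "opencv")
}

#' Build a filter spec from a YAML rule file
#'
#' The YAML holds the two rules as R logical expressions over `H`, `S`, `V`,
#' e.g. `c_filter: "H > 90 & S < 130 & V > 100"`, plus an optional
#' `hue_convention` key.  Expressions are evaluated in a sealed environment
#' containing only the three channel vectors and arithmetic/logical
#' operators.
#'
#' @param path YAML file with keys `s_filter`, `c_filter`, optionally
#'   `hue_convention`.
#' @return A [filter_spec()].
#' @export
filter_spec_from_yaml <- function(path) {
  .filter_spec_from_list(yaml::read_yaml(path))
}

.filter_spec_from_list <- function(y) {
  if (is.null(y$s_filter) || is.null(y$c_filter))
    stop("YAML filter spec needs 's_filter' and 'c_filter' keys")
  mk <- function(txt) {
    expr <- parse(text = txt)[[1]]
    function(h, s, v) {
      env <- new.env(parent = baseenv())
      assign("H", h, env); assign("S", s, env); assign("V", v, env)
      as.logical(eval(expr, env))
    }
  }
  filter_spec(mk(y$s_filter), mk(y$c_filter),
              hue_convention = y$hue_convention %||% "opencv")
}

## RGB array [h, w, 3] in [0,1] -> list of H (0-180), S, V (0-255) matrices
.rgb_to_hsv_cv <- function(image) {
  d <- dim(image)
  hsv <- grDevices::rgb2hsv(r = as.vector(image[, , 1]),
                            g = as.vector(image[, , 2]),
                            b = as.vector(image[, , 3]),
                            maxColorValue = 1)
  list(h = matrix(hsv[1, ] * 180, d[1], d[2]),
       s = matrix(hsv[2, ] * 255, d[1], d[2]),
       v = matrix(hsv[3, ] * 255, d[1], d[2]))
}

#' Segment a top-view photograph into shape and cylinder masks
#'
#' Converts the image to HSV and applies the two [filter_spec()] rules.
#' `s_mask` flags the whole object, `c_mask` the cylinder walls, and
#' `c_filter` carries the saturation-channel value where the C-rule holds
#' (0 elsewhere), which is the grayscale image the downstream geometry is
#' measured on.
#'
#' @param image RGB array `[rows, cols, 3]` with values in `[0, 1]` (as read
#'   by [read_image()]).
#' @param spec a [filter_spec()].
#' @return list with binary matrices `s_mask`, `c_mask` (values 0/1), the
#'   grayscale matrix `c_filter`, and `counts` (pixels passing each rule).
#' @export
hsv_segment <- function(image, spec) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop_stage("segmentation", "image must be a 3-channel color raster")
  stopifnot(inherits(spec, "filter_spec"))
  ch <- .rgb_to_hsv_cv(image[, , 1:3, drop = FALSE])
  ## rules written for 0-360 hue see degrees; the stored channel is 0-180
  hh <- if (spec$hue_convention == "degrees") ch$h * 2 else ch$h
  s_mask <- spec$s_rule(hh, ch$s, ch$v)
  c_mask <- spec$c_rule(hh, ch$s, ch$v)
  s_mask[is.na(s_mask)] <- FALSE
  c_mask[is.na(c_mask)] <- FALSE
  counts <- c(s = sum(s_mask), c = sum(c_mask),
              total = length(s_mask))
  if (counts["c"] == 0 || counts["s"] == 0)
    stop_stage("segmentation",
               sprintf("empty mask (S-rule: %d px, C-rule: %d px of %d)",
                       counts["s"], counts["c"], counts["total"]))
  dmat <- function(x) matrix(as.numeric(x), nrow(ch$s), ncol(ch$s))
  list(s_mask = dmat(s_mask), c_mask = dmat(c_mask),
       c_filter = ch$s * dmat(c_mask), counts = counts)
}

#' Clean a cylinder mask and find the object center
#'
#' Removes small blobs by binary erosion followed by dilation (square
#' structuring element), flood-fills the background from an image corner,
#' and inverts the filled mask: what remains are the enclosed interiors of
#' the printed cylinders, whose centroid is a robust estimate of the object
#' center (outside blobs that survive the morphology are absorbed by the
#' flood fill).
#'
#' @param c_mask binary matrix (0/1) of cylinder-wall pixels.
#' @param config a [pipeline_config()].
#' @return list with `center` (0-based `c(x, y)` pixel coordinates, x =
#'   column, y = row), `cleaned_mask` (after morphology) and `interior`
#'   (the inverted flood-filled mask whose centroid is `center`).
#' @export
clean_and_center <- function(c_mask, config = pipeline_config()) {
  if (sum(c_mask) == 0) stop_stage("centering", "empty cylinder mask")
  brush <- EBImage::makeBrush(config$erosion_kernel, shape = "box")
  m <- c_mask
  for (i in seq_len(config$erosion_iter)) m <- EBImage::erode(m, brush)
  for (i in seq_len(config$erosion_iter)) m <- EBImage::dilate(m, brush)
  m <- round(m)
  if (sum(m) == 0)
    stop_stage("centering", "mask vanished during erosion/dilation")

  nr <- nrow(m); nc <- ncol(m)
  corners <- list(c(1, 1), c(nr, 1), c(1, nc), c(nr, nc))
  seed <- NULL
  for (cn in corners) if (m[cn[1], cn[2]] == 0) { seed <- cn; break }
  if (is.null(seed))
    stop_stage("centering", "mask occupies all four corners; no background seed")
  ## EBImage images index as [x, y]; our matrices are [row, col] so the
  ## seed maps to pts = (row, col).  Box brushes and corner seeds are
  ## orientation-agnostic.
  filled <- EBImage::imageData(
    EBImage::floodFill(EBImage::Image(m), pts = c(seed[1], seed[2]), col = 1))
  interior <- 1 - filled
  if (sum(interior) == 0)
    stop_stage("centering", "no enclosed interior found after flood fill")
  idx <- which(interior == 1, arr.ind = TRUE)
  center <- c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
  list(center = center, cleaned_mask = m, interior = interior)
}
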