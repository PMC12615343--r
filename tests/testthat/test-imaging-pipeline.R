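## helper: paint an RGB image from an HSV (OpenCV-convention) label matrix
paint_hsv <- function(labels, palette) {
  h <- nrow(labels); w <- ncol(labels)
  img <- array(0, c(h, w, 3))
  for (lab in names(palette)) {
    hsv_cv <- palette[[lab]]
    hex <- grDevices::hsv(hsv_cv[1] / 180, hsv_cv[2] / 255, hsv_cv[3] / 255)
    rgb <- as.numeric(grDevices::col2rgb(hex)) / 255
    sel <- labels == lab
    for (ch in 1:3) { m <- img[, , ch]; m[sel] <- rgb[ch]; img[, , ch] <- m }
  }
  img
}

test_that("segmentation recovers a constructed-to-pass annulus exactly", {
  lab <- matrix("bg", 200, 200)
  ring <- render_annulus_mask(40, 60, 200)
  lab[ring == 1] <- "wall"
  img <- paint_hsv(lab, list(wall = c(100, 80, 180), bg = c(20, 15, 60)))
  seg <- hsv_segment(img, dough_filter_spec())
  expect_identical(seg$c_mask, ring)
  expect_identical(seg$s_mask, ring)   # wall passes the S-rule too
  # c_filter carries the saturation value (80) on the ring, 0 elsewhere
  expect_true(all(abs(seg$c_filter[ring == 1] - 80) < 1))
  expect_true(all(seg$c_filter[ring == 0] == 0))
})

test_that("segmentation fails loudly on an object-free image", {
  img <- paint_hsv(matrix("bg", 50, 50), list(bg = c(20, 15, 60)))
  expect_error(hsv_segment(img, dough_filter_spec()),
               "\\[segmentation\\] empty mask")
  expect_error(analyze_image(img, dough_filter_spec()), "segmentation")
})

test_that("segmented pixel count agrees with the renderer's own count", {
  r <- render_topview(small_render_spec())
  seg <- hsv_segment(r$image, dough_filter_spec())
  expect_lt(abs(sum(seg$c_mask) / r$truth$wall_px - 1), 0.01)
})

test_that("cleaning removes small blobs and centers on the cylinder interiors", {
  r <- render_topview(small_render_spec(blob_count = 10, blob_size = 3,
                                        seed = 5))
  seg <- hsv_segment(r$image, dough_filter_spec())
  cen <- clean_and_center(seg$c_mask, small_pipeline_config())
  mid <- r$spec$image_size / 2 - 0.5
  expect_lt(abs(cen$center[["x"]] - mid), 0.5)
  expect_lt(abs(cen$center[["y"]] - mid), 0.5)
  # the blob-free render centers at the same point
  r0 <- render_topview(small_render_spec())
  cen0 <- clean_and_center(hsv_segment(r0$image,
                                       dough_filter_spec())$c_mask,
                           small_pipeline_config())
  expect_lt(abs(cen$center[["x"]] - cen0$center[["x"]]), 0.5)
  expect_lt(abs(cen$center[["y"]] - cen0$center[["y"]]), 0.5)
  # no background seed -> failure
  expect_error(clean_and_center(matrix(1, 60, 60)), "corner")
})

test_that("a 4-fold symmetric crop is a fixed point of the averaging step", {
  L <- 460
  withr::with_seed(8, m <- matrix(runif(L * L), L, L))
  sym <- (m + rheoprint:::rot90(m) + rheoprint:::rot90(rheoprint:::rot90(m)) +
            rheoprint:::rot90(rheoprint:::rot90(rheoprint:::rot90(m)))) / 4
  canvas <- matrix(0, 600, 600)
  canvas[72:531, 72:531] <- sym
  q <- crop_correct_average(canvas, c(x = 300, y = 300),
                            matrix(1, 600, 600), small_pipeline_config())
  avg <- attr(q, "averaged_crop")
  expect_identical(avg, sym / mean(sym))     # invariance, max abs diff 0
  # constant image: mean-division makes every pixel 1 regardless of level
  q2 <- crop_correct_average(matrix(7.3, 600, 600), c(x = 300, y = 300),
                             matrix(1, 600, 600), small_pipeline_config())
  expect_true(all(attr(q2, "averaged_crop") == 1))
  # zero crop fails
  expect_error(crop_correct_average(matrix(0, 600, 600),
                                    c(x = 300, y = 300),
                                    matrix(1, 600, 600),
                                    small_pipeline_config()),
               "zero mean")
})

test_that("the averaged crop is always exactly 4-fold rotation symmetric", {
  r <- render_topview(small_render_spec(widening = 0.08, asymmetry = 0.03,
                                        illum_gradient = 0.1))
  seg <- hsv_segment(r$image, dough_filter_spec())
  cen <- clean_and_center(seg$c_mask, small_pipeline_config())
  q <- crop_correct_average(seg$c_filter, cen$center, seg$s_mask,
                            small_pipeline_config())
  avg <- attr(q, "averaged_crop")
  expect_lt(max(abs(avg - rheoprint:::rot90(avg))), 1e-12)
})

test_that("the full pipeline measures an ideal print as near-perfect", {
  r <- render_topview(small_render_spec(illum_gradient = 0.05))
  res <- analyze_image(r$image, dough_filter_spec(),
                       small_pipeline_config())
  # rasterization error scales with 1/R; the small fixture (R2 = 110 px)
  # is a little coarser than the full-size one
  expect_lt(res$fidelity$dev, 0.03)
  expect_lt(abs(res$geometry$r1 / r$truth$r1 - 1), 0.01)
  expect_lt(abs(res$geometry$r2 / r$truth$r2 - 1), 0.01)
  # centroid hits the (R2, R2) design target within a pixel
  expect_lt(abs(res$geometry$cx - res$geometry$r2), 1)
  expect_lt(abs(res$geometry$cy - res$geometry$r2), 1)
  expect_equal(res$fidelity$c_sym, 1, tolerance = 5e-3)
  expect_false(res$diagnostics$r1_clamped)
})

test_that("symmetry averaging suppresses the Cx/Cy term for asymmetric objects", {
  # the 4-rotation average superimposes the x- and y-displaced rings, so
  # the binarized quarter is symmetric about the diagonal and Cx/Cy ~ 1
  # even when the drawn object is not; the distortion still raises Dev
  # through the radius-ratio and centering terms
  r <- render_topview(small_render_spec(asymmetry = 0.05))
  res <- analyze_image(r$image, dough_filter_spec(),
                       small_pipeline_config())
  expect_equal(res$fidelity$c_sym, 1, tolerance = 0.01)
  expect_gt(res$fidelity$dev, 0.03)
})
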