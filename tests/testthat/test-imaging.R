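# A single-spot frame rendered with the package's own forward model: one
# symmetric Gaussian of width psf_sigma at a subpixel position, over a
# constant background, with optional seeded Poisson shot noise.
render_single_spot <- function(ax_px, lat_px, amplitude = 2000,
                               background = 100, shot_noise = FALSE,
                               seed = 1, side = 40) {
  img <- wallmark:::render_fluor_frame(side, side, 0.052, ax_px * 0.052,
                                       lat_px * 0.052, 0.10, amplitude,
                                       background)
  if (shot_noise) {
    set.seed(seed)
    img <- matrix(stats::rpois(length(img), img), side, side)
  }
  img
}

test_that("bicubic upsampling is an exact linear-reproducing interpolant", {
  # Catmull-Rom reproduces affine functions exactly away from the clamped edge
  m <- outer(1:20, 1:30, function(r, c) 2 * r + 3 * c)
  up <- wallmark:::bicubic_upsample(m, 4L)
  expect_equal(dim(up$img), c(80, 120))
  interior <- up$row_coords >= 1 & up$row_coords <= 18
  interiorc <- up$col_coords >= 1 & up$col_coords <= 28
  pred <- outer(up$row_coords[interior] + 1, up$col_coords[interiorc] + 1,
                function(r, c) 2 * r + 3 * c)
  expect_equal(up$img[interior, interiorc], pred, tolerance = 1e-12)
  # output coordinates convert back exactly to input pixel space
  expect_equal(up$row_coords[1], (1 - 0.5) / 4 - 0.5)
})

test_that("spot localization is exact without noise and subpixel with it", {
  set.seed(61)
  pos <- cbind(15 + runif(20, 0, 10), 15 + runif(20, 0, 10))
  err0 <- vapply(1:20, function(i) {
    sp <- detect_spots(render_single_spot(pos[i, 1], pos[i, 2]))
    sqrt((sp$x_px[1] - pos[i, 1])^2 + (sp$y_px[1] - pos[i, 2])^2)
  }, 0)
  expect_lt(max(err0), 1e-6)
  # fitted width and background recover the forward model
  sp <- detect_spots(render_single_spot(20.3, 17.7))
  expect_equal(sp$sigma_px[1], 0.10 / 0.052, tolerance = 1e-3)
  expect_equal(sp$background[1], 100, tolerance = 1e-2)
})

test_that("width and amplitude gates and border clipping reject bad fits", {
  img <- render_single_spot(20, 20)
  # a detection hugging the border is clipped and dropped by default
  img_b <- render_single_spot(2, 2)
  expect_equal(nrow(detect_spots(img_b)), 0)
  p <- spot_params(keep_clipped = TRUE)
  kept <- detect_spots(img_b, p)
  expect_equal(nrow(kept), 1)
  expect_true(kept$clipped)
  # an implausibly narrow width bound rejects the true PSF
  p2 <- spot_params(width_bounds = c(0.1, 0.5))
  expect_equal(nrow(detect_spots(img, p2)), 0)
  # an empty frame yields a typed empty table
  none <- detect_spots(matrix(100, 40, 40))
  expect_equal(nrow(none), 0)
  expect_true(all(c("x_px", "y_px", "sigma_px") %in% names(none)))
})

test_that("segmentation recovers a rendered rod to subpixel accuracy", {
  body <- wallmark:::render_body_frame(45, 112, 0.052, 2.9, 1.14, 3.2, 1.06)
  contour <- segment_cell(body)
  g <- compute_midline(contour, pixel_size = 0.052)
  expect_true(g$is_rod)
  expect_equal(g$length_um, 3.2, tolerance = 0.02)      # within 2%
  expect_equal(g$diameter_um, 1.06, tolerance = 0.02)
  # pole tips sit at the spherocylinder ends (x is the axial/column axis)
  tipdist <- abs(diff(range(g$midline$x))) * 0.052
  expect_equal(tipdist, 3.2, tolerance = 0.05)
})

test_that("segmentation refuses frames containing two comparable cells", {
  one <- wallmark:::render_body_frame(45, 112, 0.052, 1.5, 1.14, 2.0, 1.0)
  two <- wallmark:::render_body_frame(45, 112, 0.052, 4.3, 1.14, 2.0, 1.0)
  img <- pmin(one, two)
  expect_error(segment_cell(img), "cell")
})

test_that("image-frame spots map into cell coordinates consistently", {
  cfg <- sim_preset("LB", n_motors = 5, rng_seed = 67)
  cfg$render$shot_noise <- FALSE
  cell <- simulate_elongation(cfg)
  # controlled placement: mutually resolvable spots (merged detections would
  # make the nearest-truth matching below ambiguous)
  cell$motors$type <- c("active", "active", "active", "active", "inert")
  cell$motors$N <- c(-0.4, -0.15, 0.1, 0.35, NA)
  cell$motors$P_y <- c(NA, NA, NA, NA, 0.1)
  cell$motors$side <- c(-1, -1, 1, 1, 1)
  cell$motors$x_um <- c(0.2, -0.3, 0.4, 0, -0.2)
  cell <- simulate_elongation(cfg, cell)
  ren <- render_frames(cell, cfg)
  px <- cfg$render$pixel_size
  g <- compute_midline(segment_cell(ren$body[[1]]), pixel_size = px)
  sp <- detect_spots(ren$fluor[[1]])
  cc <- map_to_cell_coords(sp$x_px, sp$y_px, g)
  tr <- cell$truth[cell$truth$frame == 1, ]
  meta <- ren$meta[1, ]
  # match detections to truth in pixel space, then compare cell coordinates
  tax <- (tr$y_um + meta$axial_center_um) / px
  tlat <- (tr$x_um + meta$lateral_center_um) / px
  for (k in seq_len(nrow(sp))) {
    i <- which.min((sp$x_px[k] - tax)^2 + (sp$y_px[k] - tlat)^2)
    # the sign of the axial/lateral axes is arbitrary (pole ordering), the
    # magnitudes and the pole distance are not
    expect_equal(abs(cc$y_um[k]), abs(tr$y_um[i]), tolerance = 0.03)
    expect_equal(abs(cc$x_um[k]), abs(tr$x_um[i]), tolerance = 0.03)
    expect_equal(cc$P_y_um[k], tr$P_y_um[i], tolerance = 0.03)
  }
})

test_that("pole identity stays consistent across frames after alignment", {
  cfg <- sim_preset("LB", n_motors = 3, rng_seed = 71)
  cfg$render$shot_noise <- FALSE
  cell <- simulate_elongation(cfg, n_frames = 4)
  ren <- render_frames(cell, cfg)
  geoms <- align_geometries(lapply(ren$body, function(b) {
    compute_midline(segment_cell(b), pixel_size = cfg$render$pixel_size)
  }))
  for (i in 2:4) {
    d_same <- sum((geoms[[i]]$poles[1, ] - geoms[[i - 1]]$poles[1, ])^2)
    d_flip <- sum((geoms[[i]]$poles[2, ] - geoms[[i - 1]]$poles[1, ])^2)
    expect_lt(d_same, d_flip)
  }
})

test_that("division onset is detected from the rendered waist", {
  cfg <- sim_preset("LB", n_motors = 4, rng_seed = 5, n_frames = 8)
  cell <- simulate_elongation(cfg)
  res <- simulate_division(cell, cfg)
  ren <- render_frames(res$cell, cfg)
  geoms <- lapply(ren$body, function(b) {
    compute_midline(segment_cell(b), pixel_size = cfg$render$pixel_size)
  })
  dd <- detect_division(geoms, times = res$cell$frames$time_min)
  truth_onset <- min(which(res$cell$frames$phase == "division"))
  expect_equal(dd$onset_frame, truth_onset)
  expect_true(all(dd$phase[res$cell$frames$phase == "division"] == "division"))
  expect_true(all(dd$depth_um[seq_len(truth_onset - 1)] < 0.05))
  # a pure elongation movie reports no onset
  ren0 <- render_frames(cell, cfg)
  geoms0 <- lapply(ren0$body, function(b) {
    compute_midline(segment_cell(b), pixel_size = cfg$render$pixel_size)
  })
  dd0 <- detect_division(geoms0, times = cell$frames$time_min)
  expect_true(is.na(dd0$onset_frame))
  expect_true(all(dd0$phase == "elongation"))
})

test_that("TIFF stacks round-trip within 16-bit quantization", {
  cfg <- sim_preset("LB", n_motors = 3, rng_seed = 73, n_frames = 2)
  cell <- simulate_elongation(cfg)
  ren <- render_frames(cell, cfg)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(ren$fluor, path)
  back <- read_image_stack(path)
  expect_length(back, 2)
  expect_lt(max(abs(back[[1]] - ren$fluor[[1]])), 1)   # unit photon resolution
})

test_that("rendering uses the documented pixel convention and seeded noise", {
  # a spot at lab coordinate 3.000 um with 52 nm pixels is centred at pixel
  # 3.000 / 0.052 = 57.69...
  img <- wallmark:::render_fluor_frame(45, 112, 0.052, 3.0, 1.14, 0.10, 2000,
                                       100)
  sp <- detect_spots(img)
  expect_equal(sp$x_px[1], 3.0 / 0.052, tolerance = 1e-6)
  # shot noise is reproducible through the named substream
  cfg <- sim_preset("LB", n_motors = 3, rng_seed = 79, n_frames = 2)
  cell <- simulate_elongation(cfg)
  r1 <- render_frames(cell, cfg)
  r2 <- render_frames(cell, cfg)
  expect_identical(r1$fluor, r2$fluor)
})
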