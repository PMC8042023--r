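# Rendering of synthetic image stacks: the cell body as a filled
# spherocylinder (dark interior on a light background, phase-contrast-like)
# and the fluorescence channel as a sum of symmetric 2D Gaussian spots over a
# constant background with optional Poisson shot noise.
#
# Pixel convention: 0-based indices, pixel centre i at lab coordinate
# i * pixel_size (so a motor at lab 3.000 um with 52 nm pixels is centred at
# pixel 57.69). Matrices are [row = lateral, column = axial].

# Lab-frame placement: the founding cell's lower pole tip is anchored at
# axial = margin; the cell grows toward increasing axial coordinate.
lab_frame_offsets <- function(cell_length_um, margin) {
  list(axial0 = margin + cell_length_um / 2, lateral_center = NA_real_)
}

render_body_frame <- function(nrow_px, ncol_px, pixel_size, axial_center,
                              lateral_center, cell_length, diameter,
                              waist_depth = 0, waist_sigma = 0.15,
                              fg = 0.25, bg = 0.85) {
  R <- diameter / 2
  ax <- (seq_len(ncol_px) - 1) * pixel_size
  lat <- (seq_len(nrow_px) - 1) * pixel_size
  a1 <- axial_center - cell_length / 2 + R
  a2 <- axial_center + cell_length / 2 - R
  AX <- matrix(ax, nrow_px, ncol_px, byrow = TRUE)
  LAT <- matrix(lat, nrow_px, ncol_px)
  axc <- pmin(pmax(AX, a1), a2)
  r_local <- R - waist_depth * exp(-((AX - axial_center) / waist_sigma)^2)
  d <- sqrt((AX - axc)^2 + (LAT - lateral_center)^2) - r_local
  cov <- pmin(pmax(0.5 - d / pixel_size, 0), 1)   # anti-aliased edge
  bg + (fg - bg) * cov
}

render_fluor_frame <- function(nrow_px, ncol_px, pixel_size, spots_ax,
                               spots_lat, psf_sigma, photon_count,
                               background) {
  img <- matrix(background, nrow_px, ncol_px)
  if (length(spots_ax)) {
    s_px <- psf_sigma / pixel_size
    ax <- (seq_len(ncol_px) - 1)
    lat <- (seq_len(nrow_px) - 1)
    for (k in seq_along(spots_ax)) {
      cx <- spots_ax[k] / pixel_size
      cy <- spots_lat[k] / pixel_size
      gx <- exp(-(ax - cx)^2 / (2 * s_px^2))
      gy <- exp(-(lat - cy)^2 / (2 * s_px^2))
      img <- img + photon_count * outer(gy, gx)
    }
  }
  img
}

#' Render synthetic fluorescence and cell-body image stacks
#'
#' Produces, for every frame of a simulated cell, a fluorescence frame (sum of
#' symmetric 2D Gaussian point-spread functions at the motor positions, scaled
#' by the expected peak photon count, over a constant background, with seeded
#' Poisson shot noise) and a matched cell-body frame (anti-aliased filled
#' spherocylinder, dark on light; during division a mid-cell waist of depth
#' proportional to septal progress). Pixel centres sit at integer 0-based
#' coordinates, `pixel_size` micrometres apart.
#'
#' @param cell A simulated `wm_cell` (after [simulate_elongation()] and
#'   optionally [simulate_division()]).
#' @param config The `wm_sim_config`; rendering options under `config$render`.
#' @return List with `fluor` and `body` (lists of matrices, photons and
#'   normalized intensity respectively), `meta` (per-frame data frame with the
#'   lab-frame axial offset of the cell centre), `pixel_size`.
#' @export
render_frames <- function(cell, config = cell$config) {
  stopifnot(!is.null(cell$frames))
  r <- config$render
  px <- r$pixel_size
  margin <- r$margin
  max_len <- max(cell$frames$cell_length_um)
  ncol_px <- as.integer(ceiling((max_len + 2 * margin) / px)) + 1L
  nrow_px <- as.integer(ceiling((config$diameter_D + 2 * margin) / px)) + 1L
  lateral_center <- (nrow_px - 1) / 2 * px

  fluor <- vector("list", nrow(cell$frames))
  body <- vector("list", nrow(cell$frames))
  meta <- cell$frames
  meta$axial_center_um <- margin + meta$cell_length_um / 2
  meta$lateral_center_um <- lateral_center
  for (i in seq_len(nrow(cell$frames))) {
    fr <- cell$frames$frame[i]
    tl <- cell$frames$cell_length_um[i]
    axc <- meta$axial_center_um[i]
    waist <- 0
    if (identical(cell$frames$phase[i], "division")) {
      prog <- cell$frames$septal_offset_um[i] / config$cap_size_c
      waist <- 0.45 * (config$diameter_D / 2) * prog
    }
    body[[i]] <- render_body_frame(nrow_px, ncol_px, px, axc, lateral_center,
                                   tl, config$diameter_D, waist_depth = waist)
    tr <- cell$truth[cell$truth$frame == fr, , drop = FALSE]
    img <- render_fluor_frame(nrow_px, ncol_px, px,
                              spots_ax = tr$y_um + axc,
                              spots_lat = tr$x_um + lateral_center,
                              psf_sigma = r$psf_sigma,
                              photon_count = r$photon_count,
                              background = r$background)
    if (isTRUE(r$shot_noise)) {
      img <- with_substream(config$rng_seed,
                            sprintf("shot:%s:%d", cell$cell_id, fr), {
        matrix(stats::rpois(length(img), img), nrow(img), ncol(img))
      })
    }
    fluor[[i]] <- img
  }
  list(fluor = fluor, body = body, meta = meta, pixel_size = px)
}

# Photon-count scale used when writing 16-bit TIFF stacks.
WM_TIFF_SCALE <- 65535

#' Write a multi-frame image stack to TIFF
#'
#' Frames (matrices of photon counts or normalized intensities) are scaled by
#' `scale` into `[0, 1]` and written as a 16-bit multi-frame TIFF.
#'
#' @param frames List of numeric matrices.
#' @param path Output path.
#' @param scale Values are divided by this before writing (default 65535,
#'   i.e. unit photon resolution); clipped to `[0, 1]`.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(frames, path, scale = WM_TIFF_SCALE) {
  stopifnot(is.list(frames), length(frames) >= 1)
  imgs <- lapply(frames, function(m) pmin(pmax(m / scale, 0), 1))
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Read a multi-frame image stack from TIFF
#'
#' Inverse of [write_image_stack()]: reads all frames and rescales by
#' `scale`.
#'
#' @param path TIFF path.
#' @param scale Multiplier applied after reading (default 65535).
#' @return List of numeric matrices.
#' @export
read_image_stack <- function(path, scale = WM_TIFF_SCALE) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  lapply(imgs, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * scale
  })
}
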