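# Subpixel spot localization and cell-geometry extraction from image stacks.
# All geometry is computed in (sub)pixel coordinates with 0-based pixel
# centres at integer positions, and converted to micrometres once at output.

#' Parameters for spot detection
#'
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels, used only to
#'   find candidate maxima (the fit runs on the raw image).
#' @param threshold Absolute intensity a local maximum (on the smoothed image)
#'   must exceed; `NULL` uses `median + 6 * mad` of the smoothed frame.
#' @param min_separation Minimum distance between accepted maxima, pixels.
#' @param roi_size Side of the square fitting window, pixels (default 12).
#' @param width_bounds Accepted fitted PSF sigma range, pixels.
#' @param amp_min Minimum fitted amplitude above background.
#' @param keep_clipped Keep detections whose ROI is clipped by the image
#'   border (default `FALSE`: flagged and excluded).
#' @return List of parameters.
#' @export
spot_params <- function(smooth_sigma = 1, threshold = NULL,
                        min_separation = 5, roi_size = 12,
                        width_bounds = c(0.5, 4), amp_min = 0,
                        keep_clipped = FALSE) {
  list(smooth_sigma = smooth_sigma, threshold = threshold,
       min_separation = min_separation, roi_size = as.integer(roi_size),
       width_bounds = width_bounds, amp_min = amp_min,
       keep_clipped = keep_clipped)
}

local_maxima <- function(m, threshold) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  ok <- m >= threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ok <- ok & (m >= pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  which(ok, arr.ind = TRUE)
}

fit_gaussian_spot <- function(roi, x_coords, y_coords, start, width_bounds,
                              amp_min) {
  df <- data.frame(z = as.vector(roi),
                   x = rep(x_coords, each = length(y_coords)),
                   y = rep(y_coords, times = length(x_coords)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- as.list(stats::coef(fit))
  if (co$x0 < min(x_coords) || co$x0 > max(x_coords) ||
      co$y0 < min(y_coords) || co$y0 > max(y_coords)) return(NULL)
  s <- abs(co$s)
  if (s < width_bounds[1] || s > width_bounds[2]) return(NULL)
  if (co$A <= amp_min) return(NULL)
  list(x0 = co$x0, y0 = co$y0, amplitude = co$A, sigma = s,
       background = co$b, rss = sum(stats::resid(fit)^2))
}

#' Detect fluorescent spots in one frame with subpixel accuracy
#'
#' Smooths the frame with a Gaussian filter, takes local intensity maxima
#' above threshold (greedily enforcing a minimum separation, brightest
#' first), crops a `roi_size` x `roi_size` window around each, and fits a
#' symmetric 2D Gaussian with constant offset by nonlinear least squares.
#' Fits whose centre leaves the window, whose width falls outside
#' `width_bounds`, or whose amplitude is not positive are rejected.
#'
#' @param frame Numeric matrix (rows = lateral/y, columns = axial/x).
#' @param params [spot_params()].
#' @return Data frame with one row per accepted spot: `x_px`, `y_px`
#'   (subpixel 0-based centre), `amplitude`, `sigma_px`, `background`, `rss`,
#'   `roi_x0`, `roi_y0`, `clipped`. Empty (zero rows) for a frame with no
#'   detectable spots.
#' @export
detect_spots <- function(frame, params = spot_params()) {
  stopifnot(is.matrix(frame))
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      amplitude = numeric(0), sigma_px = numeric(0),
                      background = numeric(0), rss = numeric(0),
                      roi_x0 = integer(0), roi_y0 = integer(0),
                      clipped = logical(0))
  if (max(frame) == min(frame)) return(empty)
  sm <- as.matrix(EBImage::gblur(frame, sigma = params$smooth_sigma))
  thr <- params$threshold %||%
    (stats::median(sm) + 6 * stats::mad(sm))
  mx <- local_maxima(sm, thr)
  if (nrow(mx) == 0) return(empty)
  o <- order(sm[mx], decreasing = TRUE)
  mx <- mx[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(mx))
  for (i in seq_len(nrow(mx))) {
    if (!keep[i]) next
    if (i < nrow(mx)) {
      j <- (i + 1):nrow(mx)
      d <- sqrt((mx[j, 1] - mx[i, 1])^2 + (mx[j, 2] - mx[i, 2])^2)
      keep[j][d < params$min_separation] <- FALSE
    }
  }
  mx <- mx[keep, , drop = FALSE]

  half <- params$roi_size %/% 2
  rows <- list()
  for (i in seq_len(nrow(mx))) {
    r0 <- mx[i, 1] - half + 1L; r1 <- r0 + params$roi_size - 1L
    c0 <- mx[i, 2] - half + 1L; c1 <- c0 + params$roi_size - 1L
    clipped <- r0 < 1 || c0 < 1 || r1 > nrow(frame) || c1 > ncol(frame)
    if (clipped && !params$keep_clipped) next
    rr <- max(r0, 1):min(r1, nrow(frame))
    cc <- max(c0, 1):min(c1, ncol(frame))
    roi <- frame[rr, cc, drop = FALSE]
    x_coords <- cc - 1; y_coords <- rr - 1   # 0-based pixel centres
    start <- list(b = min(roi), A = max(roi) - min(roi),
                  x0 = mx[i, 2] - 1, y0 = mx[i, 1] - 1, s = 1.5)
    f <- fit_gaussian_spot(roi, x_coords, y_coords, start,
                           params$width_bounds, params$amp_min)
    if (is.null(f)) next
    rows[[length(rows) + 1L]] <- data.frame(
      x_px = f$x0, y_px = f$y0, amplitude = f$amplitude, sigma_px = f$sigma,
      background = f$background, rss = f$rss,
      roi_x0 = cc[1] - 1L, roi_y0 = rr[1] - 1L, clipped = clipped)
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# Separable Catmull-Rom bicubic interpolation of a vector at fractional
# 0-based positions, with edge clamping.
cubic_interp_vec <- function(v, pos) {
  n <- length(v)
  i1 <- floor(pos)
  t <- pos - i1
  idx <- function(k) v[pmin(pmax(i1 + k, 0), n - 1) + 1]
  p0 <- idx(-1); p1 <- idx(0); p2 <- idx(1); p3 <- idx(2)
  0.5 * ((2 * p1) + (-p0 + p2) * t + (2 * p0 - 5 * p1 + 4 * p2 - p3) * t^2 +
           (-p0 + 3 * p1 - 3 * p2 + p3) * t^3)
}

# Catmull-Rom interpolation at fixed positions is a linear map; represent it
# as a (dense but small) weight matrix W so that interp(v, pos) == W %*% v.
cubic_interp_matrix <- function(n, pos) {
  i1 <- floor(pos)
  t <- pos - i1
  w <- cbind(0.5 * (-t + 2 * t^2 - t^3),          # p0 at i1 - 1
             0.5 * (2 - 5 * t^2 + 3 * t^3),       # p1 at i1
             0.5 * (t + 4 * t^2 - 3 * t^3),       # p2 at i1 + 1
             0.5 * (-t^2 + t^3))                  # p3 at i1 + 2
  W <- matrix(0, length(pos), n)
  for (k in 1:4) {
    col <- pmin(pmax(i1 + k - 2L, 0L), n - 1L) + 1L
    W[cbind(seq_along(pos), col)] <- W[cbind(seq_along(pos), col)] + w[, k]
  }
  W
}

# 4x (or `factor`x) bicubic upsampling. Output sample u (0-based) sits at
# input coordinate (u + 0.5) / factor - 0.5, so coordinates convert back
# exactly; returns both the image and the input-space coordinates of its
# rows/columns. Implemented as two matrix products (separable linear map).
bicubic_upsample <- function(m, factor = 4L) {
  rp <- (seq_len(nrow(m) * factor) - 0.5) / factor - 0.5
  cp <- (seq_len(ncol(m) * factor) - 0.5) / factor - 0.5
  Wr <- cubic_interp_matrix(nrow(m), rp)
  Wc <- cubic_interp_matrix(ncol(m), cp)
  out <- Wr %*% m %*% t(Wc)
  list(img = out, row_coords = rp, col_coords = cp)
}

#' Parameters for cell segmentation
#'
#' @param smooth_sigma Gaussian smoothing sigma in (original) pixels.
#' @param upsample Upsampling factor for subpixel contours (default 4,
#'   bicubic).
#' @param polarity `"dark"` for dark cells on a light background (default)
#'   or `"bright"`.
#' @param min_area Minimum component area in upsampled pixels.
#' @return List of parameters.
#' @export
segment_params <- function(smooth_sigma = 1, upsample = 4L,
                           polarity = c("dark", "bright"), min_area = 500) {
  list(smooth_sigma = smooth_sigma, upsample = as.integer(upsample),
       polarity = match.arg(polarity), min_area = min_area)
}

polygon_area <- function(x, y) {
  n <- length(x)
  0.5 * abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y))
}

point_in_polygon <- function(px, py, x, y) {
  n <- length(x); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((y[i] > py) != (y[j] > py) &&
        px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

#' Segment a single cell and extract its subpixel contour
#'
#' Gaussian smoothing, 4x bicubic upsampling, Otsu thresholding, then the
#' subpixel iso-intensity contour at the Otsu level around the largest
#' connected component (holes are irrelevant to the outer contour). Frames
#' containing more than one comparably sized component are rejected with an
#' instruction to crop to a single cell.
#'
#' @param frame Numeric matrix (rows = lateral, cols = axial).
#' @param params [segment_params()].
#' @return Data frame `x, y`: closed contour polyline (first vertex not
#'   repeated), subpixel, in original 0-based pixel coordinates.
#' @export
segment_cell <- function(frame, params = segment_params()) {
  stopifnot(is.matrix(frame))
  rng <- range(frame)
  if (rng[1] == rng[2]) {
    stop("segmentation failed: frame is constant (no cell found)",
         call. = FALSE)
  }
  norm <- (frame - rng[1]) / (rng[2] - rng[1])
  if (params$polarity == "dark") norm <- 1 - norm
  sm <- as.matrix(EBImage::gblur(norm, sigma = params$smooth_sigma))
  up <- bicubic_upsample(sm, params$upsample)
  img <- up$img
  thr <- EBImage::otsu(EBImage::Image(pmin(pmax(img, 0), 1)), range = c(0, 1))
  mask <- img > thr
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- as.matrix(lab)
  sizes <- tabulate(labm[labm > 0])
  big <- which(sizes >= params$min_area)
  if (length(big) == 0) {
    stop("segmentation failed: no component above the minimum area",
         call. = FALSE)
  }
  if (length(big) > 1 && sort(sizes[big], decreasing = TRUE)[2] >
        0.25 * max(sizes)) {
    stop(paste("multiple cells detected in the frame;",
               "crop the image to a single cell before segmentation"),
         call. = FALSE)
  }
  comp <- which.max(sizes)
  cen <- which(labm == comp, arr.ind = TRUE)
  cen_r <- mean(up$row_coords[cen[, 1]])
  cen_c <- mean(up$col_coords[cen[, 2]])

  cl <- grDevices::contourLines(x = up$row_coords, y = up$col_coords,
                                z = img, levels = thr)
  if (!length(cl)) stop("segmentation failed: no contour at threshold",
                        call. = FALSE)
  closed <- vapply(cl, function(p) {
    length(p$x) > 8 &&
      abs(p$x[1] - p$x[length(p$x)]) < 1e-9 &&
      abs(p$y[1] - p$y[length(p$y)]) < 1e-9
  }, TRUE)
  cl <- cl[closed]
  contains <- vapply(cl, function(p) {
    point_in_polygon(cen_r, cen_c, p$x, p$y)
  }, TRUE)
  cl <- cl[contains]
  if (!length(cl)) stop("segmentation failed: no closed contour around cell",
                        call. = FALSE)
  areas <- vapply(cl, function(p) polygon_area(p$x, p$y), 0)
  best <- cl[[which.max(areas)]]
  n <- length(best$x)
  # contourLines x follows rows (lateral), y follows columns (axial)
  data.frame(x = best$y[-n], y = best$x[-n])
}

# Arc lengths along a closed or open polyline.
arc_lengths <- function(x, y, closed = FALSE) {
  dx <- diff(x); dy <- diff(y)
  seg <- sqrt(dx^2 + dy^2)
  if (closed) seg <- c(seg, sqrt((x[1] - x[length(x)])^2 +
                                 (y[1] - y[length(y)])^2))
  c(0, cumsum(seg))
}

resample_arc <- function(x, y, n_out) {
  s <- arc_lengths(x, y)
  total <- s[length(s)]
  so <- seq(0, total, length.out = n_out)
  # spline interpolation of each coordinate against arc length
  fx <- stats::splinefun(s, x, method = "natural")
  fy <- stats::splinefun(s, y, method = "natural")
  cbind(fx(so), fy(so))
}

#' Compute the midline geometry of a segmented cell
#'
#' Finds the two polar points as the contour vertex pair with maximal
#' separation among pairs that split the contour into two arcs of near-equal
#' length, resamples each half by spline interpolation to the same number of
#' equally spaced points (both running pole to pole), takes the midpoint of
#' every corresponding pair to form the midline, and derives the centre
#' (arc-length midpoint), length (midline arc length) and diameter (twice the
#' mean midline-to-contour distance over the central half).
#'
#' @param contour Data frame `x, y` from [segment_cell()] (pixel units).
#' @param pixel_size Micrometres per (original) pixel.
#' @param n_points Points per half used for the midline (default 200).
#' @param arc_balance Maximum allowed relative difference between the two
#'   contour halves' arc lengths when selecting pole pairs (default 0.2).
#' @return A `wm_geometry`: list with `contour`, `midline` (data frame,
#'   pixel units), `poles` (2 x 2 matrix, first row = midline start),
#'   `center` (interpolated point), `length_um`, `diameter_um`, `is_rod`,
#'   `pixel_size`, `midline_s` (cumulative arc length, pixels).
#' @export
compute_midline <- function(contour, pixel_size = 0.052, n_points = 200,
                            arc_balance = 0.2) {
  x <- contour$x; y <- contour$y
  if (length(x) < 8) stop("contour too small for midline extraction",
                          call. = FALSE)
  # Cap the working contour density: the pole search below is O(n^2) and
  # subpixel contours from 4x upsampling carry far more points than the
  # midline needs. 600 points on a ~10 um cell is a ~17 nm spacing.
  if (length(x) > 600) {
    res <- resample_arc(c(x, x[1]), c(y, y[1]), 601)
    x <- res[-601, 1]; y <- res[-601, 2]
  }
  n <- length(x)
  s <- arc_lengths(x, y, closed = TRUE)
  per <- s[n + 1]
  s <- s[seq_len(n)]

  D2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  A1 <- abs(outer(s, s, "-"))
  A2 <- per - A1
  ok <- abs(A1 - A2) <= arc_balance * (per / 2)
  D2[!ok] <- -Inf
  best <- arrayInd(which.max(D2), dim(D2))
  i <- min(best); j <- max(best)

  half1 <- cbind(x[i:j], y[i:j])
  idx2 <- c(j:n, 1:i)
  half2 <- cbind(x[idx2], y[idx2])
  half2 <- half2[rev(seq_len(nrow(half2))), , drop = FALSE]  # pole i -> pole j

  h1 <- resample_arc(half1[, 1], half1[, 2], n_points)
  h2 <- resample_arc(half2[, 1], half2[, 2], n_points)
  mid <- (h1 + h2) / 2
  ms <- arc_lengths(mid[, 1], mid[, 2])
  len_px <- ms[length(ms)]

  half_s <- len_px / 2
  k <- findInterval(half_s, ms)
  w <- (half_s - ms[k]) / (ms[k + 1] - ms[k])
  center <- mid[k, ] + w * (mid[k + 1, ] - mid[k, ])

  central <- which(ms >= 0.25 * len_px & ms <= 0.75 * len_px)
  dmin <- vapply(central, function(ii) {
    min(sqrt((x - mid[ii, 1])^2 + (y - mid[ii, 2])^2))
  }, 0)
  diam_um <- 2 * mean(dmin) * pixel_size
  len_um <- len_px * pixel_size

  structure(list(
    contour = contour,
    midline = data.frame(x = mid[, 1], y = mid[, 2]),
    midline_s = ms,
    poles = rbind(mid[1, ], mid[n_points, ]),
    center = center,
    length_um = len_um,
    diameter_um = diam_um,
    is_rod = len_um > 1.2 * diam_um,
    pixel_size = pixel_size
  ), class = "wm_geometry")
}

#' @export
print.wm_geometry <- function(x, ...) {
  cat(sprintf("<wm_geometry: length %.3f um, diameter %.3f um%s>\n",
              x$length_um, x$diameter_um,
              if (x$is_rod) "" else ", NON-ROD"))
  invisible(x)
}

#' Map image-frame spot positions into cell-centred coordinates
#'
#' Projects each spot perpendicularly onto the midline. The axial coordinate
#' `y` is the signed arc length from the cell centre to the foot of the
#' projection (positive toward the second pole of `geom`); the lateral
#' coordinate `x` is the signed perpendicular distance; `P_y` is the arc
#' distance to the nearer pole tip. All outputs in micrometres.
#'
#' @param x_px,y_px Spot centres in 0-based pixel coordinates.
#' @param geom A `wm_geometry`.
#' @return Data frame `x_um, y_um, P_y_um`.
#' @export
map_to_cell_coords <- function(x_px, y_px, geom) {
  mx <- geom$midline$x; my <- geom$midline$y
  ms <- geom$midline_s
  len <- ms[length(ms)]
  n <- length(mx)
  ax <- mx[-n]; ay <- my[-n]
  bx <- mx[-1]; by <- my[-1]
  ex <- bx - ax; ey <- by - ay
  el2 <- ex^2 + ey^2

  out <- data.frame(x_um = numeric(length(x_px)), y_um = NA_real_,
                    P_y_um = NA_real_)
  for (k in seq_along(x_px)) {
    tpar <- ((x_px[k] - ax) * ex + (y_px[k] - ay) * ey) / el2
    tpar <- pmin(pmax(tpar, 0), 1)
    fx <- ax + tpar * ex; fy <- ay + tpar * ey
    d2 <- (x_px[k] - fx)^2 + (y_px[k] - fy)^2
    seg <- which.min(d2)
    s_here <- ms[seg] + tpar[seg] * sqrt(el2[seg])
    cross <- ex[seg] * (y_px[k] - fy[seg]) - ey[seg] * (x_px[k] - fx[seg])
    out$y_um[k] <- (s_here - len / 2) * geom$pixel_size
    out$x_um[k] <- sign(cross) * sqrt(d2[seg]) * geom$pixel_size
    out$P_y_um[k] <- min(s_here, len - s_here) * geom$pixel_size
  }
  out
}

#' Keep pole identity consistent across a time series of geometries
#'
#' Ensures the first pole of each frame's geometry is the one nearest the
#' first pole of the previous frame, reversing midlines where needed, so that
#' the sign of the axial coordinate never flips between consecutive frames.
#'
#' @param geoms List of `wm_geometry`, in frame order.
#' @return The list, with some geometries reversed.
#' @export
align_geometries <- function(geoms) {
  if (length(geoms) < 2) return(geoms)
  for (i in 2:length(geoms)) {
    pa_prev <- geoms[[i - 1]]$poles[1, ]
    d_same <- sum((geoms[[i]]$poles[1, ] - pa_prev)^2)
    d_flip <- sum((geoms[[i]]$poles[2, ] - pa_prev)^2)
    if (d_flip < d_same) {
      g <- geoms[[i]]
      m <- g$midline[rev(seq_len(nrow(g$midline))), , drop = FALSE]
      rownames(m) <- NULL
      g$midline <- m
      g$midline_s <- g$midline_s[length(g$midline_s)] - rev(g$midline_s)
      g$poles <- g$poles[2:1, , drop = FALSE]
      geoms[[i]] <- g
    }
  }
  geoms
}

# Distance from points to the boundary of the convex hull polygon.
dist_to_hull <- function(x, y) {
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  m <- length(hx)
  ax <- hx; ay <- hy
  bx <- hx[c(2:m, 1)]; by <- hy[c(2:m, 1)]
  ex <- bx - ax; ey <- by - ay
  el2 <- pmax(ex^2 + ey^2, 1e-12)
  vapply(seq_along(x), function(k) {
    tpar <- pmin(pmax(((x[k] - ax) * ex + (y[k] - ay) * ey) / el2, 0), 1)
    fx <- ax + tpar * ex; fy <- ay + tpar * ey
    sqrt(min((x[k] - fx)^2 + (y[k] - fy)^2))
  }, 0)
}

#' Detect division onset from contour convexity defects
#'
#' Per frame, measures the maximum depth of the contour below its convex hull,
#' restricted to vertices whose projection lies in the central fraction of the
#' midline; division onset is the first frame where the depth exceeds
#' `depth_threshold_um` on at least `consecutive` consecutive frames. Frames
#' up to 10 minutes before onset are labelled `"elongation"`, frames from
#' onset `"division"`, the frames in between `"transition"`.
#'
#' @param geoms List of `wm_geometry` per frame (aligned).
#' @param times Frame times, minutes.
#' @param depth_threshold_um Defect depth threshold (default 0.05 um).
#' @param central_frac Central midline fraction searched (default 0.2).
#' @param consecutive Frames the defect must persist (default 2).
#' @param elongation_margin_min Pre-onset margin excluded from the
#'   elongation label (default 10 minutes).
#' @return List with `onset_frame` (index into `geoms`, `NA` if none),
#'   `depth_um` per frame, and `phase` labels.
#' @export
detect_division <- function(geoms, times, depth_threshold_um = 0.05,
                            central_frac = 0.2, consecutive = 2,
                            elongation_margin_min = 10) {
  stopifnot(length(geoms) == length(times))
  depth <- vapply(seq_along(geoms), function(i) {
    g <- geoms[[i]]
    cx <- g$contour$x; cy <- g$contour$y
    cc <- map_to_cell_coords(cx, cy, g)
    lim <- central_frac / 2 * (g$length_um)
    sel <- abs(cc$y_um) <= lim
    if (!any(sel)) return(0)
    max(dist_to_hull(cx, cy)[sel]) * g$pixel_size
  }, 0)
  above <- depth > depth_threshold_um
  onset <- NA_integer_
  if (length(above) >= consecutive) {
    for (i in seq_len(length(above) - consecutive + 1)) {
      if (all(above[i:(i + consecutive - 1)])) { onset <- i; break }
    }
  }
  phase <- rep("elongation", length(geoms))
  if (!is.na(onset)) {
    t_on <- times[onset]
    phase[times >= t_on] <- "division"
    phase[times < t_on & times > t_on - elongation_margin_min] <- "transition"
  }
  list(onset_frame = onset, depth_um = depth, phase = phase)
}
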