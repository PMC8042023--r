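# Exact rectangular assignment (Hungarian algorithm, shortest augmenting
# paths, O(n^2 m)). Returns, for each row, the assigned column (NA if the
# row is left unassigned when rows outnumber columns).
hungarian_assign <- function(cost) {
  transposed <- FALSE
  if (nrow(cost) > ncol(cost)) { cost <- t(cost); transposed <- TRUE }
  n <- nrow(cost); m <- ncol(cost)
  u <- numeric(n); v <- numeric(m + 1)
  p <- integer(m + 1)        # row assigned to column j (0 = none); m+1 virtual
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      cur <- cost[i0, ] - u[i0] - v[seq_len(m)]
      upd <- !used[seq_len(m)] & cur < minv
      minv[upd] <- cur[upd]
      way[seq_len(m)][upd] <- j0
      free <- which(!used[seq_len(m)])
      if (!length(free)) break
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      ju <- which(used)
      for (j in ju) {
        if (j <= m) { if (p[j] > 0) u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else u[p[j]] <- u[p[j]] + delta
      }
      minv[!used[seq_len(m)]] <- minv[!used[seq_len(m)]] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat { j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1; if (j0 == m + 1L) break }
  }
  res <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j] > 0) res[p[j]] <- j
  if (transposed) {
    out <- rep(NA_integer_, ncol(cost))
    for (r in seq_len(n)) if (!is.na(res[r])) out[res[r]] <- r
    out
  } else res
}

#' Link per-frame detections into motor traces
#'
#' Nearest-neighbour frame-to-frame linking within each cell: in every
#' consecutive frame pair, candidate links closer than the gate distance are
#' matched so that the total displacement is minimal (an exact assignment, so
#' ambiguous cases — several candidates within the gate — are resolved
#' globally and deterministically). A trace missing from one frame may be
#' bridged across a single gap; a displacement beyond the gate terminates the
#' trace and opens a new one.
#'
#' @param spots Data frame with columns `frame`, `time_min`, `x_um`, `y_um`
#'   (and optionally `cell_id`, `P_y_um`, carried through).
#' @param gate_um_per_10min Gate distance in micrometres per 10 minutes
#'   (default 0.3); the effective gate is scaled by the actual frame interval.
#' @param max_gap Number of consecutive missed frames bridged (default 1).
#' @return The input rows with a `trace_id` column added.
#' @export
link_traces <- function(spots, gate_um_per_10min = 0.3, max_gap = 1) {
  req <- c("frame", "time_min", "x_um", "y_um")
  if (!all(req %in% names(spots))) {
    stop("spots table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!"cell_id" %in% names(spots)) spots$cell_id <- "c1"
  key <- paste(spots$cell_id, spots$frame, round(spots$x_um, 9),
               round(spots$y_um, 9))
  if (anyDuplicated(key)) {
    stop("duplicate (frame, position) rows in spots table", call. = FALSE)
  }

  out <- vector("list", 0L)
  next_id <- 1L
  for (cid in unique(spots$cell_id)) {
    sc <- spots[spots$cell_id == cid, , drop = FALSE]
    frames <- sort(unique(sc$frame))
    times <- vapply(frames, function(f) sc$time_min[sc$frame == f][1], 0)
    # active traces: list of (trace_id, last x, y, last frame index)
    act <- data.frame(trace_id = integer(0), x = numeric(0), y = numeric(0),
                      fidx = integer(0))
    sc$trace_id <- NA_integer_
    for (fi in seq_along(frames)) {
      rows <- which(sc$frame == frames[fi])
      if (nrow(act)) {
        # drop traces that have been unmatched for more than max_gap frames
        act <- act[fi - act$fidx <= max_gap + 1L, , drop = FALSE]
      }
      unmatched_rows <- rows
      if (nrow(act) && length(rows)) {
        dtm <- outer(act$fidx, rep(fi, length(rows)),
                     function(a, b) times[b] - times[a])
        gate <- gate_um_per_10min * dtm / 10
        d <- sqrt(outer(act$x, sc$x_um[rows], "-")^2 +
                  outer(act$y, sc$y_um[rows], "-")^2)
        if (any(d <= gate)) {
          big <- 1e9
          cost <- ifelse(d <= gate, d, big + d)
          asg <- hungarian_assign(cost)
          used_r <- logical(length(rows))
          for (a in seq_along(asg)) {
            r <- asg[a]
            if (is.na(r) || d[a, r] > gate[a, r]) next
            used_r[r] <- TRUE
            sc$trace_id[rows[r]] <- act$trace_id[a]
            act$x[a] <- sc$x_um[rows[r]]; act$y[a] <- sc$y_um[rows[r]]
            act$fidx[a] <- fi
          }
          unmatched_rows <- rows[!used_r]
        }
      }
      for (r in unmatched_rows) {
        sc$trace_id[r] <- next_id
        act <- rbind(act, data.frame(trace_id = next_id, x = sc$x_um[r],
                                     y = sc$y_um[r], fidx = fi))
        next_id <- next_id + 1L
      }
    }
    out[[length(out) + 1L]] <- sc
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Closed-form simple OLS of y on x: slope, its standard error, intercept.
ols_slope <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  res <- y - my - slope * (x - mx)
  se <- if (n > 2) sqrt(sum(res^2) / (n - 2) / sxx) else NA_real_
  list(slope = slope, stderr = se, intercept = my - slope * mx)
}

#' Average axial velocity of one motor trace
#'
#' Ordinary least-squares slope of the pole distance `P_y` against time: the
#' motor's average axial velocity `V_Py`.
#'
#' @param time_min,P_y_um Sample times (minutes) and pole distances
#'   (micrometres) of one trace.
#' @return List with `V_Py` (um/min), `stderr`, `n_samples`, `P_y0` (first
#'   sample).
#' @export
fit_VPy <- function(time_min, P_y_um) {
  n <- length(time_min)
  stopifnot(n == length(P_y_um))
  if (n < 2) stop("a trace needs at least 2 samples", call. = FALSE)
  ols <- ols_slope(time_min, P_y_um)
  list(V_Py = ols$slope, stderr = ols$stderr,
       n_samples = n, P_y0 = P_y_um[which.min(time_min)])
}

#' Fit velocities for every trace in a linked table
#'
#' @param traces Output of [link_traces()] (needs `trace_id`, `time_min`,
#'   `P_y_um`; `cell_id`/`motor_id`/`color` carried through if present).
#' @param min_samples Minimum samples per trace (default 3).
#' @return Data frame with one row per trace: `trace_id, P_y0, V_Py, stderr,
#'   n_samples` plus carried identifiers.
#' @export
fit_VPy_all <- function(traces, min_samples = 3) {
  sp <- split(traces, traces$trace_id)
  rows <- lapply(sp, function(tr) {
    if (nrow(tr) < min_samples) return(NULL)
    f <- fit_VPy(tr$time_min, tr$P_y_um)
    d <- data.frame(trace_id = tr$trace_id[1], P_y0 = f$P_y0, V_Py = f$V_Py,
                    stderr = f$stderr, n_samples = f$n_samples,
                    stringsAsFactors = FALSE)
    for (col in c("cell_id", "motor_id", "color")) {
      if (col %in% names(tr)) d[[col]] <- tr[[col]][1]
    }
    d
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# Profile RSS of the hinge model V = k * max(0, P - c) over candidate
# changepoints. Returns the grid, per-candidate k and RSS.
hinge_profile <- function(P, V, grid) {
  W <- pmax(outer(grid, P, function(g, p) p - g), 0)   # m x n
  den <- rowSums(W^2)
  num <- as.numeric(W %*% V)
  k <- ifelse(den > 0, num / den, 0)
  rss <- sum(V^2) - ifelse(den > 0 & k > 0, num^2 / den, 0)
  list(k = k, rss = rss, den = den, num = num)
}

#' Inert-zone changepoint fit
#'
#' Fits the piecewise-linear velocity model
#' `V_Py = 0` for `P_y0 < P_yc` and `V_Py = k (P_y0 - P_yc)` for
#' `P_y0 >= P_yc` — a hinge with the plateau fixed at exactly zero — to the
#' per-motor average velocities. The changepoint `P_yc` (the inert-zone size)
#' is profiled over a grid at `grid_res` resolution with the slope `k` in
#' closed form at each candidate; a case-resampling bootstrap gives a
#' percentile confidence interval on `P_yc`.
#'
#' @param P_y0 Initial pole distances, micrometres.
#' @param V_Py Average axial velocities, um/min.
#' @param grid_res Changepoint grid resolution, micrometres (default 0.001).
#' @param n_boot Bootstrap replicates for the CI (default 1000; 0 disables).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return A `wm_inert_zone_fit`: list with `P_yc`, `k`, `rss`, `ci_Pyc`,
#'   `n_motors`, `grid_res`.
#' @export
fit_inert_zone <- function(P_y0, V_Py, grid_res = 0.001, n_boot = 1000,
                           conf = 0.95, seed = 1L) {
  stopifnot(length(P_y0) == length(V_Py))
  keep <- is.finite(P_y0) & is.finite(V_Py)
  P <- P_y0[keep]; V <- V_Py[keep]
  n <- length(P)
  if (n < 4) stop("too few motors for a changepoint fit", call. = FALSE)
  if (max(abs(V)) == 0) {
    stop("all velocities are zero: changepoint not identifiable",
         call. = FALSE)
  }
  if (max(P) - min(P) <= 2 * grid_res) {
    stop("P_y0 values span no interior changepoint candidates: not identifiable",
         call. = FALSE)
  }
  grid <- seq(min(P) + grid_res, max(P) - grid_res, by = grid_res)
  if (length(grid) < 2) {
    stop("P_y0 values span no interior changepoint candidates: not identifiable",
         call. = FALSE)
  }
  prof <- hinge_profile(P, V, grid)
  valid <- prof$den > 0 & prof$k > 0
  if (!any(valid)) {
    stop("no candidate changepoint with a positive slope: not identifiable",
         call. = FALSE)
  }
  rss <- ifelse(valid, prof$rss, Inf)
  best <- which.min(rss)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    A <- pmax(outer(grid, P, function(g, p) p - g), 0)  # m x n, reused
    B <- A^2
    AV <- A * rep(V, each = length(grid))
    boot_pyc <- with_substream(seed, "bootstrap", {
      counts <- stats::rmultinom(n_boot, n, rep(1 / n, n))  # n x n_boot
      NUM <- AV %*% counts
      DEN <- B %*% counts
      ok <- DEN > 0 & NUM > 0
      score <- matrix(-Inf, nrow(NUM), ncol(NUM))
      score[ok] <- (NUM[ok]^2) / DEN[ok]   # rss = const - score
      grid[max.col(t(score), ties.method = "first")]
    })
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot_pyc, c(alpha, 1 - alpha), type = 7))
  }

  structure(list(P_yc = grid[best], k = prof$k[best], rss = rss[best],
                 ci_Pyc = ci, n_motors = n, grid_res = grid_res),
            class = "wm_inert_zone_fit")
}

#' @export
print.wm_inert_zone_fit <- function(x, ...) {
  cat(sprintf("Inert-zone fit: P_yc = %.3f um (95%% CI %.3f-%.3f), k = %.4f /min, n = %d\n",
              x$P_yc, x$ci_Pyc[1], x$ci_Pyc[2], x$k, x$n_motors))
  invisible(x)
}

#' Pairwise separation kinematics of active-zone motors
#'
#' For every unordered pair of motors on the same cell with both pole
#' distances at least `P_yc` at the interval start (i.e. both in the active
#' zone), computes the unsigned lateral and axial separations `D_x`, `D_y`
#' at the interval start and the relative velocities
#' `V_Dx = (D_x' - D_x)/dt`, `V_Dy = (D_y' - D_y)/dt` over each frame
#' interval.
#'
#' @param traces Linked trace table (`trace_id, cell_id, frame, time_min,
#'   x_um, y_um, P_y_um`).
#' @param P_yc Inert-zone size used for the active-zone filter, micrometres.
#' @return Data frame `cell_id, trace_i, trace_j, time_min, dt, D_x, D_y,
#'   V_Dx, V_Dy`.
#' @export
pair_kinematics <- function(traces, P_yc) {
  out <- list()
  for (cid in unique(traces$cell_id)) {
    tc <- traces[traces$cell_id == cid, , drop = FALSE]
    frames <- sort(unique(tc$frame))
    if (length(frames) < 2) next
    for (fi in seq_len(length(frames) - 1)) {
      a <- tc[tc$frame == frames[fi], , drop = FALSE]
      b <- tc[tc$frame == frames[fi + 1], , drop = FALSE]
      ids <- intersect(a$trace_id[a$P_y_um >= P_yc], b$trace_id)
      if (length(ids) < 2) next
      a <- a[match(ids, a$trace_id), ]; b <- b[match(ids, b$trace_id), ]
      dt <- b$time_min[1] - a$time_min[1]
      pr <- utils::combn(length(ids), 2)
      i <- pr[1, ]; j <- pr[2, ]
      Dx <- abs(a$x_um[i] - a$x_um[j]); Dy <- abs(a$y_um[i] - a$y_um[j])
      Dx2 <- abs(b$x_um[i] - b$x_um[j]); Dy2 <- abs(b$y_um[i] - b$y_um[j])
      out[[length(out) + 1L]] <- data.frame(
        cell_id = cid, trace_i = ids[i], trace_j = ids[j],
        time_min = a$time_min[1], dt = dt, D_x = Dx, D_y = Dy,
        V_Dx = (Dx2 - Dx) / dt, V_Dy = (Dy2 - Dy) / dt,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate the per-length expansion rate H
#'
#' Regression through the origin of the axial relative velocity on the axial
#' separation, `V_Dy = H D_y`, per cell and interval: the "Hubble" parameter
#' of cell-wall expansion. Also emits the normalized points
#' `(D_y, V_Dy / H)`, which collapse onto the unit-slope line when expansion
#' is homogeneous.
#'
#' @param pairs Output of [pair_kinematics()].
#' @return List with `estimates` (data frame `cell_id, time_min, H, stderr,
#'   n_pairs`) and `normalized` (data frame `cell_id, time_min, D_y,
#'   V_Dy_over_H`).
#' @export
estimate_H <- function(pairs) {
  grp <- interaction(pairs$cell_id, pairs$time_min, drop = TRUE)
  est <- list(); norm <- list()
  for (g in levels(grp)) {
    p <- pairs[grp == g, , drop = FALSE]
    sdd <- sum(p$D_y^2)
    H <- sum(p$D_y * p$V_Dy) / sdd
    se <- if (nrow(p) >= 2) {
      sqrt(sum((p$V_Dy - H * p$D_y)^2) / (nrow(p) - 1) / sdd)
    } else NA_real_
    est[[g]] <- data.frame(cell_id = p$cell_id[1], time_min = p$time_min[1],
                           H = H, stderr = se, n_pairs = nrow(p),
                           stringsAsFactors = FALSE)
    norm[[g]] <- data.frame(cell_id = p$cell_id[1], time_min = p$time_min[1],
                            D_y = p$D_y, V_Dy_over_H = p$V_Dy / H,
                            stringsAsFactors = FALSE)
  }
  list(estimates = do.call(rbind, c(est, make.row.names = FALSE)),
       normalized = do.call(rbind, c(norm, make.row.names = FALSE)))
}

#' Normalized axial coordinates and their per-phase drift
#'
#' Computes the normalized axial position `N_y = Y / L` for every sample
#' (`Y` the axial position from the cell centre, `L` the active-zone length,
#' i.e. cell length minus twice the inert-zone size) and the per-motor
#' least-squares slope of `N_y` against time, separately within the
#' elongation and the division phase. During elongation the slopes are zero
#' (motors are fixed in the normalized coordinate); during division motors
#' are driven away from the centre, so the slope carries the sign of `N_y`.
#'
#' @param traces Trace table with `trace_id, cell_id, frame, time_min, y_um`.
#' @param geometry Per-frame geometry with `cell_id, frame, cell_length_um,
#'   phase` (phase in `"elongation"`/`"division"`; other labels are skipped
#'   in the slope fits).
#' @param P_yc Inert-zone size, micrometres.
#' @return List with `points` (per-sample `N_y`) and `slopes` (per motor and
#'   phase).
#' @export
normalize_positions <- function(traces, geometry, P_yc) {
  key <- paste(geometry$cell_id, geometry$frame)
  idx <- match(paste(traces$cell_id, traces$frame), key)
  if (anyNA(idx)) stop("geometry missing for some (cell, frame)", call. = FALSE)
  L <- geometry$cell_length_um[idx] - 2 * P_yc
  pts <- data.frame(trace_id = traces$trace_id, cell_id = traces$cell_id,
                    frame = traces$frame, time_min = traces$time_min,
                    Y_um = traces$y_um, L_um = L, N_y = traces$y_um / L,
                    phase = geometry$phase[idx], stringsAsFactors = FALSE)
  sl <- list()
  for (ph in c("elongation", "division")) {
    sub <- pts[pts$phase == ph, , drop = FALSE]
    if (!nrow(sub)) next
    for (tid in unique(sub$trace_id)) {
      s <- sub[sub$trace_id == tid, , drop = FALSE]
      if (nrow(s) < 2) next
      slope <- ols_slope(s$time_min, s$N_y)$slope
      sl[[length(sl) + 1L]] <- data.frame(
        trace_id = tid, cell_id = s$cell_id[1], phase = ph, slope = slope,
        mean_N_y = mean(s$N_y), n_samples = nrow(s), stringsAsFactors = FALSE)
    }
  }
  list(points = pts, slopes = do.call(rbind, c(sl, make.row.names = FALSE)))
}

#' Displacement from mid-cell of centrally located motors during division
#'
#' For motors whose axial position `|Y|` is below `center_threshold` at
#' division onset, reports how far from mid-cell they end up at division
#' completion: `|Y(end)| - |Y(onset)|`. A motor exactly at the division site
#' is displaced by exactly the new-cap size.
#'
#' @param traces Trace table with `trace_id, time_min, y_um`.
#' @param onset_time,end_time Times (minutes) of division onset and
#'   completion.
#' @param center_threshold Micrometres (default 0.1).
#' @return Data frame `trace_id, Y_onset, Y_end, displacement_um`.
#' @export
central_motor_displacement <- function(traces, onset_time, end_time,
                                       center_threshold = 0.1) {
  rows <- list()
  for (tid in unique(traces$trace_id)) {
    tr <- traces[traces$trace_id == tid, , drop = FALSE]
    i0 <- which.min(abs(tr$time_min - onset_time))
    i1 <- which.min(abs(tr$time_min - end_time))
    if (abs(tr$time_min[i0] - onset_time) > 1e-6 ||
        abs(tr$time_min[i1] - end_time) > 1e-6) next
    y0 <- tr$y_um[i0]
    if (abs(y0) >= center_threshold) next
    rows[[length(rows) + 1L]] <- data.frame(
      trace_id = tid, Y_onset = y0, Y_end = tr$y_um[i1],
      displacement_um = abs(tr$y_um[i1]) - abs(y0), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
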