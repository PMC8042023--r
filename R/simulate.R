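#' Sample from a truncated Gaussian on an interval by rejection
#'
#' Draws from a Gaussian with mean 0 and standard deviation `sigma` truncated
#' to `[lo, hi]`, by rejection sampling from the untruncated Gaussian (the
#' scheme used for seeding the cross-generation distribution simulation).
#' `sigma = Inf` returns the uniform law on `[lo, hi]`.
#'
#' @param n Number of draws.
#' @param sigma Standard deviation of the parent Gaussian.
#' @param lo,hi Truncation interval (default `[-0.5, 0.5]`).
#' @return Numeric vector of length `n`. Uses the current RNG state.
#' @export
rtruncgauss <- function(n, sigma = 0.4, lo = -0.5, hi = 0.5) {
  stopifnot(n >= 0, sigma > 0, hi > lo)
  if (n == 0) return(numeric(0))
  if (!is.finite(sigma)) return(stats::runif(n, lo, hi))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 16L, 0, sigma)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

new_wm_cell <- function(cell_id, config, L0, t_birth, motors) {
  structure(list(cell_id = cell_id, config = config, L0 = L0,
                 t_birth = t_birth, motors = motors,
                 frames = NULL, truth = NULL, divided = FALSE),
            class = "wm_cell")
}

#' @export
print.wm_cell <- function(x, ...) {
  nf <- if (is.null(x$frames)) 0L else nrow(x$frames)
  cat(sprintf("<wm_cell %s: %d motors, %d frames, birth t = %g min%s>\n",
              x$cell_id, nrow(x$motors), nf, x$t_birth,
              if (x$divided) ", divided" else ""))
  invisible(x)
}

# Place founding motors. Uniform placement spreads motors over the whole cell
# axis (caps included); truncated-Gaussian placement is over the active-zone
# normalized coordinate only, emulating the center-biased law of newly
# produced motors.
place_founding_motors <- function(config, cell_id = "c1", n = config$n_motors) {
  cap <- config$cap_size_c
  L0 <- config$initial_active_length_L0
  if (n == 0) {
    return(data.frame(motor_id = character(0), type = character(0),
                      N = numeric(0), P_y = numeric(0), side = numeric(0),
                      x_um = numeric(0), color = character(0),
                      stringsAsFactors = FALSE))
  }
  with_substream(config$rng_seed, paste0("placement:", cell_id), {
    mp <- config$motor_placement
    if (identical(mp$type, "uniform")) {
      tl <- L0 + 2 * cap
      y0 <- stats::runif(n, -tl / 2, tl / 2)
    } else {
      y0 <- rtruncgauss(n, mp$sigma %||% 0.4) * L0
    }
    # motors sit on the envelope at uniform azimuth; the projected lateral
    # position is R sin(theta) (arcsine-distributed across the width)
    x <- config$diameter_D / 2 * sin(stats::runif(n, 0, 2 * pi))
    active <- abs(y0) <= L0 / 2
    data.frame(
      motor_id = sprintf("%s_m%02d", cell_id, seq_len(n)),
      type = ifelse(active, "active", "inert"),
      N = ifelse(active, y0 / L0, NA_real_),
      P_y = ifelse(active, NA_real_, L0 / 2 + cap - abs(y0)),
      side = ifelse(y0 >= 0, 1, -1),
      x_um = x,
      color = "inherited",
      stringsAsFactors = FALSE
    )
  })
}

#' Place newly produced motors on a cell
#'
#' Adds `n_new` motors tagged `color = "new"`, placed in the active-zone
#' normalized coordinate with the configured placement law (default truncated
#' Gaussian, sigma 0.4, centred at 0 — the strongly centre-biased law observed
#' for newly produced motors).
#'
#' @param cell A `wm_cell`.
#' @param config The `wm_sim_config` (its `motor_placement` may be
#'   overridden via `placement`).
#' @param n_new Number of motors to add.
#' @param placement Optional placement spec, e.g.
#'   `list(type = "truncgauss", sigma = 0.4)` (the default) or
#'   `list(type = "uniform")`.
#' @return The cell with motors added.
#' @export
place_new_motors <- function(cell, config, n_new = config$n_motors,
                             placement = list(type = "truncgauss", sigma = 0.4)) {
  if (n_new == 0) return(cell)
  with_substream(config$rng_seed, paste0("placement-new:", cell$cell_id), {
    ny <- if (identical(placement$type, "uniform")) {
      stats::runif(n_new, -0.5, 0.5)
    } else {
      rtruncgauss(n_new, placement$sigma %||% 0.4)
    }
    x <- config$diameter_D / 2 * sin(stats::runif(n_new, 0, 2 * pi))
    add <- data.frame(
      motor_id = sprintf("%s_n%02d", cell$cell_id, seq_len(n_new)),
      type = "active", N = ny, P_y = NA_real_,
      side = ifelse(ny >= 0, 1, -1),
      x_um = x, color = "new", stringsAsFactors = FALSE
    )
    cell$motors <- rbind(cell$motors, add)
    cell
  })
}

# Noise-free motor positions at one relative time t (elongation phase or with
# a septal offset s during division). Active motors dilate with the active
# zone (constant normalized coordinate N); inert motors ride rigidly with
# their pole at constant pole distance P_y; every motor on side s is pushed
# outward by the accumulated mid-cell insertion `septal`.
motor_positions <- function(motors, L, cap, septal = 0) {
  y <- ifelse(motors$type == "active",
              motors$N * L + motors$side * septal,
              motors$side * (L / 2 + cap - motors$P_y + septal))
  cell_len <- L + 2 * cap + 2 * septal
  data.frame(motor_id = motors$motor_id, x_um = motors$x_um, y_um = y,
             P_y_um = cell_len / 2 - abs(y),
             N_y_true = ifelse(motors$type == "active", motors$N, NA_real_),
             color = motors$color, type = motors$type,
             stringsAsFactors = FALSE)
}

truth_rows <- function(cell, frame, t_rel, L, septal, phase) {
  pos <- motor_positions(cell$motors, L, cell$config$cap_size_c, septal)
  cbind(data.frame(cell_id = cell$cell_id, motor_id = pos$motor_id,
                   frame = frame, time_min = cell$t_birth + t_rel,
                   stringsAsFactors = FALSE),
        pos[, c("x_um", "y_um", "P_y_um", "N_y_true", "color", "type")],
        data.frame(L_active_um = L,
                   cell_length_um = L + 2 * cell$config$cap_size_c + 2 * septal,
                   septal_offset_um = septal, phase = phase,
                   stringsAsFactors = FALSE))
}

#' Simulate the elongation phase of one cell
#'
#' Grows the active zone homogeneously (`dL/dt = H(t) L` with
#' `H(t) = H0 (1 + beta t)`) over `n_frames` frames at interval
#' `frame_interval_dt`, holding each active motor fixed in the normalized
#' coordinate and each inert (polar) motor at constant distance from its pole
#' tip. Positions are exact (noise-free); see [add_noise_and_export()] for the
#' observation model.
#'
#' @param config A [sim_config()].
#' @param cell Optionally an existing `wm_cell` (e.g. a daughter from
#'   [simulate_division()]); if `NULL` a founding cell is created with
#'   motors placed per `config`.
#' @param n_frames Number of frames (default `config$n_frames`).
#' @return A `wm_cell` with `$truth` (long per-frame motor table with columns
#'   `cell_id, motor_id, frame, time_min, x_um, y_um, P_y_um, N_y_true,
#'   color, type, L_active_um, cell_length_um, septal_offset_um, phase`) and
#'   `$frames` (per-frame geometry).
#' @export
simulate_elongation <- function(config, cell = NULL, n_frames = config$n_frames) {
  validate_sim_config(config)
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  if (is.null(cell)) {
    cell <- new_wm_cell("c1", config, config$initial_active_length_L0, 0,
                        place_founding_motors(config))
  }
  bad <- cell$motors$type == "active" & abs(cell$motors$N) > 0.5 + 1e-12
  bad2 <- cell$motors$type == "inert" &
    (cell$motors$P_y < -1e-12 | cell$motors$P_y > config$cap_size_c + 1e-12)
  if (any(bad) || any(bad2)) {
    stop("motor placed outside the allowed span of the cell", call. = FALSE)
  }
  t_rel <- (seq_len(n_frames) - 1) * config$frame_interval_dt
  L <- cell$L0 * growth_factor(t_rel, config$growth_rate_H0,
                               config$growth_acceleration_beta)
  tr <- do.call(rbind, lapply(seq_len(n_frames), function(i) {
    truth_rows(cell, i, t_rel[i], L[i], 0, "elongation")
  }))
  cell$frames <- data.frame(frame = seq_len(n_frames),
                            time_min = cell$t_birth + t_rel,
                            L_active_um = L,
                            cell_length_um = L + 2 * config$cap_size_c,
                            septal_offset_um = 0, phase = "elongation",
                            stringsAsFactors = FALSE)
  cell$truth <- tr
  cell
}

#' Simulate one division of a grown cell
#'
#' Runs the septal-growth phase: over `division_duration` minutes, local
#' insertion at mid-cell displaces every motor outward (by side) by a septal
#' offset that grows linearly from 0 to the cap size, while the two half-rods
#' keep elongating homogeneously (unless
#' `config$elongation_during_division = FALSE`). At completion the cell splits
#' at mid-cell; each daughter gains a new inert endcap of size `cap_size_c`,
#' and each motor goes to the daughter on its side at onset (a motor exactly
#' at mid-cell is assigned by a seeded fair coin).
#'
#' In the normalized coordinate this implements the cross-generation map
#' `N' = 2N - 0.5` (upper daughter) or `N' = 2N + 0.5` (lower daughter)
#' exactly.
#'
#' @param cell A `wm_cell` that has been elongated past the division trigger.
#' @param config The `wm_sim_config`.
#' @param force Skip the trigger check (used for constructed scenarios).
#' @return A list with `cell` (mother, division frames appended), `daughters`
#'   (list of two `wm_cell`s, upper then lower), and `lineage` (data frame
#'   `mother_id, daughter_id, motor_id, N_y_mother, N_y_daughter, side`).
#' @export
simulate_division <- function(cell, config, force = FALSE) {
  validate_sim_config(config)
  if (is.null(cell$frames)) stop("cell has not been elongated", call. = FALSE)
  lastf <- cell$frames[nrow(cell$frames), ]
  t_on <- lastf$time_min - cell$t_birth
  if (!force) {
    ok <- if (config$division_trigger == "length") {
      lastf$cell_length_um >= config$division_trigger_length - 1e-9
    } else {
      t_on >= config$division_time - 1e-9
    }
    if (!ok) {
      stop("division invoked before the trigger condition is met",
           call. = FALSE)
    }
  }
  cap <- config$cap_size_c
  dt <- config$frame_interval_dt
  dur <- config$division_duration
  t_div <- seq(dt, dur, by = dt)
  if (length(t_div) == 0 || abs(t_div[length(t_div)] - dur) > 1e-9) {
    t_div <- c(t_div[t_div < dur - 1e-9], dur)
  }

  # side at onset; mid-cell motors resolved by a seeded fair coin
  side_on <- ifelse(cell$motors$type == "active", sign(cell$motors$N),
                    cell$motors$side)
  at_zero <- which(side_on == 0)
  if (length(at_zero)) {
    coin <- with_substream(config$rng_seed, paste0("coin:", cell$cell_id),
                           stats::runif(length(at_zero)) < 0.5)
    side_on[at_zero] <- ifelse(coin, 1, -1)
  }
  div_motors <- cell$motors
  div_motors$side <- side_on

  L_on <- lastf$L_active_um
  frame0 <- lastf$frame
  G_on <- growth_factor(t_on, config$growth_rate_H0,
                        config$growth_acceleration_beta)
  new_tr <- list(); new_fr <- list()
  for (i in seq_along(t_div)) {
    trel <- t_on + t_div[i]
    L <- if (config$elongation_during_division) {
      cell$L0 * growth_factor(trel, config$growth_rate_H0,
                              config$growth_acceleration_beta)
    } else L_on
    s <- cap * t_div[i] / dur
    cell2 <- cell; cell2$motors <- div_motors
    new_tr[[i]] <- truth_rows(cell2, frame0 + i, trel, L, s, "division")
    new_fr[[i]] <- data.frame(frame = frame0 + i, time_min = cell$t_birth + trel,
                              L_active_um = L,
                              cell_length_um = L + 2 * cap + 2 * s,
                              septal_offset_um = s, phase = "division",
                              stringsAsFactors = FALSE)
  }
  cell$truth <- rbind(cell$truth, do.call(rbind, new_tr))
  cell$frames <- rbind(cell$frames, do.call(rbind, new_fr))
  cell$divided <- TRUE

  t_end <- t_on + dur
  L_T <- if (config$elongation_during_division) {
    cell$L0 * growth_factor(t_end, config$growth_rate_H0,
                            config$growth_acceleration_beta)
  } else L_on

  make_daughter <- function(sgn, suffix) {
    idx <- which(div_motors$side == sgn)
    m <- div_motors[idx, , drop = FALSE]
    act <- m$type == "active"
    # exact cross-generation map of the normalized coordinate
    m$N[act] <- 2 * m$N[act] - sgn * 0.5
    m$side <- ifelse(m$type == "inert", sgn, ifelse(m$N >= 0, 1, -1))
    rownames(m) <- NULL
    d <- new_wm_cell(paste0(cell$cell_id, suffix), config, L_T / 2,
                     cell$t_birth + t_end, m)
    nym <- if (nrow(m)) ifelse(act, div_motors$N[idx], NA_real_) else numeric(0)
    lin <- data.frame(mother_id = rep(cell$cell_id, nrow(m)),
                      daughter_id = rep(d$cell_id, nrow(m)),
                      motor_id = m$motor_id, N_y_mother = nym,
                      N_y_daughter = if (nrow(m)) ifelse(act, m$N, NA_real_)
                                     else numeric(0),
                      side = rep(sgn, nrow(m)), stringsAsFactors = FALSE)
    list(cell = d, lineage = lin)
  }
  up <- make_daughter(1, ".1")
  lo <- make_daughter(-1, ".2")
  list(cell = cell, daughters = list(up$cell, lo$cell),
       lineage = rbind(up$lineage, lo$lineage))
}

# Number of elongation frames until the division trigger is reached.
frames_to_trigger <- function(config, L0) {
  H0 <- config$growth_rate_H0; beta <- config$growth_acceleration_beta
  dt <- config$frame_interval_dt
  if (config$division_trigger == "timer") {
    return(max(2L, as.integer(ceiling(config$division_time / dt)) + 1L))
  }
  target <- config$division_trigger_length - 2 * config$cap_size_c
  if (target <= L0) return(2L)
  r <- log(target / L0)
  t_star <- if (beta > 0) {
    (-1 + sqrt(1 + 2 * beta * r / H0)) / beta
  } else r / H0
  max(2L, as.integer(ceiling(t_star / dt)) + 1L)
}

#' Simulate a lineage over several generations
#'
#' Grows a founding cell to the division trigger, divides it, and recurses on
#' the daughters for `n_generations` divisions. Optionally places newly
#' produced (`color = "new"`) motors on each daughter at birth.
#'
#' @param config A [sim_config()].
#' @param n_generations Number of divisions to simulate.
#' @param new_motors_per_daughter Number of new motors placed on each daughter
#'   at birth (default 0).
#' @return List with `truth` (combined per-frame motor table across all
#'   cells), `lineage` (all mother/daughter normalized-position pairs) and
#'   `cells` (list of `wm_cell`s, leaves last).
#' @export
simulate_lineage <- function(config, n_generations = 1,
                             new_motors_per_daughter = 0) {
  validate_sim_config(config)
  founder <- new_wm_cell("c1", config, config$initial_active_length_L0, 0,
                         place_founding_motors(config))
  cells <- list(); lineage <- list(); truth <- list()
  grow <- function(cell, gens_left) {
    nf <- frames_to_trigger(config, cell$L0)
    cell <- simulate_elongation(config, cell, n_frames = nf)
    if (gens_left > 0) {
      res <- simulate_division(cell, config)
      cells[[length(cells) + 1L]] <<- res$cell
      truth[[length(truth) + 1L]] <<- res$cell$truth
      lineage[[length(lineage) + 1L]] <<- res$lineage
      for (d in res$daughters) {
        if (new_motors_per_daughter > 0) {
          d <- place_new_motors(d, config, new_motors_per_daughter)
        }
        grow(d, gens_left - 1)
      }
    } else {
      cells[[length(cells) + 1L]] <<- cell
      truth[[length(truth) + 1L]] <<- cell$truth
    }
  }
  grow(founder, n_generations)
  list(truth = do.call(rbind, truth),
       lineage = if (length(lineage)) do.call(rbind, lineage) else NULL,
       cells = cells)
}

#' Simulate a cohort of independently growing cells
#'
#' Simulates elongation for as many founding cells as needed to carry
#' `total_motors` landmarks at `config$n_motors` per cell (the last cell takes
#' the remainder), emulating a population imaged in parallel. Each cell draws
#' placement and noise from substreams named by its id, so the cohort is
#' reproducible cell by cell.
#'
#' @param config A [sim_config()].
#' @param total_motors Total number of motors across the cohort.
#' @return List with `truth` (combined table) and `cells`.
#' @export
simulate_cohort <- function(config, total_motors) {
  per <- max(1L, config$n_motors)
  n_cells <- as.integer(ceiling(total_motors / per))
  cells <- vector("list", n_cells)
  left <- total_motors
  for (i in seq_len(n_cells)) {
    cid <- sprintf("c%03d", i)
    n_i <- min(per, left); left <- left - n_i
    cell <- new_wm_cell(cid, config, config$initial_active_length_L0, 0,
                        place_founding_motors(config, cid, n = n_i))
    cells[[i]] <- simulate_elongation(config, cell)
  }
  list(truth = do.call(rbind, lapply(cells, `[[`, "truth")), cells = cells)
}

#' Assign trace ids from known motor identities
#'
#' For tables that carry `motor_id` (simulator output), builds the `trace_id`
#' column directly from the identities instead of nearest-neighbour linking.
#'
#' @param obs Observed table with `cell_id`, `motor_id`.
#' @return The table with an integer `trace_id` column added.
#' @export
traces_from_motor_ids <- function(obs) {
  obs$trace_id <- as.integer(factor(paste(obs$cell_id, obs$motor_id)))
  obs
}

#' Apply the observation model and export tables
#'
#' Adds i.i.d. Gaussian localization noise (`localization_sigma`) to the
#' lateral and axial positions, recomputes the pole distance `P_y` from the
#' noisy axial position, drops detections at `detection_miss_rate`, and
#' (optionally) writes `truth.csv` and `observed.csv`. Deterministic for a
#' fixed `rng_seed`: noise and misses draw from their own named substreams.
#'
#' @param truth A truth table from [simulate_elongation()] or
#'   [simulate_lineage()].
#' @param config The `wm_sim_config`.
#' @param dir Optional output directory; created if needed.
#' @return The observed table (columns `cell_id, motor_id, frame, time_min,
#'   x_um, y_um, P_y_um, color`).
#' @export
add_noise_and_export <- function(truth, config, dir = NULL) {
  validate_sim_config(config)
  obs <- truth[, c("cell_id", "motor_id", "frame", "time_min",
                   "x_um", "y_um", "P_y_um", "color")]
  n <- nrow(obs)
  if (config$localization_sigma > 0) {
    eps <- with_substream(config$rng_seed, "noise",
                          stats::rnorm(2 * n, 0, config$localization_sigma))
    obs$x_um <- obs$x_um + eps[seq_len(n)]
    obs$y_um <- obs$y_um + eps[n + seq_len(n)]
    obs$P_y_um <- truth$cell_length_um / 2 - abs(obs$y_um)
  }
  if (config$detection_miss_rate > 0) {
    keep <- with_substream(config$rng_seed, "miss",
                           stats::runif(n) >= config$detection_miss_rate)
    obs <- obs[keep, , drop = FALSE]
    rownames(obs) <- NULL
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_table(truth, file.path(dir, "truth.csv"), schema = "truth")
    write_table(obs, file.path(dir, "observed.csv"), schema = "observed")
  }
  obs
}
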