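test_that("the assignment solver matches brute-force enumeration", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:5, 1); m <- sample(n:6, 1)
    cost <- matrix(runif(n * m), n, m)
    got <- wallmark:::hungarian_assign(cost)
    ref <- brute_force_assign(cost)
    expect_equal(sum(cost[cbind(seq_len(n), got)]), ref$cost,
                 tolerance = 1e-12)
  }
  # rows > columns: some rows stay unassigned, total cost still minimal
  cost <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  got <- wallmark:::hungarian_assign(cost)
  expect_equal(sum(is.na(got)), 1)
})

test_that("linking follows motors, bridges one gap and respects the gate", {
  # two motors drifting apart, one detection missing in frame 2
  sp <- data.frame(
    frame = c(1, 1, 2, 3, 3, 4, 4),
    time_min = c(0, 0, 10, 20, 20, 30, 30),
    x_um = 0,
    y_um = c(0, 1, 0.05, 0.10, 1.30, 0.15, 1.45))
  lk <- link_traces(sp, gate_um_per_10min = 0.3, max_gap = 1)
  # motor A: frames 1-4 linked through; motor B: gap at frame 2 bridged
  a <- lk$trace_id[lk$y_um %in% c(0, 0.05, 0.10, 0.15)]
  b <- lk$trace_id[lk$y_um %in% c(1, 1.30, 1.45)]
  expect_length(unique(a), 1)
  expect_length(unique(b), 1)
  expect_false(unique(a) == unique(b))
  # a displacement beyond the gate starts a new trace
  sp2 <- data.frame(frame = 1:2, time_min = c(0, 10), x_um = 0,
                    y_um = c(0, 0.5))
  lk2 <- link_traces(sp2)
  expect_length(unique(lk2$trace_id), 2)
  # the gate scales with the frame interval
  sp3 <- data.frame(frame = 1:2, time_min = c(0, 20), x_um = 0,
                    y_um = c(0, 0.5))
  lk3 <- link_traces(sp3)
  expect_length(unique(lk3$trace_id), 1)
})

test_that("ambiguous links are resolved by minimal total displacement", {
  # A: 0 -> 0.20 and B: 0.25 -> 0.29; both candidate links fall within the
  # gate for both motors. The minimal-total-displacement assignment is the
  # order-preserving one (0.20 + 0.04 = 0.24, against 0.29 + 0.05 = 0.34 for
  # the crossing), so identities never swap.
  sp <- data.frame(frame = c(1, 1, 2, 2), time_min = c(0, 0, 10, 10),
                   x_um = 0, y_um = c(0, 0.25, 0.20, 0.29))
  lk <- link_traces(sp, gate_um_per_10min = 0.3)
  t1 <- lk$trace_id[lk$frame == 1][order(lk$y_um[lk$frame == 1])]
  t2 <- lk$trace_id[lk$frame == 2][order(lk$y_um[lk$frame == 2])]
  expect_identical(t1, t2)   # order-preserving assignment
})

test_that("duplicate (frame, position) rows are rejected", {
  sp <- data.frame(frame = c(1, 1), time_min = 0, x_um = 0, y_um = c(0.2, 0.2))
  expect_error(link_traces(sp), "duplicate")
})

test_that("link accuracy is at least 95% on the resolvable LB fixture", {
  cell <- make_resolvable_fixture(seed = 1)
  cfg <- cell$config
  obs <- add_noise_and_export(cell$truth, cfg)
  lk <- link_traces(obs[, c("cell_id", "frame", "time_min", "x_um", "y_um",
                            "P_y_um")])
  acc <- link_accuracy(obs, lk)
  expect_gte(acc$n_links, 100)
  expect_gte(acc$accuracy, 0.95)
})

test_that("fit_VPy matches the lm() slope oracle", {
  set.seed(37)
  t <- seq(0, 60, by = 10)
  p <- 0.3 + 0.002 * t + rnorm(7, 0, 0.01)
  f <- fit_VPy(t, p)
  expect_equal(f$V_Py, oracle_slope(t, p), tolerance = 1e-12)
  expect_equal(f$P_y0, p[1])
  lmfit <- stats::lm(p ~ t)
  expect_equal(f$stderr, unname(sqrt(diag(stats::vcov(lmfit)))[2]),
               tolerance = 1e-10)
  expect_error(fit_VPy(0, 0.3), "at least 2")
})

test_that("the hinge fit recovers an exact changepoint to grid resolution", {
  set.seed(41)
  P <- runif(120, 0.05, 0.8)
  V <- 0.015 * pmax(P - 0.31, 0)
  fit <- fit_inert_zone(P, V, n_boot = 200, seed = 1)
  expect_lt(abs(fit$P_yc - 0.31), 2 * fit$grid_res)
  expect_equal(fit$k, 0.015, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-8)
  expect_true(fit$ci_Pyc[1] <= fit$P_yc && fit$P_yc <= fit$ci_Pyc[2])
})

test_that("the hinge fit refuses unidentifiable inputs", {
  expect_error(fit_inert_zone(c(0.1, 0.2, 0.3), c(0, 0, 0)), "too few")
  expect_error(fit_inert_zone(runif(10, 0.1, 0.5), rep(0, 10)),
               "all velocities are zero")
  expect_error(fit_inert_zone(rep(0.3, 10), rep(0.001, 10)),
               "no interior|identifiable")
  # negative-slope data has no valid positive-slope candidate
  P <- seq(0.1, 0.8, length.out = 10)
  expect_error(fit_inert_zone(P, -0.01 * P), "positive slope")
})

test_that("the bootstrap CI is reproducible and covers a noisy truth", {
  set.seed(43)
  P <- runif(150, 0.05, 0.8)
  V <- 0.015 * pmax(P - 0.27, 0) + rnorm(150, 0, 3e-4)
  f1 <- fit_inert_zone(P, V, seed = 5)
  f2 <- fit_inert_zone(P, V, seed = 5)
  expect_identical(f1$ci_Pyc, f2$ci_Pyc)
  expect_true(f1$ci_Pyc[1] < 0.27 && 0.27 < f1$ci_Pyc[2])
})

test_that("pair kinematics on noise-free growth are exactly Hubble-like", {
  cfg <- sim_preset("LB", n_motors = 8, rng_seed = 47, localization_sigma = 0)
  cell <- simulate_elongation(cfg)
  obs <- add_noise_and_export(cell$truth, cfg)
  tr <- traces_from_motor_ids(obs)
  pairs <- pair_kinematics(tr, P_yc = cfg$cap_size_c)
  expect_gt(nrow(pairs), 0)
  # lateral separations never change
  expect_equal(max(abs(pairs$V_Dx)), 0)
  # V_Dy = H D_y exactly, with H the interval growth of the active zone
  hub <- estimate_H(pairs)
  for (i in seq_len(nrow(hub$estimates))) {
    t1 <- hub$estimates$time_min[i]
    g1 <- oracle_growth_factor(t1, cfg$growth_rate_H0,
                               cfg$growth_acceleration_beta)
    g2 <- oracle_growth_factor(t1 + cfg$frame_interval_dt, cfg$growth_rate_H0,
                               cfg$growth_acceleration_beta)
    H_exact <- (g2 / g1 - 1) / cfg$frame_interval_dt
    expect_equal(hub$estimates$H[i], H_exact, tolerance = 1e-10)
  }
  expect_equal(hub$normalized$V_Dy_over_H, hub$normalized$D_y,
               tolerance = 1e-10)
})

test_that("the worked pair-kinematics value is frozen: V_Dy = (e^0.1 - 1)/10
           for D_y = 1, H0 = 0.01, beta = 0, dt = 10", {
  # two active motors exactly 1 um apart axially
  cfg <- sim_config(growth_acceleration_beta = 0, n_motors = 2, rng_seed = 1,
                    localization_sigma = 0, initial_active_length_L0 = 2)
  cell <- simulate_elongation(cfg, n_frames = 2)
  cell$motors$type <- "active"
  cell$motors$N <- c(-0.25, 0.25)     # 1 um apart on L0 = 2
  cell$motors$P_y <- NA_real_
  cell <- simulate_elongation(cfg, cell, n_frames = 2)
  obs <- add_noise_and_export(cell$truth, cfg)
  pairs <- pair_kinematics(traces_from_motor_ids(obs), P_yc = cfg$cap_size_c)
  expect_equal(pairs$D_y, 1)
  expect_equal(pairs$V_Dy, (exp(0.1) - 1) / 10, tolerance = 1e-12)
})

test_that("normalized coordinates are constant in elongation and drift
           outward with the sign of N_y during division", {
  cfg <- sim_preset("LB", n_motors = 10, rng_seed = 53,
                    localization_sigma = 0, n_frames = 8)
  cell <- simulate_elongation(cfg)
  res <- simulate_division(cell, cfg)
  truth <- res$cell$truth[res$cell$truth$type == "active", ]
  tr <- traces_from_motor_ids(truth)
  geo <- unique(res$cell$truth[, c("cell_id", "frame", "time_min",
                                   "cell_length_um", "phase")])
  norm <- normalize_positions(tr, geo, P_yc = cfg$cap_size_c)
  el <- norm$slopes[norm$slopes$phase == "elongation", ]
  expect_gt(nrow(el), 0)
  expect_lt(max(abs(el$slope)), 1e-12)
  dv <- norm$slopes[norm$slopes$phase == "division", ]
  dv <- dv[abs(dv$mean_N_y) > 0.02, ]
  expect_gt(nrow(dv), 0)
  expect_identical(sign(dv$slope), sign(dv$mean_N_y))
})

test_that("central motors are displaced by exactly the cap size", {
  cfg <- sim_preset("LB", n_motors = 1, rng_seed = 59, n_frames = 8,
                    localization_sigma = 0)
  cell <- simulate_elongation(cfg)
  cell$motors$type <- "active"; cell$motors$N <- 0
  cell <- simulate_elongation(cfg, cell)
  res <- simulate_division(cell, cfg)
  truth <- res$cell$truth
  tr <- traces_from_motor_ids(truth)
  onset <- max(cell$frames$time_min)
  end <- max(truth$time_min)
  disp <- central_motor_displacement(tr, onset, end)
  expect_equal(nrow(disp), 1)
  expect_identical(disp$displacement_um, cfg$cap_size_c)
})
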