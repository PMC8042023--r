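test_that("elongation follows the exact integral of dL/dt = H(t) L", {
  cfg <- sim_preset("LB", rng_seed = 1)
  cell <- simulate_elongation(cfg)
  t <- (cell$frames$frame - 1) * cfg$frame_interval_dt
  expect_equal(cell$frames$L_active_um,
               cfg$initial_active_length_L0 *
                 oracle_growth_factor(t, cfg$growth_rate_H0,
                                      cfg$growth_acceleration_beta))
  expect_equal(cell$frames$cell_length_um,
               cell$frames$L_active_um + 2 * cfg$cap_size_c)
})

test_that("active motors keep their normalized coordinate exactly", {
  cfg <- sim_preset("LB", n_motors = 12, rng_seed = 2)
  cell <- simulate_elongation(cfg)
  tr <- cell$truth[cell$truth$type == "active", ]
  for (m in unique(tr$motor_id)) {
    ny <- tr$N_y_true[tr$motor_id == m]
    expect_identical(ny, rep(ny[1], length(ny)))
    # and the lab position is exactly N * L
    sub <- tr[tr$motor_id == m, ]
    expect_identical(sub$y_um, sub$N_y_true * sub$L_active_um)
  }
})

test_that("inert motors ride at constant distance from their pole tip", {
  cfg <- sim_preset("LB", n_motors = 30, rng_seed = 3)
  cell <- simulate_elongation(cfg)
  tr <- cell$truth[cell$truth$type == "inert", ]
  expect_gt(nrow(tr), 0)
  for (m in unique(tr$motor_id)) {
    py <- tr$P_y_um[tr$motor_id == m]
    expect_equal(py, rep(py[1], length(py)), tolerance = 1e-12)
    expect_true(all(py <= cfg$cap_size_c + 1e-12))
  }
})

test_that("motors placed outside the allowed span are rejected", {
  cfg <- sim_preset("LB", n_motors = 1, rng_seed = 1)
  cell <- simulate_elongation(cfg)
  cell$motors$type <- "active"
  cell$motors$N <- 0.7
  expect_error(simulate_elongation(cfg, cell), "outside the allowed span")
})

test_that("truncated-Gaussian sampling respects bounds and sigma = Inf", {
  set.seed(10)
  x <- rtruncgauss(5000, sigma = 0.4)
  expect_true(all(x >= -0.5 & x <= 0.5))
  # centre-biased: more mass in the middle fifth than uniform would give
  expect_gt(mean(abs(x) < 0.1), 0.2)
  u <- rtruncgauss(5000, sigma = Inf)
  expect_true(all(u >= -0.5 & u <= 0.5))
  expect_lt(ks_to_uniform(u), 0.03)
  expect_identical(rtruncgauss(0), numeric(0))
})

test_that("division requires the trigger unless forced", {
  cfg <- sim_preset("LB", n_motors = 4, rng_seed = 5, n_frames = 3)
  cell <- simulate_elongation(cfg)
  expect_error(simulate_division(cell, cfg), "trigger")
  expect_silent(simulate_division(cell, cfg, force = TRUE))
})

test_that("division geometry: septum grows linearly to the cap size and the
           daughters are half-rods with a new endcap", {
  cfg <- sim_preset("LB", n_motors = 6, rng_seed = 7, n_frames = 8)
  cell <- simulate_elongation(cfg)
  res <- simulate_division(cell, cfg)
  div <- res$cell$frames[res$cell$frames$phase == "division", ]
  expect_equal(div$septal_offset_um[nrow(div)], cfg$cap_size_c)
  # septal offset is linear in time since onset
  t_on <- max(cell$frames$time_min)
  expect_equal(div$septal_offset_um,
               cfg$cap_size_c * (div$time_min - t_on) / cfg$division_duration)
  # each daughter starts with half the final active zone
  L_T <- div$L_active_um[nrow(div)]
  for (d in res$daughters) expect_equal(d$L0, L_T / 2)
  # motors are conserved across the split
  expect_equal(sort(c(res$daughters[[1]]$motors$motor_id,
                      res$daughters[[2]]$motors$motor_id)),
               sort(cell$motors$motor_id))
})

test_that("a motor exactly at mid-cell is assigned by a seeded fair coin", {
  cfg <- sim_preset("LB", n_motors = 1, rng_seed = 1, n_frames = 8)
  mk <- function(seed) {
    cfg2 <- sim_preset("LB", n_motors = 1, rng_seed = seed, n_frames = 8)
    cell <- simulate_elongation(cfg2)
    cell$motors$type <- "active"; cell$motors$N <- 0
    cell <- simulate_elongation(cfg2, cell)
    res <- simulate_division(cell, cfg2)
    res$lineage$side
  }
  sides <- vapply(1:20, mk, 0)
  expect_true(all(sides %in% c(-1, 1)))
  expect_true(length(unique(sides)) == 2)  # the coin actually varies by seed
  expect_identical(mk(4), mk(4))           # and is reproducible
})

test_that("simulate_lineage returns one truth row per cell, frame and motor", {
  cfg <- sim_preset("LB", n_motors = 6, rng_seed = 11)
  sim <- simulate_lineage(cfg, n_generations = 2)
  key <- paste(sim$truth$cell_id, sim$truth$frame, sim$truth$motor_id)
  expect_false(anyDuplicated(key) > 0)
  expect_setequal(unique(sim$lineage$mother_id), c("c1", "c1.1", "c1.2"))
  # every lineage pair stays inside the normalized span
  act <- !is.na(sim$lineage$N_y_daughter)
  expect_true(all(abs(sim$lineage$N_y_daughter[act]) <= 0.5))
})

test_that("new motors are tagged and centre-biased", {
  cfg <- sim_preset("LB", n_motors = 4, rng_seed = 13)
  sim <- simulate_lineage(cfg, n_generations = 1, new_motors_per_daughter = 30)
  new <- sim$truth[sim$truth$color == "new" & sim$truth$frame == 1, ]
  expect_gt(nrow(new), 0)
  expect_true(all(abs(new$N_y_true) <= 0.5))
  inherited_frac <- mean(abs(new$N_y_true) < 0.2)
  expect_gt(inherited_frac, 0.3)  # truncgauss sigma 0.4 puts ~38% below 0.2
})

test_that("simulate_cohort spreads the requested motors over cells", {
  cfg <- sim_preset("LB", n_motors = 9, rng_seed = 17)
  sim <- simulate_cohort(cfg, 25)
  per_cell <- table(unique(sim$truth[, c("cell_id", "motor_id")])$cell_id)
  expect_equal(sum(per_cell), 25)
  expect_equal(unname(per_cell[["c001"]]), 9)
  expect_equal(unname(per_cell[["c003"]]), 7)  # remainder cell
})

test_that("the observation model is deterministic and recomputes P_y", {
  cfg <- sim_preset("LB", n_motors = 8, rng_seed = 19,
                    localization_sigma = 0.03)
  cell <- simulate_elongation(cfg)
  o1 <- add_noise_and_export(cell$truth, cfg)
  o2 <- add_noise_and_export(cell$truth, cfg)
  expect_identical(o1, o2)
  expect_identical(o1$P_y_um, cell$truth$cell_length_um / 2 - abs(o1$y_um))
  expect_false(any(o1$y_um == cell$truth$y_um))
})

test_that("zero localization noise passes positions through unchanged", {
  cfg <- sim_preset("LB", n_motors = 5, rng_seed = 23, localization_sigma = 0)
  cell <- simulate_elongation(cfg)
  obs <- add_noise_and_export(cell$truth, cfg)
  expect_identical(obs$y_um, cell$truth$y_um)
  expect_identical(obs$P_y_um, cell$truth$P_y_um)
})
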