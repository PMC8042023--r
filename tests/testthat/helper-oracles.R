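# Independent oracles used across the test files. Everything here is written
# from the mathematical definitions, not from the package internals.

# --- Bernoulli pushforward oracle -------------------------------------------
#
# CDF of the truncated Gaussian (mean 0, sd sigma) on [-0.5, 0.5].
truncgauss_cdf <- function(u, sigma = 0.4) {
  lo <- stats::pnorm(-0.5, 0, sigma)
  hi <- stats::pnorm(0.5, 0, sigma)
  pmin(pmax((stats::pnorm(u, 0, sigma) - lo) / (hi - lo), 0), 1)
}

# CDF after g applications of the shift map N' = 2N - 0.5 (N > 0),
# N' = 2N + 0.5 (N < 0). For u in [-0.5, 0.5]:
#   P(N' <= u) = [F((u + 0.5)/2) - F(0)] + F((u - 0.5)/2),
# evaluated by recursion on g (the starting law puts no mass at exactly 0 for
# an absolutely continuous initial law, so the branch at 0 is immaterial).
pushforward_cdf <- function(u, g, cdf0 = truncgauss_cdf) {
  if (g == 0) return(cdf0(u))
  f <- function(v) pushforward_cdf(v, g - 1, cdf0)
  (f((u + 0.5) / 2) - f(0)) + f((u - 0.5) / 2)
}

# Exact (up to grid refinement) KS distance of the generation-g pushforward
# law to the uniform law on [-0.5, 0.5].
pushforward_ks_to_uniform <- function(g, cdf0 = truncgauss_cdf,
                                      n_grid = 20001) {
  u <- seq(-0.5, 0.5, length.out = n_grid)
  max(abs(pushforward_cdf(u, g, cdf0) - (u + 0.5)))
}

# --- assignment oracle -------------------------------------------------------
#
# Brute-force minimal-cost assignment by permutation enumeration (rows <=
# columns required; returns per-row assigned column).
brute_force_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, n <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, ncol = length(v)))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], perms(v[-i]))
    }))
  }
  cols <- utils::combn(m, n)
  best <- NULL; best_cost <- Inf
  for (ci in seq_len(ncol(cols))) {
    pp <- perms(cols[, ci])
    for (ri in seq_len(nrow(pp))) {
      cst <- sum(cost[cbind(seq_len(n), pp[ri, ])])
      if (cst < best_cost) { best_cost <- cst; best <- pp[ri, ] }
    }
  }
  list(assignment = best, cost = best_cost)
}

# --- growth-law oracle -------------------------------------------------------
#
# Exact active-zone growth factor, written independently of the package.
oracle_growth_factor <- function(t, H0, beta) exp(H0 * t + H0 * beta * t^2 / 2)

# OLS slope oracle via lm().
oracle_slope <- function(x, y) unname(stats::coef(stats::lm(y ~ x))[2])

# --- fixture builders --------------------------------------------------------
#
# The LB linking fixture: 20 motors whose pairwise 2D separation at time 0 is
# at least `min_sep` (the optical resolution at the default pixel scale), by
# seeded thinning of the generator's own placement. Motors closer than the
# diffraction limit are not resolvable as two spots by any detector, so the
# link-accuracy claim is made on resolvable configurations.
make_resolvable_fixture <- function(seed, n_motors = 20, min_sep = 0.25,
                                    pool = 60) {
  cfg <- sim_preset("LB", n_motors = pool, rng_seed = seed,
                    localization_sigma = 0.03)
  cell <- simulate_elongation(cfg, n_frames = 1)
  pos <- cell$truth[cell$truth$frame == 1, ]
  keep <- integer(0)
  for (i in seq_len(nrow(pos))) {
    if (length(keep) == n_motors) break
    if (!length(keep)) { keep <- i; next }
    d <- sqrt((pos$x_um[keep] - pos$x_um[i])^2 +
              (pos$y_um[keep] - pos$y_um[i])^2)
    if (all(d >= min_sep)) keep <- c(keep, i)
  }
  stopifnot(length(keep) == n_motors)
  cell$motors <- cell$motors[cell$motors$motor_id %in% pos$motor_id[keep], ]
  simulate_elongation(cfg, cell = cell)
}

# Fraction of frame-to-frame links whose two endpoints belong to the same
# ground-truth motor (lineage-matched oracle: identities come from the truth
# table, matched to the noisy observations by exact position equality).
link_accuracy <- function(obs, linked) {
  key <- paste(obs$cell_id, obs$frame, round(obs$x_um, 9), round(obs$y_um, 9))
  linked$motor_id <- obs$motor_id[
    match(paste(linked$cell_id, linked$frame, round(linked$x_um, 9),
                round(linked$y_um, 9)), key)]
  linked <- linked[order(linked$trace_id, linked$frame), ]
  ok <- 0L; n <- 0L
  for (tid in unique(linked$trace_id)) {
    s <- linked[linked$trace_id == tid, ]
    if (nrow(s) < 2) next
    good <- s$motor_id[-1] == s$motor_id[-nrow(s)]
    ok <- ok + sum(good); n <- n + length(good)
  }
  list(accuracy = ok / n, n_links = n)
}

# Simulate a cohort, apply the observation model, and fit the inert zone from
# ground-truth-identified traces (the paper's n motors span many cells).
recover_pyc <- function(preset, n_total, seed, sigma = 0.03, n_boot = 0) {
  cfg <- sim_preset(preset, rng_seed = seed, localization_sigma = sigma)
  sim <- simulate_cohort(cfg, n_total)
  obs <- add_noise_and_export(sim$truth, cfg)
  tr <- traces_from_motor_ids(obs)
  vf <- fit_VPy_all(tr)
  fit_inert_zone(vf$P_y0, vf$V_Py, n_boot = n_boot, seed = seed)
}
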