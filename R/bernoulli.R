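#' One step of the Bernoulli shift map
#'
#' Maps a normalized axial position in generation `n` to generation `n + 1`:
#' `2 N - 0.5` for `0 < N <= 0.5` and `2 N + 0.5` for `-0.5 <= N < 0`.
#' `N = 0` is not covered by either branch; by default it raises an error,
#' or, with `zero_policy = "coin"`, a seeded fair coin picks the branch
#' (matching the simulator's rule for a motor exactly at the division site).
#'
#' @param ny Numeric vector of normalized positions in `[-0.5, 0.5]`.
#' @param zero_policy `"error"` (default) or `"coin"`.
#' @param coin_seed Seed for the coin when `zero_policy = "coin"`.
#' @return Numeric vector of next-generation positions.
#' @export
bernoulli_step <- function(ny, zero_policy = c("error", "coin"),
                           coin_seed = 1L) {
  zero_policy <- match.arg(zero_policy)
  if (any(!is.finite(ny)) || any(abs(ny) > 0.5)) {
    stop("normalized positions must lie in [-0.5, 0.5]", call. = FALSE)
  }
  out <- ifelse(ny > 0, 2 * ny - 0.5, 2 * ny + 0.5)
  zz <- which(ny == 0)
  if (length(zz)) {
    if (zero_policy == "error") {
      stop("the map is undefined at N_y = 0; use zero_policy = \"coin\"",
           call. = FALSE)
    }
    coin <- with_substream(coin_seed, "bernoulli-coin",
                           stats::runif(length(zz)) < 0.5)
    out[zz] <- ifelse(coin, -0.5, 0.5)
  }
  out
}

#' Iterate the Bernoulli shift map
#'
#' Applies [bernoulli_step()] `n_generations` times, recording every value and
#' the branch taken.
#'
#' @param ny0 Starting normalized position.
#' @param n_generations Number of map applications.
#' @inheritParams bernoulli_step
#' @return A `wm_bernoulli_trajectory`: list with `ny` (length
#'   `n_generations + 1`, starting value included) and `branch`
#'   (`"upper"`/`"lower"` per step).
#' @export
bernoulli_iterate <- function(ny0, n_generations,
                              zero_policy = c("error", "coin"),
                              coin_seed = 1L) {
  zero_policy <- match.arg(zero_policy)
  ny <- numeric(n_generations + 1)
  branch <- character(n_generations)
  ny[1] <- ny0
  for (i in seq_len(n_generations)) {
    branch[i] <- if (ny[i] > 0) "upper" else if (ny[i] < 0) "lower" else "zero"
    ny[i + 1] <- bernoulli_step(ny[i], zero_policy, coin_seed)
  }
  structure(list(ny = ny, branch = branch),
            class = "wm_bernoulli_trajectory")
}

# -- exact rational orbit ----------------------------------------------------

gcd2 <- function(a, b) { a <- abs(a); b <- abs(b)
  while (b) { t <- b; b <- a %% b; a <- t }; a }

reduce_frac <- function(p, q) {
  if (q < 0) { p <- -p; q <- -q }
  g <- gcd2(p, q); if (g > 1) { p <- p / g; q <- q / g }
  c(p, q)
}

#' Iterate the Bernoulli shift map in exact rational arithmetic
#'
#' For a starting position `p/q` the map stays within rationals of bounded
#' denominator, so orbits of rational points are eventually periodic; exact
#' integer arithmetic preserves this where floating point would drift. One
#' step maps `p/q` (with `p > 0`) to `(4p - q) / (2q)` and `p < 0` to
#' `(4p + q) / (2q)`, reduced to lowest terms.
#'
#' @param p,q Integer numerator and (positive) denominator, `|p/q| <= 1/2`,
#'   `p != 0`.
#' @param n_generations Number of map applications.
#' @return Data frame with columns `generation`, `num`, `den`, `value`
#'   (`num/den` as numeric).
#' @export
bernoulli_iterate_exact <- function(p, q, n_generations) {
  stopifnot(q > 0, p == round(p), q == round(q))
  if (p == 0) stop("the map is undefined at N_y = 0", call. = FALSE)
  if (2 * abs(p) > q) stop("|p/q| must be <= 1/2", call. = FALSE)
  pq <- reduce_frac(p, q)
  out <- matrix(0, nrow = n_generations + 1, ncol = 2)
  out[1, ] <- pq
  for (i in seq_len(n_generations)) {
    p <- pq[1]; q <- pq[2]
    pq <- if (p > 0) reduce_frac(4 * p - q, 2 * q) else reduce_frac(4 * p + q, 2 * q)
    if (pq[1] == 0) {
      stop("orbit reached N_y = 0, where the map is undefined", call. = FALSE)
    }
    out[i + 1, ] <- pq
  }
  data.frame(generation = 0:n_generations, num = out[, 1], den = out[, 2],
             value = out[, 1] / out[, 2])
}

#' Exact Kolmogorov-Smirnov distance to the uniform law on \[-0.5, 0.5\]
#'
#' @param x Numeric sample in `[-0.5, 0.5]`.
#' @return The supremum distance between the empirical CDF and the uniform
#'   CDF, computed exactly.
#' @export
ks_to_uniform <- function(x) {
  n <- length(x)
  u <- sort(x) + 0.5
  max(pmax(seq_len(n) / n - u, u - (seq_len(n) - 1) / n))
}

#' Evolve a population of normalized positions across generations
#'
#' Samples `n_particles` starting positions (truncated Gaussian by default,
#' the centre-biased law used to seed the distribution-evolution simulation),
#' deterministically maps each particle with [bernoulli_step()] once per
#' generation, and records per-generation histograms and the exact KS distance
#' to the uniform law. The uniform law is invariant under the map; any
#' absolutely continuous initial law is smoothed toward it, halving
#' deviation scales each generation.
#'
#' @param n_particles Number of particles (default 200000).
#' @param sigma Standard deviation of the truncated Gaussian initial law
#'   (default 0.4); ignored when `init` is given.
#' @param generations Number of divisions to simulate (default 3).
#' @param bins Number of histogram bins on `[-0.5, 0.5]` (default 50).
#' @param seed RNG seed for the initial sampling (and the rare mid-cell coin).
#' @param init Either `"truncgauss"`, `"uniform"`, or a numeric vector of
#'   starting positions (overrides `n_particles`).
#' @return A `wm_distribution_sim`: list with `histograms` (bins x
#'   generations+1 matrix of bin probabilities), `ks` (KS distance to uniform
#'   per generation, starting at generation 0), `breaks`, `n_particles`,
#'   `samples` (final-generation sample).
#' @export
evolve_distribution <- function(n_particles = 200000, sigma = 0.4,
                                generations = 3, bins = 50, seed = 1L,
                                init = "truncgauss") {
  x <- if (is.numeric(init)) {
    init
  } else {
    with_substream(seed, "bernoulli-init", switch(match.arg(init, c("truncgauss", "uniform")),
      truncgauss = rtruncgauss(n_particles, sigma),
      uniform = stats::runif(n_particles, -0.5, 0.5)))
  }
  n_particles <- length(x)
  breaks <- seq(-0.5, 0.5, length.out = bins + 1)
  hist1 <- function(v) {
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    h$counts / length(v)
  }
  H <- matrix(0, nrow = bins, ncol = generations + 1)
  ks <- numeric(generations + 1)
  H[, 1] <- hist1(x); ks[1] <- ks_to_uniform(x)
  for (g in seq_len(generations)) {
    x <- bernoulli_step(x, zero_policy = "coin", coin_seed = seed)
    H[, g + 1] <- hist1(x)
    ks[g + 1] <- ks_to_uniform(x)
  }
  colnames(H) <- paste0("gen", 0:generations)
  structure(list(histograms = H, ks = ks, breaks = breaks,
                 n_particles = n_particles, samples = x),
            class = "wm_distribution_sim")
}

#' Compare observed cross-generation position pairs with the map
#'
#' For each observed mother/daughter pair of normalized positions, computes
#' the residual `|N_daughter - step(N_mother)|` and the fraction of pairs
#' within `tolerance` of the map. A mother exactly at 0 is scored against the
#' nearer branch.
#'
#' @param ny_mother,ny_daughter Numeric vectors of paired normalized
#'   positions.
#' @param tolerance On-map tolerance (default 0.05).
#' @return List with `residuals`, `fraction_on_map`, `n`.
#' @export
predict_vs_observed <- function(ny_mother, ny_daughter, tolerance = 0.05) {
  stopifnot(length(ny_mother) == length(ny_daughter))
  keep <- is.finite(ny_mother) & is.finite(ny_daughter)
  m <- ny_mother[keep]; d <- ny_daughter[keep]
  pred_up <- 2 * m - 0.5
  pred_lo <- 2 * m + 0.5
  res <- ifelse(m > 0, abs(d - pred_up),
                ifelse(m < 0, abs(d - pred_lo),
                       pmin(abs(d - pred_up), abs(d - pred_lo))))
  list(residuals = res,
       fraction_on_map = if (length(res)) mean(res <= tolerance) else NA_real_,
       n = length(res))
}
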