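# Umbrella windows, restrained sampling, MBAR, and barrier extraction.

test_that("window layout matches the arithmetic closed form", {
  expect_equal(nrow(build_windows(c(-10, 10), 0.25, 50)), 81)
  expect_equal(nrow(build_windows(c(-8, 8), 0.25, 50)), 65)
  expect_warning(w1 <- build_windows(c(0, 1), 2, 50), "single window")
  expect_equal(nrow(w1), 1)
  expect_equal(w1$center, 0.5)
  expect_error(build_windows(c(1, 0), 0.25, 50), "lo < hi")
})

test_that("restrained harmonic sampling follows the two-spring closed form", {
  k_sys <- 4
  k_r <- 36
  sys <- make_system("harmonic", list(k = k_sys))
  cfg <- as_config(T = 1, dt = 0.01, friction = 1)
  wins <- build_windows(c(-0.2, 0.2), 0.5, k_r, n_replicas = 2, n_steps = 30000)
  expect_warning(wins, NA) # layout is fine here
  ud <- run_umbrella(sys, x_cv(), wins, cfg, seed = 6, save_stride = 2)
  q <- unlist(ud$series)
  g <- statistical_inefficiency(q)
  se_var <- sd(q^2) / sqrt(length(q) / g)
  expect_lt(abs(var(q) - 1 / (k_sys + k_r)), 3 * se_var)
  # stiff-spring limit: the sample mean collapses onto the window center
  cfg_stiff <- as_config(T = 1, dt = 0.002, friction = 1)
  wins_stiff <- suppressWarnings(build_windows(c(0.5, 1.0), 2, 2000,
                                               n_replicas = 1, n_steps = 8000))
  ud2 <- run_umbrella(sys, x_cv(), wins_stiff, cfg_stiff, seed = 7)
  expect_equal(wins_stiff$center, 0.75)
  expect_lt(abs(mean(ud2$series[[1]]) - 0.75), 0.02)
})

test_that("restraint ramp only changes the initial transient", {
  sys <- make_system("harmonic", list(k = 1))
  cfg <- as_config(T = 1, dt = 0.01, friction = 1)
  w_ramp <- build_windows(c(0.4, 0.8), 0.5, 50, n_replicas = 1,
                          n_steps = 3000, ramp_steps = 1000)
  w_flat <- build_windows(c(0.4, 0.8), 0.5, 50, n_replicas = 1,
                          n_steps = 3000, ramp_steps = 0)
  ud_r <- run_umbrella(sys, x_cv(), w_ramp, cfg, seed = 5)
  ud_f <- run_umbrella(sys, x_cv(), w_flat, cfg, seed = 5)
  # same recorded length either way; both centered on the window
  expect_equal(length(ud_r$series[[1]]), length(ud_f$series[[1]]))
  expect_lt(abs(mean(ud_r$series[[1]]) - mean(ud_f$series[[1]])), 0.1)
})

test_that("MBAR matches the independent minimization oracle to 1e-6 kBT", {
  # fixed seeded dataset: Gaussian samples from each biased window
  set.seed(88)
  centers <- seq(-1, 1, by = 0.25)
  k <- 40
  sys <- make_system("harmonic", list(k = 3))
  cfg <- as_config(T = 1, dt = 0.01, friction = 1)
  wins <- build_windows(c(-1, 1), 0.25, k, n_replicas = 1, n_steps = 4000)
  ud <- run_umbrella(sys, x_cv(), wins, cfg, seed = 13)
  pmf <- mbar_pmf(ud, n_bins = 40, tol = 1e-10)
  u_kn <- umbrella_u_kn(pmf$q_n, pmf$bias_centers, pmf$bias_k)
  f_ref <- mbar_oracle(u_kn, pmf$N_k)
  expect_lt(max(abs(pmf$f_windows - f_ref)), 1e-6)
})

test_that("two-window MBAR reduces to Zwanzig exponential averaging", {
  # with one sampled state and one unsampled-ish state the MBAR fixed point
  # coincides with free-energy perturbation on the shared samples
  set.seed(21)
  q <- rnorm(4000, 0, 0.3)
  u1 <- 0.5 * 10 * (q - 0)^2
  u2 <- 0.5 * 10 * (q - 0.15)^2
  u_kn <- rbind(u1, u2)
  sol <- mechpath:::solve_mbar(u_kn, c(4000, 0), tol = 1e-12)
  zwanzig <- -log(mean(exp(-(u2 - u1))))
  expect_equal(unname(sol$f[2]), zwanzig, tolerance = 1e-9)
})

test_that("MBAR recovers the analytic double-well PMF", {
  sys <- dw_system(barrier = 6)
  cfg <- as_config(T = 1, dt = 0.005, friction = 2)
  wins <- build_windows(c(-1.5, 1.5), 0.125, 100, n_replicas = 2,
                        n_steps = 8000)
  ud <- suppressWarnings(run_umbrella(sys, x_cv(), wins, cfg, seed = 4))
  pmf <- mbar_pmf(ud, n_bins = 50)
  expect_equal(min(pmf$profile$G), 0)
  expect_true(all(pmf$profile$err >= 0))
  expect_true(all(diff(pmf$profile$center) > 0))
  V <- vapply(pmf$profile$center, sys$energy, numeric(1))
  keep <- V - min(V) < 7
  delta <- pmf$profile$G[keep] - V[keep]
  rms <- sqrt(mean((delta - mean(delta))^2))
  expect_lt(rms, 0.2)
  bh <- barrier_height(pmf, c(-1.5, -0.5))
  expect_lt(abs(bh$dG - 6), 0.3)
})

test_that("non-overlapping window chains raise an error naming the gap", {
  set.seed(3)
  ud <- structure(list(
    series = list(rnorm(500, -2, 0.05), rnorm(500, 2, 0.05)),
    meta = data.frame(window = 1:2, replica = 1, center = c(-2, 2),
                      k = 400, n = 500, mean_q = c(-2, 2), sd_q = 0.05,
                      flagged = FALSE),
    windows = data.frame(center = c(-2, 2), width = 4, k_restraint = 400,
                         n_replicas = 1, n_steps = 500, ramp_steps = 0),
    temperature = 1, kB = 1, dt = 0.01, save_stride = 1
  ), class = "umbrella_data")
  expect_error(mbar_pmf(ud), "overlap")
})

test_that("barrier extraction is arithmetic on the profile", {
  prof <- structure(list(profile = data.frame(
    center = seq(-10, 10, by = 0.5),
    G = 16.1 * exp(-(seq(-10, 10, by = 0.5))^2 / 8),
    err = 0.3), kT = 1), class = "pmf_profile")
  prof$profile$G[prof$profile$center <= -5] <- 0
  bh <- barrier_height(prof, c(-10, -5))
  expect_equal(bh$dG, 16.1)
  expect_equal(bh$err, sqrt(0.09 + 0.09))
  # strictly increasing profile: no barrier
  mono <- structure(list(profile = data.frame(center = 1:20, G = (1:20) / 2,
                                              err = 0.1), kT = 1),
                    class = "pmf_profile")
  expect_error(barrier_height(mono, c(1, 5)), "no barrier|monotone")
})

test_that("pathway restraints confine sampling to the observed envelope", {
  sys <- dw_system(barrier = 6)
  # friction high enough that windows starting outside the walls ring down
  # within the equilibration discard
  cfg <- as_config(T = 1, dt = 0.005, friction = 5, max_steps = 4000)
  cvs <- list(x_1 = x_cv())
  ens <- aimless_shooting_campaign(sys, list(frame(0)), 60, x_basins(),
                                   cvs, cfg, seed = 3)
  walls <- pathway_restraints(ens, cvs, sys, k_wall = 2000, margin = 0.05)
  env_lo <- walls[[1]]$lo
  env_hi <- walls[[1]]$hi
  # windows extend well past the envelope; walls must keep samples inside
  wins <- build_windows(c(env_lo - 1, env_hi + 1), 0.5, 20, n_replicas = 1,
                        n_steps = 3000)
  ud <- suppressWarnings(run_umbrella(sys, x_cv(), wins, cfg, seed = 5,
                                      extra_biases = walls))
  q <- unlist(ud$series)
  # allowed penetration: static pull of the farthest window against the
  # wall stiffness, plus the expected extreme of ~6e4 thermal samples
  # inside the wall (about 4.5 standard deviations)
  slack <- 20 * 1 / 2000 + 4.5 * sqrt(1 / 2000)
  expect_gte(min(q), env_lo - slack)
  expect_lte(max(q), env_hi + slack)
})

test_that("finite-difference rates recover linear trends exactly", {
  ser <- structure(list(time = seq(0, 1, by = 0.1),
                        values = cbind(a = seq(0, 2, length.out = 11),
                                       b = rep(1, 11)),
                        dt = 0.1), class = "cv_series")
  R <- cv_series_rates(ser)
  expect_equal(unname(R[, "a"]), rep(2, 11))
  expect_equal(unname(R[, "b"]), rep(0, 11))
})

test_that("PMF is invariant under stiffer, narrower windows", {
  sys <- make_system("harmonic", list(k = 2))
  cfg <- as_config(T = 1, dt = 0.01, friction = 1)
  w_a <- build_windows(c(-1, 1), 0.25, 30, n_replicas = 1, n_steps = 20000)
  w_b <- build_windows(c(-1, 1), 0.125, 60, n_replicas = 1, n_steps = 20000)
  pa <- mbar_pmf(run_umbrella(sys, x_cv(), w_a, cfg, seed = 8), n_bins = 30)
  pb <- mbar_pmf(run_umbrella(sys, x_cv(), w_b, cfg, seed = 9), n_bins = 30)
  # compare on the overlapping interior
  ga <- approx(pa$profile$center, pa$profile$G, xout = seq(-0.7, 0.7, 0.1))$y
  gb <- approx(pb$profile$center, pb$profile$G, xout = seq(-0.7, 0.7, 0.1))$y
  expect_lt(sqrt(mean((ga - gb - mean(ga - gb))^2)), 0.1)
})
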