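# Toy landscapes and the Langevin propagator.

test_that("analytic potentials match their closed forms and limits", {
  b <- 7.3
  sys <- dw_system(barrier = b)
  expect_equal(sys$energy(0), b)
  expect_equal(sys$energy(1), 0)
  expect_equal(sys$energy(-1), 0)

  sys2 <- make_system("tilted_double_well_2d",
                      list(barrier = b, k_y = 3.1, coupling = 0))
  for (x in c(-1.2, -0.3, 0.7)) {
    expect_equal(sys2$energy(c(x, 0)), sys$energy(x))
    expect_equal(sys2$energy(c(x, 0.5)), sys$energy(x) + 0.5 * 3.1 * 0.25)
  }

  # linear_combo_nd along a unit direction reduces to the 1D double well
  w <- c(3, 4) / 5
  sysn <- make_system("linear_combo_nd",
                      list(barrier = b, weights = c(3, 4), k_perp = 2))
  for (s in c(-1.1, 0, 0.4)) {
    expect_equal(sysn$energy(s * w), sys$energy(s), tolerance = 1e-12)
  }
})

test_that("system configuration errors name the problem", {
  expect_error(make_system("no_such"), "unknown potential_id")
  expect_error(make_system("double_well_1d"), "barrier")
  expect_error(make_system("double_well_1d", list(barrier = 1), masses = -1),
               "masses")
  expect_error(make_system("double_well_1d", list(barrier = 1, bogus = 2)),
               "bogus")
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(42)
  systems <- list(
    dw_system(barrier = 6, tilt = 0.4),
    xy_system(coupling = 0.8),
    make_system("linear_combo_nd",
                list(barrier = 9, weights = c(1, -2, 0.5, 3), k_perp = 1.7)),
    make_system("harmonic", list(k = 2.5), dim = 3L, n_particles = 2L)
  )
  h <- 1e-6
  for (sys in systems) {
    for (i in seq_len(25)) {
      x <- runif(sys$ncoord, -1.5, 1.5)
      g <- sys$gradient(x)
      fd <- vapply(seq_along(x), function(j) {
        e <- numeric(length(x)); e[j] <- h
        (sys$energy(x + e) - sys$energy(x - e)) / (2 * h)
      }, numeric(1))
      denom <- pmax(abs(fd), 1)
      expect_lt(max(abs(g - fd) / denom), 1e-6)
    }
  }
})

test_that("NVE propagation has no secular energy drift and is reversible", {
  sys <- make_system("harmonic", list(k = 1))
  dt <- 2 * pi / 100
  tr <- propagate(sys, frame(1, 0), 1e5, dt)
  E <- 0.5 * tr$positions[, 1]^2 + 0.5 * tr$velocities[, 1]^2
  n <- length(E)
  head_mean <- mean(E[1:1000])
  tail_mean <- mean(E[(n - 999):n])
  expect_lt(abs(tail_mean - head_mean) / head_mean, 1e-4) # no secular drift
  expect_lt(max(abs(E - E[1])) / E[1], 2e-3)              # bounded oscillation

  # time reversal: run forward, flip velocities, return to the start
  dw <- dw_system()
  fwd <- propagate(dw, frame(0.2, 0.9), 500, 0.005)
  endf <- frame(fwd$positions[nrow(fwd$positions), ],
                -fwd$velocities[nrow(fwd$velocities), ])
  back <- propagate(dw, endf, 500, 0.005)
  expect_equal(back$positions[nrow(back$positions), ], 0.2, tolerance = 1e-8)
  expect_equal(-back$velocities[nrow(back$velocities), ], 0.9, tolerance = 1e-8)
})

test_that("Langevin propagation is deterministic given a seed", {
  sys <- dw_system()
  a <- propagate(sys, frame(0.1, 0.3), 2000, 0.005, friction = 1, T = 1, seed = 3)
  b <- propagate(sys, frame(0.1, 0.3), 2000, 0.005, friction = 1, T = 1, seed = 3)
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)
  c <- propagate(sys, frame(0.1, 0.3), 2000, 0.005, friction = 1, T = 1, seed = 4)
  expect_false(identical(a$positions, c$positions))
})

test_that("thermostatted sampling satisfies equipartition", {
  k <- 2.3
  sys <- make_system("harmonic", list(k = k))
  T <- 1.7
  tr <- propagate(sys, frame(0, 0), 2e5, 0.05, friction = 1, T = T, seed = 11)
  x <- tr$positions[-(1:2000), 1]
  g <- statistical_inefficiency(x)
  se <- sd(x^2) / sqrt(length(x) / g)
  expect_lt(abs(var(x) - T / k), 3 * se)
})

test_that("long Langevin runs reproduce the Boltzmann marginal (KL < 0.01)", {
  sys <- dw_system(barrier = 2)
  tr <- propagate(sys, frame(1, 0), 2e6, 0.01, friction = 2, T = 1, seed = 5,
                  save_stride = 10)
  x <- tr$positions[-(1:1000), 1]
  edges <- seq(-2.2, 2.2, length.out = 41)
  x <- x[x > edges[1] & x < edges[length(edges)]]
  p_hat <- tabulate(findInterval(x, edges), nbins = 40) / length(x)
  ctr <- (edges[-1] + edges[-41]) / 2
  p_ref <- exp(-vapply(ctr, sys$energy, numeric(1)))
  p_ref <- p_ref / sum(p_ref)
  keep <- p_hat > 0
  kl <- sum(p_hat[keep] * log(p_hat[keep] / p_ref[keep]))
  expect_lt(kl, 0.01)
})

test_that("Maxwell-Boltzmann draws have the right moments and mass scaling", {
  T <- 1.3
  sysl <- make_system("linear_combo_nd",
                      list(barrier = 1, weights = rep(1, 4), k_perp = 1),
                      masses = c(1, 1, 2, 2))
  V <- t(vapply(1:25000, function(i) draw_velocities(sysl, T, seed = i),
                numeric(4)))
  for (j in 1:2) {
    expect_lt(abs(var(V[, j]) / T - 1), 0.02)           # variance kT/m, m = 1
    expect_lt(abs(mean(V[, j])), 3 * sd(V[, j]) / sqrt(nrow(V)))
  }
  # doubling the mass halves the component variance
  expect_equal(var(V[, 3]) / var(V[, 1]), 0.5, tolerance = 0.05)
  expect_error(draw_velocities(sysl, -1), "temperature")
})

test_that("propagation aborts with a diagnostic on divergence", {
  sys <- dw_system(barrier = 5)
  expect_error(propagate(sys, frame(3, 0), 1000, dt = 5), "step")
})

test_that("trajectory CSV round-trips through the documented layout", {
  sys <- xy_system()
  tr <- propagate(sys, frame(c(0, 0), c(1, -1)), 50, 0.01, friction = 1,
                  T = 1, seed = 2)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_trajectory_csv(tr, path)
  df <- read.csv(path)
  expect_named(df, c("t", "x1", "x2", "v1", "v2"))
  expect_equal(df$x1, tr$positions[, 1])
  expect_equal(df$t, tr$times)
})
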