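# Basin classification, aimless-shooting moves and campaigns, the
# decorrelation filter, and transition-state seeding.

acyl_reactant_basin <- function() {
  # thresholds of a serine-hydrolase acylation reactant state, used as a
  # classification fixture over named CV values
  basin_def("reactant", list(list("d_attack", "<", 1.8),
                             list("d_OH", ">", 1.4),
                             list("d_transfer", "<", 1.2),
                             list("d_ester", ">", 2.4)))
}

acyl_product_basin <- function() {
  basin_def("product", list(list("d_attack", ">", 2.4),
                            list("d_OH", "<", 1.2),
                            list("d_transfer", ">", 1.4),
                            list("d_ester", "<", 1.8)))
}

test_that("classification is a strict conjunction over basin conditions", {
  basins <- list(reactant = acyl_reactant_basin(), product = acyl_product_basin())
  vals <- c(d_attack = 1.7, d_OH = 1.5, d_transfer = 1.1, d_ester = 2.5)
  expect_equal(classify_frame(vals, basins), "reactant")
  # any one condition violated -> neither
  for (nm in names(vals)) {
    bad <- vals
    bad[nm] <- c(d_attack = 2.0, d_OH = 1.3, d_transfer = 1.3, d_ester = 2.0)[nm]
    expect_equal(classify_frame(bad, basins), "neither")
  }
  # values exactly at a threshold do not satisfy the strict inequality
  boundary <- c(d_attack = 1.8, d_OH = 1.5, d_transfer = 1.1, d_ester = 2.5)
  expect_equal(classify_frame(boundary, basins), "neither")
})

test_that("overlapping basin definitions are surfaced as errors", {
  overlapping <- list(
    reactant = basin_def("reactant", list(list("x_1", "<", 0.5))),
    product = basin_def("product", list(list("x_1", ">", -0.5))))
  expect_error(classify_frame(c(x_1 = 0), overlapping), "overlapping")
})

test_that("ballistic moves from the saddle are always reactive", {
  sys <- dw_system()
  cfg <- as_config(T = 1, dt = 0.005, friction = 0, max_steps = 5000)
  for (s in 1:10) {
    mv <- shooting_move(sys, frame(0), x_basins(), list(x_cv()), cfg, seed = s)
    expect_true(mv$record$reactive)
    expect_setequal(c(mv$record$fwd_fate, mv$record$bwd_fate),
                    c("reactant", "product"))
  }
  # a committed starting point violates the precondition
  expect_error(shooting_move(sys, frame(-1), x_basins(), list(x_cv()), cfg, 1),
               "committed")
})

test_that("velocity reversal retraces the ballistic trajectory", {
  sys <- dw_system()
  cfg <- as_config(T = 1, dt = 0.005, friction = 0, max_steps = 5000)
  mv <- shooting_move(sys, frame(0.05), x_basins(), list(x_cv()), cfg,
                      seed = 21, keep_traj = TRUE)
  v0 <- mv$record$v0
  nf <- min(50L, nrow(mv$record$fwd_traj$positions))
  nb <- min(50L, nrow(mv$record$bwd_traj$positions))
  fwd_replay <- propagate(sys, frame(0.05, v0), nf, cfg$dt)
  expect_equal(fwd_replay$positions[-1, 1], mv$record$fwd_traj$positions[1:nf, 1],
               tolerance = 1e-12)
  bwd_replay <- propagate(sys, frame(0.05, -v0), nb, cfg$dt)
  expect_equal(bwd_replay$positions[-1, 1], mv$record$bwd_traj$positions[1:nb, 1],
               tolerance = 1e-12)
})

test_that("overdamped reactive fraction matches the committor oracle", {
  # with velocity memory suppressed (high friction) the two half-
  # trajectories decorrelate and P(reactive) -> 2 pB (1 - pB)
  sys <- dw_system()
  cfg <- as_config(T = 1, dt = 0.005, friction = 20, max_steps = 20000)
  pt <- frame(0.1)
  n_oracle <- 400
  cm <- committor_analysis(sys, list(pt), x_basins(), n_oracle, cfg, seed = 77)
  p <- cm$points$pB[1]
  n <- 300
  reac <- vapply(seq_len(n), function(i) {
    shooting_move(sys, pt, x_basins(), list(x_cv()), cfg,
                  seed = derive_seed(123, i))$record$reactive
  }, NA)
  fr <- mean(reac)
  pred <- 2 * p * (1 - p)
  se <- sqrt(fr * (1 - fr) / n + (2 - 4 * p)^2 * p * (1 - p) / n_oracle)
  expect_lt(abs(fr - pred), 3 * se)
})

test_that("campaigns are deterministic, provenance-complete, and accounted", {
  sys <- xy_system()
  cfg <- as_config(T = 1, dt = 0.005, friction = 1, max_steps = 4000)
  pts <- list(frame(c(0, 0)), frame(c(0.05, 0)))
  e1 <- aimless_shooting_campaign(sys, pts, 40, x_basins(), xy_cvs(), cfg, seed = 9)
  e2 <- aimless_shooting_campaign(sys, pts, 40, x_basins(), xy_cvs(), cfg, seed = 9)
  expect_identical(e1$cv_values, e2$cv_values)
  expect_identical(e1$fates, e2$fates)
  expect_equal(nrow(e1$fates), 80)
  expect_setequal(unique(e1$fates$chain), 1:2)
  # acceptance ratio is recomputable from the records
  expect_equal(e1$acceptance_ratio, mean(e1$fates$reactive))
  # reactive <=> opposite commitments
  opp <- (e1$fates$fwd_fate == "product" & e1$fates$bwd_fate == "reactant") |
    (e1$fates$fwd_fate == "reactant" & e1$fates$bwd_fate == "product")
  expect_identical(e1$fates$reactive, opp)

  e0 <- aimless_shooting_campaign(sys, pts, 0, x_basins(), xy_cvs(), cfg, seed = 9)
  expect_equal(nrow(e0$fates), 0)
  expect_null(e0$acceptance_ratio)
})

test_that("ensembles round-trip through JSON-lines", {
  sys <- xy_system()
  cfg <- as_config(T = 1, dt = 0.005, friction = 1, max_steps = 4000)
  ens <- aimless_shooting_campaign(sys, list(frame(c(0, 0))), 25, x_basins(),
                                   xy_cvs(), cfg, seed = 14)
  path <- tempfile(fileext = ".jsonl")
  on.exit(unlink(path))
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(back$fates, ens$fates)
  expect_equal(back$cv_values, ens$cv_values)
  expect_equal(back$cv_rates, ens$cv_rates)
  expect_equal(back$points, ens$points, ignore_attr = TRUE)
  expect_equal(back$acceptance_ratio, ens$acceptance_ratio)
})

test_that("decorrelation filter trims initialization bias, not white noise", {
  set.seed(5)
  n <- 200
  fates <- sample(c("product", "reactant"), n, TRUE)
  # chain with a deterministic approach trend over its first half
  trended <- c(seq(-2, 0, length.out = n / 2), rnorm(n / 2, 0, 0.2))
  e_tr <- as_ensemble_from_data(cbind(cv1 = trended), fates)
  dropped_tr <- attr(decorrelation_filter(e_tr, 0.05), "dropped")
  # at least the whole trended half goes; the filter may trim further
  # because the trend/noise level shift is itself long-range structure
  expect_gte(dropped_tr, n / 2 - 10)
  expect_lte(dropped_tr, n - 10)
  # i.i.d. chain: expected drop ~ 0
  e_iid <- as_ensemble_from_data(cbind(cv1 = rnorm(n)), fates)
  expect_equal(attr(decorrelation_filter(e_iid, 0.05), "dropped"), 0L)
  # monotone in alpha: tighter levels drop no more than looser ones, and a
  # vanishing level leaves i.i.d. data untouched
  d_lo <- attr(decorrelation_filter(e_tr, 1e-12), "dropped")
  d_hi <- attr(decorrelation_filter(e_tr, 0.5), "dropped")
  expect_lte(d_lo, dropped_tr)
  expect_gte(d_hi, dropped_tr)
  expect_equal(attr(decorrelation_filter(e_iid, 1e-12), "dropped"), 0L)
  # short chains are retained whole, with a warning
  e_short <- as_ensemble_from_data(cbind(cv1 = rnorm(5)), fates[1:5])
  expect_warning(f_short <- decorrelation_filter(e_short, 0.05), "minimum testable")
  expect_equal(nrow(f_short$fates), 5)
})

test_that("find_ts drags a reactant frame to verified saddle candidates", {
  sys <- dw_system()
  cfg <- as_config(T = 1, dt = 0.005, friction = 20, max_steps = 20000)
  ts <- find_ts(sys, frame(-1), x_basins(), list(x_cv()), c(x_1 = 1),
                cfg, seed = 3)
  expect_gte(length(ts), 1)
  # the best-verified candidates cluster near the analytic saddle x = 0
  expect_lt(abs(ts[[1]]$x[1]), 0.3)
  # dragging from an already-committed product frame violates the precondition
  expect_error(find_ts(sys, frame(1), x_basins(), list(x_cv()), c(x_1 = 1),
                       cfg, seed = 3), "reactant")
  expect_error(find_ts(sys, frame(-1), x_basins(), list(x_cv()), c(x_1 = 1),
                       cfg, seed = 3, n_verify = 0), "n_verify")
})

test_that("accepted next candidates lie on the forward trajectory", {
  sys <- dw_system()
  cfg <- as_config(T = 1, dt = 0.005, friction = 1, max_steps = 5000,
                   offset_window = c(0.005, 0.05))
  for (s in 1:20) {
    mv <- shooting_move(sys, frame(0), x_basins(), list(x_cv()), cfg,
                        seed = s, keep_traj = TRUE)
    if (!mv$record$reactive) next
    k <- mv$record$offset_steps
    expect_equal(mv$next_candidate$x, mv$record$fwd_traj$positions[k, ])
  }
})
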