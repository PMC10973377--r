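# Umbrella sampling along an RC (or single CV) with harmonic restraints and
# MBAR estimation of the potential of mean force.  Series are decorrelated
# by their statistical inefficiency before estimation.

#' Build evenly spaced umbrella windows
#'
#' Centers run from `lo` to `hi` in steps of `width`
#' (count = `floor((hi - lo)/width) + 1`).  A width at least as large as
#' the range collapses to a single window at the midpoint, with a warning.
#'
#' @param rc_range `c(lo, hi)` along the restrained quantity
#' @param width window spacing
#' @param k_restraint harmonic force constant (energy per unit^2)
#' @param n_replicas independent simulations per window
#' @param n_steps recorded steps per simulation
#' @param ramp_steps linear restraint ramp length (0 = none; ramp excluded
#'   from the recorded series)
#' @return an `umbrella_windows` data.frame
#' @export
build_windows <- function(rc_range, width, k_restraint, n_replicas = 5L,
                          n_steps = 20000L, ramp_steps = 0L) {
  lo <- rc_range[1]; hi <- rc_range[2]
  if (!(lo < hi)) stop_config("rc_range must satisfy lo < hi")
  if (width <= 0 || k_restraint <= 0 || n_replicas < 1L) {
    stop_config("need width > 0, k_restraint > 0, n_replicas >= 1")
  }
  if (width >= hi - lo) {
    warning("window width >= range; using a single window at the midpoint",
            call. = FALSE)
    centers <- (lo + hi) / 2
  } else {
    centers <- seq(lo, hi, by = width)
  }
  structure(data.frame(center = centers, width = width,
                       k_restraint = k_restraint, n_replicas = n_replicas,
                       n_steps = as.integer(n_steps),
                       ramp_steps = as.integer(ramp_steps)),
            class = c("umbrella_windows", "data.frame"))
}

# Translate the restrained quantity into a C++ bias descriptor and a
# function evaluating q on a position matrix.
quantity_bias <- function(quantity, system, cv_set = NULL) {
  d <- system$ncoord
  if (inherits(quantity, "rc_model")) {
    if (is.null(cv_set)) {
      cv_set <- setNames(lapply(quantity$cv_ids, function(id) {
        if (!grepl("^x_[0-9]+$", id)) {
          stop_config("restraining RC '%s' needs explicit cv_set definitions", id)
        }
        cv_def("coordinate_projection", as.integer(sub("^x_", "", id)), cv_id = id)
      }), quantity$cv_ids)
    }
    kinds <- vapply(cv_set[quantity$cv_ids], `[[`, "", "kind")
    if (!all(kinds == "coordinate_projection")) {
      stop_config("composite RC restraints support coordinate-projection CVs only")
    }
    w <- rep(0, d)
    for (i in seq_along(quantity$cv_ids)) {
      cv <- cv_set[[quantity$cv_ids[i]]]
      co <- quantity$coeffs[i]
      if (!is.null(quantity$standardization)) {
        co <- co / quantity$standardization$sd[quantity$cv_ids[i]]
      }
      w[cv$atom_indices[1]] <- w[cv$atom_indices[1]] + co
    }
    b0 <- quantity$c0
    if (!is.null(quantity$standardization)) {
      b0 <- b0 - sum(quantity$coeffs * quantity$standardization$mean[quantity$cv_ids] /
                       quantity$standardization$sd[quantity$cv_ids])
    }
    list(make_bias = function(k, center) list(type = "linear", k = k, center = center,
                                              b0 = b0, w = w),
         eval_q = function(pos) drop(b0 + pos %*% w))
  } else if (inherits(quantity, "cv_def")) {
    if (quantity$kind == "coordinate_projection") {
      w <- rep(0, d); w[quantity$atom_indices[1]] <- 1
      list(make_bias = function(k, center) list(type = "linear", k = k, center = center,
                                                b0 = 0, w = w),
           eval_q = function(pos) pos[, quantity$atom_indices[1]])
    } else if (quantity$kind == "distance") {
      i <- quantity$atom_indices[1]; j <- quantity$atom_indices[2]
      list(make_bias = function(k, center) list(type = "distance", k = k, center = center,
                                                i = i, j = j),
           eval_q = function(pos) evaluate_cv_traj(quantity, pos, system$dim))
    } else {
      stop_config("restraints on CV kind '%s' are not supported for toy dynamics",
                  quantity$kind)
    }
  } else {
    stop_config("quantity must be an rc_model or a cv_def")
  }
}

#' Pathway restraints from an aimless-shooting ensemble
#'
#' Half-harmonic walls on each constituent CV at the minimum/maximum value
#' observed over the reactive shooting records (points and committed
#' endpoints), widened by a fractional `margin`.  Passed to
#' [run_umbrella()] they confine biased sampling to the reaction-pathway
#' envelope that unbiased trajectories actually visited, preventing
#' windows far along the RC from drifting into unphysical regions.
#' Restricted to coordinate-projection CVs (the toy-dynamics restraint
#' surface).
#'
#' @param ensemble an `as_ensemble`
#' @param cvs named list of [cv_def()]s (coordinate projections)
#' @param system the [make_system()] object (for endpoint CV evaluation)
#' @param k_wall wall force constant
#' @param margin fractional widening of the observed envelope
#' @return list of wall biases for `run_umbrella(extra_biases = )`
#' @export
pathway_restraints <- function(ensemble, cvs, system, k_wall = 100,
                               margin = 0.05) {
  reac <- which(ensemble$fates$reactive)
  if (!length(reac)) stop_config("no reactive records to define an envelope")
  lapply(names(cvs), function(id) {
    cv <- cvs[[id]]
    if (cv$kind != "coordinate_projection") {
      stop_config("pathway restraints support coordinate-projection CVs only (got '%s')",
                  cv$kind)
    }
    vals <- ensemble$cv_values[reac, id]
    if (!is.null(ensemble$end_fwd) && ncol(ensemble$end_fwd)) {
      ends <- rbind(ensemble$end_fwd[reac, , drop = FALSE],
                    ensemble$end_bwd[reac, , drop = FALSE])
      vals <- c(vals, evaluate_cv_traj(cv, ends, system$dim))
    }
    lo <- min(vals); hi <- max(vals)
    pad <- margin * (hi - lo)
    w <- rep(0, system$ncoord)
    w[cv$atom_indices[1]] <- 1
    list(type = "wall", k = k_wall, lo = lo - pad, hi = hi + pad, b0 = 0, w = w)
  })
}

#' Run umbrella sampling
#'
#' Applies the window's harmonic bias `U_w = k/2 (q - center)^2` through
#' chain-rule forces and records the biased quantity every `save_stride`
#' steps, after discarding the restraint ramp (if any) and `n_equil`
#' equilibration steps.  Windows whose sample mean strays more than 2
#' standard deviations from their center are flagged.
#'
#' @param system a [make_system()] object
#' @param quantity an [rc_model()] over coordinate-projection CVs, or a
#'   coordinate-projection / distance [cv_def()]
#' @param windows an [build_windows()] table
#' @param cfg an [as_config()] (temperature, timestep, friction)
#' @param seed campaign seed; per-(window, replica) seeds derived
#' @param init_frames optional list of starting [frame()]s per window
#'   (default: analytic placement at the window center)
#' @param save_stride recording stride
#' @param n_equil unrecorded equilibration steps after the ramp
#' @param cv_set CV definitions when restraining a composite RC over
#'   non-auto-named CVs
#' @param extra_biases additional restraints applied in every window, e.g.
#'   [pathway_restraints()] walls
#' @return an `umbrella_data` store for [mbar_pmf()]
#' @export
run_umbrella <- function(system, quantity, windows, cfg, seed = 1L,
                         init_frames = NULL, save_stride = 5L,
                         n_equil = 500L, cv_set = NULL, extra_biases = NULL) {
  qb <- quantity_bias(quantity, system, cv_set)
  series <- list()
  meta <- NULL
  for (wi in seq_len(nrow(windows))) {
    w <- windows[wi, ]
    x_init <- if (!is.null(init_frames)) init_frames[[wi]]$x
              else place_on_quantity(qb, system, w$center)
    for (rep_i in seq_len(w$n_replicas)) {
      sd_seed <- derive_seed(seed, wi, rep_i)
      q <- with_seed(sd_seed, {
        v0 <- draw_velocities(system, cfg$T)
        x <- x_init
        # linear restraint ramp, stepped in 20 sub-stages
        if (w$ramp_steps > 0L) {
          n_sub <- 20L
          per <- max(1L, w$ramp_steps %/% n_sub)
          for (s in seq_len(n_sub)) {
            res <- propagate_cpp(system$pid, system$par_vec, system$mass_vec,
                                 x, v0, per, cfg$dt, cfg$friction,
                                 system$kB * cfg$T, per,
                                 bias_matrix(c(list(qb$make_bias(w$k_restraint * s / n_sub,
                                                                 w$center)),
                                               extra_biases), system))
            nr <- nrow(res$positions)
            x <- res$positions[nr, ]; v0 <- res$velocities[nr, ]
          }
        }
        n_total <- n_equil + w$n_steps
        res <- propagate_cpp(system$pid, system$par_vec, system$mass_vec,
                             x, v0, n_total, cfg$dt, cfg$friction,
                             system$kB * cfg$T, save_stride,
                             bias_matrix(c(list(qb$make_bias(w$k_restraint, w$center)),
                                           extra_biases), system))
        if (res$fail_step >= 0) {
          stop_config("window %d replica %d diverged at step %d", wi, rep_i,
                      res$fail_step)
        }
        drop_n <- ceiling(n_equil / save_stride) + 1L
        res$bias_q[-seq_len(drop_n)]
      })
      series[[length(series) + 1L]] <- q
      meta <- rbind(meta, data.frame(window = wi, replica = rep_i,
                                     center = w$center, k = w$k_restraint,
                                     n = length(q), mean_q = mean(q),
                                     sd_q = sd(q)))
    }
  }
  meta$flagged <- abs(meta$mean_q - meta$center) > 2 * meta$sd_q
  if (any(meta$flagged)) {
    warning(sprintf("%d window replica(s) did not cover their center within 2 SD",
                    sum(meta$flagged)), call. = FALSE)
  }
  structure(list(series = series, meta = meta, windows = windows,
                 temperature = cfg$T, kB = system$kB, dt = cfg$dt,
                 save_stride = save_stride),
            class = "umbrella_data")
}

# Analytic starting point with q(x) = center: minimum-norm solution for
# linear quantities; particles split along the first axis for distances.
place_on_quantity <- function(qb, system, center) {
  d <- system$ncoord
  b <- qb$make_bias(1, center)
  if (b$type == "linear") {
    w <- b$w
    x <- w * (center - b$b0) / sum(w * w)
    return(x)
  }
  x <- rep(0, d)
  dim <- system$dim
  x[coord_idx(b$i, dim)[1]] <- center / 2
  x[coord_idx(b$j, dim)[1]] <- -center / 2
  x
}

#' Statistical inefficiency of a time series
#'
#' `g = 1 + 2 * sum of the initial positive sequence of autocorrelations`;
#' a decorrelated subsample takes every `ceiling(g)`-th point.
#'
#' @param x numeric series
#' @return `g >= 1`
#' @export
statistical_inefficiency <- function(x) {
  n <- length(x)
  if (n < 3L || sd(x) < 1e-12) return(1)
  L <- min(n - 2L, 2000L)
  ac <- acf(x, lag.max = L, plot = FALSE, demean = TRUE)$acf[-1L]
  neg <- which(ac <= 0)
  if (length(neg)) ac <- ac[seq_len(neg[1L] - 1L)]
  max(1, 1 + 2 * sum(ac * (1 - seq_along(ac) / n)))
}

# Solve the MBAR self-consistent equations for the reduced window free
# energies f_k (dimensionless, f_1 = 0).  u_kn is the K x N matrix of
# reduced bias energies.  Self-consistent iteration with a Newton polish.
solve_mbar <- function(u_kn, N_k, tol = 1e-8, max_iter = 5000L) {
  K <- nrow(u_kn)
  f <- numeric(K)
  logN <- log(N_k)
  denom <- function(f) {
    # D_n = log sum_k N_k exp(f_k - u_kn)
    row_logsumexp(t(logN + f - u_kn))
  }
  newton_tried <- FALSE
  for (it in seq_len(max_iter)) {
    D <- denom(f)
    f_new <- -apply(u_kn, 1L, function(u) logsumexp(-u - D))
    f_new <- f_new - f_new[1L]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
    # after the SCF has roughly converged, polish with Newton steps
    if (delta < 1e-2 && !newton_tried && K > 1L) {
      newton_tried <- TRUE
      for (nt in seq_len(50L)) {
        D <- denom(f)
        logW <- f - u_kn - rep(D, each = K) # K x N
        W <- exp(logW)
        WN <- W * N_k # rows scaled by N_k
        g <- rowSums(WN) - N_k
        H <- diag(rowSums(WN), K) - (W %*% t(W)) * outer(N_k, N_k)
        i2 <- 2L:K
        step <- tryCatch(solve(H[i2, i2, drop = FALSE], g[i2]),
                         error = function(e) NULL)
        if (is.null(step)) break
        f[i2] <- f[i2] - step
        f <- f - f[1L]
        if (max(abs(step)) < tol / 10) break
      }
    }
  }
  D <- denom(f)
  list(f = f, log_denom = D, n_iter = it)
}

#' Estimate a PMF from umbrella data with MBAR
#'
#' Each window series is subsampled by its statistical inefficiency, the
#' MBAR equations are solved for the window free energies, and the
#' unbiased-state weights are binned along the sampled range to give the
#' potential of mean force (minimum shifted to zero).  Per-bin standard
#' errors come from a first-order delta method on the normalized MBAR
#' weights.  Adjacent windows without mutual overlap (no configuration
#' plausible under both biases) raise an error naming the gap.
#'
#' @param data an `umbrella_data`
#' @param n_bins number of equal-width PMF bins over the sampled range
#' @param tol convergence tolerance for the window free energies
#'   (dimensionless, i.e. kBT units)
#' @return a `pmf_profile`: data.frame `profile` (`center`, `G`, `err`),
#'   window free energies `f_windows` (kBT), `kT`, and estimator metadata
#' @export
mbar_pmf <- function(data, n_bins = 100L, tol = 1e-8) {
  kT <- data$kB * data$temperature
  beta <- 1 / kT
  # decorrelate
  sub <- lapply(data$series, function(x) {
    g <- statistical_inefficiency(x)
    x[seq(1L, length(x), by = ceiling(g))]
  })
  # pool replicas by window: MBAR states are the biased windows
  W <- nrow(data$windows)
  q_by_window <- lapply(seq_len(W), function(wi) {
    unlist(sub[which(data$meta$window == wi)])
  })
  N_k <- vapply(q_by_window, length, integer(1))
  if (sum(N_k > 0L) < 2L && W > 1L) stop_config("need >= 2 windows with samples")
  q_n <- unlist(q_by_window)
  centers <- data$windows$center
  ks <- data$windows$k_restraint
  # overlap check between adjacent windows (by center order)
  ordw <- order(centers)
  for (i in seq_len(W - 1L)) {
    a <- ordw[i]; b <- ordw[i + 1L]
    ua <- beta * 0.5 * ks[a] * (q_n - centers[a])^2
    ub <- beta * 0.5 * ks[b] * (q_n - centers[b])^2
    if (!any(ua < 15 & ub < 15)) {
      stop_config("no overlap between windows at centers %.4g and %.4g",
                  centers[a], centers[b])
    }
  }
  u_kn <- vapply(seq_len(W), function(k) beta * 0.5 * ks[k] * (q_n - centers[k])^2,
                 numeric(length(q_n)))
  u_kn <- t(u_kn) # K x N
  sol <- solve_mbar(u_kn, N_k, tol = tol)
  # unbiased weights: w_n propto exp(-0 - D_n)
  logw <- -sol$log_denom
  logw <- logw - logsumexp(logw)
  w <- exp(logw)
  edges <- seq(min(q_n), max(q_n), length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(q_n, edges, rightmost.closed = TRUE), 1L), n_bins)
  p <- vapply(seq_len(n_bins), function(b) sum(w[bin == b]), numeric(1))
  w2 <- vapply(seq_len(n_bins), function(b) sum(w[bin == b]^2), numeric(1))
  keep <- p > 0
  G <- -kT * log(p[keep])
  G <- G - min(G)
  # delta method: Var(log p) ~ (1 - p)/ (p * n_eff),  n_eff = p^2 / sum w^2
  n_eff <- p[keep]^2 / w2[keep]
  err <- kT * sqrt(pmax((1 - p[keep]), 0) / pmax(n_eff, 1))
  ctrs <- (edges[-1L] + edges[-length(edges)]) / 2
  structure(list(
    profile = data.frame(center = ctrs[keep], G = G, err = err),
    f_windows = sol$f, kT = kT, n_iter = sol$n_iter,
    N_k = N_k, n_samples = length(q_n), q_n = q_n,
    bias_centers = centers, bias_k = ks,
    estimator = "MBAR (self-consistent + Newton)"
  ), class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("<pmf_profile: %d bins, %d samples, %d windows; min 0 at center %.4g>\n",
              nrow(x$profile), x$n_samples, length(x$f_windows),
              x$profile$center[which.min(x$profile$G)]))
  invisible(x)
}

#' Barrier height from a PMF
#'
#' `dG = max over the barrier region - min over the reactant side`, where
#' the barrier region spans the bins between the reactant minimum and the
#' minimum on the far side.  The two bins' uncertainties combine in
#' quadrature.  A profile with no interior maximum above both minima (a
#' monotone profile) is an error.
#'
#' @param pmf a `pmf_profile`
#' @param reactant_side `c(lo, hi)` interval of the restrained quantity
#'   containing the reactant minimum
#' @return list with `dG`, `err`, and the locations used
#' @export
barrier_height <- function(pmf, reactant_side) {
  pr <- pmf$profile
  in_r <- pr$center >= reactant_side[1] & pr$center <= reactant_side[2]
  if (!any(in_r)) stop_config("no PMF bins inside the reactant interval")
  i_r <- which(in_r)[which.min(pr$G[in_r])]
  out_r <- which(!in_r)
  if (!length(out_r)) stop_config("reactant interval covers the whole profile")
  i_p <- out_r[which.min(pr$G[out_r])]
  lo <- min(i_r, i_p); hi <- max(i_r, i_p)
  if (hi - lo < 2L) stop_config("no barrier: minima are adjacent")
  mid <- (lo + 1L):(hi - 1L)
  i_ts <- mid[which.max(pr$G[mid])]
  if (pr$G[i_ts] <= pr$G[i_r] || pr$G[i_ts] <= pr$G[i_p]) {
    stop_config("no barrier: profile is monotone between the minima")
  }
  list(dG = pr$G[i_ts] - pr$G[i_r],
       err = sqrt(pr$err[i_ts]^2 + pr$err[i_r]^2),
       r_ts = pr$center[i_ts], r_reactant = pr$center[i_r],
       r_product = pr$center[i_p])
}

#' Write a PMF profile as CSV (center, G, err)
#' @param pmf a `pmf_profile`
#' @param path output file
#' @export
write_pmf_csv <- function(pmf, path) {
  write.csv(pmf$profile, path, row.names = FALSE)
  invisible(path)
}
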