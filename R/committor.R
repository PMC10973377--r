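# Committor-probability estimation and the pB histogram test that validates
# a candidate reaction coordinate: configurations picked at RC ~ 0 should
# relax to products about half the time when given fresh Maxwell-Boltzmann
# velocities.

#' Select putative transition-state configurations from an ensemble
#'
#' Returns the `n_target` shooting points whose RC magnitude `|r|` is
#' smallest, with deterministic tie-breaking by `(|r|, chain, move)`.
#'
#' @param ensemble an `as_ensemble`
#' @param model an [rc_model()] evaluable on the ensemble CVs
#' @param n_target number of configurations wanted
#' @return list of positions-only [frame()]s; the selected row indices and
#'   RC values are in attributes `"indices"` and `"r"`
#' @export
select_ts_candidates <- function(ensemble, model, n_target) {
  n <- nrow(ensemble$fates)
  if (n == 0L) stop_config("ensemble is empty")
  r <- evaluate_rc(model, ensemble$cv_values)
  if (n_target > n) {
    warning(sprintf("n_target (%d) exceeds ensemble size (%d); returning all",
                    n_target, n), call. = FALSE)
    n_target <- n
  }
  ord <- order(abs(r), ensemble$fates$chain, ensemble$fates$move)
  idx <- ord[seq_len(n_target)]
  out <- lapply(idx, function(i) frame(ensemble$points[i, ], NULL))
  attr(out, "indices") <- idx
  attr(out, "r") <- r[idx]
  out
}

#' Committor analysis: one-directional trials with random velocities
#'
#' Each configuration is used as the starting point of `n_trials`
#' simulations; each trial draws Maxwell-Boltzmann velocities and propagates
#' one-directionally until basin commitment or `cfg$max_steps`.  The
#' committor estimate is `pB = committed-to-product / committed-total`
#' (timeouts are excluded from the denominator and reported separately).
#' When `rc` is given, the RC time series `q(t)` and the initial RC rate
#' `qdot0` of every trial are recorded for reactive-flux analysis.
#'
#' @param system a [make_system()] object
#' @param points list of positions-only [frame()]s, each classifying as
#'   `"neither"`
#' @param basins reactant/product basin pair
#' @param n_trials trials per point (>= 1)
#' @param cfg an [as_config()] (temperature, timestep, friction, cap)
#' @param seed campaign seed; trial seeds derived per (point, trial)
#' @param rc optional [rc_model()] over coordinate-projection CVs whose
#'   series is recorded per trial
#' @param rc_cvs named list of [cv_def()]s underlying `rc` (required with
#'   `rc`)
#' @param flux_stride save stride of the recorded RC series
#' @return a `committor_result`: data.frame `points` (`pB`, `n_product`,
#'   `n_reactant`, `n_timeout`), `histogram` (10 right-closed bins on
#'   [0, 1]), and (with `rc`) a `flux` store for [reactive_flux()]
#' @export
committor_analysis <- function(system, points, basins, n_trials, cfg,
                               seed = 1L, rc = NULL, rc_cvs = NULL,
                               flux_stride = 5L) {
  if (n_trials < 1L) stop_config("n_trials must be >= 1")
  basin_ids <- unique(c(basins$reactant$conditions$cv_id,
                        basins$product$conditions$cv_id))
  cv_set <- NULL
  record_flux <- !is.null(rc)
  if (record_flux) {
    if (is.null(rc_cvs)) stop_config("rc_cvs must accompany rc")
    cv_set <- setNames(rc_cvs, vapply(rc_cvs, `[[`, "", "cv_id"))
  }
  n_pt <- length(points)
  bset <- basin_cv_set(basins, system)
  cls <- vapply(points, function(p) classify_frame(p, basins, bset, system$dim), "")
  if (any(cls != "neither")) {
    stop_config("%d point(s) already committed to a basin (first: point %d is '%s')",
                sum(cls != "neither"), which(cls != "neither")[1L],
                cls[cls != "neither"][1L])
  }
  tally <- matrix(0L, n_pt, 3L, dimnames = list(NULL, c("product", "reactant", "timeout")))
  flux_q <- list()
  flux_qdot0 <- numeric(0)
  flux_fate <- character(0)
  for (i in seq_len(n_pt)) {
    for (tr in seq_len(n_trials)) {
      res <- with_seed(derive_seed(seed, i, tr), {
        v0 <- draw_velocities(system, cfg$T)
        shot <- shoot_until_commit(system, points[[i]]$x, v0, basins, bset, cfg)
        list(shot = shot, v0 = v0)
      })
      fate <- res$shot$fate
      tally[i, fate] <- tally[i, fate] + 1L
      if (record_flux) {
        pos_all <- rbind(points[[i]]$x, res$shot$positions)
        keep <- unique(c(seq(1L, nrow(pos_all), by = flux_stride), nrow(pos_all)))
        qser <- evaluate_rc(rc, cv_matrix_from_positions(cv_set, pos_all[keep, , drop = FALSE],
                                                         system$dim))
        qd0 <- rc_rate(rc, cv_set, frame(points[[i]]$x, res$v0), system$dim)
        flux_q[[length(flux_q) + 1L]] <- qser
        flux_qdot0 <- c(flux_qdot0, qd0)
        flux_fate <- c(flux_fate, fate)
      }
    }
  }
  committed <- tally[, "product"] + tally[, "reactant"]
  pB <- ifelse(committed > 0L, tally[, "product"] / committed, NA_real_)
  res <- structure(list(
    points = data.frame(point = seq_len(n_pt), pB = pB,
                        n_product = tally[, "product"],
                        n_reactant = tally[, "reactant"],
                        n_timeout = tally[, "timeout"]),
    n_trials = n_trials,
    histogram = pb_histogram(pB[!is.na(pB)], 10L)
  ), class = "committor_result")
  if (record_flux) {
    res$flux <- list(q_series = flux_q, qdot0 = flux_qdot0, fates = flux_fate,
                     dt = cfg$dt, stride = flux_stride)
  }
  res
}

# CV set referenced by the basin conditions; basins on toy systems are
# defined over coordinate projections unless explicit cv_defs are attached.
basin_cv_set <- function(basins, system) {
  cvset <- attr(basins, "cv_set")
  if (!is.null(cvset)) return(cvset)
  ids <- unique(c(basins$reactant$conditions$cv_id,
                  basins$product$conditions$cv_id))
  setNames(lapply(ids, function(id) {
    if (grepl("^x_[0-9]+$", id)) {
      cv_def("coordinate_projection", as.integer(sub("^x_", "", id)), cv_id = id)
    } else {
      stop_config("basin CV '%s' has no definition; attach one via attr(basins, 'cv_set')", id)
    }
  }), ids)
}

# Matrix of CV values (frames x CVs) from a position matrix.
cv_matrix_from_positions <- function(cv_set, pos, dim) {
  out <- vapply(cv_set, function(cv) evaluate_cv_traj(cv, pos, dim),
                numeric(nrow(pos)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(pos),
                                       dimnames = list(NULL, names(cv_set)))
  colnames(out) <- names(cv_set)
  out
}

# d(r)/dt at a frame with velocities: sum over CV coefficient * CV rate.
rc_rate <- function(model, cv_set, frm, dim) {
  rates <- vapply(model$cv_ids, function(id) cv_rate(cv_set[[id]], frm, dim),
                  numeric(1))
  if (!is.null(model$standardization)) {
    rates <- rates / model$standardization$sd[model$cv_ids]
  }
  sum(model$coeffs * rates)
}

pb_histogram <- function(pB, n_bins) {
  edges <- seq(0, 1, length.out = n_bins + 1L)
  # right-closed bins; pB = 0 falls in the first bin
  idx <- pmax(1L, ceiling(pB * n_bins - 1e-12))
  counts <- tabulate(idx, nbins = n_bins)
  list(edges = edges, counts = counts)
}

#' Committor histogram test
#'
#' An RC passes when the pB histogram of its putative transition states is
#' unimodal around 0.5: sample mean in `[0.45, 0.55]`, at least 40% of
#' points with `pB` in `[0.4, 0.6]`, and no mode at the extreme bins (a
#' U-shaped histogram means the coordinate misses the true transition
#' state even though its mean can still be 0.5).
#'
#' @param result a `committor_result`
#' @param n_bins histogram bins over `[0, 1]` (right-closed)
#' @return list with `mean`, `sd`, `frac_central`, `histogram`, and `pass`
#' @export
histogram_test <- function(result, n_bins = 10L) {
  pB <- result$points$pB
  pB <- pB[!is.na(pB)]
  if (length(pB) < 10L) stop_config("need >= 10 points with defined pB (got %d)", length(pB))
  h <- pb_histogram(pB, n_bins)
  interior_max <- max(h$counts[2L:(n_bins - 1L)])
  no_extreme_mode <- h$counts[1L] <= interior_max && h$counts[n_bins] <= interior_max
  m <- mean(pB)
  frac_central <- mean(pB >= 0.4 & pB <= 0.6)
  list(mean = m, sd = sd(pB), frac_central = frac_central, histogram = h,
       n = length(pB),
       pass = (m >= 0.45 && m <= 0.55) && frac_central >= 0.4 && no_extreme_mode)
}
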