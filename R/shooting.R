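# Flexible-length aimless shooting: basin classification, two-way shooting
# moves with Maxwell-Boltzmann velocities (forward with V0, backward with
# -V0), chain campaigns, decorrelation filtering, and restrained
# transition-state seeding (find_ts).

#' Define a metastable basin by CV conditions
#'
#' A frame belongs to the basin when ALL conditions hold; inequalities are
#' strict, so a value exactly at a threshold does not satisfy it.
#'
#' @param name basin name (`"reactant"` or `"product"`)
#' @param conditions data.frame with columns `cv_id`, `comparator`
#'   (`"<"` or `">"`), `threshold`; or a list of `(cv_id, comparator,
#'   threshold)` triples
#' @return a `basin_def`
#' @export
basin_def <- function(name, conditions) {
  if (is.list(conditions) && !is.data.frame(conditions)) {
    conditions <- do.call(rbind, lapply(conditions, function(cn) {
      data.frame(cv_id = cn[[1]], comparator = cn[[2]],
                 threshold = as.numeric(cn[[3]]))
    }))
  }
  stopifnot(is.data.frame(conditions),
            all(c("cv_id", "comparator", "threshold") %in% names(conditions)))
  if (nrow(conditions) == 0L) stop_config("basin '%s' has no conditions", name)
  if (!all(conditions$comparator %in% c("<", ">"))) {
    stop_config("comparators must be '<' or '>'")
  }
  structure(list(name = name, conditions = conditions), class = "basin_def")
}

#' Aimless-shooting configuration
#'
#' @param T temperature for Maxwell-Boltzmann velocity draws
#' @param dt integration timestep
#' @param friction Langevin friction during shooting trajectories
#' @param max_steps per-direction commitment cap (flexible-length shooting;
#'   a trajectory that never commits is a `"timeout"`)
#' @param offset_window `[t_min, t_max]` time window (same units as `dt`)
#'   from which the next shooting point is drawn on the forward trajectory
#'   of a reactive move
#' @param alpha significance level of the decorrelation filter
#' @param rejection_cap consecutive rejected moves before a chain is
#'   terminated with a warning
#' @param chunk steps propagated between commitment checks (performance
#'   knob; does not affect results)
#' @return an `as_config`
#' @export
as_config <- function(T = 1, dt = 0.005, friction = 1, max_steps = 10000L,
                      offset_window = c(dt, 10 * dt), alpha = 0.05,
                      rejection_cap = 1000L, chunk = 256L) {
  if (length(offset_window) != 2L || offset_window[1] <= 0 ||
      offset_window[1] > offset_window[2]) {
    stop_config("offset_window must satisfy 0 < t_min <= t_max")
  }
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  structure(list(T = T, dt = dt, friction = friction,
                 max_steps = as.integer(max_steps),
                 offset_window = offset_window, alpha = alpha,
                 rejection_cap = as.integer(rejection_cap),
                 chunk = as.integer(chunk)), class = "as_config")
}

# Evaluate basin membership for a matrix of frames. Returns a character
# vector "reactant"/"product"/"neither"; errors if any frame satisfies both.
classify_positions <- function(pos, basins, cv_set, dim) {
  ids <- unique(c(basins$reactant$conditions$cv_id,
                  basins$product$conditions$cv_id))
  missing <- setdiff(ids, names(cv_set))
  if (length(missing)) {
    stop_config("basin condition references unknown CV(s): %s",
                paste(missing, collapse = ", "))
  }
  vals <- vapply(ids, function(id) evaluate_cv_traj(cv_set[[id]], pos, dim),
                 numeric(nrow(pos)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, ids))
  sat <- function(basin) {
    ok <- rep(TRUE, nrow(pos))
    for (i in seq_len(nrow(basin$conditions))) {
      cn <- basin$conditions[i, ]
      v <- vals[, cn$cv_id]
      ok <- ok & if (cn$comparator == "<") v < cn$threshold else v > cn$threshold
    }
    ok
  }
  in_r <- sat(basins$reactant)
  in_p <- sat(basins$product)
  both <- which(in_r & in_p)
  if (length(both)) {
    stop_config("overlapping basins: frame satisfies both reactant and product definitions")
  }
  out <- rep("neither", nrow(pos))
  out[in_r] <- "reactant"
  out[in_p] <- "product"
  out
}

#' Classify a frame (or CV values) against a basin pair
#'
#' @param x a [frame()], a flat position vector, or a named vector of CV
#'   values
#' @param basins list with elements `reactant` and `product`
#'   ([basin_def()]s)
#' @param cv_set named list of [cv_def()]s referenced by the basins
#'   (not needed when `x` is already a named CV vector)
#' @param dim spatial dimension
#' @return `"reactant"`, `"product"`, or `"neither"`
#' @export
classify_frame <- function(x, basins, cv_set = NULL, dim = 1L) {
  if (is.numeric(x) && !is.null(names(x))) {
    sat <- function(basin) {
      all(vapply(seq_len(nrow(basin$conditions)), function(i) {
        cn <- basin$conditions[i, ]
        if (!cn$cv_id %in% names(x)) stop_config("CV '%s' missing from values", cn$cv_id)
        if (cn$comparator == "<") x[[cn$cv_id]] < cn$threshold
        else x[[cn$cv_id]] > cn$threshold
      }, logical(1)))
    }
    r <- sat(basins$reactant); p <- sat(basins$product)
    if (r && p) stop_config("overlapping basins: values satisfy both definitions")
    return(if (r) "reactant" else if (p) "product" else "neither")
  }
  pos <- matrix(if (inherits(x, "frame")) x$x else as.numeric(x), nrow = 1L)
  classify_positions(pos, basins, cv_set, dim)[1L]
}

# Propagate until first basin commitment (or cap). Returns fate, the number
# of steps run, and the saved trajectory up to (and including) commitment.
shoot_until_commit <- function(system, x0, v0, basins, cv_set, cfg) {
  pos_chunks <- list()
  t_chunks <- list()
  x <- x0; v <- v0
  steps_done <- 0L
  fate <- "timeout"
  kT <- system$kB * cfg$T
  while (steps_done < cfg$max_steps) {
    n <- min(cfg$chunk, cfg$max_steps - steps_done)
    res <- propagate_cpp(system$pid, system$par_vec, system$mass_vec, x, v,
                         n, cfg$dt, cfg$friction, kT, 1L,
                         bias_matrix(NULL, system))
    if (res$fail_step >= 0) {
      stop_config("non-finite coordinates at step %d during shooting",
                  steps_done + res$fail_step)
    }
    pos <- res$positions[-1L, , drop = FALSE] # drop repeated initial frame
    cls <- classify_positions(pos, basins, cv_set, system$dim)
    hit <- which(cls != "neither")
    if (length(hit)) {
      k <- hit[1L]
      pos_chunks[[length(pos_chunks) + 1L]] <- pos[seq_len(k), , drop = FALSE]
      t_chunks[[length(t_chunks) + 1L]] <- (steps_done + seq_len(k)) * cfg$dt
      fate <- cls[k]
      steps_done <- steps_done + k
      break
    }
    pos_chunks[[length(pos_chunks) + 1L]] <- pos
    t_chunks[[length(t_chunks) + 1L]] <- (steps_done + seq_len(n)) * cfg$dt
    steps_done <- steps_done + n
    nr <- nrow(res$positions)
    x <- res$positions[nr, ]
    v <- res$velocities[nr, ]
  }
  list(fate = fate, n_steps = steps_done,
       positions = do.call(rbind, pos_chunks),
       times = unlist(t_chunks))
}

#' One aimless-shooting move
#'
#' Draws Maxwell-Boltzmann velocities `V0` at the shooting point, propagates
#' forward with `V0` and backward with `-V0`, each until basin commitment or
#' `cfg$max_steps`.  The move is reactive when the two half-trajectories
#' commit to opposite basins; a reactive move proposes the forward-trajectory
#' frame at a uniformly random time offset in `cfg$offset_window` as the next
#' shooting point.
#'
#' @param system a [make_system()] object
#' @param point shooting point [frame()] (must classify as `"neither"`)
#' @param basins reactant/product [basin_def()] pair
#' @param cvs named list of [cv_def()]s recorded (values and rates) at the
#'   shooting point for later likelihood maximization
#' @param cfg an [as_config()]
#' @param seed integer seed for this move
#' @param keep_traj keep the forward/backward position series in the record
#' @return list with `record` (a `shooting_record`) and `next_candidate`
#'   (a positions-only [frame()], or `NULL` for non-reactive moves)
#' @export
shooting_move <- function(system, point, basins, cvs, cfg, seed = NULL,
                          keep_traj = FALSE) {
  cv_set <- setNames(cvs, vapply(cvs, `[[`, "", "cv_id"))
  if (classify_frame(point, basins, cv_set, system$dim) != "neither") {
    stop_config("shooting point already committed to a basin")
  }
  with_seed(seed, {
    v0 <- draw_velocities(system, cfg$T)
    fwd <- shoot_until_commit(system, point$x, v0, basins, cv_set, cfg)
    bwd <- shoot_until_commit(system, point$x, -v0, basins, cv_set, cfg)
    reactive <- setequal(c(fwd$fate, bwd$fate), c("reactant", "product"))
    cvv <- cv_vector(cvs, frame(point$x, v0), system$dim)
    next_candidate <- NULL
    offset_steps <- NA_integer_
    if (reactive) {
      tau <- runif(1, cfg$offset_window[1], cfg$offset_window[2])
      offset_steps <- max(1L, min(round(tau / cfg$dt), fwd$n_steps))
      next_candidate <- frame(fwd$positions[offset_steps, ], NULL,
                              time = point$time + offset_steps * cfg$dt)
    }
    record <- structure(list(
      point = point$x, v0 = v0,
      fwd_fate = fwd$fate, bwd_fate = bwd$fate, reactive = reactive,
      cv_values = cvv$values, cv_rates = cvv$rates,
      fwd_end = fwd$positions[nrow(fwd$positions), ],
      bwd_end = bwd$positions[nrow(bwd$positions), ],
      accepted = reactive, offset_steps = offset_steps,
      fwd_traj = if (keep_traj) fwd[c("positions", "times")] else NULL,
      bwd_traj = if (keep_traj) bwd[c("positions", "times")] else NULL
    ), class = "shooting_record")
    list(record = record, next_candidate = next_candidate)
  })
}

# Assemble records into the ensemble container used downstream.
build_ensemble <- function(records, chain, move, cv_ids, ncoord) {
  n <- length(records)
  if (n == 0L) {
    return(structure(list(
      fates = data.frame(chain = integer(0), move = integer(0),
                         fwd_fate = character(0), bwd_fate = character(0),
                         reactive = logical(0), accepted = logical(0)),
      cv_values = matrix(numeric(0), 0, length(cv_ids),
                         dimnames = list(NULL, cv_ids)),
      cv_rates = matrix(numeric(0), 0, length(cv_ids),
                        dimnames = list(NULL, cv_ids)),
      points = matrix(numeric(0), 0, ncoord),
      end_fwd = matrix(numeric(0), 0, ncoord),
      end_bwd = matrix(numeric(0), 0, ncoord),
      cv_ids = cv_ids, acceptance_ratio = NULL
    ), class = "as_ensemble"))
  }
  fates <- data.frame(
    chain = chain, move = move,
    fwd_fate = vapply(records, `[[`, "", "fwd_fate"),
    bwd_fate = vapply(records, `[[`, "", "bwd_fate"),
    reactive = vapply(records, `[[`, NA, "reactive"),
    accepted = vapply(records, `[[`, NA, "accepted")
  )
  structure(list(
    fates = fates,
    cv_values = do.call(rbind, lapply(records, `[[`, "cv_values")),
    cv_rates = do.call(rbind, lapply(records, `[[`, "cv_rates")),
    points = do.call(rbind, lapply(records, `[[`, "point")),
    end_fwd = do.call(rbind, lapply(records, `[[`, "fwd_end")),
    end_bwd = do.call(rbind, lapply(records, `[[`, "bwd_end")),
    cv_ids = cv_ids,
    acceptance_ratio = mean(fates$reactive)
  ), class = "as_ensemble")
}

#' @export
print.as_ensemble <- function(x, ...) {
  cat(sprintf("<as_ensemble: %d records, %d chain(s), reactive fraction %s>\n",
              nrow(x$fates), length(unique(x$fates$chain)),
              if (is.null(x$acceptance_ratio)) "undefined"
              else sprintf("%.3f", x$acceptance_ratio)))
  invisible(x)
}

#' Run an aimless-shooting campaign
#'
#' Each initial point seeds an independent chain.  A chain advances to the
#' proposed next shooting point only on reactive moves; rejected moves
#' resample velocities at the same point.  All attempted moves (accepted or
#' not) are retained with chain/move provenance, and the reactive fraction
#' is reported as the acceptance ratio.
#'
#' @param system a [make_system()] object
#' @param initial_points list of [frame()]s, each classifying as `"neither"`
#' @param n_moves_per_chain moves attempted per chain
#' @param basins reactant/product basin pair
#' @param cvs named list of [cv_def()]s to record
#' @param cfg an [as_config()]
#' @param seed campaign seed; per-move seeds are derived deterministically
#' @return an `as_ensemble`
#' @export
aimless_shooting_campaign <- function(system, initial_points, n_moves_per_chain,
                                      basins, cvs, cfg, seed = 1L) {
  if (length(initial_points) == 0L) stop_config("need at least one initial point")
  cv_ids <- vapply(cvs, `[[`, "", "cv_id")
  records <- list()
  chain_idx <- integer(0)
  move_idx <- integer(0)
  for (ch in seq_along(initial_points)) {
    pt <- initial_points[[ch]]
    rejects <- 0L
    for (mv in seq_len(n_moves_per_chain)) {
      res <- shooting_move(system, pt, basins, cvs, cfg,
                           seed = derive_seed(seed, ch, mv))
      records[[length(records) + 1L]] <- res$record
      chain_idx <- c(chain_idx, ch)
      move_idx <- c(move_idx, mv)
      if (res$record$reactive) {
        pt <- res$next_candidate
        rejects <- 0L
      } else {
        rejects <- rejects + 1L
        if (rejects > cfg$rejection_cap) {
          warning(sprintf("chain %d stalled after %d consecutive rejections; terminating chain",
                          ch, rejects), call. = FALSE)
          break
        }
      }
    }
  }
  build_ensemble(records, chain_idx, move_idx, cv_ids, system$ncoord)
}

#' Remove initialization bias by CV autocorrelation filtering
#'
#' Per chain, measures the lag autocorrelation of every CV along the move
#' sequence and drops the initial segment that is still significantly
#' correlated: the dropped prefix is the largest lag (over all CVs) whose
#' sample autocorrelation exceeds the normal band
#' `+/- z[1-alpha'/2]/sqrt(n)`, with `alpha'` Bonferroni-corrected over
#' CVs and the `max_lag` tested lags so the per-CV false-positive rate
#' stays at `alpha`.  An i.i.d. chain is expected to lose nothing; a chain
#' whose early moves still remember a hand-seeded starting structure loses
#' that transient.  Lags are scanned out to the chain length (less
#' `min_len`) so that long initialization trends are removed whole, not
#' just their first `max_lag` moves.  Chains shorter than the minimal
#' testable length are retained whole with a warning; no chain is ever
#' dropped silently.
#'
#' @param ensemble an `as_ensemble` with per-chain move ordering
#' @param alpha significance level (the filter's design level is 0.05)
#' @param max_lag number of lags entering the Bonferroni correction
#' @param min_len minimal retained suffix / testable chain length
#' @return the filtered `as_ensemble`; per-chain dropped counts in
#'   `attr(, "dropped")`
#' @export
decorrelation_filter <- function(ensemble, alpha = 0.05, max_lag = 20L,
                                 min_len = 10L) {
  keep <- logical(nrow(ensemble$fates))
  dropped <- integer(0)
  n_cv <- length(ensemble$cv_ids)
  zcrit <- qnorm(1 - (alpha / (n_cv * max_lag)) / 2)
  for (ch in unique(ensemble$fates$chain)) {
    rows <- which(ensemble$fates$chain == ch)
    rows <- rows[order(ensemble$fates$move[rows])]
    n <- length(rows)
    if (n < min_len) {
      warning(sprintf("chain %d shorter than minimum testable length (%d); retained whole",
                      ch, min_len), call. = FALSE)
      keep[rows] <- TRUE
      dropped <- c(dropped, 0L)
      next
    }
    band <- zcrit / sqrt(n)
    L <- min(n - min_len, n - 2L)
    decorr <- 0L
    for (j in seq_len(n_cv)) {
      x <- ensemble$cv_values[rows, j]
      if (sd(x) < 1e-12) next # constant CV: nothing to test
      ac <- acf(x, lag.max = L, plot = FALSE, demean = TRUE)$acf[-1L]
      sig <- which(abs(ac) > band)
      if (length(sig)) decorr <- max(decorr, max(sig))
    }
    s_keep <- min(decorr, n - min_len)
    if (s_keep > 0L) keep[rows[(s_keep + 1L):n]] <- TRUE else keep[rows] <- TRUE
    dropped <- c(dropped, s_keep)
  }
  out <- subset_ensemble(ensemble, which(keep))
  attr(out, "dropped") <- dropped
  out
}

# Row-subset an ensemble, recomputing the acceptance ratio.
subset_ensemble <- function(ensemble, idx) {
  out <- ensemble
  out$fates <- ensemble$fates[idx, , drop = FALSE]
  rownames(out$fates) <- NULL
  out$cv_values <- ensemble$cv_values[idx, , drop = FALSE]
  out$cv_rates <- ensemble$cv_rates[idx, , drop = FALSE]
  out$points <- ensemble$points[idx, , drop = FALSE]
  if (!is.null(ensemble$end_fwd)) {
    out$end_fwd <- ensemble$end_fwd[idx, , drop = FALSE]
    out$end_bwd <- ensemble$end_bwd[idx, , drop = FALSE]
  }
  out$acceptance_ratio <- if (nrow(out$fates)) mean(out$fates$reactive) else NULL
  out
}

#' Seed putative transition states by dragging CVs across the barrier
#'
#' Runs restrained dynamics from a reactant-basin frame, with a harmonic
#' restraint on each drag CV whose target interpolates linearly from the
#' CV's reactant value to its product target over `n_stages` stages.  The
#' final frame of each stage is harvested, and frames not committed to
#' either basin are verified with `n_verify` aimless-shooting moves; frames
#' with at least one reactive verification move are returned.
#'
#' @param system a [make_system()] object
#' @param reactant_frame starting [frame()] (must classify as `"reactant"`)
#' @param basins reactant/product basin pair
#' @param drag_cvs named list of [cv_def()]s to drag (coordinate
#'   projections or distances)
#' @param product_targets named numeric vector: target value of each drag CV
#'   in the product state
#' @param cfg an [as_config()]
#' @param seed integer seed
#' @param n_stages number of interpolation stages
#' @param stage_steps restrained steps per stage
#' @param k_drag restraint force constant
#' @param n_verify verification shooting moves per harvested frame (>= 1)
#' @return list of verified putative-TS [frame()]s (possibly empty), with
#'   the committed fates of failed candidates in `attr(, "diagnostics")`
#' @export
find_ts <- function(system, reactant_frame, basins, drag_cvs, product_targets,
                    cfg, seed = 1L, n_stages = 20L, stage_steps = 2000L,
                    k_drag = 100, n_verify = 5L) {
  if (n_verify < 1L) stop_config("n_verify must be >= 1")
  cv_set <- setNames(drag_cvs, vapply(drag_cvs, `[[`, "", "cv_id"))
  cls <- classify_frame(reactant_frame, basins, cv_set, system$dim)
  if (cls != "reactant") {
    stop_config("find_ts requires a reactant-basin starting frame (got '%s')", cls)
  }
  start_vals <- vapply(cv_set, evaluate_cv, numeric(1),
                       frm = reactant_frame, dim = system$dim)
  targets <- product_targets[names(cv_set)]
  if (anyNA(targets)) stop_config("product_targets must name every drag CV")
  cur <- reactant_frame
  if (is.null(cur$v)) cur <- frame(cur$x, draw_velocities(system, cfg$T, seed))
  harvested <- list()
  for (st in seq_len(n_stages)) {
    lam <- st / n_stages
    biases <- lapply(seq_along(cv_set), function(i) {
      cv <- cv_set[[i]]
      ctr <- (1 - lam) * start_vals[i] + lam * targets[i]
      if (cv$kind == "coordinate_projection") {
        w <- rep(0, system$ncoord); w[cv$atom_indices[1]] <- 1
        list(type = "linear", k = k_drag, center = ctr, b0 = 0, w = w)
      } else if (cv$kind == "distance") {
        list(type = "distance", k = k_drag, center = ctr,
             i = cv$atom_indices[1], j = cv$atom_indices[2])
      } else {
        stop_config("drag CV kind '%s' not supported for restrained toy dynamics",
                    cv$kind)
      }
    })
    traj <- propagate(system, cur, stage_steps, cfg$dt, cfg$friction, cfg$T,
                      seed = derive_seed(seed, st), save_stride = stage_steps,
                      biases = biases)
    nr <- nrow(traj$positions)
    cur <- frame(traj$positions[nr, ], traj$velocities[nr, ])
    harvested[[st]] <- frame(cur$x, NULL)
  }
  verified <- list()
  n_reactive <- integer(0)
  diagnostics <- list()
  for (i in seq_along(harvested)) {
    f <- harvested[[i]]
    if (classify_frame(f, basins, cv_set, system$dim) != "neither") next
    fates <- character(0)
    hits <- 0L
    for (v in seq_len(n_verify)) {
      mv <- shooting_move(system, f, basins, drag_cvs, cfg,
                          seed = derive_seed(seed, 1000L + i, v))
      fates <- c(fates, paste(mv$record$fwd_fate, mv$record$bwd_fate, sep = "/"))
      if (mv$record$reactive) hits <- hits + 1L
    }
    if (hits >= 1L) {
      verified[[length(verified) + 1L]] <- f
      n_reactive <- c(n_reactive, hits)
    } else {
      diagnostics[[length(diagnostics) + 1L]] <- fates
    }
  }
  if (length(verified) == 0L) {
    warning("no harvested frame passed shooting verification", call. = FALSE)
  } else {
    # best-verified candidates first
    ord <- order(-n_reactive)
    verified <- verified[ord]
    n_reactive <- n_reactive[ord]
  }
  attr(verified, "n_reactive") <- n_reactive
  attr(verified, "diagnostics") <- diagnostics
  verified
}

#' Persist an ensemble as JSON-lines (one record per line)
#'
#' @param ensemble an `as_ensemble`
#' @param path output file
#' @export
write_ensemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(header = TRUE, cv_ids = ensemble$cv_ids,
                                   ncoord = ncol(ensemble$points)),
                              auto_unbox = TRUE, digits = NA), con)
  for (i in seq_len(nrow(ensemble$fates))) {
    rec <- list(chain = ensemble$fates$chain[i], move = ensemble$fates$move[i],
                fwd_fate = ensemble$fates$fwd_fate[i],
                bwd_fate = ensemble$fates$bwd_fate[i],
                reactive = ensemble$fates$reactive[i],
                accepted = ensemble$fates$accepted[i],
                cv_values = unname(ensemble$cv_values[i, ]),
                cv_rates = unname(ensemble$cv_rates[i, ]),
                point = unname(ensemble$points[i, ]),
                fwd_end = if (!is.null(ensemble$end_fwd)) unname(ensemble$end_fwd[i, ]),
                bwd_end = if (!is.null(ensemble$end_bwd)) unname(ensemble$end_bwd[i, ]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read an ensemble written by [write_ensemble()]
#' @param path JSON-lines file
#' @return an `as_ensemble`
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1L])
  recs <- lapply(lines[-1L], jsonlite::fromJSON)
  fates <- data.frame(
    chain = vapply(recs, `[[`, 1L, "chain"),
    move = vapply(recs, `[[`, 1L, "move"),
    fwd_fate = vapply(recs, `[[`, "", "fwd_fate"),
    bwd_fate = vapply(recs, `[[`, "", "bwd_fate"),
    reactive = vapply(recs, `[[`, NA, "reactive"),
    accepted = vapply(recs, `[[`, NA, "accepted")
  )
  cvv <- do.call(rbind, lapply(recs, function(r) r$cv_values))
  cvr <- do.call(rbind, lapply(recs, function(r) r$cv_rates))
  pts <- do.call(rbind, lapply(recs, function(r) r$point))
  ef <- do.call(rbind, lapply(recs, function(r) r$fwd_end))
  eb <- do.call(rbind, lapply(recs, function(r) r$bwd_end))
  colnames(cvv) <- colnames(cvr) <- header$cv_ids
  structure(list(fates = fates, cv_values = cvv, cv_rates = cvr,
                 points = pts, end_fwd = ef, end_bwd = eb,
                 cv_ids = header$cv_ids,
                 acceptance_ratio = if (nrow(fates)) mean(fates$reactive) else NULL),
            class = "as_ensemble")
}

#' Construct an ensemble directly from data
#'
#' Lets externally generated (or simulated) shooting data enter the
#' likelihood-maximization stage without running toy dynamics.
#'
#' @param cv_values numeric matrix (records x CVs) with CV ids as column
#'   names
#' @param fwd_fates character vector of forward fates
#'   (`"reactant"`/`"product"`/`"timeout"`)
#' @param cv_rates optional matrix of CV rates (zeros if omitted)
#' @param bwd_fates optional backward fates (opposite of forward by default)
#' @param chain,move optional provenance vectors
#' @return an `as_ensemble`
#' @export
as_ensemble_from_data <- function(cv_values, fwd_fates, cv_rates = NULL,
                                  bwd_fates = NULL, chain = NULL, move = NULL) {
  cv_values <- as.matrix(cv_values)
  n <- nrow(cv_values)
  if (is.null(colnames(cv_values))) {
    colnames(cv_values) <- paste0("cv", seq_len(ncol(cv_values)))
  }
  if (is.null(cv_rates)) cv_rates <- matrix(0, n, ncol(cv_values),
                                            dimnames = dimnames(cv_values))
  if (is.null(bwd_fates)) {
    bwd_fates <- ifelse(fwd_fates == "product", "reactant",
                        ifelse(fwd_fates == "reactant", "product", "timeout"))
  }
  reactive <- (fwd_fates == "product" & bwd_fates == "reactant") |
    (fwd_fates == "reactant" & bwd_fates == "product")
  structure(list(
    fates = data.frame(chain = if (is.null(chain)) rep(1L, n) else chain,
                       move = if (is.null(move)) seq_len(n) else move,
                       fwd_fate = fwd_fates, bwd_fate = bwd_fates,
                       reactive = reactive, accepted = reactive),
    cv_values = cv_values, cv_rates = as.matrix(cv_rates),
    points = matrix(NA_real_, n, 0L),
    end_fwd = matrix(NA_real_, n, 0L), end_bwd = matrix(NA_real_, n, 0L),
    cv_ids = colnames(cv_values),
    acceptance_ratio = if (n) mean(reactive) else NULL
  ), class = "as_ensemble")
}
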