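# Run configuration, validation, end-to-end orchestration, and external CV
# series import.  A single YAML config drives the whole pipeline
# (find_ts / shooting -> decorrelation -> RC fit -> committor -> umbrella /
# MBAR -> reactive flux -> Eyring), every stage seeded from one global seed.

.config_keys <- list(
  top = c("seed", "output_dir", "system", "cvs", "basins", "shooting", "rc",
          "committor", "umbrella", "kinetics", "resume"),
  system = c("potential_id", "params", "masses", "dim", "n_particles", "unit_system"),
  shooting = c("T", "dt", "friction", "max_steps", "offset_window", "alpha",
               "rejection_cap", "n_chains", "n_moves_per_chain", "initial_x",
               "find_ts"),
  rc = c("method", "inertial", "cv_subset", "k_max"),
  committor = c("n_points", "n_trials", "flux_stride"),
  umbrella = c("range", "width", "k_restraint", "n_replicas", "n_steps",
               "ramp_steps", "reactant_side", "n_bins", "save_stride"),
  kinetics = c("T", "r_tol")
)

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    stop_config("unknown config key(s) in %s: %s", where,
                paste(unknown, collapse = ", "))
  }
}

#' Read and validate a pipeline run configuration
#'
#' The configuration is YAML; unknown keys are rejected, basin definitions
#' are checked for satisfiable overlap (a geometry could belong to both
#' basins at once), and the result round-trips losslessly through
#' [yaml::write_yaml()].
#'
#' @param path YAML file (or an already-parsed list)
#' @return validated config list
#' @export
read_run_config <- function(path) {
  config <- if (is.character(path)) yaml::read_yaml(path) else path
  check_keys(config, .config_keys$top, "top level")
  for (blk in c("system", "shooting", "rc", "committor", "umbrella", "kinetics")) {
    if (!is.null(config[[blk]])) check_keys(config[[blk]], .config_keys[[blk]], blk)
  }
  if (is.null(config$system)) stop_config("config needs a 'system' block")
  if (is.null(config$basins)) stop_config("config needs a 'basins' block")
  basins <- config_basins(config)
  check_basin_overlap(basins)
  config
}

config_basins <- function(config) {
  mk <- function(name) {
    basin_def(name, do.call(rbind, lapply(config$basins[[name]], function(cn) {
      data.frame(cv_id = cn$cv_id, comparator = cn$comparator,
                 threshold = as.numeric(cn$threshold))
    })))
  }
  list(reactant = mk("reactant"), product = mk("product"))
}

# Basins are boxes in CV space (strict one-sided conditions); they overlap
# iff the intersection of all constraints is non-empty for every CV.
check_basin_overlap <- function(basins) {
  conds <- rbind(cbind(basins$reactant$conditions, basin = "reactant"),
                 cbind(basins$product$conditions, basin = "product"))
  for (id in unique(conds$cv_id)) {
    sub <- conds[conds$cv_id == id, ]
    lo <- suppressWarnings(max(sub$threshold[sub$comparator == ">"], -Inf))
    hi <- suppressWarnings(min(sub$threshold[sub$comparator == "<"], Inf))
    if (lo >= hi) return(invisible(FALSE)) # this CV separates the basins
  }
  offending <- paste(sprintf("%s %s %g [%s]", conds$cv_id, conds$comparator,
                             conds$threshold, conds$basin), collapse = "; ")
  stop_config("overlapping basins: a configuration can satisfy both definitions (%s)",
              offending)
}

config_cvs <- function(config) {
  if (is.null(config$cvs)) stop_config("config needs a 'cvs' block")
  cvs <- lapply(config$cvs, function(cv) {
    cv_def(cv$kind, unlist(cv$atom_indices), cv_id = cv$cv_id, units = cv$units)
  })
  setNames(cvs, vapply(cvs, `[[`, "", "cv_id"))
}

#' Run the full pipeline from a configuration
#'
#' Executes the stages in dependency order -- (optional) transition-state
#' seeding, aimless shooting, decorrelation filtering, reaction-coordinate
#' fitting, committor validation, umbrella sampling with MBAR, reactive
#' flux, and the Eyring rate -- persisting each stage's artifact under
#' `output_dir` and recording seeds and artifact paths in a run manifest.
#' A stage failure halts downstream stages; the manifest marks the failure
#' point.  With `resume: true`, the shooting ensemble and RC model are
#' reloaded from their artifacts when present.
#'
#' For systems in reduced units the PMF barrier is in kBT; when a
#' `kinetics` block supplies an absolute temperature, the barrier is
#' converted to kcal/mol at that temperature before the Eyring equation.
#'
#' @param config path to a YAML config or a config list (see
#'   [read_run_config()])
#' @return a `run_manifest` (invisibly also written to
#'   `output_dir/manifest.json`)
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  out_dir <- if (is.null(config$output_dir)) "." else config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- list(seed = seed, stages = list(), artifacts = character(0))
  art <- function(name) file.path(out_dir, name)
  record_stage <- function(name, seed_used, outputs, status = "ok") {
    manifest$stages[[name]] <<- list(seed = seed_used, outputs = outputs,
                                     status = status)
    manifest$artifacts <<- c(manifest$artifacts, outputs)
  }
  fail <- function(name, err) {
    record_stage(name, NA, character(0), status = paste("failed:", conditionMessage(err)))
    write_manifest(manifest, art("manifest.json"))
    stop(err)
  }

  sys_cfg <- config$system
  system <- make_system(sys_cfg$potential_id,
                        params = if (is.null(sys_cfg$params)) list() else sys_cfg$params,
                        masses = if (is.null(sys_cfg$masses)) 1 else unlist(sys_cfg$masses),
                        dim = if (is.null(sys_cfg$dim)) 1L else sys_cfg$dim,
                        n_particles = if (is.null(sys_cfg$n_particles)) 1L else sys_cfg$n_particles,
                        unit_system = if (is.null(sys_cfg$unit_system)) "reduced" else sys_cfg$unit_system)
  cvs <- config_cvs(config)
  basins <- config_basins(config)
  attr(basins, "cv_set") <- cvs
  sh <- config$shooting
  cfg <- as_config(T = sh$T, dt = sh$dt, friction = sh$friction,
                   max_steps = if (is.null(sh$max_steps)) 10000L else sh$max_steps,
                   offset_window = if (is.null(sh$offset_window)) c(sh$dt, 10 * sh$dt)
                                   else unlist(sh$offset_window),
                   alpha = if (is.null(sh$alpha)) 0.05 else sh$alpha,
                   rejection_cap = if (is.null(sh$rejection_cap)) 1000L else sh$rejection_cap)

  # --- initial shooting points -------------------------------------------
  pts_stage <- tryCatch({
    if (!is.null(sh$find_ts)) {
      ft <- sh$find_ts
      pts <- find_ts(system, frame(unlist(ft$reactant_x)), basins,
                     cvs[unlist(ft$drag_cv_ids)],
                     setNames(unlist(ft$product_targets), unlist(ft$drag_cv_ids)),
                     cfg, seed = derive_seed(seed, 1L))
      if (length(pts) == 0L) stop_config("find_ts produced no verified frames")
      pts
    } else {
      lapply(sh$initial_x, function(x) frame(unlist(x)))
    }
  }, error = function(e) fail("seed_points", e))
  # independent sampling schemes: replicate the seed points across chains
  if (!is.null(sh$n_chains)) {
    pts_stage <- rep(pts_stage, length.out = sh$n_chains)
  }
  record_stage("seed_points", derive_seed(seed, 1L), character(0))

  # --- aimless shooting ---------------------------------------------------
  ens_path <- art("ensemble.jsonl")
  ensemble <- tryCatch({
    if (isTRUE(config$resume) && file.exists(ens_path)) {
      read_ensemble(ens_path)
    } else {
      e <- aimless_shooting_campaign(system, pts_stage, sh$n_moves_per_chain,
                                     basins, cvs, cfg,
                                     seed = derive_seed(seed, 2L))
      write_ensemble(e, ens_path)
      e
    }
  }, error = function(e) fail("shooting", e))
  record_stage("shooting", derive_seed(seed, 2L), ens_path)

  filtered <- tryCatch(decorrelation_filter(ensemble, alpha = cfg$alpha),
                       error = function(e) fail("decorrelation", e))
  record_stage("decorrelation", NA, character(0))

  # --- reaction coordinate ------------------------------------------------
  rc_path <- art("rc_model.json")
  rc_cfg <- config$rc
  rc <- tryCatch({
    if (isTRUE(config$resume) && file.exists(rc_path)) {
      read_rc_model(rc_path)
    } else {
      inertial <- !isFALSE(rc_cfg$inertial)
      m <- if (identical(rc_cfg$method, "two_line")) {
        two_line_select(filtered, rc_cfg$cv_subset,
                        k_max = if (is.null(rc_cfg$k_max)) 6L else rc_cfg$k_max,
                        inertial = inertial,
                        control = list(seed = derive_seed(seed, 3L)))
      } else {
        ilmax_fit(filtered, rc_cfg$cv_subset, inertial = inertial,
                  control = list(seed = derive_seed(seed, 3L)))
      }
      # anchor the sign convention on the committed basin endpoints: the
      # near-saddle shooting points alone can leave the positional
      # orientation of an inertial fit undetermined
      if (ncol(filtered$end_fwd)) {
        ip <- which(filtered$fates$fwd_fate == "product")
        ir <- which(filtered$fates$fwd_fate == "reactant")
        if (length(ip) && length(ir)) {
          r_p <- evaluate_rc(m, cv_matrix_from_positions(
            cvs, filtered$end_fwd[ip, , drop = FALSE], system$dim))
          r_r <- evaluate_rc(m, cv_matrix_from_positions(
            cvs, filtered$end_fwd[ir, , drop = FALSE], system$dim))
          if (mean(r_p) < mean(r_r)) {
            m$c0 <- -m$c0
            m$coeffs <- -m$coeffs
            if (!is.null(m$v_coeff)) m$v_coeff <- -m$v_coeff
          }
        }
      }
      write_rc_model(m, rc_path)
      m
    }
  }, error = function(e) fail("rc_fit", e))
  record_stage("rc_fit", derive_seed(seed, 3L), rc_path)

  # --- committor validation ----------------------------------------------
  cm_cfg <- config$committor
  committor_path <- art("committor.csv")
  hist_path <- art("committor_histogram.csv")
  committor <- tryCatch({
    cands <- select_ts_candidates(filtered, rc, cm_cfg$n_points)
    res <- committor_analysis(system, cands, basins, cm_cfg$n_trials, cfg,
                              seed = derive_seed(seed, 4L), rc = rc,
                              rc_cvs = cvs[rc$cv_ids],
                              flux_stride = if (is.null(cm_cfg$flux_stride)) 5L
                                            else cm_cfg$flux_stride)
    res$candidate_r <- attr(cands, "r")
    write.csv(res$points, committor_path, row.names = FALSE)
    write.csv(data.frame(bin_lo = res$histogram$edges[-length(res$histogram$edges)],
                         bin_hi = res$histogram$edges[-1L],
                         count = res$histogram$counts),
              hist_path, row.names = FALSE)
    res
  }, error = function(e) fail("committor", e))
  htest <- histogram_test(committor)
  record_stage("committor", derive_seed(seed, 4L), c(committor_path, hist_path))

  # --- umbrella sampling + MBAR ------------------------------------------
  um <- config$umbrella
  pmf_path <- art("pmf.csv")
  pmf_res <- tryCatch({
    # "auto" range: extend somewhat past the RC values observed at the
    # committed endpoints of reactive shooting trajectories
    rc_range <- if (is.null(um$range) || identical(um$range, "auto")) {
      reac <- which(filtered$fates$reactive)
      if (length(reac) && ncol(filtered$end_fwd)) {
        ends <- rbind(filtered$end_fwd[reac, , drop = FALSE],
                      filtered$end_bwd[reac, , drop = FALSE])
        r_end <- evaluate_rc(rc, cv_matrix_from_positions(cvs, ends, system$dim))
      } else {
        r_end <- evaluate_rc(rc, filtered$cv_values)
      }
      ex <- range(r_end)
      ex + c(-0.05, 0.05) * diff(ex)
    } else unlist(um$range)
    reactant_side <- if (is.null(um$reactant_side) ||
                         identical(um$reactant_side, "auto")) {
      c(rc_range[1], rc_range[1] + 0.25 * diff(rc_range))
    } else unlist(um$reactant_side)
    wins <- build_windows(rc_range, um$width, um$k_restraint,
                          n_replicas = if (is.null(um$n_replicas)) 5L else um$n_replicas,
                          n_steps = if (is.null(um$n_steps)) 20000L else um$n_steps,
                          ramp_steps = if (is.null(um$ramp_steps)) 0L else um$ramp_steps)
    ud <- run_umbrella(system, rc, wins, cfg, seed = derive_seed(seed, 5L),
                       save_stride = if (is.null(um$save_stride)) 5L else um$save_stride,
                       cv_set = cvs)
    pmf <- mbar_pmf(ud, n_bins = if (is.null(um$n_bins)) 100L else um$n_bins)
    write_pmf_csv(pmf, pmf_path)
    list(pmf = pmf, barrier = barrier_height(pmf, reactant_side))
  }, error = function(e) fail("umbrella", e))
  record_stage("umbrella", derive_seed(seed, 5L), pmf_path)

  # --- kinetics -----------------------------------------------------------
  kin <- config$kinetics
  results_path <- art("results.json")
  kinres <- tryCatch({
    # launch tolerance: the selected candidates define the dividing-surface
    # shell, so by default accept exactly their |r| spread
    r_tol <- if (is.null(kin$r_tol)) max(abs(committor$candidate_r)) + 1e-9
             else kin$r_tol
    ks <- reactive_flux(committor$flux, r_tol = r_tol)
    kappa <- if (is.null(ks$plateau)) ks$recount else ks$plateau
    dG <- pmf_res$barrier$dG
    dG_err <- pmf_res$barrier$err
    rate <- NULL
    if (!is.null(kin$T)) {
      kB_kcal <- 0.0019872041
      scale <- if (system$unit_system == "reduced") kB_kcal * kin$T else 1
      rate <- eyring_rate(dG * scale, dG_err * scale, kappa, kin$T)
    }
    list(kappa = ks, kappa_used = kappa, rate = rate)
  }, error = function(e) fail("kinetics", e))
  results <- list(
    reactive_fraction = ensemble$acceptance_ratio,
    n_records = nrow(ensemble$fates),
    n_records_filtered = nrow(filtered$fates),
    rc = list(c0 = rc$c0, coeffs = as.list(rc$coeffs),
              v_coeff = rc$v_coeff, logL = rc$log_likelihood),
    committor = htest[c("mean", "sd", "frac_central", "pass")],
    barrier = list(dG = pmf_res$barrier$dG, err = pmf_res$barrier$err,
                   units = if (system$unit_system == "reduced") "kBT" else "kcal/mol"),
    kappa = list(plateau = kinres$kappa_used, kappa0 = kinres$kappa$kappa0),
    rate = if (!is.null(kinres$rate)) {
      list(k = kinres$rate$k, k_err = kinres$rate$k_err, T = kinres$rate$T)
    }
  )
  writeLines(jsonlite::toJSON(results, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), results_path)
  record_stage("kinetics", NA, results_path)

  manifest$results <- results
  write_manifest(manifest, art("manifest.json"))
  structure(manifest, class = "run_manifest")
}

write_manifest <- function(manifest, path) {
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-14s %s\n", nm, x$stages[[nm]]$status))
  }
  invisible(x)
}

#' Import an external collective-variable time series
#'
#' Accepts CSV with a `time` column (constant stride) plus one column per
#' CV, as produced by real MD engines.  Non-uniform time strides and
#' missing values are errors.
#'
#' @param path CSV file
#' @return a `cv_series`: `time`, `values` matrix, `dt`
#' @export
import_external_cv_series <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop_config("CSV needs a 'time' column")
  if (ncol(df) < 2L) stop_config("CSV needs at least one CV column")
  if (anyNA(df)) {
    bad <- which(rowSums(is.na(df)) > 0)[1L]
    stop_config("missing value in row %d", bad)
  }
  dt <- diff(df$time)
  if (length(dt)) {
    rel <- abs(dt - dt[1L]) > 1e-9 * max(abs(dt[1L]), 1e-300)
    if (dt[1L] <= 0 || any(rel)) {
      bad <- if (dt[1L] <= 0) 2L else which(rel)[1L] + 1L
      stop_config("non-uniform time stride at row %d", bad)
    }
  }
  vals <- as.matrix(df[, setdiff(names(df), "time"), drop = FALSE])
  structure(list(time = df$time, values = vals,
                 dt = if (length(dt)) dt[1L] else NA_real_),
            class = "cv_series")
}

#' Finite-difference CV rates for an imported series
#'
#' External trajectories carry no velocities, so instantaneous CV rates
#' are approximated by central differences ((x[t+1] - x[t-1]) / 2 dt;
#' one-sided at the ends), matching the layout of the analytic rates used
#' with toy dynamics.
#'
#' @param series a `cv_series` from [import_external_cv_series()]
#' @return matrix of d(CV)/dt aligned with `series$values`
#' @export
cv_series_rates <- function(series) {
  V <- series$values
  n <- nrow(V)
  if (n < 2L) stop_config("need at least 2 rows to differentiate")
  R <- V
  R[2:(n - 1L), ] <- (V[3:n, , drop = FALSE] - V[1:(n - 2L), , drop = FALSE]) /
    (2 * series$dt)
  R[1L, ] <- (V[2L, ] - V[1L, ]) / series$dt
  R[n, ] <- (V[n, ] - V[n - 1L, ]) / series$dt
  R
}

#' Export a CV series (round-trip counterpart of
#' [import_external_cv_series()])
#' @param series a `cv_series`
#' @param path output CSV
#' @export
write_cv_series <- function(series, path) {
  df <- data.frame(time = series$time, series$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
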