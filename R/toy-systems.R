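# Toy potential-energy systems and Langevin dynamics.  These stand in for a
# QM/MM engine: analytic landscapes with two metastable basins separated by
# a tunable barrier (order 5-20 kBT), Maxwell-Boltzmann velocities at a
# stated temperature, and friction controlling the transmission coefficient.

# Registry of analytic potentials.  `pid` indexes the C++ dispatcher;
# `required`/`defaults` drive config validation; `par_vec` flattens the
# parameter list in the layout the C++ code expects; `ncoord` gives the
# total coordinate count.
.potential_registry <- list(
  harmonic = list(
    pid = 0L, required = "k", defaults = list(),
    ncoord = function(p, dim, n_particles) n_particles * dim,
    par_vec = function(p) c(p$k)
  ),
  double_well_1d = list(
    pid = 1L, required = "barrier",
    defaults = list(well_sep = 1, tilt = 0),
    ncoord = function(p, dim, n_particles) 1L,
    par_vec = function(p) c(p$barrier, p$well_sep, p$tilt)
  ),
  tilted_double_well_2d = list(
    pid = 2L, required = "barrier",
    defaults = list(well_sep = 1, tilt = 0, k_y = 1, coupling = 0),
    ncoord = function(p, dim, n_particles) 2L,
    par_vec = function(p) c(p$barrier, p$well_sep, p$tilt, p$k_y, p$coupling)
  ),
  linear_combo_nd = list(
    pid = 3L, required = c("barrier", "weights"),
    defaults = list(well_sep = 1, k_perp = 1),
    ncoord = function(p, dim, n_particles) length(p$weights),
    par_vec = function(p) {
      w <- p$weights / sqrt(sum(p$weights^2))
      c(p$barrier, p$well_sep, p$k_perp, w)
    }
  )
)

#' Physical constants and temperature for a unit system
#'
#' In `"reduced"` units the Boltzmann constant is 1 and energies are in kBT;
#' in `"biomolecular"` units energies are kcal/mol and kB = 0.0019872041
#' kcal/(mol K), so free-energy barriers feed [eyring_rate()] directly.
#' Planck's constant is kept in SI because the Eyring prefactor kB*T/h is
#' evaluated in SI to give rates in 1/s.
#'
#' @param T absolute temperature (K in biomolecular units; arbitrary in
#'   reduced units)
#' @param unit_system `"reduced"` or `"biomolecular"`
#' @return list with `kB`, `h` (SI), `T`, and `kT = kB * T`
#' @export
thermo_constants <- function(T = 310, unit_system = c("reduced", "biomolecular")) {
  unit_system <- match.arg(unit_system)
  if (!is.finite(T) || T <= 0) stop_config("temperature must be positive, got %s", T)
  kB <- if (unit_system == "biomolecular") 0.0019872041 else 1
  list(kB = kB, h = 6.62607015e-34, T = T, kT = kB * T,
       unit_system = unit_system)
}

#' Construct a toy potential-energy system
#'
#' Registered potentials:
#' \describe{
#'   \item{`harmonic`}{`V = k/2 * |x|^2`; parameter `k`.}
#'   \item{`double_well_1d`}{`V = barrier * ((x/well_sep)^2 - 1)^2 + tilt * x`;
#'     minima near `x = +/- well_sep`, saddle at `x = 0` with height
#'     `barrier` (for `tilt = 0`).}
#'   \item{`tilted_double_well_2d`}{the 1D double well in `x` plus
#'     `k_y/2 * y^2 + coupling * x * y`; with `coupling = 0` the separatrix
#'     is exactly the `x = 0` line.}
#'   \item{`linear_combo_nd`}{a double well along the unit direction
#'     `weights` with harmonic confinement `k_perp` in the orthogonal
#'     complement; the "true" reaction coordinate is the projection on
#'     `weights` among many irrelevant coordinates.}
#' }
#'
#' @param potential_id name of a registered potential
#' @param params named list of potential parameters (see above)
#' @param masses per-particle masses (recycled)
#' @param dim spatial dimension per particle (for `harmonic`)
#' @param n_particles number of particles (for `harmonic`)
#' @param unit_system `"reduced"` (kB = 1) or `"biomolecular"`
#' @return a `toy_system` with callables `$energy(x)` and `$gradient(x)`
#'   acting on flat coordinate vectors
#' @export
make_system <- function(potential_id, params = list(), masses = 1,
                        dim = 1L, n_particles = 1L,
                        unit_system = c("reduced", "biomolecular")) {
  unit_system <- match.arg(unit_system)
  reg <- .potential_registry[[potential_id]]
  if (is.null(reg)) {
    stop_config("unknown potential_id '%s' (registered: %s)", potential_id,
                paste(names(.potential_registry), collapse = ", "))
  }
  missing <- setdiff(reg$required, names(params))
  if (length(missing)) {
    stop_config("potential '%s' is missing parameter(s): %s", potential_id,
                paste(missing, collapse = ", "))
  }
  params <- modifyList(reg$defaults, params)
  extra <- setdiff(names(params), c(reg$required, names(reg$defaults)))
  if (length(extra)) {
    stop_config("unknown parameter(s) for '%s': %s", potential_id,
                paste(extra, collapse = ", "))
  }
  ncoord <- as.integer(reg$ncoord(params, dim, n_particles))
  if (potential_id != "harmonic") {
    dim <- if (potential_id == "linear_combo_nd") 1L else ncoord
    n_particles <- ncoord %/% dim
  }
  masses <- rep_len(masses, n_particles)
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop_config("masses must be positive and finite")
  }
  par_vec <- reg$par_vec(params)
  pid <- reg$pid
  sys <- list(
    potential_id = potential_id, pid = pid, params = params,
    par_vec = par_vec, masses = masses,
    mass_vec = rep(masses, each = dim),
    n_particles = as.integer(n_particles), dim = as.integer(dim),
    ncoord = ncoord, unit_system = unit_system,
    kB = thermo_constants(1, unit_system)$kB,
    energy = function(x) pot_energy_cpp(pid, par_vec, as.numeric(x)),
    gradient = function(x) pot_grad_cpp(pid, par_vec, as.numeric(x))
  )
  class(sys) <- "toy_system"
  sys
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("<toy_system '%s': %d particle(s) x %dD, units = %s>\n",
              x$potential_id, x$n_particles, x$dim, x$unit_system))
  cat("  params:", paste(names(x$params),
                         vapply(x$params, function(p) paste(signif(p, 4), collapse = ","), ""),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Create a simulation frame
#'
#' @param positions numeric vector (flat, particle-major) or matrix
#'   (`n_particles` x `dim`)
#' @param velocities same shape as `positions`, or `NULL` for a
#'   positions-only frame
#' @param time elapsed simulation time
#' @return a `frame` object
#' @export
frame <- function(positions, velocities = NULL, time = 0) {
  x <- as.numeric(positions)
  if (!is.null(velocities)) {
    v <- as.numeric(velocities)
    if (length(v) != length(x)) {
      stop_config("positions and velocities must have identical shape (%d vs %d)",
                  length(x), length(v))
    }
  } else {
    v <- NULL
  }
  structure(list(x = x, v = v, time = time), class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("<frame t=%g: x=(%s)%s>\n", x$time,
              paste(signif(x$x, 4), collapse = ", "),
              if (is.null(x$v)) " [positions only]" else ""))
  invisible(x)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Each Cartesian component is drawn independently with zero mean and
#' variance `kB * T / m_i`.
#'
#' @param system a [make_system()] object
#' @param T temperature
#' @param seed optional integer seed
#' @return flat velocity vector of length `system$ncoord`
#' @export
draw_velocities <- function(system, T, seed = NULL) {
  if (!is.finite(T) || T <= 0) stop_config("temperature must be positive, got %s", T)
  sd <- sqrt(system$kB * T / system$mass_vec)
  with_seed(seed, rnorm(system$ncoord, 0, sd))
}

# Internal: bias list -> matrix in the C++ row layout.
# Each bias: list(type = "linear", k, center, b0, w),
#            list(type = "distance", k, center, i, j), or
#            list(type = "wall", k, lo, hi, b0, w)  (half-harmonic walls)
bias_matrix <- function(biases, system) {
  d <- system$ncoord
  width <- max(5L + d, 6L)
  if (is.null(biases) || length(biases) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = width))
  }
  if (!is.null(biases$type)) biases <- list(biases)
  B <- matrix(0, nrow = length(biases), ncol = width)
  for (i in seq_along(biases)) {
    b <- biases[[i]]
    if (b$type == "linear") {
      w <- rep_len(0, d)
      w[seq_along(b$w)] <- b$w
      B[i, seq_len(4L + d)] <- c(1, b$k, b$center, if (is.null(b$b0)) 0 else b$b0, w)
    } else if (b$type == "distance") {
      B[i, 1:6] <- c(2, b$k, b$center, b$i - 1L, b$j - 1L, system$dim)
    } else if (b$type == "wall") {
      w <- rep_len(0, d)
      w[seq_along(b$w)] <- b$w
      B[i, seq_len(5L + d)] <- c(3, b$k, b$lo, b$hi,
                                 if (is.null(b$b0)) 0 else b$b0, w)
    } else {
      stop_config("unknown bias type '%s'", b$type)
    }
  }
  B
}

#' Propagate Langevin dynamics
#'
#' BAOAB splitting of the Langevin equation; with `friction = 0` the scheme
#' reduces to velocity Verlet and conserves energy to symplectic accuracy.
#' With `friction > 0` long runs sample the canonical distribution at
#' temperature `T`.  Runs are bit-identical for a given `(start, seed)`.
#'
#' @param system a [make_system()] object
#' @param start a [frame()] with velocities (or velocities drawn separately)
#' @param n_steps number of timesteps (>= 1)
#' @param dt timestep (> 0)
#' @param friction Langevin friction (collision frequency) `gamma >= 0`
#' @param T temperature (required when `friction > 0`)
#' @param seed optional integer seed for the thermostat noise
#' @param save_stride save every `save_stride`-th frame (the initial frame is
#'   always saved)
#' @param biases optional list of harmonic restraints (internal layout; see
#'   [run_umbrella()] and [find_ts()] for the public surfaces)
#' @return a `trajectory` with `positions`/`velocities` matrices (frames in
#'   rows), `times`, and bookkeeping
#' @export
propagate <- function(system, start, n_steps, dt, friction = 0, T = NULL,
                      seed = NULL, save_stride = 1L, biases = NULL) {
  if (!is.finite(dt) || dt <= 0) stop_config("dt must be positive")
  if (friction < 0) stop_config("friction must be >= 0")
  if (n_steps < 1) stop_config("n_steps must be >= 1")
  if (friction > 0 && is.null(T)) stop_config("T is required when friction > 0")
  kT <- if (is.null(T)) 0 else system$kB * T
  v0 <- if (is.null(start$v)) rep(0, system$ncoord) else start$v
  res <- with_seed(seed, propagate_cpp(
    system$pid, system$par_vec, system$mass_vec,
    start$x, v0, as.integer(n_steps), dt, friction, kT,
    as.integer(save_stride), bias_matrix(biases, system)
  ))
  if (res$fail_step >= 0) {
    stop_config("non-finite coordinates at step %d; trajectory aborted",
                res$fail_step)
  }
  structure(list(
    positions = res$positions, velocities = res$velocities,
    times = res$times + start$time, bias_q = res$bias_q,
    dt = dt, save_stride = as.integer(save_stride), seed = seed,
    friction = friction, temperature = T
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames x %d coords, dt=%g, stride=%d>\n",
              nrow(x$positions), ncol(x$positions), x$dt, x$save_stride))
  invisible(x)
}

#' Extract one frame from a trajectory
#'
#' @param traj a [propagate()] trajectory
#' @param i frame index (1-based row)
#' @param positions_only drop velocities (shooting-point convention)
#' @return a [frame()]
#' @export
traj_frame <- function(traj, i, positions_only = FALSE) {
  frame(traj$positions[i, ],
        if (positions_only) NULL else traj$velocities[i, ],
        traj$times[i])
}

#' Write a trajectory as CSV (columns t, x1..., v1...)
#'
#' @param traj a trajectory
#' @param path output file
#' @export
write_trajectory_csv <- function(traj, path) {
  d <- ncol(traj$positions)
  df <- data.frame(t = traj$times, traj$positions, traj$velocities)
  names(df) <- c("t", paste0("x", seq_len(d)), paste0("v", seq_len(d)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write trajectory positions in XYZ format (for visualization)
#'
#' Coordinates beyond the third dimension are dropped; missing dimensions
#' are zero-padded.
#'
#' @param traj a trajectory
#' @param system the generating system (for particle count)
#' @param path output file
#' @param element element symbol to tag particles with
#' @export
write_xyz <- function(traj, system, path, element = "C") {
  con <- file(path, "w")
  on.exit(close(con))
  n <- system$n_particles
  for (i in seq_len(nrow(traj$positions))) {
    xyz <- matrix(0, n, 3)
    m <- matrix(traj$positions[i, ], nrow = n, byrow = TRUE)
    xyz[, seq_len(min(3L, ncol(m)))] <- m[, seq_len(min(3L, ncol(m)))]
    writeLines(c(as.character(n), sprintf("t = %g", traj$times[i]),
                 sprintf("%s %.8f %.8f %.8f", element, xyz[, 1], xyz[, 2], xyz[, 3])),
               con)
  }
  invisible(path)
}
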