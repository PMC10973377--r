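# Reactive-flux transmission coefficients and Eyring rate constants.
#
# kappa(t) = < qdot0 * theta(q(t)) > / ( (1/2) < |qdot0| > )
# over one-directional trajectories launched at the dividing surface
# (RC ~ 0) with Maxwell-Boltzmann velocities; kappa(0+) = 1 by symmetry and
# the plateau value multiplies the transition-state-theory rate.

#' Reactive-flux correlation function and its plateau
#'
#' Takes the committor trajectory store produced by [committor_analysis()]
#' with an RC attached (or an equivalent list).  The Heaviside factor uses
#' theta(q) = 1 for q > 0 and 0 otherwise, evaluated from each trajectory's
#' first post-launch frame; once a trajectory ends (it was run to basin
#' commitment) its theta is frozen at the final value, so kappa(t) is
#' exactly constant after the last commitment and the plateau equals the
#' direct recrossing recount over the trajectory set.
#'
#' Plateau detection: kappa is smoothed over a 5-point window, and the
#' plateau is the mean of kappa over the longest terminal interval where
#' `|d kappa/dt| < plateau_frac * kappa(0+)` per unit time, intersected
#' with the post-commitment region when every trajectory has committed.
#'
#' @param flux list with `q_series` (list of RC series, launch point
#'   first), `qdot0` (initial RC rates), `dt`, `stride`
#' @param r_tol launch-point tolerance: trajectories must start with
#'   `|q| <= r_tol` (error otherwise)
#' @param plateau_frac slope threshold as a fraction of kappa(0+)
#' @param smooth smoothing window (points)
#' @return a `kappa_series`: data.frame `series` (`t`, `kappa`), `plateau`,
#'   `plateau_window`, `kappa0`
#' @export
reactive_flux <- function(flux, r_tol = 0.1, plateau_frac = 0.01,
                          smooth = 5L) {
  q0 <- vapply(flux$q_series, `[[`, numeric(1), 1L)
  if (any(abs(q0) > r_tol)) {
    stop_config("%d trajectories launch with |RC| > %g (max %.4g)",
                sum(abs(q0) > r_tol), r_tol, max(abs(q0)))
  }
  qdot0 <- flux$qdot0
  if (length(qdot0) != length(flux$q_series)) {
    stop_config("qdot0 length must match the number of trajectories")
  }
  len <- vapply(flux$q_series, length, integer(1))
  n_t <- max(len) - 1L # post-launch frames
  # theta matrix (trajectories x time), frozen at the committed value
  num <- numeric(n_t)
  theta_last <- numeric(length(qdot0))
  for (i in seq_along(flux$q_series)) {
    q <- flux$q_series[[i]][-1L]
    th <- as.numeric(q > 0)
    if (length(th) < n_t) th <- c(th, rep(th[length(th)], n_t - length(th)))
    num <- num + qdot0[i] * th
    theta_last[i] <- th[n_t]
  }
  denom <- 0.5 * sum(abs(qdot0))
  if (denom <= 0) stop_config("all initial RC rates are zero")
  kappa <- num / denom
  tgrid <- seq_len(n_t) * flux$dt * flux$stride
  kappa0 <- kappa[1L]
  # smoothed slope
  ks <- stats::filter(kappa, rep(1 / smooth, smooth), sides = 2L)
  ks[is.na(ks)] <- kappa[is.na(ks)]
  slope <- c(0, diff(ks)) / (flux$dt * flux$stride)
  flat <- abs(slope) < plateau_frac * max(abs(kappa0), 1e-12)
  plateau <- NULL
  window <- NULL
  if (flat[n_t]) {
    # longest terminal run of flat points ...
    i0 <- n_t
    while (i0 > 1L && flat[i0 - 1L]) i0 <- i0 - 1L
    if (n_t - i0 + 1L >= 3L) {
      # ... intersected with the post-commitment region: trajectories are
      # stored to commitment and theta is frozen afterwards, so kappa is
      # exactly constant once the last trajectory has committed
      i_commit <- max(len) - 1L
      i_lo <- max(i0, min(i_commit, n_t))
      window <- c(tgrid[i_lo], tgrid[n_t])
      plateau <- mean(kappa[i_lo:n_t])
    }
  }
  structure(list(series = data.frame(t = tgrid, kappa = kappa),
                 smoothed = as.numeric(ks), plateau = plateau,
                 plateau_window = window, kappa0 = kappa0,
                 n_traj = length(qdot0),
                 recount = sum(qdot0 * theta_last) / denom),
            class = "kappa_series")
}

#' @export
print.kappa_series <- function(x, ...) {
  cat(sprintf("<kappa_series: %d trajectories, kappa(0+) = %.3f, plateau = %s>\n",
              x$n_traj, x$kappa0,
              if (is.null(x$plateau)) "none" else sprintf("%.3f", x$plateau)))
  invisible(x)
}

#' Eyring rate constant with a transmission coefficient
#'
#' `k = kappa * (kB T / h) * exp(-dG / (kB T))` with the prefactor
#' evaluated in SI (giving 1/s) and the exponent in kcal/mol using
#' kB = 0.0019872041 kcal/(mol K).  The propagated uncertainty is the
#' downward excursion at a one-sigma-higher barrier:
#' `k_err = k - k(dG + dG_err)`.
#'
#' @param dG free-energy barrier (kcal/mol)
#' @param dG_err one-sigma barrier uncertainty (kcal/mol)
#' @param kappa transmission coefficient in `[0, 1]`
#' @param T absolute temperature (K)
#' @return a `rate_estimate` with `k` and `k_err` in 1/s
#' @export
eyring_rate <- function(dG, dG_err = 0, kappa = 1, T = 310) {
  if (!is.finite(dG)) stop_config("dG must be finite")
  if (!is.finite(T) || T <= 0) stop_config("T must be positive")
  if (!is.finite(kappa) || kappa < 0 || kappa > 1) {
    stop_config("kappa must lie in [0, 1], got %s", kappa)
  }
  kB_SI <- 1.380649e-23
  h <- 6.62607015e-34
  kB_kcal <- 0.0019872041
  prefactor <- kB_SI * T / h
  k <- kappa * prefactor * exp(-dG / (kB_kcal * T))
  k_hi <- kappa * prefactor * exp(-(dG + dG_err) / (kB_kcal * T))
  structure(list(dG = dG, dG_err = dG_err, kappa = kappa, T = T,
                 k = k, k_err = k - k_hi),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate: k = %.4g +/- %.4g 1/s (dG = %.4g kcal/mol, kappa = %.3g, T = %g K)>\n",
              x$k, x$k_err, x$dG, x$kappa, x$T))
  invisible(x)
}

#' Fold difference between two rate estimates
#'
#' @param a,b [eyring_rate()] estimates
#' @return `a$k / b$k`
#' @export
rate_ratio <- function(a, b) {
  if (b$k <= 0) stop_config("cannot form a ratio against a zero rate")
  a$k / b$k
}
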