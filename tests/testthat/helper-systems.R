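# Shared fixtures: standard toy systems, basin pairs, CV sets, synthetic
# shooting ensembles, and the independent MBAR oracle used to cross-check
# the package solver.

dw_system <- function(barrier = 8, ...) {
  make_system("double_well_1d", list(barrier = barrier, ...))
}

xy_system <- function(barrier = 8, k_y = 2, tilt = 0.25, coupling = 0) {
  make_system("tilted_double_well_2d",
              list(barrier = barrier, k_y = k_y, tilt = tilt,
                   coupling = coupling))
}

x_basins <- function(edge = 0.8) {
  list(reactant = basin_def("reactant", list(list("x_1", "<", -edge))),
       product = basin_def("product", list(list("x_1", ">", edge))))
}

x_cv <- function() cv_def("coordinate_projection", 1L, cv_id = "x_1")

xy_cvs <- function() list(cv_def("coordinate_projection", 1L, cv_id = "x_1"),
                          cv_def("coordinate_projection", 2L, cv_id = "x_2"))

# Shooting fates simulated under the committor model itself:
# p(product) = (1 + erf(c0 + X %*% beta))/2 = Phi(sqrt(2)(c0 + X beta)).
synthetic_probit_ensemble <- function(n, c0, beta, n_cv = length(beta),
                                      seed = 1) {
  withr_seed <- function(code) { # local, avoid dependency
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    X <- matrix(rnorm(n * n_cv), n, n_cv,
                dimnames = list(NULL, paste0("cv", seq_len(n_cv))))
    p <- pnorm(sqrt(2) * (c0 + drop(X[, seq_along(beta), drop = FALSE] %*% beta)))
    y <- runif(n) < p
    as_ensemble_from_data(X, ifelse(y, "product", "reactant"))
  })
}

# Independent MBAR route: direct BFGS minimization of the convex MBAR
# objective Phi(f) = sum_n log sum_k N_k exp(f_k - u_kn) - sum_k N_k f_k,
# gauge-fixed at f_1 = 0.  Deliberately shares no code with the package's
# self-consistent/Newton solver.
mbar_oracle <- function(u_kn, N_k) {
  K <- nrow(u_kn)
  logN <- log(N_k)
  obj <- function(f2) {
    f <- c(0, f2)
    A <- logN + f - u_kn # K x N
    m <- apply(A, 2L, max)
    sum(m + log(colSums(exp(sweep(A, 2L, m))))) - sum(N_k * f)
  }
  grd <- function(f2) {
    f <- c(0, f2)
    A <- logN + f - u_kn
    m <- apply(A, 2L, max)
    D <- m + log(colSums(exp(sweep(A, 2L, m))))
    W <- exp(sweep(A, 2L, D))
    (rowSums(W) - N_k)[-1L]
  }
  fit <- optim(rep(0, K - 1L), obj, grd, method = "BFGS",
               control = list(maxit = 2000L, reltol = 1e-15))
  c(0, fit$par)
}

# Reduced bias energies for harmonic windows over pooled samples.
umbrella_u_kn <- function(q_n, centers, k, beta = 1) {
  t(vapply(seq_along(centers),
           function(j) beta * 0.5 * k[min(j, length(k))] * (q_n - centers[j])^2,
           numeric(length(q_n))))
}
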