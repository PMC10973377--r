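# Reaction-coordinate discovery by (inertial) likelihood maximization.
# The committor model is sigmoidal in an affine combination of CVs,
#   p(product | x, v) = (1 + erf(r + a_v * rdot)) / 2,   r = c0 + sum c_i CV_i,
# with rdot = sum c_i d(CV_i)/dt included only in the inertial variant.
# Since (1 + erf(z))/2 = Phi(sqrt(2) z), the fit is evaluated through the
# normal CDF with stable log-probabilities.

#' Construct a reaction-coordinate model
#'
#' The RC is dimensionless with an arbitrary scale; by convention negative
#' values denote progress toward the reactant and positive toward the
#' product.
#'
#' @param c0 intercept
#' @param coeffs per-CV coefficients, aligned with `cv_ids`
#' @param cv_ids ids of the included CVs
#' @param v_coeff optional inertial velocity-term coefficient
#' @param standardization optional list with named vectors `mean` and `sd`
#'   applied to CV values before the linear form (`NULL` = identity)
#' @param log_likelihood attained fit objective (if fitted)
#' @param separable flag set when the training data were perfectly
#'   separable and the coefficient norm was capped
#' @return an `rc_model`
#' @export
rc_model <- function(c0, coeffs, cv_ids, v_coeff = NULL,
                     standardization = NULL, log_likelihood = NA_real_,
                     separable = FALSE) {
  if (length(coeffs) != length(cv_ids)) {
    stop_config("coeffs (%d) and cv_ids (%d) must have equal length",
                length(coeffs), length(cv_ids))
  }
  structure(list(c0 = c0, coeffs = setNames(as.numeric(coeffs), cv_ids),
                 cv_ids = cv_ids, v_coeff = v_coeff,
                 standardization = standardization,
                 log_likelihood = log_likelihood, separable = separable),
            class = "rc_model")
}

#' @export
print.rc_model <- function(x, ...) {
  terms <- paste(sprintf("%+.4g*%s", x$coeffs, x$cv_ids), collapse = " ")
  cat(sprintf("<rc_model: r = %.4g %s%s>\n", x$c0, terms,
              if (!is.null(x$v_coeff)) sprintf(" (inertial, a_v = %.4g)", x$v_coeff) else ""))
  if (!is.na(x$log_likelihood)) cat(sprintf("  logL = %.4f%s\n", x$log_likelihood,
                                            if (x$separable) " [separable]" else ""))
  invisible(x)
}

#' Evaluate a reaction coordinate
#'
#' @param model an [rc_model()]
#' @param cvs named numeric vector of CV values, or a matrix with CV ids as
#'   column names (rows = configurations)
#' @return RC value(s), dimensionless
#' @export
evaluate_rc <- function(model, cvs) {
  if (is.matrix(cvs) || is.data.frame(cvs)) {
    cvs <- as.matrix(cvs)
    missing <- setdiff(model$cv_ids, colnames(cvs))
    if (length(missing)) stop_config("missing CV(s): %s", paste(missing, collapse = ", "))
    Z <- cvs[, model$cv_ids, drop = FALSE]
    if (!is.null(model$standardization)) {
      Z <- sweep(sweep(Z, 2L, model$standardization$mean[model$cv_ids]), 2L,
                 model$standardization$sd[model$cv_ids], "/")
    }
    return(drop(model$c0 + Z %*% model$coeffs))
  }
  missing <- setdiff(model$cv_ids, names(cvs))
  if (length(missing)) stop_config("missing CV(s): %s", paste(missing, collapse = ", "))
  z <- cvs[model$cv_ids]
  if (!is.null(model$standardization)) {
    z <- (z - model$standardization$mean[model$cv_ids]) /
      model$standardization$sd[model$cv_ids]
  }
  unname(model$c0 + sum(model$coeffs * z))
}

# log p and log(1-p) for u = r + a_v*rdot, via p = Phi(sqrt(2) u).
ilmax_nll <- function(theta, Z, Zd, y, inertial) {
  k <- ncol(Z)
  c0 <- theta[1L]
  cc <- theta[2L:(k + 1L)]
  av <- if (inertial) theta[k + 2L] else 0
  u <- c0 + drop(Z %*% cc) + if (inertial) av * drop(Zd %*% cc) else 0
  su <- sqrt(2) * u
  -sum(ifelse(y, pnorm(su, log.p = TRUE), pnorm(-su, log.p = TRUE)))
}

ilmax_nll_grad <- function(theta, Z, Zd, y, inertial) {
  k <- ncol(Z)
  c0 <- theta[1L]
  cc <- theta[2L:(k + 1L)]
  av <- if (inertial) theta[k + 2L] else 0
  zd_c <- if (inertial) drop(Zd %*% cc) else rep(0, nrow(Z))
  u <- c0 + drop(Z %*% cc) + av * zd_c
  su <- sqrt(2) * u
  # d log p / du = sqrt(2) * phi(su)/Phi(su); mirrored for 1-p
  lam <- exp(dnorm(su, log = TRUE) - pnorm(su, log.p = TRUE))
  lam_m <- exp(dnorm(su, log = TRUE) - pnorm(-su, log.p = TRUE))
  dldu <- sqrt(2) * ifelse(y, lam, -lam_m)
  gc0 <- sum(dldu)
  gcc <- drop(crossprod(Z + av * Zd, dldu))
  g <- c(gc0, gcc)
  if (inertial) g <- c(g, sum(dldu * zd_c))
  -g
}

#' Fit a committor model by (inertial) likelihood maximization
#'
#' Maximizes `L = sum_(fwd->product) log p + sum_(fwd->reactant) log(1-p)`
#' over the forward fates of the shooting records, with
#' `p = (1 + erf(r + a_v * rdot))/2`.  Records whose forward trajectory
#' timed out are excluded.  CVs are standardized internally for optimizer
#' conditioning; coefficients are reported in raw CV units.  Constant CVs
#' are excluded with a warning.  Perfectly separable data are handled by
#' capping the standardized coefficient norm (`control$norm_cap`, default
#' 20) and flagging the model `separable`.
#'
#' @param ensemble an `as_ensemble`
#' @param cv_subset CV ids to include (default: all)
#' @param inertial include the velocity term `a_v * rdot`
#' @param control list: `n_starts` (multi-start count, default 5), `seed`
#'   (start seed, default 1), `norm_cap` (default 20), `reltol`
#'   (default 1e-12)
#' @return an [rc_model()] with `log_likelihood`; the standard errors of
#'   `(c0, coeffs)` from the observed information matrix are in
#'   `attr(, "se")`, and the sign convention (mean r higher over
#'   product-committed than reactant-committed points) is enforced post-fit
#' @export
ilmax_fit <- function(ensemble, cv_subset = NULL, inertial = TRUE,
                      control = list()) {
  ctrl <- modifyList(list(n_starts = 5L, seed = 1L, norm_cap = 20,
                          reltol = 1e-12, maxit = 1000L), control)
  if (is.null(cv_subset)) cv_subset <- ensemble$cv_ids
  ok <- ensemble$fates$fwd_fate %in% c("reactant", "product")
  if (!any(ensemble$fates$fwd_fate[ok] == "product") ||
      !any(ensemble$fates$fwd_fate[ok] == "reactant")) {
    stop_config("need at least one product-committed and one reactant-committed forward fate")
  }
  X <- ensemble$cv_values[ok, cv_subset, drop = FALSE]
  Xd <- ensemble$cv_rates[ok, cv_subset, drop = FALSE]
  y <- ensemble$fates$fwd_fate[ok] == "product"
  sds <- apply(X, 2L, sd)
  degenerate <- sds < 1e-12
  if (any(degenerate)) {
    warning(sprintf("excluding constant CV(s): %s",
                    paste(cv_subset[degenerate], collapse = ", ")), call. = FALSE)
    cv_subset <- cv_subset[!degenerate]
    X <- X[, !degenerate, drop = FALSE]
    Xd <- Xd[, !degenerate, drop = FALSE]
    sds <- sds[!degenerate]
  }
  if (length(cv_subset) == 0L) stop_config("no non-degenerate CVs to fit")
  if (inertial && all(abs(Xd) < 1e-300)) inertial <- FALSE
  mus <- colMeans(X)
  Z <- sweep(sweep(X, 2L, mus), 2L, sds, "/")
  Zd <- sweep(Xd, 2L, sds, "/")
  k <- ncol(Z)
  n_par <- 1L + k + as.integer(inertial)
  start0 <- c(qnorm(max(min(mean(y), 1 - 1e-6), 1e-6)) / sqrt(2),
              rep(0, k), if (inertial) 0)
  fits <- lapply(seq_len(ctrl$n_starts), function(s) {
    st <- if (s == 1L) start0 else with_seed(derive_seed(ctrl$seed, s),
                                             start0 + rnorm(n_par, 0, 0.5))
    optim(st, ilmax_nll, ilmax_nll_grad, Z = Z, Zd = Zd, y = y,
          inertial = inertial, method = "BFGS",
          control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  theta <- best$par
  separable <- FALSE
  lin_norm <- sqrt(sum(theta[1:(k + 1L)]^2))
  if (lin_norm > ctrl$norm_cap) {
    theta[1:(k + 1L)] <- theta[1:(k + 1L)] * ctrl$norm_cap / lin_norm
    separable <- TRUE
  }
  logL <- -ilmax_nll(theta, Z, Zd, y, inertial)
  # sign convention: product-committed points score higher on r than
  # reactant-committed ones
  r_std <- theta[1L] + drop(Z %*% theta[2L:(k + 1L)])
  if (mean(r_std[y]) < mean(r_std[!y])) {
    theta <- -theta
    logL <- -ilmax_nll(theta, Z, Zd, y, inertial)
  }
  # back to raw CV units: c_raw = c_std / sd; c0_raw = c0 - sum c_std*mu/sd
  c_std <- theta[2L:(k + 1L)]
  c_raw <- c_std / sds
  c0_raw <- theta[1L] - sum(c_std * mus / sds)
  av <- if (inertial) theta[k + 2L] else NULL
  # standard errors from the observed information (standardized scale,
  # mapped back through the same linear transform)
  se <- rep(NA_real_, k + 1L)
  hess <- tryCatch(
    optim(theta, ilmax_nll, ilmax_nll_grad, Z = Z, Zd = Zd, y = y,
          inertial = inertial, method = "BFGS", hessian = TRUE,
          control = list(maxit = 1L))$hessian,
    error = function(e) NULL)
  if (!is.null(hess)) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc)) {
      # raw (c0, c) = A %*% std (c0, c): c0_raw row has -mu/sd entries
      A <- diag(1L + k)
      A[1L, 2L:(k + 1L)] <- -mus / sds
      for (j in seq_len(k)) A[j + 1L, j + 1L] <- 1 / sds[j]
      vr <- A %*% vc[1:(k + 1L), 1:(k + 1L), drop = FALSE] %*% t(A)
      se <- sqrt(pmax(diag(vr), 0))
    }
  }
  model <- rc_model(c0_raw, c_raw, cv_subset, v_coeff = av,
                    standardization = NULL, log_likelihood = logL,
                    separable = separable)
  attr(model, "se") <- setNames(se, c("c0", cv_subset))
  attr(model, "n_obs") <- length(y)
  attr(model, "converged") <- best$convergence == 0L
  model
}

#' Automatic model-size selection for the RC (two-line test)
#'
#' For each `k = 1..k_max`, finds the best `k`-CV model by greedy forward
#' selection and records its maximized log-likelihood `L_k`.  A broken-line
#' model (two least-squares segments joined at a breakpoint) is fitted to
#' `(k, L_k)`; the breakpoint minimizing the combined residual sum of
#' squares is the candidate `k*`, accepted only when the likelihood curve
#' actually breaks from steep to flat there: the first-segment slope must
#' exceed the second-segment slope by at least `control$slope_ratio_min`
#' (default 10).  A featureless (straight or gently saturating) curve --
#' the signature of pure noise CVs, whose greedy overfitting gains are
#' small at every `k` -- falls back to the single best CV (`k* = 1`).
#' Ties prefer the smallest `k`.
#'
#' @param ensemble an `as_ensemble`
#' @param candidate_cvs pool of CV ids (default: all)
#' @param k_max largest model size scanned (>= 2, pool must allow it)
#' @param inertial passed to [ilmax_fit()]
#' @param control optimizer control, plus `slope_ratio_min`
#' @return the selected [rc_model()]; the scan is in
#'   `attr(, "selection")` (`k`, `logL`, chosen ids, `k_star`)
#' @export
two_line_select <- function(ensemble, candidate_cvs = NULL, k_max = 6L,
                            inertial = TRUE, control = list()) {
  ctrl <- modifyList(list(slope_ratio_min = 10, n_starts = 2L), control)
  if (is.null(candidate_cvs)) candidate_cvs <- ensemble$cv_ids
  if (k_max < 1L) stop_config("k_max must be >= 1")
  k_max <- min(k_max, length(candidate_cvs))
  selected <- character(0)
  models <- vector("list", k_max)
  logL <- numeric(k_max)
  for (k in seq_len(k_max)) {
    remaining <- setdiff(candidate_cvs, selected)
    cand_fits <- lapply(remaining, function(cv) {
      suppressWarnings(ilmax_fit(ensemble, c(selected, cv), inertial = inertial,
                                 control = ctrl))
    })
    Ls <- vapply(cand_fits, `[[`, numeric(1), "log_likelihood")
    best <- which.max(Ls)
    selected <- c(selected, remaining[best])
    models[[k]] <- cand_fits[[best]]
    logL[k] <- Ls[best]
  }
  pick_k <- function() {
    if (k_max == 1L) return(1L)
    if (k_max < 3L) {
      warning("fewer than 3 model sizes scanned; returning the largest model",
              call. = FALSE)
      return(k_max)
    }
    ks <- seq_len(k_max)
    seg <- function(idx) {
      f <- lm(logL[idx] ~ ks[idx])
      c(rss = sum(f$residuals^2), slope = unname(coef(f)[2L]))
    }
    cand_m <- 2L:(k_max - 1L)
    fits <- lapply(cand_m, function(m) list(a = seg(1L:m), b = seg(m:k_max)))
    rss2 <- vapply(fits, function(f) f$a[["rss"]] + f$b[["rss"]], numeric(1))
    i_best <- which(rss2 <= min(rss2) + 1e-9 * max(max(rss2), 1))[1L]
    s1 <- fits[[i_best]]$a[["slope"]]
    s2 <- fits[[i_best]]$b[["slope"]]
    ratio <- if (s2 <= 1e-12) Inf else s1 / s2
    if (ratio < ctrl$slope_ratio_min) return(1L)
    cand_m[i_best]
  }
  k_star <- pick_k()
  out <- models[[k_star]]
  attr(out, "selection") <- list(k = seq_len(k_max), logL = logL,
                                 cv_order = selected, k_star = k_star)
  out
}

#' Write an RC model to JSON (exact round-trip)
#' @param model an [rc_model()]
#' @param path output file (or `NULL` to return the JSON string)
#' @export
write_rc_model <- function(model, path = NULL) {
  obj <- list(c0 = model$c0, coeffs = unname(model$coeffs),
              cv_ids = model$cv_ids, v_coeff = model$v_coeff,
              standardization = model$standardization,
              log_likelihood = model$log_likelihood,
              separable = model$separable)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read an RC model written by [write_rc_model()]
#' @param path JSON file
#' @return an [rc_model()]
#' @export
read_rc_model <- function(path) {
  o <- jsonlite::fromJSON(path)
  std <- if (!is.null(o$standardization)) {
    list(mean = unlist(o$standardization$mean), sd = unlist(o$standardization$sd))
  }
  rc_model(o$c0, o$coeffs, o$cv_ids, v_coeff = o$v_coeff,
           standardization = std, log_likelihood = o$log_likelihood,
           separable = isTRUE(o$separable))
}
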