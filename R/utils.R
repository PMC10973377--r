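# Seed discipline: every stochastic entry point takes an explicit seed and
# restores the caller's RNG state afterwards, so campaign-level seeds can
# spawn per-trajectory streams deterministically without clobbering the
# session RNG.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a parent seed and integer tags
#'
#' Deterministic splitting of one campaign-level seed into per-chain,
#' per-move, or per-trial streams.  The result is always a valid 32-bit
#' R seed.
#'
#' @param seed parent seed (integer)
#' @param ... integer tags (chain index, move index, trial index, ...)
#' @return an integer seed in `[0, 2^31 - 2]`
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483629 # largest prime < 2^31
  h <- as.numeric(seed) %% m
  for (tag in c(...)) {
    h <- (h * 48271 + as.numeric(tag) + 1) %% m
  }
  as.integer(h)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# log(sum(exp(x))) without overflow; used by the MBAR solver.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp of a matrix.
row_logsumexp <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}
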