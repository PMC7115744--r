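# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Truncated normal draws by inverse-CDF; vectorized and seed-deterministic.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  stopifnot(lower < upper, sd >= 0)
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Min-max scaling to [0, 1]; a constant vector maps to all zeros.
scale01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) {
    return(rep(0, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

assertScalarProb <- function(x, name, openLeft = TRUE, openRight = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (openLeft) x > 0 else x >= 0) &&
    (if (openRight) x < 1 else x <= 1)
  if (!ok) stop(sprintf("'%s' must be a single value in %s0,1%s",
                        name,
                        if (openLeft) "(" else "[",
                        if (openRight) ")" else "]"), call. = FALSE)
  invisible(x)
}
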