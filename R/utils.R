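## Internal numeric helpers shared across modules.

## Trapezoidal integral over a unit-spaced grid.
.trapz <- function(y) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) / 2)
}

## Round half away from zero (so +0.5 -> +1, -0.5 -> -1), unlike base
## round()'s banker's rounding.  Deterministic and sign-symmetric.
.roundAway <- function(x) sign(x) * floor(abs(x) + 0.5)

## Sliding-window extreme (min or max) with centred window of odd width w,
## shrinking at the edges.  van Herk block decomposition: O(n) in vector
## operations, exact.
.slideExtreme <- function(x, w, minimum = TRUE) {
  n <- length(x)
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  pad <- if (minimum) Inf else -Inf
  y <- c(rep(pad, h), x, rep(pad, h))
  N <- length(y)
  nb <- ceiling(N / w)
  yp <- c(y, rep(pad, nb * w - N))
  m <- matrix(yp, nrow = w)
  cf <- if (minimum) cummin else cummax
  pref <- m
  suff <- m
  for (j in seq_len(ncol(m))) {
    pref[, j] <- cf(m[, j])
    suff[, j] <- rev(cf(rev(m[, j])))
  }
  pref <- as.vector(pref)
  suff <- as.vector(suff)
  i <- seq_len(n)
  if (minimum) pmin(suff[i], pref[i + w - 1L]) else pmax(suff[i], pref[i + w - 1L])
}

## Evaluate code with a temporary RNG state seeded at `seed`, restoring the
## caller's stream afterwards.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Structured condition constructors so callers (and the CLI) can branch on
## error class.
.idaaError <- function(class, msg, ...) {
  stop(structure(class = c(class, "idaa_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
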