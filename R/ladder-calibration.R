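## Ladder-to-size-standard assignment and scan->bp calibration.  The
## assignment minimises the residual sum of squares of a straight-line fit
## of scan on fragment size over all order-preserving injective assignments;
## sizing uses the Local Southern method (reciprocal fragment-mobility law
## fitted through neighbouring ladder points) or a monotone cubic spline.

## Exact optimum by vectorised enumeration of all order-preserving subsets.
.matchExhaustive <- function(scans, sizes) {
  n <- length(scans)
  k <- length(sizes)
  combos <- utils::combn(n, k)              # columns are ascending subsets
  Y <- matrix(scans[combos], nrow = k)
  xc <- sizes - mean(sizes)
  Sxx <- sum(xc^2)
  Sy <- colSums(Y)
  Syy <- colSums(Y^2)
  Sxy <- as.numeric(crossprod(xc, Y))
  rss <- Syy - Sy^2 / k - Sxy^2 / Sxx
  best <- which.min(rss)
  list(idx = combos[, best], rss = max(rss[best], 0))
}

## Order-preserving assignment DP against a fixed line scan = a + b*size,
## iterated with line refits (for pathological candidate counts where
## enumeration is infeasible).
.matchIterative <- function(scans, sizes, maxIter = 25L) {
  n <- length(scans)
  k <- length(sizes)
  idx <- round(seq(1L, n, length.out = k))    # rank-interpolated start
  for (iter in seq_len(maxIter)) {
    fit <- stats::lm.fit(cbind(1, sizes), scans[idx])
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
    cost <- outer(sizes, scans, function(L, s) (s - (a + b * L))^2)
    f <- matrix(Inf, k, n)
    pick <- matrix(FALSE, k, n)
    f[1, ] <- cummin(cost[1, ])
    pick[1, ] <- cost[1, ] <= f[1, ]
    for (i in 2:k) {
      for (j in i:n) {
        stay <- if (j > i) f[i, j - 1] else Inf
        take <- f[i - 1, j - 1] + cost[i, j]
        f[i, j] <- min(stay, take)
        pick[i, j] <- take <= stay
      }
    }
    newIdx <- integer(k)
    j <- n
    for (i in k:1) {
      while (!pick[i, j]) j <- j - 1L
      newIdx[i] <- j
      j <- j - 1L
    }
    if (identical(newIdx, idx)) break
    idx <- newIdx
  }
  fit <- stats::lm.fit(cbind(1, sizes), scans[idx])
  list(idx = idx, rss = sum(fit$residuals^2))
}

#' Match detected ladder peaks to a size standard
#'
#' Chooses, among all order-preserving injective assignments of the
#' standard's fragment sizes to candidate peak apexes, the one minimising
#' the residual sum of squares of a linear fit of scan on size.  The
#' optimum is found exactly by enumeration whenever
#' \code{choose(n, k) <= maxCombos}; beyond that an iterated
#' assignment-DP/line-refit scheme is used.
#'
#' @param peaks Peak data.frame from [detectPeaks()] run on the ladder
#'   channel (the fractional \code{apex} column is used when present).
#' @param standard A [SizeStandard-class].
#' @param rssCeiling Maximum admissible RSS (scan^2 units) of the best
#'   linear fit; above it the ladder is declared failed.  Default
#'   \code{Inf}: migration is genuinely curved, so calibration quality is
#'   instead gated on leave-one-out residuals in [fitCalibration()].
#' @param maxCombos Enumeration budget.
#' @return data.frame with columns \code{scan}, \code{size}, sorted by
#'   size, with the optimal RSS in \code{attr(, "rss")}.
#' @seealso [fitCalibration()]
#' @export
matchLadder <- function(peaks, standard, rssCeiling = Inf, maxCombos = 2e5) {
  stopifnot(is(standard, "SizeStandard"))
  scans <- if ("apex" %in% names(peaks)) peaks$apex else peaks$apex_scan
  scans <- sort(as.numeric(scans))
  sizes <- standard@sizes
  n <- length(scans)
  k <- length(sizes)
  if (n < k)
    .idaaError("idaa_ladder_error",
               sprintf("ladder failure: %d candidate peaks for %d fragments",
                       n, k))
  res <- if (choose(n, k) <= maxCombos) .matchExhaustive(scans, sizes)
         else .matchIterative(scans, sizes)
  if (res$rss > rssCeiling)
    .idaaError("idaa_ladder_error",
               sprintf("ladder failure: assignment RSS %.1f exceeds ceiling %.1f",
                       res$rss, rssCeiling))
  out <- data.frame(scan = scans[res$idx], size = sizes)
  attr(out, "rss") <- res$rss
  out
}

## Fit the reciprocal mobility law L = c/(m - m0) + L0 exactly through
## three points and evaluate at q; quadratic fallback when the hyperbola is
## degenerate or its pole lies inside the data interval.
.southern3 <- function(m, L, q) {
  quad <- function() {
    mc <- m - mean(m)
    co <- solve(cbind(1, mc, mc^2), L)
    x <- q - mean(m)
    co[1] + co[2] * x + co[3] * x^2
  }
  a <- (L[1] - L[2]) * (m[3] - m[2])
  b <- (L[2] - L[3]) * (m[2] - m[1])
  if (abs(a - b) < 1e-12 * max(abs(a), abs(b), 1)) return(quad())
  m0 <- (a * m[1] - b * m[3]) / (a - b)
  if (m0 >= min(m) && m0 <= max(m)) return(quad())
  cc <- (L[1] - L[2]) * (m[1] - m0) * (m[2] - m0) / (m[2] - m[1])
  L0 <- L[1] - cc / (m[1] - m0)
  if (abs(q - m0) < 1e-9) return(quad())
  cc / (q - m0) + L0
}

## Local Southern evaluation against a matched-points table.
.predictLocalSouthern <- function(points, q) {
  scan <- points$scan
  size <- points$size
  np <- nrow(points)
  vapply(q, function(m) {
    lows <- which(scan <= m)
    his <- which(scan > m)
    ests <- numeric(0)
    if (length(lows) >= 2L && length(his) >= 1L) {
      t1 <- c(lows[length(lows) - 1L], lows[length(lows)], his[1L])
      ests <- c(ests, .southern3(scan[t1], size[t1], m))
    }
    if (length(lows) >= 1L && length(his) >= 2L) {
      t2 <- c(lows[length(lows)], his[1L], his[2L])
      ests <- c(ests, .southern3(scan[t2], size[t2], m))
    }
    if (length(ests) == 0L) {
      t0 <- if (m <= scan[1L]) 1:3 else (np - 2L):np
      ests <- .southern3(scan[t0], size[t0], m)
    }
    mean(ests)
  }, numeric(1))
}

.predictPoints <- function(points, q, method) {
  if (method == "local_southern") .predictLocalSouthern(points, q)
  else stats::splinefun(points$scan, points$size, method = "hyman")(q)
}

#' Fit a scan-to-size calibration from matched ladder points
#'
#' \code{local_southern}: for a query scan the two matched points below and
#' two above are taken; the reciprocal law \code{L = c/(m - m0) + L0} is
#' fitted exactly through each group of three consecutive neighbours (lower
#' two + upper one, lower one + upper two) and the two fitted values are
#' averaged, falling back to the single available triple near either end of
#' the calibrated range.  \code{spline}: monotone cubic interpolation.
#' Per-point residuals are computed by leave-one-out refitting.
#'
#' @param matched data.frame of matched \code{(scan, size)} pairs from
#'   [matchLadder()], strictly increasing in both columns, at least 4 rows.
#' @param method \code{"local_southern"} (default) or \code{"spline"}.
#' @return A [Calibration-class].
#' @examples
#' pts <- data.frame(scan = 10000 - 2e5 / c(50, 100, 200, 400),
#'                   size = c(50, 100, 200, 400))
#' cal <- fitCalibration(pts)
#' predictSize(cal, 8000)  # exactly 100
#' @export
fitCalibration <- function(matched, method = c("local_southern", "spline")) {
  method <- match.arg(method)
  if (nrow(matched) < 4L)
    .idaaError("idaa_parameter_error", "need at least 4 matched pairs")
  if (any(diff(matched$scan) <= 0) || any(diff(matched$size) <= 0))
    .idaaError("idaa_parameter_error",
               "matched pairs must be strictly increasing in scan and size")
  res <- vapply(seq_len(nrow(matched)), function(i) {
    .predictPoints(matched[-i, , drop = FALSE], matched$scan[i], method) -
      matched$size[i]
  }, numeric(1))
  new("Calibration",
      points = data.frame(scan = matched$scan, size = matched$size),
      method = method, residuals = res,
      scanRange = range(matched$scan))
}

#' @describeIn fitCalibration Evaluate a calibration at scan coordinates.
#' @param object A [Calibration-class].
#' @param scans Numeric scan coordinates.
#' @export
setMethod("predictSize", "Calibration", function(object, scans) {
  .predictPoints(object@points, as.numeric(scans), object@method)
})

#' Annotate detected peaks with fragment sizes
#'
#' Sizes each peak at its (fractional) apex scan through the calibration;
#' peaks outside the calibrated scan range are flagged
#' \code{extrapolated}.
#'
#' @param calibration A [Calibration-class].
#' @param peaks Peak data.frame from [detectPeaks()].
#' @return The peak data.frame with \code{size_bp} and \code{extrapolated}
#'   columns appended.
#' @export
sizePeaks <- function(calibration, peaks) {
  stopifnot(is(calibration, "Calibration"))
  if (nrow(peaks) == 0L) {
    peaks$size_bp <- numeric(0)
    peaks$extrapolated <- logical(0)
    return(peaks)
  }
  at <- if ("apex" %in% names(peaks)) peaks$apex else peaks$apex_scan
  peaks$size_bp <- predictSize(calibration, at)
  peaks$extrapolated <- at < calibration@scanRange[1] |
    at > calibration@scanRange[2]
  peaks
}
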