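## Signal conditioning and peak extraction for a single electropherogram
## channel: morphological baseline estimation, Savitzky-Golay smoothing,
## local-maximum peak detection with valley/threshold boundaries, and
## trapezoidal area integration.

#' Estimate the signal baseline by morphological opening
#'
#' Rolling minimum followed by rolling maximum with the same centred window
#' (a grey-scale opening).  The result never exceeds the input, is flat under
#' peaks narrower than the window, and tracks slow drift.
#'
#' @param intensities Numeric vector of per-scan intensities.
#' @param window Odd window width in scans, >= 3 and not larger than the
#'   signal.
#' @return Numeric baseline vector, same length as the input.
#' @examples
#' x <- 100 + 0.01 * seq_len(2000)
#' b <- estimateBaseline(x, 151)
#' all(b <= x)
#' @export
estimateBaseline <- function(intensities, window = 151L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    .idaaError("idaa_parameter_error", "window must be odd and >= 3")
  if (window > length(intensities))
    .idaaError("idaa_parameter_error", "window larger than the signal")
  eroded <- .slideExtreme(intensities, window, minimum = TRUE)
  .slideExtreme(eroded, window, minimum = FALSE)
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing; exact on polynomial signals of
#' degree <= \code{order}, so peak heights and apex positions are far less
#' biased than with a moving average.
#'
#' @param intensities Numeric vector.
#' @param window Odd filter length in scans; \code{1} is the identity.
#' @param order Polynomial order, \code{order < window}.
#' @return Smoothed vector of the same length.
#' @export
smoothTrace <- function(intensities, window = 9L, order = 3L) {
  window <- as.integer(window)
  order <- as.integer(order)
  if (window < 1L || window %% 2L == 0L)
    .idaaError("idaa_parameter_error", "window must be odd and positive")
  if (order >= window)
    .idaaError("idaa_parameter_error", "order must be smaller than window")
  if (window == 1L || length(intensities) < window) return(intensities)
  as.numeric(signal::sgolayfilt(intensities, p = order, n = window))
}

## Local maxima of a vector, plateau-aware: a run of equal values higher
## than both neighbouring runs is one maximum at the plateau centre.
.localMaxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k == 0L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  prev <- c(-Inf, r$values[-k])
  nxt <- c(r$values[-1L], -Inf)
  hit <- which(r$values > prev & r$values > nxt)
  as.integer(floor((starts[hit] + ends[hit]) / 2))
}

## Walk outward from an apex to find a boundary: stop at the first scan
## whose value drops below `thresh`, or at the first local minimum,
## whichever comes first (i.e. is closer to the apex).
.walkBoundary <- function(y, apex, thresh, dir) {
  n <- length(y)
  i <- apex
  repeat {
    j <- i + dir
    if (j < 1L || j > n) return(i)
    if (y[j] < thresh) return(j)
    if (y[j] > y[i]) return(i)   # i was the valley
    i <- j
  }
}

## Sub-scan apex refinement: a Gaussian is an exact parabola in log space,
## so fit a parabola through the three top samples (log scale when all are
## positive, raw values otherwise) and take its vertex.
.refineApex <- function(y, apex) {
  n <- length(y)
  if (apex <= 1L || apex >= n) return(as.numeric(apex))
  l <- y[apex - 1L]; c0 <- y[apex]; r <- y[apex + 1L]
  if (l > 0 && c0 > 0 && r > 0) {
    l <- log(l); c0 <- log(c0); r <- log(r)
  }
  den <- l - 2 * c0 + r
  if (den >= 0) return(as.numeric(apex))
  delta <- 0.5 * (l - r) / den
  as.numeric(apex) + max(-0.5, min(0.5, delta))
}

#' Detect peaks in a baseline-corrected channel
#'
#' Finds local maxima at least \code{minHeight} high and
#' \code{minSeparation} scans apart (the higher of a conflicting pair is
#' kept).  Peak boundaries lie at the nearest flanking local minimum or
#' where the signal falls below \code{max(0.01 * apex height,
#' minHeight / 2)}, whichever is closer to the apex; areas are trapezoidal
#' integrals of the non-negative signal over the boundary interval.  A
#' fractional apex position (\code{apex}) is estimated by parabolic
#' interpolation through the three top samples and is what [sizePeaks()]
#' uses for sizing.
#'
#' @param intensities Baseline-corrected (and typically smoothed) signal.
#' @param minHeight Minimum apex height in fluorescence units.
#' @param minSeparation Minimum apex separation in scans.
#' @param raw Optional raw (uncorrected) signal used only for the
#'   saturation check.
#' @param saturation Raw-intensity saturation threshold.
#' @return data.frame sorted by \code{apex_scan} with columns
#'   \code{apex_scan}, \code{apex}, \code{apex_height}, \code{left_scan},
#'   \code{right_scan}, \code{area}, \code{saturated}.
#' @examples
#' x <- 1000 * exp(-((1:400 - 200)^2) / (2 * 25))
#' detectPeaks(x, minHeight = 50)
#' @export
detectPeaks <- function(intensities, minHeight = 50, minSeparation = 10L,
                        raw = NULL, saturation = 32000) {
  if (minHeight <= 0)
    .idaaError("idaa_parameter_error", "minHeight must be positive")
  empty <- data.frame(apex_scan = integer(0), apex = numeric(0),
                      apex_height = numeric(0), left_scan = integer(0),
                      right_scan = integer(0), area = numeric(0),
                      saturated = logical(0))
  if (length(intensities) < 3L) return(empty)
  y <- intensities
  apexes <- .localMaxima(y)
  apexes <- apexes[y[apexes] >= minHeight]
  if (length(apexes) == 0L) return(empty)
  ## enforce min separation, keeping the higher peak of any conflict
  ord <- order(y[apexes], decreasing = TRUE)
  kept <- integer(0)
  for (a in apexes[ord]) {
    if (all(abs(kept - a) >= minSeparation)) kept <- c(kept, a)
  }
  kept <- sort(kept)
  yc <- pmax(y, 0)
  rows <- lapply(kept, function(a) {
    thresh <- max(0.01 * y[a], minHeight / 2)
    l <- .walkBoundary(y, a, thresh, -1L)
    r <- .walkBoundary(y, a, thresh, 1L)
    data.frame(
      apex_scan = a,
      apex = .refineApex(y, a),
      apex_height = y[a],
      left_scan = l,
      right_scan = r,
      area = .trapz(yc[l:r]),
      saturated = if (is.null(raw)) FALSE else raw[a] >= saturation
    )
  })
  out <- do.call(rbind, rows)
  out[out$area > 0, , drop = FALSE]
}

#' Trapezoidal integral of a signal region
#'
#' @param intensities Numeric signal vector.
#' @param left,right Scan bounds (1-based, inclusive), \code{left < right},
#'   both within the signal.
#' @return The trapezoidal integral over \code{[left, right]} (a constant 1
#'   over 101 points integrates to 100).
#' @export
integrateRegion <- function(intensities, left, right) {
  left <- as.integer(left)
  right <- as.integer(right)
  if (left < 1L || right > length(intensities) || left >= right)
    .idaaError("idaa_parameter_error",
               "need 1 <= left < right <= length(intensities)")
  .trapz(intensities[left:right])
}
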