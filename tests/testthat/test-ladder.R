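# Ladder matching and scan-to-size calibration.

peaksAt <- function(scans) data.frame(apex_scan = round(scans),
                                      apex = scans,
                                      apex_height = rep(1000, length(scans)),
                                      left_scan = round(scans) - 5,
                                      right_scan = round(scans) + 5,
                                      area = rep(1000, length(scans)),
                                      saturated = rep(FALSE, length(scans)))

test_that("collinear candidates match identically with zero RSS", {
  sizes <- c(50, 100, 150, 200, 250)
  scans <- 500 + 20 * sizes
  m <- matchLadder(peaksAt(scans), sizeStandard(sizes, "affine"))
  expect_equal(m$scan, scans)
  expect_equal(m$size, sizes)
  expect_lt(attr(m, "rss"), 1e-6)
})

test_that("a spurious peak is skipped, agreeing with exhaustive search", {
  sizes <- c(50, 100, 150, 200, 250)
  scans <- 500 + 20 * sizes
  withSpur <- sort(c(scans, 1700))   # spurious peak between fragments 1 and 2
  m <- matchLadder(peaksAt(withSpur), sizeStandard(sizes, "affine"))
  expect_equal(m$scan, scans)
  oracle <- bruteLadder(withSpur, sizes)
  expect_equal(m$scan, oracle$scan)
  expect_equal(attr(m, "rss"), oracle$rss, tolerance = 1e-8)
})

test_that("too few candidate peaks is a ladder failure", {
  expect_error(matchLadder(peaksAt(c(1000, 2000, 3000)),
                           sizeStandard(c(50, 100, 150, 200, 250), "s")),
               class = "idaa_ladder_error")
})

test_that("assignment equals brute force for random candidate sets (<= 9 peaks)", {
  set.seed(77)
  for (rep in 1:20) {
    k <- sample(4:6, 1)
    n <- sample(k:9, 1)
    sizes <- sort(sample(30:600, k))
    true <- sort(1000 + 15 * sizes + rnorm(k, 0, 3))
    spur <- runif(n - k, 500, 12000)
    cands <- sort(c(true, spur))
    m <- matchLadder(peaksAt(cands), sizeStandard(sizes, "r"))
    oracle <- bruteLadder(cands, sizes)
    expect_equal(m$scan, oracle$scan, tolerance = 1e-9)
  }
})

test_that("the RSS ceiling converts bad ladders into failures", {
  sizes <- c(50, 100, 150, 200, 250)
  scans <- sort(runif(5, 1000, 9000))
  expect_error(matchLadder(peaksAt(scans), sizeStandard(sizes, "s"),
                           rssCeiling = 1e-6),
               class = "idaa_ladder_error")
})

test_that("Local Southern inverts reciprocal-law data exactly", {
  m0 <- 10000; cc <- 2e5
  sizes <- c(50, 100, 200, 400)
  scans <- m0 - cc / sizes
  cal <- fitCalibration(data.frame(scan = scans, size = sizes))
  expect_equal(predictSize(cal, 8000), 100, tolerance = 1e-9)
  # arbitrary query: closed-form inverse of the generating law
  q <- 8765.4
  expect_equal(predictSize(cal, q), cc / (m0 - q), tolerance = 1e-9)
  # knots reproduce their fragment sizes
  expect_equal(predictSize(cal, scans), sizes, tolerance = 1e-6)
})

test_that("spline calibration also interpolates through knots", {
  m0 <- 10000; cc <- 2e5
  sizes <- c(50, 100, 150, 200, 300, 400)
  scans <- m0 - cc / sizes
  cal <- fitCalibration(data.frame(scan = scans, size = sizes), "spline")
  expect_equal(predictSize(cal, scans), sizes, tolerance = 1e-6)
})

test_that("leave-one-out residuals stay below 1 bp under scan noise", {
  set.seed(31)
  sizes <- sizeStandard("LIZ500")@sizes
  scans <- 12000 - 4e5 / sizes + rnorm(length(sizes), 0, 1)
  cal <- fitCalibration(data.frame(scan = sort(scans), size = sizes))
  expect_lt(max(abs(cal@residuals)), 1)
})

test_that("calibration is strictly increasing across the calibrated range", {
  sizes <- sizeStandard("LIZ500")@sizes
  scans <- 12000 - 4e5 / sizes
  for (meth in c("local_southern", "spline")) {
    cal <- fitCalibration(data.frame(scan = scans, size = sizes), meth)
    grid <- seq(min(scans), max(scans), length.out = 2000)
    expect_true(all(diff(predictSize(cal, grid)) > 0), info = meth)
  }
})

test_that("non-monotone matched pairs are rejected", {
  expect_error(fitCalibration(data.frame(scan = c(1, 3, 2, 4),
                                         size = c(50, 100, 150, 200))),
               class = "idaa_parameter_error")
  expect_error(fitCalibration(data.frame(scan = c(1, 2, 3),
                                         size = c(50, 100, 150))),
               class = "idaa_parameter_error")
})

test_that("sizePeaks annotates sizes and extrapolation flags", {
  m0 <- 10000; cc <- 2e5
  sizes <- c(50, 100, 200, 400)
  scans <- m0 - cc / sizes
  cal <- fitCalibration(data.frame(scan = scans, size = sizes))
  # ladder peaks size to their nominal values
  sized <- sizePeaks(cal, peaksAt(scans))
  expect_equal(sized$size_bp, sizes, tolerance = 1e-6)
  expect_false(any(sized$extrapolated))
  # midway (in scan space) between the 100 and 200 bp knots: closed form
  q <- mean(scans[2:3])
  mid <- sizePeaks(cal, peaksAt(q))
  expect_equal(mid$size_bp, cc / (m0 - q), tolerance = 1e-9)
  # outside the calibrated range is flagged
  out <- sizePeaks(cal, peaksAt(max(scans) + 100))
  expect_true(out$extrapolated)
  # empty in, empty out
  empty <- sizePeaks(cal, peaksAt(numeric(0)))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("size_bp", "extrapolated") %in% names(empty)))
})
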