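# Trace simulator: determinism, geometry, area linearity, round-trip
# recovery through the full pipeline, stutter characterization.

test_that("simulation is deterministic for a fixed spec and seed", {
  sp <- quickSpec(alleles = c("0" = 0.6, "-4" = 0.4), seed = 99)
  t1 <- simulateTrace(sp)
  t2 <- simulateTrace(sp)
  expect_identical(t1@intensities, t2@intensities)
  f1 <- tempfile(); f2 <- tempfile()
  writeABIF(t1, f1); writeABIF(t2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  t3 <- simulateTrace(quickSpec(alleles = c("0" = 0.6, "-4" = 0.4), seed = 100))
  expect_false(identical(t1@intensities, t3@intensities))
})

test_that("ladder channel carries one peak per standard fragment", {
  tr <- simulateTrace(quickSpec(noiseSd = 0))
  lad <- channel(tr, "LIZ")
  pk <- detectPeaks(lad, minHeight = 50, minSeparation = 10)
  expect_equal(nrow(pk), length(sizeStandard("LIZ500")@sizes))
})

test_that("noiseless single-allele round trip is exact", {
  p <- analyzeSpec(quickSpec(noiseSd = 0))
  expect_equal(p@alleles$indel_bp, 0L)
  expect_equal(p@alleles$fraction, 1)
  expect_equal(cuttingEfficiency(p), 0)
  # called size within 1e-3 bp of truth under the shared migration law
  expect_equal(p@alleles$mean_size_bp, 150, tolerance = 1e-3)
})

test_that("noiseless sizes across a size span stay within 1e-3 bp of truth", {
  for (ind in c(-40, -7, 3, 25)) {
    sp <- quickSpec(alleles = stats::setNames(1, as.character(ind)),
                    noiseSd = 0)
    p <- analyzeSpec(sp)
    expect_equal(p@alleles$mean_size_bp, 150 + ind, tolerance = 1e-3,
                 info = sprintf("indel %d", ind))
  }
})

test_that("recovered fractions are area-linear at zero noise", {
  truth <- c("-20" = 0.2, "0" = 0.5, "12" = 0.3)
  p <- analyzeSpec(quickSpec(alleles = truth, noiseSd = 0))
  expect_equal(p@alleles$fraction, unname(truth[order(as.integer(names(truth)))]),
               tolerance = 1e-3)
})

test_that("seeded default-noise pools recover fractions within 0.02", {
  truth <- c("-13" = 0.14, "0" = 0.54, "1" = 0.32)
  p <- analyzeSpec(quickSpec(alleles = truth, seed = 7))
  expect_equal(p@alleles$indel_bp, c(-13L, 0L, 1L))
  expect_equal(p@alleles$fraction, c(0.14, 0.54, 0.32), tolerance = 0.021)
  expect_equal(cuttingEfficiency(p), 0.46, tolerance = 0.02)
})

test_that("a quadratic migration model is sized correctly too", {
  # monotone quadratic fitted loosely to the default law's range
  sp <- quickSpec(alleles = c("0" = 0.7, "2" = 0.3), noiseSd = 0,
                  migration = list(model = "poly", coef = c(300, 25, -0.008)))
  p <- analyzeSpec(sp)
  expect_equal(p@alleles$indel_bp, c(0L, 2L))
  # local-Southern sizing of a non-reciprocal law stays within rounding
  expect_equal(p@alleles$mean_size_bp, c(150, 152), tolerance = 0.5)
})

test_that("alleles outside the trace raise a spec error", {
  # 150 - 120 = 30 bp migrates off the front of the trace under the
  # default reciprocal law
  expect_error(simulateTrace(quickSpec(alleles = c("-120" = 1))),
               class = "idaa_spec_error")
  expect_error(simulationSpec(alleles = c("0" = 0.5, "1" = 0.4)),
               "sum to 1")
})

test_that("stutter satellites surface as -1 calls only above min fraction", {
  # 5% stutter: the satellite is a real peak at 4.8% of total area, well
  # above the 0.5% min fraction, so a -1 allele is (correctly) reported --
  # stutter this strong is indistinguishable from a deletion allele.
  p5 <- analyzeSpec(quickSpec(stutterRate = 0.05, seed = 21))
  expect_true(-1L %in% p5@alleles$indel_bp)
  expect_lt(abs(p5@alleles$fraction[p5@alleles$indel_bp == -1L] - 0.05 / 1.05),
            0.01)
  # 0.3% stutter falls below min fraction and is filtered out
  p03 <- analyzeSpec(quickSpec(stutterRate = 0.003, seed = 21))
  expect_false(-1L %in% p03@alleles$indel_bp)
  expect_equal(p03@alleles$indel_bp, 0L)
})

test_that("clone panels derive per-clone seeds and stable names", {
  base <- quickSpec()
  panel <- simulateClonePanel(base, list(c("0" = 1), c("1" = 1)), seed = 5)
  expect_identical(names(panel), c("clone_001", "clone_002"))
  cfg <- quickConfig()
  g1 <- genotypeClone(analyzeTrace(panel[[1]], cfg))
  g2 <- genotypeClone(analyzeTrace(panel[[2]], cfg))
  expect_equal(g1@classification, "wild_type")
  expect_equal(g2@classification, "all_alleles_disrupted")
  expect_equal(g2@alleleCount, 1L)
  expect_true(all(classifyFrame(alleles(analyzeTrace(panel[[2]], cfg))$indel_bp)))
  # same seed, same genotypes: byte-identical traces
  again <- simulateClonePanel(base, list(c("0" = 1), c("1" = 1)), seed = 5)
  expect_identical(panel[[1]]@intensities, again[[1]]@intensities)
})

test_that("YAML simulation specs round-trip their keys", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c(
    "wt_size_bp: 180",
    "alleles:",
    "  \"0\": 0.75",
    "  \"-5\": 0.25",
    "standard: LIZ600",
    "migration: {m0: 12000, c: 200000}",
    "peak_sigma_scan: 3",
    "noise_sd: 5",
    "stutter_rate: 0.0",
    "seed: 17"), y)
  sp <- readSimulationSpec(y)
  expect_equal(sp@wtSize, 180)
  expect_equal(sort(names(sp@alleles)), c("-5", "0"))
  expect_equal(sp@standard@name, "LIZ600")
  expect_equal(sp@peakSigma, 3)
  expect_equal(sp@seed, 17L)
  tr <- simulateTrace(sp)
  expect_s4_class(tr, "Trace")
})
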