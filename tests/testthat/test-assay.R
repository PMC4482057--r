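# Assay design: primer stats, amplicon location, expected sizes, off-target
# enumeration against a brute-force oracle.

test_that("primer statistics match direct counting", {
  s <- primerStats(FamFExtension)
  expect_equal(s$length, 21L)
  expect_equal(s$gc_display, 52L)
  expect_equal(s$gc_percent, 100 * 11 / 21)
  expect_equal(primerStats("GGCC"), list(length = 4L, gc_percent = 100,
                                         gc_display = 100L))
  expect_error(primerStats(""), class = "idaa_validation_error")
  expect_error(primerStats("ACGN"), class = "idaa_validation_error")
})

revcomp <- function(s) chartr("ACGT", "TGCA",
                              paste(rev(strsplit(s, "")[[1]]), collapse = ""))

test_that("amplicon location and expected size follow primer placement", {
  set.seed(9)
  fwd <- randomDNA(20)
  rev <- randomDNA(20)
  ref <- paste0(randomDNA(100), fwd, randomDNA(180), revcomp(rev),
                randomDNA(80))
  loc <- locateAmplicon(ref, fwd, rev)
  expect_equal(unname(loc), c(100, 320))
  d <- assayDesign(ref, fwd, rev)        # default 21-nt universal extension
  expect_equal(expectedWtSize(d), 241L)
  d0 <- assayDesign(ref, fwd, rev, extension = "")
  expect_equal(expectedWtSize(d0), 220L)
  # padding the reference leaves the expected size invariant
  padded <- paste0(randomDNA(57), ref, randomDNA(33))
  dp <- assayDesign(padded, fwd, rev)
  expect_equal(expectedWtSize(dp), 241L)
  expect_equal(dp@ampliconStart, 157L)
})

test_that("ambiguous or misoriented primer placements are design errors", {
  set.seed(10)
  fwd <- randomDNA(20)
  rev <- randomDNA(20)
  twice <- paste0(fwd, randomDNA(50), fwd, randomDNA(50), revcomp(rev))
  expect_error(locateAmplicon(twice, fwd, rev), class = "idaa_design_error")
  upstream <- paste0(randomDNA(30), revcomp(rev), randomDNA(50), fwd,
                     randomDNA(30))
  expect_error(locateAmplicon(upstream, fwd, rev),
               class = "idaa_design_error")
  none <- randomDNA(200)
  expect_error(locateAmplicon(none, fwd, rev), class = "idaa_design_error")
})

test_that("planted on- and off-target sites are found at the right thresholds", {
  set.seed(12)
  proto <- randomDNA(20)
  # a perfect site with NGG PAM embedded once
  g1 <- c(chr1 = paste0(randomDNA(100), proto, "AGG", randomDNA(100)))
  hits <- findOffTargets(g1, proto, "NGG", 0)
  expect_equal(length(hits), 1L)
  expect_equal(hits$mismatches, 0L)
  expect_true(hits$on_target)
  expect_equal(GenomicRanges::start(hits), 101L)
  # a 2-mismatch site appears iff maxMismatch >= 2
  mut <- proto
  substr(mut, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(proto, 3, 3))[1]
  substr(mut, 11, 11) <- setdiff(c("A", "C", "G", "T"), substr(proto, 11, 11))[1]
  g2 <- c(chr1 = paste0(randomDNA(60), mut, "TGG", randomDNA(60)))
  expect_equal(length(findOffTargets(g2, proto, "NGG", 1)), 0L)
  h2 <- findOffTargets(g2, proto, "NGG", 2)
  expect_equal(h2$mismatches, 2L)
  expect_false(h2$on_target)
})

test_that("reverse-strand sites project onto forward coordinates", {
  set.seed(13)
  proto <- randomDNA(20)
  insert <- revcomp(paste0(proto, "CGG"))
  g <- c(chrX = paste0(randomDNA(40), insert, randomDNA(40)))
  hits <- findOffTargets(g, proto, "NGG", 0)
  expect_equal(length(hits), 1L)
  expect_equal(as.character(GenomicRanges::strand(hits)), "-")
  # protospacer occupies forward positions 44..63 (after the 3-nt rc'd PAM)
  expect_equal(GenomicRanges::start(hits), 44L)
  expect_equal(GenomicRanges::end(hits), 63L)
  oracle <- bruteOffTargets(as.list(g), proto, "NGG", 0)
  expect_equal(GenomicRanges::start(hits), oracle$start)
  expect_equal(GenomicRanges::end(hits), oracle$end)
})

test_that("off-target scan equals the brute-force Hamming oracle on random genomes", {
  set.seed(14)
  proto <- randomDNA(18)
  for (rep in 1:3) {
    contigs <- list(c1 = randomDNA(4000), c2 = randomDNA(2500))
    # plant some near-matches so the comparison is not vacuous
    for (nm in names(contigs)) {
      mut <- proto
      k <- sample(0:4, 1)
      if (k > 0) for (pos in sample(18, k))
        substr(mut, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
      at <- sample(1000, 1)
      s <- contigs[[nm]]
      contigs[[nm]] <- paste0(substr(s, 1, at), mut, "AGG",
                              substr(s, at + 1, nchar(s)))
    }
    genome <- unlist(contigs)
    mm <- sample(2:4, 1)
    hits <- findOffTargets(genome, proto, "NGG", mm)
    oracle <- bruteOffTargets(as.list(genome), proto, "NGG", mm)
    expect_equal(length(hits), nrow(oracle))
    if (length(hits)) {
      expect_equal(as.character(GenomicRanges::seqnames(hits)), oracle$contig)
      expect_equal(GenomicRanges::start(hits), oracle$start)
      expect_equal(as.character(GenomicRanges::strand(hits)), oracle$strand)
      expect_equal(hits$mismatches, oracle$mismatches)
    }
  }
})

test_that("hit counts are monotone non-decreasing in the mismatch budget", {
  set.seed(15)
  genome <- c(g = randomDNA(20000))
  proto <- randomDNA(16)
  counts <- sapply(0:4, function(mm)
    length(findOffTargets(genome, proto, "NGG", mm)))
  expect_true(all(diff(counts) >= 0))
})

test_that("off-target hits export as BED6 with mismatch-count names", {
  set.seed(16)
  proto <- randomDNA(20)
  g <- c(chr1 = paste0(randomDNA(30), proto, "AGG", randomDNA(30)))
  hits <- findOffTargets(g, proto, "NGG", 1)
  bed <- tempfile(fileext = ".bed")
  writeOffTargetsBed(hits, bed)
  lines <- strsplit(readLines(bed), "\t")
  expect_equal(length(lines), length(hits))
  # BED is 0-based half-open
  expect_equal(as.integer(lines[[1]][2]), GenomicRanges::start(hits)[1] - 1L)
  expect_equal(as.integer(lines[[1]][3]), GenomicRanges::end(hits)[1])
  expect_equal(lines[[1]][4], as.character(hits$mismatches[1]))
  expect_equal(lines[[1]][6], as.character(GenomicRanges::strand(hits)[1]))
})

test_that("protospacer validation rejects bad inputs", {
  expect_error(findOffTargets(c(a = "ACGTACGTACGT"), "ACGTN", "NGG", 2),
               class = "idaa_validation_error")
  expect_error(findOffTargets(c(a = "ACGT"), randomDNA(10), "NGG", 2),
               class = "idaa_validation_error")
})
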