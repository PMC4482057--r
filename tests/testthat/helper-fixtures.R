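# Shared fixtures: signal builders, quick spec/config constructors, and the
# independent brute-force oracles used to cross-check the optimised code
# paths.

# Gaussian bump of given apex height (not area) at fractional position mu.
gauss <- function(n, mu, sigma, height) {
  height * exp(-((seq_len(n) - mu)^2) / (2 * sigma^2))
}

# Default-condition simulation spec with overridable alleles/seed.
quickSpec <- function(alleles = c("0" = 1), seed = 1L, ...) {
  simulationSpec(alleles = alleles, seed = seed, ...)
}

# Config resolving the wild type from the simulator's own default size.
quickConfig <- function(...) idaaConfig(expectedSize = 150, ...)

# Analyse a simulated spec end to end through the ABIF file round trip.
analyzeSpec <- function(spec, cfg = quickConfig()) {
  f <- tempfile(fileext = ".fsa")
  on.exit(unlink(f))
  writeABIF(simulateTrace(spec), f)
  analyzeSample(f, cfg)
}

# Brute-force ladder assignment oracle: enumerate every order-preserving
# injective assignment and minimise linear-fit RSS with lm().
bruteLadder <- function(scans, sizes) {
  scans <- sort(scans)
  combos <- combn(length(scans), length(sizes))
  best <- NULL
  bestRss <- Inf
  for (j in seq_len(ncol(combos))) {
    y <- scans[combos[, j]]
    rss <- sum(stats::lm(y ~ sizes)$residuals^2)
    if (rss < bestRss) {
      bestRss <- rss
      best <- combos[, j]
    }
  }
  list(scan = scans[best], size = sizes, rss = bestRss)
}

# Brute-force off-target oracle: position-by-position Hamming scan of both
# strands at the character level.
bruteOffTargets <- function(contigs, protospacer, pam, maxMismatch) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  pv <- strsplit(protospacer, "")[[1]]
  pamv <- strsplit(pam, "")[[1]]
  L <- length(pv)
  rows <- list()
  for (cn in names(contigs)) {
    fwd <- contigs[[cn]]
    n <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else revcomp(fwd)
      sv <- strsplit(s, "")[[1]]
      for (st in seq_len(n - L - length(pamv) + 1L)) {
        site <- sv[st:(st + L - 1L)]
        mm <- sum(site != pv | !(site %in% c("A", "C", "G", "T")))
        if (mm > maxMismatch) next
        pamSite <- sv[(st + L):(st + L + length(pamv) - 1L)]
        ok <- all(mapply(function(b, p) b %in% iupac[[p]], pamSite, pamv))
        if (!ok) next
        en <- st + L - 1L
        if (strand == "-") {
          fs <- n - en + 1L
          fe <- n - st + 1L
        } else {
          fs <- st
          fe <- en
        }
        rows[[length(rows) + 1L]] <- data.frame(
          contig = cn, start = fs, end = fe, strand = strand,
          mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0)))
  df <- do.call(rbind, rows)
  df[order(df$contig, df$start, df$strand), , drop = FALSE]
}

# Random DNA string.
randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
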