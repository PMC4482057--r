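## Synthetic electropherogram generator: multi-allele amplicon pools plus a
## co-injected size standard, rendered as Gaussian peaks under a monotone
## migration model with baseline drift and seeded Gaussian noise.  Output
## is a Trace (and, via writeABIF, an .fsa file), so simulated data flow
## through exactly the same code path as instrument data.

#' Build a simulation specification
#'
#' Defaults describe a realistic fragment run: a 150-bp wild-type amplicon
#' sized against LIZ500 under the reciprocal migration law
#' \code{scan(L) = m0 - c/L} with \code{m0 = 12000}, \code{c = 4e5}
#' (about 17.8 scans per bp at 150 bp), Gaussian peaks of sd 4 scans
#' (FWHM about 0.5 bp), a total sample area of 2e5 giving a single-allele
#' apex near 20000 RFU, ladder apexes near 2000 RFU, and additive noise of
#' sd 10 RFU.
#'
#' @param wtSize Wild-type amplicon size in bp.
#' @param alleles Named numeric vector of fractions, names = signed indel
#'   bp (\code{"0"} = wild type); must sum to 1.
#' @param standard A [SizeStandard-class] or standard name.
#' @param migration \code{list(model = "southern", m0, c)} or
#'   \code{list(model = "poly", coef)} (ascending coefficients).
#' @param peakSigma Gaussian peak sd in scans.
#' @param amplitude Total integrated sample-channel area
#'   (fluorescence x scans), split across alleles by fraction.
#' @param ladderAmplitude Integrated area per ladder fragment.
#' @param noiseSd Additive Gaussian noise sd (fluorescence units).
#' @param baselineDrift Linear baseline slope (fluorescence units/scan).
#' @param stutterRate Optional -1 bp PCR-stutter satellite area as a
#'   fraction of its parent peak, in [0, 1).
#' @param scanCount Trace length in scans.
#' @param seed RNG seed.
#' @return A [SimulationSpec-class].
#' @seealso [simulateTrace()], [readSimulationSpec()]
#' @export
simulationSpec <- function(wtSize = 150, alleles = c("0" = 1),
                           standard = "LIZ500",
                           migration = list(model = "southern",
                                            m0 = 12000, c = 4e5),
                           peakSigma = 4, amplitude = 2e5,
                           ladderAmplitude = 2e4, noiseSd = 10,
                           baselineDrift = 0, stutterRate = 0,
                           scanCount = 12000L, seed = 1L) {
  if (is.character(standard)) standard <- sizeStandard(standard)
  al <- as.numeric(alleles)
  names(al) <- names(alleles)
  new("SimulationSpec", wtSize = as.numeric(wtSize), alleles = al,
      standard = standard, migration = migration,
      peakSigma = as.numeric(peakSigma), amplitude = as.numeric(amplitude),
      ladderAmplitude = as.numeric(ladderAmplitude),
      noiseSd = as.numeric(noiseSd),
      baselineDrift = as.numeric(baselineDrift),
      stutterRate = as.numeric(stutterRate),
      scanCount = as.integer(scanCount), seed = as.integer(seed))
}

#' Read a simulation spec from a YAML file
#'
#' Keys mirror the [SimulationSpec-class] fields: \code{wt_size_bp},
#' \code{alleles} (map of signed indel bp to fraction), \code{standard}
#' (name or TSV path), \code{migration} (\code{m0}/\code{c} or
#' \code{coef}), \code{peak_sigma_scan}, \code{amplitude},
#' \code{ladder_amplitude}, \code{noise_sd}, \code{baseline_drift},
#' \code{stutter_rate}, \code{scan_count}, \code{seed}.  Missing keys take
#' the [simulationSpec()] defaults.
#'
#' @param path YAML file path.
#' @return A [SimulationSpec-class].
#' @export
readSimulationSpec <- function(path) {
  if (!file.exists(path))
    .idaaError("idaa_io_error", sprintf("spec file '%s' does not exist", path))
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$wt_size_bp)) args$wtSize <- y$wt_size_bp
  if (!is.null(y$alleles)) {
    al <- unlist(y$alleles)
    args$alleles <- stats::setNames(as.numeric(al), names(al))
  }
  if (!is.null(y$standard)) args$standard <- y$standard
  if (!is.null(y$migration)) {
    m <- y$migration
    args$migration <- if (!is.null(m$coef))
      list(model = "poly", coef = as.numeric(m$coef))
    else list(model = "southern", m0 = as.numeric(m$m0), c = as.numeric(m$c))
  }
  map <- c(peak_sigma_scan = "peakSigma", amplitude = "amplitude",
           ladder_amplitude = "ladderAmplitude", noise_sd = "noiseSd",
           baseline_drift = "baselineDrift", stutter_rate = "stutterRate",
           scan_count = "scanCount", seed = "seed")
  for (k in names(map)) if (!is.null(y[[k]])) args[[map[k]]] <- y[[k]]
  do.call(simulationSpec, args)
}

## scan coordinate of a fragment of size L under the migration model
.migrationScan <- function(migration, L) {
  if (migration$model == "southern") {
    migration$m0 - migration$c / L
  } else if (migration$model == "poly") {
    co <- migration$coef
    out <- 0
    for (i in seq_along(co)) out <- out + co[i] * L^(i - 1)
    out
  } else {
    .idaaError("idaa_spec_error",
               sprintf("unknown migration model '%s'", migration$model))
  }
}

## add a Gaussian of given integrated area at fractional scan position mu
.addGaussian <- function(signal, mu, sigma, area) {
  n <- length(signal)
  lo <- max(1L, floor(mu - 6 * sigma))
  hi <- min(n, ceiling(mu + 6 * sigma))
  i <- lo:hi
  signal[i] <- signal[i] +
    area / (sigma * sqrt(2 * pi)) * exp(-((i - mu)^2) / (2 * sigma^2))
  signal
}

#' Simulate a two-channel electropherogram
#'
#' Channel 1 (\code{6-FAM}) carries one Gaussian per allele at
#' \code{scan(wtSize + indel)} with area proportional to its fraction
#' (plus an optional -1 bp stutter satellite); channel 2 (\code{LIZ})
#' carries one Gaussian per ladder fragment.  Both channels receive the
#' linear baseline drift and seeded Gaussian noise, are quantised to
#' integers and clamped to the signed 16-bit instrument range.  The result
#' is deterministic for a fixed spec (the seed lives in the spec).
#'
#' @param spec A [SimulationSpec-class].
#' @param name Sample name stored in the trace.
#' @return A [Trace-class] with dyes \code{"6-FAM"} and \code{"LIZ"}.
#' @examples
#' tr <- simulateTrace(simulationSpec(alleles = c("0" = 0.7, "1" = 0.3)))
#' scanCount(tr)
#' @export
simulateTrace <- function(spec, name = "sim") {
  stopifnot(is(spec, "SimulationSpec"))
  validObject(spec)
  n <- spec@scanCount
  indels <- as.numeric(names(spec@alleles))
  sizes <- spec@wtSize + indels
  if (any(sizes <= 0))
    .idaaError("idaa_spec_error", "allele sizes must stay positive")
  allSizes <- sort(unique(c(sizes, spec@standard@sizes,
                            if (spec@stutterRate > 0) sizes - 1)))
  scansAll <- .migrationScan(spec@migration, allSizes)
  if (any(diff(scansAll) <= 0))
    .idaaError("idaa_spec_error",
               "migration model must be strictly increasing over simulated sizes")
  margin <- 6 * spec@peakSigma
  if (any(scansAll < 1 + margin) || any(scansAll > n - margin))
    .idaaError("idaa_spec_error",
               "simulated peak falls outside the trace; increase scanCount")
  sample <- numeric(n)
  for (j in seq_along(indels)) {
    mu <- .migrationScan(spec@migration, sizes[j])
    area <- spec@alleles[j] * spec@amplitude
    sample <- .addGaussian(sample, mu, spec@peakSigma, area)
    if (spec@stutterRate > 0) {
      muS <- .migrationScan(spec@migration, sizes[j] - 1)
      sample <- .addGaussian(sample, muS, spec@peakSigma,
                             spec@stutterRate * area)
    }
  }
  ladder <- numeric(n)
  for (L in spec@standard@sizes) {
    ladder <- .addGaussian(ladder, .migrationScan(spec@migration, L),
                           spec@peakSigma, spec@ladderAmplitude)
  }
  drift <- spec@baselineDrift * (seq_len(n) - 1)
  m <- .withSeed(spec@seed, {
    cbind(sample + drift + stats::rnorm(n, 0, spec@noiseSd),
          ladder + drift + stats::rnorm(n, 0, spec@noiseSd))
  })
  m <- pmin(pmax(round(m), .INT16_MIN), .INT16_MAX)
  Trace(m, dyeNames = c("6-FAM", "LIZ"), sampleName = name)
}

#' Simulate a panel of single-cell clones
#'
#' One trace per genotype, with per-clone seeds derived from \code{seed}
#' (\code{seed + index}) and stable sortable names.
#'
#' @param base A [SimulationSpec-class] providing all shared parameters.
#' @param genotypes List of named fraction vectors (as the \code{alleles}
#'   field), one per clone.
#' @param seed Base seed.
#' @return Named list of [Trace-class] objects
#'   (\code{clone_001}, \code{clone_002}, ...).
#' @export
simulateClonePanel <- function(base, genotypes, seed = base@seed) {
  stopifnot(is(base, "SimulationSpec"), is.list(genotypes))
  out <- vector("list", length(genotypes))
  names(out) <- sprintf("clone_%03d", seq_along(genotypes))
  for (i in seq_along(genotypes)) {
    spec <- base
    al <- as.numeric(genotypes[[i]])
    names(al) <- names(genotypes[[i]])
    spec@alleles <- al
    spec@seed <- as.integer(seed + i)
    validObject(spec)
    out[[i]] <- simulateTrace(spec, name = names(out)[i])
  }
  out
}
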