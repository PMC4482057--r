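#' @import methods
NULL

## 16-bit signed range of the instrument ADC; ABIF DATA tags store shorts.
.INT16_MIN <- -32768L
.INT16_MAX <- 32767L

#' Multi-channel fragment-analysis trace
#'
#' A \code{Trace} holds the per-scan fluorescence intensities recorded by a
#' capillary electrophoresis instrument, one column per dye channel, plus the
#' instrument metadata retained from the ABIF directory.  All channels share
#' the scan axis, so intensities are a single \code{scanCount x nChannels}
#' matrix with dye names as column names.
#'
#' @slot sampleName Sample name (ABIF tag \code{SMPL1}), possibly \code{""}.
#' @slot intensities Numeric matrix of integer-valued fluorescence units,
#'   one row per scan, one column per channel; values must fit in a signed
#'   16-bit integer.
#' @slot dyeNames Character vector of unique dye names, one per channel.
#' @slot metadata Named list of retained ABIF tags not mapped to a slot.
#'
#' @seealso [readABIF()], [writeABIF()], [simulateTrace()]
#' @export
setClass("Trace",
  representation(
    sampleName = "character",
    intensities = "matrix",
    dyeNames = "character",
    metadata = "list"
  ),
  prototype(
    sampleName = "",
    intensities = matrix(numeric(0), nrow = 0, ncol = 0),
    dyeNames = character(0),
    metadata = list()
  )
)

setValidity("Trace", function(object) {
  msg <- character(0)
  m <- object@intensities
  if (length(object@sampleName) != 1L)
    msg <- c(msg, "sampleName must be a single string")
  if (ncol(m) != length(object@dyeNames))
    msg <- c(msg, "one dye name per channel required")
  if (anyDuplicated(object@dyeNames))
    msg <- c(msg, "dye names must be unique within a trace")
  if (length(m) > 0) {
    if (any(!is.finite(m)))
      msg <- c(msg, "intensities must be finite")
    else {
      if (any(m != round(m)))
        msg <- c(msg, "intensities must be integer-valued")
      if (any(m < .INT16_MIN | m > .INT16_MAX))
        msg <- c(msg, "intensities must fit in a signed 16-bit integer")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Trace
#'
#' @param intensities Matrix of intensities (scans x channels) or a list of
#'   equal-length numeric vectors.
#' @param dyeNames Character vector of dye names, one per channel.
#' @param sampleName Optional sample name.
#' @param metadata Optional named list of extra ABIF tags.
#' @return A [Trace-class] object.
#' @examples
#' tr <- Trace(cbind(c(0, 5, 9, 5, 0)), dyeNames = "6-FAM")
#' scanCount(tr)
#' @export
Trace <- function(intensities, dyeNames, sampleName = "", metadata = list()) {
  if (is.list(intensities) && !is.matrix(intensities)) {
    lens <- lengths(intensities)
    if (length(unique(lens)) > 1L)
      stop("all channels must have identical length")
    intensities <- if (length(intensities))
      do.call(cbind, lapply(intensities, as.numeric))
    else matrix(numeric(0), 0, 0)
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  colnames(intensities) <- dyeNames
  new("Trace", sampleName = as.character(sampleName),
      intensities = intensities, dyeNames = as.character(dyeNames),
      metadata = metadata)
}

#' Size standard (ladder) fragment table
#'
#' The set of known fragment sizes co-injected with every sample that anchors
#' the scan-to-bp calibration (e.g. the GeneScan LIZ500 / LIZ600 sets).
#'
#' @slot name Standard name.
#' @slot sizes Strictly increasing fragment sizes in bp (at least 4).
#' @seealso [sizeStandard()]
#' @export
setClass("SizeStandard",
  representation(name = "character", sizes = "numeric"))

setValidity("SizeStandard", function(object) {
  s <- object@sizes
  if (length(s) < 4L) return("a size standard needs at least 4 fragments")
  if (any(s <= 0)) return("fragment sizes must be positive")
  if (any(diff(s) <= 0)) return("fragment sizes must be strictly increasing")
  TRUE
})

#' Scan-to-size calibration
#'
#' Monotone mapping from scan coordinate to fragment size in bp, fitted from
#' matched ladder peaks.  Evaluate it with [predictSize()].
#'
#' @slot points data.frame with columns \code{scan} and \code{size}, strictly
#'   increasing in both.
#' @slot method \code{"local_southern"} or \code{"spline"}.
#' @slot residuals Leave-one-out refit error in bp at each matched point.
#' @slot scanRange Scan range covered by the matched points; sizing outside
#'   it is flagged as extrapolated.
#' @seealso [fitCalibration()], [sizePeaks()]
#' @export
setClass("Calibration",
  representation(
    points = "data.frame",
    method = "character",
    residuals = "numeric",
    scanRange = "numeric"
  )
)

setValidity("Calibration", function(object) {
  p <- object@points
  if (!all(c("scan", "size") %in% names(p)))
    return("points must have 'scan' and 'size' columns")
  if (nrow(p) < 4L) return("at least 4 calibration points required")
  if (any(diff(p$scan) <= 0) || any(diff(p$size) <= 0))
    return("calibration points must be strictly increasing in scan and size")
  if (!object@method %in% c("local_southern", "spline"))
    return("method must be 'local_southern' or 'spline'")
  TRUE
})

#' Per-sample indel profile
#'
#' The result of the analysis pipeline for one sample: the wild-type
#' reference size, the allele table (signed integer indel, observed mean
#' size, peak-area fraction, frameshift flag), the cutting efficiency and
#' any QC flags.
#'
#' @slot sampleName Sample name.
#' @slot wtSize Wild-type amplicon size in bp (NA if sizing failed).
#' @slot wtSource One of \code{"control_trace"}, \code{"expected_design"},
#'   \code{"fixed"} or \code{""}.
#' @slot alleles data.frame with columns \code{indel_bp}, \code{mean_size_bp},
#'   \code{fraction}, \code{raw_fraction}, \code{frameshift},
#'   \code{n_peaks_merged}.
#' @slot efficiency Cutting efficiency in [0,1]: summed fraction of
#'   non-wild-type alleles (NA when no peaks).
#' @slot qcFlags Subset of \code{ladder_fail}, \code{saturated_peak},
#'   \code{no_peaks}, \code{extrapolated}.
#' @slot peaks Sized sample-channel peaks retained in the analysis window.
#' @slot ladderResiduals Per-fragment leave-one-out calibration residuals.
#' @seealso [analyzeSample()], [callAlleles()], [cuttingEfficiency()]
#' @export
setClass("IndelProfile",
  representation(
    sampleName = "character",
    wtSize = "numeric",
    wtSource = "character",
    alleles = "data.frame",
    efficiency = "numeric",
    qcFlags = "character",
    peaks = "data.frame",
    ladderResiduals = "numeric"
  ),
  prototype(
    sampleName = "", wtSize = NA_real_, wtSource = "",
    alleles = data.frame(), efficiency = NA_real_,
    qcFlags = character(0), peaks = data.frame(),
    ladderResiduals = numeric(0)
  )
)

setValidity("IndelProfile", function(object) {
  a <- object@alleles
  if (nrow(a)) {
    need <- c("indel_bp", "mean_size_bp", "fraction", "frameshift")
    if (!all(need %in% names(a)))
      return(paste("alleles must have columns:", paste(need, collapse = ", ")))
    if (abs(sum(a$fraction) - 1) > 1e-9)
      return("allele fractions must sum to 1")
    if (any(a$fraction <= 0)) return("allele fractions must be positive")
    if (any(a$frameshift != (a$indel_bp != 0 & a$indel_bp %% 3 != 0)))
      return("frameshift flag inconsistent with indel size")
  }
  TRUE
})

#' Clone genotype classification
#'
#' @slot alleleCount Number of alleles counted above the clone allele
#'   fraction threshold.
#' @slot classification One of \code{wild_type}, \code{mono_allelic},
#'   \code{multi_allelic_mixed}, \code{all_alleles_disrupted}.
#' @slot frameDisruptedFraction Fraction of counted allele signal carrying a
#'   frame-disrupting (non-multiple-of-3) indel.
#' @slot flags QC warnings (e.g. more alleles than expected ploidy).
#' @seealso [genotypeClone()]
#' @export
setClass("CloneGenotype",
  representation(
    alleleCount = "integer",
    classification = "character",
    frameDisruptedFraction = "numeric",
    flags = "character"
  )
)

setValidity("CloneGenotype", function(object) {
  ok <- c("wild_type", "mono_allelic", "multi_allelic_mixed",
          "all_alleles_disrupted")
  if (!object@classification %in% ok)
    return(paste("classification must be one of:", paste(ok, collapse = ", ")))
  TRUE
})

#' Tri-primer assay design
#'
#' Locates a primer pair on a reference sequence and records the expected
#' wild-type labelled-amplicon size, i.e. the genomic amplicon plus the
#' universal 5' extension carried by the forward primer (the FAM-labelled
#' universal primer target).
#'
#' @slot referenceId Reference sequence name.
#' @slot fwdPrimer,revPrimer Primer sequences (uppercase ACGT).
#' @slot extension Universal extension prepended to the forward primer.
#' @slot ampliconStart,ampliconEnd 0-based half-open amplicon coordinates on
#'   the reference.
#' @slot expectedSize Expected wild-type labelled amplicon size in bp.
#' @seealso [assayDesign()], [expectedWtSize()]
#' @export
setClass("AssayDesign",
  representation(
    referenceId = "character",
    fwdPrimer = "character",
    revPrimer = "character",
    extension = "character",
    ampliconStart = "integer",
    ampliconEnd = "integer",
    expectedSize = "integer"
  )
)

setValidity("AssayDesign", function(object) {
  if (object@ampliconEnd <= object@ampliconStart)
    return("ampliconEnd must exceed ampliconStart")
  minLen <- nchar(object@fwdPrimer) + nchar(object@revPrimer) +
    nchar(object@extension)
  if (object@expectedSize < minLen)
    return("expected size smaller than primers plus extension")
  if (object@expectedSize !=
      (object@ampliconEnd - object@ampliconStart) + nchar(object@extension))
    return("expectedSize inconsistent with coordinates and extension")
  TRUE
})

#' Electropherogram simulation specification
#'
#' Describes a synthetic sample: a pool of amplicon alleles (wild type plus
#' indel alleles at stated fractions) co-injected with a size standard, under
#' a monotone migration model with Gaussian peaks, baseline drift and noise.
#'
#' @slot wtSize Wild-type amplicon size in bp.
#' @slot alleles Named numeric vector: names are signed integer indel sizes
#'   in bp ("0" = wild type), values are molar fractions summing to 1.
#' @slot standard The co-injected [SizeStandard-class].
#' @slot migration List describing the scan(L) migration model: either
#'   \code{list(model = "southern", m0, c)} for scan(L) = m0 - c/L, or
#'   \code{list(model = "poly", coef)} with ascending polynomial
#'   coefficients.
#' @slot peakSigma Gaussian peak width (sd) in scans.
#' @slot amplitude Total integrated sample-channel signal
#'   (fluorescence x scans); each allele peak gets its fraction of it.
#' @slot ladderAmplitude Integrated area per ladder fragment peak.
#' @slot noiseSd Additive Gaussian noise sd in fluorescence units.
#' @slot baselineDrift Linear baseline slope in fluorescence units per scan.
#' @slot stutterRate Area of the optional -1 bp PCR stutter satellite as a
#'   fraction of its parent peak area, in [0, 1).
#' @slot scanCount Number of scans in the simulated trace.
#' @slot seed RNG seed making the trace reproducible.
#' @seealso [simulationSpec()], [simulateTrace()]
#' @export
setClass("SimulationSpec",
  representation(
    wtSize = "numeric",
    alleles = "numeric",
    standard = "SizeStandard",
    migration = "list",
    peakSigma = "numeric",
    amplitude = "numeric",
    ladderAmplitude = "numeric",
    noiseSd = "numeric",
    baselineDrift = "numeric",
    stutterRate = "numeric",
    scanCount = "integer",
    seed = "integer"
  )
)

setValidity("SimulationSpec", function(object) {
  msg <- character(0)
  a <- object@alleles
  if (length(a) == 0 || is.null(names(a)))
    msg <- c(msg, "alleles must be a named vector (names = signed indel bp)")
  else {
    if (anyNA(suppressWarnings(as.numeric(names(a)))))
      msg <- c(msg, "allele names must be signed integer indel sizes")
    if (abs(sum(a) - 1) > 1e-9)
      msg <- c(msg, "allele fractions must sum to 1")
    if (any(a <= 0)) msg <- c(msg, "allele fractions must be positive")
  }
  if (object@stutterRate < 0 || object@stutterRate >= 1)
    msg <- c(msg, "stutterRate must be in [0, 1)")
  if (object@wtSize <= 0) msg <- c(msg, "wtSize must be positive")
  if (object@peakSigma <= 0) msg <- c(msg, "peakSigma must be positive")
  if (object@scanCount < 1L) msg <- c(msg, "scanCount must be positive")
  if (!is.list(object@migration) || is.null(object@migration$model))
    msg <- c(msg, "migration must be a list with a 'model' element")
  if (length(msg)) msg else TRUE
})
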