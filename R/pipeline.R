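## End-to-end analysis: read trace -> baseline/smooth -> detect peaks ->
## ladder match -> calibrate -> size -> call alleles -> quantify, plus
## batch processing over a sample manifest.

#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its default.  Thresholds are
#' validated up front so a bad configuration fails before any file is
#' touched.
#'
#' @param sampleDye,ladderDye Dye-name patterns selecting the sample and
#'   ladder channels (case-insensitive substring match).
#' @param sampleChannel,ladderChannel Explicit channel indices overriding
#'   the dye-name match.
#' @param standard Size-standard name (\code{"LIZ500"}, \code{"LIZ600"}) or
#'   TSV path.
#' @param baselineWindow Morphological-opening window (odd scans).
#' @param smoothWindow,smoothOrder Savitzky-Golay filter length and order.
#' @param minHeight Minimum peak height (fluorescence units), sample
#'   channel.
#' @param ladderMinHeight Minimum peak height, ladder channel.
#' @param minSeparation Minimum apex separation (scans).
#' @param saturation Raw-intensity saturation threshold.
#' @param rssCeiling Ladder-assignment RSS ceiling (see [matchLadder()]).
#' @param maxLooResidual Maximum leave-one-out calibration residual (bp)
#'   before the ladder is flagged as failed.
#' @param calibrationMethod \code{"local_southern"} or \code{"spline"}.
#' @param windowBp Analysis half-window around the wild-type size (bp).
#' @param clusterTolBp Peak-merge tolerance around an integer offset (bp).
#' @param minFraction Minimum allele fraction retained.
#' @param minAlleleFraction Minimum fraction for clone-genotype counting.
#' @param maxAlleles Expected ploidy bound for clone genotyping.
#' @param control Path to a wild-type control trace (reference mode
#'   \code{control_trace}).
#' @param expectedSize Expected wild-type size in bp (reference mode
#'   \code{expected_design}); exactly one of \code{control} /
#'   \code{expectedSize} must be set for [analyzeSample()].
#' @return A validated configuration (classed list).
#' @export
idaaConfig <- function(sampleDye = "FAM", ladderDye = "LIZ",
                       sampleChannel = NA_integer_,
                       ladderChannel = NA_integer_,
                       standard = "LIZ500",
                       baselineWindow = 151L, smoothWindow = 9L,
                       smoothOrder = 3L, minHeight = 50,
                       ladderMinHeight = 50, minSeparation = 10L,
                       saturation = 32000, rssCeiling = Inf,
                       maxLooResidual = 2,
                       calibrationMethod = "local_southern",
                       windowBp = 150, clusterTolBp = 0.5,
                       minFraction = 0.005, minAlleleFraction = 0.15,
                       maxAlleles = 4L, control = NULL,
                       expectedSize = NULL) {
  cfg <- list(sampleDye = sampleDye, ladderDye = ladderDye,
              sampleChannel = sampleChannel, ladderChannel = ladderChannel,
              standard = standard, baselineWindow = as.integer(baselineWindow),
              smoothWindow = as.integer(smoothWindow),
              smoothOrder = as.integer(smoothOrder), minHeight = minHeight,
              ladderMinHeight = ladderMinHeight,
              minSeparation = as.integer(minSeparation),
              saturation = saturation, rssCeiling = rssCeiling,
              maxLooResidual = maxLooResidual,
              calibrationMethod = calibrationMethod,
              windowBp = windowBp, clusterTolBp = clusterTolBp,
              minFraction = minFraction,
              minAlleleFraction = minAlleleFraction,
              maxAlleles = as.integer(maxAlleles),
              control = control, expectedSize = expectedSize)
  if (cfg$baselineWindow < 3L || cfg$baselineWindow %% 2L == 0L)
    .idaaError("idaa_config_error", "baselineWindow must be odd and >= 3")
  if (cfg$smoothWindow %% 2L == 0L || cfg$smoothOrder >= cfg$smoothWindow)
    .idaaError("idaa_config_error",
               "smoothWindow must be odd with smoothOrder < smoothWindow")
  for (f in c("minHeight", "ladderMinHeight", "windowBp"))
    if (cfg[[f]] <= 0)
      .idaaError("idaa_config_error", sprintf("%s must be positive", f))
  if (cfg$minFraction < 0 || cfg$minFraction >= 1)
    .idaaError("idaa_config_error", "minFraction must be in [0, 1)")
  if (!cfg$calibrationMethod %in% c("local_southern", "spline"))
    .idaaError("idaa_config_error",
               "calibrationMethod must be 'local_southern' or 'spline'")
  if (!is.null(cfg$control) && !is.null(cfg$expectedSize))
    .idaaError("idaa_config_error",
               "set either a control trace or an expected size, not both")
  class(cfg) <- "idaaConfig"
  cfg
}

.pickChannel <- function(trace, dye, index, what) {
  if (!is.na(index)) {
    if (index < 1L || index > ncol(trace@intensities))
      .idaaError("idaa_config_error",
                 sprintf("%s channel index %d out of range", what, index))
    return(as.integer(index))
  }
  hit <- grep(dye, trace@dyeNames, ignore.case = TRUE, fixed = FALSE)
  if (length(hit) == 0L)
    .idaaError("idaa_config_error",
               sprintf("no %s channel matching dye '%s' (dyes: %s)",
                       what, dye, paste(trace@dyeNames, collapse = ", ")))
  hit[1L]
}

## baseline-correct and smooth one channel; returns the conditioned signal
.conditionChannel <- function(v, cfg) {
  sm <- smoothTrace(v, cfg$smoothWindow, cfg$smoothOrder)
  base <- estimateBaseline(sm, min(cfg$baselineWindow,
                                   (length(sm) - 1L) %/% 2L * 2L + 1L))
  pmax(sm - base, 0)
}

## sized sample-channel peaks of a trace, or a condition on ladder failure
.sizedSamplePeaks <- function(trace, cfg) {
  si <- .pickChannel(trace, cfg$sampleDye, cfg$sampleChannel, "sample")
  li <- .pickChannel(trace, cfg$ladderDye, cfg$ladderChannel, "ladder")
  raw <- trace@intensities
  sampleSig <- .conditionChannel(raw[, si], cfg)
  ladderSig <- .conditionChannel(raw[, li], cfg)
  ladderPeaks <- detectPeaks(ladderSig, cfg$ladderMinHeight,
                             cfg$minSeparation)
  standard <- if (is(cfg$standard, "SizeStandard")) cfg$standard
              else sizeStandard(cfg$standard)
  matched <- matchLadder(ladderPeaks, standard, rssCeiling = cfg$rssCeiling)
  cal <- fitCalibration(matched, cfg$calibrationMethod)
  ## QC on interior points only: dropping an end point turns its refit into
  ## an extrapolation, which is not a fair measure of calibration quality
  inner <- abs(cal@residuals[-c(1L, length(cal@residuals))])
  if (max(inner) > cfg$maxLooResidual)
    .idaaError("idaa_ladder_error",
               sprintf("ladder failure: max leave-one-out residual %.2f bp exceeds %.2f bp",
                       max(inner), cfg$maxLooResidual))
  samplePeaks <- detectPeaks(sampleSig, cfg$minHeight, cfg$minSeparation,
                             raw = raw[, si], saturation = cfg$saturation)
  list(peaks = sizePeaks(cal, samplePeaks), calibration = cal)
}

.resolveReference <- function(cfg, controlTrace = NULL) {
  if (!is.null(cfg$expectedSize))
    return(referenceSize(as.numeric(cfg$expectedSize)))
  ctl <- controlTrace
  if (is.null(ctl) && !is.null(cfg$control)) ctl <- readABIF(cfg$control)
  if (is.null(ctl))
    .idaaError("idaa_config_error",
               "no reference: supply a control trace or an expected size")
  sized <- .sizedSamplePeaks(ctl, cfg)$peaks
  ref <- referenceSize(sized)
  ref
}

#' Analyse one sample trace
#'
#' Runs the full pipeline on a [Trace-class] (or, via [analyzeSample()], an
#' .fsa file): signal conditioning, ladder matching and calibration, peak
#' sizing, allele calling and quantification.  A ladder failure does not
#' raise: it yields a profile flagged \code{ladder_fail} with no allele
#' calls, so batches keep going.
#'
#' @param trace A [Trace-class].
#' @param config An [idaaConfig()].
#' @param reference Optional pre-resolved reference (list with
#'   \code{wt_size_bp} and \code{source}, as returned by
#'   [referenceSize()]); when missing it is resolved from the config's
#'   control path or expected size.
#' @return An [IndelProfile-class].
#' @export
analyzeTrace <- function(trace, config = idaaConfig(), reference = NULL) {
  stopifnot(is(trace, "Trace"))
  if (is.null(reference)) reference <- .resolveReference(config)
  sized <- tryCatch(.sizedSamplePeaks(trace, config),
                    idaa_ladder_error = function(e) e)
  if (inherits(sized, "condition")) {
    return(new("IndelProfile", sampleName = trace@sampleName,
               wtSize = reference$wt_size_bp, wtSource = reference$source,
               alleles = data.frame(), efficiency = NA_real_,
               qcFlags = "ladder_fail", peaks = data.frame(),
               ladderResiduals = numeric(0)))
  }
  peaks <- sized$peaks
  alleles <- callAlleles(peaks, reference$wt_size_bp,
                         windowBp = config$windowBp,
                         minFraction = config$minFraction,
                         clusterTolBp = config$clusterTolBp)
  flags <- character(0)
  inWindow <- if (nrow(peaks))
    abs(peaks$size_bp - reference$wt_size_bp) <= config$windowBp
  else logical(0)
  if (nrow(alleles) == 0L) flags <- c(flags, "no_peaks")
  if (any(peaks$saturated[inWindow])) flags <- c(flags, "saturated_peak")
  if (any(peaks$extrapolated[inWindow])) flags <- c(flags, "extrapolated")
  eff <- if (nrow(alleles)) sum(alleles$fraction[alleles$indel_bp != 0])
         else NA_real_
  new("IndelProfile", sampleName = trace@sampleName,
      wtSize = reference$wt_size_bp, wtSource = reference$source,
      alleles = alleles, efficiency = eff, qcFlags = flags,
      peaks = peaks[inWindow, , drop = FALSE],
      ladderResiduals = sized$calibration@residuals)
}

#' @describeIn analyzeTrace Read an .fsa file and analyse it.
#' @param path Path to an ABIF file.
#' @export
analyzeSample <- function(path, config = idaaConfig(), reference = NULL) {
  trace <- readABIF(path)
  if (!nzchar(trace@sampleName))
    trace@sampleName <- sub("\\.fsa$", "", basename(path), ignore.case = TRUE)
  analyzeTrace(trace, config, reference = reference)
}

#' Analyse a batch of samples from a manifest
#'
#' The manifest is a TSV with columns \code{sample}, \code{path} and
#' optionally \code{control} / \code{expected_size} per-row overrides.
#' Rows that fail to read are reported in \code{errors} and the batch
#' continues.  The summary carries one row per sample with cutting
#' efficiency and clone genotype classification, plus an indel-size
#' histogram across the batch.
#'
#' @param manifest Path to the manifest TSV, or an equivalent data.frame.
#' @param config An [idaaConfig()].
#' @return List with \code{profiles} (named list of
#'   [IndelProfile-class]), \code{summary} (data.frame), \code{histogram}
#'   (table of indel sizes over counted clone alleles) and \code{errors}
#'   (data.frame of per-row failures).
#' @export
analyzeBatch <- function(manifest, config = idaaConfig()) {
  tab <- if (is.data.frame(manifest)) manifest
         else utils::read.delim(manifest, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    warning("empty manifest: no samples to analyse")
    return(list(profiles = list(),
                summary = data.frame(), histogram = table(integer(0)),
                errors = data.frame()))
  }
  if (!all(c("sample", "path") %in% names(tab)))
    .idaaError("idaa_config_error",
               "manifest needs 'sample' and 'path' columns")
  refCache <- new.env(parent = emptyenv())
  profiles <- list()
  errors <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    res <- tryCatch({
      cfg <- config
      if (!is.null(row$expected_size) && !is.na(row$expected_size) &&
          nzchar(as.character(row$expected_size))) {
        cfg$expectedSize <- as.numeric(row$expected_size)
        cfg$control <- NULL
      } else if (!is.null(row$control) && !is.na(row$control) &&
                 nzchar(row$control)) {
        cfg$control <- row$control
        cfg$expectedSize <- NULL
      }
      ref <- if (!is.null(cfg$expectedSize)) {
        referenceSize(as.numeric(cfg$expectedSize))
      } else if (!is.null(cfg$control)) {
        key <- cfg$control
        if (is.null(refCache[[key]]))
          refCache[[key]] <- .resolveReference(cfg)
        refCache[[key]]
      } else {
        .idaaError("idaa_config_error",
                   sprintf("row %d: no control or expected size", i))
      }
      analyzeSample(row$path, cfg, reference = ref)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <-
        data.frame(sample = row$sample, path = row$path,
                   error = conditionMessage(res))
    } else {
      res@sampleName <- as.character(row$sample)
      profiles[[as.character(row$sample)]] <- res
    }
  }
  summ <- do.call(rbind, lapply(profiles, function(p) {
    geno <- if (nrow(p@alleles))
      genotypeClone(p, config$maxAlleles, config$minAlleleFraction)
    else NULL
    data.frame(
      sample = p@sampleName,
      wt_size_bp = p@wtSize,
      n_alleles = nrow(p@alleles),
      cutting_efficiency = p@efficiency,
      classification = if (is.null(geno)) NA_character_
                       else geno@classification,
      frame_disrupted_fraction = if (is.null(geno)) NA_real_
                                 else geno@frameDisruptedFraction,
      qc_flags = paste(p@qcFlags, collapse = ";")
    )
  }))
  if (!is.null(summ)) rownames(summ) <- NULL
  counted <- unlist(lapply(profiles, function(p) {
    a <- p@alleles
    if (nrow(a) == 0L) return(integer(0))
    a$indel_bp[a$fraction >= config$minAlleleFraction]
  }))
  list(profiles = profiles,
       summary = if (is.null(summ)) data.frame() else summ,
       histogram = table(counted),
       errors = if (length(errors)) do.call(rbind, errors) else data.frame())
}
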