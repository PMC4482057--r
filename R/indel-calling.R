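## Allele calling from sized sample-channel peaks: signed integer indel
## sizes relative to the wild-type amplicon, peak-area allele fractions,
## cutting efficiency, frameshift annotation, clone genotype classes.

#' Frame-disruption test for an indel size
#'
#' An indel disrupts the reading frame iff its size is non-zero and not a
#' multiple of 3 (mathematical modulo, so -74 disrupts: 74 = 3*24 + 2).
#'
#' @param indel Signed integer indel size(s) in bp (0 = wild type).
#' @return Logical vector.
#' @examples
#' classifyFrame(c(1, -3, -74))
#' @export
classifyFrame <- function(indel) {
  indel != 0 & indel %% 3 != 0
}

#' Wild-type reference size
#'
#' Resolves the wild-type amplicon size either from a wild-type control
#' trace's sized peaks (the preferred mode: the dominant peak must carry at
#' least \code{minDominant} of the total area) or from an
#' [AssayDesign-class] / explicit expected size.  Using a same-run control
#' cancels systematic mobility offsets, since indel sizes are differences
#' of sizes under one calibration.
#'
#' @param x A sized-peak data.frame (from [sizePeaks()] on the control
#'   sample channel), an [AssayDesign-class], or a single numeric expected
#'   size.
#' @param minDominant Minimum area fraction of the top control peak.
#' @return List with \code{wt_size_bp} and \code{source} (one of
#'   \code{"control_trace"}, \code{"expected_design"}, \code{"fixed"}).
#' @export
referenceSize <- function(x, minDominant = 0.8) {
  if (is(x, "AssayDesign"))
    return(list(wt_size_bp = as.numeric(x@expectedSize),
                source = "expected_design"))
  if (is.numeric(x) && length(x) == 1L)
    return(list(wt_size_bp = as.numeric(x), source = "fixed"))
  if (!is.data.frame(x) || !all(c("size_bp", "area") %in% names(x)))
    .idaaError("idaa_reference_error",
               "control must be a sized-peak data.frame, an AssayDesign or a number")
  if (nrow(x) == 0L)
    .idaaError("idaa_reference_error", "control trace has no peaks")
  top <- which.max(x$area)
  if (x$area[top] / sum(x$area) < minDominant)
    .idaaError("idaa_reference_error",
               sprintf(paste0("ambiguous control: dominant peak carries %.0f%% ",
                              "of area (< %.0f%%); supply an explicit expected size"),
                       100 * x$area[top] / sum(x$area), 100 * minDominant))
  list(wt_size_bp = x$size_bp[top], source = "control_trace")
}

#' Call indel alleles from sized peaks
#'
#' Retains peaks within \code{windowBp} of the wild-type size, assigns each
#' the signed integer indel \code{round(size - wt)} (ties rounded away from
#' zero), merges peaks lying within \code{clusterTolBp} of the same integer
#' offset (areas summed, sizes area-weighted), converts merged areas to
#' fractions of the total retained area, drops alleles below
#' \code{minFraction} and renormalises.  Raw (pre-renormalisation)
#' fractions are kept in \code{raw_fraction}.
#'
#' @param sized Sized-peak data.frame from [sizePeaks()].
#' @param wtSize Wild-type amplicon size in bp.
#' @param windowBp Half-width of the analysis window around the wild type.
#' @param minFraction Minimum allele fraction retained.
#' @param clusterTolBp Merge tolerance around an integer offset, in bp.
#' @return data.frame sorted by \code{indel_bp} with columns
#'   \code{indel_bp}, \code{mean_size_bp}, \code{fraction},
#'   \code{raw_fraction}, \code{frameshift}, \code{n_peaks_merged}; zero
#'   rows when no peak falls in the window.
#' @examples
#' pk <- data.frame(size_bp = c(287.0, 300.1, 301.2),
#'                  area = c(140, 540, 320))
#' callAlleles(pk, wtSize = 300)
#' @export
callAlleles <- function(sized, wtSize, windowBp = 150, minFraction = 0.005,
                        clusterTolBp = 0.5) {
  if (!is.numeric(wtSize) || wtSize <= 0)
    .idaaError("idaa_parameter_error", "wtSize must be positive")
  empty <- data.frame(indel_bp = integer(0), mean_size_bp = numeric(0),
                      fraction = numeric(0), raw_fraction = numeric(0),
                      frameshift = logical(0), n_peaks_merged = integer(0))
  if (nrow(sized) == 0L) return(empty)
  keep <- abs(sized$size_bp - wtSize) <= windowBp
  sized <- sized[keep, , drop = FALSE]
  if (nrow(sized) == 0L) return(empty)
  offset <- sized$size_bp - wtSize
  indel <- as.integer(.roundAway(offset))
  ## peaks within tolerance of their integer offset merge per integer;
  ## peaks further out remain individual calls at that integer
  near <- abs(offset - indel) <= clusterTolBp
  grp <- ifelse(near, sprintf("i%d", indel),
                sprintf("p%d", seq_along(indel)))
  total <- sum(sized$area)
  rows <- lapply(split(seq_along(grp), grp), function(ix) {
    area <- sum(sized$area[ix])
    data.frame(
      indel_bp = indel[ix][1L],
      mean_size_bp = sum(sized$size_bp[ix] * sized$area[ix]) / area,
      fraction = area / total,
      n_peaks_merged = length(ix)
    )
  })
  out <- do.call(rbind, rows)
  out$raw_fraction <- out$fraction
  out <- out[out$fraction >= minFraction, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out$fraction <- out$fraction / sum(out$fraction)
  out$frameshift <- classifyFrame(out$indel_bp)
  out <- out[order(out$indel_bp, out$mean_size_bp), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("indel_bp", "mean_size_bp", "fraction", "raw_fraction",
          "frameshift", "n_peaks_merged")]
}

.fractionTable <- function(x) {
  if (is(x, "IndelProfile")) x <- x@alleles
  if (is.data.frame(x)) {
    if (nrow(x) == 0L)
      .idaaError("idaa_result_error",
                 "cutting efficiency undefined: no alleles")
    return(data.frame(indel_bp = x$indel_bp, fraction = x$fraction))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    if (length(x) == 0L)
      .idaaError("idaa_result_error",
                 "cutting efficiency undefined: no alleles")
    return(data.frame(indel_bp = as.integer(names(x)), fraction = as.numeric(x)))
  }
  .idaaError("idaa_parameter_error",
             "expected an IndelProfile, allele data.frame or named fraction vector")
}

#' @describeIn cuttingEfficiency Sum of non-wild-type allele fractions of
#'   an allele table or named fraction vector (names = signed indel bp).
#' @examples
#' cuttingEfficiency(c("-13" = 0.14, "0" = 0.54, "1" = 0.32))  # 0.46
#' @export
setMethod("cuttingEfficiency", "ANY", function(x) {
  tab <- .fractionTable(x)
  if (abs(sum(tab$fraction) - 1) > 1e-6)
    .idaaError("idaa_parameter_error", "allele fractions must sum to 1")
  sum(tab$fraction[tab$indel_bp != 0])
})

#' @describeIn cuttingEfficiency Efficiency of a profile's allele table.
#' @export
setMethod("cuttingEfficiency", "IndelProfile", function(x) {
  tab <- .fractionTable(x@alleles)
  sum(tab$fraction[tab$indel_bp != 0])
})

#' Classify a single-cell clone genotype
#'
#' Counts alleles at or above \code{minAlleleFraction} and classifies the
#' clone: \code{wild_type} (only the 0 allele), \code{all_alleles_disrupted}
#' (no 0 allele and every counted allele frame-disrupting — the clones the
#' method is designed to pick out), \code{mono_allelic} (a single in-frame
#' non-zero allele, no wild type), otherwise \code{multi_allelic_mixed}.
#'
#' @param profile An [IndelProfile-class] or allele data.frame.
#' @param maxAlleles Expected ploidy bound; more counted alleles raises a
#'   \code{possible_clone_impurity} flag (not fatal).
#' @param minAlleleFraction Minimum fraction for an allele to count.
#' @return A [CloneGenotype-class].
#' @examples
#' genotypeClone(data.frame(indel_bp = c(-74L, 1L),
#'                          fraction = c(0.5, 0.5),
#'                          frameshift = c(TRUE, TRUE)))
#' @export
genotypeClone <- function(profile, maxAlleles = 4L, minAlleleFraction = 0.15) {
  a <- if (is(profile, "IndelProfile")) profile@alleles else profile
  if (!is.data.frame(a) || nrow(a) == 0L)
    .idaaError("idaa_parameter_error", "profile has no alleles")
  counted <- a[a$fraction >= minAlleleFraction, , drop = FALSE]
  if (nrow(counted) == 0L)      # nothing above threshold: keep the top allele
    counted <- a[which.max(a$fraction), , drop = FALSE]
  flags <- character(0)
  if (nrow(counted) > maxAlleles)
    flags <- c(flags, "possible_clone_impurity")
  fs <- classifyFrame(counted$indel_bp)
  hasWt <- any(counted$indel_bp == 0)
  cls <- if (all(counted$indel_bp == 0)) {
    "wild_type"
  } else if (!hasWt && all(fs)) {
    "all_alleles_disrupted"
  } else if (!hasWt && nrow(counted) == 1L && !fs[1L]) {
    "mono_allelic"
  } else {
    "multi_allelic_mixed"
  }
  frac <- sum(counted$fraction[fs]) / sum(counted$fraction)
  new("CloneGenotype", alleleCount = nrow(counted), classification = cls,
      frameDisruptedFraction = frac, flags = flags)
}
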