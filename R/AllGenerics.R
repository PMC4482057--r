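#' Number of scans in a trace
#' @param x A [Trace-class].
#' @return Integer scan count.
#' @export
setGeneric("scanCount", function(x) standardGeneric("scanCount"))

#' Dye names of a trace
#' @param x A [Trace-class].
#' @return Character vector of dye names, one per channel.
#' @export
setGeneric("dyeNames", function(x) standardGeneric("dyeNames"))

#' Sample name
#' @param x A [Trace-class] or [IndelProfile-class].
#' @return Character sample name.
#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))

#' Extract one intensity channel
#' @param x A [Trace-class].
#' @param which Channel index or dye name (partial, case-insensitive match
#'   on dye names is allowed, e.g. \code{"FAM"} matches \code{"6-FAM"}).
#' @return Numeric vector of per-scan intensities.
#' @export
setGeneric("channel", function(x, which) standardGeneric("channel"))

#' Evaluate a calibration at scan coordinates
#' @param object A [Calibration-class].
#' @param scans Numeric vector of scan coordinates.
#' @return Numeric vector of fragment sizes in bp.
#' @export
setGeneric("predictSize", function(object, scans) standardGeneric("predictSize"))

#' Allele table of a profile
#' @param x An [IndelProfile-class].
#' @return data.frame of allele calls.
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' Cutting efficiency
#'
#' Fraction of amplicon signal carried by non-wild-type alleles, computed
#' from peak areas relative to total peak area.
#'
#' @param x An [IndelProfile-class] or an allele data.frame / named fraction
#'   vector as produced by [callAlleles()].
#' @return Numeric value in [0, 1].
#' @export
setGeneric("cuttingEfficiency", function(x) standardGeneric("cuttingEfficiency"))

#' Expected wild-type labelled-amplicon size
#' @param design An [AssayDesign-class].
#' @return Integer size in bp: amplicon length plus universal extension.
#' @export
setGeneric("expectedWtSize", function(design) standardGeneric("expectedWtSize"))

#' QC flags of a profile
#' @param x An [IndelProfile-class].
#' @return Character vector of QC flags.
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))
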