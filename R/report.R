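## Accessors, show methods, and TSV/JSON report rendering.

#' @describeIn Trace-class Number of scans.
#' @param x A Trace.
#' @export
setMethod("scanCount", "Trace", function(x) nrow(x@intensities))

#' @describeIn Trace-class Dye names, one per channel.
#' @export
setMethod("dyeNames", "Trace", function(x) x@dyeNames)

#' @describeIn Trace-class Sample name.
#' @export
setMethod("sampleName", "Trace", function(x) x@sampleName)

#' @describeIn Trace-class Extract one channel by index or dye name.
#' @param which Channel index or dye-name pattern.
#' @export
setMethod("channel", "Trace", function(x, which) {
  if (is.numeric(which)) {
    if (which < 1 || which > ncol(x@intensities))
      .idaaError("idaa_parameter_error", "channel index out of range")
    return(as.numeric(x@intensities[, which]))
  }
  hit <- grep(which, x@dyeNames, ignore.case = TRUE)
  if (length(hit) == 0L)
    .idaaError("idaa_parameter_error",
               sprintf("no channel matching dye '%s'", which))
  as.numeric(x@intensities[, hit[1L]])
})

#' @describeIn IndelProfile-class Sample name.
#' @param x An IndelProfile.
#' @export
setMethod("sampleName", "IndelProfile", function(x) x@sampleName)

#' @describeIn IndelProfile-class Allele call table.
#' @export
setMethod("alleles", "IndelProfile", function(x) x@alleles)

#' @describeIn IndelProfile-class QC flags.
#' @export
setMethod("qcFlags", "IndelProfile", function(x) x@qcFlags)

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace '%s': %d scans, %d channel(s) [%s]\n",
              object@sampleName, nrow(object@intensities),
              ncol(object@intensities),
              paste(object@dyeNames, collapse = ", ")))
})

setMethod("show", "SizeStandard", function(object) {
  cat(sprintf("SizeStandard '%s': %d fragments, %g-%g bp\n",
              object@name, length(object@sizes),
              min(object@sizes), max(object@sizes)))
})

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration (%s): %d points, scans %.0f-%.0f, sizes %g-%g bp\n",
              object@method, nrow(object@points),
              object@scanRange[1], object@scanRange[2],
              min(object@points$size), max(object@points$size)))
  cat(sprintf("  leave-one-out residuals: max |%.3g| bp\n",
              max(abs(object@residuals))))
})

setMethod("show", "IndelProfile", function(object) {
  cat(sprintf("IndelProfile '%s' (wt %.2f bp, %s)\n", object@sampleName,
              object@wtSize, object@wtSource))
  if (nrow(object@alleles)) {
    a <- object@alleles
    cat(sprintf("  %+d bp: %.1f%%%s\n", a$indel_bp, 100 * a$fraction,
                ifelse(a$frameshift, " (frameshift)", "")), sep = "")
    cat(sprintf("  cutting efficiency: %.1f%%\n", 100 * object@efficiency))
  } else cat("  no allele calls\n")
  if (length(object@qcFlags))
    cat("  QC:", paste(object@qcFlags, collapse = ", "), "\n")
})

setMethod("show", "CloneGenotype", function(object) {
  cat(sprintf("CloneGenotype: %s (%d allele(s), %.0f%% frame-disrupted)\n",
              object@classification, object@alleleCount,
              100 * object@frameDisruptedFraction))
})

setMethod("show", "AssayDesign", function(object) {
  cat(sprintf("AssayDesign on '%s': amplicon [%d, %d) + %d nt extension -> %d bp\n",
              object@referenceId, object@ampliconStart, object@ampliconEnd,
              nchar(object@extension), object@expectedSize))
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf("SimulationSpec: wt %g bp, %d allele(s), %s, %d scans, seed %d\n",
              object@wtSize, length(object@alleles),
              object@standard@name, object@scanCount, object@seed))
})

.profileRows <- function(p) {
  if (nrow(p@alleles) == 0L) {
    return(data.frame(
      sample = p@sampleName, wt_size_bp = sprintf("%.2f", p@wtSize),
      wt_source = p@wtSource, indel_bp = NA_integer_,
      mean_size_bp = NA_character_, fraction = NA_character_,
      raw_fraction = NA_character_, frameshift = NA,
      n_peaks_merged = NA_integer_, cutting_efficiency = NA_character_,
      qc_flags = paste(p@qcFlags, collapse = ";")))
  }
  a <- p@alleles
  data.frame(
    sample = p@sampleName,
    wt_size_bp = sprintf("%.2f", p@wtSize),
    wt_source = p@wtSource,
    indel_bp = a$indel_bp,
    mean_size_bp = sprintf("%.2f", a$mean_size_bp),
    fraction = sprintf("%.4f", a$fraction),
    raw_fraction = sprintf("%.4f", a$raw_fraction),
    frameshift = a$frameshift,
    n_peaks_merged = a$n_peaks_merged,
    cutting_efficiency = sprintf("%.4f", p@efficiency),
    qc_flags = paste(p@qcFlags, collapse = ";"))
}

.profileList <- function(p) {
  list(
    sample = p@sampleName,
    wt_size_bp = p@wtSize,
    wt_source = p@wtSource,
    alleles = p@alleles,
    cutting_efficiency = p@efficiency,
    qc_flags = as.list(p@qcFlags),
    peaks = p@peaks,
    ladder_qc = list(loo_residuals_bp = p@ladderResiduals)
  )
}

#' Render profiles as TSV and/or JSON reports
#'
#' The TSV has exactly one row per (sample, allele), sizes formatted to 2
#' decimals and fractions to 4; the JSON mirror keeps full numeric
#' precision and nests the per-sample peak table, ladder QC, a config echo
#' and the tool version.
#'
#' @param profiles A single [IndelProfile-class] or a list of them.
#' @param prefix Output path prefix; files are \code{<prefix>.tsv} and/or
#'   \code{<prefix>.json}.
#' @param format Subset of \code{c("tsv", "json")}.
#' @param config Optional [idaaConfig()] echoed into the JSON.
#' @return Invisibly, a character vector of the files written.
#' @export
renderReport <- function(profiles, prefix, format = c("tsv", "json"),
                         config = NULL) {
  format <- match.arg(format, several.ok = TRUE)
  if (is(profiles, "IndelProfile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, is, logical(1), "IndelProfile")))
  dir <- dirname(prefix)
  if (!dir.exists(dir))
    .idaaError("idaa_io_error", sprintf("output directory '%s' does not exist", dir))
  written <- character(0)
  if ("tsv" %in% format) {
    tab <- do.call(rbind, lapply(profiles, .profileRows))
    path <- paste0(prefix, ".tsv")
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, path)
  }
  if ("json" %in% format) {
    payload <- list(
      tool = "idaa",
      version = as.character(utils::packageVersion("idaa")),
      config = if (is.null(config)) NULL else unclass(config),
      samples = lapply(profiles, .profileList)
    )
    path <- paste0(prefix, ".json")
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null", na = "null")
    written <- c(written, path)
  }
  invisible(written)
}
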