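## Tri-primer assay design: primer statistics, amplicon location on a
## reference, expected wild-type labelled-amplicon size (amplicon plus the
## universal FAM-primer extension), and PAM-adjacent off-target candidate
## enumeration by Hamming distance.

#' Universal FAM-primer extension sequence
#'
#' The 21-nt non-M13 universal sequence appended 5' to the forward target
#' primer; the 6-FAM-labelled universal primer anneals to it, so the
#' labelled amplicon is the genomic amplicon plus this extension.
#'
#' @format A character string of 21 bases.
#' @export
FamFExtension <- "AGCTGACCGGCAGCAAAATTG"

.checkACGT <- function(seq, what) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    .idaaError("idaa_validation_error", sprintf("%s must be a non-empty sequence", what))
  s <- toupper(seq)
  if (grepl("[^ACGT]", s))
    .idaaError("idaa_validation_error",
               sprintf("%s contains non-ACGT characters", what))
  s
}

#' Primer length and GC content
#'
#' @param seq Primer sequence (ACGT).
#' @return List with \code{length} (bases), \code{gc_percent} (exact
#'   fractional percentage) and \code{gc_display} (rounded to the nearest
#'   integer for reporting).
#' @examples
#' primerStats(FamFExtension)  # length 21, GC 52%
#' @export
primerStats <- function(seq) {
  s <- .checkACGT(seq, "primer")
  n <- nchar(s)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C"))
  pct <- 100 * gc / n
  list(length = n, gc_percent = pct, gc_display = as.integer(round(pct)))
}

.asDNAStringSet <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(toupper(x))
    if (is.null(names(x))) names(out) <- paste0("seq", seq_along(out))
    else names(out) <- names(x)
    return(out)
  }
  .idaaError("idaa_validation_error",
             "expected a DNAStringSet, DNAString, FASTA path or character sequence")
}

#' Locate an amplicon on a reference sequence
#'
#' The forward primer must occur exactly once on the forward strand and the
#' reverse complement of the reverse primer exactly once, downstream of it.
#'
#' @param reference Reference sequence (character, \code{DNAString}, or a
#'   single-sequence FASTA path / \code{DNAStringSet}).
#' @param fwd,rev Primer sequences (ACGT).
#' @return Named numeric vector \code{c(start, end)}: 0-based half-open
#'   amplicon coordinates (fwd match start to just past the rev-complement
#'   match end).
#' @export
locateAmplicon <- function(reference, fwd, rev) {
  fwd <- .checkACGT(fwd, "forward primer")
  rev <- .checkACGT(rev, "reverse primer")
  ref <- .asDNAStringSet(reference)
  if (length(ref) != 1L)
    .idaaError("idaa_design_error", "reference must be a single sequence")
  subject <- ref[[1L]]
  fhits <- Biostrings::matchPattern(fwd, subject)
  if (length(fhits) != 1L)
    .idaaError("idaa_design_error",
               sprintf("forward primer matches the reference %d times (need exactly 1)",
                       length(fhits)))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  rhits <- Biostrings::matchPattern(rc, subject)
  if (length(rhits) != 1L)
    .idaaError("idaa_design_error",
               sprintf("reverse primer matches the reference %d times (need exactly 1)",
                       length(rhits)))
  start0 <- BiocGenerics::start(fhits)[1L] - 1L
  end0 <- BiocGenerics::end(rhits)[1L]
  if (BiocGenerics::start(rhits)[1L] <= BiocGenerics::end(fhits)[1L])
    .idaaError("idaa_design_error",
               "reverse-primer site lies upstream of (or overlaps) the forward primer")
  c(start = start0, end = end0)
}

#' Build a tri-primer assay design
#'
#' @param reference Reference sequence (see [locateAmplicon()]).
#' @param fwd,rev Target-specific primer sequences.
#' @param extension Universal 5' extension on the forward primer; defaults
#'   to [FamFExtension]; \code{""} for an unextended (directly labelled)
#'   design.
#' @param referenceId Reference name recorded in the design.
#' @return An [AssayDesign-class] whose \code{expectedSize} is the amplicon
#'   length plus the extension length.
#' @export
assayDesign <- function(reference, fwd, rev, extension = FamFExtension,
                        referenceId = NULL) {
  if (nzchar(extension)) extension <- .checkACGT(extension, "extension")
  loc <- locateAmplicon(reference, fwd, rev)
  ref <- .asDNAStringSet(reference)
  id <- if (!is.null(referenceId)) referenceId
        else if (!is.null(names(ref))) names(ref)[1L] else "reference"
  new("AssayDesign",
      referenceId = id,
      fwdPrimer = toupper(fwd), revPrimer = toupper(rev),
      extension = extension,
      ampliconStart = as.integer(loc["start"]),
      ampliconEnd = as.integer(loc["end"]),
      expectedSize = as.integer(loc["end"] - loc["start"] + nchar(extension)))
}

#' @describeIn assayDesign Expected wild-type labelled-amplicon size in bp.
#' @param design An [AssayDesign-class].
#' @export
setMethod("expectedWtSize", "AssayDesign", function(design) {
  design@expectedSize
})

## IUPAC nucleotide code expansion over ACGT.
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## Does `site` (plain bases) match the IUPAC `pattern`?  Ambiguous bases in
## the genome never match (they are treated as mismatches).
.iupacMatch <- function(site, pattern) {
  sc <- strsplit(site, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  if (length(sc) != length(pc)) return(FALSE)
  all(mapply(function(s, p) {
    set <- .IUPAC[[p]]
    !is.null(set) && s %in% set
  }, sc, pc))
}

.hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av != bv | !(bv %in% c("A", "C", "G", "T")))
}

## Scan one strand of one contig; returns hits in forward-strand
## coordinates (1-based, as GRanges expects).
.scanStrand <- function(contigSeq, contigName, strand, protospacer, pam,
                        maxMismatch) {
  L <- nchar(protospacer)
  pamLen <- nchar(pam)
  subject <- if (strand == "+") contigSeq
             else Biostrings::reverseComplement(contigSeq)
  hits <- Biostrings::matchPattern(protospacer, subject,
                                   max.mismatch = maxMismatch,
                                   with.indels = FALSE, fixed = TRUE)
  if (length(hits) == 0L) return(NULL)
  st <- BiocGenerics::start(hits)
  en <- BiocGenerics::end(hits)
  ## PAM must be immediately 3' of the protospacer on this strand
  ok <- en + pamLen <= length(subject)
  st <- st[ok]; en <- en[ok]
  if (length(st) == 0L) return(NULL)
  sites <- as.character(Biostrings::extractAt(
    subject, IRanges::IRanges(st, en)))
  pams <- as.character(Biostrings::extractAt(
    subject, IRanges::IRanges(en + 1L, en + pamLen)))
  pamOk <- vapply(pams, .iupacMatch, logical(1), pattern = pam)
  st <- st[pamOk]; en <- en[pamOk]
  sites <- sites[pamOk]; pams <- pams[pamOk]
  if (length(st) == 0L) return(NULL)
  mm <- vapply(sites, .hamming, numeric(1), a = protospacer)
  keep <- mm <= maxMismatch
  st <- st[keep]; en <- en[keep]; sites <- sites[keep]; pams <- pams[keep]
  mm <- mm[keep]
  if (length(st) == 0L) return(NULL)
  if (strand == "-") {
    n <- length(contigSeq)
    fwdStart <- n - en + 1L
    fwdEnd <- n - st + 1L
    st <- fwdStart; en <- fwdEnd
  }
  data.frame(contig = contigName, start = st, end = en, strand = strand,
             mismatches = as.integer(mm), site_sequence = sites,
             pam_sequence = pams, stringsAsFactors = FALSE)
}

#' Enumerate off-target candidate sites
#'
#' Scans both strands of a genome for windows of protospacer length within
#' \code{maxMismatch} Hamming distance of the protospacer whose immediately
#' 3'-adjacent bases match the IUPAC PAM pattern.  Mismatches are counted
#' over the full protospacer (no position weighting, no bulges); ambiguous
#' genome bases count as mismatches and never satisfy the PAM.  Perfect
#' matches (the on-target site) are included and labelled.
#'
#' @param genome FASTA path, \code{DNAStringSet}, or named character vector
#'   of contigs.
#' @param protospacer Protospacer sequence, 15--30 ACGT bases.
#' @param pam IUPAC PAM pattern 3' of the protospacer (default
#'   \code{"NGG"}).
#' @param maxMismatch Maximum Hamming distance.
#' @return A [GenomicRanges::GRanges] sorted by (contig, start) with
#'   metadata columns \code{mismatches}, \code{site_sequence},
#'   \code{pam_sequence}, \code{on_target}.  Minus-strand hits carry
#'   forward-strand (projected) coordinates.
#' @seealso [writeOffTargetsBed()]
#' @export
findOffTargets <- function(genome, protospacer, pam = "NGG", maxMismatch = 4L) {
  protospacer <- .checkACGT(protospacer, "protospacer")
  if (nchar(protospacer) < 15L || nchar(protospacer) > 30L)
    .idaaError("idaa_validation_error", "protospacer length must be 15-30")
  pam <- toupper(pam)
  if (grepl(sprintf("[^%s]", paste(names(.IUPAC), collapse = "")), pam))
    .idaaError("idaa_validation_error", "PAM must use IUPAC codes")
  g <- .asDNAStringSet(genome)
  if (is.null(names(g))) names(g) <- paste0("contig", seq_along(g))
  rows <- list()
  for (i in seq_along(g)) {
    for (s in c("+", "-")) {
      r <- .scanStrand(g[[i]], names(g)[i], s, protospacer, pam, maxMismatch)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }
  if (length(rows) == 0L) {
    return(GenomicRanges::GRanges(
      seqnames = character(0), ranges = IRanges::IRanges(),
      strand = character(0), mismatches = integer(0),
      site_sequence = character(0), pam_sequence = character(0),
      on_target = logical(0)))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$contig, df$start, df$strand), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    mismatches = df$mismatches,
    site_sequence = df$site_sequence,
    pam_sequence = df$pam_sequence,
    on_target = df$mismatches == 0L)
  gr
}

#' Write off-target hits as BED6
#'
#' BED conventions: 0-based half-open coordinates, \code{name} = mismatch
#' count, \code{score} = 0, strand column used.
#'
#' @param hits GRanges from [findOffTargets()].
#' @param path Output BED path.
#' @return Invisibly, \code{path}.
#' @export
writeOffTargetsBed <- function(hits, path) {
  gr <- hits
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = as.character(hits$mismatches),
    score = rep(0L, length(hits)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
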