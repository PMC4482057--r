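## ABIF (Applied Biosystems File Format) reader/writer, restricted to the
## tag subset fragment-analysis .fsa files need: DATA* intensity channels,
## DyeN* dye names, SMPL1 sample name, LANE1.  Layout: big-endian; 4-byte
## magic "ABIF"; int16 version; a 28-byte "tdir" directory-pointer entry;
## directory entries of 28 bytes each (name, int32 number, int16 element
## type, int16 element size, int32 element count, int32 data size, int32
## data offset, int32 handle); data blocks of <= 4 bytes live inline in the
## offset field.

.ABIF_MAGIC <- charToRaw("ABIF")
.ABIF_VERSION <- 101L
.ABIF_DIRSIZE <- 28L
.ABIF_HEADER <- 128L

## --- low-level big-endian readers on a raw vector (1-based offsets) ------

.rd_int <- function(r, at, size, signed = TRUE) {
  readBin(r[at:(at + size - 1L)], "integer", n = 1L, size = size,
          endian = "big", signed = signed)
}

.rd_shorts <- function(r, at, n) {
  if (n == 0L) return(integer(0))
  readBin(r[at:(at + 2L * n - 1L)], "integer", n = n, size = 2L,
          endian = "big", signed = TRUE)
}

.wr_int <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "big")
}

## --- tag payload decoding -------------------------------------------------

.decodeElements <- function(bytes, type, count, name) {
  if (type == 1L) {        # unsigned byte
    as.integer(bytes[seq_len(count)])
  } else if (type == 2L) { # char
    rawToChar(bytes[seq_len(count)])
  } else if (type == 4L) { # short
    .rd_shorts(bytes, 1L, count)
  } else if (type == 5L) { # long (int32)
    if (count == 0L) integer(0)
    else readBin(bytes, "integer", n = count, size = 4L, endian = "big")
  } else if (type == 18L) { # pString: length byte + chars
    len <- as.integer(bytes[1L])
    if (len > 0L) rawToChar(bytes[2L:(1L + len)]) else ""
  } else if (type == 19L) { # cString: NUL-terminated
    nul <- which(bytes == as.raw(0L))[1L]
    if (is.na(nul) || nul == 1L) "" else rawToChar(bytes[seq_len(nul - 1L)])
  } else {
    warning(sprintf("ABIF tag %s: element type %d not decoded, kept as raw bytes",
                    name, type))
    bytes
  }
}

.readDirectory <- function(r, path) {
  if (length(r) < .ABIF_HEADER || !identical(r[1:4], .ABIF_MAGIC))
    .idaaError("idaa_format_error",
               sprintf("'%s' is not an ABIF file (bad magic)", path))
  nEntries <- .rd_int(r, 7L + 12L, 4L)   # tdir element count
  dirOffset <- .rd_int(r, 7L + 20L, 4L)  # tdir data offset
  if (nEntries < 0L ||
      (nEntries > 0L &&
       (dirOffset < 0L ||
        dirOffset + nEntries * .ABIF_DIRSIZE > length(r))))
    .idaaError("idaa_corrupt_error",
               sprintf("'%s': directory truncated or out of bounds", path))
  entries <- vector("list", nEntries)
  for (i in seq_len(nEntries)) {
    at <- dirOffset + (i - 1L) * .ABIF_DIRSIZE + 1L
    name <- rawToChar(r[at:(at + 3L)])
    number <- .rd_int(r, at + 4L, 4L)
    type <- .rd_int(r, at + 8L, 2L)
    elsize <- .rd_int(r, at + 10L, 2L)
    count <- .rd_int(r, at + 12L, 4L)
    datasize <- .rd_int(r, at + 16L, 4L)
    if (datasize <= 4L) {
      bytes <- r[(at + 20L):(at + 20L + max(datasize, 1L) - 1L)]
      if (datasize == 0L) bytes <- raw(0)
    } else {
      offset <- .rd_int(r, at + 20L, 4L)
      if (offset < 0L || offset + datasize > length(r))
        .idaaError("idaa_corrupt_error",
                   sprintf("'%s': data block for tag %s%d truncated",
                           path, name, number))
      bytes <- r[(offset + 1L):(offset + datasize)]
    }
    entries[[i]] <- list(name = name, number = number, type = type,
                         elsize = elsize, count = count,
                         datasize = datasize, bytes = bytes)
  }
  entries
}

#' Read an ABIF (.fsa) fragment-analysis trace
#'
#' Parses the ABIF directory and returns a [Trace-class] holding every
#' \code{DATA} intensity channel present (tags \code{DATA1}..\code{DATA4}
#' and, when present, \code{DATA105} and any further \code{DATA} tags), in
#' ascending tag-number order.  Dye names come from \code{DyeN} tags
#' (\code{DyeN}\emph{k} names the k-th channel in that order); the sample
#' name from \code{SMPL1}.  Remaining decoded tags are retained in
#' \code{metadata}.
#'
#' @param path Path to an ABIF file.
#' @return A [Trace-class].
#' @seealso [writeABIF()], [listABIFTags()]
#' @examples
#' f <- tempfile(fileext = ".fsa")
#' writeABIF(Trace(cbind(c(0, 10, 20, 10, 0)), "6-FAM", "demo"), f)
#' readABIF(f)
#' @export
readABIF <- function(path) {
  if (!file.exists(path))
    .idaaError("idaa_io_error", sprintf("file '%s' does not exist", path))
  r <- readBin(path, "raw", n = file.size(path))
  entries <- .readDirectory(r, path)
  isData <- vapply(entries, function(e) e$name == "DATA", logical(1))
  data <- entries[isData]
  if (length(data)) {
    bad <- vapply(data, function(e) e$type != 4L, logical(1))
    if (any(bad))
      .idaaError("idaa_corrupt_error",
                 sprintf("'%s': DATA%d has element type %d, expected short (4)",
                         path, data[[which(bad)[1]]]$number,
                         data[[which(bad)[1]]]$type))
    ord <- order(vapply(data, `[[`, integer(1), "number"))
    data <- data[ord]
  }
  chans <- lapply(data, function(e) .decodeElements(e$bytes, 4L, e$count, "DATA"))
  lens <- lengths(chans)
  if (length(lens) && length(unique(lens)) > 1L)
    .idaaError("idaa_corrupt_error",
               sprintf("'%s': DATA channels differ in length", path))
  dyeEntries <- entries[vapply(entries, function(e) e$name == "DyeN", logical(1))]
  dyes <- character(0)
  if (length(dyeEntries)) {
    nums <- vapply(dyeEntries, `[[`, integer(1), "number")
    dyes <- vapply(dyeEntries[order(nums)], function(e)
      as.character(.decodeElements(e$bytes, e$type, e$count, "DyeN")),
      character(1))
  }
  dataNums <- vapply(data, `[[`, integer(1), "number")
  dyeNames <- vapply(seq_along(data), function(i) {
    if (i <= length(dyes) && nzchar(dyes[i])) dyes[i]
    else sprintf("DATA%d", dataNums[i])
  }, character(1))
  sampleName <- ""
  meta <- list()
  for (e in entries) {
    if (e$name %in% c("DATA", "DyeN", "tdir")) next
    key <- sprintf("%s%d", e$name, e$number)
    val <- .decodeElements(e$bytes, e$type, e$count, key)
    if (e$name == "SMPL" && e$number == 1L) sampleName <- as.character(val)
    else meta[[key]] <- val
  }
  m <- if (length(chans))
    do.call(cbind, lapply(chans, as.numeric))
  else matrix(numeric(0), 0, 0)
  colnames(m) <- dyeNames
  new("Trace", sampleName = sampleName, intensities = m,
      dyeNames = dyeNames, metadata = meta)
}

#' List the tags of an ABIF file
#'
#' @param path Path to an ABIF file.
#' @return data.frame with one row per directory entry, in file order:
#'   \code{name}, \code{number}, \code{type} (element type code),
#'   \code{size} (element size in bytes), \code{count} (element count).
#' @export
listABIFTags <- function(path) {
  if (!file.exists(path))
    .idaaError("idaa_io_error", sprintf("file '%s' does not exist", path))
  r <- readBin(path, "raw", n = file.size(path))
  entries <- .readDirectory(r, path)
  data.frame(
    name = vapply(entries, `[[`, character(1), "name"),
    number = vapply(entries, `[[`, integer(1), "number"),
    type = vapply(entries, `[[`, integer(1), "type"),
    size = vapply(entries, `[[`, integer(1), "elsize"),
    count = vapply(entries, `[[`, integer(1), "count"),
    stringsAsFactors = FALSE
  )
}

## Build one 28-byte directory entry plus (if needed) its payload.
.abifEntry <- function(name, number, type, elsize, count, bytes) {
  list(name = name, number = as.integer(number), type = as.integer(type),
       elsize = as.integer(elsize), count = as.integer(count),
       bytes = bytes)
}

.pStringBytes <- function(s) {
  ch <- charToRaw(s)
  if (length(ch) > 255L)
    .idaaError("idaa_range_error", "pString longer than 255 bytes")
  c(as.raw(length(ch)), ch)
}

#' Write a Trace as a minimal ABIF (.fsa) file
#'
#' Emits a big-endian ABIF file, version 101: intensity channels as
#' \code{DATA} tags of element type short (channels 1--4 become
#' \code{DATA1}..\code{DATA4}, a 5th becomes \code{DATA105}), dye names as
#' \code{DyeN} pStrings, the sample name as \code{SMPL1}, with the directory
#' placed after the payload.  Files round-trip through [readABIF()] and are
#' readable by third-party ABIF readers.
#'
#' @param trace A [Trace-class]; intensities must be within the signed
#'   16-bit range.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeABIF <- function(trace, path) {
  stopifnot(is(trace, "Trace"))
  m <- trace@intensities
  if (length(m) && (any(m < .INT16_MIN) || any(m > .INT16_MAX)))
    .idaaError("idaa_range_error",
               "intensities outside the signed 16-bit range")
  validObject(trace)
  nch <- ncol(m)
  if (nch > 5L)
    .idaaError("idaa_range_error",
               "writer supports at most 5 channels (DATA1-4, DATA105)")
  dataNums <- c(1L, 2L, 3L, 4L, 105L)[seq_len(nch)]
  entries <- list()
  for (i in seq_len(nch)) {
    bytes <- if (nrow(m) > 0L)
      writeBin(as.integer(m[, i]), raw(), size = 2L, endian = "big")
    else raw(0)
    entries[[length(entries) + 1L]] <-
      .abifEntry("DATA", dataNums[i], 4L, 2L, nrow(m), bytes)
  }
  for (i in seq_len(nch)) {
    pb <- .pStringBytes(trace@dyeNames[i])
    entries[[length(entries) + 1L]] <-
      .abifEntry("DyeN", i, 18L, 1L, length(pb), pb)
  }
  if (nzchar(trace@sampleName)) {
    pb <- .pStringBytes(trace@sampleName)
    entries[[length(entries) + 1L]] <-
      .abifEntry("SMPL", 1L, 18L, 1L, length(pb), pb)
  }
  if (!is.null(trace@metadata$LANE1))
    entries[[length(entries) + 1L]] <-
      .abifEntry("LANE", 1L, 4L, 2L, 1L,
                 .wr_int(trace@metadata$LANE1, 2L))

  payload <- raw(0)
  dirRaw <- raw(0)
  offsetBase <- .ABIF_HEADER
  for (e in entries) {
    datasize <- length(e$bytes)
    if (datasize > 4L) {
      offsetField <- .wr_int(offsetBase + length(payload), 4L)
      payload <- c(payload, e$bytes)
    } else {
      offsetField <- c(e$bytes, raw(4L - datasize))
    }
    dirRaw <- c(dirRaw,
                charToRaw(e$name),
                .wr_int(e$number, 4L),
                .wr_int(e$type, 2L),
                .wr_int(e$elsize, 2L),
                .wr_int(e$count, 4L),
                .wr_int(datasize, 4L),
                offsetField,
                .wr_int(0L, 4L))
  }
  dirOffset <- offsetBase + length(payload)
  tdir <- c(charToRaw("tdir"),
            .wr_int(1L, 4L),
            .wr_int(1023L, 2L),
            .wr_int(.ABIF_DIRSIZE, 2L),
            .wr_int(length(entries), 4L),
            .wr_int(length(entries) * .ABIF_DIRSIZE, 4L),
            .wr_int(dirOffset, 4L),
            .wr_int(0L, 4L))
  header <- c(.ABIF_MAGIC, .wr_int(.ABIF_VERSION, 2L), tdir)
  header <- c(header, raw(.ABIF_HEADER - length(header)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, payload, dirRaw), con)
  invisible(path)
}
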