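# ABIF reader/writer: byte-level conformance against an independently
# constructed fixture, round-trip identity, and error handling.

# Build a minimal ABIF file directly from raw bytes, independently of
# writeABIF, following the published directory layout: 128-byte header
# (magic, version, tdir entry), payload, then the directory.
buildAbifFixture <- function(path, channels, dyes, sample = NULL) {
  be <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                   endian = "big")
  pstr <- function(s) c(as.raw(nchar(s)), charToRaw(s))
  entries <- list()
  payload <- raw(0)
  add <- function(name, number, type, elsize, count, bytes) {
    entries[[length(entries) + 1L]] <<- list(
      name = name, number = number, type = type, elsize = elsize,
      count = count, bytes = bytes)
  }
  for (i in seq_along(channels))
    add("DATA", i, 4L, 2L, length(channels[[i]]),
        be(channels[[i]], 2L))
  for (i in seq_along(dyes))
    add("DyeN", i, 18L, 1L, nchar(dyes[i]) + 1L, pstr(dyes[i]))
  if (!is.null(sample))
    add("SMPL", 1L, 18L, 1L, nchar(sample) + 1L, pstr(sample))
  dirRaw <- raw(0)
  for (e in entries) {
    ds <- length(e$bytes)
    if (ds > 4L) {
      off <- be(128L + length(payload), 4L)
      payload <- c(payload, e$bytes)
    } else off <- c(e$bytes, raw(4L - ds))
    dirRaw <- c(dirRaw, charToRaw(e$name), be(e$number, 4L), be(e$type, 2L),
                be(e$elsize, 2L), be(e$count, 4L), be(ds, 4L), off,
                be(0L, 4L))
  }
  dirOff <- 128L + length(payload)
  hdr <- c(charToRaw("ABIF"), be(101L, 2L), charToRaw("tdir"), be(1L, 4L),
           be(1023L, 2L), be(28L, 2L), be(length(entries), 4L),
           be(length(entries) * 28L, 4L), be(dirOff, 4L), be(0L, 4L))
  writeBin(c(hdr, raw(128L - length(hdr)), payload, dirRaw), path)
  path
}

test_that("reader decodes an independently built byte-level fixture", {
  f <- tempfile(fileext = ".fsa")
  buildAbifFixture(f, list(c(0L, 10L, 20L, 10L, 0L), c(1L, 2L, 3L, 2L, 1L)),
                   c("6-FAM", "LIZ"), sample = "fix01")
  tr <- readABIF(f)
  expect_identical(channel(tr, 1), c(0, 10, 20, 10, 0))
  expect_identical(channel(tr, 2), c(1, 2, 3, 2, 1))
  expect_identical(dyeNames(tr), c("6-FAM", "LIZ"))
  expect_identical(sampleName(tr), "fix01")
  expect_identical(scanCount(tr), 5L)
})

test_that("listABIFTags reports one entry per directory record in file order", {
  f <- tempfile(fileext = ".fsa")
  buildAbifFixture(f, list(1:4, 5:8, 9:12, 13:16), c("A", "B", "C", "D"),
                   sample = "s")
  tags <- listABIFTags(f)
  expect_equal(nrow(tags), 9L)           # 4 DATA + 4 DyeN + SMPL1
  expect_equal(sum(tags$name == "DATA"), 4L)
  expect_true(all(tags$type[tags$name == "DATA"] == 4L))
  expect_true(all(tags$count[tags$name == "DATA"] == 4L))
})

test_that("bad magic raises a format error and truncation a corruption error", {
  f <- tempfile(fileext = ".fsa")
  writeBin(c(charToRaw("XXXX"), raw(200)), f)
  expect_error(readABIF(f), class = "idaa_format_error")
  expect_error(readABIF(tempfile()), class = "idaa_io_error")
  # truncate a valid file inside its payload
  g <- tempfile(fileext = ".fsa")
  buildAbifFixture(g, list(1:5000), "FAM")
  r <- readBin(g, "raw", file.size(g))
  writeBin(r[1:2000], g)
  expect_error(readABIF(g), class = "idaa_corrupt_error")
})

test_that("write-read round trip is the identity on all Trace fields", {
  set.seed(42)
  lens <- c(0L, 1L, 7L, 1000L, 10000L)
  for (n in lens) {
    nch <- sample(1:5, 1)
    m <- matrix(sample(-32768:32767, n * nch, replace = TRUE), ncol = nch)
    tr <- Trace(m, dyeNames = paste0("dye", seq_len(nch)),
                sampleName = sprintf("rt_%d", n))
    f <- tempfile(fileext = ".fsa")
    writeABIF(tr, f)
    back <- readABIF(f)
    expect_identical(unname(back@intensities), unname(tr@intensities))
    expect_identical(dyeNames(back), dyeNames(tr))
    expect_identical(sampleName(back), sampleName(tr))
    expect_identical(scanCount(back), nrow(m))
    unlink(f)
  }
})

test_that("reader never drops a DATA tag present in the directory", {
  f <- tempfile(fileext = ".fsa")
  buildAbifFixture(f, list(1:10, 11:20, 21:30, 31:40, 41:50),
                   c("a", "b", "c", "d", "e"))
  tr <- readABIF(f)
  expect_equal(ncol(tr@intensities), 5L)
  expect_identical(channel(tr, 5), as.numeric(41:50))
})

test_that("file size follows from the stated record layout", {
  n <- 5000L
  tr <- Trace(matrix(0L, n, 2), dyeNames = c("6-FAM", "LIZ"))
  f <- tempfile(fileext = ".fsa")
  writeABIF(tr, f)
  # header 128 + 2 channels of 2n bytes + the "6-FAM" pString (6 bytes, in
  # the payload) + 4 directory entries of 28 bytes; the 4-byte "LIZ"
  # pString is stored inline in its directory entry's offset field
  expect_identical(file.size(f), 128 + 2 * (2 * n) + 6 + 4 * 28)
})

test_that("out-of-range intensities are rejected at construction and write", {
  expect_error(Trace(cbind(c(0, 40000)), dyeNames = "FAM"),
               "16-bit")
  tr <- Trace(cbind(c(0, 100)), dyeNames = "FAM")
  slot(tr, "intensities", check = FALSE) <- cbind(c(0, 40000))
  expect_error(writeABIF(tr, tempfile()), class = "idaa_range_error")
})

test_that("degenerate zero-scan traces still round-trip", {
  tr <- Trace(matrix(numeric(0), 0, 2), dyeNames = c("x", "y"), sampleName = "empty")
  f <- tempfile(fileext = ".fsa")
  writeABIF(tr, f)
  back <- readABIF(f)
  expect_identical(scanCount(back), 0L)
  expect_identical(dyeNames(back), c("x", "y"))
  expect_identical(sampleName(back), "empty")
})
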