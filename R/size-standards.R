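#' Load a size standard
#'
#' Built-in standards are the manufacturer fragment tables for the GeneScan
#' LIZ500 (16 fragments, 35--500 bp) and LIZ600 (36 fragments, 20--600 bp)
#' dye-labelled ladders.  A path to a TSV file with a \code{size_bp} column
#' (one fragment size per line) defines a custom standard.
#'
#' @param x Standard name (\code{"LIZ500"}, \code{"LIZ600"}), a TSV path, or
#'   a numeric vector of fragment sizes.
#' @param name Name to record when \code{x} is a path or numeric vector.
#' @return A [SizeStandard-class].
#' @examples
#' sizeStandard("LIZ500")
#' @export
sizeStandard <- function(x, name = NULL) {
  if (is.numeric(x)) {
    return(new("SizeStandard", name = if (is.null(name)) "custom" else name,
               sizes = as.numeric(sort(x))))
  }
  stopifnot(is.character(x), length(x) == 1L)
  builtin <- c("LIZ500", "LIZ600")
  if (toupper(x) %in% builtin) {
    path <- system.file("extdata", "size_standards",
                        paste0(toupper(x), ".tsv"), package = "idaa",
                        mustWork = TRUE)
    nm <- toupper(x)
  } else {
    if (!file.exists(x))
      .idaaError("idaa_io_error",
                 sprintf("size standard '%s': not a built-in name and no such file", x))
    path <- x
    nm <- if (is.null(name)) basename(x) else name
  }
  tab <- utils::read.delim(path)
  if (!"size_bp" %in% names(tab))
    .idaaError("idaa_format_error",
               sprintf("size-standard TSV '%s' must have a 'size_bp' column", path))
  new("SizeStandard", name = nm, sizes = as.numeric(tab$size_bp))
}
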