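#' GenomeMap: chromosome lengths plus a marker physical map
#'
#' Container for the physical frame of an SSSL experiment: the chromosome
#' lengths of the reference genome and the 1-based point positions of the
#' SSR markers that delimit substituted segments.
#'
#' @slot chromosomes data.frame with columns `chrom` (character) and
#'   `length` (bp, numeric).
#' @slot markers data.frame with columns `name`, `chrom`, `pos` (bp).
#' @export
setClass("GenomeMap",
  slots = c(chromosomes = "data.frame", markers = "data.frame"))

setValidity("GenomeMap", function(object) {
  ch <- object@chromosomes
  mk <- object@markers
  msg <- character()
  if (!all(c("chrom", "length") %in% names(ch)))
    msg <- c(msg, "chromosomes must have columns 'chrom' and 'length'")
  else {
    if (anyDuplicated(ch$chrom))
      msg <- c(msg, "chromosome ids must be unique")
    if (any(is.na(ch$length)) || any(ch$length <= 0))
      msg <- c(msg, "chromosome lengths must be > 0")
  }
  if (!all(c("name", "chrom", "pos") %in% names(mk)))
    msg <- c(msg, "markers must have columns 'name', 'chrom', 'pos'")
  else if (nrow(mk)) {
    if (anyDuplicated(mk$name))
      msg <- c(msg, "marker names must be unique")
    if (any(is.na(mk$pos)) || any(mk$pos < 1))
      msg <- c(msg, "marker positions must be >= 1")
    i <- match(mk$chrom, ch$chrom)
    if (anyNA(i))
      msg <- c(msg, "marker on unknown chromosome: ",
               mk$name[which(is.na(i))[1L]])
    else if (any(mk$pos > ch$length[i]))
      msg <- c(msg, "marker position beyond chromosome end: ",
               mk$name[which(mk$pos > ch$length[i])[1L]])
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a GenomeMap
#'
#' @param chromosomes data.frame with columns `chrom`, `length` (bp).
#' @param markers optional data.frame with columns `name`, `chrom`, `pos`.
#' @return a [GenomeMap-class] object.
#' @examples
#' gm <- GenomeMap(data.frame(chrom = "Chr01", length = 4e7),
#'                 data.frame(name = "RM001", chrom = "Chr01", pos = 1.5e6))
#' @export
GenomeMap <- function(chromosomes,
                      markers = data.frame(name = character(),
                                           chrom = character(),
                                           pos = numeric())) {
  chromosomes <- data.frame(chrom = as.character(chromosomes$chrom),
                            length = as.numeric(chromosomes$length),
                            stringsAsFactors = FALSE)
  markers <- data.frame(name = as.character(markers$name),
                        chrom = as.character(markers$chrom),
                        pos = as.numeric(markers$pos),
                        stringsAsFactors = FALSE)
  markers <- markers[order(match(markers$chrom, chromosomes$chrom),
                           markers$pos), , drop = FALSE]
  rownames(markers) <- NULL
  new("GenomeMap", chromosomes = chromosomes, markers = markers)
}

#' @describeIn GenomeMap-class named vector of chromosome lengths (bp).
#' @param x a `GenomeMap`.
#' @export
chromLengths <- function(x) {
  stopifnot(is(x, "GenomeMap"))
  setNames(x@chromosomes$length, x@chromosomes$chrom)
}

#' @describeIn GenomeMap-class total genome length (bp), the denominator of
#'   coverage percentages.
#' @export
genomeSize <- function(x) {
  stopifnot(is(x, "GenomeMap"))
  sum(x@chromosomes$length)
}

#' @describeIn GenomeMap-class the marker table (sorted by chromosome then
#'   position).
#' @export
markerTable <- function(x) {
  stopifnot(is(x, "GenomeMap"))
  x@markers
}

setMethod("show", "GenomeMap", function(object) {
  cat("GenomeMap:", nrow(object@chromosomes), "chromosomes,",
      format(genomeSize(object), big.mark = ","), "bp;",
      nrow(object@markers), "markers\n")
})

#' Read a genome map from TSV files
#'
#' `genome` is a TSV with columns `chrom`, `length_bp`; `markers` (optional)
#' a TSV with columns `name`, `chrom`, `pos_bp` (1-based).
#'
#' @param genome path to the chromosome-length TSV.
#' @param markers optional path to the marker TSV.
#' @return a [GenomeMap-class].
#' @export
readGenomeMap <- function(genome, markers = NULL) {
  g <- read.delim(genome, stringsAsFactors = FALSE)
  if (!all(c("chrom", "length_bp") %in% names(g)))
    stop("genome TSV needs columns 'chrom' and 'length_bp'")
  ch <- data.frame(chrom = g$chrom, length = g$length_bp)
  mk <- if (is.null(markers)) {
    data.frame(name = character(), chrom = character(), pos = numeric())
  } else {
    m <- read.delim(markers, stringsAsFactors = FALSE)
    if (!all(c("name", "chrom", "pos_bp") %in% names(m)))
      stop("marker TSV needs columns 'name', 'chrom', 'pos_bp'")
    data.frame(name = m$name, chrom = m$chrom, pos = m$pos_bp)
  }
  GenomeMap(ch, mk)
}

#' Packaged rice reference chromosome lengths
#'
#' Convenience loader for the shipped IRGSP-1.0 chromosome-length table
#' (12 chromosomes, ~373.2 Mb), the usual denominator for rice coverage
#' statistics.
#'
#' @return a [GenomeMap-class] with no markers.
#' @export
riceGenome <- function() {
  readGenomeMap(system.file("extdata", "genome_rice.tsv", package = "sslmap",
                            mustWork = TRUE))
}
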