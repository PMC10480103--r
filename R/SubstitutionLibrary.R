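#' SubstitutionLibrary: one donor segment per line
#'
#' A population of single segment substitution lines (SSSLs): every line
#' carries exactly one homozygous donor segment in a common recipient
#' background. Segments are stored as a `GRanges` in marker point
#' coordinates (see [segmentLength()]) with `line_id` names.
#'
#' @slot recipient recipient cultivar label.
#' @slot donor donor accession label.
#' @slot segments `GRanges`, one range per line, names = line ids.
#' @export
setClass("SubstitutionLibrary",
  slots = c(recipient = "character", donor = "character",
            segments = "GRanges"))

setValidity("SubstitutionLibrary", function(object) {
  gr <- object@segments
  msg <- character()
  if (length(object@recipient) != 1L || length(object@donor) != 1L)
    msg <- c(msg, "recipient and donor must be single labels")
  if (length(gr)) {
    ids <- names(gr)
    if (is.null(ids) || anyNA(ids) || anyDuplicated(ids))
      msg <- c(msg, "line ids must be present and unique")
    if (any(GenomicRanges::start(gr) >= GenomicRanges::end(gr)))
      msg <- c(msg, "all segments must satisfy start < end")
    if (any(GenomicRanges::start(gr) < 1))
      msg <- c(msg, "segment start coordinates must be >= 1")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a SubstitutionLibrary
#'
#' @param lines data.frame with columns `line_id`, `chrom`, `start_bp`,
#'   `end_bp` (1-based marker point coordinates, start < end).
#' @param donor donor label.
#' @param recipient recipient label (default `"HJX74"`).
#' @return a [SubstitutionLibrary-class].
#' @examples
#' lib <- SubstitutionLibrary(
#'   data.frame(line_id = "SN58", chrom = "Chr04",
#'              start_bp = 33031813, end_bp = 35336720),
#'   donor = "NIV1")
#' @export
SubstitutionLibrary <- function(lines, donor, recipient = "HJX74") {
  need <- c("line_id", "chrom", "start_bp", "end_bp")
  if (!all(need %in% names(lines)))
    stop("'lines' needs columns ", paste(need, collapse = ", "))
  gr <- .makeSegments(lines$chrom, lines$start_bp, lines$end_bp,
                      line_id = lines$line_id)
  new("SubstitutionLibrary", recipient = as.character(recipient),
      donor = as.character(donor), segments = gr)
}

#' @describeIn SubstitutionLibrary-class the segments as a `GRanges` in point
#'   coordinates, names = line ids.
#' @param x a `SubstitutionLibrary`.
#' @export
segmentRanges <- function(x) {
  stopifnot(is(x, "SubstitutionLibrary"))
  x@segments
}

#' @describeIn SubstitutionLibrary-class line identifiers.
#' @export
lineIds <- function(x) names(segmentRanges(x))

#' @describeIn SubstitutionLibrary-class number of lines.
#' @export
nLines <- function(x) length(segmentRanges(x))

#' @describeIn SubstitutionLibrary-class donor label.
#' @export
donor <- function(x) {
  stopifnot(is(x, "SubstitutionLibrary"))
  x@donor
}

#' @describeIn SubstitutionLibrary-class recipient label.
#' @export
recipient <- function(x) {
  stopifnot(is(x, "SubstitutionLibrary"))
  x@recipient
}

setMethod("show", "SubstitutionLibrary", function(object) {
  n <- nLines(object)
  cat("SubstitutionLibrary:", n, "lines; donor", object@donor,
      "in", object@recipient, "background\n")
  if (n) {
    len <- segmentLength(object@segments)
    cat("  segment length: mean", toMb(mean(len)), "Mb, range",
        toMb(min(len)), "-", toMb(max(len)), "Mb\n")
  }
})

## error (naming the offending line) if any segment leaves genome bounds
.checkBounds <- function(library, genome) {
  gr <- segmentRanges(library)
  if (length(gr) == 0L) return(invisible(TRUE))
  lens <- chromLengths(genome)
  ch <- as.character(GenomicRanges::seqnames(gr))
  unknown <- !(ch %in% names(lens))
  if (any(unknown))
    stop("line ", names(gr)[which(unknown)[1L]],
         " has a segment on unknown chromosome '", ch[which(unknown)[1L]], "'")
  over <- GenomicRanges::end(gr) > lens[ch]
  if (any(over))
    stop("line ", names(gr)[which(over)[1L]],
         " has a segment beyond the end of ", ch[which(over)[1L]])
  invisible(TRUE)
}

#' Read substitution segments from a TSV
#'
#' The segments TSV has columns `line_id`, `donor`, `chrom`, `start_bp`,
#' `end_bp` (1-based point coordinates). One `SubstitutionLibrary` is
#' returned per donor.
#'
#' @param path path to the segments TSV.
#' @param recipient recipient label.
#' @return named list of [SubstitutionLibrary-class], one per donor.
#' @export
readSegments <- function(path, recipient = "HJX74") {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("line_id", "donor", "chrom", "start_bp", "end_bp")
  if (!all(need %in% names(d)))
    stop("segments TSV needs columns ", paste(need, collapse = ", "))
  out <- lapply(split(d, d$donor), function(dd)
    SubstitutionLibrary(dd, donor = dd$donor[1L], recipient = recipient))
  out[unique(d$donor)]
}

#' Write substitution segments to TSV / BED
#'
#' `writeSegmentsTsv` writes the canonical point-coordinate TSV;
#' `writeSegmentsBed` exports 0-based half-open BED (under the point
#' convention the BED start equals the TSV start and the BED end equals the
#' TSV end), with the line id in the name column.
#'
#' @param libraries a `SubstitutionLibrary` or list of them.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSegmentsTsv <- function(libraries, path) {
  if (is(libraries, "SubstitutionLibrary")) libraries <- list(libraries)
  rows <- do.call(rbind, lapply(libraries, function(lib) {
    gr <- segmentRanges(lib)
    data.frame(line_id = names(gr), donor = donor(lib),
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start_bp = GenomicRanges::start(gr),
               end_bp = GenomicRanges::end(gr))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSegmentsTsv
#' @export
writeSegmentsBed <- function(libraries, path) {
  if (is(libraries, "SubstitutionLibrary")) libraries <- list(libraries)
  rows <- do.call(rbind, lapply(libraries, function(lib) {
    gr <- segmentRanges(lib)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),  # 0-based half-open == (s,e]
               end = GenomicRanges::end(gr),
               name = names(gr))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
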