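## Segment coordinate convention -------------------------------------------
##
## Externally, a substituted segment is written with the 1-based point
## coordinates of its two delimiting markers, (start, end), start < end, and
## its length is end - start: a 20,286,300-21,478,312 bp interval is 1.19 Mb.
## Equivalently the segment is the half-open base-pair set (start, end].
## Internally every operation converts to closed integer ranges
## [start + 1, end] so that IRanges arithmetic is exact, and converts back.
## Two segments that merely share a marker endpoint do not overlap.

.toHO <- function(gr) {
  IRanges::IRanges(start = GenomicRanges::start(gr) + 1L,
                   end = GenomicRanges::end(gr))
}

.fromHO <- function(ir, chrom) {
  if (length(ir) == 0L) return(.emptySegments())
  GenomicRanges::GRanges(
    seqnames = rep(chrom, length(ir)),
    ranges = IRanges::IRanges(start = IRanges::start(ir) - 1L,
                              end = IRanges::end(ir)))
}

## assemble per-chromosome half-open closed IRanges into one sorted GRanges
## in point coordinates (sorted seqlevels keep results order-invariant)
.bindHO <- function(pieces) {
  pieces <- pieces[vapply(pieces, function(p) length(p$ir) > 0L, TRUE)]
  if (length(pieces) == 0L) return(.emptySegments())
  chrom <- unlist(lapply(pieces, function(p)
    rep(p$chrom, length(p$ir))))
  st <- unlist(lapply(pieces, function(p) IRanges::start(p$ir)))
  en <- unlist(lapply(pieces, function(p) IRanges::end(p$ir)))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = sort(unique(chrom))),
    ranges = IRanges::IRanges(start = st - 1L, end = en))
  sort(gr)
}

.emptySegments <- function() GenomicRanges::GRanges()

## construct a segment GRanges from point coordinates, with validation
.makeSegments <- function(chrom, start, end, line_id = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("segment coordinates must not be NA")
  if (any(start < 1))
    stop("segment start coordinates must be >= 1")
  bad <- which(start >= end)
  if (length(bad))
    stop("degenerate segment (start >= end): ",
         paste0(chrom[bad[1L]], ":", start[bad[1L]], "-", end[bad[1L]]))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = start, end = end))
  if (!is.null(line_id)) {
    S4Vectors::mcols(gr)$line_id <- as.character(line_id)
    names(gr) <- as.character(line_id)
  }
  gr
}

#' Segment lengths under the point-coordinate convention
#'
#' A segment delimited by marker positions (start, end) spans end - start
#' base pairs (the half-open set (start, end]); this is the convention under
#' which the printed marker coordinates of mapped loci reproduce their
#' printed Mb sizes.
#'
#' @param segments a `GRanges` of segments in point coordinates.
#' @return numeric vector of lengths in bp.
#' @examples
#' seg <- GenomicRanges::GRanges("Chr08", IRanges::IRanges(20286300, 21478312))
#' segmentLength(seg)        # 1192012
#' toMb(segmentLength(seg))  # 1.19
#' @export
segmentLength <- function(segments) {
  GenomicRanges::end(segments) - GenomicRanges::start(segments)
}

#' Union of segments
#'
#' Returns the minimal disjoint cover of a set of segments (the "coverage"
#' of a set of substituted segments). Segments touching at a shared marker
#' position are merged in the union (the result is canonical: sorted,
#' disjoint, non-adjacent), although they do not count as overlapping.
#'
#' @param segments `GRanges` of segments in point coordinates (any mix of
#'   chromosomes).
#' @return canonical `GRanges` in point coordinates.
#' @seealso [segmentIntersect()], [segmentSubtract()]
#' @export
segmentUnion <- function(segments) {
  if (length(segments) == 0L) return(.emptySegments())
  chroms <- as.character(GenomicRanges::seqnames(segments))
  .bindHO(lapply(unique(chroms), function(ch)
    # default min.gapwidth merges touching segments
    list(chrom = ch, ir = IRanges::reduce(.toHO(segments[chroms == ch])))))
}

#' Common region of a set of segments
#'
#' Positions present in every input segment; the "overlapped interval" used
#' in substitution mapping. All segments must lie on one chromosome.
#'
#' @param segments non-empty `GRanges`, all on one chromosome.
#' @return canonical `GRanges` (possibly empty) in point coordinates.
#' @export
segmentIntersect <- function(segments) {
  if (length(segments) == 0L)
    stop("'segments' must be non-empty")
  chroms <- unique(as.character(GenomicRanges::seqnames(segments)))
  if (length(chroms) != 1L)
    stop("segments span multiple chromosomes: ",
         paste(chroms, collapse = ", "))
  acc <- .toHO(segments[1L])
  for (i in seq_along(segments)[-1L]) {
    acc <- IRanges::intersect(acc, .toHO(segments[i]))
    if (length(acc) == 0L) break
  }
  .fromHO(acc, chroms)
}

#' Subtract segments from an interval set
#'
#' Positions of `base` not covered by any segment of `minus` (exclusion of
#' non-carrier segments in substitution mapping). Subtraction only applies
#' per chromosome; a `minus` segment sharing just a boundary marker with
#' `base` removes nothing.
#'
#' @param base canonical `GRanges` in point coordinates.
#' @param minus `GRanges` of segments to remove.
#' @return canonical `GRanges` in point coordinates.
#' @export
segmentSubtract <- function(base, minus) {
  if (length(base) == 0L) return(.emptySegments())
  if (length(minus) == 0L) return(sort(segmentUnion(base)))
  bch <- as.character(GenomicRanges::seqnames(base))
  mch <- as.character(GenomicRanges::seqnames(minus))
  .bindHO(lapply(unique(bch), function(ch) {
    bho <- IRanges::reduce(.toHO(base[bch == ch]))
    m <- minus[mch == ch]
    if (length(m))
      bho <- IRanges::setdiff(bho, IRanges::reduce(.toHO(m)))
    list(chrom = ch, ir = bho)
  }))
}

#' Spatial relation between two segments
#'
#' Classifies an (outer, inner) pair as `"contained"` (inner fully inside
#' outer), `"overlap"` (some shared base pairs) or `"disjoint"`, reporting
#' the gap between nearest endpoints when disjoint on the same chromosome.
#' Segments on different chromosomes are disjoint with an undefined gap
#' (`NA`), flagged via `same_chrom`.
#'
#' @param outer,inner single-range `GRanges` in point coordinates.
#' @return list with elements `relation`, `gap` (bp or NA) and `same_chrom`.
#' @examples
#' outer <- GenomicRanges::GRanges("Chr07", IRanges::IRanges(2679666, 3555628))
#' prog1 <- GenomicRanges::GRanges("Chr07", IRanges::IRanges(2839476, 2839979))
#' segmentRelation(outer, prog1)$relation # "contained"
#' @export
segmentRelation <- function(outer, inner) {
  stopifnot(length(outer) == 1L, length(inner) == 1L)
  och <- as.character(GenomicRanges::seqnames(outer))
  ich <- as.character(GenomicRanges::seqnames(inner))
  if (och != ich)
    return(list(relation = "disjoint", gap = NA_real_, same_chrom = FALSE))
  os <- GenomicRanges::start(outer); oe <- GenomicRanges::end(outer)
  is <- GenomicRanges::start(inner); ie <- GenomicRanges::end(inner)
  if (is >= os && ie <= oe)
    return(list(relation = "contained", gap = 0, same_chrom = TRUE))
  if (max(os, is) < min(oe, ie))   # non-empty half-open intersection
    return(list(relation = "overlap", gap = 0, same_chrom = TRUE))
  gap <- if (is >= oe) is - oe else os - ie
  list(relation = "disjoint", gap = as.numeric(gap), same_chrom = TRUE)
}

## total bp in a canonical (or any) segment set, counted once per position
.coverageLength <- function(segments) {
  sum(segmentLength(segmentUnion(segments)))
}
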