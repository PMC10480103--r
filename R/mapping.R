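#' MappedLocus: a trait mapped to a physical candidate interval
#'
#' Result of substitution mapping: the positions compatible with every
#' phenotype observation under a single-locus, fully penetrant model — the
#' common region of all carrier-line segments minus every non-carrier
#' segment on the same chromosome. Normally a single interval; when the
#' exclusions split the region, all sub-intervals are kept and the locus is
#' flagged ambiguous.
#'
#' @slot trait trait label.
#' @slot chrom chromosome id.
#' @slot intervals `GRanges` (point coordinates), one or more sub-intervals.
#' @slot lengthMb Mb length of each sub-interval (via [toMb()]).
#' @slot leftMarker,rightMarker flanking marker names per sub-interval
#'   (`NA` when the map has no marker on that side).
#' @slot carriers,excluders line ids: carriers define the common region;
#'   excluders are the non-carriers whose segments trimmed it.
#' @slot ambiguous `TRUE` when more than one sub-interval survived.
#' @export
setClass("MappedLocus",
  slots = c(trait = "character", chrom = "character",
            intervals = "GRanges", lengthMb = "numeric",
            leftMarker = "character", rightMarker = "character",
            carriers = "character", excluders = "character",
            ambiguous = "logical"))

setMethod("show", "MappedLocus", function(object) {
  cat("MappedLocus:", object@trait, "on", object@chrom,
      if (object@ambiguous) "(ambiguous)" else "", "\n")
  s <- GenomicRanges::start(object@intervals)
  e <- GenomicRanges::end(object@intervals)
  for (i in seq_along(object@intervals))
    cat(sprintf("  %s:%s-%s  %.2f Mb  [%s - %s]\n", object@chrom,
                format(s[i], big.mark = ","), format(e[i], big.mark = ","),
                object@lengthMb[i], object@leftMarker[i],
                object@rightMarker[i]))
  cat("  carriers:", paste(object@carriers, collapse = ", "), "\n")
  if (length(object@excluders))
    cat("  excluders:", paste(object@excluders, collapse = ", "), "\n")
})

#' @describeIn MappedLocus-class the (first) mapped interval as a `GRanges`.
#' @param x a `MappedLocus`.
#' @export
locusInterval <- function(x) {
  stopifnot(is(x, "MappedLocus"))
  x@intervals[1L]
}

#' @describeIn MappedLocus-class one row per sub-interval, TSV-ready.
#' @export
lociTable <- function(x) {
  if (is(x, "MappedLocus")) x <- list(x)
  do.call(rbind, lapply(x, function(l)
    data.frame(trait = l@trait, chrom = l@chrom,
               start_bp = GenomicRanges::start(l@intervals),
               end_bp = GenomicRanges::end(l@intervals),
               length_mb = l@lengthMb,
               left_marker = l@leftMarker, right_marker = l@rightMarker,
               carriers = paste(l@carriers, collapse = ","),
               excluders = paste(l@excluders, collapse = ","),
               ambiguous = l@ambiguous)))
}

#' Read binary trait observations
#'
#' TSV with columns `line_id`, `trait`, `state` (1 = donor-like phenotype,
#' 0 = recipient-like). One state per (line, trait).
#'
#' @param path path to the phenotype TSV.
#' @return data.frame with those columns.
#' @export
readPhenotypes <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("line_id", "trait", "state")
  if (!all(need %in% names(d)))
    stop("phenotype TSV needs columns ", paste(need, collapse = ", "))
  .checkObs(d)
  d
}

.checkObs <- function(obs) {
  need <- c("line_id", "trait", "state")
  if (!all(need %in% names(obs)))
    stop("observations need columns ", paste(need, collapse = ", "))
  if (!all(obs$state %in% c(0L, 1L)))
    stop("phenotype states must be 0 or 1")
  if (anyDuplicated(obs[c("line_id", "trait")]))
    stop("more than one state for some (line, trait) pair")
  invisible(obs)
}

.carrierIds <- function(obs, trait)
  obs$line_id[obs$trait == trait & obs$state == 1L]
.nonCarrierIds <- function(obs, trait)
  obs$line_id[obs$trait == trait & obs$state == 0L]

#' Group carrier lines into independent loci
#'
#' Carriers of a binary trait are grouped by chromosome and then into
#' connected components of the segment-overlap graph; each component is a
#' candidate locus (two components on different chromosomes, or disjoint on
#' one chromosome, are mapped independently). Segments that merely share a
#' boundary marker do not connect.
#'
#' @param library a [SubstitutionLibrary-class].
#' @param obs phenotype observations (see [readPhenotypes()]).
#' @param trait trait label.
#' @return list of groups, each a list with elements `chrom` and `lines`.
#' @export
groupCarriers <- function(library, obs, trait) {
  .checkObs(obs)
  ids <- intersect(.carrierIds(obs, trait), lineIds(library))
  if (length(ids) == 0L)
    stop("trait '", trait, "' has no carrier lines")
  gr <- segmentRanges(library)[ids]
  ch <- as.character(GenomicRanges::seqnames(gr))
  out <- list()
  for (c1 in unique(ch)) {
    sub <- gr[ch == c1]
    ho <- .toHO(sub)
    ## blocks of strict overlap: adjacency (touching markers) kept apart
    blocks <- IRanges::reduce(ho, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ho, blocks, type = "within")
    comp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    for (b in sort(unique(comp)))
      out[[length(out) + 1L]] <- list(chrom = c1,
                                      lines = names(sub)[comp == b])
  }
  out
}

#' Flanking markers of an interval
#'
#' The left flank is the marker with the greatest position at or before the
#' interval start on its chromosome; the right flank the marker with the
#' least position at or after the interval end. `NA` when no such marker
#' exists on that side.
#'
#' @param interval single-range `GRanges` in point coordinates.
#' @param genome a [GenomeMap-class] carrying the marker map.
#' @return list with `left` and `right` marker names (or `NA`).
#' @export
flankingMarkers <- function(interval, genome) {
  stopifnot(length(interval) == 1L, is(genome, "GenomeMap"))
  mk <- markerTable(genome)
  mk <- mk[mk$chrom == as.character(GenomicRanges::seqnames(interval)), ,
           drop = FALSE]
  s <- GenomicRanges::start(interval); e <- GenomicRanges::end(interval)
  left <- mk$name[mk$pos <= s]
  right <- mk$name[mk$pos >= e]
  list(left = if (length(left)) left[length(left)] else NA_character_,
       right = if (length(right)) right[1L] else NA_character_)
}

#' Substitution mapping of one carrier group
#'
#' Maps a trait locus from one carrier group: the candidate interval is the
#' intersection of all carrier segments minus the union of the segments of
#' every non-carrier line (state 0) on the same chromosome. Non-carriers
#' whose segments do not touch the carriers' common region are recorded
#' nowhere — they carry no information about the locus. Flanking markers and
#' Mb lengths are attached per surviving sub-interval.
#'
#' With `maxConflicts = k > 0` the single-locus model is relaxed: up to `k`
#' observations among the constraining lines (carriers and trimming
#' non-carriers) may be discarded, and the largest surviving interval set is
#' reported. The default 0 assumes noise-free phenotypes.
#'
#' @param group one element of [groupCarriers()] output (or a character
#'   vector of carrier line ids).
#' @param library a [SubstitutionLibrary-class].
#' @param obs phenotype observations.
#' @param genome a [GenomeMap-class] (markers used for flanks).
#' @param trait trait label (defaults to the single trait present in `obs`).
#' @param maxConflicts allowed phenotype conflicts (small integer).
#' @return a [MappedLocus-class].
#' @export
mapLocus <- function(group, library, obs, genome, trait = NULL,
                     maxConflicts = 0L) {
  .checkObs(obs)
  if (is.null(trait)) {
    tr <- unique(obs$trait)
    if (length(tr) != 1L)
      stop("'trait' must be given when obs has several traits")
    trait <- tr
  }
  carriers <- if (is.list(group)) group$lines else as.character(group)
  if (length(carriers) == 0L)
    stop("carrier group is empty")
  gr <- segmentRanges(library)
  if (!all(carriers %in% names(gr)))
    stop("unknown carrier line id")
  segs <- gr[carriers]
  chrom <- unique(as.character(GenomicRanges::seqnames(segs)))
  if (length(chrom) != 1L)
    stop("carrier group spans multiple chromosomes")
  noncar <- intersect(.nonCarrierIds(obs, trait), names(gr))
  noncar <- noncar[as.character(GenomicRanges::seqnames(gr[noncar])) == chrom]

  core <- segmentIntersect(segs)
  excluders <- character()
  if (length(core) && length(noncar)) {
    ov <- IRanges::overlapsAny(.toHO(gr[noncar]), .toHO(core))
    excluders <- noncar[ov]
  }
  result <- segmentSubtract(core, gr[noncar])

  if (length(result) == 0L && maxConflicts > 0L) {
    sol <- .relaxedMap(carriers, excluders, gr, maxConflicts)
    if (!is.null(sol)) {
      carriers <- sol$carriers; excluders <- sol$excluders
      result <- sol$result
    }
  }
  if (length(result) == 0L)
    stop("phenotypes inconsistent with single-locus model for trait '",
         trait, "' on ", chrom)

  fl <- lapply(seq_along(result), function(i)
    flankingMarkers(result[i], genome))
  new("MappedLocus", trait = trait, chrom = chrom, intervals = result,
      lengthMb = toMb(segmentLength(result)),
      leftMarker = vapply(fl, `[[`, "", "left"),
      rightMarker = vapply(fl, `[[`, "", "right"),
      carriers = carriers, excluders = excluders,
      ambiguous = length(result) > 1L)
}

## exact search over dropping <= k constraining observations; returns the
## solution whose surviving interval set has the largest total length
.relaxedMap <- function(carriers, excluders, gr, k) {
  ids <- c(carriers, excluders)
  best <- NULL
  for (j in seq_len(min(k, length(ids)))) {
    for (drop in as.data.frame(combn(ids, j), stringsAsFactors = FALSE)) {
      ca <- setdiff(carriers, drop)
      if (length(ca) == 0L) next
      ex <- setdiff(excluders, drop)
      res <- try(segmentSubtract(segmentIntersect(gr[ca]), gr[ex]),
                 silent = TRUE)
      if (inherits(res, "try-error") || length(res) == 0L) next
      tot <- sum(segmentLength(res))
      if (is.null(best) || tot > best$total)
        best <- list(carriers = ca, excluders = ex, result = res,
                     total = tot)
    }
    if (!is.null(best)) break  # fewest conflicts first
  }
  best
}

#' Map every locus of a trait
#'
#' Convenience wrapper: [groupCarriers()] then [mapLocus()] per group.
#'
#' @inheritParams mapLocus
#' @return named list of [MappedLocus-class] (`trait_chrom_i`).
#' @examples
#' gm <- GenomeMap(
#'   data.frame(chrom = "Chr04", length = 36e6),
#'   data.frame(name = c("OSR15", "PSM361", "RM559"), chrom = "Chr04",
#'              pos = c(33031813, 33865656, 35336720)))
#' lib <- SubstitutionLibrary(
#'   data.frame(line_id = c("SN57", "SN58"), chrom = "Chr04",
#'              start_bp = c(33031813, 33031813),
#'              end_bp = c(33865656, 35336720)),
#'   donor = "NIV1")
#' obs <- data.frame(line_id = c("SN57", "SN58"),
#'                   trait = "seed_shattering", state = c(0L, 1L))
#' loci <- mapTrait(lib, obs, "seed_shattering", gm)
#' lociTable(loci)  # 1.47 Mb between PSM361 and RM559
#' @export
mapTrait <- function(library, obs, trait, genome, maxConflicts = 0L) {
  groups <- groupCarriers(library, obs, trait)
  loci <- lapply(groups, mapLocus, library = library, obs = obs,
                 genome = genome, trait = trait,
                 maxConflicts = maxConflicts)
  names(loci) <- vapply(seq_along(loci), function(i)
    paste(trait, loci[[i]]@chrom, i, sep = "_"), "")
  loci
}
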