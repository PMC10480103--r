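#' ConstitutionStats: genetic-constitution summary of one SSSL population
#'
#' Per-population summary of the substituted segments: total length (sum of
#' per-line segment lengths), mean length per line, coverage length (length
#' of the union of all segments) and coverage percent of the genome, with a
#' per-chromosome breakdown.
#'
#' @slot donor donor label.
#' @slot nLines number of lines.
#' @slot totalLength,meanLength,coverageLength bp.
#' @slot coveragePercent percent of the genome covered by the union.
#' @slot perChromosome data.frame: `chrom`, `n_segments`, `total_bp`,
#'   `coverage_bp`, `coverage_percent` (of that chromosome).
#' @export
setClass("ConstitutionStats",
  slots = c(donor = "character", nLines = "integer",
            totalLength = "numeric", meanLength = "numeric",
            coverageLength = "numeric", coveragePercent = "numeric",
            perChromosome = "data.frame"))

setValidity("ConstitutionStats", function(object) {
  msg <- character()
  if (object@coverageLength > object@totalLength + 1e-6)
    msg <- c(msg, "coverage length cannot exceed total length")
  if (object@coveragePercent < 0 || object@coveragePercent > 100)
    msg <- c(msg, "coverage percent must lie in [0, 100]")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "ConstitutionStats", function(object) {
  cat("ConstitutionStats for donor", object@donor, "\n")
  cat(sprintf("  %d lines; total %.2f Mb; mean %.2f Mb\n", object@nLines,
              toMb(object@totalLength), toMb(object@meanLength)))
  cat(sprintf("  coverage %.2f Mb (%.2f%% of genome)\n",
              toMb(object@coverageLength), object@coveragePercent))
})

#' @describeIn ConstitutionStats-class one-row data.frame of the headline
#'   fields (Mb values rendered with [toMb()]).
#' @param x a `ConstitutionStats`.
#' @export
statsTable <- function(x) {
  stopifnot(is(x, "ConstitutionStats"))
  data.frame(donor = x@donor, n_lines = x@nLines,
             total_mb = toMb(x@totalLength), mean_mb = toMb(x@meanLength),
             coverage_mb = toMb(x@coverageLength),
             coverage_percent = x@coveragePercent)
}

#' Genetic-constitution statistics of an SSSL population
#'
#' Computes, for one library, the total substituted length, the mean segment
#' length per line, the coverage length (union of segments) and the coverage
#' percent of the genome, overall and per chromosome.
#'
#' @param library a [SubstitutionLibrary-class].
#' @param genome a [GenomeMap-class]; every segment must lie within its
#'   chromosome bounds.
#' @return a [ConstitutionStats-class].
#' @examples
#' gm <- GenomeMap(data.frame(chrom = c("c1", "c2"), length = c(5e7, 5e7)))
#' lib <- SubstitutionLibrary(
#'   data.frame(line_id = c("L1", "L2"), chrom = c("c1", "c2"),
#'              start_bp = c(1, 1), end_bp = c(2e6 + 1, 4e6 + 1)),
#'   donor = "D")
#' statsTable(populationStats(lib, gm))
#' @export
populationStats <- function(library, genome) {
  stopifnot(is(library, "SubstitutionLibrary"), is(genome, "GenomeMap"))
  if (nLines(library) == 0L)
    stop("library is empty")
  .checkBounds(library, genome)
  gr <- segmentRanges(library)
  lens <- segmentLength(gr)
  total <- sum(lens)
  cov <- segmentUnion(gr)
  covlen <- sum(segmentLength(cov))
  gsize <- genomeSize(genome)
  ch <- as.character(GenomicRanges::seqnames(gr))
  covch <- as.character(GenomicRanges::seqnames(cov))
  per <- do.call(rbind, lapply(genome@chromosomes$chrom, function(c1) {
    sel <- ch == c1
    cbp <- sum(segmentLength(cov[covch == c1]))
    data.frame(chrom = c1, n_segments = sum(sel),
               total_bp = sum(lens[sel]), coverage_bp = cbp,
               coverage_percent = .roundHalfUp(
                 100 * cbp / chromLengths(genome)[[c1]], 2L))
  }))
  rownames(per) <- NULL
  new("ConstitutionStats", donor = donor(library),
      nLines = nLines(library), totalLength = total,
      meanLength = total / nLines(library),
      coverageLength = covlen,
      coveragePercent = .roundHalfUp(100 * covlen / gsize, 2L),
      perChromosome = per)
}

#' Coverage rate of a set of SSSL populations
#'
#' The coverage rate sums each population's coverage length (its segment
#' union) and divides by the genome length, so it can exceed 100% when the
#' populations cover the same regions independently. Returned per chromosome
#' plus an `"overall"` row.
#'
#' @param libraries list of [SubstitutionLibrary-class] (or a single one).
#' @param genome a [GenomeMap-class].
#' @return data.frame with columns `chrom`, `length_bp`,
#'   `coverage_sum_bp` (sum over populations of their union length there)
#'   and `coverage_rate` (percent, half-up 2 decimals).
#' @export
coverageRate <- function(libraries, genome) {
  if (is(libraries, "SubstitutionLibrary")) libraries <- list(libraries)
  if (length(libraries) == 0L)
    stop("need at least one library")
  stats <- lapply(libraries, populationStats, genome = genome)
  chroms <- genome@chromosomes$chrom
  covsum <- rowSums(do.call(cbind, lapply(stats, function(s)
    s@perChromosome$coverage_bp)))
  out <- data.frame(chrom = chroms,
                    length_bp = unname(chromLengths(genome)),
                    coverage_sum_bp = covsum)
  out <- rbind(out, data.frame(chrom = "overall",
                               length_bp = genomeSize(genome),
                               coverage_sum_bp = sum(covsum)))
  out$coverage_rate <- .roundHalfUp(100 * out$coverage_sum_bp /
                                      out$length_bp, 2L)
  out
}

#' Segment-length histogram of a population
#'
#' Bins the per-line segment lengths (in Mb, unrounded) into
#' `[0, e1), [e1, e2), ..., [ek, Inf)` for the supplied edges; used to
#' summarise what fraction of a library is shorter than 5 Mb or longer than
#' 10 Mb.
#'
#' @param library a [SubstitutionLibrary-class].
#' @param edges strictly increasing bin edges in Mb (default `c(5, 10)`).
#' @return data.frame with columns `bin`, `count`, `fraction`
#'   (fractions sum to 1).
#' @export
lengthHistogram <- function(library, edges = c(5, 10)) {
  stopifnot(is(library, "SubstitutionLibrary"))
  if (length(edges) < 1L || any(diff(edges) <= 0) || any(edges <= 0))
    stop("'edges' must be strictly increasing positive Mb values")
  mb <- segmentLength(segmentRanges(library)) / 1e6
  breaks <- c(0, edges, Inf)
  labs <- c(paste0("[0,", edges[1L], ")"),
            if (length(edges) > 1L)
              paste0("[", edges[-length(edges)], ",", edges[-1L], ")"),
            paste0(">=", edges[length(edges)]))
  cnt <- table(cut(mb, breaks = breaks, right = FALSE, labels = labs))
  data.frame(bin = labs, count = as.integer(cnt),
             fraction = as.integer(cnt) / max(1L, length(mb)))
}
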