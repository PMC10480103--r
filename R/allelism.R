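#' Read a catalog of cloned (known) genes
#'
#' TSV with columns `name`, `chrom`, `start_bp`, `end_bp`, `trait`,
#' `source`. Coordinates may be `NA` for genes whose physical position is
#' not available (their positional relation is then untestable and allelism
#' rests on sequence evidence alone).
#'
#' @param path path to the catalog TSV.
#' @return data.frame with those columns.
#' @export
readKnownGenes <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "chrom", "start_bp", "end_bp", "trait", "source")
  if (!all(need %in% names(d)))
    stop("known-gene TSV needs columns ", paste(need, collapse = ", "))
  has <- !is.na(d$start_bp) & !is.na(d$end_bp)
  if (any(has & d$start_bp >= d$end_bp))
    stop("known gene with start >= end")
  d
}

#' Packaged catalog of cloned rice domestication genes
#'
#' Ships the cloned-gene coordinates used for positional allelism testing of
#' rice domestication loci: PROG1 and TIG1 (tiller angle), OsLG1 (spreading
#' panicle), An-1 and LABA1 (awn), SH4 (seed shattering) and Rc (red
#' pericarp; no published physical coordinates, position untestable).
#'
#' @return data.frame in [readKnownGenes()] format.
#' @export
riceGeneCatalog <- function() {
  readKnownGenes(system.file("extdata", "known_genes_rice.tsv",
                             package = "sslmap", mustWork = TRUE))
}

#' Positional relation of a mapped locus to a known gene
#'
#' `"contained"` when the gene lies fully inside the mapped interval,
#' `"overlap"` when they share base pairs, `"proximal"` when disjoint on the
#' same chromosome with a gap at most `proxThreshold` (default 1 Mb — close
#' enough that sequencing is warranted before calling the locus novel),
#' otherwise `"distal"`. A gene on another chromosome is `"distal"`; a gene
#' without coordinates is `"untestable"`.
#'
#' @param locus a [MappedLocus-class] or single-range `GRanges`.
#' @param gene one row of a [readKnownGenes()] catalog (data.frame or list
#'   with `name`, `chrom`, `start_bp`, `end_bp`).
#' @param proxThreshold gap threshold (bp) for `"proximal"`.
#' @return list with `positional` and `gap` (bp; `NA` unless proximal or
#'   disjoint on the same chromosome).
#' @export
positionalRelation <- function(locus, gene, proxThreshold = 1e6) {
  interval <- if (is(locus, "MappedLocus")) locusInterval(locus) else locus
  stopifnot(is(interval, "GRanges"), length(interval) == 1L)
  if (is.na(gene$start_bp) || is.na(gene$end_bp))
    return(list(positional = "untestable", gap = NA_real_))
  ggr <- .makeSegments(gene$chrom, gene$start_bp, gene$end_bp)
  rel <- segmentRelation(interval, ggr)
  if (!rel$same_chrom)
    return(list(positional = "distal", gap = NA_real_))
  switch(rel$relation,
    contained = list(positional = "contained", gap = 0),
    overlap = list(positional = "overlap", gap = 0),
    disjoint = list(
      positional = if (rel$gap <= proxThreshold) "proximal" else "distal",
      gap = rel$gap))
}

#' Allelism verdict from position and sequence evidence
#'
#' Deterministic rule table combining the positional relation of a mapped
#' locus to a known gene with the outcome of sequencing that gene in the
#' carrier line versus the recipient:
#' \itemize{
#'   \item sequence `"identical"` (recipient and carrier share the gene
#'     sequence) rules the gene out: verdict `"novel"` regardless of
#'     position;
#'   \item `"distal"` position: `"novel"`;
#'   \item `"contained"`/`"overlap"` with `"variants_found"`:
#'     `"allele_candidate"`;
#'   \item everything else (proximal, untested sequence, untestable
#'     position): `"inconclusive"`.
#' }
#' Partial overlap counts like containment because mapped intervals bound,
#' rather than pinpoint, the causal gene.
#'
#' @param positional one of `"contained"`, `"overlap"`, `"proximal"`,
#'   `"distal"`, `"untestable"` (see [positionalRelation()]).
#' @param sequenceEvidence one of `"variants_found"`, `"identical"`,
#'   `"untested"`.
#' @return `"allele_candidate"`, `"novel"` or `"inconclusive"`.
#' @export
allelismVerdict <- function(positional = c("contained", "overlap",
                                           "proximal", "distal",
                                           "untestable"),
                            sequenceEvidence = c("untested",
                                                 "variants_found",
                                                 "identical")) {
  positional <- match.arg(positional)
  sequenceEvidence <- match.arg(sequenceEvidence)
  if (sequenceEvidence == "identical") return("novel")
  if (positional == "distal") return("novel")
  if (positional %in% c("contained", "overlap") &&
      sequenceEvidence == "variants_found") return("allele_candidate")
  "inconclusive"
}

#' Allelism calls for a set of mapped loci against a gene catalog
#'
#' For each locus, tests every catalog gene annotated with the same trait:
#' computes the positional relation, joins optional sequence evidence and
#' applies [allelismVerdict()]. A locus whose trait has no catalog gene, or
#' that is distal to all of them, is reported once with gene `NA` and
#' verdict `"novel"`.
#'
#' @param loci list of [MappedLocus-class] (e.g. from [mapTrait()]).
#' @param catalog data.frame from [readKnownGenes()].
#' @param sequenceEvidence optional named character vector: gene name ->
#'   `"variants_found"` / `"identical"` / `"untested"`.
#' @param proxThreshold passed to [positionalRelation()].
#' @return data.frame: `trait`, `locus_chrom`, `locus_start`, `locus_end`,
#'   `gene`, `positional`, `gap_bp`, `sequence_evidence`, `verdict`.
#' @export
allelismCalls <- function(loci, catalog, sequenceEvidence = character(),
                          proxThreshold = 1e6) {
  if (is(loci, "MappedLocus")) loci <- list(loci)
  rows <- list()
  for (l in loci) {
    genes <- catalog[catalog$trait == l@trait, , drop = FALSE]
    iv <- locusInterval(l)
    base <- data.frame(trait = l@trait, locus_chrom = l@chrom,
                       locus_start = GenomicRanges::start(iv),
                       locus_end = GenomicRanges::end(iv))
    if (nrow(genes) == 0L) {
      rows[[length(rows) + 1L]] <-
        cbind(base, gene = NA_character_, positional = "distal",
              gap_bp = NA_real_, sequence_evidence = "untested",
              verdict = "novel")
      next
    }
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      pr <- positionalRelation(l, g, proxThreshold)
      se <- if (g$name %in% names(sequenceEvidence))
        unname(sequenceEvidence[[g$name]]) else "untested"
      rows[[length(rows) + 1L]] <-
        cbind(base, gene = g$name, positional = pr$positional,
              gap_bp = pr$gap, sequence_evidence = se,
              verdict = allelismVerdict(pr$positional, se))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
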