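#' Simulation configuration for synthetic SSSL data sets
#'
#' Bundles every knob of the simulator with defaults emulating a rice SSSL
#' experiment: 12 chromosomes with the shipped IRGSP-1.0 lengths, SSR-like
#' markers every ~1.5 Mb (jittered), one homozygous marker-delimited donor
#' segment per line with exponentially distributed raw length (mean 5 Mb,
#' truncated to [0.2 Mb, chromosome length]), fully penetrant binary
#' phenotypes (noise `epsilon`, default 0) and per-gene CDS edit counts.
#'
#' @param seed integer seed; mandatory, every simulator output is a pure
#'   function of (seed, config).
#' @param chromLengths named numeric vector of chromosome lengths (bp);
#'   default the packaged rice lengths.
#' @param markerSpacing mean marker spacing (bp).
#' @param markerJitter relative jitter of inter-marker gaps (uniform on
#'   `spacing * [1 - j, 1 + j]`).
#' @param nLines lines per donor: named integer vector, one library per
#'   donor (defaults to the three-population design 123/39/133).
#' @param segmentDist `"exponential"` or `"gamma"` raw segment lengths.
#' @param segmentMeanMb mean raw segment length (Mb).
#' @param segmentShape gamma shape (ignored for exponential).
#' @param segmentMinMb lower truncation (Mb).
#' @param epsilon phenotype flip probability.
#' @param causalGenes optional data.frame `trait`, `chrom`, `start_bp`,
#'   `end_bp`; when NULL, [simulateDataset()] plants one gene per trait in
#'   `traits` inside the simulated libraries.
#' @param traits trait labels used when planting genes automatically.
#' @param cdsCodons codons (excluding start/stop) of each simulated
#'   reference CDS.
#' @param editSnps,editInframe,editFrameshift per-gene edit counts for the
#'   donor CDS: SNPs, in-frame indels, frameshift indels.
#' @return a list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(seed,
                             chromLengths = NULL,
                             markerSpacing = 1.5e6,
                             markerJitter = 0.3,
                             nLines = c(RUF = 123L, NIV1 = 39L,
                                        NIV2 = 133L),
                             segmentDist = c("exponential", "gamma"),
                             segmentMeanMb = 5,
                             segmentShape = 2,
                             segmentMinMb = 0.2,
                             epsilon = 0,
                             causalGenes = NULL,
                             traits = c("tiller_angle",
                                        "spreading_panicle", "awn",
                                        "seed_shattering",
                                        "red_pericarp"),
                             cdsCodons = 200L,
                             editSnps = 8L, editInframe = 1L,
                             editFrameshift = 1L) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (is.null(chromLengths)) chromLengths <- chromLengths(riceGenome())
  if (is.null(names(chromLengths)))
    names(chromLengths) <- sprintf("Chr%02d", seq_along(chromLengths))
  if (any(chromLengths <= 0)) stop("chromosome lengths must be positive")
  if (markerSpacing > min(chromLengths))
    stop("marker spacing exceeds the shortest chromosome")
  if (epsilon < 0 || epsilon > 1) stop("'epsilon' must be in [0, 1]")
  structure(list(seed = as.integer(seed), chromLengths = chromLengths,
                 markerSpacing = markerSpacing,
                 markerJitter = markerJitter, nLines = nLines,
                 segmentDist = match.arg(segmentDist),
                 segmentMeanMb = segmentMeanMb,
                 segmentShape = segmentShape,
                 segmentMinMb = segmentMinMb, epsilon = epsilon,
                 causalGenes = causalGenes, traits = traits,
                 cdsCodons = as.integer(cdsCodons),
                 editSnps = as.integer(editSnps),
                 editInframe = as.integer(editInframe),
                 editFrameshift = as.integer(editFrameshift)),
            class = "SimulationConfig")
}

#' Simulate a genome map with jittered evenly spaced markers
#'
#' Marker positions on each chromosome are cumulative sums of gaps drawn
#' uniformly from `spacing * [1 - jitter, 1 + jitter]`; names are synthetic
#' SSR-style labels (`S<chrom>M<index>`). Deterministic given the config
#' seed.
#'
#' @param config a [simulationConfig()].
#' @return a [GenomeMap-class].
#' @export
makeGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .withSeed(config$seed, {
    lens <- config$chromLengths
    sp <- config$markerSpacing
    j <- config$markerJitter
    mk <- do.call(rbind, lapply(seq_along(lens), function(ci) {
      L <- lens[[ci]]
      gaps <- runif(ceiling(L / (sp * (1 - j))) + 1L,
                    sp * (1 - j), sp * (1 + j))
      pos <- round(cumsum(gaps))
      pos <- pos[pos <= L]
      data.frame(name = sprintf("S%02dM%03d", ci, seq_along(pos)),
                 chrom = names(lens)[ci], pos = pos)
    }))
    GenomeMap(data.frame(chrom = names(lens), length = unname(lens)), mk)
  })
}

## nearest-marker snap; returns sorted distinct (start, end) marker
## positions bracketing at least one inter-marker gap
.snapToMarkers <- function(rawStart, rawEnd, pos) {
  i <- which.min(abs(pos - rawStart))
  k <- which.min(abs(pos - rawEnd))
  if (i == k) {                      # degenerate snap: take one gap
    if (k < length(pos)) k <- k + 1L else i <- i - 1L
  }
  if (i > k) { tmp <- i; i <- k; k <- tmp }
  if (i < 1L) return(NULL)
  c(pos[i], pos[k])
}

#' Simulate one SSSL library
#'
#' Each line gets one homozygous donor segment: chromosome sampled
#' proportional to its length, anchor uniform, raw length from the
#' configured distribution (truncated), then both endpoints snapped to the
#' nearest markers — segments are marker-delimited, as they are when
#' detected with SSR markers.
#'
#' @param genome a [GenomeMap-class] from [makeGenome()].
#' @param config a [simulationConfig()].
#' @param donorLabel donor label (also keys `config$nLines`; when absent
#'   there, `n` is used).
#' @param n number of lines (default from `config$nLines[donorLabel]`).
#' @param seed optional seed override (default derived from the config
#'   seed and the donor label, so each donor library differs).
#' @return a [SubstitutionLibrary-class].
#' @export
simulateLibrary <- function(genome, config, donorLabel = "SYN",
                            n = NULL, seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(n))
    n <- if (donorLabel %in% names(config$nLines))
      config$nLines[[donorLabel]] else stop("no line count for donor '",
                                            donorLabel, "'")
  if (is.null(seed))
    seed <- config$seed + sum(utf8ToInt(donorLabel)) * 131L
  lens <- chromLengths(genome)
  mk <- markerTable(genome)
  meanBp <- config$segmentMeanMb * 1e6
  minBp <- config$segmentMinMb * 1e6
  if (n == 0L)
    return(SubstitutionLibrary(
      data.frame(line_id = character(), chrom = character(),
                 start_bp = numeric(), end_bp = numeric()),
      donor = donorLabel))
  .withSeed(seed, {
    rows <- vector("list", n)
    made <- 0L
    while (made < n) {
      ch <- sample(names(lens), 1L, prob = lens)
      L <- lens[[ch]]
      raw <- switch(config$segmentDist,
        exponential = rexp(1L, rate = 1 / meanBp),
        gamma = stats::rgamma(1L, shape = config$segmentShape,
                              scale = meanBp / config$segmentShape))
      raw <- min(max(raw, minBp), L)
      anchor <- runif(1L, 1, L - 1)
      s <- max(1, anchor - raw / 2)
      e <- min(L, s + raw)
      snap <- .snapToMarkers(s, e, mk$pos[mk$chrom == ch])
      if (is.null(snap) || snap[1L] >= snap[2L]) next
      made <- made + 1L
      rows[[made]] <- data.frame(chrom = ch, start_bp = snap[1L],
                                 end_bp = snap[2L])
    }
    d <- do.call(rbind, rows)
    d$line_id <- sprintf("%s%03d", substr(donorLabel, 1L, 3L), seq_len(n))
    SubstitutionLibrary(d, donor = donorLabel)
  })
}

#' Plant a causal gene inside a simulated library
#'
#' Picks a random line and a random inter-marker gap fully inside its
#' segment, and places a short causal gene strictly within that gap. With
#' marker-delimited segments this guarantees that a segment either covers
#' the whole gene or none of it, so noise-free phenotypes are exactly the
#' single-locus carrier model.
#'
#' @param library a [SubstitutionLibrary-class] with marker-snapped
#'   segments.
#' @param genome the [GenomeMap-class] the library was simulated on.
#' @param trait trait label for the gene.
#' @param seed integer seed.
#' @param width gene width (bp).
#' @return one-row data.frame `trait`, `chrom`, `start_bp`, `end_bp`.
#' @export
plantCausalGene <- function(library, genome, trait, seed, width = 2000) {
  gr <- segmentRanges(library)
  mk <- markerTable(genome)
  .withSeed(seed, {
    for (attempt in seq_len(1000L)) {
      i <- sample(length(gr), 1L)
      ch <- as.character(GenomicRanges::seqnames(gr[i]))
      s <- GenomicRanges::start(gr[i]); e <- GenomicRanges::end(gr[i])
      pos <- mk$pos[mk$chrom == ch]
      pos <- pos[pos >= s & pos <= e]
      if (length(pos) < 2L) next
      gapIdx <- sample(length(pos) - 1L, 1L)
      lo <- pos[gapIdx]; hi <- pos[gapIdx + 1L]
      if (hi - lo <= width + 2) next
      gs <- floor(runif(1L, lo, hi - width))
      return(data.frame(trait = trait, chrom = ch, start_bp = gs,
                        end_bp = gs + width))
    }
    stop("could not place a causal gene inside any segment")
  })
}

#' Assign binary phenotypes from causal genes
#'
#' A line shows the donor-like state (1) iff its segment overlaps the
#' causal gene interval of the trait (SSSLs are homozygous, so penetrance
#' and dominance collapse into carrier status); each state is then flipped
#' with probability `epsilon`.
#'
#' @param library a [SubstitutionLibrary-class].
#' @param genes data.frame `trait`, `chrom`, `start_bp`, `end_bp`.
#' @param epsilon flip probability (default 0 = noise-free).
#' @param seed integer seed (used only when `epsilon > 0`).
#' @return data.frame `line_id`, `trait`, `state`.
#' @export
assignPhenotypes <- function(library, genes, epsilon = 0, seed = 0L) {
  gr <- segmentRanges(library)
  out <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ggr <- .makeSegments(g$chrom, g$start_bp, g$end_bp)
    same <- as.character(GenomicRanges::seqnames(gr)) ==
      as.character(g$chrom)
    state <- integer(length(gr))
    if (any(same))
      state[same] <- as.integer(
        IRanges::overlapsAny(.toHO(gr[same]), .toHO(ggr)))
    data.frame(line_id = names(gr), trait = g$trait, state = state)
  }))
  if (epsilon > 0) {
    out$state <- .withSeed(seed, {
      flip <- rbinom(nrow(out), 1L, epsilon) == 1L
      ifelse(flip, 1L - out$state, out$state)
    })
  }
  rownames(out) <- NULL
  out
}

#' Random reference CDS
#'
#' `ATG`, then `nCodons` random non-stop codons, then `TAA`.
#'
#' @param nCodons internal codon count.
#' @param seed integer seed.
#' @return DNA string of length `3 * (nCodons + 2)`.
#' @export
randomCds <- function(nCodons, seed) {
  .withSeed(seed, {
    codons <- apply(expand.grid(c("A", "C", "G", "T"),
                                c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1L, paste,
                    collapse = "")
    codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
    paste0("ATG", paste(sample(codons, nCodons, replace = TRUE),
                        collapse = ""), "TAA")
  })
}

#' Random sparse edit specification for a CDS
#'
#' Draws non-overlapping, well-separated edits (SNPs, insertions,
#' deletions) inside the CDS body, in the [callVariants()] encoding.
#' Insertion/deletion lengths are drawn from `indelLengths`. Edits are kept
#' at least `minGap` bp apart and away from the start/stop codons.
#'
#' @param refCds reference CDS.
#' @param nSnp,nIns,nDel edit counts.
#' @param seed integer seed.
#' @param indelLengths candidate indel lengths (bp).
#' @param minGap minimum distance between edit footprints.
#' @return variant data.frame (`kind`, `pos`, `ref`, `alt`), normalized.
#' @export
randomEditSpec <- function(refCds, nSnp = 5L, nIns = 1L, nDel = 1L, seed,
                           indelLengths = c(1L, 2L, 3L, 6L, 18L),
                           minGap = 10L) {
  refCds <- .checkDna(refCds, "'refCds'")
  n <- nchar(refCds)
  refChars <- strsplit(refCds, "")[[1L]]
  .withSeed(seed, {
    kinds <- c(rep("SNP", nSnp), rep("insertion", nIns),
               rep("deletion", nDel))
    kinds <- sample(kinds)
    out <- .variantDf()
    used <- cbind(numeric(0), numeric(0))
    tries <- 0L
    bases <- c("A", "C", "G", "T")
    while (length(kinds) && tries < 5000L) {
      tries <- tries + 1L
      kind <- kinds[1L]
      L <- if (kind == "SNP") 1L else sample(indelLengths, 1L)
      pos <- sample(seq(4L, n - 3L - L), 1L)
      if (nrow(out)) {
        fp <- .variantFootprint(out)
        if (any(pos - minGap <= fp[, 2L] & pos + L - 1L + minGap >=
                fp[, 1L])) next
      }
      v <- switch(kind,
        SNP = {
          refb <- refChars[pos]
          .variantDf("SNP", pos, refb, sample(setdiff(bases, refb), 1L))
        },
        insertion = .variantDf("insertion", pos, "",
                               paste(sample(bases, L, replace = TRUE),
                                     collapse = "")),
        deletion = .variantDf("deletion", pos,
                              paste(refChars[pos:(pos + L - 1L)],
                                    collapse = ""), ""))
      out <- rbind(out, v)
      kinds <- kinds[-1L]
    }
    if (length(kinds))
      stop("could not place all edits; CDS too short for the spec")
    ## report in normalized (leftmost) form, as callVariants would
    for (i in seq_len(nrow(out))) {
      if (out$kind[i] == "SNP") next
      seq <- if (out$kind[i] == "deletion") out$ref[i] else out$alt[i]
      norm <- .leftNormalize(out$kind[i], out$pos[i], seq, refChars)
      out$pos[i] <- norm$pos
      if (out$kind[i] == "deletion") out$ref[i] <- norm$seq
      else out$alt[i] <- norm$seq
    }
    out <- out[order(out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Apply an edit specification to a reference CDS
#'
#' Applies the edits right-to-left (positions stay reference-anchored) and
#' returns the mutated sequence together with the ground-truth variant list
#' in normalized form — the list [callVariants()] is expected to recover.
#'
#' @param refCds reference CDS.
#' @param spec variant data.frame (`kind`, `pos`, `ref`, `alt`); for
#'   deletions `ref` may be given as a length instead of the deleted run.
#' @return list with `alt` (mutated CDS) and `truth` (normalized variant
#'   data.frame).
#' @export
mutateCds <- function(refCds, spec) {
  refCds <- .checkDna(refCds, "'refCds'")
  refChars <- strsplit(refCds, "")[[1L]]
  spec <- as.data.frame(spec, stringsAsFactors = FALSE)
  ## allow deletions specified by length
  del <- spec$kind == "deletion" & grepl("^[0-9]+$", spec$ref)
  if (any(del))
    spec$ref[del] <- vapply(which(del), function(i)
      paste(refChars[spec$pos[i]:(spec$pos[i] +
                                    as.integer(spec$ref[i]) - 1L)],
            collapse = ""), "")
  .checkVariantTable(spec, nchar(refCds))
  alt <- applyVariants(refCds, spec)
  truth <- spec
  for (i in seq_len(nrow(truth))) {
    if (truth$kind[i] == "SNP") next
    seq <- if (truth$kind[i] == "deletion") truth$ref[i] else truth$alt[i]
    norm <- .leftNormalize(truth$kind[i], truth$pos[i], seq, refChars)
    truth$pos[i] <- norm$pos
    if (truth$kind[i] == "deletion") truth$ref[i] <- norm$seq
    else truth$alt[i] <- norm$seq
  }
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  list(alt = alt, truth = truth)
}

#' Simulate a complete SSSL data set
#'
#' Generates the genome and marker map, one library per donor, one planted
#' causal gene per configured trait (placed inside a random segment of a
#' random library so each trait has at least one carrier), noise-`epsilon`
#' phenotypes, and one recipient/donor CDS pair per gene with known edits.
#'
#' @param config a [simulationConfig()].
#' @return list of class `"SSSLDataset"`: `config`, `genome`, `libraries`
#'   (named list), `genes`, `phenotypes`, `cds` (per gene: `ref`, `alt`,
#'   `truth`).
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  genome <- makeGenome(config)
  donors <- names(config$nLines)
  libraries <- setNames(lapply(donors, function(d)
    simulateLibrary(genome, config, donorLabel = d)), donors)
  genes <- config$causalGenes
  if (is.null(genes)) {
    genes <- do.call(rbind, lapply(seq_along(config$traits), function(i) {
      lib <- libraries[[1L + (i - 1L) %% length(libraries)]]
      plantCausalGene(lib, genome, config$traits[i],
                      seed = config$seed + 7L * i)
    }))
  }
  phenotypes <- do.call(rbind, lapply(seq_along(libraries), function(i)
    assignPhenotypes(libraries[[i]], genes, epsilon = config$epsilon,
                     seed = config$seed + 977L * i)))
  cds <- lapply(seq_len(nrow(genes)), function(i) {
    ref <- randomCds(config$cdsCodons, seed = config$seed + 31L * i)
    spec <- randomEditSpec(ref, nSnp = config$editSnps,
                           nIns = config$editInframe,
                           nDel = config$editFrameshift,
                           seed = config$seed + 53L * i,
                           indelLengths = c(3L, 6L, 18L, 1L, 2L, 14L))
    c(list(gene = genes$trait[i]), mutateCds(ref, spec), list(ref = ref))
  })
  names(cds) <- genes$trait
  structure(list(config = config, genome = genome, libraries = libraries,
                 genes = genes, phenotypes = phenotypes, cds = cds),
            class = "SSSLDataset")
}

#' Write a simulated data set to disk
#'
#' Emits plain-text files: `genome.tsv`, `markers.tsv`, `segments.tsv`,
#' `segments.bed`, `phenotypes.tsv`, `genes.tsv`, `cds_ref.fa`,
#' `cds_alt.fa`, `truth_variants.tsv` and `manifest.json` (seed + config),
#' so a data set can be regenerated or read back exactly.
#'
#' @param dataset an `"SSSLDataset"` from [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "SSSLDataset"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory ", dir)
  gm <- dataset$genome
  write.table(data.frame(chrom = gm@chromosomes$chrom,
                         length_bp = as.integer(gm@chromosomes$length)),
              file.path(dir, "genome.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  mk <- markerTable(gm)
  write.table(data.frame(name = mk$name, chrom = mk$chrom,
                         pos_bp = as.integer(mk$pos)),
              file.path(dir, "markers.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeSegmentsTsv(dataset$libraries, file.path(dir, "segments.tsv"))
  writeSegmentsBed(dataset$libraries, file.path(dir, "segments.bed"))
  write.table(dataset$phenotypes, file.path(dir, "phenotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  genes <- dataset$genes
  genes$start_bp <- as.integer(genes$start_bp)
  genes$end_bp <- as.integer(genes$end_bp)
  write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ids <- names(dataset$cds)
  writeLines(unlist(lapply(ids, function(g)
    c(paste0(">", g, "_ref"), dataset$cds[[g]]$ref))),
    file.path(dir, "cds_ref.fa"))
  writeLines(unlist(lapply(ids, function(g)
    c(paste0(">", g, "_alt"), dataset$cds[[g]]$alt))),
    file.path(dir, "cds_alt.fa"))
  truth <- do.call(rbind, lapply(ids, function(g)
    cbind(gene = g, dataset$cds[[g]]$truth)))
  write.table(truth, file.path(dir, "truth_variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- unclass(dataset$config)
  cfg$chromLengths <- as.list(cfg$chromLengths)
  cfg$nLines <- as.list(cfg$nLines)
  if (is.null(cfg$causalGenes)) cfg$causalGenes <- NULL
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read back a written data set
#'
#' @param dir directory written by [writeDataset()].
#' @return list with `genome` ([GenomeMap-class]), `libraries`,
#'   `phenotypes`, `genes`, `truth`, `manifest`.
#' @export
readDataset <- function(dir) {
  genome <- readGenomeMap(file.path(dir, "genome.tsv"),
                          file.path(dir, "markers.tsv"))
  libraries <- readSegments(file.path(dir, "segments.tsv"))
  list(genome = genome, libraries = libraries,
       phenotypes = readPhenotypes(file.path(dir, "phenotypes.tsv")),
       genes = read.delim(file.path(dir, "genes.tsv"),
                          stringsAsFactors = FALSE),
       truth = read.delim(file.path(dir, "truth_variants.tsv"),
                          stringsAsFactors = FALSE),
       manifest = jsonlite::read_json(file.path(dir, "manifest.json")))
}
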