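# Shared fixtures built in code.

# printed physical intervals of the six mapped rice loci with coordinates
paperLoci <- function() {
  data.frame(
    locus = c("TA7-RUF", "TA8-RUF", "SPR4-NIV", "AN4-NIV", "AN4-RUF",
              "SH4-NIV"),
    trait = c("tiller_angle", "tiller_angle", "spreading_panicle", "awn",
              "awn", "seed_shattering"),
    chrom = c("Chr07", "Chr08", "Chr04", "Chr04", "Chr04", "Chr04"),
    start = c(2679666, 20286300, 33031813, 24044220, 7971563, 33865656),
    end = c(3555628, 21478312, 33865656, 25364277, 16789753, 35336720))
}

lociAsGRanges <- function(df = paperLoci()) {
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  names(gr) <- df$locus
  gr
}

# seed-shattering worked example: SN58 carrier, SN57 non-carrier, with the
# three markers that flank and delimit the mapped interval
shatteringFixture <- function() {
  gm <- GenomeMap(
    data.frame(chrom = "Chr04", length = 36e6),
    data.frame(name = c("OSR15", "PSM361", "RM559"), chrom = "Chr04",
               pos = c(33031813, 33865656, 35336720)))
  lib <- SubstitutionLibrary(
    data.frame(line_id = c("SN57", "SN58"), chrom = "Chr04",
               start_bp = c(33031813, 33031813),
               end_bp = c(33865656, 35336720)),
    donor = "NIV1")
  obs <- data.frame(line_id = c("SN57", "SN58"), trait = "seed_shattering",
                    state = c(0L, 1L))
  list(genome = gm, library = lib, obs = obs)
}

# a library with exact total and coverage lengths: disjoint base segments
# fill the target coverage chromosome by chromosome, remaining lines are
# duplicates nested inside the first base segment so they add total length
# but no new coverage
tunedLibrary <- function(donorLabel, n, totalBp, coverageBp, genome) {
  lens <- chromLengths(genome)
  rows <- list()
  rem <- coverageBp
  ci <- 1L
  while (rem > 0) {
    stopifnot(ci <= length(lens))
    take <- min(lens[[ci]] - 1, rem)
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = names(lens)[ci], start_bp = 1, end_bp = 1 + take)
    rem <- rem - take
    ci <- ci + 1L
  }
  k <- length(rows)
  n2 <- n - k
  extra <- totalBp - coverageBp
  stopifnot(n2 >= 1, extra >= n2)
  per <- floor(extra / n2)
  stopifnot(per + (extra - per * n2) <= lens[[1L]] - 1)
  for (i in seq_len(n2)) {
    len <- per + if (i == 1L) extra - per * n2 else 0
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = names(lens)[1L], start_bp = 1, end_bp = 1 + len)
  }
  d <- do.call(rbind, rows)
  d$line_id <- sprintf("%s%03d", donorLabel, seq_len(nrow(d)))
  SubstitutionLibrary(d, donor = donorLabel)
}

# small, fast simulator settings used by the property suites
smallSimConfig <- function(seed, nLines = 30L) {
  simulationConfig(
    seed = seed,
    chromLengths = setNames(rep(25e6, 4), sprintf("Chr%02d", 1:4)),
    nLines = setNames(as.integer(nLines), "SYN"),
    traits = "trait1")
}
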