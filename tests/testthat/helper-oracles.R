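# Independent oracles used across the suite. None of these share code with
# the package internals: interval operations are checked against a per-base
# occupancy scan, alignment scores against a hand-rolled Gotoh DP, and
# translation against seqinr's codon table.

# occupancy vector of a point-coordinate segment set on a chromosome of
# length L: position p (1..L) is covered iff some segment (s, e] has
# s < p <= e
occOf <- function(starts, ends, L) {
  v <- logical(L)
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    if (e >= s + 1) v[(s + 1):e] <- TRUE
  }
  v
}

grToOcc <- function(gr, L) {
  if (length(gr) == 0L) return(logical(L))
  occOf(GenomicRanges::start(gr), GenomicRanges::end(gr), L)
}

randomSegs <- function(n, L, chrom = "c1") {
  s <- sample.int(L - 2L, n, replace = TRUE)
  e <- pmin(L, s + 1L + stats::rgeom(n, 2 / L))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))
}

# Gotoh global alignment score with affine gaps: a gap of length g costs
# open + (g - 1) * ext; match/mismatch as given. Quadratic space, score only.
gotohScore <- function(a, b, match = 2, mismatch = -3, open = 6, ext = 1) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a
  M[1L, 1L] <- 0
  for (i in 2L:(n + 1L)) X[i, 1L] <- -(open + (i - 2L) * ext)
  for (j in 2L:(m + 1L)) Y[1L, j] <- -(open + (j - 2L) * ext)
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- if (a[i - 1L] == b[j - 1L]) match else mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - open, X[i - 1L, j] - ext,
                     Y[i - 1L, j] - open)
      Y[i, j] <- max(M[i, j - 1L] - open, Y[i, j - 1L] - ext,
                     X[i, j - 1L] - open)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# independent translation via seqinr's codon table, first-stop truncation
# applied the same way the contract states
seqinrTranslate <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3L
  aa <- seqinr::translate(strsplit(substr(cds, 1L, n), "")[[1L]])
  stop1 <- which(aa == "*")
  if (length(stop1)) aa <- aa[seq_len(stop1[1L])]
  paste(aa, collapse = "")
}

# brute-force flanking markers by linear search
bruteFlanks <- function(mk, chrom, s, e) {
  mk <- mk[mk$chrom == chrom, , drop = FALSE]
  left <- NA_character_; lbest <- -Inf
  right <- NA_character_; rbest <- Inf
  for (i in seq_len(nrow(mk))) {
    if (mk$pos[i] <= s && mk$pos[i] > lbest) {
      lbest <- mk$pos[i]; left <- mk$name[i]
    }
    if (mk$pos[i] >= e && mk$pos[i] < rbest) {
      rbest <- mk$pos[i]; right <- mk$name[i]
    }
  }
  list(left = left, right = right)
}

# positions compatible with every observation under the single-locus
# carrier model, per-bp
bpScanLocus <- function(carrierSegs, nonCarrierSegs, L) {
  occC <- lapply(seq_len(nrow(carrierSegs)), function(i)
    occOf(carrierSegs$start[i], carrierSegs$end[i], L))
  ok <- Reduce(`&`, occC)
  for (i in seq_len(nrow(nonCarrierSegs)))
    ok <- ok & !occOf(nonCarrierSegs$start[i], nonCarrierSegs$end[i], L)
  ok
}

# variant tables as comparable strings
vkey <- function(v) paste(v$kind, v$pos, v$ref, v$alt, sep = ":")
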