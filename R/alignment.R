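#' Global pairwise alignment of a recipient/donor CDS pair
#'
#' End-to-end (Needleman-Wunsch) alignment with affine gap costs via
#' Biostrings. Defaults: match +2, mismatch -3, a gap costs `gapOpen` (-6)
#' for its first base and `gapExtend` (-1) for each additional base.
#' Comparisons involving N score 0. The optimal alignment is deterministic;
#' indel placement inside repeats is settled downstream by the
#' left-normalization in [callVariants()], so reported variants do not
#' depend on which of several equal-scoring gap placements the aligner
#' returns.
#'
#' @param ref,alt reference (recipient) and alternate (donor) DNA strings
#'   over `{A,C,G,T,N}` (or `DNAString`s).
#' @param match,mismatch,gapOpen,gapExtend scoring parameters (see above;
#'   `gapOpen`/`gapExtend` are negative).
#' @return list with gapped strings `ref` and `alt` (equal length, `-` for
#'   gaps) and the alignment `score`.
#' @examples
#' alignGlobal("ACGT", "AGT")
#' @export
alignGlobal <- function(ref, alt, match = 2, mismatch = -3,
                        gapOpen = -6, gapExtend = -1) {
  ref <- .checkDna(ref, "'ref'")
  alt <- .checkDna(alt, "'alt'")
  if (gapOpen > 0 || gapExtend > 0)
    stop("gap penalties must be <= 0")
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- match
  mat["N", ] <- 0; mat[, "N"] <- 0
  ## Biostrings charges gapOpening + L*gapExtension for a length-L gap;
  ## convert so the first gapped base costs |gapOpen| in our convention
  pwa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(alt),
    subject = Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = mat,
    gapOpening = -(gapOpen - gapExtend), gapExtension = -gapExtend)
  list(ref = as.character(Biostrings::alignedSubject(pwa)),
       alt = as.character(Biostrings::alignedPattern(pwa)),
       score = Biostrings::score(pwa))
}
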