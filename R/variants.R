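## Variants are reported against the ungapped reference, 1-based:
##   SNP       pos = the substituted base;    ref = 1 base, alt = 1 base
##   deletion  pos = first deleted base;      ref = deleted run, alt = ""
##   insertion pos = base the run is inserted BEFORE (1..len+1);
##             ref = "", alt = inserted run
## Indels are left-normalized: shifted left through repeats to the leftmost
## equivalent placement, so equal edits are always described identically.

.variantDf <- function(kind = character(), pos = integer(),
                       ref = character(), alt = character()) {
  data.frame(kind = kind, pos = as.integer(pos), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

## leftmost equivalent placement of one indel against ref (a char vector)
.leftNormalize <- function(kind, pos, seq, refChars) {
  L <- nchar(seq)
  s <- strsplit(seq, "")[[1L]]
  if (kind == "deletion") {
    while (pos > 1L && refChars[pos - 1L] == refChars[pos + L - 1L])
      pos <- pos - 1L
    seq <- paste(refChars[pos:(pos + L - 1L)], collapse = "")
  } else if (kind == "insertion") {
    while (pos > 1L && refChars[pos - 1L] == s[L]) {
      s <- c(refChars[pos - 1L], s[-L])
      pos <- pos - 1L
    }
    seq <- paste(s, collapse = "")
  }
  list(pos = pos, seq = seq)
}

#' Extract variants from a global alignment
#'
#' Walks the alignment columns: mismatch columns become SNPs; each maximal
#' run of gap columns becomes a single insertion (gaps in the reference) or
#' deletion (gaps in the alternate). Indels are left-normalized against the
#' reference, positions are 1-based on the ungapped reference.
#'
#' @param alignment list with gapped `ref` and `alt` strings (from
#'   [alignGlobal()]), or pass the two strings via `ref`/`alt`.
#' @param ref,alt optional gapped strings, used when `alignment` is NULL.
#' @return data.frame with columns `kind` (`"SNP"`, `"insertion"`,
#'   `"deletion"`), `pos`, `ref`, `alt` (empty string for the absent side
#'   of an indel), sorted by position.
#' @examples
#' callVariants(alignGlobal("ATGAAAC", "ATGAAC")) # deletion at pos 4
#' @export
callVariants <- function(alignment = NULL, ref = NULL, alt = NULL) {
  if (!is.null(alignment)) { ref <- alignment$ref; alt <- alignment$alt }
  if (is.null(ref) || is.null(alt) || nchar(ref) != nchar(alt))
    stop("need gapped 'ref' and 'alt' strings of equal length")
  r <- strsplit(toupper(ref), "")[[1L]]
  a <- strsplit(toupper(alt), "")[[1L]]
  if (any(r == "-" & a == "-"))
    stop("alignment has a column that is gap in both sequences")
  refChars <- r[r != "-"]
  n <- length(r)
  out <- .variantDf()
  refPos <- 0L
  i <- 1L
  while (i <= n) {
    if (r[i] != "-" && a[i] != "-") {
      refPos <- refPos + 1L
      if (r[i] != a[i])
        out <- rbind(out, .variantDf("SNP", refPos, r[i], a[i]))
      i <- i + 1L
    } else if (a[i] == "-") {            # run of gaps in alt -> deletion
      j <- i
      while (j <= n && a[j] == "-") j <- j + 1L
      delSeq <- paste(r[i:(j - 1L)], collapse = "")
      norm <- .leftNormalize("deletion", refPos + 1L, delSeq, refChars)
      out <- rbind(out, .variantDf("deletion", norm$pos, norm$seq, ""))
      refPos <- refPos + (j - i)
      i <- j
    } else {                             # run of gaps in ref -> insertion
      j <- i
      while (j <= n && r[j] == "-") j <- j + 1L
      insSeq <- paste(a[i:(j - 1L)], collapse = "")
      norm <- .leftNormalize("insertion", refPos + 1L, insSeq, refChars)
      out <- rbind(out, .variantDf("insertion", norm$pos, "", norm$seq))
      i <- j
    }
  }
  out <- out[order(out$pos, match(out$kind, c("insertion", "SNP",
                                              "deletion"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply variants to a reference sequence
#'
#' Reconstructs the alternate sequence from a reference plus a variant list
#' in the [callVariants()] encoding. Edits are applied right-to-left so
#' reference-anchored positions stay valid. Variants must not overlap on
#' the reference.
#'
#' @param ref reference DNA string.
#' @param variants data.frame with columns `kind`, `pos`, `ref`, `alt`.
#' @return the edited sequence (character).
#' @export
applyVariants <- function(ref, variants) {
  ref <- .checkDna(ref, "'ref'")
  .checkVariantTable(variants, nchar(ref))
  s <- ref
  ord <- order(variants$pos, decreasing = TRUE)
  for (i in ord) {
    v <- variants[i, ]
    if (v$kind == "SNP") {
      substr(s, v$pos, v$pos) <- v$alt
    } else if (v$kind == "deletion") {
      s <- paste0(substr(s, 1L, v$pos - 1L),
                  substr(s, v$pos + nchar(v$ref), nchar(s)))
    } else {
      s <- paste0(substr(s, 1L, v$pos - 1L), v$alt,
                  substr(s, v$pos, nchar(s)))
    }
  }
  s
}

.variantFootprint <- function(variants) {
  ## half-open footprints on the reference; insertions sit between bases
  st <- ifelse(variants$kind == "insertion", variants$pos - 0.5,
               variants$pos)
  en <- ifelse(variants$kind == "insertion", variants$pos - 0.5,
               variants$pos + nchar(variants$ref) - 1)
  cbind(st, en)
}

.checkVariantTable <- function(variants, refLen) {
  need <- c("kind", "pos", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop("variant table needs columns ", paste(need, collapse = ", "))
  if (!all(variants$kind %in% c("SNP", "insertion", "deletion")))
    stop("variant kind must be SNP, insertion or deletion")
  if (nrow(variants) == 0L) return(invisible(variants))
  bad <- (variants$kind == "SNP" &
            (nchar(variants$ref) != 1L | nchar(variants$alt) != 1L)) |
         (variants$kind == "insertion" &
            (nchar(variants$ref) != 0L | nchar(variants$alt) == 0L)) |
         (variants$kind == "deletion" &
            (nchar(variants$alt) != 0L | nchar(variants$ref) == 0L))
  if (any(bad)) stop("malformed variant at row ", which(bad)[1L])
  maxEnd <- ifelse(variants$kind == "insertion", variants$pos - 1L,
                   variants$pos + nchar(variants$ref) - 1L)
  if (any(variants$pos < 1L) ||
      any(maxEnd > refLen) ||
      any(variants$kind == "insertion" & variants$pos > refLen + 1L))
    stop("variant beyond the end of the reference")
  fp <- .variantFootprint(variants)
  o <- order(fp[, 1L])
  if (nrow(variants) > 1L &&
      any(fp[o, 1L][-1L] <= fp[o, 2L][-nrow(fp)]))
    stop("overlapping variants")
  invisible(variants)
}

#' Translate a CDS with the standard genetic code
#'
#' Translation stops at (and includes) the first stop codon, rendered
#' `"*"`. Codons containing N translate to `"X"`. A trailing incomplete
#' codon is dropped with a warning.
#'
#' @param cds DNA string over `{A,C,G,T,N}`, length >= 3.
#' @return amino-acid string.
#' @examples
#' translateCds("ATGAAATAA") # "MK*"
#' @export
translateCds <- function(cds) {
  cds <- .checkDna(cds, "'cds'")
  n <- nchar(cds)
  if (n < 3L) stop("'cds' must be at least one codon")
  if (n %% 3L != 0L) {
    warning("CDS length not a multiple of 3; ignoring ", n %% 3L,
            " trailing base(s)")
    cds <- substr(cds, 1L, n - n %% 3L)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X",
                                           no.init.codon = TRUE))
  stop1 <- regexpr("*", aa, fixed = TRUE)
  if (stop1 > 0L) aa <- substr(aa, 1L, stop1)
  aa
}

#' Codon-level consequences of CDS variants
#'
#' Annotates each variant against the reference reading frame: SNPs by
#' translating the reference versus mutated codon (synonymous / missense /
#' stop_gained / stop_lost), indels by the length-mod-3 rule
#' (inframe_insertion / inframe_deletion with `aa_delta` = length/3, else
#' frameshift). For in-frame indels whose breakpoints respect codon
#' boundaries the affected residues are reported in `aa_ref`/`aa_alt`.
#' A SNP's consequence is always relative to the reference frame, even when
#' an indel precedes it; compound effects surface only in the summary's
#' `protein_length_delta`.
#'
#' @param variants data.frame from [callVariants()].
#' @param refCds the reference CDS (warns when it does not start with ATG).
#' @return list with `consequences` (one row per variant: `kind`, `pos`,
#'   `category`, `codon_index`, `aa_ref`, `aa_alt`, `aa_delta`) and
#'   `summary` (one row: `n_snp`, `n_insertion`, `n_deletion`,
#'   `n_aa_substitutions`, `protein_length_delta`, `has_frameshift`).
#' @examples
#' v <- data.frame(kind = "SNP", pos = 119L, ref = "A", alt = "G")
#' cds <- paste0(strrep("ATG", 39), "AAC", strrep("GCT", 60))
#' annotateCds(v, cds)$consequences$category # missense (Asn -> Ser)
#' @export
annotateCds <- function(variants, refCds) {
  refCds <- .checkDna(refCds, "'refCds'")
  if (substr(refCds, 1L, 3L) != "ATG")
    warning("reference CDS does not start with ATG")
  .checkVariantTable(variants, nchar(refCds))
  n <- nrow(variants)
  cons <- data.frame(kind = character(n), pos = integer(n),
                     category = character(n), codon_index = integer(n),
                     aa_ref = character(n), aa_alt = character(n),
                     aa_delta = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    ci <- as.integer(ceiling(v$pos / 3))
    cons$kind[i] <- v$kind; cons$pos[i] <- v$pos; cons$codon_index[i] <- ci
    if (v$kind == "SNP") {
      cod0 <- substr(refCds, 3L * ci - 2L, 3L * ci)
      if (nchar(cod0) < 3L) {     # SNP in a trailing partial codon
        cons$category[i] <- "incomplete_codon"
        cons$aa_ref[i] <- cons$aa_alt[i] <- NA_character_
        cons$aa_delta[i] <- 0L
        next
      }
      off <- v$pos - (3L * ci - 3L)
      cod1 <- cod0
      substr(cod1, off, off) <- v$alt
      aa0 <- .translateCodon(cod0); aa1 <- .translateCodon(cod1)
      cons$aa_ref[i] <- aa0; cons$aa_alt[i] <- aa1; cons$aa_delta[i] <- 0L
      cons$category[i] <-
        if (aa0 == aa1) "synonymous"
        else if (aa1 == "*") "stop_gained"
        else if (aa0 == "*") "stop_lost"
        else "missense"
    } else {
      L <- max(nchar(v$ref), nchar(v$alt))
      if (L %% 3L != 0L) {
        cons$category[i] <- "frameshift"
        cons$aa_ref[i] <- cons$aa_alt[i] <- NA_character_
        cons$aa_delta[i] <- NA_integer_
      } else if (v$kind == "deletion") {
        cons$category[i] <- "inframe_deletion"
        cons$aa_delta[i] <- -L %/% 3L
        if (v$pos %% 3L == 1L) {
          cons$aa_ref[i] <- translateCds(v$ref)
          cons$aa_alt[i] <- ""
        } else cons$aa_ref[i] <- cons$aa_alt[i] <- NA_character_
      } else {
        cons$category[i] <- "inframe_insertion"
        cons$aa_delta[i] <- L %/% 3L
        if (v$pos %% 3L == 1L) {
          cons$aa_ref[i] <- ""
          cons$aa_alt[i] <- translateCds(v$alt)
        } else cons$aa_ref[i] <- cons$aa_alt[i] <- NA_character_
      }
    }
  }
  isIns <- variants$kind == "insertion"
  isDel <- variants$kind == "deletion"
  net <- sum(nchar(variants$alt[isIns])) - sum(nchar(variants$ref[isDel]))
  summary <- data.frame(
    n_snp = sum(variants$kind == "SNP"),
    n_insertion = sum(isIns),
    n_deletion = sum(isDel),
    n_aa_substitutions = sum(cons$category == "missense"),
    protein_length_delta = if (net %% 3L == 0L) net %/% 3L else NA_integer_,
    has_frameshift = any(cons$category == "frameshift"))
  list(consequences = cons, summary = summary)
}

.translateCodon <- function(codon) {
  if (grepl("N", codon)) return("X")
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

#' Full recipient-vs-donor CDS comparison
#'
#' Convenience pipeline: [alignGlobal()] then [callVariants()] then
#' [annotateCds()].
#'
#' @inheritParams alignGlobal
#' @param ... scoring parameters passed to [alignGlobal()].
#' @return list with `alignment`, `variants`, `consequences`, `summary`.
#' @export
variantPipeline <- function(ref, alt, ...) {
  aln <- alignGlobal(ref, alt, ...)
  variants <- callVariants(aln)
  ann <- annotateCds(variants, gsub("-", "", aln$ref, fixed = TRUE))
  list(alignment = aln, variants = variants,
       consequences = ann$consequences, summary = ann$summary)
}

#' Read a recipient/donor CDS pair from FASTA
#'
#' Either one FASTA with two records (reference first) or two single-record
#' FASTAs.
#'
#' @param ref path to the FASTA holding the reference (and possibly both)
#'   sequences.
#' @param alt optional path to the alternate FASTA.
#' @return list with `ref_id`, `alt_id`, `ref`, `alt` (plain strings).
#' @export
readCdsPair <- function(ref, alt = NULL) {
  x <- Biostrings::readDNAStringSet(ref)
  if (is.null(alt)) {
    if (length(x) < 2L)
      stop("FASTA must contain two records when 'alt' is not given")
    y <- x[2L]; x <- x[1L]
  } else {
    y <- Biostrings::readDNAStringSet(alt)[1L]
  }
  list(ref_id = names(x), alt_id = names(y),
       ref = as.character(x[[1L]]), alt = as.character(y[[1L]]))
}

#' Write variants as TSV or minimal VCF 4.2
#'
#' The VCF uses the conventional anchored representation for indels (REF
#' and ALT share a leading anchor base; an insertion before position 1 is
#' anchored on the base after it).
#'
#' @param variants data.frame from [callVariants()].
#' @param refCds the reference CDS (for indel anchor bases).
#' @param path output path.
#' @param seqId CHROM label (the reference sequence id).
#' @param consequences optional consequence table to merge into the TSV.
#' @return the path, invisibly.
#' @export
writeVariantsTsv <- function(variants, path, consequences = NULL) {
  out <- variants
  if (!is.null(consequences))
    out <- cbind(out, consequences[c("category", "codon_index",
                                     "aa_ref", "aa_alt", "aa_delta")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVariantsTsv
#' @export
writeVariantsVcf <- function(variants, refCds, path, seqId = "cds") {
  refCds <- .checkDna(refCds, "'refCds'")
  .checkVariantTable(variants, nchar(refCds))
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", seqId, ",length=", nchar(refCds), ">"),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$kind == "SNP") {
      pos <- v$pos; ref <- v$ref; alt <- v$alt
    } else if (v$kind == "deletion") {
      if (v$pos > 1L) {
        pos <- v$pos - 1L
        anchor <- substr(refCds, pos, pos)
        ref <- paste0(anchor, v$ref); alt <- anchor
      } else {
        pos <- 1L
        anchor <- substr(refCds, v$pos + nchar(v$ref),
                         v$pos + nchar(v$ref))
        ref <- paste0(v$ref, anchor); alt <- anchor
      }
    } else {
      if (v$pos > 1L) {
        pos <- v$pos - 1L
        anchor <- substr(refCds, pos, pos)
        ref <- anchor; alt <- paste0(anchor, v$alt)
      } else {
        pos <- 1L
        anchor <- substr(refCds, 1L, 1L)
        ref <- anchor; alt <- paste0(v$alt, anchor)
      }
    }
    lines <- c(lines, paste(seqId, pos, ".", ref, alt, ".", "PASS", ".",
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
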