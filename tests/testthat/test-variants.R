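test_that("identical sequences align gap-free at the match score", {
  s <- randomCds(60, seed = 2)
  aln <- alignGlobal(s, s)
  expect_equal(aln$ref, s)
  expect_equal(aln$alt, s)
  expect_equal(aln$score, 2 * nchar(s))
  expect_equal(nrow(callVariants(aln)), 0)
  expect_error(alignGlobal("", "ACGT"), "non-empty")
})

test_that("a single-base deletion aligns and normalizes leftmost", {
  v <- callVariants(alignGlobal("ACGT", "AGT"))
  expect_equal(nrow(v), 1)
  expect_equal(v$kind, "deletion")
  expect_equal(v$pos, 2)  # deleting C: the unique, leftmost explanation
  expect_equal(v$ref, "C")
  # homopolymer run: leftmost equivalent placement
  v2 <- callVariants(alignGlobal("ATGAAAC", "ATGAAC"))
  expect_equal(v2$pos, 4)
  expect_equal(v2$kind, "deletion")
})

test_that("alignment scores match an independent Gotoh DP", {
  set.seed(17)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:5) {
    ref <- paste(sample(bases, 150, replace = TRUE), collapse = "")
    # ~95% identity with small indels
    alt <- ref
    mut <- mutateCds(ref, randomEditSpec(ref, nSnp = 5, nIns = 1,
                                         nDel = 1, seed = rep,
                                         indelLengths = c(1L, 2L, 3L)))
    alt <- mut$alt
    aln <- alignGlobal(ref, alt)
    expect_equal(aln$score, gotohScore(ref, alt))
    # removing gaps recovers the inputs
    expect_equal(gsub("-", "", aln$ref, fixed = TRUE), ref)
    expect_equal(gsub("-", "", aln$alt, fixed = TRUE), alt)
  }
})

test_that("SNP calling reports position and alleles", {
  v <- callVariants(ref = "ATGAACGGT", alt = "ATGAGCGGT")
  expect_equal(v$kind, "SNP")
  expect_equal(v$pos, 5)
  expect_equal(v$ref, "A")
  expect_equal(v$alt, "G")
})

test_that("called variants reconstruct the alternate sequence", {
  set.seed(31)
  for (rep in 1:100) {
    ref <- randomCds(80, seed = 1000 + rep)
    mut <- mutateCds(ref, randomEditSpec(ref, nSnp = 4, nIns = 1,
                                         nDel = 1, seed = 2000 + rep))
    v <- callVariants(alignGlobal(ref, mut$alt))
    expect_equal(applyVariants(ref, v), mut$alt)
  }
})

test_that("overlapping or out-of-range variants are rejected", {
  ref <- "ATGAAACCCGGGTAA"
  expect_error(annotateCds(data.frame(kind = "SNP", pos = 99L, ref = "A",
                                      alt = "G"), ref), "beyond")
  bad <- data.frame(kind = c("deletion", "SNP"), pos = c(4L, 5L),
                    ref = c("AAA", "C"), alt = c("", "G"))
  expect_error(annotateCds(bad, ref), "overlap")
})

test_that("codon-level consequences follow the printed examples", {
  # 119th A>G hits base 2 of codon 40 (AAC): Asn -> Ser missense
  cds <- paste0(strrep("ATG", 39), "AAC", strrep("GCT", 20), "TAA")
  ann <- annotateCds(data.frame(kind = "SNP", pos = 119L, ref = "A",
                                alt = "G"), cds)
  expect_equal(ann$consequences$category, "missense")
  expect_equal(ann$consequences$codon_index, 40)
  expect_equal(ann$consequences$aa_ref, "N")
  expect_equal(ann$consequences$aa_alt, "S")
  # synonymous third-position change
  syn <- annotateCds(data.frame(kind = "SNP", pos = 6L, ref = "G",
                                alt = "A"), "ATGACGTTTTAA")
  expect_equal(syn$consequences$category, "synonymous")
  # 18-bp codon-boundary deletion: 6 residues out
  del18 <- annotateCds(data.frame(kind = "deletion", pos = 10L,
                                  ref = strrep("GCA", 6), alt = ""),
                       paste0("ATGCCCGGG", strrep("GCA", 6),
                              strrep("TTC", 30), "TAA"))
  expect_equal(del18$consequences$category, "inframe_deletion")
  expect_equal(del18$consequences$aa_delta, -6)
  expect_equal(del18$summary$protein_length_delta, -6)
  expect_false(del18$summary$has_frameshift)
  # 14-bp deletion: frameshift
  ref <- randomCds(60, seed = 5)
  d14 <- substr(ref, 31, 44)
  fs <- annotateCds(data.frame(kind = "deletion", pos = 31L, ref = d14,
                               alt = ""), ref)
  expect_equal(fs$consequences$category, "frameshift")
  expect_true(fs$summary$has_frameshift)
  expect_true(is.na(fs$summary$protein_length_delta))
  # 72-bp insertion: +24 residues
  ins <- annotateCds(data.frame(kind = "insertion", pos = 10L, ref = "",
                                alt = strrep("GAC", 24)), ref)
  expect_equal(ins$consequences$category, "inframe_insertion")
  expect_equal(ins$consequences$aa_delta, 24)
  expect_equal(ins$summary$protein_length_delta, 24)
  # stop gained
  sg <- annotateCds(data.frame(kind = "SNP", pos = 4L, ref = "A",
                               alt = "T"), "ATGAAACCCTAA")
  expect_equal(sg$consequences$category, "stop_gained")
})

test_that("summaries tally the variant list exactly", {
  set.seed(8)
  for (rep in 1:20) {
    ref <- randomCds(100, seed = 300 + rep)
    spec <- randomEditSpec(ref, nSnp = sample(0:6, 1),
                           nIns = sample(0:2, 1), nDel = sample(0:2, 1),
                           seed = 400 + rep)
    if (nrow(spec) == 0) next
    ann <- annotateCds(spec, ref)
    expect_equal(ann$summary$n_snp, sum(spec$kind == "SNP"))
    expect_equal(ann$summary$n_insertion, sum(spec$kind == "insertion"))
    expect_equal(ann$summary$n_deletion, sum(spec$kind == "deletion"))
    expect_equal(ann$summary$n_aa_substitutions,
                 sum(ann$consequences$category == "missense"))
    net <- sum(nchar(spec$alt[spec$kind == "insertion"])) -
      sum(nchar(spec$ref[spec$kind == "deletion"]))
    if (net %% 3 == 0)
      expect_equal(ann$summary$protein_length_delta, net / 3)
    # single-indel equivalence: frameshift iff net indel length mod 3 != 0
    if (sum(spec$kind != "SNP") == 1)
      expect_equal(ann$summary$has_frameshift, net %% 3 != 0)
  }
})

test_that("translation matches an independent codon table", {
  expect_equal(translateCds("ATGAAATAA"), "MK*")
  expect_equal(translateCds("AACAGC"), "NS")
  expect_equal(translateCds("ATGANATGC"), "MXC")
  expect_error(translateCds("ATGAXA"), "outside")
  expect_warning(out <- translateCds("ATGAAAT"), "multiple of 3")
  expect_equal(out, "MK")
  skip_if_not_installed("seqinr")
  set.seed(12)
  for (rep in 1:200) {
    n <- sample(1:50, 1)
    s <- paste(sample(c("A", "C", "G", "T"), 3 * n + 3, replace = TRUE),
               collapse = "")
    expect_equal(translateCds(s), seqinrTranslate(s))
  }
})

test_that("FASTA pairs, TSV and VCF writers round-trip", {
  ref <- randomCds(50, seed = 44)
  mut <- mutateCds(ref, randomEditSpec(ref, nSnp = 2, nIns = 1, nDel = 1,
                                       seed = 45))
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">HJX74_cds", ref, ">donor_cds", mut$alt), fa)
  pair <- readCdsPair(fa)
  expect_equal(pair$ref, ref)
  expect_equal(pair$alt, mut$alt)
  res <- variantPipeline(pair$ref, pair$alt)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeVariantsTsv(res$variants, tsv, res$consequences)
  back <- read.delim(tsv, na.strings = "NA")
  expect_equal(nrow(back), nrow(res$variants))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeVariantsVcf(res$variants, ref, vcf, seqId = "cds1")
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- read.delim(text = lines[-(1:2)], comment.char = "")
  expect_equal(nrow(body), nrow(res$variants))
  # anchored REF/ALT: applying VCF rows to ref also reconstructs alt
  for (i in seq_len(nrow(body))) {
    p <- body$POS[i]
    expect_equal(substr(ref, p, p + nchar(body$REF[i]) - 1L),
                 as.character(body$REF[i]))
  }
})
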