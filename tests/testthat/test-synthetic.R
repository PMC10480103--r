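test_that("genome simulation is deterministic and marker-dense as set", {
  cfg <- smallSimConfig(seed = 3)
  g1 <- makeGenome(cfg)
  g2 <- makeGenome(cfg)
  expect_identical(markerTable(g1), markerTable(g2))
  expect_false(identical(markerTable(g1),
                         markerTable(makeGenome(smallSimConfig(seed = 4)))))
  # marker count ~ total length / spacing under symmetric jitter
  expected <- genomeSize(g1) / cfg$markerSpacing
  expect_lt(abs(nrow(markerTable(g1)) - expected), 0.1 * expected)
  # all markers within bounds (GenomeMap validity re-checked explicitly)
  mk <- markerTable(g1)
  expect_true(all(mk$pos >= 1 & mk$pos <= chromLengths(g1)[mk$chrom]))
  expect_error(simulationConfig(seed = 1, chromLengths = c(a = 1e5),
                                markerSpacing = 2e5), "spacing")
  expect_error(simulationConfig(), "mandatory")
})

test_that("simulated libraries are marker-delimited with the set mean", {
  cfg <- simulationConfig(
    seed = 10, chromLengths = c(C1 = 200e6),
    nLines = c(SYN = 1500L), markerSpacing = 1.5e6)
  gm <- makeGenome(cfg)
  lib <- simulateLibrary(gm, cfg, donorLabel = "SYN")
  expect_equal(nLines(lib), 1500)
  gr <- segmentRanges(lib)
  pos <- markerTable(gm)$pos
  expect_true(all(GenomicRanges::start(gr) %in% pos))
  expect_true(all(GenomicRanges::end(gr) %in% pos))
  # sample mean of segment lengths near the configured 5 Mb (snapping is
  # symmetric, truncation negligible on a 200 Mb chromosome)
  m <- mean(segmentLength(gr)) / 1e6
  se <- 5 / sqrt(1500)
  expect_lt(abs(m - 5), 3 * se + 0.75)  # slack for snap discretization
  # empty library
  lib0 <- simulateLibrary(gm, cfg, donorLabel = "SYN", n = 0L)
  expect_equal(nLines(lib0), 0)
})

test_that("phenotypes encode the carrier model and flip at rate epsilon", {
  cfg <- smallSimConfig(seed = 6, nLines = 400L)
  gm <- makeGenome(cfg)
  lib <- simulateLibrary(gm, cfg, donorLabel = "SYN")
  gene <- plantCausalGene(lib, gm, "trait1", seed = 60)
  obs <- assignPhenotypes(lib, gene, epsilon = 0)
  gr <- segmentRanges(lib)
  ggr <- GenomicRanges::GRanges(gene$chrom,
                                IRanges::IRanges(gene$start_bp,
                                                 gene$end_bp))
  covers <- vapply(seq_along(gr), function(i)
    segmentRelation(gr[i], ggr)$relation == "contained", TRUE)
  expect_equal(obs$state == 1L, covers)
  expect_gte(sum(obs$state), 1)
  # with noise the flip fraction tracks epsilon
  eps <- 0.1
  obsN <- assignPhenotypes(lib, gene, epsilon = eps, seed = 61)
  flips <- mean(obsN$state != obs$state)
  se <- sqrt(eps * (1 - eps) / nrow(obs))
  expect_lt(abs(flips - eps), 4 * se)
})

test_that("edit specs apply right-to-left and report normalized truth", {
  ref <- "ATGAAACCCGGGTTTAAATAA"
  out <- mutateCds(ref, data.frame(kind = character(), pos = integer(),
                                   ref = character(), alt = character()))
  expect_equal(out$alt, ref)
  expect_equal(nrow(out$truth), 0)
  # deletions can be given by length; truth comes back left-normalized
  out2 <- mutateCds(ref, data.frame(kind = "deletion", pos = 5L,
                                    ref = "2", alt = ""))
  expect_equal(nchar(out2$alt), nchar(ref) - 2)
  expect_equal(out2$truth$pos, 4)  # shifted left through the A-run
  expect_error(mutateCds(ref, data.frame(
    kind = c("deletion", "SNP"), pos = c(4L, 5L),
    ref = c("AAC", "A"), alt = c("", "G"))), "overlap")
  # an 18-bp codon-boundary deletion annotates as -6 residues
  ref2 <- randomCds(80, seed = 70)
  out3 <- mutateCds(ref2, data.frame(kind = "deletion", pos = 16L,
                                     ref = "18", alt = ""))
  ann <- annotateCds(out3$truth, ref2)
  expect_equal(ann$consequences$aa_delta, -6)
})

test_that("a written data set reads back identically and re-generates", {
  cfg <- smallSimConfig(seed = 8)
  ds <- simulateDataset(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeDataset(ds, d1)
  writeDataset(simulateDataset(cfg), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  back <- readDataset(d1)
  expect_identical(segmentRanges(back$libraries$SYN),
                   segmentRanges(ds$libraries$SYN))
  expect_identical(chromLengths(back$genome), chromLengths(ds$genome))
  expect_identical(markerTable(back$genome), markerTable(ds$genome))
  expect_equal(back$phenotypes, ds$phenotypes)
  expect_equal(back$manifest$seed, 8)
  # truth table matches the in-memory edits
  truth <- do.call(rbind, lapply(names(ds$cds), function(g)
    cbind(gene = g, ds$cds[[g]]$truth)))
  expect_equal(back$truth$pos, truth$pos)
  expect_equal(back$truth$kind, truth$kind)
})

test_that("simulate-phenotype-map recovers the planted gene", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- smallSimConfig(seed = 100 + s)
    gm <- makeGenome(cfg)
    lib <- simulateLibrary(gm, cfg, donorLabel = "SYN")
    gene <- plantCausalGene(lib, gm, "trait1", seed = 200 + s)
    obs <- assignPhenotypes(lib, gene, epsilon = 0)
    loci <- mapTrait(lib, obs, "trait1", gm)
    ggr <- GenomicRanges::GRanges(gene$chrom,
                                  IRanges::IRanges(gene$start_bp,
                                                   gene$end_bp))
    ok <- any(vapply(loci, function(l)
      any(vapply(seq_along(l@intervals), function(i)
        segmentRelation(l@intervals[i], ggr)$relation == "contained",
        TRUE)), TRUE))
    hits <- hits + ok
  }
  expect_equal(hits, 20L)
})
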