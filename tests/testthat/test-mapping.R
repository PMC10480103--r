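test_that("carriers group by chromosome and overlap connectivity", {
  lib <- SubstitutionLibrary(
    data.frame(line_id = c("A", "B", "C", "D", "E"),
               chrom = c("c7", "c7", "c8", "c4", "c4"),
               start_bp = c(2e6, 3e6, 20e6, 1e6, 10e6),
               end_bp = c(4e6, 5e6, 22e6, 3e6, 12e6)),
    donor = "D")
  obs <- data.frame(line_id = c("A", "B", "C", "D", "E"), trait = "t",
                    state = 1L)
  g <- groupCarriers(lib, obs, "t")
  expect_length(g, 4)  # c7 connected pair, c8 singleton, c4 two disjoint
  chroms <- vapply(g, `[[`, "", "chrom")
  expect_equal(sort(chroms), c("c4", "c4", "c7", "c8"))
  sizes <- vapply(g, function(x) length(x$lines), 0L)
  expect_equal(sum(sizes), 5)
  expect_true(any(vapply(g, function(x)
    setequal(x$lines, c("A", "B")), TRUE)))
  # segments touching at a marker are separate components
  lib2 <- SubstitutionLibrary(
    data.frame(line_id = c("P", "Q"), chrom = "c1",
               start_bp = c(1e6, 2e6), end_bp = c(2e6, 3e6)), donor = "D")
  obs2 <- data.frame(line_id = c("P", "Q"), trait = "t", state = 1L)
  expect_length(groupCarriers(lib2, obs2, "t"), 2)
  expect_error(groupCarriers(lib, obs[obs$state == 0, ], "t"),
               "no carrier")
})

test_that("seed-shattering worked example maps to 1.47 Mb PSM361-RM559", {
  fx <- shatteringFixture()
  loci <- mapTrait(fx$library, fx$obs, "seed_shattering", fx$genome)
  expect_length(loci, 1)
  l <- loci[[1]]
  iv <- locusInterval(l)
  expect_equal(GenomicRanges::start(iv), 33865656)
  expect_equal(GenomicRanges::end(iv), 35336720)
  expect_equal(l@lengthMb, 1.47)
  expect_equal(l@leftMarker, "PSM361")
  expect_equal(l@rightMarker, "RM559")
  expect_equal(l@carriers, "SN58")
  expect_equal(l@excluders, "SN57")
  expect_false(l@ambiguous)
})

test_that("two awn carriers minus a non-carrier give the common interval", {
  gm <- GenomeMap(data.frame(chrom = "Chr04", length = 36e6))
  lib <- SubstitutionLibrary(
    data.frame(line_id = c("SR118", "SR119", "SR123"), chrom = "Chr04",
               start_bp = c(5e6, 7971563, 16789753),
               end_bp = c(16789753, 20e6, 22e6)),
    donor = "RUF")
  obs <- data.frame(line_id = c("SR118", "SR119", "SR123"), trait = "awn",
                    state = c(1L, 1L, 0L))
  l <- mapTrait(lib, obs, "awn", gm)[[1]]
  iv <- locusInterval(l)
  expect_equal(GenomicRanges::start(iv), 7971563)
  expect_equal(GenomicRanges::end(iv), 16789753)
  # bp-scan oracle on a scaled copy of the same configuration
  sc <- function(x) as.integer(round(x / 1e3))
  ok <- bpScanLocus(
    data.frame(start = sc(c(5e6, 7971563)), end = sc(c(16789753, 20e6))),
    data.frame(start = sc(16789753), end = sc(22e6)), sc(36e6))
  expect_equal(range(which(ok)), c(sc(7971563) + 1, sc(16789753)))
})

test_that("a lone carrier maps to its whole segment", {
  gm <- GenomeMap(data.frame(chrom = "c1", length = 1e6))
  lib <- SubstitutionLibrary(
    data.frame(line_id = "S1", chrom = "c1", start_bp = 100,
               end_bp = 2000), donor = "D")
  obs <- data.frame(line_id = "S1", trait = "t", state = 1L)
  l <- mapTrait(lib, obs, "t", gm)[[1]]
  expect_equal(GenomicRanges::start(locusInterval(l)), 100)
  expect_equal(GenomicRanges::end(locusInterval(l)), 2000)
  expect_true(is.na(l@leftMarker))
})

test_that("mapLocus equals the per-bp compatibility oracle", {
  set.seed(21)
  L <- 5000L
  gm <- GenomeMap(data.frame(chrom = "c1", length = L))
  for (rep in 1:100) {
    n <- sample(3:6, 1)
    s <- sample.int(L - 100L, n)
    e <- pmin(L, s + 50L + sample.int(1000L, n))
    lib <- SubstitutionLibrary(
      data.frame(line_id = sprintf("S%d", 1:n), chrom = "c1",
                 start_bp = s, end_bp = e), donor = "D")
    gene <- sample.int(L - 1L, 1)
    state <- as.integer(s < gene + 1 & gene + 1 <= e)  # covers bp gene+1
    if (sum(state) == 0) next
    obs <- data.frame(line_id = sprintf("S%d", 1:n), trait = "t",
                      state = state)
    groups <- groupCarriers(lib, obs, "t")
    got <- logical(L)
    err <- FALSE
    for (g in groups) {
      l <- try(mapLocus(g, lib, obs, gm, trait = "t"), silent = TRUE)
      if (inherits(l, "try-error")) { err <- TRUE; next }
      got <- got | grToOcc(l@intervals, L)
    }
    # oracle: positions compatible with all observations, restricted to
    # the carrier components actually mapped
    ok <- bpScanLocus(data.frame(start = s[state == 1],
                                 end = e[state == 1]),
                      data.frame(start = s[state == 0],
                                 end = e[state == 0]), L)
    if (!err) expect_identical(got, ok) else expect_true(all(!ok))
  }
})

test_that("adding informative lines never widens the interval", {
  set.seed(5)
  L <- 1e5L
  gm <- GenomeMap(data.frame(chrom = "c1", length = L))
  for (rep in 1:30) {
    gene <- sample.int(L - 1000L, 1)
    n <- 8L
    s <- pmax(1L, gene - sample.int(2e4L, n))
    e <- pmin(L, gene + 1000L + sample.int(2e4L, n))
    state <- rep(1L, n)
    ids <- sprintf("S%d", 1:n)
    widths <- numeric(0)
    for (k in 2:n) {
      lib <- SubstitutionLibrary(
        data.frame(line_id = ids[1:k], chrom = "c1", start_bp = s[1:k],
                   end_bp = e[1:k]), donor = "D")
      obs <- data.frame(line_id = ids[1:k], trait = "t", state = state[1:k])
      l <- mapTrait(lib, obs, "t", gm)[[1]]
      widths <- c(widths, sum(segmentLength(l@intervals)))
    }
    expect_true(all(diff(widths) <= 0))
  }
})

test_that("inconsistent phenotypes are refused, tolerance can rescue them", {
  gm <- GenomeMap(data.frame(chrom = "c1", length = 1e6))
  lib <- SubstitutionLibrary(
    data.frame(line_id = c("A", "B", "C"), chrom = "c1",
               start_bp = c(100, 100, 50), end_bp = c(5000, 5000, 9000)),
    donor = "D")
  # C covers the carriers' whole common region yet scores 0: contradiction
  obs <- data.frame(line_id = c("A", "B", "C"), trait = "t",
                    state = c(1L, 1L, 0L))
  expect_error(mapTrait(lib, obs, "t", gm), "inconsistent")
  l <- mapLocus(list(chrom = "c1", lines = c("A", "B")), lib, obs, gm,
                trait = "t", maxConflicts = 1L)
  expect_s4_class(l, "MappedLocus")
  expect_gt(sum(segmentLength(l@intervals)), 0)
})

test_that("exclusions splitting the interval flag the locus ambiguous", {
  gm <- GenomeMap(data.frame(chrom = "c1", length = 1e6))
  lib <- SubstitutionLibrary(
    data.frame(line_id = c("A", "B"), chrom = "c1",
               start_bp = c(1000, 4000), end_bp = c(9000, 6000)),
    donor = "D")
  obs <- data.frame(line_id = c("A", "B"), trait = "t", state = c(1L, 0L))
  l <- mapTrait(lib, obs, "t", gm)[[1]]
  expect_true(l@ambiguous)
  expect_length(l@intervals, 2)
  expect_equal(l@excluders, "B")
})

test_that("flanking markers match a brute-force search", {
  set.seed(13)
  for (rep in 1:50) {
    mk <- data.frame(name = sprintf("M%03d", 1:40), chrom = "c1",
                     pos = sort(sample.int(1e6, 40)))
    gm <- GenomeMap(data.frame(chrom = "c1", length = 1e6), mk)
    s <- sample.int(9e5, 1); e <- s + sample.int(9e4, 1)
    iv <- GenomicRanges::GRanges("c1", IRanges::IRanges(s, e))
    got <- flankingMarkers(iv, gm)
    want <- bruteFlanks(mk, "c1", s, e)
    expect_identical(got$left, want$left)
    expect_identical(got$right, want$right)
  }
  # interval before the first marker
  gm <- GenomeMap(data.frame(chrom = "c1", length = 1e6),
                  data.frame(name = "M1", chrom = "c1", pos = 5e5))
  fl <- flankingMarkers(GenomicRanges::GRanges("c1",
                                               IRanges::IRanges(10, 100)),
                        gm)
  expect_true(is.na(fl$left))
  expect_equal(fl$right, "M1")
})
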