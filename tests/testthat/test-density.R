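test_that("window densities merge overlapping repeats into coverage fractions", {
  genome <- c(chr1 = 30000)
  # [100,600) + [500,1100) zero-based == 101..600 and 501..1100 one-based;
  # union covers 1000 bases of the first 10-kb window
  reps <- makeRepeats("chr1", c(101, 501), c(600, 1100),
                      family = c("DNA/a", "LINE/b"), genome = genome)
  tr <- computeWindowDensities(reps, genome, w = 10000)
  d <- densityMatrix(tr)
  expect_equal(unname(d[, "all_te"]), c(0.1, 0, 0))

  # no repeats -> all zero
  tr0 <- computeWindowDensities(reps[0], genome, w = 10000)
  expect_true(all(densityMatrix(tr0) == 0))

  # one repeat spanning the whole chromosome -> density 1 in every window
  full <- makeRepeats("chr1", 1, 30000, family = "LINE/L2", genome = genome)
  tr1 <- computeWindowDensities(full, genome, w = 10000)
  expect_equal(unname(densityMatrix(tr1)[, "all_te"]), c(1, 1, 1))
  expect_equal(unname(densityMatrix(tr1)[, "retro"]), c(1, 1, 1))
  expect_equal(unname(densityMatrix(tr1)[, "dna"]), c(0, 0, 0))

  # unknown chromosome is an error naming it
  stray <- makeRepeats("chrZ", 1, 10)
  expect_error(computeWindowDensities(stray, genome), "chrZ")
})

test_that("densities match a per-base mask oracle on random instances", {
  set.seed(202)
  for (rep in 1:30) {
    L <- sample(50000:200000, 1)
    n <- sample(1:120, 1)
    s <- sample.int(L - 1, n, replace = TRUE)
    e <- pmin(L, s + sample.int(5000, n, replace = TRUE))
    reps <- makeRepeats("c", s, e, family = "DNA/x",
                        genome = c(c = L))
    w <- sample(c(1000L, 2500L, 10000L), 1)
    tr <- computeWindowDensities(reps, c(c = L), w = w)
    win <- densityWindows(tr)
    oracle <- maskCoverageOracle(L, s, e, GenomicRanges::start(win),
                                 GenomicRanges::end(win))
    got <- densityMatrix(tr)[, "dna"] * GenomicRanges::width(win)
    expect_equal(round(got), oracle, tolerance = 0)
  }
})

test_that("densities are translation invariant and monotone under added features", {
  set.seed(7)
  L <- 100000
  s <- sample.int(L - 3000, 40); e <- s + sample.int(2000, 40)
  shift <- 10000L
  t1 <- computeWindowDensities(makeRepeats("c", s, e, genome = c(c = L)),
                               c(c = L), w = 5000)
  t2 <- computeWindowDensities(
    makeRepeats("c", s + shift, e + shift, genome = c(c = L + shift)),
    c(c = L + shift), w = 5000)
  d1 <- densityMatrix(t1)[, "dna"]
  d2 <- densityMatrix(t2)[, "dna"]
  expect_equal(d1, d2[(shift / 5000 + 1):(shift / 5000 + length(d1))],
               ignore_attr = TRUE)

  more <- computeWindowDensities(
    makeRepeats("c", c(s, 500), c(e, 2500), genome = c(c = L)),
    c(c = L), w = 5000)
  expect_true(all(densityMatrix(more)[, "dna"] >= d1 - 1e-12))
})

test_that("category totals respect coverage semantics", {
  set.seed(31)
  L <- 80000
  fams <- c("DNA/a", "LINE/b", "Unknown/c", "LTR/d")
  s <- sample.int(L - 2000, 60, replace = TRUE)
  reps <- suppressWarnings(makeRepeats(
    "c", s, s + sample.int(1500, 60, replace = TRUE),
    family = sample(fams, 60, TRUE), genome = c(c = L)))
  tr <- computeWindowDensities(reps, c(c = L), w = 10000)
  d <- densityMatrix(tr)
  # all_te is at least each part and at most the sum of parts + Unknown
  dUnk <- densityMatrix(computeWindowDensities(
    reps[reps$repClass == "Unknown"], c(c = L), w = 10000))[, "all_te"]
  expect_true(all(d[, "all_te"] >= pmax(d[, "dna"], d[, "retro"]) - 1e-12))
  expect_true(all(d[, "all_te"] <= d[, "dna"] + d[, "retro"] + dUnk + 1e-12))
})

test_that("peak calling uses strict exceedance of the chromosomal percentile", {
  # 99 windows at density 0.1, one at 0.9 -> exactly that window peaks
  L <- 100 * 10000
  s <- seq(1, L, by = 10000)
  reps <- makeRepeats("c", s, s + 999, family = "DNA/a", genome = c(c = L))
  big <- makeRepeats("c", s[43], s[43] + 8999, family = "DNA/a",
                     genome = c(c = L))
  tr <- computeWindowDensities(c(reps, big), c(c = L), w = 10000)
  pk <- callPeaks(tr, "dna", percentile = 95)
  expect_equal(which(pk$is_peak), 43L)
  expect_equal(pk$chrom_median[1], 0.1)

  # flat distribution -> no peaks
  trFlat <- computeWindowDensities(reps, c(c = L), w = 10000)
  expect_false(any(callPeaks(trFlat, "dna")$is_peak))

  # percentile 0 -> everything above the minimum peaks
  pk0 <- callPeaks(tr, "dna", percentile = 0)
  expect_equal(sum(pk0$is_peak), 1L)  # min is 0.1 shared by 99 windows

  expect_error(callPeaks(methods::new("WindowDensityTrack",
    windows = GenomicRanges::GRanges("c", IRanges::IRanges(1, 10),
                                     d = 0)[0],
    windowSize = 10L, scheme = defaultCategoryScheme())), "empty")
  expect_warning(callPeaks(computeWindowDensities(reps[1:2],
    c(c = 50000), w = 10000)), "fewer than 20")
})

test_that("region densities tile from the region start and report the median", {
  # 10 subwindows with densities 0, 0.1, ..., 0.9 -> median 0.45
  L <- 200000
  regionStart <- 50001
  s <- integer(0); e <- integer(0)
  for (k in 1:9) {
    s <- c(s, regionStart + (k) * 10000)
    e <- c(e, regionStart + (k) * 10000 + k * 1000 - 1)
  }
  reps <- makeRepeats("c", s, e, family = "DNA/a", genome = c(c = L))
  reg <- GenomicRanges::GRanges("c", IRanges::IRanges(regionStart,
                                                      regionStart + 99999))
  rd <- regionDensity(reps, reg, c(c = L), w = 10000, category = "dna")
  expect_equal(rd$density, seq(0, 0.9, by = 0.1))
  expect_equal(rd$median, 0.45)

  # uniform coverage c over the region -> median = c
  u <- makeRepeats("c", regionStart, regionStart + 99999, genome = c(c = L))
  expect_equal(regionDensity(u, reg, c(c = L), category = "dna")$median, 1)

  # region shorter than w -> one fractional window
  short <- GenomicRanges::GRanges("c", IRanges::IRanges(100, 599))
  rs <- regionDensity(reps[0], short, c(c = L), w = 10000)
  expect_length(rs$density, 1L)
  expect_equal(rs$median, rs$density)
})

test_that("cluster mode reproduces window-density semantics at 500 bp", {
  L <- 200000
  set.seed(5)
  s <- sample.int(L - 1000, 80); e <- s + sample.int(800, 80)
  reps <- makeRepeats("c", s, e, family = "DNA/MITE-224", genome = c(c = L))
  cl <- GenomicRanges::GRanges("c", IRanges::IRanges(90001, 110000))
  tr <- clusterDensity(reps, cl, c(c = L), flank = 25000, w = 500)
  win <- densityWindows(tr)
  expect_equal(GenomicRanges::start(win)[1], 65001L)
  expect_equal(max(GenomicRanges::end(win)), 135000L)
  expect_true(all(GenomicRanges::width(win) == 500L))
  oracle <- maskCoverageOracle(L, s, e, GenomicRanges::start(win),
                               GenomicRanges::end(win))
  expect_equal(densityMatrix(tr)[, "dna"] * 500, oracle,
               ignore_attr = TRUE)
})

test_that("shared TE families require presence in at least two regions", {
  regions <- GenomicRanges::GRanges("c", IRanges::IRanges(
    c(1000, 5000, 9000), c(2000, 6000, 10000)),
    name = c("cl1", "cl2", "cl3"))
  reps <- makeRepeats("c",
    c(1100, 5100, 1200, 9100, 5200, 9200),
    c(1150, 5150, 1250, 9150, 5250, 9250),
    family = c("DNA/MITE-224", "DNA/MITE-224", "LINE/only1",
               "LTR/only3", "SINE/only2", "DNA/MITE-224"))
  sh <- sharedTeFamilies(reps, regions)
  expect_equal(unique(sh$family), "DNA/MITE-224")
  expect_setequal(unique(sh$region), c("cl1", "cl2", "cl3"))
  expect_equal(nrow(sh), 3L)
  expect_error(sharedTeFamilies(reps, regions[1]), "at least 2")
})
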