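test_that("generator output is a deterministic function of the seed", {
  cfg <- simConfig(seed = 12,
                   chromosomes = data.frame(name = c("a", "b"),
                                            length = c(2e6, 1e6)),
                   inversions = data.frame(chrom = "a", start = 5e5,
                                           end = 1.5e6, lambda = 3,
                                           families = ""))
  l1 <- simulateLandscape(cfg)
  l2 <- simulateLandscape(cfg)
  expect_identical(GenomicRanges::start(l1$repeats),
                   GenomicRanges::start(l2$repeats))
  expect_identical(l1$repeats$family, l2$repeats$family)
  a1 <- simulateAnchorTable(cfg)
  a2 <- simulateAnchorTable(cfg)
  expect_identical(a1$anchors, a2$anchors)
  g1 <- simulateGenotypes(cfg)
  g2 <- simulateGenotypes(cfg)
  expect_identical(g1$genotypes@alleles, g2$genotypes@alleles)

  # different seed -> different draws
  l3 <- simulateLandscape(simConfig(seed = 13, chromosomes = cfg@chromosomes,
                                    inversions = cfg@inversions))
  expect_false(identical(GenomicRanges::start(l1$repeats),
                         GenomicRanges::start(l3$repeats)))
})

test_that("landscape rates behave as a Poisson process with step enrichment", {
  # zero rates -> empty annotation
  cfg0 <- simConfig(seed = 1, teFamilies = data.frame(
    family = "LINE/L2", class = "LINE", rate = 0, minLen = 100,
    maxLen = 200))
  expect_length(simulateLandscape(cfg0)$repeats, 0L)

  # zero background with an enriched inversion still yields nothing
  # (enrichment multiplies the background rate)
  cfg00 <- simConfig(seed = 1,
    teFamilies = data.frame(family = "LINE/L2", class = "LINE", rate = 0,
                            minLen = 100, maxLen = 200),
    inversions = data.frame(chrom = "chr1", start = 2e6, end = 5e6,
                            lambda = 10, families = ""))
  expect_length(simulateLandscape(cfg00)$repeats, 0L)

  # lambda > 1 concentrates enriched-family insertions in the flanks
  cfgE <- simConfig(seed = 2,
    chromosomes = data.frame(name = "c", length = 4e6),
    teFamilies = data.frame(family = "LINE/L2", class = "LINE", rate = 1e-5,
                            minLen = 100, maxLen = 200),
    inversions = data.frame(chrom = "c", start = 1e6, end = 3e6,
                            lambda = 40, families = "LINE/L2"))
  land <- simulateLandscape(cfgE)
  bp <- c(makeBreakpointRegions(land$truth$inversions[1], 50000,
                                land$genome))
  inside <- sum(IRanges::overlapsAny(GenomicRanges::ranges(land$repeats),
                                     GenomicRanges::ranges(bp)))
  # flanks are 200 kb of 4 Mb (5%) but carry rate x40: expect the majority
  expect_gt(inside / length(land$repeats), 0.5)

  # Poisson count oracle at lambda = 1: over 200 seeds, the total count on a
  # 10-Mb chromosome stays within +-3 sqrt(rL) of rL for ~99% of seeds
  r <- 1e-4; L <- 10e6
  counts <- vapply(1:200, function(s) {
    cc <- simConfig(seed = s, chromosomes = data.frame(name = "c",
                                                       length = L),
                    teFamilies = data.frame(family = "DNA/x", class = "DNA",
                                            rate = r, minLen = 100,
                                            maxLen = 200))
    length(simulateLandscape(cc)$repeats)
  }, 0)
  within <- mean(abs(counts - r * L) <= 3 * sqrt(r * L))
  expect_gte(within, 0.95)
  # aggregated chi-square goodness of fit against Poisson(rL)
  chi <- sum((counts - r * L)^2 / (r * L))
  expect_gt(stats::pchisq(chi, df = 200, lower.tail = FALSE), 0.01)

  expect_error(simConfig(teFamilies = data.frame(
    family = "x/y", class = "DNA", rate = -1, minLen = 1, maxLen = 2)),
    "rates")
  expect_error(simConfig(
    inversions = data.frame(chrom = "chr1", start = c(1e6, 2e6),
                            end = c(3e6, 4e6), lambda = 1, families = "")),
    "overlapping")
})

test_that("anchor tables reflect fusions, inversions and bounds checks", {
  # no rearrangements -> anchors form a monotone identity map per chromosome
  cfg <- simConfig(seed = 5, chromosomes = data.frame(
    name = c("r1", "r2"), length = c(3e6, 2e6)))
  a <- simulateAnchorTable(cfg)$anchors
  expect_identical(a$qchrom, a$rchrom)
  expect_identical(a$qstart, a$rstart)
  for (ch in unique(a$qchrom)) {
    sub <- a[a$qchrom == ch, ]
    expect_false(is.unsorted(sub$rstart[order(sub$qstart)]))
  }

  # fusion concatenation arithmetic: 10 Mb + 8 Mb -> 18 Mb, A then B
  cfgF <- simConfig(seed = 6, chromosomes = data.frame(
    name = c("A", "B"), length = c(10e6, 8e6)),
    fusions = data.frame(chromA = "A", chromB = "B"))
  atF <- simulateAnchorTable(cfgF)
  expect_equal(GenomeInfoDb::seqlengths(atF$truth$genome)[["A_B"]], 18e6)
  aF <- atF$anchors
  expect_true(all(aF$qchrom == "A_B"))
  fromA <- aF[aF$rchrom == "A", ]
  fromB <- aF[aF$rchrom == "B", ]
  expect_true(max(fromA$qend) <= 10e6)
  expect_true(min(fromB$qstart) > 10e6)
  expect_equal(fromB$qstart, fromB$rstart + 10e6)

  # an inversion reverses exactly the contained anchor ranks
  cfgI <- simConfig(seed = 7, chromosomes = data.frame(name = "c",
                                                       length = 10e6),
                    genesPerMb = 10,
                    inversions = data.frame(chrom = "c", start = 2e6,
                                            end = 4e6, lambda = 1,
                                            families = ""))
  aI <- simulateAnchorTable(cfgI)$anchors
  ord <- order(aI$qstart)
  rOrder <- aI$rstart[ord]
  inside <- aI$qstart[ord] >= 2e6 & aI$qend[ord] <= 4e6
  expect_true(all(diff(rOrder[inside]) < 0))     # reversed run
  expect_true(all(diff(rOrder[!inside]) > 0))    # background untouched

  expect_error(simConfig(seed = 1, inversions = data.frame(
    chrom = "chr1", start = 5e6, end = 20e6, lambda = 1, families = "")),
    "bounds")
  expect_error(simConfig(seed = 1, translocations = data.frame(
    srcChrom = "chr1", srcStart = 1, srcEnd = 99e6, destChrom = "chr2",
    destPos = 1)), "bounds")
})

test_that("genotype simulation hits degenerate and binomial expectations", {
  # d = 0, pi = 0 -> all samples identical everywhere
  cfg0 <- simConfig(seed = 3, popgen = list(d = 0, piX = 0, piY = 0,
                                            nSites = 5000L))
  g0 <- simulateGenotypes(cfg0)
  expect_true(all(g0$genotypes@alleles == 0L))

  # d = 0.01 over 100,000 sites -> fixed differences within 3 sd of 1,000
  cfgD <- simConfig(seed = 4, popgen = list(d = 0.01, piX = 0, piY = 0,
                                            nSites = 100000L))
  gD <- simulateGenotypes(cfgD)
  acx <- alleleCounts(gD$genotypes, 1:28)
  acy <- alleleCounts(gD$genotypes, 29:56)
  fixedDiff <- sum(acx[, "alt"] == 0 & acy[, "ref"] == 0 & acy[, "alt"] > 0)
  expect_lt(abs(fixedDiff - 1000), 3 * sqrt(1000 * 0.99))

  # a conserved tract with d' = 0 holds zero fixed differences
  cfgT <- simConfig(seed = 5, popgen = list(
    d = 0.05, piX = 0, piY = 0, nSites = 20000L,
    conservedTracts = data.frame(start = 5001, end = 10000, d = 0)))
  gT <- simulateGenotypes(cfgT)
  aT <- gT$genotypes@alleles
  tract <- 5001:10000
  expect_true(all(aT[tract, ] == 0L))
  expect_gt(sum(aT[-tract, 29:56]), 0)

  expect_error(simulateGenotypes(simConfig(popgen = list(d = 1.5))), "d")
})
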