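test_that("chaining handles identity, inverted runs, and gap splits", {
  # identity order -> one forward block
  sb <- chainBlocks(permAnchors(1:10), maxGap = 10, minAnchors = 5)
  tab <- syntenyBlockTable(sb)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n, 10L)
  expect_equal(tab$orientation, "forward")

  # collinear anchors with an inverted middle run (longer than twice the
  # gap bound, so no legal chain can bridge across it) -> three blocks:
  # forward, reverse, forward
  perm <- c(1:20, 40:21, 41:60)
  sb2 <- chainBlocks(permAnchors(perm), maxGap = 10, minAnchors = 5)
  tab2 <- syntenyBlockTable(sb2)
  tab2 <- tab2[order(tab2$qstart), ]
  expect_equal(nrow(tab2), 3L)
  expect_equal(tab2$n, c(20L, 20L, 20L))
  expect_equal(tab2$orientation, c("forward", "reverse", "forward"))

  # a query-rank gap of 11 with max_gap 10 splits chains: 11 interleaved
  # anchors from a second reference chromosome hold the dense ranks apart
  filler <- data.frame(gene = paste0("f", 1:11), qchrom = "q1",
                       qstart = 5100 + (1:11) * 10,
                       qend = 5100 + (1:11) * 10 + 5,
                       rchrom = "r2", rstart = (1:11) * 1000,
                       rend = (1:11) * 1000 + 100)
  gapAnch <- rbind(permAnchors(1:20)[c(1:5, 16:20), ], filler)
  sb3 <- chainBlocks(gapAnch, maxGap = 10, minAnchors = 2)
  tab3 <- syntenyBlockTable(sb3)
  r1blocks <- tab3[tab3$rchrom == "r1", ]
  expect_equal(nrow(r1blocks), 2L)  # split by the 11-rank query gap
  expect_equal(sort(r1blocks$n), c(5L, 5L))

  expect_error(chainBlocks(rbind(permAnchors(1:5), permAnchors(1:5))),
               "duplicate")
})

test_that("chained blocks satisfy invariants and cover the brute-force optimum", {
  checkInstance <- function(perm, maxGap = 10, minAnchors = 2) {
    sb <- chainBlocks(permAnchors(perm), maxGap = maxGap,
                      minAnchors = minAnchors)
    a <- syntenyAnchors(sb)
    for (b in unique(stats::na.omit(a$block))) {
      rows <- a[!is.na(a$block) & a$block == b, ]
      rows <- rows[order(rows$qrank), ]
      expect_gte(nrow(rows), minAnchors)
      if (nrow(rows) > 1L) {
        dq <- diff(rows$qrank); dr <- diff(rows$rrank)
        expect_true(all(dq >= 1 & dq <= maxGap))
        expect_true(all(abs(dr) <= maxGap))
        expect_true(all(dr > 0) || all(dr < 0))
      }
    }
    covered <- sum(!is.na(a$block))
    expect_gte(covered, bruteBestChainLen(perm, maxGap))
  }
  # exhaustive for small n, random larger instances
  for (n in 2:6) {
    perms <- allPermutations(n)
    for (r in seq_len(nrow(perms))) checkInstance(perms[r, ])
  }
  set.seed(17)
  for (r in 1:50) checkInstance(sample(15L), maxGap = sample(2:10, 1))
})

test_that("query/reference swap preserves blocks and orientations", {
  cfg <- simConfig(seed = 21,
                   chromosomes = data.frame(name = c("r1", "r2"),
                                            length = c(6e6, 5e6)),
                   fusions = data.frame(chromA = "r1", chromB = "r2"),
                   inversions = data.frame(chrom = "r1_r2", start = 2e6,
                                           end = 3e6, lambda = 1,
                                           families = ""))
  at <- simulateAnchorTable(cfg)
  a <- at$anchors
  swapped <- data.frame(gene = a$gene, qchrom = a$rchrom, qstart = a$rstart,
                        qend = a$rend, rchrom = a$qchrom, rstart = a$qstart,
                        rend = a$qend, stringsAsFactors = FALSE)
  sb <- chainBlocks(a)
  sbS <- chainBlocks(swapped)
  key <- function(x) {
    an <- syntenyAnchors(x)
    sets <- split(an$gene, an$block)
    ors <- stats::setNames(
      syntenyBlockTable(x)$orientation,
      syntenyBlockTable(x)$block)
    sapply(names(sets), function(b)
      paste(ors[[b]], paste(sort(sets[[b]]), collapse = ",")))
  }
  expect_setequal(unname(key(sb)), unname(key(sbS)))
})

test_that("fusion detection reports partner sets and junctions from planted truth", {
  # one-to-one map -> no fusion
  cfg0 <- simConfig(seed = 4, chromosomes = data.frame(
    name = c("r1", "r2"), length = c(5e6, 5e6)))
  sb0 <- chainBlocks(simulateAnchorTable(cfg0)$anchors)
  expect_equal(nrow(detectFusions(sb0)), 0L)

  # planted fusion of 10 Mb + 8 Mb
  cfg <- simConfig(seed = 8, chromosomes = data.frame(
    name = c("chrA", "chrB", "chrC"), length = c(10e6, 8e6, 6e6)),
    fusions = data.frame(chromA = "chrA", chromB = "chrB"))
  at <- simulateAnchorTable(cfg)
  expect_equal(GenomeInfoDb::seqlengths(at$truth$genome)[["chrA_chrB"]],
               18e6)
  sb <- chainBlocks(at$anchors)
  fus <- detectFusions(sb)
  expect_equal(fus$qchrom, "chrA_chrB")
  expect_setequal(strsplit(fus$partners, ",")[[1]], c("chrA", "chrB"))
  spacing <- 1e6 / cfg@genesPerMb
  expect_lt(abs(as.numeric(fus$junctions) - 10e6), spacing + 1)

  # fusion plus a small central translocated run from chrC:
  # partners stay {chrA, chrB}
  cfgT <- simConfig(seed = 9, chromosomes = data.frame(
    name = c("chrA", "chrB", "chrC"), length = c(10e6, 8e6, 6e6)),
    fusions = data.frame(chromA = "chrA", chromB = "chrB"),
    translocations = data.frame(srcChrom = "chrC", srcStart = 1e6,
                                srcEnd = 2e6, destChrom = "chrA_chrB",
                                destPos = 9e6))
  sbT <- chainBlocks(simulateAnchorTable(cfgT)$anchors)
  fusT <- detectFusions(sbT)
  fusT <- fusT[fusT$qchrom == "chrA_chrB", ]
  expect_setequal(strsplit(fusT$partners, ",")[[1]], c("chrA", "chrB"))
})

test_that("translocation detection distinguishes internal and terminal segments", {
  cfg0 <- simConfig(seed = 14, chromosomes = data.frame(
    name = c("A", "C"), length = c(10e6, 6e6)))
  sb0 <- chainBlocks(simulateAnchorTable(cfg0)$anchors)
  expect_equal(nrow(detectTranslocations(sb0)), 0L)

  # 2-Mb insertion from C into the middle of A -> internal segment from C
  cfg <- simConfig(seed = 15, chromosomes = data.frame(
    name = c("A", "C"), length = c(30e6, 20e6)),
    translocations = data.frame(srcChrom = "C", srcStart = 5e6,
                                srcEnd = 7e6, destChrom = "A",
                                destPos = 15e6))
  at <- simulateAnchorTable(cfg)
  trl <- detectTranslocations(chainBlocks(at$anchors))
  hit <- trl[trl$qchrom == "A" & trl$source == "C", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$status, "internal")
  spacing <- 1e6 / cfg@genesPerMb
  expect_lt(abs(hit$qstart - at$truth$translocations$destStart),
            spacing + 1000)
  expect_lt(abs(hit$qend - at$truth$translocations$destEnd), spacing + 1000)

  # segment moved to the chromosome start -> terminal flag
  cfgT <- simConfig(seed = 16, chromosomes = data.frame(
    name = c("A", "C"), length = c(30e6, 20e6)),
    translocations = data.frame(srcChrom = "C", srcStart = 5e6,
                                srcEnd = 7e6, destChrom = "A", destPos = 1))
  trlT <- detectTranslocations(chainBlocks(simulateAnchorTable(cfgT)$anchors))
  hitT <- trlT[trlT$qchrom == "A" & trlT$source == "C", ]
  expect_equal(hitT$status, "terminal")
})

test_that("interval projection interpolates within blocks, orientation-aware", {
  # forward block with uniform anchors
  a <- permAnchors(1:50, spacing = 10000L)
  sb <- chainBlocks(a)
  tab <- syntenyBlockTable(sb)
  full <- GenomicRanges::GRanges("q1", IRanges::IRanges(tab$qstart, tab$qend))
  pr <- projectInterval(sb, full)
  expect_equal(GenomicRanges::start(pr), tab$rstart)
  expect_equal(GenomicRanges::end(pr), tab$rend)

  mid <- GenomicRanges::GRanges("q1", IRanges::IRanges(
    (tab$qstart + tab$qend) %/% 2, (tab$qstart + tab$qend) %/% 2 + 1))
  prMid <- projectInterval(sb, mid)
  expect_lt(abs(GenomicRanges::start(prMid) - (tab$rstart + tab$rend) / 2),
            10000 / 2 + 1)

  # reverse block: projected endpoints swap
  rev <- permAnchors(50:1, spacing = 10000L)
  sbR <- chainBlocks(rev)
  tabR <- syntenyBlockTable(sbR)
  expect_equal(tabR$orientation, "reverse")
  left <- GenomicRanges::GRanges("q1", IRanges::IRanges(
    tabR$qstart, tabR$qstart + 20000))
  prL <- projectInterval(sbR, left)
  # query left edge maps to the reference right edge
  expect_gt(GenomicRanges::end(prL), tabR$rend - 30000)

  none <- GenomicRanges::GRanges("qZ", IRanges::IRanges(1, 10))
  expect_warning(pr0 <- projectInterval(sb, none), "no synteny block")
  expect_length(pr0, 0L)
})

test_that("inversion overlap calls match planted intersections", {
  # identity map, identical intervals -> reciprocal fractions 1, both flags
  a <- permAnchors(1:200, spacing = 10000L)
  sb <- chainBlocks(a)
  iv <- GenomicRanges::GRanges("q1", IRanges::IRanges(400000, 900000))
  ivB <- GenomicRanges::GRanges("r1", IRanges::IRanges(400000, 900000))
  ov <- inversionOverlap(iv, ivB, sb)
  expect_true(ov$overlapping)
  expect_gt(ov$fracA, 0.98)
  expect_gt(ov$fracB, 0.98)
  expect_true(ov$breakpointStart)
  expect_true(ov$breakpointEnd)

  # disjoint intervals -> no overlap
  far <- GenomicRanges::GRanges("r1", IRanges::IRanges(1500000, 1700000))
  ovF <- inversionOverlap(iv, far, sb)
  expect_equal(ovF$overlap, 0)
  expect_false(ovF$overlapping)

  # planted partial overlap: A's end falls inside B, near B's start
  # breakpoint, so exactly one breakpoint flag is raised
  ivB2 <- GenomicRanges::GRanges("r1", IRanges::IRanges(820000, 1300000))
  ov2 <- inversionOverlap(iv, ivB2, sb, flank = 50000)
  planted <- 900000 - 820000 + 1
  expect_lt(abs(ov2$overlap - planted), 10000 + 1)
  expect_true(ov2$breakpointEnd)    # A-end region meets B-start region
  expect_false(ov2$breakpointStart) # A-start is far from both B breakpoints
})
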