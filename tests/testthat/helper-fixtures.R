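# Shared builders and independent oracles for the test suite. Oracles are
# deliberately naive (per-base masks, exhaustive enumeration, textbook
# formulas) and independent of the package's vectorized code paths.

# GRanges repeat set from parallel vectors (1-based closed coordinates).
makeRepeats <- function(chrom, start, end, family = "DNA/test-1",
                        genome = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               family = family,
                               repClass = repeatClassOf(family))
  if (!is.null(genome)) {
    si <- GenomeInfoDb::Seqinfo(seqnames = names(genome),
                                seqlengths = as.integer(genome))
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(si)
    GenomeInfoDb::seqinfo(gr) <- si
  }
  gr
}

# Per-base boolean-mask coverage oracle: covered bases of each window on one
# chromosome of length L, for intervals given as 1-based closed start/end.
maskCoverageOracle <- function(L, starts, ends, winStarts, winEnds) {
  mask <- logical(L)
  for (i in seq_along(starts)) {
    s <- max(1L, starts[i]); e <- min(L, ends[i])
    if (s <= e) mask[s:e] <- TRUE
  }
  vapply(seq_along(winStarts), function(k)
    sum(mask[winStarts[k]:winEnds[k]]), 0L)
}

# Brute-force longest single collinear chain (either orientation) over
# anchors with query ranks 1..n and reference ranks `perm`, same gap bound
# as chainBlocks. O(n^2) DP, written independently of the package DP.
bruteBestChainLen <- function(perm, maxGap) {
  n <- length(perm)
  best <- 1L
  for (sgn in c(1L, -1L)) {
    len <- rep(1L, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        if (i - j <= maxGap && abs(perm[i] - perm[j]) <= maxGap &&
            sgn * (perm[i] - perm[j]) > 0L && len[j] + 1L > len[i])
          len[i] <- len[j] + 1L
      }
    }
    best <- max(best, len)
  }
  best
}

# Anchor data.frame for a single query chromosome with query ranks 1..n (at
# fixed spacing) and reference order given by `perm` on one ref chromosome.
permAnchors <- function(perm, spacing = 1000L) {
  n <- length(perm)
  data.frame(gene = paste0("g", seq_len(n)),
             qchrom = "q1", qstart = seq_len(n) * spacing,
             qend = seq_len(n) * spacing + 100L,
             rchrom = "r1", rstart = perm * spacing,
             rend = perm * spacing + 100L, stringsAsFactors = FALSE)
}

# All permutations of 1..n (recursive; fine for n <= 9).
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      p <- sub[r, ]
      p[p >= k] <- p[p >= k] + 1L
      out[row, ] <- c(k, p)
      row <- row + 1L
    }
  }
  out
}

# Textbook per-site Weir-Cockerham (1984) theta components for two
# populations of haploid-sampled allele counts, written scalar-by-scalar from
# the published formulas (h_bar = 0). Independent oracle for windowedFst.
wcThetaOracle <- function(n1, p1, n2, p2) {
  r <- 2
  aa <- bb <- numeric(length(n1))
  for (i in seq_along(n1)) {
    nbar <- (n1[i] + n2[i]) / r
    nc <- (n1[i] + n2[i] - (n1[i]^2 + n2[i]^2) / (n1[i] + n2[i])) / (r - 1)
    pbar <- (n1[i] * p1[i] + n2[i] * p2[i]) / (n1[i] + n2[i])
    s2 <- (n1[i] * (p1[i] - pbar)^2 + n2[i] * (p2[i] - pbar)^2) /
      ((r - 1) * nbar)
    aa[i] <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2))
    bb[i] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2)
  }
  sum(aa) / sum(aa + bb)
}

# Small GenotypeTable straight from an allele matrix (rows sites, cols
# haplotypes; two consecutive haplotypes per sample).
makeGenotypes <- function(alleles, chrom = "c1", pos = seq_len(nrow(alleles))) {
  nH <- ncol(alleles)
  stopifnot(nH %% 2 == 0)
  samples <- paste0("s", seq_len(nH / 2))
  colnames(alleles) <- paste0(rep(samples, each = 2), c("_1", "_2"))
  methods::new("GenotypeTable", chrom = rep(chrom, nrow(alleles)),
               pos = as.integer(pos), alleles = alleles,
               sampleMap = data.frame(haplotype = colnames(alleles),
                                      sample = rep(samples, each = 2),
                                      stringsAsFactors = FALSE))
}

# Population map putting the first half of samples in popX, rest in popY.
splitPops <- function(gt) {
  samples <- unique(gt@sampleMap$sample)
  half <- length(samples) / 2
  data.frame(sample = samples,
             population = rep(c("popX", "popY"), each = half),
             stringsAsFactors = FALSE)
}
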