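#' @include density.R
NULL

#' Breakpoint regions of an inversion
#'
#' Each inversion yields two regions of width \code{2 * flank} centered on
#' its start and end boundaries, clipped to the chromosome.
#'
#' @param inversion GRanges of length 1.
#' @param flank flank width in bp on each side of a breakpoint (default
#'   50000, i.e. 100-kb regions).
#' @param genome Seqinfo or named chromosome lengths.
#' @return GRanges of length 2 with metadata column \code{side}
#'   ("start"/"end").
#' @export
makeBreakpointRegions <- function(inversion, flank = 50000, genome) {
  stopifnot(length(inversion) == 1L)
  if (GenomicRanges::width(inversion) < 1L)
    stop("inversion must span at least 1 bp")
  if (flank <= 0) stop("flank must be > 0")
  si <- .asSeqinfo(genome)
  ch <- as.character(GenomicRanges::seqnames(inversion))
  if (!ch %in% GenomeInfoDb::seqnames(si))
    stop("inversion chromosome ", ch, " absent from genome index")
  L <- GenomeInfoDb::seqlengths(si)[[ch]]
  s <- GenomicRanges::start(inversion)
  e <- GenomicRanges::end(inversion)
  if (s < 1L || e > L) stop("inversion exceeds chromosome bounds")
  flank <- as.integer(flank)
  reg <- GenomicRanges::GRanges(
    ch,
    IRanges::IRanges(start = pmax(1L, c(s - flank, e - flank + 1L)),
                     end = pmin(L, c(s + flank - 1L, e + flank))),
    side = c("start", "end"), seqinfo = si)
  reg
}

# Valid start positions for a regionLen interval on [1, L] avoiding all
# `excluded` ranges (IRanges).
.allowedStarts <- function(L, regionLen, excluded) {
  maxStart <- L - regionLen + 1L
  if (maxStart < 1L) return(IRanges::IRanges())
  universe <- IRanges::IRanges(1L, maxStart)
  if (length(excluded) == 0L) return(universe)
  blocked <- IRanges::restrict(
    IRanges::IRanges(IRanges::start(excluded) - regionLen + 1L,
                     IRanges::end(excluded)),
    start = 1L, end = maxStart)
  IRanges::setdiff(universe, IRanges::reduce(blocked))
}

# Draw n start positions uniformly over an allowed IRanges set.
.sampleStarts <- function(allowed, n) {
  w <- IRanges::width(allowed)
  tot <- sum(as.double(w))
  u <- ceiling(stats::runif(n) * tot)
  cw <- cumsum(as.double(w))
  idx <- findInterval(u - 1, cw) + 1L
  offset <- u - c(0, cw)[idx]
  as.integer(IRanges::start(allowed)[idx] + offset - 1)
}

#' Sample non-breakpoint region pairs for the permutation null
#'
#' Per replicate, two intervals of \code{regionLen} bp are drawn uniformly
#' over the valid start positions of the same chromosome: each interval is
#' disjoint from every excluded (breakpoint) region, and the two members of a
#' pair are disjoint from each other. Pairs across replicates are drawn
#' independently and may coincide.
#'
#' @param genome Seqinfo or named lengths.
#' @param chromosome chromosome name to sample from.
#' @param n number of replicate pairs (default 1000).
#' @param regionLen interval length in bp (default 100000).
#' @param excluded GRanges (or IRanges) of regions no interval may touch.
#' @param seed optional integer seed for reproducible draws.
#' @return list with GRanges \code{first} and \code{second}, each of length
#'   \code{n}.
#' @export
sampleNullPairs <- function(genome, chromosome, n = 1000, regionLen = 100000,
                            excluded = NULL, seed = NULL) {
  stopifnot(n >= 1, regionLen > 0)
  si <- .asSeqinfo(genome)
  if (!chromosome %in% GenomeInfoDb::seqnames(si))
    stop("chromosome ", chromosome, " absent from genome index")
  L <- GenomeInfoDb::seqlengths(si)[[chromosome]]
  regionLen <- as.integer(regionLen)
  ex <- if (is.null(excluded)) IRanges::IRanges() else {
    if (methods::is(excluded, "GRanges")) {
      keep <- as.character(GenomicRanges::seqnames(excluded)) == chromosome
      GenomicRanges::ranges(excluded[keep])
    } else excluded
  }
  allowed <- .allowedStarts(L, regionLen, ex)
  if (length(allowed) == 0L)
    stop("no valid placement for ", regionLen, "-bp regions on chromosome ",
         chromosome, " after exclusions")
  minA <- min(IRanges::start(allowed))
  maxA <- max(IRanges::end(allowed))
  feas <- IRanges::intersect(
    allowed,
    IRanges::reduce(c(
      IRanges::IRanges(1L, max(0L, maxA - regionLen)),
      if (minA + regionLen <= maxA)
        IRanges::IRanges(minA + regionLen, maxA) else IRanges::IRanges())))
  if (length(feas) == 0L || sum(IRanges::width(feas)) == 0L)
    stop("no disjoint region pair can be placed on chromosome ", chromosome)
  .withSeed(seed, {
    s1 <- .sampleStarts(feas, n)
    s2 <- .sampleStarts(allowed, n)
    bad <- abs(s2 - s1) < regionLen
    tries <- 0L
    while (any(bad) && tries < 50L) {
      s2[bad] <- .sampleStarts(allowed, sum(bad))
      bad <- abs(s2 - s1) < regionLen
      tries <- tries + 1L
    }
    for (i in which(bad)) {  # rare: resolve exactly, conditional on s1[i]
      a2 <- IRanges::setdiff(allowed, IRanges::IRanges(
        s1[i] - regionLen + 1L, s1[i] + regionLen - 1L))
      if (length(a2) == 0L)
        stop("no disjoint partner interval on chromosome ", chromosome)
      s2[i] <- .sampleStarts(a2, 1L)
    }
    list(first = GenomicRanges::GRanges(
           chromosome, IRanges::IRanges(s1, s1 + regionLen - 1L),
           seqinfo = si),
         second = GenomicRanges::GRanges(
           chromosome, IRanges::IRanges(s2, s2 + regionLen - 1L),
           seqinfo = si))
  })
}

# Pooled-median statistic over one or more regions: tile each region from its
# start in w-bp subwindows, pool the densities, take the median.
.pooledMedian <- function(covRle, starts, ends, w) {
  sw <- .regionSubwindows(starts, ends, w)
  d <- .windowCovered(covRle, sw$start, sw$end) / (sw$end - sw$start + 1)
  stats::median(d)
}

# Null statistics for n pairs of equal-length intervals, vectorized.
.nullPairStats <- function(covRle, s1, s2, regionLen, w) {
  k <- as.integer(ceiling(regionLen / w))
  off <- (seq_len(k) - 1L) * as.integer(w)
  n <- length(s1)
  startsMat <- rbind(outer(off, s1, "+"), outer(off, s2, "+"))  # 2k x n
  limit <- rbind(matrix(s1 + regionLen - 1L, nrow = k, ncol = n,
                        byrow = TRUE),
                 matrix(s2 + regionLen - 1L, nrow = k, ncol = n,
                        byrow = TRUE))
  endsMat <- pmin(startsMat + as.integer(w) - 1L, limit)
  covered <- .windowCovered(covRle, as.vector(startsMat), as.vector(endsMat))
  dens <- matrix(covered / (as.vector(endsMat) - as.vector(startsMat) + 1),
                 nrow = 2L * k)
  apply(dens, 2L, stats::median)
}

.permCore <- function(covRle, inversion, genome, excluded, flank, regionLen,
                      n, percentile, w, seed, id, category) {
  si <- .asSeqinfo(genome)
  ch <- as.character(GenomicRanges::seqnames(inversion))
  bp <- makeBreakpointRegions(inversion, flank = flank, genome = si)
  observed <- .pooledMedian(covRle, GenomicRanges::start(bp),
                            GenomicRanges::end(bp), w)
  pairs <- sampleNullPairs(si, ch, n = n, regionLen = regionLen,
                           excluded = excluded, seed = seed)
  nullStats <- .nullPairStats(covRle,
                              GenomicRanges::start(pairs$first),
                              GenomicRanges::start(pairs$second),
                              as.integer(regionLen), w)
  ref <- stats::quantile(nullStats, percentile / 100, type = 7,
                         names = FALSE)
  p <- (1 + sum(nullStats >= observed)) / (n + 1)
  methods::new("PermutationResult", inversionId = id, category = category,
               observed = observed, nullStats = nullStats,
               nullPercentile = ref, pValue = p,
               significant = observed > ref)
}

#' Permutation test for repeat enrichment at inversion breakpoints
#'
#' The observed statistic is the median repeat density over the pooled
#' \code{w}-bp subwindows of the inversion's two breakpoint regions. The null
#' distribution is the identical statistic on \code{n} randomly placed pairs
#' of non-breakpoint regions from the same chromosome (see
#' [sampleNullPairs()]). The inversion is flagged significant when the
#' observed median strictly exceeds the \code{percentile}-th percentile of
#' the null distribution; the add-one empirical p-value
#' \eqn{(1 + \#\{null \ge obs\})/(n + 1)} is reported alongside.
#'
#' @param repeats GRanges with \code{repClass}.
#' @param inversion GRanges of length 1 (use [enrichmentTest()] for a set of
#'   inversions sharing chromosomes).
#' @param genome Seqinfo or named lengths.
#' @param flank breakpoint flank in bp (default 50000).
#' @param regionLen null-region length in bp (default 100000).
#' @param n number of null replicates (default 1000).
#' @param percentile significance percentile of the null (default 95).
#' @param w subwindow width in bp (default 10000).
#' @param category density category tested.
#' @param scheme a [CategoryScheme].
#' @param seed optional integer seed.
#' @param excluded GRanges of regions the null must avoid; defaults to this
#'   inversion's own breakpoint regions. When several inversions share a
#'   chromosome, pass the union of all their breakpoint regions (as
#'   [enrichmentTest()] does).
#' @return A [PermutationResult].
#' @export
permutationTest <- function(repeats, inversion, genome, flank = 50000,
                            regionLen = 100000, n = 1000, percentile = 95,
                            w = 10000, category = "all_te",
                            scheme = defaultCategoryScheme(), seed = NULL,
                            excluded = NULL) {
  si <- .asSeqinfo(genome)
  .checkRepeatChroms(repeats, si)
  ch <- as.character(GenomicRanges::seqnames(inversion))
  cov <- .categoryCoverage(repeats, si, scheme, category)
  if (is.null(excluded))
    excluded <- makeBreakpointRegions(inversion, flank = flank, genome = si)
  id <- if (!is.null(inversion$name)) inversion$name else "inversion"
  .permCore(cov[[ch]], inversion, si, excluded, flank, regionLen, n,
            percentile, w, seed, id, category)
}

#' Permutation tests for a set of inversions
#'
#' Runs [permutationTest()] for every inversion, computing the category
#' coverage once per chromosome and excluding the breakpoint regions of
#' \emph{all} inversions on a chromosome from that chromosome's null
#' sampling.
#'
#' @inheritParams permutationTest
#' @param inversions GRanges (one row per inversion; a \code{name} metadata
#'   column supplies identifiers).
#' @return data.frame with one row per inversion: \code{inversion},
#'   \code{chrom}, \code{observed}, \code{null_ref}, \code{p},
#'   \code{significant}.
#' @export
enrichmentTest <- function(repeats, inversions, genome, flank = 50000,
                           regionLen = 100000, n = 1000, percentile = 95,
                           w = 10000, category = "all_te",
                           scheme = defaultCategoryScheme(), seed = NULL) {
  si <- .asSeqinfo(genome)
  .checkRepeatChroms(repeats, si)
  ids <- if (!is.null(inversions$name)) inversions$name else
    paste0("inv", seq_along(inversions))
  chrom <- as.character(GenomicRanges::seqnames(inversions))
  out <- data.frame(inversion = ids, chrom = chrom, observed = NA_real_,
                    null_ref = NA_real_, p = NA_real_, significant = NA,
                    stringsAsFactors = FALSE)
  # repeats grouped once; coverage built once per chromosome
  grSplit <- split(seq_along(repeats),
                   as.character(GenomicRanges::seqnames(repeats)))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    idx <- grSplit[[ch]]
    reps <- if (is.null(idx)) repeats[0] else repeats[idx]
    cov <- .categoryCoverage(reps, si, scheme, category)[[ch]]
    bpAll <- do.call(c, lapply(sel, function(i)
      makeBreakpointRegions(inversions[i], flank = flank, genome = si)))
    for (j in seq_along(sel)) {
      i <- sel[j]
      subSeed <- if (is.null(seed)) NULL else .substream(seed, 7L, i)
      res <- .permCore(cov, inversions[i], si, bpAll, flank, regionLen, n,
                       percentile, w, subSeed, ids[i], category)
      out$observed[i] <- res@observed
      out$null_ref[i] <- res@nullPercentile
      out$p[i] <- res@pValue
      out$significant[i] <- res@significant
    }
  }
  out
}

#' Tabulate enrichment results with optional multiplicity adjustment
#'
#' @param results data.frame from [enrichmentTest()] (or a list of
#'   [PermutationResult] objects).
#' @param adjust "none" or "bonferroni" (raw p is always kept; the adjusted
#'   value multiplies by the number of inversions tested, capped at 1).
#' @return data.frame with columns inversion, observed, null_ref, p,
#'   p_adjusted, significant.
#' @export
enrichmentReport <- function(results, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, function(r)
      data.frame(inversion = r@inversionId, chrom = NA_character_,
                 observed = r@observed, null_ref = r@nullPercentile,
                 p = r@pValue, significant = r@significant,
                 stringsAsFactors = FALSE)))
  }
  results$p_adjusted <- if (adjust == "bonferroni")
    stats::p.adjust(results$p, method = "bonferroni", n = nrow(results))
  else results$p
  results[, c("inversion", "chrom", "observed", "null_ref", "p",
              "p_adjusted", "significant")]
}
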