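#' @include AllClasses.R AllGenerics.R
NULL

# Dense per-chromosome ranks by start coordinate.
.denseRank <- function(chrom, start) {
  r <- integer(length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    r[sel] <- rank(start[sel], ties.method = "first")
  }
  r
}

# Longest collinear chain (DP) over anchors of one query chromosome, among
# the anchors flagged in `avail`, for one orientation sign. Anchors are given
# in query-rank order. Consecutive chain members must share the reference
# chromosome, have query-rank and reference-rank differences of at most
# maxGap, and strictly monotone reference ranks with the given sign.
# Returns the index vector of the best chain (possibly length 1).
.bestChain <- function(qrank, rrank, rchrom, avail, maxGap, sign) {
  idx <- which(avail)
  m <- length(idx)
  if (m == 0L) return(integer(0))
  q <- qrank[idx]; r <- rrank[idx]; ch <- rchrom[idx]
  len <- rep(1L, m); prev <- rep(0L, m)
  for (i in seq_len(m)[-1L]) {
    js <- which(ch[seq_len(i - 1L)] == ch[i] &
                q[i] - q[seq_len(i - 1L)] <= maxGap &
                sign * (r[i] - r[seq_len(i - 1L)]) > 0L &
                abs(r[i] - r[seq_len(i - 1L)]) <= maxGap)
    if (length(js)) {
      best <- js[which.max(len[js])]
      len[i] <- len[best] + 1L
      prev[i] <- best
    }
  }
  endAt <- which.max(len)
  chain <- integer(len[endAt])
  k <- len[endAt]; at <- endAt
  while (at != 0L) { chain[k] <- at; k <- k - 1L; at <- prev[at] }
  idx[chain]
}

# Core chaining loop on rank vectors for one query chromosome (input in
# query-rank order). Iteratively extracts the longest collinear chain in
# either orientation until none of minAnchors length remains. Returns a list
# of lists(idx, orientation) with idx positions into the input vectors.
.chainRanks <- function(qrank, rrank, rchrom, maxGap, minAnchors) {
  avail <- rep(TRUE, length(qrank))
  chains <- list()
  repeat {
    fwd <- .bestChain(qrank, rrank, rchrom, avail, maxGap, 1L)
    rev <- .bestChain(qrank, rrank, rchrom, avail, maxGap, -1L)
    take <- if (length(fwd) >= length(rev)) fwd else rev
    orientation <- if (length(fwd) >= length(rev)) "forward" else "reverse"
    if (length(take) < minAnchors) break
    chains[[length(chains) + 1L]] <- list(idx = take,
                                          orientation = orientation)
    avail[take] <- FALSE
  }
  chains
}

#' Chain gene-order anchors into collinear synteny blocks
#'
#' Anchors are ranked densely per chromosome by start coordinate. Per query
#' chromosome, maximal collinear chains are extracted iteratively: the
#' longest chain satisfying the gap bounds (rank difference between
#' consecutive anchors at most \code{maxGap} on both genomes, i.e. at most
#' \code{maxGap - 1} skipped genes), a single reference
#' chromosome, and strictly monotone reference ranks with a fixed sign is
#' found by dynamic programming, its anchors are removed, and the search
#' repeats until no chain of at least \code{minAnchors} anchors remains.
#' Forward orientation means increasing reference ranks. Every anchor belongs
#' to at most one block.
#'
#' @param anchors data.frame with columns \code{gene}, \code{qchrom},
#'   \code{qstart}, \code{qend}, \code{rchrom}, \code{rstart}, \code{rend}
#'   (one ortholog pair per gene).
#' @param maxGap maximum intervening ranks between consecutive anchors
#'   (default 10, the MCScanX default gene gap).
#' @param minAnchors minimum anchors per block (default 5).
#' @return A [SyntenyBlocks] object.
#' @export
chainBlocks <- function(anchors, maxGap = 10, minAnchors = 5) {
  stopifnot(maxGap >= 0, minAnchors >= 2)
  if (anyDuplicated(anchors$gene))
    stop("duplicate gene ids in anchor table")
  anchors <- as.data.frame(anchors)
  anchors$qrank <- .denseRank(anchors$qchrom, anchors$qstart)
  anchors$rrank <- .denseRank(anchors$rchrom, anchors$rstart)
  anchors$block <- NA_integer_
  blockRows <- list()
  nextId <- 1L
  for (ch in unique(anchors$qchrom)) {
    sel <- which(anchors$qchrom == ch)
    sel <- sel[order(anchors$qrank[sel])]
    chains <- .chainRanks(anchors$qrank[sel], anchors$rrank[sel],
                          anchors$rchrom[sel], maxGap, minAnchors)
    for (chn in chains) {
      rows <- sel[chn$idx]
      anchors$block[rows] <- nextId
      blockRows[[nextId]] <- data.frame(
        block = nextId, qchrom = ch,
        qstart = min(anchors$qstart[rows]), qend = max(anchors$qend[rows]),
        rchrom = anchors$rchrom[rows[1L]],
        rstart = min(anchors$rstart[rows]), rend = max(anchors$rend[rows]),
        n = length(rows), orientation = chn$orientation,
        stringsAsFactors = FALSE)
      nextId <- nextId + 1L
    }
  }
  blocks <- if (length(blockRows)) do.call(rbind, blockRows) else
    data.frame(block = integer(0), qchrom = character(0),
               qstart = numeric(0), qend = numeric(0), rchrom = character(0),
               rstart = numeric(0), rend = numeric(0), n = integer(0),
               orientation = character(0))
  methods::new("SyntenyBlocks", anchors = anchors, blocks = blocks,
               params = list(maxGap = maxGap, minAnchors = minAnchors))
}

# Chained-anchor counts per (query chromosome, reference partner).
.partnerCounts <- function(sb) {
  a <- sb@anchors
  chained <- a[!is.na(a$block), , drop = FALSE]
  if (nrow(chained) == 0L)
    return(data.frame(qchrom = character(0), rchrom = character(0),
                      n = integer(0)))
  agg <- stats::aggregate(list(n = rep(1L, nrow(chained))),
                          by = list(qchrom = chained$qchrom,
                                    rchrom = chained$rchrom), FUN = sum)
  agg
}

#' Detect chromosomal fusions from synteny blocks
#'
#' A query chromosome is called a fusion product when at least two reference
#' partners each hold at least \code{partnerMinFrac} of its anchors
#' ("major" partners) and the major partners jointly cover at least
#' \code{coverageMin} of its anchors. The junction between adjacent partner
#' spans is estimated as the midpoint between them on the query chromosome.
#'
#' @param sb a [SyntenyBlocks] object (one query genome vs one reference
#'   genome).
#' @param coverageMin minimum joint anchor share of the major partners
#'   (default 0.8).
#' @param partnerMinFrac minimum anchor share to count a partner as major
#'   (default 0.1).
#' @return data.frame with one row per fusion call: \code{qchrom},
#'   \code{n_partners}, comma-separated \code{partners} (ordered along the
#'   query chromosome), \code{partner_anchors}, \code{coverage}, and
#'   comma-separated \code{junctions} (bp).
#' @export
detectFusions <- function(sb, coverageMin = 0.8, partnerMinFrac = 0.1) {
  a <- sb@anchors
  counts <- .partnerCounts(sb)
  calls <- list()
  for (ch in unique(a$qchrom)) {
    total <- sum(a$qchrom == ch)
    pc <- counts[counts$qchrom == ch, , drop = FALSE]
    major <- pc[pc$n / total >= partnerMinFrac, , drop = FALSE]
    if (nrow(major) < 2L) next
    if (sum(major$n) / total < coverageMin) next
    # order majors along the query chromosome by their block-span midpoints
    spans <- t(vapply(major$rchrom, function(rc) {
      b <- sb@blocks[sb@blocks$qchrom == ch & sb@blocks$rchrom == rc, ,
                     drop = FALSE]
      c(min(b$qstart), max(b$qend))
    }, numeric(2)))
    ord <- order(rowMeans(spans))
    major <- major[ord, , drop = FALSE]
    spans <- spans[ord, , drop = FALSE]
    junctions <- vapply(seq_len(nrow(major) - 1L), function(i)
      round((spans[i, 2L] + spans[i + 1L, 1L]) / 2), numeric(1))
    calls[[length(calls) + 1L]] <- data.frame(
      qchrom = ch, n_partners = nrow(major),
      partners = paste(major$rchrom, collapse = ","),
      partner_anchors = paste(major$n, collapse = ","),
      coverage = sum(major$n) / total,
      junctions = paste(junctions, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(calls)) do.call(rbind, calls) else
    data.frame(qchrom = character(0), n_partners = integer(0),
               partners = character(0), partner_anchors = character(0),
               coverage = numeric(0), junctions = character(0))
}

#' Detect translocated segments from synteny blocks
#'
#' Reports maximal runs of consecutive blocks (in query order) whose
#' reference chromosome is not a major partner of the query chromosome.
#' Runs flanked on both sides by major-partner blocks are flagged
#' "internal"; runs touching a chromosome end (or lacking a major flank) are
#' flagged "terminal".
#'
#' @param sb a [SyntenyBlocks] object.
#' @param minAnchorsSeg minimum anchors in a reported segment (default 5).
#' @param partnerMinFrac threshold defining major partners (default 0.1).
#' @return data.frame with columns \code{qchrom}, \code{source} (reference
#'   chromosome of origin), \code{qstart}, \code{qend}, \code{n_anchors},
#'   \code{status}.
#' @export
detectTranslocations <- function(sb, minAnchorsSeg = 5,
                                 partnerMinFrac = 0.1) {
  a <- sb@anchors
  counts <- .partnerCounts(sb)
  segs <- list()
  for (ch in unique(a$qchrom)) {
    total <- sum(a$qchrom == ch)
    pc <- counts[counts$qchrom == ch, , drop = FALSE]
    major <- pc$rchrom[pc$n / total >= partnerMinFrac]
    b <- sb@blocks[sb@blocks$qchrom == ch, , drop = FALSE]
    if (nrow(b) == 0L) next
    b <- b[order(b$qstart), , drop = FALSE]
    isMinor <- !(b$rchrom %in% major)
    # group consecutive minority blocks sharing a source chromosome
    grp <- cumsum(c(TRUE, b$rchrom[-1L] != b$rchrom[-nrow(b)] |
                      isMinor[-1L] != isMinor[-nrow(b)]))
    for (g in unique(grp[isMinor])) {
      rows <- which(grp == g)
      if (sum(b$n[rows]) < minAnchorsSeg) next
      before <- if (min(rows) > 1L) b$rchrom[min(rows) - 1L] else NA
      after <- if (max(rows) < nrow(b)) b$rchrom[max(rows) + 1L] else NA
      status <- if (!is.na(before) && !is.na(after) &&
                    before %in% major && after %in% major)
        "internal" else "terminal"
      segs[[length(segs) + 1L]] <- data.frame(
        qchrom = ch, source = b$rchrom[rows[1L]],
        qstart = min(b$qstart[rows]), qend = max(b$qend[rows]),
        n_anchors = sum(b$n[rows]), status = status,
        stringsAsFactors = FALSE)
    }
  }
  if (length(segs)) do.call(rbind, segs) else
    data.frame(qchrom = character(0), source = character(0),
               qstart = numeric(0), qend = numeric(0),
               n_anchors = integer(0), status = character(0))
}

#' Project a query-genome interval into reference coordinates
#'
#' For every block whose query span intersects the interval, the overlapping
#' part is mapped by linear interpolation between the block's endpoint
#' coordinates, orientation-aware (reverse blocks flip endpoints). The result
#' is the union of the projected pieces, merged per reference chromosome.
#' Projection resolution is bounded by the local anchor spacing.
#'
#' @param sb a [SyntenyBlocks] object.
#' @param interval GRanges of length 1 on the query genome.
#' @return GRanges on the reference genome (possibly empty, with a warning,
#'   when the interval hits no block).
#' @export
projectInterval <- function(sb, interval) {
  stopifnot(length(interval) == 1L)
  ch <- as.character(GenomicRanges::seqnames(interval))
  s <- GenomicRanges::start(interval)
  e <- GenomicRanges::end(interval)
  b <- sb@blocks[sb@blocks$qchrom == ch & sb@blocks$qend >= s &
                   sb@blocks$qstart <= e, , drop = FALSE]
  if (nrow(b) == 0L) {
    warning("interval hits no synteny block; empty projection")
    return(GenomicRanges::GRanges())
  }
  pieces <- lapply(seq_len(nrow(b)), function(i) {
    qs <- max(s, b$qstart[i]); qe <- min(e, b$qend[i])
    f <- function(p) {
      t <- (p - b$qstart[i]) / max(1, b$qend[i] - b$qstart[i])
      if (b$orientation[i] == "forward")
        b$rstart[i] + t * (b$rend[i] - b$rstart[i])
      else b$rend[i] - t * (b$rend[i] - b$rstart[i])
    }
    p1 <- f(qs); p2 <- f(qe)
    GenomicRanges::GRanges(b$rchrom[i],
                           IRanges::IRanges(round(min(p1, p2)),
                                            round(max(p1, p2))))
  })
  GenomicRanges::reduce(do.call(c, pieces))
}

#' Overlap between two inversions in different genomes
#'
#' Projects inversion A through the synteny blocks into genome B coordinates
#' and intersects with inversion B. Overlap length, reciprocal overlap
#' fractions, and per-side breakpoint-region overlap flags (projected
#' \code{flank}-regions of A intersecting either breakpoint region of B) are
#' reported; the pair is "partly overlapping" when the overlap reaches
#' \code{minOverlap} bp.
#'
#' @param invA GRanges of length 1 on the query genome of \code{sb}.
#' @param invB GRanges of length 1 on the reference genome of \code{sb}.
#' @param sb a [SyntenyBlocks] object mapping genome A (query) to genome B
#'   (reference).
#' @param flank breakpoint flank in bp (default 50000).
#' @param minOverlap minimum overlap in bp to call the pair overlapping
#'   (default 10000).
#' @return list with \code{projected} (GRanges), \code{overlap} (bp),
#'   \code{fracA}, \code{fracB}, \code{overlapping},
#'   \code{breakpointStart}, \code{breakpointEnd}.
#' @export
inversionOverlap <- function(invA, invB, sb, flank = 50000,
                             minOverlap = 10000) {
  stopifnot(length(invA) == 1L, length(invB) == 1L)
  proj <- suppressWarnings(projectInterval(sb, invA))
  invBr <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(invB)),
    IRanges::IRanges(GenomicRanges::start(invB), GenomicRanges::end(invB)))
  ov <- if (length(proj)) GenomicRanges::intersect(proj, invBr) else
    GenomicRanges::GRanges()
  overlap <- sum(GenomicRanges::width(ov))
  fracA <- if (length(proj)) overlap / sum(GenomicRanges::width(proj)) else 0
  fracB <- overlap / GenomicRanges::width(invB)
  sideRegion <- function(gr, side) {
    p <- if (side == "start") GenomicRanges::start(gr) else
      GenomicRanges::end(gr)
    GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(gr)),
                           IRanges::IRanges(max(1, p - flank), p + flank))
  }
  bRegions <- c(sideRegion(invBr, "start"), sideRegion(invBr, "end"))
  sideFlag <- function(side) {
    reg <- sideRegion(invA, side)
    pr <- suppressWarnings(projectInterval(sb, reg))
    length(pr) > 0L &&
      length(GenomicRanges::intersect(pr, bRegions)) > 0L
  }
  list(projected = proj, overlap = overlap, fracA = fracA, fracB = fracB,
       overlapping = overlap >= minOverlap,
       breakpointStart = sideFlag("start"), breakpointEnd = sideFlag("end"))
}
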