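#' @include AllClasses.R AllGenerics.R
NULL

# Merged (reduced) coverage Rle per chromosome for the repeats of one
# category. Overlaps across families within a category are merged, so window
# densities are covered-base fractions in [0, 1].
.categoryCoverage <- function(repeats, genome, scheme, category) {
  si <- .asSeqinfo(genome)
  sub <- repeats[repeats$repClass %in% categoryClasses(scheme, category)]
  sub <- GenomicRanges::GRanges(GenomicRanges::seqnames(sub),
                                GenomicRanges::ranges(sub))
  GenomeInfoDb::seqlevels(sub) <- GenomeInfoDb::seqnames(si)
  GenomeInfoDb::seqinfo(sub) <- si
  sub <- GenomicRanges::trim(sub)
  GenomicRanges::coverage(GenomicRanges::reduce(sub))
}

.checkRepeatChroms <- function(repeats, si) {
  unknown <- setdiff(unique(as.character(GenomicRanges::seqnames(repeats))),
                     GenomeInfoDb::seqnames(si))
  if (length(unknown))
    stop("repeat features on chromosome(s) absent from the genome index: ",
         paste(unknown, collapse = ", "))
}

#' Compute per-window repeat densities by category
#'
#' Each chromosome is tiled from its first base with non-overlapping windows
#' of width \code{w} (the last window may be shorter and is normalized by its
#' true width). Per category, features are clipped to the chromosome, merged,
#' and the covered-base fraction of each window reported.
#'
#' @param repeats GRanges with a \code{repClass} metadata column (as from
#'   [readRepeatAnnotation()] or [simulateLandscape()]).
#' @param genome Seqinfo (or named numeric of chromosome lengths).
#' @param w window width in bp (default 10000).
#' @param scheme a [CategoryScheme]; default [defaultCategoryScheme()].
#' @return A [WindowDensityTrack].
#' @export
computeWindowDensities <- function(repeats, genome, w = 10000,
                                   scheme = defaultCategoryScheme()) {
  stopifnot(w > 0)
  si <- .asSeqinfo(genome)
  .checkRepeatChroms(repeats, si)
  chroms <- GenomeInfoDb::seqnames(si)
  lens <- GenomeInfoDb::seqlengths(si)
  tiles <- lapply(seq_along(chroms), function(i) {
    tw <- .tileStarts(1L, lens[[i]], as.integer(w))
    cbind(chrom = i, tw)
  })
  tiles <- do.call(rbind, tiles)
  win <- GenomicRanges::GRanges(chroms[tiles$chrom],
                                IRanges::IRanges(tiles$start, tiles$end),
                                seqinfo = si)
  dens <- lapply(names(categoryClasses(scheme)), function(cat) {
    cov <- .categoryCoverage(repeats, si, scheme, cat)
    unlist(lapply(seq_along(chroms), function(i) {
      sel <- tiles$chrom == i
      covered <- .windowCovered(cov[[chroms[[i]]]],
                                tiles$start[sel], tiles$end[sel])
      covered / (tiles$end[sel] - tiles$start[sel] + 1)
    }), use.names = FALSE)
  })
  names(dens) <- names(categoryClasses(scheme))
  S4Vectors::mcols(win) <- S4Vectors::DataFrame(dens)
  methods::new("WindowDensityTrack", windows = win,
               windowSize = as.integer(w), scheme = scheme)
}

#' Call density peaks against chromosome-level percentiles
#'
#' A window is a peak when its density strictly exceeds the given percentile
#' of all window densities of its own chromosome (linear interpolation
#' between order statistics). The chromosomal median is reported alongside.
#'
#' @param track a [WindowDensityTrack].
#' @param category category name (a density column of the track).
#' @param percentile reference percentile in [0, 100] (default 95).
#' @return data.frame with one row per window: chromosome, start, end,
#'   density, chromosome median, chromosome percentile, and \code{is_peak}.
#' @export
callPeaks <- function(track, category = "all_te", percentile = 95) {
  win <- densityWindows(track)
  if (length(win) == 0L) stop("empty density track")
  d <- S4Vectors::mcols(win)[[category]]
  if (is.null(d)) stop("no density column for category '", category, "'")
  chrom <- as.character(GenomicRanges::seqnames(win))
  out <- data.frame(chrom = chrom,
                    start = GenomicRanges::start(win),
                    end = GenomicRanges::end(win),
                    density = d,
                    chrom_median = NA_real_, chrom_ref = NA_real_,
                    is_peak = NA)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    if (sum(sel) < 20L)
      warning("chromosome ", ch, " has fewer than 20 windows; ",
              "percentile reference is unstable")
    ref <- stats::quantile(d[sel], percentile / 100, type = 7, names = FALSE)
    out$chrom_median[sel] <- stats::median(d[sel])
    out$chrom_ref[sel] <- ref
    out$is_peak[sel] <- d[sel] > ref
  }
  out
}

# Subwindow tiling of arbitrary regions (tiled from each region's start; the
# final subwindow of a region may be short) plus covered-base densities for
# one category coverage Rle. `regions` must be on a single chromosome.
.regionSubwindows <- function(starts, ends, w) {
  out <- lapply(seq_along(starts), function(i) {
    tw <- .tileStarts(starts[i], ends[i], as.integer(w))
    cbind(region = i, tw)
  })
  do.call(rbind, out)
}

#' Per-subwindow densities and median over a region
#'
#' The region is tiled from its own start in subwindows of width \code{w}
#' (the last may be fractional); densities use the same merged-coverage
#' semantics as [computeWindowDensities()]. Returns the subwindow densities
#' and their median.
#'
#' @param repeats GRanges with \code{repClass}.
#' @param region GRanges of length 1.
#' @param genome Seqinfo or named lengths.
#' @param w subwindow width in bp.
#' @param scheme a [CategoryScheme].
#' @param category category to evaluate.
#' @return list with \code{windows} (GRanges), \code{density} (numeric) and
#'   \code{median}.
#' @export
regionDensity <- function(repeats, region, genome, w = 10000,
                          scheme = defaultCategoryScheme(),
                          category = "all_te") {
  stopifnot(length(region) == 1L, w > 0)
  si <- .asSeqinfo(genome)
  .checkRepeatChroms(repeats, si)
  ch <- as.character(GenomicRanges::seqnames(region))
  if (!ch %in% GenomeInfoDb::seqnames(si))
    stop("region chromosome ", ch, " absent from genome index")
  L <- GenomeInfoDb::seqlengths(si)[[ch]]
  s <- max(1L, GenomicRanges::start(region))
  e <- min(L, GenomicRanges::end(region))
  cov <- .categoryCoverage(repeats, si, scheme, category)
  tw <- .tileStarts(s, e, as.integer(w))
  covered <- .windowCovered(cov[[ch]], tw$start, tw$end)
  dens <- covered / (tw$end - tw$start + 1)
  list(windows = GenomicRanges::GRanges(ch, IRanges::IRanges(tw$start, tw$end),
                                        seqinfo = si),
       density = dens,
       median = stats::median(dens))
}

#' Fine-scale density track across a gene cluster and its flanks
#'
#' Identical semantics to [computeWindowDensities()], restricted to the
#' cluster region extended by \code{flank} bp on each side (clipped to the
#' chromosome), with a small default window suited to gene-cluster scale.
#'
#' @param repeats GRanges with \code{repClass}.
#' @param cluster GRanges of length 1 (the gene cluster span).
#' @param genome Seqinfo or named lengths.
#' @param flank flank width in bp added on each side (default 25000).
#' @param w subwindow width in bp (default 500).
#' @param scheme a [CategoryScheme].
#' @return A [WindowDensityTrack] whose windows tile the extended region.
#' @export
clusterDensity <- function(repeats, cluster, genome, flank = 25000, w = 500,
                           scheme = defaultCategoryScheme()) {
  stopifnot(length(cluster) == 1L, flank >= 0, w > 0)
  si <- .asSeqinfo(genome)
  .checkRepeatChroms(repeats, si)
  ch <- as.character(GenomicRanges::seqnames(cluster))
  L <- GenomeInfoDb::seqlengths(si)[[ch]]
  s <- max(1L, GenomicRanges::start(cluster) - as.integer(flank))
  e <- min(L, GenomicRanges::end(cluster) + as.integer(flank))
  tw <- .tileStarts(s, e, as.integer(w))
  win <- GenomicRanges::GRanges(ch, IRanges::IRanges(tw$start, tw$end),
                                seqinfo = si)
  dens <- lapply(names(categoryClasses(scheme)), function(cat) {
    cov <- .categoryCoverage(repeats, si, scheme, cat)
    .windowCovered(cov[[ch]], tw$start, tw$end) / (tw$end - tw$start + 1)
  })
  names(dens) <- names(categoryClasses(scheme))
  S4Vectors::mcols(win) <- S4Vectors::DataFrame(dens)
  methods::new("WindowDensityTrack", windows = win,
               windowSize = as.integer(w), scheme = scheme)
}

#' TE families shared by at least two annotated regions
#'
#' For a set of named regions (e.g. gene clusters), reports the repeat
#' families present in two or more regions, with the individual insertions
#' per region; families present in exactly one region are excluded.
#'
#' @param repeats GRanges with \code{family} metadata.
#' @param regions named GRanges of length >= 2 (names from the \code{name}
#'   metadata column or \code{names(regions)}).
#' @return data.frame of insertions (family, region, chrom, start, end) for
#'   the shared families, ordered by family then region.
#' @export
sharedTeFamilies <- function(repeats, regions) {
  if (length(regions) < 2L) stop("need at least 2 regions")
  regNames <- if (!is.null(regions$name)) regions$name else names(regions)
  if (is.null(regNames)) regNames <- paste0("region", seq_along(regions))
  hits <- GenomicRanges::findOverlaps(repeats, regions, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.frame(family = character(0), region = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0)))
  ins <- data.frame(
    family = repeats$family[S4Vectors::queryHits(hits)],
    region = regNames[S4Vectors::subjectHits(hits)],
    chrom = as.character(
      GenomicRanges::seqnames(repeats))[S4Vectors::queryHits(hits)],
    start = GenomicRanges::start(repeats)[S4Vectors::queryHits(hits)],
    end = GenomicRanges::end(repeats)[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  nReg <- vapply(split(ins$region, ins$family),
                 function(r) length(unique(r)), 0L)
  shared <- names(nReg)[nReg >= 2L]
  out <- ins[ins$family %in% shared, , drop = FALSE]
  out <- out[order(out$family, out$region, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
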