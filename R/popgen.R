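#' @include AllClasses.R AllGenerics.R
NULL

# Haplotype column indices for a population given a populations mapping
# (named list pop -> sample names, or data.frame sample/population).
.popHaplotypes <- function(gt, population, populations) {
  if (is.data.frame(populations)) {
    samples <- populations$sample[populations$population == population]
  } else {
    if (!population %in% names(populations))
      stop("unknown population '", population, "'")
    samples <- populations[[population]]
  }
  idx <- which(gt@sampleMap$sample %in% samples)
  if (length(idx) == 0L)
    stop("no haplotypes found for population '", population, "'")
  idx
}

# Window assignment and boundaries for sites of one chromosome.
.windowIndex <- function(pos, w) (pos - 1L) %/% as.integer(w)

# Ratio-of-sums aggregation of per-site numerators/denominators into
# fixed-width windows per chromosome.
.windowAggregate <- function(chrom, pos, num, den, w, extra = NULL) {
  key <- paste(chrom, .windowIndex(pos, w), sep = "\r")
  first <- !duplicated(key)
  ord <- order(match(key, key[first]))
  numS <- rowsum(num, key, reorder = FALSE)
  denS <- rowsum(den, key, reorder = FALSE)
  nS <- rowsum(rep(1L, length(pos)), key, reorder = FALSE)
  k <- key[first]
  wi <- as.integer(sub("^.*\r", "", k))
  data.frame(
    chromosome = sub("\r.*$", "", k),
    window_pos_1 = wi * as.integer(w) + 1L,
    window_pos_2 = (wi + 1L) * as.integer(w),
    no_sites = as.integer(nS[, 1L]),
    numerator = as.numeric(numS[, 1L]),
    denominator = as.numeric(denS[, 1L]),
    stringsAsFactors = FALSE)
}

#' Windowed nucleotide diversity (pi) with invariant sites
#'
#' Per site, with \eqn{n_1} reference and \eqn{n_2} alternate alleles among
#' the population's non-missing haplotypes, the pairwise difference count is
#' \eqn{k = n_1 n_2} and the comparison count
#' \eqn{c = (n_1+n_2)(n_1+n_2-1)/2}. Windowed pi is the ratio of sums
#' \eqn{\sum k / \sum c} over all sites of the window — invariant sites
#' contribute comparisons but no differences, so they must be present in the
#' input for an unbiased estimate (a warning is issued when every site is
#' variant). Windows with zero comparisons get NA, not 0.
#'
#' @param gt a [GenotypeTable] including invariant sites.
#' @param population population name.
#' @param populations named list (population -> sample names) or data.frame
#'   with columns \code{sample}, \code{population}.
#' @param w window size in bp (default 10000).
#' @return data.frame with columns chromosome, window_pos_1, window_pos_2,
#'   no_sites, count_diffs, count_comparisons, avg_pi.
#' @export
windowedPi <- function(gt, population, populations, w = 10000) {
  idx <- .popHaplotypes(gt, population, populations)
  ac <- alleleCounts(gt, idx)
  if (all(isVariantSite(gt)))
    warning("no invariant sites in input; pi will be inflated")
  n <- ac[, "ref"] + ac[, "alt"]
  k <- as.numeric(ac[, "ref"]) * ac[, "alt"]
  cc <- as.numeric(n) * (n - 1) / 2
  out <- .windowAggregate(gt@chrom, gt@pos, k, cc, w)
  names(out)[names(out) == "numerator"] <- "count_diffs"
  names(out)[names(out) == "denominator"] <- "count_comparisons"
  out$avg_pi <- ifelse(out$count_comparisons > 0,
                       out$count_diffs / out$count_comparisons, NA_real_)
  out
}

#' Windowed absolute divergence (DXY) with invariant sites
#'
#' Per site, with reference/alternate counts \eqn{(x_1, x_2)} in population X
#' and \eqn{(y_1, y_2)} in population Y over non-missing haplotypes, the
#' between-population difference count is \eqn{k = x_1 y_2 + x_2 y_1} and the
#' comparison count \eqn{c = (x_1+x_2)(y_1+y_2)}; windowed DXY is
#' \eqn{\sum k / \sum c}. Sites entirely missing in either population
#' contribute nothing.
#'
#' @inheritParams windowedPi
#' @param popX,popY the two population names.
#' @return data.frame with columns chromosome, window_pos_1, window_pos_2,
#'   no_sites, count_diffs, count_comparisons, avg_dxy.
#' @export
windowedDxy <- function(gt, popX, popY, populations, w = 10000) {
  acx <- alleleCounts(gt, .popHaplotypes(gt, popX, populations))
  acy <- alleleCounts(gt, .popHaplotypes(gt, popY, populations))
  k <- as.numeric(acx[, "ref"]) * acy[, "alt"] +
    as.numeric(acx[, "alt"]) * acy[, "ref"]
  cc <- as.numeric(acx[, "ref"] + acx[, "alt"]) *
    (acy[, "ref"] + acy[, "alt"])
  out <- .windowAggregate(gt@chrom, gt@pos, k, cc, w)
  names(out)[names(out) == "numerator"] <- "count_diffs"
  names(out)[names(out) == "denominator"] <- "count_comparisons"
  out$avg_dxy <- ifelse(out$count_comparisons > 0,
                        out$count_diffs / out$count_comparisons, NA_real_)
  out
}

# Per-site Weir-Cockerham variance components for two haploid-sampled
# populations (h_bar = 0). Returns cbind(a, b) per site; sites that are not
# usable (monomorphic pooled, a population fully missing, or n_bar <= 1)
# come back NA.
.wcComponents <- function(n1, p1, n2, p2) {
  r <- 2
  nbar <- (n1 + n2) / r
  usable <- n1 >= 1 & n2 >= 1 & nbar > 1
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
  a[!usable] <- NA_real_
  b[!usable] <- NA_real_
  cbind(a = a, b = b)
}

#' Windowed FST between two populations
#'
#' The default estimator is Weir & Cockerham's variance-component theta in
#' its haploid-sample (haplotype count) form, windowed as the ratio of summed
#' components \eqn{\sum a / \sum (a + b)} over polymorphic biallelic sites.
#' Hudson's estimator (numerator \eqn{(p_1 - p_2)^2} minus sampling
#' corrections over \eqn{p_1(1-p_2) + p_2(1-p_1)}) is available for
#' sensitivity analysis. Windows with no usable polymorphic site are NA;
#' negative values are reported as computed.
#'
#' @inheritParams windowedDxy
#' @param estimator "wc" (Weir-Cockerham, default) or "hudson".
#' @return data.frame with columns chromosome, window_pos_1, window_pos_2,
#'   no_snps, numerator, denominator, avg_fst.
#' @export
windowedFst <- function(gt, popX, popY, populations, w = 10000,
                        estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  acx <- alleleCounts(gt, .popHaplotypes(gt, popX, populations))
  acy <- alleleCounts(gt, .popHaplotypes(gt, popY, populations))
  n1 <- acx[, "ref"] + acx[, "alt"]
  n2 <- acy[, "ref"] + acy[, "alt"]
  totAlt <- acx[, "alt"] + acy[, "alt"]
  totRef <- acx[, "ref"] + acy[, "ref"]
  poly <- totAlt > 0L & totRef > 0L
  keep <- poly & n1 >= 1L & n2 >= 1L
  if (estimator == "wc") keep <- keep & (n1 + n2) / 2 > 1
  else keep <- keep & n1 > 1L & n2 > 1L
  if (!any(keep)) {
    return(data.frame(chromosome = character(0), window_pos_1 = integer(0),
                      window_pos_2 = integer(0), no_snps = integer(0),
                      numerator = numeric(0), denominator = numeric(0),
                      avg_fst = numeric(0)))
  }
  p1 <- acx[keep, "alt"] / n1[keep]
  p2 <- acy[keep, "alt"] / n2[keep]
  if (estimator == "wc") {
    comp <- .wcComponents(n1[keep], p1, n2[keep], p2)
    num <- comp[, "a"]
    den <- comp[, "a"] + comp[, "b"]
  } else {
    num <- (p1 - p2)^2 -
      p1 * (1 - p1) / (n1[keep] - 1) - p2 * (1 - p2) / (n2[keep] - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  }
  out <- .windowAggregate(gt@chrom[keep], gt@pos[keep], num, den, w)
  names(out)[names(out) == "no_sites"] <- "no_snps"
  out$avg_fst <- ifelse(out$denominator != 0,
                        out$numerator / out$denominator, NA_real_)
  out
}

#' Scan for conserved tracts (runs of low-FST windows)
#'
#' Maximal runs of consecutive windows whose FST lies strictly below the
#' threshold, merged across at most one intervening missing (NA) window;
#' windows at or above the threshold break runs.
#'
#' @param fst data.frame from [windowedFst()] (columns chromosome,
#'   window_pos_1, window_pos_2, avg_fst).
#' @param threshold FST threshold (default 0.5).
#' @return data.frame with columns chromosome, start, end, n_windows.
#' @export
scanConservedTracts <- function(fst, threshold = 0.5) {
  out <- list()
  for (ch in unique(fst$chromosome)) {
    d <- fst[fst$chromosome == ch, , drop = FALSE]
    d <- d[order(d$window_pos_1), , drop = FALSE]
    state <- ifelse(is.na(d$avg_fst), "na",
                    ifelse(d$avg_fst < threshold, "low", "high"))
    run <- NULL
    naGap <- 0L
    flush <- function(run) {
      if (is.null(run)) return(NULL)
      out[[length(out) + 1L]] <<- data.frame(
        chromosome = ch, start = d$window_pos_1[run[1L]],
        end = d$window_pos_2[run[length(run)]],
        n_windows = length(run), stringsAsFactors = FALSE)
      NULL
    }
    for (i in seq_len(nrow(d))) {
      if (state[i] == "low") {
        if (!is.null(run) && naGap <= 1L) run <- c(run, i)
        else { flush(run); run <- i }
        naGap <- 0L
      } else if (state[i] == "na") {
        naGap <- naGap + 1L
        if (naGap > 1L) { flush(run); run <- NULL }
      } else {
        flush(run); run <- NULL; naGap <- 0L
      }
    }
    flush(run)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chromosome = character(0), start = integer(0),
               end = integer(0), n_windows = integer(0))
}
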