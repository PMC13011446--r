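#' @include AllClasses.R
NULL

#' Phylogenetic regression under Brownian motion (closed-form GLS)
#'
#' Fits \code{y ~ x} by generalized least squares with residual covariance
#' \eqn{\sigma^2 C}, where \eqn{C_{ij}} is the shared root-to-tip path length
#' of tips i and j on the supplied tree (the Brownian-motion model). For a
#' fixed tree this is exact:
#' \eqn{\hat\beta = (X'C^{-1}X)^{-1} X'C^{-1} y},
#' \eqn{\hat\sigma^2 = (y - X\hat\beta)' C^{-1} (y - X\hat\beta) / (n - 2)},
#' standard errors from \eqn{\hat\sigma^2 (X'C^{-1}X)^{-1}}, and two-sided
#' p-values from the t distribution on n - 2 degrees of freedom. On a star
#' tree with equal tip depths the fit coincides with ordinary least squares.
#'
#' @param tree rooted \code{phylo} with non-negative branch lengths, or a
#'   Newick string.
#' @param y named numeric response (names = tip labels), e.g. haploid
#'   chromosome number.
#' @param x named numeric predictor, e.g. northernmost latitude or preferred
#'   temperature.
#' @return A [PglsResult].
#' @examples
#' tr <- ape::rcoal(8)
#' x <- stats::setNames(rnorm(8), tr$tip.label)
#' y <- 2 - 0.5 * x + stats::setNames(rnorm(8, sd = 0.1), tr$tip.label)
#' pglsBM(tr, y, x)
#' @export
pglsBM <- function(tree, y, x) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  tips <- tree$tip.label
  n <- length(tips)
  if (n < 4L) stop("need at least 4 tips")
  if (is.null(names(y)) || is.null(names(x)))
    stop("y and x must be named by tip label")
  miss <- setdiff(tips, names(y))
  if (length(miss)) stop("missing response for tips: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(tips, names(x))
  if (length(miss)) stop("missing predictor for tips: ",
                         paste(miss, collapse = ", "))
  y <- y[tips]; x <- x[tips]
  C <- ape::vcv(tree)
  R <- tryCatch(chol(C), error = function(e)
    stop("singular phylogenetic covariance (duplicate zero-length tips?)"))
  X <- cbind(`(Intercept)` = 1, x = as.numeric(x))
  Xs <- backsolve(R, X, transpose = TRUE)
  ys <- backsolve(R, as.numeric(y), transpose = TRUE)
  qrX <- qr(Xs)
  if (qrX$rank < 2L) stop("collinear design (constant predictor?)")
  beta <- qr.coef(qrX, ys)
  resid <- ys - Xs %*% beta
  df <- n - 2L
  sigma2 <- sum(resid^2) / df
  XtX <- crossprod(Xs)
  covBeta <- sigma2 * solve(XtX)
  se <- sqrt(diag(covBeta))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = df)
  methods::new("PglsResult",
               coefficients = stats::setNames(as.numeric(beta),
                                              c("(Intercept)", "slope")),
               se = stats::setNames(as.numeric(se),
                                    c("(Intercept)", "slope")),
               tValue = stats::setNames(as.numeric(tval),
                                        c("(Intercept)", "slope")),
               df = as.numeric(df),
               pValue = stats::setNames(as.numeric(pval),
                                        c("(Intercept)", "slope")),
               pAdjusted = NA_real_,
               sigma2 = sigma2, n = as.integer(n))
}

#' Bonferroni adjustment of p-values
#'
#' Thin wrapper around \code{stats::p.adjust(..., method = "bonferroni")}
#' with an explicit number of tests (defaults to the number of p-values
#' supplied, i.e. the number of models fitted in one invocation).
#'
#' @param p numeric p-values.
#' @param m number of tests.
#' @return adjusted p-values, capped at 1.
#' @examples
#' bonferroniAdjust(c(0.01, 0.03))
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  stats::p.adjust(p, method = "bonferroni", n = m)
}

# Coerce an alignment (character vector, matrix, file path to FASTA, or
# Biostrings XStringSet) to an upper-case character matrix, rows = sequences.
.asAlignmentMatrix <- function(alignment) {
  if (methods::is(alignment, "DNAStringSet") ||
      methods::is(alignment, "AAStringSet") ||
      methods::is(alignment, "BStringSet"))
    alignment <- as.character(alignment)
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment))
    alignment <- as.character(Biostrings::readBStringSet(alignment))
  if (is.character(alignment)) {
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequences have unequal lengths")
    alignment <- do.call(rbind, strsplit(toupper(alignment), ""))
  }
  if (!is.matrix(alignment)) stop("cannot interpret alignment input")
  toupper(alignment)
}

#' Per-alignment site statistics
#'
#' A column is \emph{variable} when it holds at least two distinct non-gap
#' states, \emph{parsimony-informative} when at least two distinct non-gap
#' states are each present at least twice, and \emph{gap-containing} when it
#' holds at least one gap character ("-"). Percentages are over all columns.
#'
#' @param alignment character vector of equal-length sequences, a character
#'   matrix, a Biostrings XStringSet, or a FASTA file path.
#' @param id alignment identifier (default "aln").
#' @return one-row data.frame: id, length, pct_variable,
#'   pct_parsimony_informative, pct_gap.
#' @export
alignmentStats <- function(alignment, id = "aln") {
  m <- .asAlignmentMatrix(alignment)
  L <- ncol(m)
  gapChars <- c("-", ".")
  isVar <- logical(L); isPI <- logical(L); hasGap <- logical(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    hasGap[j] <- any(col %in% gapChars)
    states <- table(col[!(col %in% gapChars)])
    isVar[j] <- length(states) >= 2L
    isPI[j] <- sum(states >= 2L) >= 2L
  }
  data.frame(id = id, length = L,
             pct_variable = 100 * sum(isVar) / L,
             pct_parsimony_informative = 100 * sum(isPI) / L,
             pct_gap = 100 * sum(hasGap) / L,
             stringsAsFactors = FALSE)
}

#' Filter alignments on length, variability and gap content
#'
#' Kept alignments must be strictly longer than \code{minLen} columns, hold
#' strictly more than \code{minVar} percent variable and \code{minPi} percent
#' parsimony-informative sites, and at most \code{maxGap} percent
#' gap-containing columns (boundary values: length exactly \code{minLen} or
#' PI exactly \code{minPi} are removed; gap exactly \code{maxGap} is kept).
#'
#' @param stats data.frame of [alignmentStats()] rows.
#' @param minLen minimum length in columns (exclusive; default 500).
#' @param minVar minimum percent variable sites (exclusive; default 5).
#' @param minPi minimum percent parsimony-informative sites (exclusive;
#'   default 2.5).
#' @param maxGap maximum percent gap-containing columns (inclusive; default
#'   30).
#' @return list with data.frames \code{kept} and \code{removed}.
#' @export
filterAlignments <- function(stats, minLen = 500, minVar = 5, minPi = 2.5,
                             maxGap = 30) {
  keep <- stats$length > minLen &
    stats$pct_variable > minVar &
    stats$pct_parsimony_informative > minPi &
    stats$pct_gap <= maxGap
  list(kept = stats[keep, , drop = FALSE],
       removed = stats[!keep, , drop = FALSE])
}

#' Quartet frequencies of gene trees around a focal branch
#'
#' Each gene tree is restricted to the tips of four taxon groups and
#' classified into one of the three unrooted resolutions of the quartet: a
#' tree supports a resolution when some internal bipartition splits the four
#' groups cleanly two against two. Trees where the focal split is a polytomy
#' (or where no clean 2+2 bipartition exists) are counted unresolved and
#' excluded from the frequency denominator; trees missing a group entirely
#' are skipped.
#'
#' @param trees a \code{multiPhylo} (or list of \code{phylo}).
#' @param groups named list of exactly four character vectors of tip labels.
#' @return list with \code{frequencies} (named numeric of the three
#'   resolutions, summing to 1 over resolved trees), \code{counts},
#'   \code{n_resolved}, \code{n_unresolved}, \code{n_skipped}.
#' @export
quartetFrequencies <- function(trees, groups) {
  if (length(groups) != 4L || is.null(names(groups)))
    stop("groups must be a named list of 4 tip-label vectors")
  gn <- names(groups)
  topoNames <- c(paste0(gn[1], ",", gn[2], "|", gn[3], ",", gn[4]),
                 paste0(gn[1], ",", gn[3], "|", gn[2], ",", gn[4]),
                 paste0(gn[1], ",", gn[4], "|", gn[2], ",", gn[3]))
  pairSets <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L))
  counts <- stats::setNames(c(0L, 0L, 0L), topoNames)
  unresolved <- 0L; skipped <- 0L
  if (inherits(trees, "phylo")) trees <- list(trees)
  for (tr in trees) {
    present <- lapply(groups, intersect, tr$tip.label)
    if (any(lengths(present) == 0L)) { skipped <- skipped + 1L; next }
    keep <- unlist(present, use.names = FALSE)
    sub <- ape::keep.tip(tr, keep)
    sub <- ape::unroot(sub)
    groupOf <- rep(seq_along(groups), lengths(present))
    names(groupOf) <- keep
    parts <- ape::prop.part(sub)
    labs <- attr(parts, "labels")
    resolved <- NA_integer_
    for (p in parts) {
      side <- unique(groupOf[labs[p]])
      other <- unique(groupOf[labs[-p]])
      if (length(side) == 2L && length(other) == 2L) {
        hit <- which(vapply(pairSets, function(ps)
          setequal(side, ps) || setequal(other, ps), TRUE))
        if (length(hit) == 1L) { resolved <- hit; break }
      }
    }
    if (is.na(resolved)) unresolved <- unresolved + 1L
    else counts[resolved] <- counts[resolved] + 1L
  }
  nRes <- sum(counts)
  freqs <- if (nRes > 0L) counts / nRes else counts * NA_real_
  list(frequencies = freqs, counts = counts, n_resolved = nRes,
       n_unresolved = unresolved, n_skipped = skipped)
}
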