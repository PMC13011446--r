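#' @include AllClasses.R
NULL

#' Build a synthetic-study configuration
#'
#' Defaults describe a desk-scale two-species comparative study: a handful of
#' 10-Mb ancestral chromosomes, a TE complement spanning the major classes at
#' rates giving realistic interspersed-repeat coverage, two populations of 14
#' diploid individuals (28 haplotypes) with high background differentiation,
#' and no rearrangements until the caller plants some.
#'
#' @param seed integer master seed.
#' @param chromosomes data.frame (\code{name}, \code{length}) of the
#'   ancestral genome.
#' @param teFamilies data.frame (\code{family}, \code{class}, \code{rate}
#'   insertions per bp, \code{minLen}, \code{maxLen}).
#' @param inversions data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{lambda}, \code{families}) on the derived genome; \code{lambda}
#'   multiplies the insertion rate of the enriched families within 50 kb of
#'   each breakpoint (1 = no enrichment), \code{families} is a
#'   comma-separated family list ("" = all families).
#' @param fusions data.frame (\code{chromA}, \code{chromB}) of ancestral
#'   chromosomes concatenated in the derived genome.
#' @param translocations data.frame (\code{srcChrom}, \code{srcStart},
#'   \code{srcEnd}, \code{destChrom}, \code{destPos}) on the derived genome.
#' @param genesPerMb gene density for the anchor table (default 35,
#'   comparable to a compact teleost genome).
#' @param popgen list: \code{nHapPerPop} (default 28), \code{nSites}
#'   (default 100000), \code{d} between-population fixed-difference rate
#'   (default 0.02), \code{piX} (default 0.002), \code{piY} (default 0.004),
#'   \code{conservedTracts} data.frame (\code{start}, \code{end}, \code{d})
#'   with the reduced rate inside each tract.
#' @param bm list: \code{tree} (phylo, Newick string, or NULL to simulate a
#'   13-tip coalescent tree), \code{intercept}, \code{slope}, \code{sigma2}.
#' @return A [SimConfig].
#' @export
simConfig <- function(seed = 1L,
                      chromosomes = data.frame(
                        name = paste0("chr", 1:4),
                        length = rep(10e6, 4)),
                      teFamilies = data.frame(
                        family = c("DNA/hAT-10", "DNA/MITE-224", "LINE/L2",
                                   "LTR/Gypsy-7", "SINE/tRNA-3",
                                   "Simple_repeat"),
                        class = c("DNA", "DNA", "LINE", "LTR", "SINE",
                                  "Simple_repeat"),
                        rate = c(1e-4, 5e-5, 1e-4, 5e-5, 5e-5, 1e-4),
                        minLen = c(100, 80, 300, 500, 80, 20),
                        maxLen = c(2000, 600, 4000, 6000, 400, 300)),
                      inversions = NULL,
                      fusions = NULL,
                      translocations = NULL,
                      genesPerMb = 35,
                      popgen = list(),
                      bm = list()) {
  emptyInv <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0), lambda = numeric(0),
                         families = character(0))
  emptyFus <- data.frame(chromA = character(0), chromB = character(0))
  emptyTrl <- data.frame(srcChrom = character(0), srcStart = numeric(0),
                         srcEnd = numeric(0), destChrom = character(0),
                         destPos = numeric(0))
  if (is.null(inversions)) inversions <- emptyInv
  if (is.null(fusions)) fusions <- emptyFus
  if (is.null(translocations)) translocations <- emptyTrl
  if (!"lambda" %in% names(inversions) && nrow(inversions))
    inversions$lambda <- 1
  if (!"families" %in% names(inversions) && nrow(inversions))
    inversions$families <- ""
  pg <- list(
    nHapPerPop = 28L, nSites = 100000L, d = 0.02, piX = 0.002, piY = 0.004,
    conservedTracts = data.frame(start = numeric(0), end = numeric(0),
                                 d = numeric(0)))
  for (nm in names(popgen)) pg[[nm]] <- popgen[[nm]]
  bmD <- list(tree = NULL, intercept = 23, slope = -0.1, sigma2 = 1)
  for (nm in names(bm)) bmD[[nm]] <- bm[[nm]]
  bm <- bmD
  cfg <- methods::new("SimConfig", seed = as.integer(seed),
                      chromosomes = chromosomes, teFamilies = teFamilies,
                      inversions = inversions, fusions = fusions,
                      translocations = translocations,
                      genesPerMb = genesPerMb, popgen = pg, bm = bm)
  .validateSimConfig(cfg)
  cfg
}

.validateSimConfig <- function(cfg) {
  if (any(cfg@teFamilies$rate < 0)) stop("insertion rates must be >= 0")
  if (any(cfg@chromosomes$length <= 0))
    stop("chromosome lengths must be > 0")
  dg <- derivedGenome(cfg)
  lens <- GenomeInfoDb::seqlengths(dg)
  inv <- cfg@inversions
  if (nrow(inv)) {
    bad <- !(inv$chrom %in% names(lens))
    if (any(bad)) stop("inversion on unknown derived chromosome: ",
                       paste(inv$chrom[bad], collapse = ", "))
    if (any(inv$start < 1 | inv$end > lens[inv$chrom] | inv$start >= inv$end))
      stop("inversion interval outside chromosome bounds")
    if (any(inv$lambda < 0)) stop("lambda must be >= 0")
    for (ch in unique(inv$chrom)) {
      ir <- inv[inv$chrom == ch, , drop = FALSE]
      ir <- ir[order(ir$start), , drop = FALSE]
      if (nrow(ir) > 1L && any(ir$start[-1L] <= ir$end[-nrow(ir)]))
        stop("overlapping planted inversions on chromosome ", ch)
    }
  }
  trl <- cfg@translocations
  if (nrow(trl)) {
    bad <- !(trl$srcChrom %in% names(lens)) |
      !(trl$destChrom %in% names(lens))
    if (any(bad)) stop("translocation on unknown derived chromosome")
    if (any(trl$srcStart < 1 | trl$srcEnd > lens[trl$srcChrom] |
            trl$srcStart >= trl$srcEnd |
            trl$destPos < 1 | trl$destPos > lens[trl$destChrom]))
      stop("translocation interval outside chromosome bounds")
  }
  fus <- cfg@fusions
  if (nrow(fus)) {
    miss <- setdiff(c(fus$chromA, fus$chromB), cfg@chromosomes$name)
    if (length(miss)) stop("fusion of unknown ancestral chromosome: ",
                           paste(miss, collapse = ", "))
    if (anyDuplicated(c(fus$chromA, fus$chromB)))
      stop("a chromosome may participate in at most one fusion")
  }
  invisible(TRUE)
}

#' Derived (focal-species) genome of a configuration
#'
#' Applies the configured fusions to the ancestral chromosome set: each
#' fusion pair A, B is replaced by a single chromosome named "A_B" with the
#' summed length; unfused chromosomes are carried over.
#'
#' @param config a [SimConfig].
#' @return Seqinfo of the derived genome.
#' @export
derivedGenome <- function(config) {
  chroms <- config@chromosomes
  lens <- stats::setNames(as.numeric(chroms$length),
                          as.character(chroms$name))
  fus <- config@fusions
  used <- character(0)
  out <- c()
  for (i in seq_len(nrow(fus))) {
    a <- fus$chromA[i]; b <- fus$chromB[i]
    out[paste0(a, "_", b)] <- lens[[a]] + lens[[b]]
    used <- c(used, a, b)
  }
  rest <- setdiff(names(lens), used)
  out <- c(out, lens[rest])
  .asSeqinfo(out)
}

#' Simulate a repeat landscape with optional breakpoint enrichment
#'
#' Repeats of each family are placed on the derived genome as a homogeneous
#' Poisson process at the family's per-bp insertion rate, with lengths drawn
#' uniformly from the family's length range. Within 50 kb of a planted
#' inversion breakpoint, families listed as enriched for that inversion are
#' placed at rate times \code{lambda} (a step function over the flank;
#' \code{lambda = 1} makes flanks statistically indistinguishable from
#' background). Output is byte-identical for identical configurations.
#'
#' @param config a [SimConfig].
#' @param enrichFlank half-width of the enriched breakpoint flank in bp
#'   (default 50000).
#' @return list with \code{genome} (Seqinfo of the derived genome),
#'   \code{repeats} (GRanges with \code{family}, \code{repClass}) and
#'   \code{truth} (planted inversions as GRanges with \code{lambda}, and the
#'   enriched flank regions).
#' @export
simulateLandscape <- function(config, enrichFlank = 50000) {
  .validateSimConfig(config)
  si <- derivedGenome(config)
  chroms <- GenomeInfoDb::seqnames(si)
  lens <- GenomeInfoDb::seqlengths(si)
  fam <- config@teFamilies
  inv <- config@inversions
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[[ci]]
    L <- lens[[ch]]
    set.seed(.substream(config@seed, 1L, ci))
    chromInv <- inv[inv$chrom == ch, , drop = FALSE]
    pieces <- list()
    for (fi in seq_len(nrow(fam))) {
      r <- fam$rate[fi]
      # enriched flanks of this family on this chromosome
      enr <- IRanges::IRanges()
      if (nrow(chromInv)) {
        famList <- strsplit(chromInv$families, ",")
        hit <- vapply(seq_len(nrow(chromInv)), function(k) {
          fl <- trimws(famList[[k]])
          chromInv$lambda[k] != 1 &&
            (all(!nzchar(fl)) || fam$family[fi] %in% fl)
        }, TRUE)
        if (any(hit)) {
          bp <- c(chromInv$start[hit], chromInv$end[hit])
          lam <- rep(chromInv$lambda[hit], 2L)
          enr <- IRanges::restrict(
            IRanges::IRanges(bp - enrichFlank, bp + enrichFlank - 1),
            start = 1L, end = L)
          S4Vectors::mcols(enr)$lambda <- lam
        }
      }
      segs <- if (length(enr)) {
        red <- IRanges::reduce(enr)
        gaps <- IRanges::setdiff(IRanges::IRanges(1L, L), red)
        lamSeg <- vapply(seq_along(red), function(k) {
          ov <- IRanges::overlapsAny(enr, red[k])
          max(S4Vectors::mcols(enr)$lambda[ov])
        }, 0)
        rbind(data.frame(start = IRanges::start(gaps),
                         end = IRanges::end(gaps), mult = 1),
              data.frame(start = IRanges::start(red),
                         end = IRanges::end(red), mult = lamSeg))
      } else data.frame(start = 1L, end = L, mult = 1)
      for (sg in seq_len(nrow(segs))) {
        segLen <- segs$end[sg] - segs$start[sg] + 1
        lam <- r * segs$mult[sg] * segLen
        if (lam <= 0) next
        nIns <- stats::rpois(1L, lam)
        if (nIns == 0L) next
        starts <- segs$start[sg] + floor(stats::runif(nIns) * segLen)
        widths <- floor(stats::runif(nIns, fam$minLen[fi],
                                     fam$maxLen[fi] + 1))
        ends <- pmin(starts + widths - 1, L)
        pieces[[length(pieces) + 1L]] <- data.frame(
          start = starts, end = ends, family = fam$family[fi],
          class = fam$class[fi], stringsAsFactors = FALSE)
      }
    }
    out[[ci]] <- if (length(pieces)) {
      d <- do.call(rbind, pieces)
      d$chrom <- ch
      d
    } else NULL
  }
  d <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  repeats <- if (is.null(d) || nrow(d) == 0L) {
    g <- GenomicRanges::GRanges(seqinfo = si)
    S4Vectors::mcols(g)$family <- character(0)
    S4Vectors::mcols(g)$repClass <- character(0)
    g
  } else {
    d <- d[order(match(d$chrom, chroms), d$start), , drop = FALSE]
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end),
                           family = d$family, repClass = d$class,
                           seqinfo = si)
  }
  invGr <- if (nrow(inv)) GenomicRanges::GRanges(
    inv$chrom, IRanges::IRanges(inv$start, inv$end),
    lambda = inv$lambda, name = paste0("inv", seq_len(nrow(inv))),
    seqinfo = si) else GenomicRanges::GRanges(seqinfo = si)
  list(genome = si, repeats = repeats,
       truth = list(inversions = invGr, enrichFlank = enrichFlank))
}

#' Simulate a rearranged gene-order anchor table
#'
#' Genes are laid down uniformly on the ancestral genome at the configured
#' density; the derived genome is obtained by concatenating fused chromosome
#' pairs, reversing the gene runs contained in each planted inversion, and
#' moving the gene runs of each translocated segment to its destination. Each
#' gene yields one ortholog anchor pair (derived/query vs ancestral/
#' reference).
#'
#' @param config a [SimConfig].
#' @return list with \code{anchors} (data.frame gene/qchrom/qstart/qend/
#'   rchrom/rstart/rend) and \code{truth} (fusion partners and junction
#'   coordinates, inversion intervals, translocated destination spans, and
#'   the derived genome Seqinfo).
#' @export
simulateAnchorTable <- function(config) {
  .validateSimConfig(config)
  if (config@genesPerMb <= 0) stop("gene density must be > 0")
  set.seed(.substream(config@seed, 2L))
  chroms <- config@chromosomes
  geneLen <- 1000L
  genes <- list()
  for (i in seq_len(nrow(chroms))) {
    L <- chroms$length[i]
    n <- max(2L, round(config@genesPerMb * L / 1e6))
    starts <- sort(floor(stats::runif(n, 1, L - geneLen)))
    genes[[i]] <- data.frame(
      gene = sprintf("%s_g%04d", chroms$name[i], seq_len(n)),
      rchrom = chroms$name[i], rstart = starts, rend = starts + geneLen - 1L,
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  # derived coordinates start as a copy of the ancestral layout
  genes$qchrom <- genes$rchrom
  genes$qstart <- genes$rstart
  genes$qend <- genes$rend
  lens <- stats::setNames(as.numeric(chroms$length),
                          as.character(chroms$name))
  # fusions: concatenate B after A
  fus <- config@fusions
  fusTruth <- list()
  for (i in seq_len(nrow(fus))) {
    a <- fus$chromA[i]; b <- fus$chromB[i]
    newName <- paste0(a, "_", b)
    offB <- lens[[a]]
    selA <- genes$qchrom == a
    selB <- genes$qchrom == b
    genes$qchrom[selA | selB] <- newName
    genes$qstart[selB] <- genes$qstart[selB] + offB
    genes$qend[selB] <- genes$qend[selB] + offB
    lens[[newName]] <- lens[[a]] + lens[[b]]
    lens <- lens[setdiff(names(lens), c(a, b))]
    fusTruth[[i]] <- data.frame(qchrom = newName, partnerA = a,
                                partnerB = b, junction = offB,
                                stringsAsFactors = FALSE)
  }
  # inversions: reflect genes fully contained in the interval
  inv <- config@inversions
  for (i in seq_len(nrow(inv))) {
    sel <- genes$qchrom == inv$chrom[i] & genes$qstart >= inv$start[i] &
      genes$qend <= inv$end[i]
    ns <- inv$start[i] + inv$end[i] - genes$qend[sel]
    ne <- inv$start[i] + inv$end[i] - genes$qstart[sel]
    genes$qstart[sel] <- ns
    genes$qend[sel] <- ne
  }
  # translocations: move contained genes, shift the rest
  trl <- config@translocations
  trlTruth <- list()
  for (i in seq_len(nrow(trl))) {
    segLen <- trl$srcEnd[i] - trl$srcStart[i] + 1
    src <- trl$srcChrom[i]; dst <- trl$destChrom[i]
    destPos <- trl$destPos[i]
    if (src == dst && destPos > trl$srcEnd[i]) destPos <- destPos - segLen
    moved <- genes$qchrom == src & genes$qstart >= trl$srcStart[i] &
      genes$qend <= trl$srcEnd[i]
    after <- genes$qchrom == src & genes$qstart > trl$srcEnd[i]
    genes$qstart[after] <- genes$qstart[after] - segLen
    genes$qend[after] <- genes$qend[after] - segLen
    lens[[src]] <- lens[[src]] - segLen
    shiftDst <- genes$qchrom == dst & !moved & genes$qstart >= destPos
    genes$qstart[shiftDst] <- genes$qstart[shiftDst] + segLen
    genes$qend[shiftDst] <- genes$qend[shiftDst] + segLen
    off <- destPos - trl$srcStart[i]
    genes$qstart[moved] <- genes$qstart[moved] + off
    genes$qend[moved] <- genes$qend[moved] + off
    genes$qchrom[moved] <- dst
    lens[[dst]] <- lens[[dst]] + segLen
    trlTruth[[i]] <- data.frame(
      qchrom = dst, source = src, destStart = destPos,
      destEnd = destPos + segLen - 1, nGenes = sum(moved),
      stringsAsFactors = FALSE)
  }
  anchors <- genes[order(genes$qchrom, genes$qstart),
                   c("gene", "qchrom", "qstart", "qend",
                     "rchrom", "rstart", "rend")]
  rownames(anchors) <- NULL
  list(anchors = anchors,
       truth = list(
         fusions = if (length(fusTruth)) do.call(rbind, fusTruth) else NULL,
         inversions = inv,
         translocations = if (length(trlTruth))
           do.call(rbind, trlTruth) else NULL,
         genome = .asSeqinfo(lens)))
}

#' Simulate two-population genotypes with conserved tracts
#'
#' Sites 1..\code{nSites} on a single chromosome are drawn independently.
#' With probability \code{d} (or the reduced tract rate inside a conserved
#' tract) a site is a fixed difference: population X carries the reference,
#' population Y the alternate allele. Otherwise the site may be polymorphic
#' within each population: a single random haplotype carries a derived
#' allele, with per-site probabilities calibrated so the expected
#' window-mean nucleotide diversity equals \code{piX} (resp. \code{piY})
#' exactly. Invariant sites are retained.
#'
#' @param config a [SimConfig] (parameters from its \code{popgen} block).
#' @param chromName chromosome name for the site coordinates.
#' @return list with \code{genotypes} (a [GenotypeTable]; populations
#'   \code{popX}, \code{popY}, samples \code{X1..}, \code{Y1..}),
#'   \code{populations} (data.frame sample/population) and \code{truth}
#'   (generating rates and conserved tracts).
#' @export
simulateGenotypes <- function(config, chromName = "sim1") {
  pg <- config@popgen
  nH <- as.integer(pg$nHapPerPop)
  nS <- as.integer(pg$nSites)
  if (nH %% 2L != 0L)
    stop("nHapPerPop must be even (two haplotypes per diploid sample)")
  if (nS <= 0) stop("nSites must be > 0")
  if (pg$d < 0 || pg$d > 1) stop("d must lie in [0, 1]")
  if (pg$piX < 0 || pg$piY < 0) stop("diversity rates must be >= 0")
  set.seed(.substream(config@seed, 3L))
  dSite <- rep(pg$d, nS)
  tr <- pg$conservedTracts
  for (i in seq_len(NROW(tr))) {
    sel <- seq.int(max(1L, tr$start[i]), min(nS, tr$end[i]))
    dSite[sel] <- tr$d[i]
  }
  fixed <- stats::runif(nS) < dSite
  # singleton polymorphism probabilities giving E[pi-hat] = piX / piY
  sX <- pmin(1, pg$piX * nH / 2 / pmax(1e-12, 1 - dSite))
  sY <- pmin(1, pg$piY * nH / 2 / pmax(1e-12, 1 - dSite))
  polyX <- !fixed & stats::runif(nS) < sX
  polyY <- !fixed & stats::runif(nS) < sY
  alleles <- matrix(0L, nrow = nS, ncol = 2L * nH)
  alleles[fixed, (nH + 1L):(2L * nH)] <- 1L
  carrierX <- sample.int(nH, nS, replace = TRUE)
  carrierY <- nH + sample.int(nH, nS, replace = TRUE)
  iX <- which(polyX)
  alleles[cbind(iX, carrierX[iX])] <- 1L
  iY <- which(polyY)
  alleles[cbind(iY, carrierY[iY])] <- 1L - alleles[cbind(iY, carrierY[iY])]
  samples <- c(paste0("X", seq_len(ceiling(nH / 2))),
               paste0("Y", seq_len(ceiling(nH / 2))))
  sampleMap <- data.frame(
    haplotype = paste0(rep(samples, each = 2L), c("_1", "_2")),
    sample = rep(samples, each = 2L), stringsAsFactors = FALSE)
  colnames(alleles) <- sampleMap$haplotype
  gt <- methods::new("GenotypeTable", chrom = rep(chromName, nS),
                     pos = seq_len(nS), alleles = alleles,
                     sampleMap = sampleMap)
  pops <- data.frame(sample = samples,
                     population = rep(c("popX", "popY"),
                                      each = ceiling(nH / 2)),
                     stringsAsFactors = FALSE)
  list(genotypes = gt, populations = pops,
       truth = list(d = pg$d, piX = pg$piX, piY = pg$piY,
                    conservedTracts = tr,
                    # expected DXY of the generative model
                    expectedDxy = pg$d + (pg$piX + pg$piY) / 2))
}

#' Simulate traits under Brownian motion on a tree
#'
#' Residuals are drawn from a multivariate normal with covariance
#' \eqn{\sigma^2 C}, \eqn{C_{ij}} the shared root-to-tip path length; the
#' trait is intercept + slope * predictor + residual. With
#' \eqn{\sigma^2 = 0} traits are exactly the linear predictor.
#'
#' @param tree rooted \code{phylo} (or Newick string) with non-negative
#'   branch lengths.
#' @param intercept,slope,sigma2 generating parameters.
#' @param x named numeric predictor covering every tip.
#' @param seed optional integer seed.
#' @return data.frame with columns species, x, trait.
#' @export
simulateBMTraits <- function(tree, intercept, slope, sigma2, x,
                             seed = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  tips <- tree$tip.label
  miss <- setdiff(tips, names(x))
  if (length(miss))
    stop("missing predictor for tips: ", paste(miss, collapse = ", "))
  x <- x[tips]
  n <- length(tips)
  resid <- if (sigma2 > 0) {
    C <- ape::vcv(tree)
    .withSeed(seed, as.numeric(t(chol(C)) %*% stats::rnorm(n)) *
                sqrt(sigma2))
  } else rep(0, n)
  data.frame(species = tips, x = as.numeric(x),
             trait = intercept + slope * as.numeric(x) + resid,
             stringsAsFactors = FALSE)
}
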