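#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom S4Vectors DataFrame
NULL

# Recognized RepeatMasker-style repeat classes (prefix before "/").
.REPEAT_CLASSES <- c("DNA", "LINE", "SINE", "LTR", "RC", "Unknown",
                     "Simple_repeat", "Low_complexity", "Satellite")

#' Category scheme mapping repeat classes to density categories
#'
#' A \code{CategoryScheme} groups repeat classes into the categories used by
#' the density and enrichment modules. The default scheme distinguishes
#' retroelements (LINE, SINE, LTR), DNA elements (DNA, RC), total interspersed
#' repeats ("all TEs": retroelements, DNA elements and Unknown), and simple
#' tandem repeats (Simple_repeat, Low_complexity, Satellite). Unknown-class
#' repeats count toward "all TEs" but neither subcategory.
#'
#' @slot categories named list mapping category name to a character vector of
#'   repeat classes.
#' @export
setClass("CategoryScheme", representation(categories = "list"),
         validity = function(object) {
  cats <- object@categories
  if (is.null(names(cats)) || any(!nzchar(names(cats))))
    return("categories must be a named list")
  bad <- setdiff(unlist(cats), .REPEAT_CLASSES)
  if (length(bad))
    return(paste0("unknown repeat classes: ", paste(bad, collapse = ", ")))
  if (all(c("all_te", "dna", "retro") %in% names(cats))) {
    if (!all(c(cats$dna, cats$retro) %in% cats$all_te))
      return("'all_te' must contain every class of 'dna' and 'retro'")
  }
  TRUE
})

#' Configuration of a synthetic comparative-genomics study
#'
#' Bundles every parameter of the synthetic-data generator: an ancestral
#' (reference) chromosome set, transposable-element families with per-bp
#' insertion rates, planted inversions with optional breakpoint enrichment,
#' chromosomal fusions and translocations, gene density for anchor tables,
#' two-population genotype parameters, and Brownian-motion trait parameters.
#' Build with [simConfig()].
#'
#' @slot seed integer master seed; all generator output is a deterministic
#'   function of it.
#' @slot chromosomes data.frame with columns \code{name}, \code{length} (bp)
#'   describing the ancestral genome.
#' @slot teFamilies data.frame with columns \code{family}, \code{class},
#'   \code{rate} (insertions per bp), \code{minLen}, \code{maxLen}.
#' @slot inversions data.frame with columns \code{chrom} (derived-genome
#'   chromosome), \code{start}, \code{end}, \code{lambda} (breakpoint
#'   enrichment factor, 1 = none) and \code{families} (comma-separated
#'   enriched family names, "" = all).
#' @slot fusions data.frame with columns \code{chromA}, \code{chromB}:
#'   ancestral chromosome pairs concatenated (in that order) in the derived
#'   genome.
#' @slot translocations data.frame with columns \code{srcChrom},
#'   \code{srcStart}, \code{srcEnd}, \code{destChrom}, \code{destPos}
#'   (derived-genome coordinates).
#' @slot genesPerMb numeric gene density for the anchor table.
#' @slot popgen list with \code{nHapPerPop}, \code{nSites}, \code{d}
#'   (between-population fixed-difference rate), \code{piX}, \code{piY}
#'   (within-population diversity rates) and \code{conservedTracts}
#'   (data.frame start/end/d with the reduced rate inside each tract).
#' @slot bm list with \code{tree} (phylo or Newick string or NULL),
#'   \code{intercept}, \code{slope}, \code{sigma2}.
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  chromosomes = "data.frame",
  teFamilies = "data.frame",
  inversions = "data.frame",
  fusions = "data.frame",
  translocations = "data.frame",
  genesPerMb = "numeric",
  popgen = "list",
  bm = "list"
))

#' Haplotype-level genotype table with invariant sites
#'
#' Sites by haplotypes allele matrix (0 = reference, 1 = alternate, NA =
#' missing), with chromosome and position per site. Invariant sites are
#' retained; [isVariantSite()] flags the polymorphic ones. Haplotypes are
#' grouped into samples via \code{sampleMap} (two haplotypes per diploid
#' individual when written to or read from VCF).
#'
#' @slot chrom character chromosome per site.
#' @slot pos integer 1-based position per site.
#' @slot alleles integer matrix, sites x haplotypes.
#' @slot sampleMap data.frame with columns \code{haplotype}, \code{sample}.
#' @export
setClass("GenotypeTable", representation(
  chrom = "character",
  pos = "integer",
  alleles = "matrix",
  sampleMap = "data.frame"
), validity = function(object) {
  n <- length(object@pos)
  if (length(object@chrom) != n) return("chrom and pos lengths differ")
  if (nrow(object@alleles) != n) return("alleles must have one row per site")
  if (nrow(object@sampleMap) != ncol(object@alleles))
    return("sampleMap must have one row per haplotype column")
  ok <- object@alleles %in% c(0L, 1L, NA)
  if (!all(ok)) return("alleles must be 0, 1 or NA")
  TRUE
})

#' Per-window repeat density track
#'
#' Non-overlapping windows tiling each chromosome from its first base, with
#' merged-coverage density (fraction of window bases covered, in [0, 1]) per
#' category of a [CategoryScheme]. The final window of a chromosome may be
#' shorter than the nominal width and its density is a fraction of its true
#' width.
#'
#' @slot windows GRanges of the windows, with one density metadata column per
#'   category.
#' @slot windowSize integer nominal window width in bp.
#' @slot scheme the CategoryScheme used.
#' @export
setClass("WindowDensityTrack", representation(
  windows = "GRanges",
  windowSize = "integer",
  scheme = "CategoryScheme"
), validity = function(object) {
  d <- S4Vectors::mcols(object@windows)
  if (ncol(d) == 0L) return("no density columns")
  v <- unlist(lapply(seq_len(ncol(d)), function(i) d[[i]]), use.names = FALSE)
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    return("densities must lie in [0, 1]")
  TRUE
})

#' Result of the breakpoint TE-enrichment permutation test
#'
#' Observed statistic is the median repeat density over the pooled subwindows
#' of the two breakpoint regions of one inversion; the null distribution is
#' the same statistic on randomly placed non-breakpoint region pairs from the
#' same chromosome. The significance flag follows the 95th-percentile rule
#' (observed strictly greater); the add-one empirical p-value is reported
#' alongside and can disagree with the flag near the boundary, in which case
#' the flag is authoritative.
#'
#' @slot inversionId character identifier of the tested inversion.
#' @slot category density category tested.
#' @slot observed observed pooled-median density.
#' @slot nullStats numeric vector of null statistics.
#' @slot nullPercentile the null reference percentile (e.g. the 95th).
#' @slot pValue add-one empirical p-value, in (0, 1].
#' @slot significant logical, observed > null percentile.
#' @export
setClass("PermutationResult", representation(
  inversionId = "character",
  category = "character",
  observed = "numeric",
  nullStats = "numeric",
  nullPercentile = "numeric",
  pValue = "numeric",
  significant = "logical"
))

#' Collinear synteny blocks chained from gene-order anchors
#'
#' @slot anchors data.frame of the input anchors with dense per-chromosome
#'   ranks (\code{qrank}, \code{rrank}) and the block assignment
#'   (\code{block}, NA when unchained).
#' @slot blocks data.frame with one row per block: query and reference spans,
#'   anchor count and orientation ("forward"/"reverse").
#' @slot params list of the chaining parameters used.
#' @export
setClass("SyntenyBlocks", representation(
  anchors = "data.frame",
  blocks = "data.frame",
  params = "list"
))

#' Brownian-motion phylogenetic regression fit
#'
#' Closed-form generalized least squares fit of \code{y ~ x} with residual
#' covariance proportional to the Brownian-motion phylogenetic covariance
#' matrix (shared root-to-tip path lengths).
#'
#' @slot coefficients named numeric, intercept and slope.
#' @slot se standard errors of the coefficients.
#' @slot tValue t statistics.
#' @slot df residual degrees of freedom (n - 2).
#' @slot pValue two-sided p-values from the t distribution.
#' @slot pAdjusted optional Bonferroni-adjusted slope p-value (NA until set).
#' @slot sigma2 profiled Brownian-motion rate estimate.
#' @slot n number of tips used.
#' @export
setClass("PglsResult", representation(
  coefficients = "numeric",
  se = "numeric",
  tValue = "numeric",
  df = "numeric",
  pValue = "numeric",
  pAdjusted = "numeric",
  sigma2 = "numeric",
  n = "integer"
))
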