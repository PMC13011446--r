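#' @include AllClasses.R
NULL

#' Accessors for karyoshift classes
#'
#' Small accessor generics: \code{densityWindows()} returns the window GRanges
#' of a track (with density metadata columns), \code{densityMatrix()} the
#' densities as a plain matrix, \code{windowSize()} the nominal window width,
#' \code{categoryClasses()} the classes of one category of a scheme,
#' \code{syntenyAnchors()}/\code{syntenyBlockTable()} the components of a
#' [SyntenyBlocks] object, and \code{isVariantSite()}/\code{alleleCounts()}
#' genotype-table summaries.
#'
#' @param x object.
#' @param ... further arguments for methods.
#' @return See each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("densityWindows", function(x) standardGeneric("densityWindows"))

#' @rdname accessors
#' @export
setGeneric("densityMatrix", function(x) standardGeneric("densityMatrix"))

#' @rdname accessors
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))

#' @rdname accessors
#' @export
setGeneric("categoryClasses", function(x, ...) standardGeneric("categoryClasses"))

#' @rdname accessors
#' @export
setGeneric("syntenyAnchors", function(x) standardGeneric("syntenyAnchors"))

#' @rdname accessors
#' @export
setGeneric("syntenyBlockTable", function(x) standardGeneric("syntenyBlockTable"))

#' @rdname accessors
#' @export
setGeneric("isVariantSite", function(x) standardGeneric("isVariantSite"))

#' @rdname accessors
#' @param haplotypes optional haplotype column names or indices to restrict to.
#' @export
setGeneric("alleleCounts", function(x, haplotypes = NULL)
  standardGeneric("alleleCounts"))

#' @rdname accessors
#' @export
setMethod("densityWindows", "WindowDensityTrack", function(x) x@windows)

#' @rdname accessors
#' @export
setMethod("densityMatrix", "WindowDensityTrack", function(x)
  as.matrix(as.data.frame(S4Vectors::mcols(x@windows))))

#' @rdname accessors
#' @export
setMethod("windowSize", "WindowDensityTrack", function(x) x@windowSize)

#' @rdname accessors
#' @param x a CategoryScheme.
#' @param category category name; omit to get the full named list.
#' @export
setMethod("categoryClasses", "CategoryScheme", function(x, category) {
  if (missing(category)) return(x@categories)
  if (!category %in% names(x@categories))
    stop("unknown category '", category, "'; available: ",
         paste(names(x@categories), collapse = ", "))
  x@categories[[category]]
})

#' @rdname accessors
#' @export
setMethod("syntenyAnchors", "SyntenyBlocks", function(x) x@anchors)

#' @rdname accessors
#' @export
setMethod("syntenyBlockTable", "SyntenyBlocks", function(x) x@blocks)

#' @rdname accessors
#' @export
setMethod("isVariantSite", "GenotypeTable", function(x) {
  a <- x@alleles
  n1 <- rowSums(a == 0L, na.rm = TRUE)
  n2 <- rowSums(a == 1L, na.rm = TRUE)
  n1 > 0L & n2 > 0L
})

#' @rdname accessors
#' @export
setMethod("alleleCounts", "GenotypeTable", function(x, haplotypes = NULL) {
  a <- x@alleles
  if (!is.null(haplotypes)) {
    if (is.character(haplotypes)) {
      miss <- setdiff(haplotypes, colnames(a))
      if (length(miss))
        stop("unknown haplotypes: ", paste(miss, collapse = ", "))
    }
    a <- a[, haplotypes, drop = FALSE]
  }
  alt <- rowSums(a == 1L, na.rm = TRUE)
  tot <- rowSums(!is.na(a))
  cbind(ref = tot - alt, alt = alt)
})

setMethod("show", "WindowDensityTrack", function(object) {
  cat("WindowDensityTrack:", length(object@windows), "windows of",
      object@windowSize, "bp over",
      length(GenomeInfoDb::seqlevels(object@windows)), "chromosome(s)\n")
  cat("  categories:",
      paste(colnames(S4Vectors::mcols(object@windows)), collapse = ", "), "\n")
})

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult for", object@inversionId,
      sprintf("[%s]\n", object@category))
  cat(sprintf("  observed = %.4g, null %g replicates, null ref = %.4g\n",
              object@observed, length(object@nullStats),
              object@nullPercentile))
  cat(sprintf("  p = %.4g, significant: %s\n", object@pValue,
              object@significant))
})

setMethod("show", "SyntenyBlocks", function(object) {
  cat("SyntenyBlocks:", nrow(object@blocks), "blocks over",
      sum(!is.na(object@anchors$block)), "of", nrow(object@anchors),
      "anchors (max_gap =", object@params$maxGap,
      ", min_anchors =", object@params$minAnchors, ")\n")
})

setMethod("show", "PglsResult", function(object) {
  cat("Brownian-motion PGLS fit (n =", object@n, ")\n")
  tab <- data.frame(Estimate = object@coefficients, SE = object@se,
                    t = object@tValue, p = object@pValue)
  print(tab)
  cat(sprintf("  sigma2 = %.4g, df = %d", object@sigma2, as.integer(object@df)))
  if (!is.na(object@pAdjusted))
    cat(sprintf(", adjusted slope p = %.4g", object@pAdjusted))
  cat("\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: seed", object@seed, "|", nrow(object@chromosomes),
      "ancestral chromosomes |", nrow(object@teFamilies), "TE families |",
      nrow(object@inversions), "inversions |", nrow(object@fusions),
      "fusions |", nrow(object@translocations), "translocations\n")
})

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", length(object@pos), "sites x",
      ncol(object@alleles), "haplotypes (",
      length(unique(object@sampleMap$sample)), "samples );",
      sum(isVariantSite(object)), "variant sites\n")
})
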