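#' @include AllClasses.R
NULL

#' Default repeat category scheme
#'
#' Retroelements are LINE, SINE and LTR; DNA elements are DNA and RC
#' (rolling-circle); total interspersed repeats ("all_te") add Unknown-class
#' repeats to the union of the two; simple tandem repeats collect
#' Simple_repeat, Low_complexity and Satellite.
#'
#' @return A [CategoryScheme].
#' @examples
#' categoryClasses(defaultCategoryScheme(), "dna")
#' @export
defaultCategoryScheme <- function() {
  methods::new("CategoryScheme", categories = list(
    all_te = c("DNA", "RC", "LINE", "SINE", "LTR", "Unknown"),
    dna    = c("DNA", "RC"),
    retro  = c("LINE", "SINE", "LTR"),
    simple = c("Simple_repeat", "Low_complexity", "Satellite")
  ))
}

#' Build a custom category scheme
#'
#' @param categories named list mapping category names to repeat classes.
#' @return A [CategoryScheme].
#' @export
categoryScheme <- function(categories) {
  methods::new("CategoryScheme", categories = categories)
}

#' Derive the repeat class from a family string
#'
#' The class is the family prefix before "/" (e.g. "DNA/MITE-224" is class
#' "DNA"). Families whose prefix is not a recognized class map to "Unknown"
#' with a warning.
#'
#' @param family character vector of family names.
#' @return character vector of classes.
#' @examples
#' repeatClassOf(c("DNA/MITE-224", "LINE/L2", "Simple_repeat"))
#' @export
repeatClassOf <- function(family) {
  cls <- sub("/.*$", "", family)
  bad <- !(cls %in% .REPEAT_CLASSES)
  if (any(bad)) {
    warning("unrecognized repeat class(es) mapped to Unknown: ",
            paste(unique(cls[bad]), collapse = ", "))
    cls[bad] <- "Unknown"
  }
  cls
}

#' Read a genome index (chromosome name/length table)
#'
#' @param path TSV with columns \code{name} and \code{length} (header
#'   optional).
#' @return A \code{Seqinfo}.
#' @export
readGenomeIndex <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("name", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = hasHeader, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!hasHeader) names(df)[1:2] <- c("name", "length")
  .asSeqinfo(df)
}

#' Write a genome index
#'
#' @param genome Seqinfo or named numeric of chromosome lengths.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeGenomeIndex <- function(genome, path) {
  si <- .asSeqinfo(genome)
  df <- data.frame(name = GenomeInfoDb::seqnames(si),
                   length = GenomeInfoDb::seqlengths(si))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a repeat annotation (RepeatMasker .out or BED)
#'
#' RepeatMasker \code{.out} files are whitespace-delimited with a three-line
#' header and 1-based inclusive coordinates; the repeat class/family column
#' supplies both family and class. The BED dialect is BED6 with the family in
#' the name field and, optionally, the class in a seventh column (derived from
#' the family prefix when absent). BED intervals (0-based half-open) are
#' converted to the 1-based closed GRanges convention at this boundary.
#'
#' @param path input file.
#' @param format "auto" (by extension), "rm_out" or "bed".
#' @param genome optional Seqinfo; when given, features are checked against it
#'   and the returned GRanges carries its seqlengths.
#' @return GRanges with metadata columns \code{family} and \code{repClass}.
#' @export
readRepeatAnnotation <- function(path, format = c("auto", "rm_out", "bed"),
                                 genome = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.out$", path)) "rm_out" else "bed"
  if (format == "rm_out") {
    lines <- readLines(path)
    # header: two column-name lines plus a blank line
    body <- lines[-seq_len(min(3L, length(lines)))]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0L) {
      gr <- GenomicRanges::GRanges()
      S4Vectors::mcols(gr)$family <- character(0)
      S4Vectors::mcols(gr)$repClass <- character(0)
      return(gr)
    }
    fields <- strsplit(trimws(body), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 11L))
      stop("malformed RepeatMasker .out line ",
           which(nf < 11L)[1L] + 3L, " in ", path)
    chrom <- vapply(fields, `[`, "", 5L)
    start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 6L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 7L)))
    strand <- vapply(fields, `[`, "", 9L)
    strand <- ifelse(strand == "C", "-", ifelse(strand == "+", "+", "*"))
    family <- vapply(fields, `[`, "", 11L)
    if (anyNA(start) || anyNA(end))
      stop("malformed coordinates at RepeatMasker .out line ",
           which(is.na(start) | is.na(end))[1L] + 3L, " in ", path)
    repClass <- repeatClassOf(family)
  } else {
    df <- tryCatch(
      utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                        col.names = paste0("V", 1:7), fill = TRUE),
      error = function(e) stop("cannot parse BED file ", path, ": ",
                               conditionMessage(e)))
    if (nrow(df) == 0L || all(!nzchar(df$V1))) {
      gr <- GenomicRanges::GRanges()
      S4Vectors::mcols(gr)$family <- character(0)
      S4Vectors::mcols(gr)$repClass <- character(0)
      return(gr)
    }
    chrom <- df$V1
    start <- as.integer(df$V2) + 1L  # 0-based half-open -> 1-based closed
    end <- as.integer(df$V3)
    family <- if (all(is.na(df$V4))) rep("Unknown", nrow(df)) else df$V4
    strand <- if (all(is.na(df$V6))) rep("*", nrow(df)) else
      ifelse(df$V6 %in% c("+", "-"), df$V6, "*")
    if (anyNA(start) || anyNA(end))
      stop("malformed BED line ", which(is.na(start) | is.na(end))[1L],
           " in ", path)
    cls <- df$V7
    if (!all(is.na(cls)) && any(nzchar(stats::na.omit(cls)))) {
      cls[is.na(cls) | !nzchar(cls)] <- "Unknown"
      bad <- !(cls %in% .REPEAT_CLASSES)
      if (any(bad)) {
        warning("unrecognized repeat class(es) mapped to Unknown: ",
                paste(unique(cls[bad]), collapse = ", "))
        cls[bad] <- "Unknown"
      }
      repClass <- cls
    } else repClass <- repeatClassOf(family)
  }
  if (any(end < start))
    stop("interval with end < start at line ", which(end < start)[1L],
         " in ", path)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand,
    family = family, repClass = repClass)
  if (!is.null(genome)) {
    si <- .asSeqinfo(genome)
    unknown <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                       GenomeInfoDb::seqnames(si))
    if (length(unknown))
      stop("repeat features on chromosome(s) absent from genome index: ",
           paste(unknown, collapse = ", "))
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(si)
    GenomeInfoDb::seqinfo(gr) <- si
  }
  gr
}

#' Write a repeat annotation as BED (family in name, class in column 7)
#'
#' @param repeats GRanges with \code{family} and \code{repClass} metadata.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeRepeatAnnotation <- function(repeats, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(repeats)),
    start = GenomicRanges::start(repeats) - 1L,
    end = GenomicRanges::end(repeats),
    name = repeats$family,
    score = 0L,
    strand = as.character(GenomicRanges::strand(repeats)),
    class = repeats$repClass)
  df$strand[df$strand == "*"] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an interval table (inversions, breakpoints, conserved tracts)
#'
#' BED input is 0-based half-open; the TSV dialect requires columns
#' \code{chrom}, \code{start}, \code{end}, \code{name} and is 0-based
#' half-open unless \code{oneBased = TRUE}.
#'
#' @param path input file.
#' @param format "auto", "bed" or "tsv".
#' @param oneBased logical; TSV coordinates are 1-based inclusive.
#' @return GRanges with a \code{name} metadata column.
#' @export
readIntervals <- function(path, format = c("auto", "bed", "tsv"),
                          oneBased = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path)) "bed" else "tsv"
  if (format == "bed") {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                            col.names = paste0("V", 1:4), fill = TRUE)
    names(df) <- c("chrom", "start", "end", "name")
    df$start <- df$start + 1L
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "name")
    if (!all(need %in% names(df)))
      stop("TSV interval table must have columns: ",
           paste(need, collapse = ", "))
    if (!oneBased) df$start <- df$start + 1L
  }
  if (any(df$end < df$start))
    stop("interval with start >= end at line ",
         which(df$end < df$start)[1L], " in ", path)
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start, df$end),
                         name = as.character(df$name))
}

#' Write an interval table as BED4
#'
#' @param gr GRanges (a \code{name} metadata column is used when present).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeIntervals <- function(gr, path) {
  nm <- if (!is.null(gr$name)) gr$name else
    paste0("iv", seq_along(gr))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr), name = nm)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF (invariant sites retained)
#'
#' Biallelic SNV records (and invariant records with no ALT) become rows of a
#' [GenotypeTable]; multiallelic records are dropped with a message giving the
#' count. Genotypes are split into haplotypes (two per diploid sample);
#' missing alleles (".") become NA.
#'
#' @param path VCF path (plain or gzipped).
#' @return A [GenotypeTable].
#' @export
readGenotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- !is.na(alt) & grepl(",", alt)
  if (any(multi))
    message(sum(multi), " multiallelic site(s) excluded")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)
  n <- nrow(gt)
  hap <- matrix(NA_integer_, nrow = n, ncol = 2L * length(samples))
  for (j in seq_along(samples)) {
    parts <- strsplit(ifelse(is.na(gt[, j]), "./.", gt[, j]), "[/|]")
    a1 <- vapply(parts, function(p) if (length(p) >= 1) p[1] else ".", "")
    a2 <- vapply(parts, function(p) if (length(p) >= 2) p[2] else ".", "")
    hap[, 2L * j - 1L] <- suppressWarnings(as.integer(a1))
    hap[, 2L * j] <- suppressWarnings(as.integer(a2))
  }
  colnames(hap) <- paste0(rep(samples, each = 2L), c("_1", "_2"))
  methods::new("GenotypeTable",
               chrom = as.character(fix[, "CHROM"]),
               pos = as.integer(fix[, "POS"]),
               alleles = hap,
               sampleMap = data.frame(haplotype = colnames(hap),
                                      sample = rep(samples, each = 2L),
                                      stringsAsFactors = FALSE))
}

#' Write a genotype table as a diploid VCF with invariant sites
#'
#' Consecutive haplotype pairs are combined into phased diploid genotypes
#' (\code{a|b}); missing alleles are written as ".". Invariant sites get
#' ALT ".".
#'
#' @param gt a [GenotypeTable].
#' @param path output VCF path.
#' @param genome optional Seqinfo for contig header lines.
#' @return invisibly, the path.
#' @export
writeGenotypesVcf <- function(gt, path, genome = NULL) {
  a <- gt@alleles
  samples <- unique(gt@sampleMap$sample)
  header <- c("##fileformat=VCFv4.2",
              "##source=karyoshift")
  if (!is.null(genome)) {
    si <- .asSeqinfo(genome)
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                GenomeInfoDb::seqnames(si),
                                GenomeInfoDb::seqlengths(si)))
  }
  header <- c(header,
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  variant <- isVariantSite(gt)
  chr <- function(x) ifelse(is.na(x), ".", as.character(x))
  gtCols <- vapply(seq_along(samples), function(j) {
    a1 <- a[, 2L * j - 1L]
    a2 <- a[, 2L * j]
    paste0(chr(a1), "|", chr(a2))
  }, character(nrow(a)))
  if (is.null(dim(gtCols)))
    gtCols <- matrix(gtCols, nrow = nrow(a))
  gtCols[gtCols == ".|."] <- "./."
  lines <- paste(gt@chrom, gt@pos, ".", "A",
                 ifelse(variant, "T", "."), ".", "PASS", ".", "GT",
                 apply(gtCols, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read/write gene-order anchor tables
#'
#' Eight-column TSV: geneA, chromA, startA, endA, geneB, chromB, startB,
#' endB, with A the query genome and B the reference genome, 1-based
#' inclusive coordinates.
#'
#' @param path file path.
#' @return \code{readAnchors}: data.frame with columns \code{gene},
#'   \code{qchrom}, \code{qstart}, \code{qend}, \code{rchrom}, \code{rstart},
#'   \code{rend}.
#' @export
readAnchors <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("geneA", "chromA", "startA", "endA",
            "geneB", "chromB", "startB", "endB")
  if (!all(need %in% names(df)))
    stop("anchor table must have columns: ", paste(need, collapse = ", "))
  data.frame(gene = df$geneA, qchrom = df$chromA, qstart = df$startA,
             qend = df$endA, rchrom = df$chromB, rstart = df$startB,
             rend = df$endB, stringsAsFactors = FALSE)
}

#' @rdname readAnchors
#' @param anchors data.frame as returned by [readAnchors()] or
#'   [simulateAnchorTable()].
#' @export
writeAnchors <- function(anchors, path) {
  df <- data.frame(geneA = anchors$gene, chromA = anchors$qchrom,
                   startA = anchors$qstart, endA = anchors$qend,
                   geneB = anchors$gene, chromB = anchors$rchrom,
                   startB = anchors$rstart, endB = anchors$rend)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write species trait tables
#'
#' @param path TSV with a \code{species} column plus numeric trait columns.
#' @return \code{readTraits}: data.frame.
#' @export
readTraits <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname readTraits
#' @param traits data.frame with a \code{species} column.
#' @export
writeTraits <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
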