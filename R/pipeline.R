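#' @include simdata.R density.R enrichment.R synteny.R popgen.R phylotrait.R
NULL

# Build a SimConfig from the plain-list `simulate` block of a run config.
.configFromList <- function(sim, seed) {
  args <- list(seed = seed)
  if (!is.null(sim$chromosomes))
    args$chromosomes <- as.data.frame(do.call(rbind.data.frame,
                                              sim$chromosomes))
  for (f in c("teFamilies", "inversions", "fusions", "translocations")) {
    if (!is.null(sim[[f]]))
      args[[f]] <- as.data.frame(do.call(rbind.data.frame, sim[[f]]))
  }
  if (!is.null(sim$genesPerMb)) args$genesPerMb <- sim$genesPerMb
  if (!is.null(sim$popgen)) args$popgen <- sim$popgen
  if (!is.null(sim$bm)) args$bm <- sim$bm
  do.call(simConfig, args)
}

#' Run the analysis stages end-to-end on simulated or supplied inputs
#'
#' Executes the enabled stages in dependency order — simulate, density (with
#' peak calls), breakpoint enrichment, synteny (chaining plus fusion and
#' translocation calls), popgen (pi, DXY, FST and conserved tracts), and the
#' Brownian-motion trait regression — writing stage outputs under
#' \code{outdir} and returning a manifest that records every parameter, the
#' seed, and an md5 checksum of every written file. A fixed seed makes the
#' whole run (and the manifest, timestamp aside) reproducible.
#'
#' @param config either a named list or a YAML file path. Top-level fields:
#'   \code{seed}; \code{simulate} (a [simConfig()] argument block) or
#'   explicit input paths (\code{repeats}, \code{genomeIndex},
#'   \code{inversions}, \code{anchors}, \code{vcf}, \code{populations},
#'   \code{tree}, \code{traits}); \code{stages} (character vector among
#'   "simulate", "density", "enrichment", "synteny", "popgen", "pgls");
#'   per-stage parameter blocks (\code{density}: w; \code{enrichment}:
#'   flank, regionLen, n, percentile, category; \code{synteny}: maxGap,
#'   minAnchors; \code{popgen}: w, fstThreshold; \code{pgls}: response,
#'   predictor columns of the trait table).
#' @param outdir output directory (created if needed).
#' @return the manifest, invisibly also written to
#'   \code{file.path(outdir, "manifest.json")}.
#' @export
runPipeline <- function(config, outdir = tempfile("karyoshift_run")) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  stages <- config$stages
  if (is.null(stages))
    stages <- c("simulate", "density", "enrichment", "synteny", "popgen",
                "pgls")
  manifest <- list(seed = seed, stages = stages,
                   parameters = config[setdiff(names(config),
                                               c("stages", "seed"))],
                   outputs = list(), results = list(),
                   package_version = as.character(
                     utils::packageVersion("karyoshift")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  record <- function(name, path) {
    manifest$outputs[[name]] <<- list(
      path = path, md5 = unname(tools::md5sum(path)))
  }
  land <- anch <- geno <- NULL
  repeats <- genome <- inversions <- NULL

  if ("simulate" %in% stages) {
    if (is.null(config$simulate))
      stop("stage 'simulate' enabled but no simulate block in config")
    simcfg <- .configFromList(config$simulate, seed)
    land <- simulateLandscape(simcfg)
    anch <- simulateAnchorTable(simcfg)
    geno <- simulateGenotypes(simcfg)
    repeats <- land$repeats
    genome <- land$genome
    inversions <- land$truth$inversions
    writeGenomeIndex(genome, file.path(outdir, "genome.tsv"))
    record("genome", file.path(outdir, "genome.tsv"))
    writeRepeatAnnotation(repeats, file.path(outdir, "repeats.bed"))
    record("repeats", file.path(outdir, "repeats.bed"))
    writeAnchors(anch$anchors, file.path(outdir, "anchors.tsv"))
    record("anchors", file.path(outdir, "anchors.tsv"))
    if (length(inversions)) {
      writeIntervals(inversions, file.path(outdir, "inversions.bed"))
      record("inversions", file.path(outdir, "inversions.bed"))
    }
    writeGenotypesVcf(geno$genotypes, file.path(outdir, "genotypes.vcf"),
                      genome = NULL)
    record("genotypes", file.path(outdir, "genotypes.vcf"))
  } else {
    if (!is.null(config$repeats) && !is.null(config$genomeIndex)) {
      genome <- readGenomeIndex(config$genomeIndex)
      repeats <- readRepeatAnnotation(config$repeats, genome = genome)
    }
    if (!is.null(config$inversions))
      inversions <- readIntervals(config$inversions)
  }

  if ("density" %in% stages) {
    if (is.null(repeats))
      stop("stage 'density' needs repeats: simulate them or supply ",
           "'repeats' and 'genomeIndex'")
    w <- if (!is.null(config$density$w)) config$density$w else 10000
    track <- computeWindowDensities(repeats, genome, w = w)
    peaks <- suppressWarnings(callPeaks(track))
    utils::write.table(peaks, file.path(outdir, "density_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("density_peaks", file.path(outdir, "density_peaks.tsv"))
    manifest$results$density <- list(
      n_windows = nrow(peaks), n_peaks = sum(peaks$is_peak))
  }

  if ("enrichment" %in% stages) {
    if (is.null(repeats) || is.null(inversions) || length(inversions) == 0L)
      stop("stage 'enrichment' needs repeats and inversions: simulate ",
           "them or supply 'repeats', 'genomeIndex' and 'inversions'")
    ep <- config$enrichment
    enr <- enrichmentTest(
      repeats, inversions, genome,
      flank = if (!is.null(ep$flank)) ep$flank else 50000,
      regionLen = if (!is.null(ep$regionLen)) ep$regionLen else 100000,
      n = if (!is.null(ep$n)) ep$n else 1000,
      percentile = if (!is.null(ep$percentile)) ep$percentile else 95,
      category = if (!is.null(ep$category)) ep$category else "all_te",
      seed = seed)
    rep <- enrichmentReport(enr, adjust = "bonferroni")
    utils::write.table(rep, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("enrichment", file.path(outdir, "enrichment.tsv"))
    manifest$results$enrichment <- list(
      n_tested = nrow(rep), n_significant = sum(rep$significant))
  }

  if ("synteny" %in% stages) {
    anchors <- if (!is.null(anch)) anch$anchors else {
      if (is.null(config$anchors))
        stop("stage 'synteny' needs anchors: simulate them or supply ",
             "'anchors'")
      readAnchors(config$anchors)
    }
    sp <- config$synteny
    sb <- chainBlocks(
      anchors,
      maxGap = if (!is.null(sp$maxGap)) sp$maxGap else 10,
      minAnchors = if (!is.null(sp$minAnchors)) sp$minAnchors else 5)
    fus <- detectFusions(sb)
    trl <- detectTranslocations(sb)
    utils::write.table(syntenyBlockTable(sb),
                       file.path(outdir, "synteny_blocks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("synteny_blocks", file.path(outdir, "synteny_blocks.tsv"))
    utils::write.table(fus, file.path(outdir, "fusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("fusions", file.path(outdir, "fusions.tsv"))
    utils::write.table(trl, file.path(outdir, "translocations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("translocations", file.path(outdir, "translocations.tsv"))
    manifest$results$synteny <- list(
      n_blocks = nrow(syntenyBlockTable(sb)), n_fusions = nrow(fus),
      n_translocations = nrow(trl))
  }

  if ("popgen" %in% stages) {
    if (!is.null(geno)) {
      gt <- geno$genotypes; pops <- geno$populations
    } else {
      if (is.null(config$vcf) || is.null(config$populations))
        stop("stage 'popgen' needs genotypes: simulate them or supply ",
             "'vcf' and 'populations'")
      gt <- readGenotypes(config$vcf)
      pops <- utils::read.table(config$populations, header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
    }
    pp <- config$popgen
    w <- if (!is.null(pp$w)) pp$w else 10000
    popNames <- unique(pops$population)
    pi1 <- windowedPi(gt, popNames[1], pops, w = w)
    pi2 <- windowedPi(gt, popNames[2], pops, w = w)
    dxy <- windowedDxy(gt, popNames[1], popNames[2], pops, w = w)
    fst <- windowedFst(gt, popNames[1], popNames[2], pops, w = w)
    tracts <- scanConservedTracts(
      fst, threshold = if (!is.null(pp$fstThreshold)) pp$fstThreshold
      else 0.5)
    for (nm in c("pi1", "pi2", "dxy", "fst", "tracts")) {
      f <- file.path(outdir, paste0("popgen_", nm, ".tsv"))
      utils::write.table(get(nm), f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record(paste0("popgen_", nm), f)
    }
    manifest$results$popgen <- list(
      mean_pi_1 = mean(pi1$avg_pi, na.rm = TRUE),
      mean_pi_2 = mean(pi2$avg_pi, na.rm = TRUE),
      mean_dxy = mean(dxy$avg_dxy, na.rm = TRUE),
      mean_fst = mean(fst$avg_fst, na.rm = TRUE),
      n_conserved_tracts = nrow(tracts))
  }

  if ("pgls" %in% stages) {
    gp <- config$pgls
    if (!is.null(config$tree) && !is.null(config$traits)) {
      tree <- ape::read.tree(config$tree)
      traits <- readTraits(config$traits)
      resp <- gp$response; pred <- gp$predictor
      y <- stats::setNames(traits[[resp]], traits$species)
      x <- stats::setNames(traits[[pred]], traits$species)
    } else {
      simcfg <- if (!is.null(config$simulate))
        .configFromList(config$simulate, seed) else simConfig(seed = seed)
      bm <- simcfg@bm
      tree <- bm$tree
      if (is.null(tree))
        tree <- .withSeed(.substream(seed, 4L), ape::rcoal(13L))
      if (is.character(tree)) tree <- ape::read.tree(text = tree)
      x <- .withSeed(.substream(seed, 5L),
                     stats::setNames(stats::rnorm(length(tree$tip.label)),
                                     tree$tip.label))
      tt <- simulateBMTraits(tree, bm$intercept, bm$slope, bm$sigma2, x,
                             seed = .substream(seed, 6L))
      y <- stats::setNames(tt$trait, tt$species)
    }
    fit <- pglsBM(tree, y, x)
    manifest$results$pgls <- list(
      slope = unname(fit@coefficients["slope"]),
      se = unname(fit@se["slope"]),
      t = unname(fit@tValue["slope"]),
      p = unname(fit@pValue["slope"]),
      sigma2 = fit@sigma2, n = fit@n)
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
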