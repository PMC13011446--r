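# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL means "use the current stream".
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seed per (stage, index), so partial re-runs of one
# chromosome or stage reproduce the full-run draws. Kept below 2^31 - 1.
.substream <- function(seed, stage, index = 0L) {
  as.integer((as.double(seed) %% 1e6 * 1009 + stage * 9973 + index * 97) %%
               2147483629)
}

# Coerce a genome description (Seqinfo, named numeric, or data.frame with
# name/length columns) to a Seqinfo.
.asSeqinfo <- function(genome) {
  if (methods::is(genome, "Seqinfo")) return(genome)
  if (is.data.frame(genome)) {
    nm <- if ("name" %in% names(genome)) genome$name else genome[[1L]]
    ln <- if ("length" %in% names(genome)) genome$length else genome[[2L]]
    genome <- stats::setNames(as.numeric(ln), as.character(nm))
  }
  if (is.numeric(genome) && !is.null(names(genome))) {
    if (anyDuplicated(names(genome)))
      stop("duplicated chromosome names in genome index")
    if (any(genome <= 0)) stop("chromosome lengths must be > 0")
    return(GenomeInfoDb::Seqinfo(seqnames = names(genome),
                                 seqlengths = as.integer(genome)))
  }
  stop("cannot interpret 'genome' as a genome index (Seqinfo, named numeric, ",
       "or data.frame with name/length)")
}

# Non-overlapping window tiling of [1, len] with width w; the final partial
# window is kept at its true width.
.tileStarts <- function(from, to, w) {
  starts <- seq.int(from, to, by = w)
  data.frame(start = starts, end = pmin(starts + w - 1, to))
}

# Sum of per-base coverage over windows on one chromosome, given a coverage Rle.
.windowCovered <- function(covRle, starts, ends) {
  if (length(starts) == 0L) return(numeric(0))
  as.numeric(sum(IRanges::Views(covRle, start = starts, end = ends)))
}
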