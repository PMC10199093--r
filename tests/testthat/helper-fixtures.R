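## compact pileup builder: one call per (site, sample); bases/offsets/mapqs
## are parallel per-read vectors
tinyPileup <- function(..., sample_id = "S1") {
  rows <- list(...)
  sites <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref,
               sample_id = r$sample %||% sample_id,
               stringsAsFactors = FALSE)))
  obs <- do.call(rbind, lapply(rows, function(r) {
    n <- length(r$bases %||% character())
    if (!n) return(NULL)
    data.frame(chrom = r$chrom, pos = r$pos,
               sample_id = r$sample %||% sample_id,
               base = r$bases,
               offset = r$offsets %||% rep(50L, n),
               mapq = r$mapqs %||% rep(60L, n),
               stringsAsFactors = FALSE)
  }))
  pileupSet(sites, obs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## site row shorthand for tinyPileup: a site with nRef reference reads and
## nAlt alternative reads
siteReads <- function(chrom, pos, ref, alt, nRef, nAlt, offsets = NULL,
                      mapqs = NULL, sample = NULL) {
  bases <- c(rep(ref, nRef), rep(alt, nAlt))
  list(chrom = chrom, pos = pos, ref = ref, bases = bases,
       offsets = offsets %||% rep(50L, nRef + nAlt),
       mapqs = mapqs %||% rep(60L, nRef + nAlt), sample = sample)
}

## random EditingSiteSet for property tests
randomSites <- function(n, seed, chroms = c("chr1", "chr2")) {
  set.seed(seed)
  pos <- sample.int(1e6, n)
  ref <- sample(c("A", "T"), n, replace = TRUE)
  depth <- sample(8:60, n, replace = TRUE)
  alt <- pmin(depth, sample(3:20, n, replace = TRUE))
  editingSiteSet(data.frame(
    chrom = sample(chroms, n, replace = TRUE), pos = pos,
    strand = ifelse(ref == "A", "+", "-"),
    ref = ref, alt = ifelse(ref == "A", "G", "C"),
    depth = depth, altDepth = alt, stringsAsFactors = FALSE))
}

## random KnownSiteDB drawn partly from a site set's keys
randomDb <- function(sites, frac, seed, source = "CUSTOM", tissues = "") {
  set.seed(seed)
  keys <- siteKeys(sites)
  pick <- sample(keys, max(0, round(frac * length(keys))))
  parts <- strsplit(pick, ":", fixed = TRUE)
  knownSiteDB(source, data.frame(
    chrom = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    strand = vapply(parts, `[`, "", 3),
    tissues = tissues, stringsAsFactors = FALSE))
}
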