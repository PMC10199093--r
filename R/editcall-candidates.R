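## Tally a single sample's observations into per-site base counts.
## Returns sites data.frame with depth and A/C/G/T/N counts (N covers the
## site and contributes to depth but can never be the alternative base).
tallySample <- function(pileups, sampleId = NULL) {
  s <- pileups@sites; o <- pileups@obs
  if (!is.null(sampleId)) {
    s <- s[s$sample_id == sampleId, , drop = FALSE]
    o <- o[o$sample_id == sampleId, , drop = FALSE]
  }
  if (length(unique(s$sample_id)) > 1L)
    stop("pileups contain multiple samples; pass sampleId", call. = FALSE)
  key_s <- paste(s$chrom, s$pos, sep = ":")
  if (anyDuplicated(key_s)) {
    keep <- !duplicated(key_s)
    s <- s[keep, , drop = FALSE]; key_s <- key_s[keep]
  }
  cnt <- matrix(0L, nrow = nrow(s), ncol = length(OBS_BASES),
                dimnames = list(NULL, OBS_BASES))
  if (nrow(o)) {
    key_o <- paste(o$chrom, o$pos, sep = ":")
    tb <- table(factor(key_o, levels = key_s),
                factor(o$base, levels = OBS_BASES))
    cnt[] <- as.integer(tb)
  }
  s$depth <- as.integer(rowSums(cnt))
  for (b in OBS_BASES) s[[paste0("n", b)]] <- cnt[, b]
  s
}

## A-to-I alternative base for a genomic reference base (strand-resolved):
## ref A -> alt G on "+", ref T -> alt C on "-"; others are not A-to-I.
aToIStrand <- function(ref) ifelse(ref == "A", "+", ifelse(ref == "T", "-", "*"))

#' Call candidate A-to-I editing sites (matched-organoid cascade entry)
#'
#' Keeps sites whose RNA pileup shows an A>G (plus strand) or T>C (minus
#' strand) change with read depth strictly greater than `minDepthExclusive`
#' and alternative-allele depth strictly greater than `minAltExclusive`
#' (defaults: depth > 7, alt > 2, i.e. depth >= 8 and alt >= 3).
#'
#' @param pileups a [PileupSet-class] from one RNA sample.
#' @param minDepthExclusive exclusive read-depth threshold (default 7).
#' @param minAltExclusive exclusive alt-depth threshold (default 2).
#' @param sampleId sample to tally when `pileups` holds several.
#' @return an [EditingSiteSet-class] of candidates.
#' @export
callCandidatesOrganoid <- function(pileups, minDepthExclusive = 7,
                                   minAltExclusive = 2, sampleId = NULL) {
  t <- tallySample(pileups, sampleId)
  sid <- sampleId %||% (if (nrow(t)) t$sample_id[1] else "")
  if (!nrow(t)) return(editingSiteSet(t, sampleId = sid))
  alt <- ifelse(t$ref == "A", t$nG, ifelse(t$ref == "T", t$nC, NA_integer_))
  keep <- !is.na(alt) & t$depth > minDepthExclusive & alt > minAltExclusive
  d <- t[keep, , drop = FALSE]
  if (!nrow(d)) return(editingSiteSet(d, sampleId = sid))
  editingSiteSet(data.frame(
    chrom = d$chrom, pos = d$pos,
    strand = aToIStrand(d$ref),
    ref = d$ref, alt = ifelse(d$ref == "A", "G", "C"),
    depth = d$depth, altDepth = alt[keep],
    filters = "candidates_organoid",
    stringsAsFactors = FALSE), sampleId = sid)
}

#' Call candidate variant sites de novo (TCGA-style cascade entry)
#'
#' Observations with mapping quality below `minMapq` are discarded before
#' counting (mapq 255 = unavailable is treated as passing, logged once).
#' The alternative is the most frequent non-reference base; sites are kept
#' when the surviving alternative support is at least `minSupport`
#' (inclusive, unlike the strict organoid thresholds).
#'
#' @param pileups a [PileupSet-class] from one sample with mapq recorded.
#' @param minSupport inclusive minimum supporting reads (default 2).
#' @param minMapq minimum Phred mapping quality (default 20).
#' @param aToIOnly restrict to A>G / T>C classes (default FALSE).
#' @param sampleId sample to tally when `pileups` holds several.
#' @return an [EditingSiteSet-class] of candidates.
#' @export
callCandidatesDenovo <- function(pileups, minSupport = 2, minMapq = 20,
                                 aToIOnly = FALSE, sampleId = NULL) {
  o <- pileups@obs
  if (nrow(o) && any(o$mapq == 255L))
    message("mapq 255 (unavailable) observed; treating as passing the mapq filter")
  censored <- pileupSet(pileups@sites,
                        o[o$mapq >= minMapq | o$mapq == 255L, , drop = FALSE])
  t <- tallySample(censored, sampleId)
  sid <- sampleId %||% (if (nrow(t)) t$sample_id[1] else "")
  if (!nrow(t)) return(editingSiteSet(t, sampleId = sid))
  cnt <- as.matrix(t[paste0("n", BASES)])
  colnames(cnt) <- BASES
  cnt[cbind(seq_len(nrow(t)), match(t$ref, BASES))] <- -1L  # exclude ref
  altIdx <- max.col(cnt, ties.method = "first")
  altBase <- BASES[altIdx]
  altDepth <- cnt[cbind(seq_len(nrow(t)), altIdx)]
  keep <- altDepth >= minSupport
  if (aToIOnly)
    keep <- keep & ((t$ref == "A" & altBase == "G") |
                    (t$ref == "T" & altBase == "C"))
  d <- t[keep, , drop = FALSE]
  if (!nrow(d)) return(editingSiteSet(d, sampleId = sid))
  isAI <- (d$ref == "A" & altBase[keep] == "G") |
          (d$ref == "T" & altBase[keep] == "C")
  editingSiteSet(data.frame(
    chrom = d$chrom, pos = d$pos,
    strand = ifelse(isAI, aToIStrand(d$ref), "*"),
    ref = d$ref, alt = altBase[keep],
    depth = d$depth, altDepth = altDepth[keep],
    filters = "candidates_denovo",
    stringsAsFactors = FALSE), sampleId = sid)
}

#' Call DNA variant positions from a matched DNA pileup
#'
#' A DNA site counts as variant when at least `minAlt` reads support any
#' non-reference base; the returned keys feed [subtractDnaVariants()].
#'
#' @param pileups a [PileupSet-class] of DNA (exome) observations.
#' @param minAlt minimum supporting reads for any non-reference base
#'   (default 2, symmetric with the de novo support rule).
#' @param sampleId sample to tally when `pileups` holds several.
#' @return character vector of "chrom:pos" keys.
#' @export
callDnaVariants <- function(pileups, minAlt = 2, sampleId = NULL) {
  t <- tallySample(pileups, sampleId)
  if (!nrow(t)) return(character())
  cnt <- as.matrix(t[paste0("n", BASES)])
  cnt[cbind(seq_len(nrow(t)), match(t$ref, BASES))] <- 0L
  hit <- apply(cnt, 1L, max) >= minAlt
  siteKey(t$chrom[hit], t$pos[hit])
}
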