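#' Per-sample editing levels at a fixed set of sites
#'
#' Computes the editing level (alt fraction in transcript orientation) of
#' each query site in one sample's pileup. A site is measurable only when
#' its read depth passes the depth criterion (`depth > minDepthExclusive`,
#' matching the candidate-calling depth rule); unmeasurable sites get `NA`.
#'
#' @param pileups a [PileupSet-class].
#' @param sites an [EditingSiteSet-class] (typically the union of candidate
#'   sites across samples) or a data.frame with chrom, pos, ref, alt.
#' @param sampleId sample to tally.
#' @param minDepthExclusive exclusive depth threshold for measurability
#'   (default 7).
#' @return data.frame with key, chrom, pos, strand, level, depth, altDepth.
#' @export
levelsAtSites <- function(pileups, sites, sampleId = NULL,
                          minDepthExclusive = 7) {
  if (is(sites, "EditingSiteSet")) {
    st <- siteTable(sites)
  } else st <- sites
  t <- tallySample(pileups, sampleId)
  key_t <- siteKey(t$chrom, t$pos)
  key_q <- siteKey(st$chrom, st$pos)
  idx <- match(key_q, key_t)
  depth <- ifelse(is.na(idx), 0L, t$depth[idx])
  altCol <- paste0("n", st$alt)
  altDepth <- vapply(seq_along(idx), function(i) {
    if (is.na(idx[i])) 0L else as.integer(t[[altCol[i]]][idx[i]])
  }, 0L)
  measurable <- depth > minDepthExclusive
  data.frame(key = siteKey(st$chrom, st$pos,
                           if (is.null(st$strand)) "*" else st$strand),
             chrom = st$chrom, pos = st$pos,
             strand = if (is.null(st$strand)) "*" else st$strand,
             level = ifelse(measurable, altDepth / pmax(depth, 1L), NA_real_),
             depth = depth, altDepth = altDepth,
             stringsAsFactors = FALSE)
}

#' Paired editing-level deltas across parental/resistant lines
#'
#' For each site and each (parental, resistant) pair, computes
#' `delta = level(resistant) - level(parental)`. A site contributes to a
#' pair only when measurable in both members; otherwise that pair's entry
#' is `NA` (non-evaluable), never silently dropped.
#'
#' @param siteTables named list of per-sample level tables from
#'   [levelsAtSites()]; names are sample ids.
#' @param pairs data.frame with columns line_id, parental_id, resistant_id.
#' @return a [DifferentialTable-class].
#' @export
pairDeltas <- function(siteTables, pairs) {
  need <- unique(c(pairs$parental_id, pairs$resistant_id))
  missing <- setdiff(need, names(siteTables))
  if (length(missing))
    stop("pair sample id(s) not found in site tables: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ref <- siteTables[[need[1]]]
  keys <- ref$key
  for (s in need[-1])
    if (!identical(siteTables[[s]]$key, keys))
      stop("site tables must cover the same sites in the same order",
           call. = FALSE)
  np <- nrow(pairs)
  par <- res <- matrix(NA_real_, nrow = length(keys), ncol = np,
                       dimnames = list(keys, pairs$line_id))
  for (j in seq_len(np)) {
    par[, j] <- siteTables[[pairs$parental_id[j]]]$level
    res[, j] <- siteTables[[pairs$resistant_id[j]]]$level
  }
  delta <- res - par
  new("DifferentialTable",
      sites = ref[c("key", "chrom", "pos", "strand")],
      parental = par, resistant = res, delta = delta,
      pairs = as.data.frame(pairs))
}

#' Call hyper-edited sites by the delta-in-multiple-lines rule
#'
#' A site is called hyper-edited when its resistant-minus-parental editing
#' level changes by at least `minDelta` (inclusive, "at least 10\% change")
#' in at least `minLines` of the evaluable pairs. `direction` selects
#' increases (`hyper`, delta >= +minDelta), decreases (`hypo`,
#' delta <= -minDelta), or either (|delta| >= minDelta).
#'
#' @param table a [DifferentialTable-class].
#' @param minDelta absolute editing-fraction change (default 0.10).
#' @param minLines minimum number of pairs meeting the change (default 2).
#' @param direction "hyper" (default), "hypo" or "either".
#' @return character vector of called site keys.
#' @export
callHyperEdited <- function(table, minDelta = 0.10, minLines = 2,
                            direction = c("hyper", "hypo", "either")) {
  direction <- match.arg(direction)
  if (minLines > ncol(table@delta))
    stop("minLines (", minLines, ") exceeds the number of pairs (",
         ncol(table@delta), ")", call. = FALSE)
  d <- table@delta
  pass <- switch(direction,
                 hyper = d >= minDelta,
                 hypo = d <= -minDelta,
                 either = abs(d) >= minDelta)
  pass[is.na(pass)] <- FALSE
  called <- rowSums(pass) >= minLines
  table@sites$key[called]
}

#' Count called sites per transcript region
#'
#' @param sites an [EditingSiteSet-class] annotated by [annotateRegion()].
#' @return named integer vector over all region levels (zeros kept); counts
#'   sum to the number of sites. Unannotated sites count as INTERGENIC with
#'   a warning.
#' @export
summarizeRegions <- function(sites) {
  region <- mcols(sites@gr)$region
  if (is.null(region)) {
    if (nSites(sites))
      warning("sites are unannotated; counting all as INTERGENIC", call. = FALSE)
    region <- rep("INTERGENIC", nSites(sites))
  }
  tab <- table(factor(region, levels = REGION_LEVELS))
  setNames(as.integer(tab), names(tab))
}

#' Group called sites by biological process
#'
#' @param sites an [EditingSiteSet-class] with a `geneName` annotation.
#' @param geneToProcess data.frame with columns gene, process (a gene may
#'   map to several processes and then contributes to each).
#' @param mode "gene" (default; a gene with several called sites counts
#'   once per process) or "site" (each site counts).
#' @return named integer vector of counts per process; genes absent from
#'   the mapping are bucketed as "unannotated".
#' @export
groupByProcess <- function(sites, geneToProcess, mode = c("gene", "site")) {
  mode <- match.arg(mode)
  gene <- mcols(sites@gr)$geneName
  if (is.null(gene)) stop("sites lack gene annotations; run annotateRegion first",
                          call. = FALSE)
  gene[is.na(gene)] <- "<intergenic>"
  units <- if (mode == "gene") unique(gene) else gene
  proc <- lapply(units, function(g) {
    p <- geneToProcess$process[geneToProcess$gene == g]
    if (!length(p)) "unannotated" else unique(p)
  })
  tab <- table(unlist(proc))
  setNames(as.integer(tab), names(tab))
}
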