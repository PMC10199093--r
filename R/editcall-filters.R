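#' Remove RNA sites with variant evidence in matched DNA
#'
#' @param rnaSites an [EditingSiteSet-class].
#' @param dnaVariants character "chrom:pos" keys of DNA variant positions
#'   (see [callDnaVariants()]).
#' @return the surviving [EditingSiteSet-class].
#' @export
subtractDnaVariants <- function(rnaSites, dnaVariants) {
  if (!nSites(rnaSites) || !length(dnaVariants))
    return(subsetSites(rnaSites, rep(TRUE, nSites(rnaSites)), "dna_subtraction"))
  dnaChrom <- sub(":.*$", "", dnaVariants)
  checkChromStyles(as.character(seqnames(rnaSites@gr)), dnaChrom,
                   c("RNA sites", "DNA variants"))
  keep <- !(siteKeys(rnaSites, stranded = FALSE) %in% dnaVariants)
  subsetSites(rnaSites, keep, "dna_subtraction")
}

#' Filter candidates against known editing resources
#'
#' Default (`mode = "literal_and"`): a site is removed iff it is absent
#' from RADAR AND absent from DARNED AND not labeled as edited in `tissue`
#' by the atlas; present in any one resource keeps it.
#' `mode = "any_resource"` is the stricter alternative reading: a site is
#' kept only if present in at least one editing database AND
#' tissue-edited in the atlas.
#'
#' Surviving sites get their resource hits appended to `annotations`.
#'
#' @param sites an [EditingSiteSet-class].
#' @param radar,darned [KnownSiteDB-class] editing databases.
#' @param atlas [KnownSiteDB-class] with tissue labels.
#' @param tissue tissue label to query in the atlas (default "stomach").
#' @param mode "literal_and" (default) or "any_resource".
#' @return the surviving [EditingSiteSet-class].
#' @export
filterKnownResources <- function(sites, radar, darned, atlas,
                                 tissue = "stomach",
                                 mode = c("literal_and", "any_resource")) {
  mode <- match.arg(mode)
  if (nSites(atlas) && !any(nzchar(atlas@sites$tissues)))
    stop("atlas database carries no tissue labels; cannot apply the '",
         tissue, "' tissue rule", call. = FALSE)
  keys <- siteKeys(sites)
  inRadar <- keys %in% siteKeys(radar)
  inDarned <- keys %in% siteKeys(darned)
  inAtlas <- hasTissue(atlas, keys, tissue)
  keep <- if (mode == "literal_and") inRadar | inDarned | inAtlas
          else (inRadar | inDarned) & inAtlas
  out <- subsetSites(sites, keep, paste0("known_resources_", mode))
  if (nSites(out)) {
    tag <- cbind(ifelse(inRadar[keep], "RADAR", NA),
                 ifelse(inDarned[keep], "DARNED", NA),
                 ifelse(inAtlas[keep], paste0("ATLAS:", tissue), NA))
    hits <- apply(tag, 1L, function(x) paste(x[!is.na(x)], collapse = ";"))
    a <- mcols(out@gr)$annotations
    mcols(out@gr)$annotations <-
      ifelse(nzchar(a) & nzchar(hits), paste(a, hits, sep = ";"),
             paste0(a, hits))
  }
  out
}

#' Annotate sites with membership in a known-site database
#'
#' Appends the database source tag to the `annotations` of matching sites;
#' removes nothing.
#'
#' @param sites an [EditingSiteSet-class].
#' @param db a [KnownSiteDB-class].
#' @return the annotated [EditingSiteSet-class].
#' @export
annotateKnown <- function(sites, db) {
  hit <- siteKeys(sites) %in% siteKeys(db)
  if (any(hit)) {
    a <- mcols(sites@gr)$annotations
    mcols(sites@gr)$annotations[hit] <-
      ifelse(nzchar(a[hit]), paste(a[hit], db@source, sep = ";"), db@source)
  }
  sites
}

#' Censor alternative reads near the 5' read end, then re-test support
#'
#' Alternative-base observations whose 1-based read offset is `<= firstN`
#' are discarded (imperfect random-hexamer priming artifact); depths and the
#' editing level are recomputed from the surviving observations and the site
#' is re-tested against `minSupport`.
#'
#' @param sites an [EditingSiteSet-class].
#' @param pileups the [PileupSet-class] the sites were called from (already
#'   mapq-censored in the de novo cascade).
#' @param firstN read-end window to censor (default 6).
#' @param minSupport inclusive minimum surviving alt reads (default 2).
#' @return the surviving, recomputed [EditingSiteSet-class].
#' @export
filterReadPosition <- function(sites, pileups, firstN = 6, minSupport = 2) {
  if (!nSites(sites)) return(subsetSites(sites, logical(), "read_position"))
  o <- pileups@obs
  if (nzchar(sites@sampleId) && any(o$sample_id == sites@sampleId))
    o <- o[o$sample_id == sites@sampleId, , drop = FALSE]
  key_o <- paste(o$chrom, o$pos, sep = ":")
  keys <- siteKeys(sites, stranded = FALSE)
  alt <- mcols(sites@gr)$alt
  idx <- match(key_o, keys)
  rel <- !is.na(idx)
  drop <- rep(FALSE, nrow(o))
  drop[rel] <- o$base[rel] == alt[idx[rel]] & o$offset[rel] <= firstN
  keepObs <- o[!drop, , drop = FALSE]
  key_k <- paste(keepObs$chrom, keepObs$pos, sep = ":")
  depth <- as.integer(table(factor(key_k, levels = keys)))
  isAlt <- keepObs$base == alt[match(key_k, keys)]
  altDepth <- as.integer(table(factor(key_k[isAlt], levels = keys)))
  keep <- altDepth >= minSupport
  out <- subsetSites(sites, keep, "read_position")
  if (nSites(out)) {
    mcols(out@gr)$depth <- depth[keep]
    mcols(out@gr)$altDepth <- altDepth[keep]
    mcols(out@gr)$editingLevel <-
      ifelse(depth[keep] > 0, altDepth[keep] / depth[keep], 0)
  }
  out
}

#' Remove sites reported as SNPs in any provided cohort database
#'
#' @param sites an [EditingSiteSet-class].
#' @param snpDbs a list of [KnownSiteDB-class] (e.g. 1000 Genomes, ESP);
#'   membership is by (chrom, pos), union across databases.
#' @return the surviving [EditingSiteSet-class].
#' @export
filterSnps <- function(sites, snpDbs) {
  if (is(snpDbs, "KnownSiteDB")) snpDbs <- list(snpDbs)
  keys <- siteKeys(sites, stranded = FALSE)
  inSnp <- rep(FALSE, length(keys))
  for (db in snpDbs)
    inSnp <- inSnp | keys %in% siteKeys(db, stranded = FALSE)
  subsetSites(sites, !inSnp, "snp_removal")
}

## run length of the reference homopolymer containing each 1-based position;
## reference is a named DNAStringSet (or a single DNAString used for every chrom)
homopolymerRunAt <- function(reference, chrom, pos) {
  out <- integer(length(pos))
  for (ch in unique(chrom)) {
    seqch <- if (is(reference, "DNAStringSet")) {
      if (!ch %in% names(reference))
        stop("reference lookup failure for site(s) on '", ch, "'", call. = FALSE)
      reference[[ch]]
    } else reference
    r <- S4Vectors::Rle(strsplit(as.character(seqch), "")[[1]])
    idx <- which(chrom == ch)
    if (any(pos[idx] < 1 | pos[idx] > length(seqch)))
      stop("reference lookup failure: position outside reference for site(s) ",
           paste(siteKey(ch, pos[idx][pos[idx] < 1 | pos[idx] > length(seqch)]),
                 collapse = ", "), call. = FALSE)
    rl <- S4Vectors::runLength(r)
    starts <- cumsum(c(1L, rl[-length(rl)]))
    out[idx] <- rl[findInterval(pos[idx], starts)]
  }
  out
}

#' Alu-conditional artifact filter (splice junctions, homopolymers, repeats)
#'
#' Sites inside an Alu interval bypass this filter entirely. A non-Alu site
#' is removed if it lies (a) within `junctionMargin` bases of a splice
#' junction on the intronic side, (b) inside a reference homopolymer run of
#' length `>= homopolymerMinRun` containing the site, or (c) inside a
#' simple-repeat interval.
#'
#' @param sites an [EditingSiteSet-class].
#' @param alu GRanges of Alu elements.
#' @param junctions GRanges of introns; the filter removes sites within
#'   `junctionMargin` bases inside either intron boundary.
#' @param reference named `DNAStringSet` (or single `DNAString`) giving the
#'   genomic sequence for the homopolymer test.
#' @param repeats GRanges of simple repeats.
#' @param junctionMargin bases into the intron from a junction (default 4).
#' @param homopolymerMinRun minimum homopolymer run length (default 5).
#' @return the surviving [EditingSiteSet-class].
#' @export
filterNonAlu <- function(sites, alu, junctions, reference, repeats,
                         junctionMargin = 4, homopolymerMinRun = 5) {
  if (!nSites(sites)) return(subsetSites(sites, logical(), "nonalu_artifacts"))
  gr <- sites@gr
  inAlu <- overlapsAnyUnstranded(gr, alu)
  ## intronic-side junction margins
  jm <- junctionMarginRanges(junctions, junctionMargin)
  nearJunction <- overlapsAnyUnstranded(gr, jm)
  inRepeat <- overlapsAnyUnstranded(gr, repeats)
  run <- homopolymerRunAt(reference, as.character(seqnames(gr)), start(gr))
  inHomopolymer <- run >= homopolymerMinRun
  remove <- !inAlu & (nearJunction | inHomopolymer | inRepeat)
  subsetSites(sites, !remove, "nonalu_artifacts")
}

## first/last `margin` bases inside each intron interval
junctionMarginRanges <- function(junctions, margin) {
  if (!length(junctions)) return(GRanges())
  s <- start(junctions); e <- end(junctions)
  left <- GRanges(seqnames(junctions), IRanges(s, pmin(s + margin - 1L, e)))
  right <- GRanges(seqnames(junctions), IRanges(pmax(e - margin + 1L, s), e))
  c(left, right)
}

overlapsAnyUnstranded <- function(query, subject) {
  if (!length(subject)) return(rep(FALSE, length(query)))
  q <- query; strand(q) <- "*"
  s <- subject; strand(s) <- "*"
  IRanges::overlapsAny(q, s)
}

#' Keep only sites inside the uniquely-alignable mask
#'
#' The mask is a precomputed BED of uniquely alignable regions; sites
#' falling outside it are removed. Applied unconditionally (including to
#' Alu-resident sites) by default; set `aluExempt = TRUE` to scope the
#' filter to non-Alu sites.
#'
#' @param sites an [EditingSiteSet-class].
#' @param uniqueMask GRanges of uniquely alignable regions.
#' @param alu GRanges of Alu elements (only used when `aluExempt = TRUE`).
#' @param aluExempt exempt Alu-resident sites (default FALSE).
#' @return the surviving [EditingSiteSet-class].
#' @export
filterUniqueness <- function(sites, uniqueMask, alu = NULL, aluExempt = FALSE) {
  if (!length(uniqueMask))
    warning("empty uniqueness mask: removing all sites", call. = FALSE)
  inMask <- overlapsAnyUnstranded(sites@gr, uniqueMask)
  keep <- inMask
  if (aluExempt && !is.null(alu))
    keep <- keep | overlapsAnyUnstranded(sites@gr, alu)
  subsetSites(sites, keep, "uniqueness")
}

#' Annotate sites with transcript region labels from gene models
#'
#' Assigns each site a region label (`THREE_UTR`, `FIVE_UTR`, `CDS`,
#' `NONCODING_EXON`, `INTRON`, or `INTERGENIC` when no model overlaps) with
#' precedence THREE_UTR > FIVE_UTR > CDS > NONCODING_EXON > INTRON when
#' models conflict (logged). The model strand assigns transcript
#' orientation: a genomic T>C site inside a minus-strand gene is A-to-I in
#' the transcript (`aToI` metadata column).
#'
#' @param sites an [EditingSiteSet-class].
#' @param models GRanges of gene-model features (see [readGeneModels()]).
#' @return the [EditingSiteSet-class] with `region`, `geneId`, `geneName`
#'   and `aToI` metadata columns added.
#' @export
annotateRegion <- function(sites, models) {
  gr <- sites@gr
  n <- length(gr)
  region <- rep("INTERGENIC", n)
  geneId <- rep(NA_character_, n)
  geneName <- rep(NA_character_, n)
  txStrand <- rep(NA_character_, n)
  if (n && length(models)) {
    prec <- c(THREE_UTR = 1L, FIVE_UTR = 2L, CDS = 3L,
              NONCODING_EXON = 4L, INTRON = 5L)
    hits <- findOverlaps(gr, models, ignore.strand = TRUE)
    if (length(hits)) {
      qh <- queryHits(hits); sh <- subjectHits(hits)
      feat <- mcols(models)$feature[sh]
      ord <- order(qh, prec[feat])
      first <- !duplicated(qh[ord])
      qsel <- qh[ord][first]; ssel <- sh[ord][first]
      conflict <- unique(qh[duplicated(qh)])
      if (length(conflict))
        message(length(conflict),
                " site(s) overlap multiple model features; precedence ",
                "THREE_UTR > FIVE_UTR > CDS > NONCODING_EXON > INTRON applied")
      region[qsel] <- mcols(models)$feature[ssel]
      geneId[qsel] <- mcols(models)$gene_id[ssel]
      geneName[qsel] <- mcols(models)$gene_name[ssel]
      txStrand[qsel] <- as.character(strand(models))[ssel]
    }
  }
  vc <- mcols(gr)$variantClass
  effStrand <- ifelse(is.na(txStrand), as.character(strand(gr)), txStrand)
  aToI <- (vc == "A>G" & effStrand == "+") | (vc == "T>C" & effStrand == "-")
  mcols(gr)$region <- region
  mcols(gr)$geneId <- geneId
  mcols(gr)$geneName <- geneName
  mcols(gr)$aToI <- aToI
  new("EditingSiteSet", gr = gr, sampleId = sites@sampleId)
}
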