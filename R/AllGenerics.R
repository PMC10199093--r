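#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end strand strand<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

#' Number of sites in a container
#' @param x an EditingSiteSet, PileupSet, KnownSiteDB or DifferentialTable.
#' @return integer count of distinct sites.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' Site keys ("chrom:pos:strand" or "chrom:pos")
#' @param x a site container.
#' @param ... passed to methods.
#' @return character vector of keys.
#' @export
setGeneric("siteKeys", function(x, ...) standardGeneric("siteKeys"))

#' Editing levels of a site set
#' @param x an EditingSiteSet.
#' @return numeric vector in [0,1].
#' @export
setGeneric("editingLevel", function(x) standardGeneric("editingLevel"))

#' Genomic ranges underlying a site container
#' @param x an EditingSiteSet.
#' @return a GRanges.
#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))

#' Per-stage counts of a cascade run
#' @param x a CascadeReport.
#' @return data.frame with stage, n_in, n_out.
#' @export
setGeneric("cascadeStages", function(x) standardGeneric("cascadeStages"))

#' @describeIn nSites sites in an EditingSiteSet
#' @export
setMethod("nSites", "EditingSiteSet", function(x) length(x@gr))

#' @describeIn nSites distinct (site, sample) rows in a PileupSet
#' @export
setMethod("nSites", "PileupSet", function(x) nrow(x@sites))

#' @describeIn nSites sites in a KnownSiteDB
#' @export
setMethod("nSites", "KnownSiteDB", function(x) nrow(x@sites))

#' @describeIn nSites sites in a DifferentialTable
#' @export
setMethod("nSites", "DifferentialTable", function(x) nrow(x@sites))

#' @describeIn siteKeys keys of an EditingSiteSet; `stranded = FALSE` drops strand
#' @param stranded include the strand in the key (default TRUE).
#' @export
setMethod("siteKeys", "EditingSiteSet", function(x, stranded = TRUE) {
  if (!length(x@gr)) return(character())
  if (stranded)
    siteKey(as.character(seqnames(x@gr)), start(x@gr), as.character(strand(x@gr)))
  else siteKey(as.character(seqnames(x@gr)), start(x@gr))
})

#' @describeIn siteKeys keys of a KnownSiteDB
#' @export
setMethod("siteKeys", "KnownSiteDB", function(x, stranded = TRUE) {
  s <- x@sites
  if (!nrow(s)) return(character())
  if (stranded) siteKey(s$chrom, s$pos, s$strand) else siteKey(s$chrom, s$pos)
})

#' @describeIn editingLevel editing levels of an EditingSiteSet
#' @export
setMethod("editingLevel", "EditingSiteSet", function(x) mcols(x@gr)$editingLevel)

#' @describeIn siteRanges GRanges of an EditingSiteSet
#' @export
setMethod("siteRanges", "EditingSiteSet", function(x) x@gr)

#' @describeIn cascadeStages stage table of a CascadeReport
#' @export
setMethod("cascadeStages", "CascadeReport", function(x) x@stages)

setMethod("show", "PileupSet", function(object) {
  cat("PileupSet (", object@dialect, "): ",
      nrow(object@sites), " site rows, ",
      nrow(object@obs), " read observations, ",
      length(unique(object@sites$sample_id)), " sample(s)\n", sep = "")
})

setMethod("show", "KnownSiteDB", function(object) {
  cat("KnownSiteDB [", object@source, "]: ", nrow(object@sites), " sites\n",
      sep = "")
})

setMethod("show", "EditingSiteSet", function(object) {
  cat("EditingSiteSet: ", length(object@gr), " sites",
      if (nzchar(object@sampleId)) paste0(" (sample ", object@sampleId, ")"),
      "\n", sep = "")
  if (length(object@gr)) {
    lv <- mcols(object@gr)$editingLevel
    cat("  editing level: median ", sprintf("%.3f", stats::median(lv)),
        ", range [", sprintf("%.3f", min(lv)), ", ",
        sprintf("%.3f", max(lv)), "]\n", sep = "")
  }
})

setMethod("show", "CascadeReport", function(object) {
  cat("CascadeReport (", object@cascade, " cascade)\n", sep = "")
  print(object@stages, row.names = FALSE)
})

setMethod("show", "DifferentialTable", function(object) {
  cat("DifferentialTable: ", nrow(object@sites), " sites x ",
      nrow(object@pairs), " pairs\n", sep = "")
})

setMethod("show", "LDAResult", function(object) {
  n <- if (object@freq > 0) round(1 / object@freq) else Inf
  cat("LDAResult: frequency ", signif(object@freq, 6), " (1/", n, ")\n",
      "  95% CI [", signif(object@ciLower, 6), ", ",
      signif(object@ciUpper, 6), "]  (Wald on log frequency)\n",
      "  logLik ", signif(object@logLik, 8),
      if (object@boundary != "none") paste0("  [boundary: ", object@boundary, "]"),
      "\n", sep = "")
})
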