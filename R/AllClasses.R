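#' @import methods
NULL

BASES <- c("A", "C", "G", "T")
OBS_BASES <- c("A", "C", "G", "T", "N")
REGION_LEVELS <- c("THREE_UTR", "FIVE_UTR", "CDS", "NONCODING_EXON",
                   "INTRON", "INTERGENIC")
KNOWN_SOURCES <- c("REDIPORTAL", "RADAR", "DARNED", "ATLAS",
                   "SNP_1000G", "SNP_ESP", "CUSTOM")

#' PileupSet: per-site, per-read pileup observations for one or more samples
#'
#' A `PileupSet` holds one row per (site, sample) in `sites` and one row per
#' read observation in `obs`. Sites with no covering reads are legal (depth 0).
#' Positions are 1-based; `offset` is the 1-based distance of the site from
#' the read's 5' end; `mapq` is Phred-scaled mapping quality with 255 meaning
#' "unavailable".
#'
#' @slot sites data.frame with columns chrom, pos, ref, sample_id.
#' @slot obs data.frame with columns chrom, pos, sample_id, base, offset, mapq.
#' @slot dialect character, pileup dialect version tag.
#' @exportClass PileupSet
setClass("PileupSet",
  representation(sites = "data.frame", obs = "data.frame", dialect = "character"),
  prototype(dialect = "editomekit-pileup-v1"))

setValidity("PileupSet", function(object) {
  s <- object@sites; o <- object@obs
  need_s <- c("chrom", "pos", "ref", "sample_id")
  need_o <- c("chrom", "pos", "sample_id", "base", "offset", "mapq")
  if (!all(need_s %in% names(s))) return("sites must have chrom,pos,ref,sample_id")
  if (!all(need_o %in% names(o))) return("obs must have chrom,pos,sample_id,base,offset,mapq")
  if (nrow(s) && any(s$pos < 1)) return("positions must be >= 1")
  if (nrow(s) && !all(s$ref %in% BASES)) return("ref base must be one of A/C/G/T")
  if (nrow(o) && !all(o$base %in% OBS_BASES)) return("observed base must be A/C/G/T/N")
  if (nrow(o) && any(o$offset < 1)) return("read offsets are 1-based (>= 1)")
  TRUE
})

#' KnownSiteDB: a set of known editing or SNP sites
#'
#' Sites are keyed by (chrom, pos, strand), 1-based. The `tissues` column is a
#' comma-separated label set (possibly empty), as used by the inosinome-atlas
#' style tissue filter.
#'
#' @slot source one of REDIPORTAL, RADAR, DARNED, ATLAS, SNP_1000G, SNP_ESP, CUSTOM.
#' @slot sites data.frame with columns chrom, pos, strand, tissues.
#' @exportClass KnownSiteDB
setClass("KnownSiteDB",
  representation(source = "character", sites = "data.frame"))

setValidity("KnownSiteDB", function(object) {
  if (length(object@source) != 1L || !object@source %in% KNOWN_SOURCES)
    return(paste("source must be one of:", paste(KNOWN_SOURCES, collapse = ", ")))
  s <- object@sites
  if (!all(c("chrom", "pos", "strand", "tissues") %in% names(s)))
    return("sites must have chrom,pos,strand,tissues")
  if (nrow(s)) {
    if (any(s$pos < 1)) return("positions must be >= 1")
    if (anyDuplicated(paste(s$chrom, s$pos, s$strand)))
      return("duplicate (chrom,pos,strand) keys")
  }
  TRUE
})

#' EditingSiteSet: candidate or accepted A-to-I editing sites
#'
#' Wraps a width-1 `GRanges` (1-based) whose metadata columns carry genomic
#' REF/ALT, depths, the editing level (alt fraction in transcript
#' orientation), the variant class, the ordered filter provenance
#' (semicolon-joined) and any known-resource annotations.
#'
#' @slot gr GRanges with mcols ref, alt, depth, altDepth, editingLevel,
#'   variantClass, filters, annotations.
#' @slot sampleId character, sample the sites were called in ("" if pooled).
#' @exportClass EditingSiteSet
setClass("EditingSiteSet",
  representation(gr = "GRanges", sampleId = "character"),
  prototype(sampleId = ""))

setValidity("EditingSiteSet", function(object) {
  m <- S4Vectors::mcols(object@gr)
  need <- c("ref", "alt", "depth", "altDepth", "editingLevel",
            "variantClass", "filters", "annotations")
  if (!all(need %in% names(m)))
    return(paste("mcols must include:", paste(need, collapse = ", ")))
  if (length(object@gr)) {
    if (any(m$altDepth > m$depth) || any(m$altDepth < 0))
      return("0 <= altDepth <= depth violated")
    pos <- m$depth > 0
    if (any(abs(m$editingLevel[pos] - m$altDepth[pos] / m$depth[pos]) > 1e-12))
      return("editingLevel must equal altDepth/depth when depth > 0")
    if (any(m$editingLevel < 0 | m$editingLevel > 1))
      return("editingLevel must lie in [0,1]")
    vc <- paste0(m$ref, ">", m$alt)
    if (any(vc != m$variantClass))
      return("variantClass inconsistent with ref/alt")
  }
  TRUE
})

#' CascadeReport: per-stage bookkeeping of a filter cascade
#'
#' @slot stages data.frame with columns stage, n_in, n_out.
#' @slot removed named list of character site keys removed at each stage.
#' @slot cascade cascade name ("organoid" or "denovo").
#' @exportClass CascadeReport
setClass("CascadeReport",
  representation(stages = "data.frame", removed = "list", cascade = "character"))

setValidity("CascadeReport", function(object) {
  s <- object@stages
  if (!all(c("stage", "n_in", "n_out") %in% names(s)))
    return("stages must have stage,n_in,n_out")
  if (nrow(s)) {
    if (any(s$n_out > s$n_in)) return("stage counts must be non-increasing")
    if (nrow(s) > 1 && any(s$n_in[-1] != s$n_out[-nrow(s)]))
      return("stage inputs must chain to previous stage outputs")
  }
  TRUE
})

#' DifferentialTable: per-site editing deltas across paired sample lines
#'
#' Editing levels and deltas are stored as sites x pairs matrices; `NA` marks
#' a pair in which the site was not measurable (insufficient depth in one or
#' both members). `delta = resistant - parental`.
#'
#' @slot sites data.frame with columns key, chrom, pos, strand.
#' @slot parental,resistant,delta numeric matrices, sites x pairs.
#' @slot pairs data.frame with columns line_id, parental_id, resistant_id.
#' @exportClass DifferentialTable
setClass("DifferentialTable",
  representation(sites = "data.frame", parental = "matrix",
                 resistant = "matrix", delta = "matrix", pairs = "data.frame"))

setValidity("DifferentialTable", function(object) {
  d <- object@delta
  if (nrow(d) != nrow(object@sites)) return("delta rows must match sites")
  if (ncol(d) != nrow(object@pairs)) return("delta cols must match pairs")
  fin <- d[is.finite(d)]
  if (length(fin) && (any(fin < -1) || any(fin > 1)))
    return("deltas must lie in [-1, 1]")
  TRUE
})

#' LDAResult: single-hit limiting-dilution frequency estimate
#'
#' @slot freq estimated initiating-cell fraction.
#' @slot ciLower,ciUpper 95\% bounds (Wald on log frequency when interior).
#' @slot logLik binomial log-likelihood at the optimum.
#' @slot boundary one of "none", "all_negative", "all_positive".
#' @slot data the dose/tested/responding table the fit used.
#' @exportClass LDAResult
setClass("LDAResult",
  representation(freq = "numeric", ciLower = "numeric", ciUpper = "numeric",
                 logLik = "numeric", boundary = "character", data = "data.frame"))

setValidity("LDAResult", function(object) {
  if (!object@boundary %in% c("none", "all_negative", "all_positive"))
    return("boundary must be none/all_negative/all_positive")
  if (object@boundary == "none" &&
      !(object@ciLower <= object@freq && object@freq <= object@ciUpper))
    return("ciLower <= freq <= ciUpper required when interior")
  TRUE
})
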