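## thresholds anchoring both cascades; every run's provenance records these
defaultThresholds <- function() {
  list(minDepthExclusive = 7, minAltExclusive = 2,   # organoid: depth > 7, alt > 2
       minSupport = 2, minMapq = 20,                  # de novo: alt >= 2, mapq >= 20
       firstN = 6, junctionMargin = 4,                # read-position, splice margin
       homopolymerMinRun = 5, dnaMinAlt = 2,          # homopolymer run, DNA evidence
       minDelta = 0.10, minLines = 2)                 # hyper-editing rule
}

#' Run a full editing-site filter cascade
#'
#' Two cascades are provided. The `organoid` cascade (matched-exome design)
#' runs: candidate calling (depth > 7, alt > 2, A-to-I classes only) ->
#' subtraction of matched-DNA variants -> known-resource filtering
#' (RADAR/DARNED/tissue atlas). The `denovo` cascade (no matched DNA) runs:
#' candidate calling (mapq >= 20, support >= 2) -> SNP removal ->
#' read-position censoring -> Alu-conditional artifact filter -> uniqueness
#' mask. Missing resources for an enabled stage raise an error before any
#' work; stages named in `config$disable` are skipped.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{cascade}{"organoid" or "denovo".}
#'     \item{rna}{RNA [PileupSet-class] (required).}
#'     \item{sampleId}{sample to call when the pileup holds several.}
#'     \item{dna}{matched DNA [PileupSet-class] (organoid), or}
#'     \item{dnaVariants}{precomputed "chrom:pos" keys.}
#'     \item{radar, darned, atlas}{[KnownSiteDB-class] resources (organoid).}
#'     \item{tissue}{atlas tissue label (default "stomach").}
#'     \item{knownMode}{"literal_and" (default) or "any_resource".}
#'     \item{snp}{list of SNP [KnownSiteDB-class] (denovo).}
#'     \item{alu, junctions, repeats, mask}{GRanges resources (denovo).}
#'     \item{reference}{named DNAStringSet / DNAString (denovo).}
#'     \item{thresholds}{overrides of `defaultThresholds()` entries.}
#'     \item{disable}{character stage names to skip.}
#'   }
#' @return list with `sites` (final [EditingSiteSet-class]) and `report`
#'   (a [CascadeReport-class] of per-stage counts and removed keys).
#' @export
runCascade <- function(config) {
  cascade <- match.arg(config$cascade, c("organoid", "denovo"))
  if (is.null(config$rna) || !is(config$rna, "PileupSet"))
    stop("config$rna must be a PileupSet", call. = FALSE)
  th <- defaultThresholds()
  th[names(config$thresholds %||% list())] <- config$thresholds
  disable <- config$disable %||% character()
  tissue <- config$tissue %||% "stomach"
  knownMode <- config$knownMode %||% "literal_and"

  if (cascade == "organoid") {
    if (!"dna_subtraction" %in% disable &&
        is.null(config$dna) && is.null(config$dnaVariants))
      stop("organoid cascade requires config$dna or config$dnaVariants",
           call. = FALSE)
    if (!"known_resources" %in% disable &&
        (is.null(config$radar) || is.null(config$darned) || is.null(config$atlas)))
      stop("organoid cascade requires radar, darned and atlas databases",
           call. = FALSE)
    stages <- list(
      candidates = function(x)
        callCandidatesOrganoid(config$rna, th$minDepthExclusive,
                               th$minAltExclusive, sampleId = config$sampleId),
      dna_subtraction = function(x) {
        dv <- config$dnaVariants %||%
          callDnaVariants(config$dna, th$dnaMinAlt, sampleId = config$dnaSampleId)
        subtractDnaVariants(x, dv)
      },
      known_resources = function(x)
        filterKnownResources(x, config$radar, config$darned, config$atlas,
                             tissue = tissue, mode = knownMode))
  } else {
    if (!"snp_removal" %in% disable && is.null(config$snp))
      stop("denovo cascade requires config$snp databases", call. = FALSE)
    if (!"nonalu_artifacts" %in% disable &&
        (is.null(config$alu) || is.null(config$junctions) ||
         is.null(config$repeats) || is.null(config$reference)))
      stop("denovo cascade requires alu, junctions, repeats and reference",
           call. = FALSE)
    if (!"uniqueness" %in% disable && is.null(config$mask))
      stop("denovo cascade requires config$mask", call. = FALSE)
    mapqPileup <- NULL
    stages <- list(
      candidates = function(x) {
        o <- config$rna@obs
        mapqPileup <<- pileupSet(config$rna@sites,
          o[o$mapq >= th$minMapq | o$mapq == 255L, , drop = FALSE])
        callCandidatesDenovo(config$rna, th$minSupport, th$minMapq,
                             aToIOnly = isTRUE(config$aToIOnly),
                             sampleId = config$sampleId)
      },
      snp_removal = function(x) filterSnps(x, config$snp),
      read_position = function(x)
        filterReadPosition(x, mapqPileup, th$firstN, th$minSupport),
      nonalu_artifacts = function(x)
        filterNonAlu(x, config$alu, config$junctions, config$reference,
                     config$repeats, th$junctionMargin, th$homopolymerMinRun),
      uniqueness = function(x)
        filterUniqueness(x, config$mask, alu = config$alu,
                         aluExempt = isTRUE(config$aluExemptUniqueness)))
  }

  sites <- NULL
  rows <- list()
  removed <- list()
  for (nm in names(stages)) {
    if (nm != "candidates" && nm %in% disable) next
    n_in <- if (is.null(sites)) NA_integer_ else nSites(sites)
    before <- if (is.null(sites)) character() else siteKeys(sites)
    sites <- stages[[nm]](sites)
    n_out <- nSites(sites)
    rows[[nm]] <- data.frame(stage = nm,
                             n_in = if (is.na(n_in)) n_out else n_in,
                             n_out = n_out, stringsAsFactors = FALSE)
    removed[[nm]] <- setdiff(before, siteKeys(sites))
  }
  report <- new("CascadeReport", stages = do.call(rbind, rows),
                removed = removed, cascade = cascade)
  list(sites = sites, report = report)
}
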