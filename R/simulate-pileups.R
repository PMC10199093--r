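## Draw per-read observations at a set of sites: depth ~ Poisson(depthMean);
## each read carries the alt base with probability `level`, then a uniform
## sequencing error replaces the drawn base with one of the three others
## with probability errorRate; offsets uniform in 1..readLength.
drawSiteObs <- function(sites, level, depthMean, errorRate, readLength,
                        sampleId, mapq = 60L) {
  n <- nrow(sites)
  depth <- rpois(n, depthMean)
  tot <- sum(depth)
  if (tot == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      sample_id = character(), base = character(),
                      offset = integer(), mapq = integer()))
  idx <- rep.int(seq_len(n), depth)
  base <- ifelse(runif(tot) < level[idx], sites$alt[idx], sites$ref[idx])
  err <- runif(tot) < errorRate
  if (any(err)) {
    ## uniform over the three non-drawn bases
    base[err] <- vapply(base[err], function(b) sample(setdiff(BASES, b), 1), "")
  }
  data.frame(chrom = sites$chrom[idx], pos = sites$pos[idx],
             sample_id = sampleId, base = base,
             offset = sample.int(readLength, tot, replace = TRUE),
             mapq = as.integer(mapq), stringsAsFactors = FALSE)
}

#' Simulate matched RNA and DNA pileups for one sample role
#'
#' RNA pileups carry the role-specific true editing fraction at planted
#' edit sites (binomial sampling around it), heterozygous germline SNPs at
#' SNP sites (fraction 0.5 in both RNA and DNA), and alternative reads
#' arising only from the uniform error model elsewhere. DNA pileups carry
#' the germline SNPs but no edits. Per-read offsets are uniform in
#' `[1, readLength]`; deterministic given (truth, role, seed).
#'
#' @param truth a SimTruth from [simulateEditingTruth()].
#' @param sampleRole "parental" or "resistant".
#' @param depthMean mean per-site read depth (Poisson; default 50).
#' @param errorRate per-base uniform sequencing error in [0, 0.1]
#'   (default 0.005).
#' @param readLength read length for offset draws (default 100).
#' @param sampleId sample label (default derived from the role).
#' @param seed integer seed.
#' @return list with `rna` and `dna` [PileupSet-class] objects.
#' @export
simulatePileupPair <- function(truth, sampleRole = c("parental", "resistant"),
                               depthMean = 50, errorRate = 0.005,
                               readLength = 100, sampleId = NULL, seed = 1) {
  sampleRole <- match.arg(sampleRole)
  if (errorRate < 0 || errorRate > 0.1)
    stop("errorRate must lie in [0, 0.1]", call. = FALSE)
  sampleId <- sampleId %||% sampleRole
  stream <- if (sampleRole == "parental") 10L else 11L
  withStreamSeed(seed, stream, {
    sites <- rbind(truth$edits[c("chrom", "pos", "ref", "strand", "alt")],
                   truth$nulls[c("chrom", "pos", "ref", "strand", "alt")],
                   truth$snps[c("chrom", "pos", "ref", "strand", "alt")])
    lv <- c(if (nrow(truth$edits))
              if (sampleRole == "parental") truth$edits$parentalLevel
              else truth$edits$resistantLevel,
            rep(0, nrow(truth$nulls)),
            rep(0.5, nrow(truth$snps)))      # heterozygous germline
    rnaObs <- drawSiteObs(sites, lv, depthMean, errorRate, readLength,
                          sampleId)
    dnaLv <- c(rep(0, nrow(truth$edits)), rep(0, nrow(truth$nulls)),
               rep(0.5, nrow(truth$snps)))
    dnaObs <- drawSiteObs(sites, dnaLv, depthMean, errorRate, readLength,
                          sampleId)
    siteRows <- data.frame(chrom = sites$chrom, pos = sites$pos,
                           ref = sites$ref, sample_id = sampleId,
                           stringsAsFactors = FALSE)
    list(rna = pileupSet(siteRows, rnaObs), dna = pileupSet(siteRows, dnaObs))
  })
}

#' Simulate a full paired-line organoid editing study
#'
#' Builds a reference, plants hyper-edit, null and germline-SNP truth, and
#' simulates matched RNA/DNA pileups for `nLines` parental/resistant pairs.
#' Planted edit sites are registered in the RADAR-style known-editing
#' database (and labeled as stomach-edited in the atlas) so the
#' known-resource stage retains them; null and SNP sites are absent from
#' the editing resources.
#'
#' @param nPlanted planted hyper-edited sites (default 200).
#' @param nNull covered null sites (default 2000).
#' @param nSnps germline SNP sites (default 50).
#' @param nLines paired lines (default 3).
#' @param delta true resistant-minus-parental editing change (default 0.3).
#' @param parentalLevel parental editing fraction (default 0).
#' @param depthMean mean depth (default 50).
#' @param errorRate sequencing error (default 0.005).
#' @param refLength reference length (default 200000).
#' @param seed integer seed.
#' @return list with `truth`, per-line `samples` (named list of
#'   rna/dna pileups per role), `pairs` data.frame, and `radar`, `darned`,
#'   `atlas` [KnownSiteDB-class] resources.
#' @export
simulateOrganoidStudy <- function(nPlanted = 200, nNull = 2000, nSnps = 50,
                                  nLines = 3, delta = 0.3, parentalLevel = 0,
                                  depthMean = 50, errorRate = 0.005,
                                  refLength = 200000L, seed = 1) {
  ref <- simulateReference(refLength, seed = seed)
  truth <- simulateEditingTruth(ref, nEdits = nPlanted, nNull = nNull,
                                nSnps = nSnps,
                                parentalLevel = parentalLevel,
                                resistantLevel = parentalLevel + delta,
                                seed = seed)
  samples <- list()
  pairs <- data.frame(line_id = paste0("L", seq_len(nLines)),
                      parental_id = paste0("L", seq_len(nLines), "_parental"),
                      resistant_id = paste0("L", seq_len(nLines), "_resistant"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nLines)) {
    for (role in c("parental", "resistant")) {
      sid <- paste0("L", i, "_", role)
      samples[[sid]] <- simulatePileupPair(
        truth, role, depthMean = depthMean, errorRate = errorRate,
        sampleId = sid, seed = seed * 131L + i)
    }
  }
  ed <- truth$edits
  radar <- knownSiteDB("RADAR", data.frame(
    chrom = ed$chrom, pos = ed$pos, strand = ed$strand, tissues = ""))
  darned <- knownSiteDB("DARNED", data.frame(
    chrom = character(), pos = integer(), strand = character(),
    tissues = character()))
  atlas <- knownSiteDB("ATLAS", data.frame(
    chrom = ed$chrom, pos = ed$pos, strand = ed$strand, tissues = "stomach"))
  list(truth = truth, samples = samples, pairs = pairs,
       radar = radar, darned = darned, atlas = atlas)
}
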