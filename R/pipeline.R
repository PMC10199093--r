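#' Organoid cascade plus differential hyper-editing on a paired study
#'
#' For each line, runs the matched-exome (organoid) cascade on the
#' resistant RNA pileup against that line's DNA, unions the accepted sites
#' across lines, measures per-sample editing levels at the union
#' (measurable when depth passes the candidate depth rule), computes paired
#' resistant-minus-parental deltas and calls hyper-edited sites.
#'
#' @param study a study from [simulateOrganoidStudy()], or any list with
#'   the same `samples`/`pairs`/`radar`/`darned`/`atlas` layout.
#' @param minDelta hyper-editing change threshold (default 0.10).
#' @param minLines lines required to meet the change (default 2).
#' @param tissue atlas tissue label (default "stomach").
#' @return list with `called` (hyper site keys), `table`
#'   (the [DifferentialTable-class]), `unionSites` (data.frame) and
#'   `reports` (per-line [CascadeReport-class]).
#' @export
runOrganoidStudyPipeline <- function(study, minDelta = 0.10, minLines = 2,
                                     tissue = "stomach") {
  pairs <- study$pairs
  unionSites <- NULL
  reports <- list()
  for (i in seq_len(nrow(pairs))) {
    rid <- pairs$resistant_id[i]
    res <- runCascade(list(
      cascade = "organoid",
      rna = study$samples[[rid]]$rna,
      dna = study$samples[[rid]]$dna,
      radar = study$radar, darned = study$darned, atlas = study$atlas,
      tissue = tissue))
    reports[[pairs$line_id[i]]] <- res$report
    st <- siteTable(res$sites)[c("chrom", "pos", "strand", "ref", "alt")]
    unionSites <- if (is.null(unionSites)) st else rbind(unionSites, st)
  }
  unionSites <- unique(unionSites)
  unionSites <- unionSites[order(unionSites$chrom, unionSites$pos), ,
                           drop = FALSE]
  ids <- unique(c(pairs$parental_id, pairs$resistant_id))
  tables <- lapply(ids, function(id)
    levelsAtSites(study$samples[[id]]$rna, unionSites, sampleId = id))
  names(tables) <- ids
  dt <- pairDeltas(tables, pairs)
  called <- callHyperEdited(dt, minDelta = minDelta, minLines = minLines)
  list(called = called, table = dt, unionSites = unionSites,
       reports = reports)
}
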