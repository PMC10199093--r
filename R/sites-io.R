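#' Construct an EditingSiteSet from a site table
#'
#' @param df data.frame with columns chrom, pos (1-based), strand, ref, alt,
#'   depth, altDepth and optionally filters (semicolon-joined provenance) and
#'   annotations. The editing level is computed as `altDepth/depth` (0 at
#'   depth 0).
#' @param sampleId sample label, "" if pooled.
#' @return a validated [EditingSiteSet-class].
#' @export
editingSiteSet <- function(df, sampleId = "") {
  if (!nrow(df)) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(
      ref = character(), alt = character(), depth = integer(),
      altDepth = integer(), editingLevel = numeric(),
      variantClass = character(), filters = character(),
      annotations = character())
    return(new("EditingSiteSet", gr = gr, sampleId = sampleId))
  }
  gr <- GRanges(df$chrom, IRanges(df$pos, width = 1L),
                strand = if (is.null(df$strand)) "*" else df$strand)
  mcols(gr)$ref <- as.character(df$ref)
  mcols(gr)$alt <- as.character(df$alt)
  mcols(gr)$depth <- as.integer(df$depth)
  mcols(gr)$altDepth <- as.integer(df$altDepth)
  mcols(gr)$editingLevel <- ifelse(df$depth > 0, df$altDepth / df$depth, 0)
  mcols(gr)$variantClass <- paste0(df$ref, ">", df$alt)
  mcols(gr)$filters <- if (is.null(df$filters)) rep("", nrow(df)) else df$filters
  mcols(gr)$annotations <-
    if (is.null(df$annotations)) rep("", nrow(df)) else df$annotations
  new("EditingSiteSet", gr = gr, sampleId = sampleId)
}

## EditingSiteSet -> plain data.frame (the TSV twin schema)
siteTable <- function(sites) {
  gr <- sites@gr
  data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
             strand = as.character(strand(gr)),
             ref = mcols(gr)$ref, alt = mcols(gr)$alt,
             depth = mcols(gr)$depth, altDepth = mcols(gr)$altDepth,
             editingLevel = mcols(gr)$editingLevel,
             variantClass = mcols(gr)$variantClass,
             filters = mcols(gr)$filters,
             annotations = mcols(gr)$annotations,
             stringsAsFactors = FALSE)
}

## subset an EditingSiteSet by logical/integer index, appending a passed
## filter name to the provenance of the survivors
subsetSites <- function(sites, keep, filterName = NULL) {
  gr <- sites@gr[keep]
  if (!is.null(filterName) && length(gr)) {
    f <- mcols(gr)$filters
    mcols(gr)$filters <- ifelse(nzchar(f), paste(f, filterName, sep = ";"),
                                filterName)
  }
  new("EditingSiteSet", gr = gr, sampleId = sites@sampleId)
}

#' Write editing sites as minimal VCF 4.2 plus a TSV twin
#'
#' Records are written with genomic REF/ALT; a minus-strand A-to-I site is
#' therefore reported as T/C with `STRAND=-` in INFO. INFO carries
#' `EDLEVEL` (editing level), `DEPTH`, `ALTDEPTH`, `STRAND` and `FILTERS`
#' (semicolon provenance, `.` if empty). Unsorted input is sorted on write.
#'
#' @param sites an [EditingSiteSet-class].
#' @param path output VCF path; the TSV twin is written next to it with a
#'   `.tsv` extension.
#' @return invisible character vector of the two paths written.
#' @export
writeSitesVcf <- function(sites, path) {
  stopifnot(is(sites, "EditingSiteSet"))
  tab <- siteTable(sites)
  if (nrow(tab)) tab <- tab[order(tab$chrom, tab$pos, tab$strand), , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=editomekit",
    "##INFO=<ID=EDLEVEL,Number=1,Type=Float,Description=\"Editing level (alt fraction, transcript orientation)\">",
    "##INFO=<ID=DEPTH,Number=1,Type=Integer,Description=\"Read depth at site\">",
    "##INFO=<ID=ALTDEPTH,Number=1,Type=Integer,Description=\"Reads carrying the alternative base\">",
    "##INFO=<ID=STRAND,Number=1,Type=String,Description=\"Transcript strand of the editing event\">",
    "##INFO=<ID=FILTERS,Number=1,Type=String,Description=\"Ordered filter provenance\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rec <- if (nrow(tab)) {
    info <- sprintf("EDLEVEL=%.6g;DEPTH=%d;ALTDEPTH=%d;STRAND=%s;FILTERS=%s",
                    tab$editingLevel, tab$depth, tab$altDepth, tab$strand,
                    ifelse(nzchar(tab$filters), tab$filters, "."))
    paste(tab$chrom, tab$pos, ".", tab$ref, tab$alt, ".", "PASS", info,
          sep = "\t")
  } else character()
  writeLines(c(hdr, rec), path)
  tsv <- sub("\\.vcf$", "", path)
  tsv <- paste0(tsv, ".tsv")
  writeSitesTsv(sites, tsv)
  invisible(c(path, tsv))
}

#' Write an EditingSiteSet as a TSV site table
#' @param sites an [EditingSiteSet-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeSitesTsv <- function(sites, path) {
  tab <- siteTable(sites)
  if (nrow(tab)) tab <- tab[order(tab$chrom, tab$pos, tab$strand), , drop = FALSE]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV site table written by [writeSitesTsv()]
#' @param path path to the TSV.
#' @param sampleId sample label to attach.
#' @return an [EditingSiteSet-class].
#' @export
readSitesTsv <- function(path, sampleId = "") {
  if (!file.exists(path)) stop("site table not found: ", path, call. = FALSE)
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "ref", "alt", "depth", "altDepth")
  if (!all(need %in% names(d)))
    stop("site TSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(d$filters)) d$filters <- ""
  d$filters[is.na(d$filters)] <- ""
  if (is.null(d$annotations)) d$annotations <- ""
  d$annotations[is.na(d$annotations)] <- ""
  editingSiteSet(d, sampleId = sampleId)
}
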