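#' Read a BED file of genomic intervals into a GRanges
#'
#' Accepts BED3+ (tab- or space-separated, CRLF tolerated). BED is 0-based
#' half-open on disk; the returned `GRanges` follows the Bioconductor 1-based
#' closed convention (`start+1 .. end`), so interval membership queries via
#' `findOverlaps` agree with half-open BED semantics exactly.
#'
#' @param path path to a BED file.
#' @return a `GRanges` with a `name` metadata column.
#' @export
readBedIntervals <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) {
    gr <- GRanges()
    mcols(gr)$name <- character()
    return(gr)
  }
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("BED rows need at least 3 columns (line(s) ",
         paste(which(nf < 3L), collapse = ", "), ")", call. = FALSE)
  chrom <- vapply(parts, `[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  if (anyNA(start0) || anyNA(end0))
    stop("non-integer BED coordinates", call. = FALSE)
  if (any(start0 < 0) || any(start0 >= end0))
    stop("validation error: BED requires 0 <= start < end (line(s) ",
         paste(which(start0 < 0 | start0 >= end0), collapse = ", "), ")",
         call. = FALSE)
  name <- ifelse(nf >= 4L, vapply(parts, function(p) p[4L] %||% ".", ""), ".")
  strand <- ifelse(nf >= 6L, vapply(parts, function(p) p[6L] %||% "*", ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  mcols(gr)$name <- name
  gr
}

#' Read a known-site table (editing databases, SNP cohorts, tissue atlases)
#'
#' TSV with columns `chrom`, `pos` (1-based), `strand`, and optionally
#' `tissues` (comma-separated labels). Duplicate (chrom,pos,strand) rows are
#' collapsed with their tissue label sets unioned.
#'
#' @param path path to the TSV.
#' @param source one of `REDIPORTAL`, `RADAR`, `DARNED`, `ATLAS`,
#'   `SNP_1000G`, `SNP_ESP`, `CUSTOM`.
#' @return a [KnownSiteDB-class].
#' @export
readKnownSites <- function(path, source) {
  if (!source %in% KNOWN_SOURCES)
    stop("unknown source tag '", source, "'; must be one of: ",
         paste(KNOWN_SOURCES, collapse = ", "), call. = FALSE)
  if (!file.exists(path)) stop("known-site file not found: ", path, call. = FALSE)
  d <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               colClasses = NA, comment.char = "#"),
    error = function(e) NULL)
  if (is.null(d) || !nrow(d)) {
    warning("empty known-site file: ", path, call. = FALSE)
    return(knownSiteDB(source,
                       data.frame(chrom = character(), pos = integer(),
                                  strand = character(), tissues = character())))
  }
  if (!all(c("chrom", "pos", "strand") %in% names(d)))
    stop("known-site TSV needs columns chrom, pos, strand", call. = FALSE)
  if (is.null(d$tissues)) d$tissues <- ""
  d$tissues[is.na(d$tissues)] <- ""
  key <- paste(d$chrom, d$pos, d$strand)
  if (anyDuplicated(key)) {
    tiss <- vapply(split(d$tissues, key), function(t) {
      labs <- unique(unlist(strsplit(t[nzchar(t)], ",", fixed = TRUE)))
      paste(sort(labs), collapse = ",")
    }, "")
    first <- !duplicated(key)
    d <- d[first, , drop = FALSE]
    d$tissues <- tiss[paste(d$chrom, d$pos, d$strand)]
  }
  knownSiteDB(source, d[c("chrom", "pos", "strand", "tissues")])
}

#' Construct a KnownSiteDB from a data.frame
#'
#' @param source source tag (see [readKnownSites()]).
#' @param sites data.frame with chrom, pos, strand and optional tissues.
#' @return a [KnownSiteDB-class].
#' @export
knownSiteDB <- function(source, sites) {
  if (is.null(sites$tissues)) sites$tissues <- rep("", nrow(sites))
  sites$chrom <- as.character(sites$chrom)
  rownames(sites) <- NULL
  new("KnownSiteDB", source = source, sites = as.data.frame(sites))
}

#' Tissue membership query on a KnownSiteDB
#'
#' @param db a [KnownSiteDB-class] carrying tissue labels.
#' @param keys character stranded site keys ("chrom:pos:strand").
#' @param tissue tissue label, e.g. `"stomach"`.
#' @return logical vector: is each key recorded as edited in `tissue`?
#' @export
hasTissue <- function(db, keys, tissue) {
  s <- db@sites
  if (!nrow(s)) return(rep(FALSE, length(keys)))
  lab <- strsplit(s$tissues, ",", fixed = TRUE)
  hit <- vapply(lab, function(t) tissue %in% t, TRUE)
  keys %in% siteKeys(db)[hit]
}

#' Read a gene-model TSV into a GRanges of labeled transcript features
#'
#' Columns: `gene_id`, `gene_name`, `chrom`, `strand` (+/-), `feature`
#' (FIVE_UTR, CDS, THREE_UTR, INTRON, NONCODING_EXON), `start`, `end`
#' (0-based half-open, BED-style).
#'
#' @param path path to the TSV.
#' @return a `GRanges` with mcols gene_id, gene_name, feature.
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("gene-model file not found: ", path, call. = FALSE)
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "gene_name", "chrom", "strand", "feature", "start", "end")
  if (!all(need %in% names(d)))
    stop("gene-model TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  okfeat <- c("FIVE_UTR", "CDS", "THREE_UTR", "INTRON", "NONCODING_EXON")
  if (!all(d$feature %in% okfeat))
    stop("unknown feature labels: ",
         paste(setdiff(d$feature, okfeat), collapse = ", "), call. = FALSE)
  if (!all(d$strand %in% c("+", "-")))
    stop("gene-model strand must be + or -", call. = FALSE)
  if (any(d$start >= d$end)) stop("gene-model intervals need start < end", call. = FALSE)
  gr <- GRanges(d$chrom, IRanges(d$start + 1L, d$end), strand = d$strand)
  mcols(gr)$gene_id <- d$gene_id
  mcols(gr)$gene_name <- d$gene_name
  mcols(gr)$feature <- d$feature
  gr
}
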