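PILEUP_DIALECT <- "editomekit-pileup v1"

#' Construct a PileupSet
#'
#' @param sites data.frame with columns chrom, pos, ref, sample_id (one row
#'   per site/sample, including depth-0 sites).
#' @param obs data.frame with columns chrom, pos, sample_id, base, offset,
#'   mapq (one row per read observation). Defaults to no observations.
#' @return a validated [PileupSet-class] object.
#' @export
pileupSet <- function(sites, obs = NULL) {
  if (is.null(obs))
    obs <- data.frame(chrom = character(), pos = integer(),
                      sample_id = character(), base = character(),
                      offset = integer(), mapq = integer())
  sites$chrom <- as.character(sites$chrom)
  obs$chrom <- as.character(obs$chrom)
  new("PileupSet", sites = as.data.frame(sites), obs = as.data.frame(obs))
}

#' Read a per-site pileup TSV
#'
#' The dialect is one row per (site, sample): tab-separated columns
#' `chrom pos ref sample obs`, where `obs` is a comma-separated list of
#' per-read entries `base:offset[:mapq]` (offset 1-based from the read 5'
#' end; mapq defaults to 255 = unavailable). The first line must declare the
#' dialect (`#editomekit-pileup v1`); an empty `obs` field is a covered site
#' with depth 0.
#'
#' @param path path to a pileup TSV file.
#' @return a [PileupSet-class].
#' @export
readPileupTsv <- function(path) {
  if (!file.exists(path)) stop("pileup file not found: ", path, call. = FALSE)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  if (!length(lines) || !startsWith(lines[1], "#editomekit-pileup"))
    stop("not a pileup TSV: missing dialect header line '#",
         sub(" ", " ", PILEUP_DIALECT), "'", call. = FALSE)
  body <- lines[-1]
  lineno <- seq_along(body) + 1L
  keep <- nzchar(body) & !startsWith(body, "#")
  body <- body[keep]; lineno <- lineno[keep]
  if (!length(body))
    return(pileupSet(data.frame(chrom = character(), pos = integer(),
                                ref = character(), sample_id = character())))
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- nf < 4L
  if (any(bad))
    stop("format error: missing columns at line(s) ",
         paste(lineno[bad], collapse = ", "), call. = FALSE)
  chrom <- vapply(parts, `[`, "", 1L)
  pos <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  ref <- toupper(vapply(parts, `[`, "", 3L))
  sample_id <- vapply(parts, `[`, "", 4L)
  obs_str <- ifelse(nf >= 5L, vapply(parts, function(p) p[5L] %||% "", ""), "")
  if (anyNA(pos) || any(pos < 1))
    stop("validation error: bad position at line(s) ",
         paste(lineno[is.na(pos) | pos < 1], collapse = ", "), call. = FALSE)
  if (!all(ref %in% BASES))
    stop("validation error: ref base not A/C/G/T at line(s) ",
         paste(lineno[!ref %in% BASES], collapse = ", "), call. = FALSE)
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref,
                      sample_id = sample_id, stringsAsFactors = FALSE)

  has_obs <- nzchar(obs_str)
  if (any(has_obs)) {
    per_site <- strsplit(obs_str[has_obs], ",", fixed = TRUE)
    counts <- lengths(per_site)
    entry <- unlist(per_site, use.names = FALSE)
    row_line <- rep(lineno[has_obs], counts)
    f <- strsplit(entry, ":", fixed = TRUE)
    nf2 <- lengths(f)
    if (any(nf2 < 2L | nf2 > 3L))
      stop("format error: obs entry must be base:offset[:mapq] at line(s) ",
           paste(unique(row_line[nf2 < 2L | nf2 > 3L]), collapse = ", "),
           call. = FALSE)
    base <- toupper(vapply(f, `[`, "", 1L))
    offset <- suppressWarnings(as.integer(vapply(f, `[`, "", 2L)))
    mapq <- suppressWarnings(as.integer(vapply(
      f, function(x) if (length(x) >= 3L) x[3L] else "255", "")))
    if (!all(base %in% OBS_BASES))
      stop("validation error: observed base not A/C/G/T/N at line(s) ",
           paste(unique(row_line[!base %in% OBS_BASES]), collapse = ", "),
           call. = FALSE)
    if (anyNA(offset) || any(offset < 1))
      stop("validation error: read offsets are 1-based; bad offset at line(s) ",
           paste(unique(row_line[is.na(offset) | offset < 1]), collapse = ", "),
           call. = FALSE)
    if (anyNA(mapq))
      stop("validation error: non-integer mapq at line(s) ",
           paste(unique(row_line[is.na(mapq)]), collapse = ", "), call. = FALSE)
    idx <- which(has_obs)
    obs <- data.frame(chrom = rep(chrom[idx], counts),
                      pos = rep(pos[idx], counts),
                      sample_id = rep(sample_id[idx], counts),
                      base = base, offset = offset, mapq = mapq,
                      stringsAsFactors = FALSE)
  } else obs <- NULL
  pileupSet(sites, obs)
}

#' Write a PileupSet in the pileup TSV dialect
#'
#' @param pileups a [PileupSet-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writePileupTsv <- function(pileups, path) {
  stopifnot(is(pileups, "PileupSet"))
  s <- pileups@sites; o <- pileups@obs
  key_s <- paste(s$chrom, s$pos, s$sample_id, sep = "\r")
  if (nrow(o)) {
    key_o <- paste(o$chrom, o$pos, o$sample_id, sep = "\r")
    ent <- ifelse(o$mapq == 255L, paste(o$base, o$offset, sep = ":"),
                  paste(o$base, o$offset, o$mapq, sep = ":"))
    obs_by <- vapply(split(ent, factor(key_o, levels = key_s)),
                     paste, "", collapse = ",")
  } else obs_by <- rep("", nrow(s))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", PILEUP_DIALECT), con)
  writeLines(paste(s$chrom, s$pos, s$ref, s$sample_id, obs_by, sep = "\t"), con)
  invisible(path)
}
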