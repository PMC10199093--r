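#' @importFrom methods new validObject is slot
#' @importFrom stats optimize uniroot qchisq pchisq qnorm pnorm rpois rbinom
#'   rnorm runif rexp qbeta sd cor cor.test quantile lm coef setNames
#' @importFrom utils read.table write.table head
NULL

## Site keys are "chrom:pos:strand"; chrom:pos keys drop the strand.  Keys are
## the currency every filter and the differential caller trade in.
siteKey <- function(chrom, pos, strand = NULL) {
  if (is.null(strand)) paste(chrom, pos, sep = ":")
  else paste(chrom, pos, strand, sep = ":")
}

## Evaluate `expr` under a private RNG stream seeded from (seed, stream):
## each generator owns a stream index so adding one generator never perturbs
## the draws of another.  Restores the caller's RNG state on exit.
withStreamSeed <- function(seed, stream, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  ## splittable counter scheme: fold (seed, stream) into [0, 2^31)
  sub <- (as.double(seed) * 2654435.0 + as.double(stream) * 97561.0) %% 2147483647
  set.seed(as.integer(sub))
  expr
}

## Detect mixed chromosome naming (chr1 vs 1) between two chromosome vectors.
## The pipeline never normalizes silently: a mix is a hard error.
checkChromStyles <- function(a, b, what = c("first set", "second set")) {
  hasChr <- function(x) {
    x <- unique(as.character(x))
    c(any(startsWith(x, "chr")), any(!startsWith(x, "chr")) && length(x) > 0)
  }
  sa <- hasChr(a); sb <- hasChr(b)
  if ((sa[1] && !sa[2] && sb[2] && !sb[1]) || (sb[1] && !sb[2] && sa[2] && !sa[1]))
    stop("chromosome naming styles differ between ", what[1], " ('",
         utils::head(unique(a), 1), "') and ", what[2], " ('",
         utils::head(unique(b), 1), "'); refusing to normalize silently",
         call. = FALSE)
  invisible(TRUE)
}

## FNV-1a over a string; used for config provenance hashes only.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
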