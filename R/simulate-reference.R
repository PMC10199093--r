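#' @importFrom Biostrings DNAString DNAStringSet
NULL

#' Simulate a reference chromosome with planted annotation intervals
#'
#' Draws an i.i.d. base sequence, plants homopolymer runs at recorded
#' coordinates, and labels Alu-like intervals, simple-repeat intervals, a
#' set of intron (splice-junction) intervals and a uniqueness mask (the
#' whole chromosome minus a few non-unique holes). Deterministic given the
#' seed.
#'
#' @param length chromosome length in bases (>= 1000).
#' @param seed integer seed.
#' @param chrom chromosome name (default "chrS").
#' @param nHomopolymers,nAlu,nRepeats,nIntrons,nMaskHoles interval counts;
#'   defaults scale with length.
#' @return list with `seq` (named DNAStringSet), `chrom`, and GRanges
#'   `alu`, `repeats`, `junctions` (introns), `mask`, `homopolymers`.
#' @export
simulateReference <- function(length, seed, chrom = "chrS",
                              nHomopolymers = max(3L, length %/% 2000L),
                              nAlu = max(2L, length %/% 5000L),
                              nRepeats = max(2L, length %/% 8000L),
                              nIntrons = max(2L, length %/% 6000L),
                              nMaskHoles = 2L) {
  if (length < 1000) stop("reference length must be >= 1000", call. = FALSE)
  withStreamSeed(seed, 1L, {
    bases <- sample(BASES, length, replace = TRUE)
    ivals <- function(n, w) {
      st <- sort(sample.int(length - w, n))
      GRanges(chrom, IRanges(st, width = w))
    }
    ## plant homopolymer runs of 6-10 identical bases
    hp_w <- sample(6:10, nHomopolymers, replace = TRUE)
    hp_st <- sort(sample.int(length - 12L, nHomopolymers))
    hp <- GRanges(chrom, IRanges(hp_st, width = hp_w))
    hp <- hp[!duplicated(hp_st)]
    mcols(hp)$base <- NA_character_
    for (i in seq_along(hp)) {
      b <- sample(BASES, 1)
      bases[start(hp)[i]:end(hp)[i]] <- b
      mcols(hp)$base[i] <- b
    }
    alu <- ivals(nAlu, 300L); mcols(alu)$name <- "Alu"
    repeats <- ivals(nRepeats, 50L); mcols(repeats)$name <- "simple_repeat"
    junctions <- ivals(nIntrons, 400L); mcols(junctions)$name <- "intron"
    holeStart <- sort(sample.int(length - 200L, nMaskHoles))
    holes <- IRanges(holeStart, width = 150L)
    maskIr <- IRanges::setdiff(IRanges(1L, length), IRanges::reduce(holes))
    mask <- GRanges(chrom, maskIr); mcols(mask)$name <- "unique"
    seqset <- DNAStringSet(paste(bases, collapse = ""))
    names(seqset) <- chrom
    list(seq = seqset, chrom = chrom, alu = alu, repeats = repeats,
         junctions = junctions, mask = mask, homopolymers = hp)
  })
}

#' Plant editing-site and SNP truth on a simulated reference
#'
#' Chooses edit sites at reference A (plus strand) or T (minus strand)
#' positions and germline SNP sites at distinct positions; truth sites and
#' SNPs are disjoint by construction. Each edit site carries a parental and
#' a resistant true editing fraction.
#'
#' @param ref a reference from [simulateReference()].
#' @param nEdits planted (hyper-)edit sites.
#' @param nNull covered null sites (no editing in either role).
#' @param nSnps germline SNP sites (present in DNA and RNA).
#' @param parentalLevel,resistantLevel true editing fractions per role at
#'   planted sites (defaults 0 and 0.3: a delta of 0.3).
#' @param seed integer seed.
#' @return a list (`SimTruth`): data.frames `edits`, `nulls`, `snps`, plus
#'   the reference annotations carried through.
#' @export
simulateEditingTruth <- function(ref, nEdits, nNull, nSnps,
                                 parentalLevel = 0, resistantLevel = 0.3,
                                 seed = 1) {
  withStreamSeed(seed, 2L, {
    seqchar <- strsplit(as.character(ref$seq[[1]]), "")[[1]]
    isA <- which(seqchar == "A"); isT <- which(seqchar == "T")
    pool <- sort(c(isA, isT))
    need <- nEdits + nNull + nSnps
    if (length(pool) < need)
      stop("reference too short for requested site counts", call. = FALSE)
    picked <- sort(sample(pool, need))
    grp <- sample(rep(c("edit", "null", "snp"),
                      c(nEdits, nNull, nSnps)))
    mk <- function(pos) {
      refb <- seqchar[pos]
      data.frame(chrom = rep(ref$chrom, length(pos)), pos = pos, ref = refb,
                 strand = ifelse(refb == "A", "+", "-"),
                 alt = ifelse(refb == "A", "G", "C"),
                 stringsAsFactors = FALSE)
    }
    edits <- mk(picked[grp == "edit"])
    if (nrow(edits)) {
      edits$parentalLevel <- parentalLevel
      edits$resistantLevel <- resistantLevel
    }
    snps <- mk(picked[grp == "snp"])
    list(edits = edits, nulls = mk(picked[grp == "null"]), snps = snps,
         reference = ref, seed = seed)
  })
}
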