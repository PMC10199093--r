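test_that("organoid candidate thresholds are strictly exclusive (depth > 7, alt > 2)", {
  p <- tinyPileup(
    siteReads("chr1", 100, "A", "G", nRef = 5, nAlt = 3),   # depth 8, alt 3: kept
    siteReads("chr1", 200, "A", "G", nRef = 6, nAlt = 2),   # depth 8, alt 2: dropped
    siteReads("chr1", 300, "A", "G", nRef = 4, nAlt = 3),   # depth 7: dropped
    siteReads("chr1", 400, "C", "T", nRef = 15, nAlt = 5),  # not A-to-I: dropped
    siteReads("chr1", 500, "T", "C", nRef = 10, nAlt = 4))  # T>C minus strand: kept
  cand <- callCandidatesOrganoid(p)
  expect_setequal(siteKeys(cand), c("chr1:100:+", "chr1:500:-"))
  m <- S4Vectors::mcols(siteRanges(cand))
  expect_equal(m$variantClass[order(GenomicRanges::start(siteRanges(cand)))],
               c("A>G", "T>C"))
  expect_equal(sort(editingLevel(cand)), sort(c(3 / 8, 4 / 14)))
  expect_equal(nSites(callCandidatesOrganoid(pileupSet(
    data.frame(chrom = character(), pos = integer(), ref = character(),
               sample_id = character())))), 0L)
})

test_that("DNA subtraction removes exactly the matched positions", {
  rna <- randomSites(5, seed = 11)
  keys <- siteKeys(rna, stranded = FALSE)
  dna <- keys[c(2, 4)]
  out <- subtractDnaVariants(rna, dna)
  expect_equal(nSites(out), 3L)                       # 5 sites - 2 matches
  expect_setequal(siteKeys(out, stranded = FALSE), setdiff(keys, dna))
  expect_equal(siteKeys(subtractDnaVariants(rna, character())), siteKeys(rna))
  expect_error(subtractDnaVariants(rna, "1:12345"), "naming styles")
})

test_that("DNA variant evidence uses the any-alt >= 2 rule", {
  dna <- tinyPileup(
    siteReads("chr1", 100, "A", "G", nRef = 48, nAlt = 2),  # variant
    siteReads("chr1", 200, "A", "C", nRef = 49, nAlt = 1),  # not
    siteReads("chr1", 300, "T", "A", nRef = 10, nAlt = 5))  # variant (non A-to-I alt)
  expect_setequal(callDnaVariants(dna), c("chr1:100", "chr1:300"))
})

test_that("known-resource filter: literal conjunction of absences removes a site", {
  sites <- randomSites(10, seed = 7)
  keys <- siteKeys(sites)
  mkdb <- function(src, keep, tissues = "") {
    parts <- strsplit(keys[keep], ":", fixed = TRUE)
    knownSiteDB(src, data.frame(
      chrom = vapply(parts, `[`, "", 1),
      pos = as.integer(vapply(parts, `[`, "", 2)),
      strand = vapply(parts, `[`, "", 3), tissues = tissues))
  }
  radar <- mkdb("RADAR", 1:2)
  darned <- mkdb("DARNED", 3)
  atlas <- mkdb("ATLAS", c(4, 5), tissues = "stomach")
  ## hand enumeration: kept iff in radar (1,2) or darned (3) or stomach atlas (4,5)
  out <- filterKnownResources(sites, radar, darned, atlas)
  expect_setequal(siteKeys(out), keys[1:5])
  expect_match(S4Vectors::mcols(siteRanges(out))$annotations, "RADAR|DARNED|ATLAS")

  ## strict alternative: requires an editing db AND the tissue label
  atlas2 <- mkdb("ATLAS", c(1, 4), tissues = "stomach")
  out2 <- filterKnownResources(sites, radar, darned, atlas2,
                               mode = "any_resource")
  expect_setequal(siteKeys(out2), keys[1])

  ## atlas without tissue labels cannot participate
  expect_error(filterKnownResources(sites, radar, darned, mkdb("ATLAS", 1:3)),
               "tissue")
})

test_that("de novo calling censors low-mapq reads before support counting", {
  kept <- tinyPileup(siteReads("chr1", 10, "A", "G", nRef = 5, nAlt = 2))
  expect_equal(nSites(callCandidatesDenovo(kept)), 1L)
  ## one of two supporting reads below mapq 20 -> support 1 -> dropped
  lowq <- tinyPileup(siteReads("chr1", 10, "A", "G", nRef = 5, nAlt = 2,
                               mapqs = c(rep(60L, 5), 30L, 10L)))
  expect_equal(nSites(callCandidatesDenovo(lowq)), 0L)
  ## mapq 255 = unavailable passes, with a one-time log line
  nav <- tinyPileup(siteReads("chr1", 10, "A", "G", nRef = 5, nAlt = 2,
                              mapqs = rep(255L, 7)))
  expect_message(res <- callCandidatesDenovo(nav), "255")
  expect_equal(nSites(res), 1L)
  empty <- pileupSet(data.frame(chrom = "chr1", pos = 10L, ref = "A",
                                sample_id = "S1"))
  expect_equal(nSites(callCandidatesDenovo(empty)), 0L)
})

test_that("read-position filter censors 5'-end alt reads and recomputes levels", {
  p <- tinyPileup(
    siteReads("chr1", 10, "A", "G", nRef = 5, nAlt = 3,
              offsets = c(rep(50L, 5), 2L, 3L, 50L)),
    siteReads("chr1", 20, "A", "G", nRef = 5, nAlt = 3,
              offsets = c(rep(50L, 5), 7L, 8L, 9L)),
    siteReads("chr1", 30, "A", "G", nRef = 4, nAlt = 4,
              offsets = c(rep(50L, 4), 6L, 6L, 50L, 50L)))
  cand <- callCandidatesDenovo(p)
  expect_equal(nSites(cand), 3L)
  out <- filterReadPosition(cand, p)
  ## site 10: only 1 alt survives (offset 50) -> dropped
  expect_false("chr1:10:+" %in% siteKeys(out))
  ## site 20: offsets 7,8,9 all > 6 -> retained, level unchanged
  expect_true("chr1:20:+" %in% siteKeys(out))
  m <- S4Vectors::mcols(siteRanges(out))
  i20 <- which(GenomicRanges::start(siteRanges(out)) == 20)
  expect_equal(m$editingLevel[i20], 3 / 8)
  ## site 30: 2 of 4 alt at offset 6 censored -> level = 2/6 of surviving reads
  i30 <- which(GenomicRanges::start(siteRanges(out)) == 30)
  expect_equal(m$depth[i30], 6L)
  expect_equal(m$altDepth[i30], 2L)
  expect_equal(m$editingLevel[i30], 2 / 6)
})

test_that("SNP removal is a union over databases and order-independent", {
  sites <- randomSites(20, seed = 5)
  db1 <- randomDb(sites, 0.3, seed = 6, source = "SNP_1000G")
  db2 <- randomDb(sites, 0.3, seed = 7, source = "SNP_ESP")
  a <- filterSnps(sites, list(db1, db2))
  b <- filterSnps(filterSnps(sites, list(db1)), list(db2))
  c2 <- filterSnps(filterSnps(sites, list(db2)), list(db1))
  expect_setequal(siteKeys(a), siteKeys(b))
  expect_setequal(siteKeys(a), siteKeys(c2))
  inAny <- siteKeys(sites, stranded = FALSE) %in%
    c(siteKeys(db1, stranded = FALSE), siteKeys(db2, stranded = FALSE))
  expect_equal(nSites(a), sum(!inAny))
})

test_that("Alu-conditional filter removes junction-margin, homopolymer and repeat sites", {
  ## reference: positions 1..60; homopolymer AAAAA at 41..45
  seq <- paste0(paste(rep("ACGT", 10), collapse = ""),     # 1..40
                "AAAAA", "CGTACGTACGTACGT")                # 41..45, 46..60
  ref <- Biostrings::DNAStringSet(seq); names(ref) <- "chr1"
  alu <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 12))
  junctions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20, 35)) # intron
  repeats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 55))
  mk <- function(pos) editingSiteSet(data.frame(
    chrom = "chr1", pos = pos, strand = "+", ref = "A", alt = "G",
    depth = 10L, altDepth = 3L))
  run <- function(pos, aluGr = alu)
    nSites(filterNonAlu(mk(pos), aluGr, junctions, ref, repeats))
  expect_equal(run(22L), 0L)   # 3 bases into the intron from the 5' junction
  expect_equal(run(33L), 0L)   # 3 bases inside the 3' junction boundary
  expect_equal(run(27L), 1L)   # mid-intron, outside the 4-base margins
  ## the same junction-proximal coordinate inside an Alu bypasses the filter
  aluJ <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20, 24))
  expect_equal(run(22L, c(alu, aluJ)), 1L)
  expect_equal(run(5L), 1L)    # plain Alu-resident site kept
  expect_equal(run(43L), 0L)   # inside the AAAAA run
  expect_equal(run(52L), 0L)   # simple repeat
  expect_equal(run(47L), 1L)   # unremarkable non-Alu site survives
  expect_error(filterNonAlu(mk(999L), alu, junctions, ref, repeats),
               "reference lookup")
})

test_that("uniqueness mask keeps only covered sites", {
  sites <- randomSites(30, seed = 9)
  whole <- GenomicRanges::GRanges(c("chr1", "chr2"),
                                  IRanges::IRanges(1, 2e6))
  expect_equal(siteKeys(filterUniqueness(sites, whole)), siteKeys(sites))
  half <- GenomicRanges::GRanges(c("chr1", "chr2"),
                                 IRanges::IRanges(1, 5e5))
  out <- filterUniqueness(sites, half)
  inMask <- GenomicRanges::start(siteRanges(sites)) <= 5e5
  expect_equal(nSites(out), sum(inMask))
  expect_warning(none <- filterUniqueness(sites, GenomicRanges::GRanges()),
                 "empty uniqueness mask")
  expect_equal(nSites(none), 0L)
})

test_that("region annotation applies precedence and resolves transcript strand", {
  models <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 100, 300), c(200, 150, 400)),
    strand = c("-", "+", "+"))
  S4Vectors::mcols(models)$gene_id <- c("G1", "G2", "G3")
  S4Vectors::mcols(models)$gene_name <- c("SCD", "OTHER", "THIRD")
  S4Vectors::mcols(models)$feature <- c("THREE_UTR", "INTRON", "CDS")
  sites <- editingSiteSet(data.frame(
    chrom = "chr1", pos = c(120L, 350L, 900L),
    strand = c("-", "+", "+"),
    ref = c("T", "A", "A"), alt = c("C", "G", "G"),
    depth = 10L, altDepth = 3L))
  expect_message(ann <- annotateRegion(sites, models), "precedence")
  m <- S4Vectors::mcols(siteRanges(ann))
  ## genomic T>C in a minus-strand 3'UTR is A-to-I, and 3'UTR wins over intron
  expect_equal(m$region, c("THREE_UTR", "CDS", "INTERGENIC"))
  expect_equal(m$geneName[1], "SCD")
  expect_true(all(m$aToI))
  expect_equal(summarizeRegions(ann)[["THREE_UTR"]], 1L)
})
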