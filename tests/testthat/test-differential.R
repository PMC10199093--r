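## level tables for a fixed site list, given per-sample levels (NA = not measurable)
mkTables <- function(keys, ...) {
  lv <- list(...)
  parts <- strsplit(keys, ":", fixed = TRUE)
  base <- data.frame(key = keys,
                     chrom = vapply(parts, `[`, "", 1),
                     pos = as.integer(vapply(parts, `[`, "", 2)),
                     strand = vapply(parts, `[`, "", 3),
                     stringsAsFactors = FALSE)
  lapply(lv, function(v) { base$level <- v; base })
}

threePairs <- data.frame(line_id = c("L1", "L2", "L3"),
                         parental_id = c("P1", "P2", "P3"),
                         resistant_id = c("R1", "R2", "R3"),
                         stringsAsFactors = FALSE)

test_that("paired deltas are signed resistant-minus-parental with NA for non-evaluable", {
  keys <- c("chr1:10:+", "chr1:20:+")
  tb <- mkTables(keys,
                 P1 = c(0.10, NA), R1 = c(0.30, 0.5),
                 P2 = c(0.05, 0.2), R2 = c(0.05, 0.4),
                 P3 = c(0.20, 0.1), R3 = c(0.10, 0.3))
  names(tb) <- c("P1", "R1", "P2", "R2", "P3", "R3")
  dt <- pairDeltas(tb, threePairs)
  expect_equal(dt@delta["chr1:10:+", ], c(L1 = 0.20, L2 = 0, L3 = -0.10))
  ## site missing in a parental: that pair non-evaluable, not dropped
  expect_true(is.na(dt@delta["chr1:20:+", "L1"]))
  expect_equal(unname(dt@delta["chr1:20:+", "L2"]), 0.2)
  expect_equal(ncol(dt@delta), 3L)
  expect_error(pairDeltas(tb[-1], threePairs), "not found")
})

test_that("hyper-edit rule: at least a 0.10 increase in at least 2 of 3 lines, inclusive", {
  keys <- paste0("chr1:", 1:4, ":+")
  tb <- mkTables(keys,
                 P1 = rep(0, 4), R1 = c(0.12, 0.12, 0.10, 0.05),
                 P2 = rep(0, 4), R2 = c(0.11, 0.05, 0.10, 0.06),
                 P3 = rep(0, 4), R3 = c(0.05, 0.05, 0, 0.04))
  names(tb) <- c("P1", "R1", "P2", "R2", "P3", "R3")
  dt <- pairDeltas(tb, threePairs)
  ## deltas: site1 (+.12,+.11,+.05) called; site2 (+.12,+.05,+.05) not;
  ## site3 (+.10,+.10, 0) called at the inclusive boundary; site4 never
  expect_setequal(callHyperEdited(dt), keys[c(1, 3)])
  ## hypo direction and either direction
  tb2 <- mkTables(keys,
                  P1 = c(0.5, 0.5, 0.5, 0.5), R1 = c(0.3, 0.5, 0.62, 0.5),
                  P2 = c(0.5, 0.5, 0.5, 0.5), R2 = c(0.35, 0.5, 0.38, 0.5),
                  P3 = c(0.5, 0.5, 0.5, 0.5), R3 = c(0.5, 0.5, 0.5, 0.5))
  names(tb2) <- c("P1", "R1", "P2", "R2", "P3", "R3")
  dt2 <- pairDeltas(tb2, threePairs)
  expect_setequal(callHyperEdited(dt2, direction = "hypo"), keys[1])
  expect_setequal(callHyperEdited(dt2, direction = "either"), keys[c(1, 3)])
  expect_error(callHyperEdited(dt, minLines = 4), "exceeds")
})

test_that("hyper caller equals a brute-force double loop and is threshold-monotone", {
  set.seed(42)
  n <- 400
  keys <- paste0("chr1:", seq_len(n), ":+")
  mkLv <- function() runif(n)
  par <- replicate(3, mkLv()); res <- replicate(3, mkLv())
  par[sample(length(par), 150)] <- NA     # sprinkle non-evaluable pairs
  tb <- list(P1 = NULL, R1 = NULL, P2 = NULL, R2 = NULL, P3 = NULL, R3 = NULL)
  lv <- mkTables(keys, P1 = par[, 1], R1 = res[, 1], P2 = par[, 2],
                 R2 = res[, 2], P3 = par[, 3], R3 = res[, 3])
  names(lv) <- names(tb)
  dt <- pairDeltas(lv, threePairs)

  bruteForce <- function(minDelta, minLines) {
    out <- character()
    for (i in seq_len(n)) {
      hits <- 0L
      for (j in 1:3) {
        d <- res[i, j] - par[i, j]
        if (!is.na(d) && d >= minDelta) hits <- hits + 1L
      }
      if (hits >= minLines) out <- c(out, keys[i])
    }
    out
  }
  for (minDelta in c(0.05, 0.10, 0.30)) {
    for (minLines in 1:3) {
      expect_setequal(callHyperEdited(dt, minDelta, minLines),
                      bruteForce(minDelta, minLines))
    }
  }
  ## monotonicity: raising either threshold never enlarges the called set
  base <- callHyperEdited(dt, 0.10, 2)
  expect_true(all(callHyperEdited(dt, 0.20, 2) %in% base))
  expect_true(all(callHyperEdited(dt, 0.10, 3) %in% base))
})

test_that("region and process summaries count every called site exactly once", {
  sites <- editingSiteSet(data.frame(
    chrom = "chr1", pos = 1:8, strand = "+", ref = "A", alt = "G",
    depth = 10L, altDepth = 3L))
  models <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 4, 7), c(3, 6, 7)), strand = "+")
  S4Vectors::mcols(models)$gene_id <- c("G1", "G2", "G3")
  S4Vectors::mcols(models)$gene_name <- c("SCD", "CPT1A", "SOAT1")
  S4Vectors::mcols(models)$feature <- c("THREE_UTR", "INTRON", "CDS")
  ann <- annotateRegion(sites, models)
  counts <- summarizeRegions(ann)
  expect_equal(counts[["THREE_UTR"]], 3L)
  expect_equal(counts[["INTRON"]], 3L)
  expect_equal(counts[["CDS"]], 1L)
  expect_equal(counts[["INTERGENIC"]], 1L)
  expect_equal(sum(counts), nSites(ann))
  expect_equal(sum(summarizeRegions(editingSiteSet(data.frame()))), 0L)
  ## order invariance
  shuffled <- editomekit:::subsetSites(ann, c(5:8, 1:4))
  expect_equal(summarizeRegions(shuffled), counts)

  map <- data.frame(gene = c("SCD", "SCD", "CPT1A"),
                    process = c("lipid_metabolism", "desaturation",
                                "lipid_metabolism"))
  byGene <- groupByProcess(ann, map, mode = "gene")
  expect_equal(byGene[["lipid_metabolism"]], 2L)  # SCD + CPT1A once each
  expect_equal(byGene[["desaturation"]], 1L)      # multi-process gene counts in both
  expect_equal(byGene[["unannotated"]], 2L)       # SOAT1 + intergenic bucket
  bySite <- groupByProcess(ann, map, mode = "site")
  expect_equal(bySite[["lipid_metabolism"]], 6L)  # 3 SCD sites + 3 CPT1A sites
})
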