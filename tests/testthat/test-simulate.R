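test_that("reference simulation is deterministic with planted annotation truth", {
  r1 <- simulateReference(20000, seed = 5)
  r2 <- simulateReference(20000, seed = 5)
  expect_identical(as.character(r1$seq), as.character(r2$seq))
  expect_identical(r1$alu, r2$alu)
  ## planted homopolymer runs present at their recorded coordinates
  chars <- strsplit(as.character(r1$seq[[1]]), "")[[1]]
  hp <- r1$homopolymers
  for (i in seq_along(hp)) {
    run <- chars[GenomicRanges::start(hp)[i]:GenomicRanges::end(hp)[i]]
    expect_true(all(run == S4Vectors::mcols(hp)$base[i]))
  }
  ## every annotation interval within the reference
  for (gr in list(r1$alu, r1$repeats, r1$junctions, r1$mask, hp)) {
    expect_true(all(GenomicRanges::start(gr) >= 1))
    expect_true(all(GenomicRanges::end(gr) <= 20000))
  }
  expect_error(simulateReference(500, seed = 1), ">= 1000")
})

test_that("planted truth sites are disjoint between edits, nulls and SNPs", {
  ref <- simulateReference(50000, seed = 6)
  tr <- simulateEditingTruth(ref, nEdits = 30, nNull = 100, nSnps = 20,
                             seed = 6)
  keys <- c(tr$edits$pos, tr$nulls$pos, tr$snps$pos)
  expect_equal(anyDuplicated(keys), 0L)
  expect_equal(nrow(tr$edits), 30L)
  ## A ref sites are plus strand, T ref sites minus
  expect_true(all(tr$edits$strand[tr$edits$ref == "A"] == "+"))
  expect_true(all(tr$edits$strand[tr$edits$ref == "T"] == "-"))
})

test_that("simulated pileups honor the error model and planted fractions", {
  ref <- simulateReference(50000, seed = 7)
  tr <- simulateEditingTruth(ref, nEdits = 5, nNull = 40, nSnps = 5,
                             parentalLevel = 0, resistantLevel = 0.5, seed = 7)
  ## zero error rate: non-edit RNA sites and DNA at edit sites are pure reference
  pp <- simulatePileupPair(tr, "resistant", depthMean = 30, errorRate = 0,
                           seed = 7)
  o <- pp$rna@obs
  nullKeys <- paste(tr$nulls$chrom, tr$nulls$pos)
  atNull <- o[paste(o$chrom, o$pos) %in% nullKeys, ]
  refAt <- tr$nulls$ref[match(paste(atNull$chrom, atNull$pos), nullKeys)]
  expect_true(all(atNull$base == refAt))
  d <- pp$dna@obs
  editKeys <- paste(tr$edits$chrom, tr$edits$pos)
  atEdit <- d[paste(d$chrom, d$pos) %in% editKeys, ]
  refE <- tr$edits$ref[match(paste(atEdit$chrom, atEdit$pos), editKeys)]
  expect_true(all(atEdit$base == refE))

  ## planted fraction 0.5 at high depth recovered within binomial error
  tr2 <- simulateEditingTruth(ref, nEdits = 3, nNull = 3, nSnps = 0,
                              parentalLevel = 0, resistantLevel = 0.5, seed = 8)
  hi <- simulatePileupPair(tr2, "resistant", depthMean = 10000, errorRate = 0,
                           seed = 8)
  t <- editomekit:::tallySample(hi$rna)
  for (i in seq_len(nrow(tr2$edits))) {
    row <- t[t$pos == tr2$edits$pos[i], ]
    altN <- if (tr2$edits$ref[i] == "A") row$nG else row$nC
    expect_lt(abs(altN / row$depth - 0.5), 0.02)
  }
  expect_error(simulatePileupPair(tr, "parental", errorRate = 0.5),
               "0, 0.1")
})

test_that("simulated cohorts hit the target correlation with valid fractions", {
  coh <- simulateCohort(500, targetR = 0.5, seed = 31)
  expect_true(all(coh$scd1_editing >= 0 & coh$scd1_editing <= 1))
  expect_lt(abs(correlateExprEditing(coh)$r - 0.5), 0.08)
  expect_equal(mean(coh$signature_score), 0, tolerance = 1e-12)
  ## determinism
  expect_identical(coh, simulateCohort(500, targetR = 0.5, seed = 31))
  expect_error(simulateCohort(10, targetR = 1), "\\(-1, 1\\)")
})

test_that("a null survival effect leaves the strata indistinguishable", {
  skip_if_not_installed("survival")
  worse <- 0L; total <- 200L
  for (i in seq_len(total)) {
    coh <- simulateCohort(80, targetR = 0.5, hazardRatioPerUnitScore = 1,
                          censorFrac = 0.2, seed = 9000 + i)
    coh <- coh[coh$stratum != "EXCLUDED", ]
    fit <- survival::survfit(
      survival::Surv(survival_time, event) ~ stratum, data = coh)
    med <- summary(fit)$table[, "median"]
    hi <- med[grepl("HIGH", rownames(summary(fit)$table))]
    lo <- med[grepl("LOW", rownames(summary(fit)$table))]
    if (!is.na(hi) && !is.na(lo) && hi < lo) worse <- worse + 1L
  }
  ## under no effect the HIGH stratum is shorter-lived only about half the time
  expect_gt(worse / total, 0.25)
  expect_lt(worse / total, 0.75)
})

test_that("generators are pure functions of parameters and seed", {
  expect_identical(simulateLda(1 / 800, c(100, 1000), 24, seed = 12),
                   simulateLda(1 / 800, c(100, 1000), 24, seed = 12))
  ref <- simulateReference(30000, seed = 2)
  tr <- simulateEditingTruth(ref, 10, 20, 5, seed = 2)
  p1 <- simulatePileupPair(tr, "parental", seed = 3)
  p2 <- simulatePileupPair(tr, "parental", seed = 3)
  expect_identical(p1$rna@obs, p2$rna@obs)
  ## and the RNG stream of the caller is left untouched
  set.seed(99); before <- .Random.seed
  invisible(simulateCohort(50, seed = 1))
  expect_identical(.Random.seed, before)
})
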