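amps <- brafAmplicons()
ex15 <- amps$BRAF_ex15
cfg <- simConfig(seed = 5)

# align a read set (plain inserts) and call in targeted mode
callInserts <- function(inserts, config = callConfig()) {
  al <- alignReads(inserts, ex15)
  pp <- buildPileup(al, ex15)
  callVariants(pp, ex15, config)
}

test_that("pileup counts reads per position and per event", {
  wt <- ampliconSeq(ex15)
  mut <- spliceVariant(ex15, variantSubstitution(1799, "T", "A"))
  inserts <- setNames(c(rep(mut, 27), rep(wt, 73)), paste0("r", 1:100))
  al <- alignReads(inserts, ex15)
  pp <- buildPileup(al, ex15)
  expect_equal(pp@nReads, 100)
  expect_equal(depthAt(pp, 1799), 100)
  expect_equal(pp@subs$count[pp@subs$cdsPos == 1799], 27)
  # a single insertion read contributes one insertion event
  ins <- spliceVariant(ex15, variantInsertion(1797, "GATCTAGCTACA"))
  ppi <- buildPileup(alignReads(c(i1 = ins), ex15), ex15)
  expect_equal(nrow(ppi@ins), 1)
  expect_equal(ppi@ins$count, 1)
})

test_that("RMA is the proportion of reads containing the mutation", {
  expect_equal(computeRMA(27, 200), 0.135)
  expect_equal(computeRMA(0, 500), 0)
  expect_equal(computeRMA(250, 500), 0.5)
  expect_error(computeRMA(1, 0), "depth")
  expect_error(computeRMA(10, 5))
})

test_that("Wilson intervals behave at boundaries and match direct evaluation", {
  expect_equal(unname(wilsonCI(0, 500)["low"]), 0)
  ci50 <- wilsonCI(250, 500)
  expect_equal(unname(0.5 - ci50["low"]), unname(ci50["high"] - 0.5),
               tolerance = 1e-12)
  ci5 <- wilsonCI(5, 500)
  expect_equal(unname(ci5["low"]), 0.004279, tolerance = 1e-4)
  expect_equal(unname(ci5["high"]), 0.023193, tolerance = 1e-4)
  expect_true(all(wilsonCI(500, 500) <= 1))
})

test_that("detection thresholds come from exact binomial tails", {
  expect_identical(detectionThreshold(500, 0.002, 0.01), 5L)
  expect_identical(detectionThreshold(1000, 0.002, 0.001), 9L)
  expect_identical(detectionThreshold(1000, 0, 0.001), 1L)
  # definition check: c is the smallest count with tail <= bound
  cc <- detectionThreshold(750, 0.003, 0.005)
  expect_lte(pbinom(cc - 1, 750, 0.003, lower.tail = FALSE), 0.005)
  expect_gt(pbinom(cc - 2, 750, 0.003, lower.tail = FALSE), 0.005)
  expect_error(detectionThreshold(100, 0.002, 0.5, nSites = 0.4),
               "configuration|nSites")
})

test_that("limit of detection matches the assay's 1-2% operating window", {
  lod <- estimateLOD(1000)
  expect_equal(lod, 0.0144, tolerance = 1e-6)
  expect_lte(lod, 0.02)
  # closed form when any mutant read is significant (c = 1):
  # smallest f with 1 - (1-f)^n >= 0.95, about 3/n
  cfg0 <- callConfig(backgroundError = 0, alpha = 0.001)
  lod0 <- estimateLOD(1000, cfg0)
  fClosed <- 1 - (1 - 0.95)^(1 / 1000)
  expect_lt(abs(lod0 - fClosed), 1e-4 + 1e-9)   # grid resolution
  # monotonicity: doubling depth never raises the LOD
  expect_lte(estimateLOD(2000), estimateLOD(1000))
  expect_lte(estimateLOD(4000), estimateLOD(2000))
})

test_that("a mixed sample is called at its simulated fraction", {
  sp <- sampleSpec("p1", ampliconBarcodes(1), "BRAF_ex15",
                   variant = variantSubstitution(1799, "T", "A"),
                   trueFraction = 0.135, depth = 2000)
  b <- simulateSample(sp, ex15, errorModel(), cfg)
  tr <- trimReads(b$reads, cfg)
  calls <- callInserts(tr$inserts)
  hit <- calls[calls$label %in% "V600E", ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$detected)
  # recovered RMA consistent with the true fraction
  expect_true(hit$ciLow <= 0.135 && 0.135 <= hit$ciHigh)
  expect_false(any(calls$detected & !calls$label %in% "V600E"))
})

test_that("wild-type samples yield no detected hotspot call", {
  sp <- sampleSpec("wt", ampliconBarcodes(2)[2], "BRAF_ex15", depth = 1000)
  b <- simulateSample(sp, ex15, errorModel(), cfg)
  tr <- trimReads(b$reads, cfg)
  calls <- callInserts(tr$inserts)
  expect_false(any(calls$detected))
})

test_that("detection requires the threshold count and minimum depth", {
  wt <- ampliconSeq(ex15)
  mut <- spliceVariant(ex15, variantSubstitution(1799, "T", "A"))
  # 4 mutant reads of 1000: below the threshold of 9
  inserts <- setNames(c(rep(mut, 4), rep(wt, 996)), paste0("r", 1:1000))
  calls <- callInserts(inserts)
  row <- calls[calls$cdsPos == 1799 & calls$alt == "A", ]
  expect_equal(row$altCount, 4)
  expect_false(row$detected)
  # plenty of mutant reads but depth below minDepth: lowDepth flag
  few <- setNames(c(rep(mut, 40), rep(wt, 60)), paste0("s", 1:100))
  calls2 <- callInserts(few)
  row2 <- calls2[calls2$cdsPos == 1799, ]
  expect_false(row2$detected)
  expect_true(row2$lowDepth)
})

test_that("RMA recovery is unbiased beyond the background error", {
  fractions <- c(0.05, 0.1, 0.2, 0.4, 0.5)
  recovered <- vapply(seq_along(fractions), function(i) {
    sp <- sampleSpec(paste0("f", i), ampliconBarcodes(i)[i], "BRAF_ex15",
                     variant = variantSubstitution(1799, "T", "A"),
                     trueFraction = fractions[i], depth = 1000)
    b <- simulateSample(sp, ex15, errorModel(), cfg)
    tr <- trimReads(b$reads, cfg)
    calls <- callInserts(tr$inserts)
    calls$rma[calls$label %in% "V600E"][1]
  }, numeric(1))
  se <- sqrt(fractions * (1 - fractions) / 1000)
  expect_true(all(abs(recovered - fractions) < 3 * se + 0.002))
  # systematic upward bias from background errors stays below the error
  # rate; allow Monte-Carlo noise on the mean of five samples
  bias <- mean(recovered - fractions)
  mcSE <- sqrt(mean(fractions * (1 - fractions) / 1000) / length(fractions))
  expect_lt(bias, 0.002 + 3 * mcSE)
})

test_that("null samples rarely trigger detection (type-I control)", {
  # 60 wild-type samples at 600x: expected false detections per sample are
  # bounded by alpha per interrogated hotspot
  cfgN <- simConfig(seed = 17)
  nRep <- 60
  hits <- vapply(seq_len(nRep), function(k) {
    sp <- sampleSpec(paste0("null", k), ampliconBarcodes(1), "BRAF_ex15",
                     depth = 600)
    b <- simulateSample(sp, ex15, errorModel(),
                        simConfig(seed = 1000 + k))
    tr <- trimReads(b$reads, cfgN)
    any(callInserts(tr$inserts)$detected)
  }, logical(1))
  bound <- 0.001 * length(hotspots(ex15))
  expect_lte(sum(hits), nRep * bound + 3 * sqrt(nRep * bound * (1 - bound)))
})

test_that("discovery mode applies a Bonferroni threshold over sites", {
  wt <- ampliconSeq(ex15)
  mut <- spliceVariant(ex15, variantSubstitution(1751, "T", "C"))
  inserts <- setNames(c(rep(mut, 100), rep(wt, 900)), paste0("r", 1:1000))
  disc <- callInserts(inserts, callConfig(mode = "discovery"))
  row <- disc[disc$cdsPos == 1751, ]
  expect_equal(nrow(row), 1)            # non-hotspot site is evaluated
  expect_true(row$detected)
  expect_gte(row$thresholdCount, detectionThreshold(1000, 0.002, 0.001))
  targ <- callInserts(inserts, callConfig(mode = "targeted"))
  expect_false(1751 %in% targ$cdsPos)   # targeted mode ignores it
})

test_that("replicate support pools counts and requires joint detection", {
  wt <- ampliconSeq(ex15)
  mut <- spliceVariant(ex15, variantSubstitution(1799, "T", "A"))
  rep1 <- callInserts(setNames(c(rep(mut, 80), rep(wt, 920)),
                               paste0("a", 1:1000)))
  rep2 <- callInserts(setNames(c(rep(mut, 70), rep(wt, 930)),
                               paste0("b", 1:1000)))
  comb <- combineReplicates(list(rep1, rep2))
  row <- comb[comb$cdsPos == 1799, ]
  expect_true(row$confirmed)
  expect_equal(row$pooledRMA, 150 / 2000)
  # a variant present in only one replicate is not confirmed
  rep3 <- callInserts(setNames(rep(wt, 1000), paste0("c", 1:1000)))
  comb2 <- combineReplicates(list(rep1, rep3))
  expect_false(any(comb2$confirmed))
})

test_that("VCF output round-trips position, alleles and counts", {
  wt <- ampliconSeq(ex15)
  mutS <- spliceVariant(ex15, variantSubstitution(1799, "T", "A"))
  mutI <- spliceVariant(ex15, variantInsertion(1797, "GATCTAGCTACA"))
  inserts <- setNames(c(rep(mutS, 200), rep(mutI, 100), rep(wt, 700)),
                      paste0("r", 1:1000))
  calls <- callInserts(inserts)
  tf <- tempfile(fileext = ".vcf")
  writeCallsVCF(calls, ex15, tf)
  back <- readCallsVCF(tf)
  expect_equal(nrow(back), nrow(calls))
  expect_equal(back$cdsPos, calls$cdsPos)
  expect_equal(back$depth, calls$depth)
  expect_equal(back$altCount, calls$altCount)
  expect_equal(back$rma, calls$rma, tolerance = 1e-5)
  expect_identical(back$detected, calls$detected)
  expect_identical(back$label, calls$label)
  # substitution row holds ref/alt directly; insertion row is anchored
  sub <- back[back$label == "V600E", ]
  expect_identical(c(sub$ref, sub$alt), c("T", "A"))
  ins <- back[back$label == "600DLAT", ]
  expect_equal(nchar(ins$alt) - nchar(ins$ref), 12)
})
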