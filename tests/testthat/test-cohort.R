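test_that("bundled clinical table carries ages and the multisystem flag", {
  pts <- lchPatients()
  expect_equal(nrow(pts), 16)
  expect_true(all(pts$age_years >= 0))
  expect_identical(pts$patient[pts$multisystem], c(4L, 7L, 10L, 12L))
})

test_that("compartment profiles reproduce the published verdicts", {
  profiles <- compartmentProfiles()
  expect_length(profiles, 11)
  # patient 1: granuloma 13.5% detected, all three blood compartments wt
  expect_identical(classifyVariant(profiles[["1"]])$verdict, "somatic")
  expect_identical(classifyVariant(profiles[["2"]])$verdict, "somatic")
  # patient 16: granuloma 44%, blood 37-45% detected -> germline
  expect_identical(classifyVariant(profiles[["16"]])$verdict, "germline")
  # patients without blood data stay undetermined, never germline
  for (p in as.character(3:10)) {
    v <- classifyVariant(profiles[[p]])$verdict
    expect_identical(v, "undetermined")
  }
  expect_false(any(vapply(as.character(1:10), function(p)
    classifyVariant(profiles[[p]])$verdict, character(1)) == "germline"))
})

test_that("classification is invariant to compartment bookkeeping", {
  profiles <- compartmentProfiles()
  p1 <- profiles[["1"]]
  # reorder compartments
  shuffled <- compartmentProfile(p1@patient, p1@allele,
                                 p1@compartments[c(3, 1, 4, 2), ])
  expect_identical(classifyVariant(shuffled)$verdict,
                   classifyVariant(p1)$verdict)
  # adding an undetected lesional compartment never flips a somatic call
  extra <- rbind(p1@compartments,
                 data.frame(compartment = "effluent_gDNA", detected = FALSE,
                            rma = NA_real_, ciLow = NA_real_,
                            ciHigh = NA_real_))
  expect_identical(classifyVariant(compartmentProfile("1", "V600E",
                                                      extra))$verdict,
                   "somatic")
  # lesion-only detection with no blood assayed is undetermined
  lesionOnly <- compartmentProfile("x", "V600E", data.frame(
    compartment = "granuloma_total_gDNA", detected = TRUE, rma = 0.2,
    ciLow = 0.18, ciHigh = 0.23))
  expect_identical(classifyVariant(lesionOnly)$verdict, "undetermined")
})

test_that("Fisher exact p-values match the enumeration oracle", {
  expect_equal(fisherExact2x2(matrix(c(3, 8, 1, 4), 2, byrow = TRUE)), 1)
  expect_equal(fisherExact2x2(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(fisherExact2x2(matrix(c(0, 0, 3, 5), 2)), 1)  # zero margin
  expect_error(fisherExact2x2(matrix(c(-1, 1, 1, 1), 2)), "negative")
  set.seed(77)
  for (k in 1:50) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (sum(tab) == 0 || sum(tab) > 30) next
    expect_equal(fisherExact2x2(tab), oracle_fisher_2x2(tab),
                 tolerance = 1e-7, info = paste(tab, collapse = ","))
  }
})

test_that("Kruskal-Wallis reproduces the cohort age comparison", {
  pts <- lchPatients()
  mutated <- pts$patient %in% c(1:10, 16)
  kw <- kruskalWallis(list(pts$age_years[mutated], pts$age_years[!mutated]))
  expect_equal(kw$H, 0.5422, tolerance = 1e-3)
  expect_equal(kw$p, 0.4615, tolerance = 1e-3)
  expect_gt(kw$p, 0.05)
  # degenerate and extreme cases
  expect_equal(kruskalWallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)
  blocks <- kruskalWallis(list(1:8, 9:16))
  expect_lt(blocks$p, 0.01)
  expect_error(kruskalWallis(list(1:3, numeric(0))), "empty")
})

test_that("Kruskal-Wallis agrees with a permutation oracle", {
  pts <- lchPatients()
  mutated <- pts$patient %in% c(1:10, 16)
  groups <- list(pts$age_years[mutated], pts$age_years[!mutated])
  pPerm <- oracle_kw_perm(groups, B = 10000)
  pChi <- kruskalWallis(groups)$p
  # chi-square approximation vs exact permutation: agree within MC error
  # plus the approximation error expected at n = 16
  expect_lt(abs(pChi - pPerm), 0.05)
})

test_that("CD1a+ enrichment test flags the published contrasts", {
  # patient 8 cDNA: 48% vs 6% at 500x
  e8 <- enrichmentTest(list(altCount = 240, depth = 500),
                       list(altCount = 30, depth = 500))
  expect_true(e8$enriched)
  expect_lt(e8$p, 1e-6)
  expect_equal(e8$rmaRatio, 8)
  # patient 9 gDNA-style contrast: 47% vs 35% at 500x
  e9 <- enrichmentTest(list(altCount = 235, depth = 500),
                       list(altCount = 175, depth = 500))
  expect_true(e9$enriched)
  expect_lt(e9$p, 0.05)
  # identical counts: p = 1, not enriched
  eq <- enrichmentTest(list(altCount = 100, depth = 500),
                       list(altCount = 100, depth = 500))
  expect_equal(eq$p, 1)
  expect_false(eq$enriched)
  expect_error(enrichmentTest(list(altCount = 0, depth = 0),
                              list(altCount = 1, depth = 10)), "zero depth")
})

test_that("cohort summary reports the headline counts and tests", {
  sm <- summarizeCohort()
  expect_equal(sm$nPatients, 16)
  expect_equal(sm$nMutated, 11)
  expect_equal(unname(sm$alleleCounts[["V600E"]]), 9)
  expect_equal(unname(sm$alleleCounts[["600DLAT"]]), 1)
  expect_equal(unname(sm$alleleCounts[["T599A"]]), 1)
  expect_equal(sm$tests$multisystemTable,
               matrix(c(3, 8, 1, 4), 2, byrow = TRUE))
  expect_equal(sm$tests$fisherMultisystem, 1)
  expect_gt(sm$tests$kruskalWallisAge$p, 0.05)
  expect_identical(unname(sm$verdicts["16"]), "germline")
  # empty cohort: zero counts, tests skipped with a notice
  expect_message(sm0 <- summarizeCohort(lchPatients()[0, ], list()),
                 "skipped")
  expect_equal(sm0$nMutated, 0)
  expect_null(sm0$tests)
})
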