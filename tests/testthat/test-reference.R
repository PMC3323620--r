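test_that("genetic code and translation follow the standard code", {
  code <- geneticCode()
  expect_length(code, 64)
  expect_true(all(unlist(strsplit(names(code), "")) %in% c("A", "C", "G", "T")))
  expect_true(all(code %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*")))
  expect_identical(translateDNA("GTG"), "V")
  expect_identical(translateDNA("GAG"), "E")
  expect_identical(translateDNA("GATCTAGCTACA"), "DLAT")
  expect_error(translateDNA("GTGA"), "frame")
  expect_error(translateDNA("GTN"), "alphabet")
})

test_that("CDS positions map to codons by exact arithmetic", {
  expect_equal(cdsToCodon(1799), data.frame(codon = 600L, offset = 2L))
  expect_equal(cdsToCodon(1795), data.frame(codon = 599L, offset = 1L))
  expect_equal(cdsToCodon(1), data.frame(codon = 1L, offset = 1L))
  expect_error(cdsToCodon(0), "domain")
  # bijection between positions and (codon, offset) pairs
  m <- cdsToCodon(1:300)
  keys <- paste(m$codon, m$offset)
  expect_false(anyDuplicated(keys) > 0)
  expect_equal(3L * (m$codon - 1L) + m$offset, 1:300)
})

test_that("bundled amplicons carry the expected hotspot context", {
  amps <- brafAmplicons()
  amp <- amps$BRAF_ex15
  s <- ampliconSeq(amp)
  expect_identical(substr(s, cdsToLocal(amp, 1795), cdsToLocal(amp, 1797)),
                   "ACA")  # codon 599 = Thr
  expect_identical(substr(s, cdsToLocal(amp, 1798), cdsToLocal(amp, 1800)),
                   "GTG")  # codon 600 = Val
  expect_true(all(c(1795L, 1797L, 1799L) %in% hotspots(amp)))
  expect_error(referenceAmplicon("bad", "ACGT", 10, hotspots = 100L),
               "hotspot")
  expect_error(referenceAmplicon("bad", "ACGU", 1), "alphabet")
})

test_that("FASTA round trip preserves amplicon metadata", {
  amps <- brafAmplicons()
  tf <- tempfile(fileext = ".fasta")
  writeAmplicons(amps, tf)
  back <- readAmplicons(tf)
  expect_identical(names(back), names(amps))
  for (n in names(amps)) {
    expect_identical(ampliconSeq(back[[n]]), ampliconSeq(amps[[n]]))
    expect_identical(cdsStart(back[[n]]), cdsStart(amps[[n]]))
    expect_identical(hotspots(back[[n]]), hotspots(amps[[n]]))
  }
})

test_that("hotspot substitutions annotate to the known protein labels", {
  amp <- brafAmplicons()$BRAF_ex15
  v600e <- annotateSubstitution(amp, variantSubstitution(1799, "T", "A"))
  expect_identical(consequenceLabel(v600e), "V600E")
  expect_false(isSynonymous(v600e))
  t599a <- annotateSubstitution(amp, variantSubstitution(1795, "A", "G"))
  expect_identical(consequenceLabel(t599a), "T599A")
  # third-position wobble: ACA -> ACG both encode Thr
  syn <- annotateSubstitution(amp, variantSubstitution(1797, "A", "G"))
  expect_true(isSynonymous(syn))
  expect_identical(consequenceLabel(syn), "T599T")
  expect_error(annotateSubstitution(amp, variantSubstitution(1799, "G", "A")),
               "reference inconsistency")
})

test_that("in-frame insertions annotate via the protein diff convention", {
  amp <- brafAmplicons()$BRAF_ex15
  dlat <- variantInsertion(1797, "GATCTAGCTACA")
  pc <- annotateInsertion(amp, dlat)
  expect_identical(consequenceLabel(pc), "600DLAT")
  expect_identical(insertedPeptide(pc), "DLAT")
  expect_equal(nchar(insertedPeptide(pc)), 4)
  expect_identical(pc@context, "TDLATV")
  # the left-normalized nucleotide representation must give the same answer
  norm <- normalizeVariant(dlat, amp)
  expect_identical(variantLabel(norm), "1787insTCTAGCTACAGA")
  pcn <- annotateInsertion(amp, norm)
  expect_identical(consequenceLabel(pcn), "600DLAT")
  expect_identical(pcn@context, "TDLATV")
  # single-codon insertion at a codon boundary
  a <- annotateInsertion(amp, variantInsertion(1800, "GCT"))
  expect_identical(insertedPeptide(a), "A")
  expect_equal(nchar(insertedPeptide(a)), 1)
  expect_error(annotateInsertion(amp, variantInsertion(1797, "GATCTAGCTAC")),
               "frameshift")
  expect_error(annotateVariant(amp, variantDeletion(1795, "ACA")),
               "out of scope")
})

test_that("annotation agrees with the splice-translate-diff oracle", {
  amp <- brafAmplicons()$BRAF_ex15
  code <- geneticCode()
  # all hotspot alleles
  for (v in list(variantSubstitution(1799, "T", "A"),
                 variantSubstitution(1795, "A", "G"),
                 variantInsertion(1797, "GATCTAGCTACA"))) {
    d <- oracle_protein_diff(amp, v)
    pc <- annotateVariant(amp, v, code)
    expect_equal(pc@codonIndex, d$codon)
    if (d$kind == "insertion")
      expect_identical(insertedPeptide(pc), d$peptide)
    else
      expect_identical(consequenceLabel(pc),
                       paste0(d$refAA, d$codon, d$altAA))
  }
  # 100 random in-frame variants across the amplicon
  set.seed(991)
  s <- ampliconSeq(amp)
  for (k in 1:100) {
    if (k %% 2 == 0) {
      i <- sample(nchar(s), 1)
      ref <- substr(s, i, i)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      v <- variantSubstitution(localToCds(amp, i), ref, alt)
    } else {
      b <- sample(seq(3, nchar(s) - 3, by = 3), 1)   # codon boundary
      v <- variantInsertion(localToCds(amp, b), random_dna(3 * sample(1:4, 1)))
    }
    d <- oracle_protein_diff(amp, v)
    pc <- annotateVariant(amp, v, code)
    if (d$kind == "synonymous") {
      expect_true(isSynonymous(pc))
    } else if (d$kind == "substitution") {
      expect_identical(consequenceLabel(pc),
                       paste0(d$refAA, d$codon, d$altAA))
    } else {
      expect_equal(pc@codonIndex, d$codon)
      expect_identical(insertedPeptide(pc), d$peptide)
    }
  }
})

test_that("consequence report TSV writes and validates columns", {
  rep <- data.frame(sample = "s1", cds_change = "1799T>A", label = "V600E",
                    synonymous = FALSE)
  tf <- tempfile(fileext = ".tsv")
  writeConsequences(rep, tf)
  back <- read.delim(tf)
  expect_identical(back$label, "V600E")
  expect_error(writeConsequences(data.frame(a = 1), tf), "columns")
})
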