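#' @title Protein-level consequence of a cDNA variant
#'
#' @description Codon-level interpretation of a substitution or in-frame
#' insertion: the affected codon index, reference and alternate residues (or
#' inserted peptide), a compact label such as `"V600E"` or `"600DLAT"`, and
#' the local mutant protein context (e.g. `"TDLATV"` for the 12-nt
#' insertion, whose inserted Asp occupies position 600).
#'
#' @slot codonIndex 1-based codon number of the consequence.
#' @slot refAA Reference residue at `codonIndex` (empty for insertions).
#' @slot altAA Alternate residue (substitutions only).
#' @slot insertedPeptide Inserted residues (insertions only).
#' @slot label Compact name, regenerable from the other slots.
#' @slot synonymous TRUE when the protein is unchanged.
#' @slot context Local mutant protein motif around the event.
#' @export
setClass("ProteinConsequence",
  representation(codonIndex = "integer", refAA = "character",
                 altAA = "character", insertedPeptide = "character",
                 label = "character", synonymous = "logical",
                 context = "character"),
  validity = function(object) {
    msg <- character(0)
    if (object@codonIndex < 1L) msg <- c(msg, "codonIndex must be >= 1")
    expected <- if (nzchar(object@insertedPeptide))
      paste0(object@codonIndex, object@insertedPeptide)
    else paste0(object@refAA, object@codonIndex, object@altAA)
    if (object@label != expected)
      msg <- c(msg, sprintf("label '%s' not regenerable from fields ('%s')",
                            object@label, expected))
    if (length(msg)) msg else TRUE
  })

#' @describeIn ProteinConsequence-class compact label, e.g. `"V600E"`
#' @param x,object A `ProteinConsequence`.
#' @export
consequenceLabel <- function(x) x@label

#' @describeIn ProteinConsequence-class inserted peptide (empty for
#'   substitutions)
#' @export
insertedPeptide <- function(x) x@insertedPeptide

#' @describeIn ProteinConsequence-class is the event synonymous?
#' @export
isSynonymous <- function(x) x@synonymous

setMethod("show", "ProteinConsequence", function(object) {
  cat("ProteinConsequence:", object@label,
      if (object@synonymous) "(synonymous)" else "",
      "\n  context:", object@context, "\n")
})

# Amplicon segment trimmed to whole codons, with the codon index of its
# first codon. Used to translate reference/mutant sequence in frame.
.codonFrame <- function(amp) {
  lead <- (3L - (cdsStart(amp) - 1L) %% 3L) %% 3L  # bases before 1st full codon
  from <- 1L + lead
  len <- nchar(ampliconSeq(amp)) - lead
  len <- len - len %% 3L
  list(from = from, length = len,
       firstCodon = (cdsStart(amp) + lead - 1L) %/% 3L + 1L)
}

#' Annotate a coding substitution
#'
#' Builds the mutant codon by swapping the affected base and reports the
#' residue change, e.g. c.1799 T>A in the exon-15 amplicon gives `"V600E"`.
#'
#' @param amp A [ReferenceAmplicon-class] covering the variant.
#' @param v A substitution [VariantDescriptor-class].
#' @param code Genetic code, see [geneticCode()].
#' @return A [ProteinConsequence-class].
#' @examples
#' amp <- brafAmplicons()$BRAF_ex15
#' annotateSubstitution(amp, variantSubstitution(1799, "T", "A"))
#' @export
annotateSubstitution <- function(amp, v, code = geneticCode()) {
  stopifnot(is(v, "VariantDescriptor"), v@kind == "substitution")
  i <- cdsToLocal(amp, v@cdsPos)
  if (substr(ampliconSeq(amp), i, i) != v@ref)
    stop("reference inconsistency: amplicon has ",
         substr(ampliconSeq(amp), i, i), " at CDS ", v@cdsPos)
  cc <- cdsToCodon(v@cdsPos)
  codonStartCds <- 3L * (cc$codon - 1L) + 1L
  jj <- cdsToLocal(amp, codonStartCds)      # errors if codon truncated
  refCodon <- substr(ampliconSeq(amp), jj, jj + 2L)
  altCodon <- refCodon
  substr(altCodon, cc$offset, cc$offset) <- v@alt
  refAA <- unname(code[refCodon]); altAA <- unname(code[altCodon])
  new("ProteinConsequence", codonIndex = cc$codon, refAA = refAA,
      altAA = altAA, insertedPeptide = "",
      label = paste0(refAA, cc$codon, altAA),
      synonymous = identical(refAA, altAA),
      context = .mutantContext(amp, v, code))
}

# maximal-common-prefix/suffix diff between reference and mutant protein;
# returns the inserted peptide and the codon index it starts at
.proteinInsertionDiff <- function(refProt, mutProt, firstCodon) {
  nr <- nchar(refProt); nm <- nchar(mutProt)
  stopifnot(nm > nr)
  r <- strsplit(refProt, "")[[1]]; m <- strsplit(mutProt, "")[[1]]
  p <- 0L
  while (p < nr && r[p + 1L] == m[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < nr - p && r[nr - s] == m[nm - s]) s <- s + 1L
  # prefix maximality can overlap the suffix; inserted block sits after p
  list(codonIndex = firstCodon + p,
       peptide = paste(m[(p + 1L):(nm - s)], collapse = ""))
}

#' Annotate an in-frame coding insertion
#'
#' Translates reference and mutant amplicon in frame and reports the inserted
#' peptide by maximal-common-prefix protein diff. This convention names the
#' bundled 12-nt insertion `"600DLAT"` (inserted Asp occupying position 600,
#' local motif `TDLATV`) regardless of whether the nucleotide event is given
#' at its 3' anchor (after c.1797) or in left-normalized form.
#'
#' @inheritParams annotateSubstitution
#' @param v An insertion [VariantDescriptor-class]; length must be a
#'   multiple of 3 (frameshifts are out of scope).
#' @return A [ProteinConsequence-class].
#' @examples
#' amp <- brafAmplicons()$BRAF_ex15
#' annotateInsertion(amp, variantInsertion(1797, "GATCTAGCTACA"))
#' @export
annotateInsertion <- function(amp, v, code = geneticCode()) {
  stopifnot(is(v, "VariantDescriptor"), v@kind == "insertion")
  if (nchar(v@alt) == 0L) stop("domain error: empty insertion")
  if (!isInFrame(v))
    stop("frameshift error: insertion of ", nchar(v@alt),
         " nt is not a multiple of 3")
  fr <- .codonFrame(amp)
  refNt <- substr(ampliconSeq(amp), fr$from, fr$from + fr$length - 1L)
  mutFull <- spliceVariant(amp, v)
  # the insertion point is at local index i; splice preserved the leading
  # out-of-frame bases, so the same trim applies
  mutNt <- substr(mutFull, fr$from, fr$from + fr$length + nchar(v@alt) - 1L)
  refProt <- translateDNA(refNt, code)
  mutProt <- translateDNA(mutNt, code)
  d <- .proteinInsertionDiff(refProt, mutProt, fr$firstCodon)
  new("ProteinConsequence", codonIndex = d$codonIndex, refAA = "",
      altAA = "", insertedPeptide = d$peptide,
      label = paste0(d$codonIndex, d$peptide), synonymous = FALSE,
      context = .mutantContext(amp, v, code))
}

# local mutant protein motif: one reference residue either side of the event
.mutantContext <- function(amp, v, code) {
  fr <- .codonFrame(amp)
  mutFull <- spliceVariant(amp, v)
  extra <- if (v@kind == "insertion") nchar(v@alt)
           else if (v@kind == "deletion") -nchar(v@ref) else 0L
  mutNt <- substr(mutFull, fr$from, fr$from + fr$length + extra - 1L)
  mutProt <- translateDNA(mutNt, code)
  refProt <- translateDNA(substr(ampliconSeq(amp), fr$from,
                                 fr$from + fr$length - 1L), code)
  if (v@kind == "substitution") {
    k <- cdsToCodon(v@cdsPos)$codon - fr$firstCodon + 1L
    substr(mutProt, max(1L, k - 1L), min(nchar(mutProt), k + 1L))
  } else {
    d <- .proteinInsertionDiff(refProt, mutProt, fr$firstCodon)
    k <- d$codonIndex - fr$firstCodon + 1L        # mutant index of 1st inserted
    substr(mutProt, max(1L, k - 1L),
           min(nchar(mutProt), k + nchar(d$peptide)))
  }
}

#' Annotate any supported variant
#'
#' Dispatches to [annotateSubstitution()] or [annotateInsertion()].
#' Deletion consequences are out of scope and raise an error.
#'
#' @inheritParams annotateSubstitution
#' @param v A [VariantDescriptor-class].
#' @return A [ProteinConsequence-class].
#' @export
annotateVariant <- function(amp, v, code = geneticCode()) {
  switch(v@kind,
         substitution = annotateSubstitution(amp, v, code),
         insertion = annotateInsertion(amp, v, code),
         stop("deletion consequence annotation is out of scope"))
}

#' Write a consequence report as TSV
#'
#' @param report Data frame with at least columns `sample`, `cds_change`,
#'   `label`, `synonymous`.
#' @param path Output file.
#' @export
writeConsequences <- function(report, path) {
  need <- c("sample", "cds_change", "label", "synonymous")
  if (!all(need %in% names(report)))
    stop("report needs columns: ", paste(need, collapse = ", "))
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
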