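#' @title cDNA-level variant descriptor
#'
#' @description A single nucleotide-level event in 1-based CDS coordinates:
#' a substitution (`ref` and single-base `alt`), an insertion (`cdsPos` is
#' the base immediately 5' of the insertion point, `alt` the inserted DNA),
#' or a deletion (`ref` the deleted bases following `cdsPos`). Deletions are
#' tallied by the caller but carry no hotspot in this assay.
#'
#' @slot kind `"substitution"`, `"insertion"` or `"deletion"`.
#' @slot cdsPos 1-based CDS coordinate (anchor base for indels).
#' @slot ref Reference base(s); empty for insertions.
#' @slot alt Alternate base (substitution) or inserted DNA (insertion).
#' @export
setClass("VariantDescriptor",
  representation(kind = "character", cdsPos = "integer",
                 ref = "character", alt = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!object@kind %in% c("substitution", "insertion", "deletion"))
      msg <- c(msg, "kind must be substitution, insertion or deletion")
    if (object@cdsPos < 1L) msg <- c(msg, "cdsPos must be >= 1")
    if (object@kind == "substitution") {
      if (nchar(object@alt) != 1L || nchar(object@ref) != 1L)
        msg <- c(msg, "substitution needs single-base ref and alt")
      else if (object@alt == object@ref)
        msg <- c(msg, "substitution alt must differ from ref")
    }
    if (object@kind == "insertion" && nchar(object@alt) == 0L)
      msg <- c(msg, "insertion alt must be non-empty")
    if (object@kind == "deletion" && nchar(object@ref) == 0L)
      msg <- c(msg, "deletion ref must be non-empty")
    if (any(grepl("[^ACGT]", c(object@ref, object@alt))))
      msg <- c(msg, "ref/alt alphabet must be {A,C,G,T}")
    if (length(msg)) msg else TRUE
  })

#' Construct variant descriptors
#'
#' @param cdsPos 1-based CDS position; for insertions, the base immediately
#'   5' of the insertion point.
#' @param ref Reference base(s).
#' @param alt Alternate base or inserted DNA string.
#' @return A [VariantDescriptor-class].
#' @examples
#' variantSubstitution(1799, "T", "A")          # V600E at the cDNA level
#' variantInsertion(1797, "GATCTAGCTACA")       # 12-nt in-frame insertion
#' @export
variantSubstitution <- function(cdsPos, ref, alt)
  new("VariantDescriptor", kind = "substitution", cdsPos = as.integer(cdsPos),
      ref = toupper(ref), alt = toupper(alt))

#' @rdname variantSubstitution
#' @export
variantInsertion <- function(cdsPos, alt)
  new("VariantDescriptor", kind = "insertion", cdsPos = as.integer(cdsPos),
      ref = "", alt = toupper(alt))

#' @rdname variantSubstitution
#' @export
variantDeletion <- function(cdsPos, ref)
  new("VariantDescriptor", kind = "deletion", cdsPos = as.integer(cdsPos),
      ref = toupper(ref), alt = "")

#' @describeIn VariantDescriptor-class is an insertion in frame (length
#'   multiple of 3)?
#' @param x,object A `VariantDescriptor`.
#' @export
isInFrame <- function(x) {
  stopifnot(is(x, "VariantDescriptor"))
  switch(x@kind,
         substitution = TRUE,
         insertion = nchar(x@alt) %% 3L == 0L,
         deletion = nchar(x@ref) %% 3L == 0L)
}

#' @describeIn VariantDescriptor-class event kind
#' @export
variantKind <- function(x) x@kind

#' @describeIn VariantDescriptor-class 1-based CDS position
#' @export
variantCdsPos <- function(x) x@cdsPos

#' @describeIn VariantDescriptor-class compact cDNA-level label, e.g.
#'   `"1799T>A"` or `"1797insGATCTAGCTACA"`
#' @export
variantLabel <- function(x) {
  switch(x@kind,
         substitution = paste0(x@cdsPos, x@ref, ">", x@alt),
         insertion = paste0(x@cdsPos, "ins", x@alt),
         deletion = paste0(x@cdsPos, "del", x@ref))
}

setMethod("show", "VariantDescriptor", function(object) {
  cat("VariantDescriptor:", variantLabel(object), paste0("(", object@kind,
      if (object@kind != "substitution")
        paste0(", ", if (isInFrame(object)) "in-frame" else "frameshifting"),
      ")"), "\n")
})

#' Splice a variant into its reference amplicon
#'
#' Applies the event to the amplicon sequence, checking reference consistency
#' for substitutions and deletions.
#'
#' @param amp A [ReferenceAmplicon-class].
#' @param v A [VariantDescriptor-class].
#' @return Mutant amplicon sequence (character string).
#' @export
spliceVariant <- function(amp, v) {
  s <- ampliconSeq(amp)
  i <- cdsToLocal(amp, v@cdsPos)
  if (v@kind == "substitution") {
    if (substr(s, i, i) != v@ref)
      stop("reference inconsistency: amplicon has ", substr(s, i, i),
           " at CDS ", v@cdsPos, ", descriptor says ", v@ref)
    paste0(substr(s, 1L, i - 1L), v@alt, substr(s, i + 1L, nchar(s)))
  } else if (v@kind == "insertion") {
    paste0(substr(s, 1L, i), v@alt, substr(s, i + 1L, nchar(s)))
  } else {
    L <- nchar(v@ref)
    if (substr(s, i + 1L, i + L) != v@ref)
      stop("reference inconsistency: deletion ref does not match amplicon")
    paste0(substr(s, 1L, i), substr(s, i + L + 1L, nchar(s)))
  }
}

#' Left-normalize an indel against its reference
#'
#' Shifts insertion/deletion events to their 5'-most equivalent placement
#' (the representation produced by the aligner's event extraction), so that
#' identical alleles from different reads compare equal. Substitutions are
#' returned unchanged.
#'
#' @param v A [VariantDescriptor-class].
#' @param amp The [ReferenceAmplicon-class] the event refers to.
#' @return A normalized [VariantDescriptor-class].
#' @examples
#' amp <- brafAmplicons()$BRAF_ex15
#' normalizeVariant(variantInsertion(1797, "GATCTAGCTACA"), amp)
#' @export
normalizeVariant <- function(v, amp) {
  if (v@kind == "substitution") return(v)
  s <- ampliconSeq(amp)
  j <- cdsToLocal(amp, v@cdsPos)          # local index of the anchor base
  if (v@kind == "insertion") {
    ins <- v@alt
    while (j > 0L && substr(s, j, j) == substr(ins, nchar(ins), nchar(ins))) {
      ins <- paste0(substr(s, j, j), substr(ins, 1L, nchar(ins) - 1L))
      j <- j - 1L
    }
    variantInsertion(localToCds(amp, j + 1L) - 1L, ins)
  } else {
    L <- nchar(v@ref)
    while (j > 0L && substr(s, j, j) == substr(s, j + L, j + L)) j <- j - 1L
    variantDeletion(localToCds(amp, j + 1L) - 1L, substr(s, j + 1L, j + L))
  }
}
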