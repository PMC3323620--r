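#' The standard genetic code
#'
#' Returns the standard nuclear genetic code as a named character vector of
#' all 64 DNA codons mapped to one-letter amino-acid symbols (`*` for stop).
#'
#' @return Named character vector of length 64.
#' @examples
#' code <- geneticCode()
#' code[["GTG"]]  # "V"
#' @export
geneticCode <- function() {
  code <- Biostrings::GENETIC_CODE
  stopifnot(length(code) == 64L)
  code
}

#' Translate a DNA sequence
#'
#' In-frame translation of a DNA string using the standard genetic code.
#'
#' @param ntSeq DNA string; length must be a multiple of 3, alphabet ACGT.
#' @param code Genetic code as returned by [geneticCode()].
#' @return Amino-acid string of length `nchar(ntSeq)/3`.
#' @examples
#' translateDNA("GATCTAGCTACA")  # "DLAT"
#' @export
translateDNA <- function(ntSeq, code = geneticCode()) {
  stopifnot(is.character(ntSeq), length(ntSeq) == 1L)
  n <- nchar(ntSeq)
  if (n %% 3L != 0L)
    stop("frame error: sequence length ", n, " is not a multiple of 3")
  if (grepl("[^ACGT]", ntSeq))
    stop("alphabet error: sequence contains symbols outside {A,C,G,T}")
  if (n == 0L) return("")
  starts <- seq(1L, n, by = 3L)
  codons <- substring(ntSeq, starts, starts + 2L)
  paste(code[codons], collapse = "")
}

#' Map a CDS coordinate to its codon
#'
#' Converts 1-based coding-sequence positions to 1-based codon indices and
#' within-codon offsets, e.g. CDS 1799 lies at offset 2 of codon 600.
#'
#' @param cdsPos Integer vector of 1-based CDS positions.
#' @return Data frame with columns `codon` and `offset` (1..3).
#' @examples
#' cdsToCodon(c(1795, 1799))  # codons 599 and 600
#' @export
cdsToCodon <- function(cdsPos) {
  cdsPos <- as.integer(cdsPos)
  if (any(is.na(cdsPos)) || any(cdsPos < 1L))
    stop("domain error: CDS positions must be integers >= 1")
  codon <- (cdsPos + 2L) %/% 3L
  data.frame(codon = codon, offset = cdsPos - 3L * (codon - 1L))
}
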