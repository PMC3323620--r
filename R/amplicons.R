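#' @title Reference amplicon
#'
#' @description An amplified target region with its mapping into 1-based CDS
#' coordinates and the CDS positions of known hotspot variants. Amplicon-local
#' indices are 1-based internally; conversion helpers translate between the
#' two systems at the boundary.
#'
#' @slot name Amplicon identifier, e.g. `"BRAF_ex15"`.
#' @slot sequence Uppercase DNA string (alphabet ACGT).
#' @slot cdsStart 1-based CDS coordinate of the amplicon's first base.
#' @slot hotspots Integer CDS positions of known variants within the amplicon.
#' @export
setClass("ReferenceAmplicon",
  representation(name = "character", sequence = "character",
                 cdsStart = "integer", hotspots = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@sequence) != 1L || nchar(object@sequence) == 0L)
      msg <- c(msg, "sequence must be a single non-empty string")
    else if (grepl("[^ACGT]", object@sequence))
      msg <- c(msg, "sequence alphabet must be {A,C,G,T}")
    if (length(object@cdsStart) != 1L || object@cdsStart < 1L)
      msg <- c(msg, "cdsStart must be a single integer >= 1")
    else {
      end <- object@cdsStart + nchar(object@sequence) - 1L
      if (any(object@hotspots < object@cdsStart | object@hotspots > end))
        msg <- c(msg, "every hotspot must fall within the amplicon CDS range")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a reference amplicon
#'
#' @param name Amplicon identifier.
#' @param sequence Uppercase DNA string.
#' @param cdsStart 1-based CDS coordinate of the first base.
#' @param hotspots Integer CDS positions of known variants (may be empty).
#' @return A [ReferenceAmplicon-class] object.
#' @examples
#' amp <- referenceAmplicon("toy", "ATGGTGAAA", cdsStart = 1, hotspots = 5L)
#' @export
referenceAmplicon <- function(name, sequence, cdsStart, hotspots = integer(0)) {
  new("ReferenceAmplicon", name = as.character(name),
      sequence = toupper(as.character(sequence)),
      cdsStart = as.integer(cdsStart), hotspots = as.integer(hotspots))
}

#' @describeIn ReferenceAmplicon-class amplicon identifier
#' @param x,object A `ReferenceAmplicon`.
#' @export
ampliconName <- function(x) x@name

#' @describeIn ReferenceAmplicon-class amplicon DNA sequence as a string
#' @export
ampliconSeq <- function(x) x@sequence

#' @describeIn ReferenceAmplicon-class 1-based CDS coordinate of the first base
#' @export
cdsStart <- function(x) x@cdsStart

#' @describeIn ReferenceAmplicon-class last CDS coordinate of the amplicon
#' @export
cdsEnd <- function(x) x@cdsStart + nchar(x@sequence) - 1L

#' @describeIn ReferenceAmplicon-class CDS positions of known hotspots
#' @export
hotspots <- function(x) x@hotspots

#' Convert between CDS and amplicon-local coordinates
#'
#' @param amp A [ReferenceAmplicon-class].
#' @param cdsPos 1-based CDS position(s).
#' @return `cdsToLocal()`: 1-based offset(s) into the amplicon sequence;
#'   `localToCds()` the inverse.
#' @export
cdsToLocal <- function(amp, cdsPos) {
  idx <- as.integer(cdsPos) - amp@cdsStart + 1L
  if (any(idx < 1L | idx > nchar(amp@sequence)))
    stop("CDS position outside amplicon ", amp@name)
  idx
}

#' @rdname cdsToLocal
#' @param localPos 1-based offset(s) into the amplicon sequence.
#' @export
localToCds <- function(amp, localPos) amp@cdsStart + as.integer(localPos) - 1L

setMethod("show", "ReferenceAmplicon", function(object) {
  cat("ReferenceAmplicon", object@name, "\n",
      " ", nchar(object@sequence), "bp, CDS", object@cdsStart, "-",
      cdsEnd(object), "\n",
      "  hotspots:", if (length(object@hotspots))
        paste(object@hotspots, collapse = ", ") else "none", "\n")
})

#' Read reference amplicons from FASTA
#'
#' Headers carry the CDS offset and hotspot annotation as
#' `>name cds_start=<int> hotspots=<int>,<int>,...`.
#'
#' @param path FASTA file.
#' @return Named list of [ReferenceAmplicon-class] objects.
#' @export
readAmplicons <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  amps <- lapply(seq_along(seqs), function(i) {
    header <- names(seqs)[i]
    name <- sub("\\s.*$", "", header)
    cs <- regmatches(header, regexpr("cds_start=\\d+", header))
    if (!length(cs)) stop("header of '", name, "' lacks cds_start=")
    hs <- regmatches(header, regexpr("hotspots=[0-9,]+", header))
    referenceAmplicon(
      name, as.character(seqs[[i]]),
      cdsStart = as.integer(sub("cds_start=", "", cs)),
      hotspots = if (length(hs))
        as.integer(strsplit(sub("hotspots=", "", hs), ",")[[1]])
      else integer(0))
  })
  names(amps) <- vapply(amps, ampliconName, character(1))
  amps
}

#' Write reference amplicons to FASTA
#'
#' @param amps List of [ReferenceAmplicon-class] objects.
#' @param path Output FASTA file.
#' @export
writeAmplicons <- function(amps, path) {
  seqs <- Biostrings::DNAStringSet(vapply(amps, ampliconSeq, character(1)))
  names(seqs) <- vapply(amps, function(a)
    paste0(ampliconName(a), " cds_start=", cdsStart(a),
           if (length(hotspots(a)))
             paste0(" hotspots=", paste(hotspots(a), collapse = ","))
           else ""), character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Bundled B-RAF reference amplicons
#'
#' Exon-15 (CDS codons 582-611; codon 599 = ACA, codon 600 = GTG, hotspots
#' c.1795/c.1797/c.1799) and an abridged exon-11 P-loop segment.
#'
#' @return Named list of [ReferenceAmplicon-class] objects.
#' @examples
#' brafAmplicons()$BRAF_ex15
#' @export
brafAmplicons <- function() {
  readAmplicons(system.file("extdata", "braf_amplicons.fasta",
                            package = "rafamp", mustWork = TRUE))
}
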