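#' Alignment scoring scheme
#'
#' Affine-gap scoring for the semi-global aligner. A gap of length L costs
#' `gapOpen + (L - 1) * gapExtend`. The defaults strongly penalize gap
#' opening so that the 12-nt insertion allele is recovered as one event
#' rather than scattered mismatches.
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (< 0).
#' @param gapOpen Cost of the first gapped base (<= `gapExtend`).
#' @param gapExtend Cost of each further gapped base (< 0).
#' @param minScoreFrac Reads scoring below `minScoreFrac * match * length`
#'   are flagged unaligned and excluded from the pileup.
#' @return An object of class `ScoringScheme`.
#' @export
scoringScheme <- function(match = 2L, mismatch = -3L, gapOpen = -6L,
                          gapExtend = -1L, minScoreFrac = 0.6) {
  stopifnot(match > 0, mismatch < 0, gapExtend < 0, gapOpen <= gapExtend)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gapOpen = as.integer(gapOpen),
                 gapExtend = as.integer(gapExtend),
                 minScoreFrac = minScoreFrac),
            class = "ScoringScheme")
}

#' Semi-global alignment of an insert to a reference amplicon
#'
#' Optimal affine-gap alignment with the insert aligned end-to-end and free
#' leading/trailing reference positions (reads are amplicon-confined, so
#' ends are free only on the reference). Ties are broken toward the smallest
#' reference coordinate and indels are subsequently left-normalized by
#' [eventsOf()].
#'
#' @param insert DNA string (non-empty).
#' @param amp A [ReferenceAmplicon-class] (or plain reference string).
#' @param scheme A [scoringScheme()].
#' @return List with `score`, `refStart` (0-based offset of the first
#'   aligned reference base), `cigar` (over `M`, `I`, `D`; `M` is
#'   match-or-mismatch) and `aligned` (score filter verdict).
#' @examples
#' amp <- brafAmplicons()$BRAF_ex15
#' semiglobalAlign(substr(ampliconSeq(amp), 11, 70), amp)
#' @export
semiglobalAlign <- function(insert, amp, scheme = scoringScheme()) {
  if (!is.character(insert) || length(insert) != 1L || nchar(insert) == 0L)
    stop("domain error: insert must be a single non-empty DNA string")
  refSeq <- if (is(amp, "ReferenceAmplicon")) ampliconSeq(amp) else amp
  r <- .semiglobal_align_cpp(insert, refSeq, scheme$match, scheme$mismatch,
                             scheme$gapOpen, scheme$gapExtend)
  r$aligned <- r$score >= scheme$minScoreFrac * scheme$match * nchar(insert)
  r
}

# "12M1I3M" -> data.frame(op, len)
.parseCigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  if (length(ops) != length(lens)) stop("malformed CIGAR: ", cigar)
  data.frame(op = ops, len = lens)
}

#' Extract variant events from an alignment
#'
#' Walks the CIGAR and reports every mismatch as a substitution, every `I`
#' run as an insertion and every `D` run as a deletion, in CDS coordinates.
#' Indels are left-normalized ([normalizeVariant()]) so identical alleles
#' from different reads compare equal.
#'
#' @param aln Result of [semiglobalAlign()].
#' @param insert The aligned insert sequence.
#' @param amp The [ReferenceAmplicon-class] aligned against.
#' @return List of [VariantDescriptor-class] objects (empty for a perfect
#'   alignment).
#' @export
eventsOf <- function(aln, insert, amp) {
  df <- .eventsDF(aln, insert, amp)
  lapply(seq_len(nrow(df)), function(k)
    switch(df$kind[k],
           substitution = variantSubstitution(df$cdsPos[k], df$ref[k],
                                              df$alt[k]),
           insertion = variantInsertion(df$cdsPos[k], df$alt[k]),
           deletion = variantDeletion(df$cdsPos[k], df$ref[k])))
}

# data.frame version used by the pileup path: kind, cdsPos, ref, alt
.eventsDF <- function(aln, insert, amp) {
  refSeq <- ampliconSeq(amp)
  cig <- .parseCigar(aln$cigar)
  out <- list()
  i <- 0L                      # consumed insert bases
  j <- aln$ref_start           # consumed reference bases (0-based offset)
  for (k in seq_len(nrow(cig))) {
    L <- cig$len[k]
    op <- cig$op[k]
    if (op == "M") {
      rs <- substr(refSeq, j + 1L, j + L)
      qs <- substr(insert, i + 1L, i + L)
      if (rs != qs) {
        rv <- strsplit(rs, "")[[1]]; qv <- strsplit(qs, "")[[1]]
        mm <- which(rv != qv)
        for (p in mm)
          out[[length(out) + 1L]] <- data.frame(
            kind = "substitution", cdsPos = localToCds(amp, j + p),
            ref = rv[p], alt = qv[p])
      }
      i <- i + L; j <- j + L
    } else if (op == "I") {
      # anchor = CDS position of the base immediately 5' of the insertion
      anchor <- amp@cdsStart + j - 1L
      seq <- substr(insert, i + 1L, i + L)
      if (j > 0L) {
        v <- normalizeVariant(variantInsertion(anchor, seq), amp)
        anchor <- v@cdsPos; seq <- v@alt
      }
      out[[length(out) + 1L]] <- data.frame(
        kind = "insertion", cdsPos = anchor, ref = "", alt = seq)
      i <- i + L
    } else { # D
      anchor <- amp@cdsStart + j - 1L
      del <- substr(refSeq, j + 1L, j + L)
      if (j > 0L) {
        v <- normalizeVariant(variantDeletion(anchor, del), amp)
        anchor <- v@cdsPos; del <- v@ref
      }
      out[[length(out) + 1L]] <- data.frame(
        kind = "deletion", cdsPos = anchor, ref = del, alt = "")
      j <- j + L
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(kind = character(0), cdsPos = integer(0),
                  ref = character(0), alt = character(0))
}

#' Align a batch of inserts to one amplicon
#'
#' Aligns each distinct insert once (error-free amplicon reads are heavily
#' duplicated) and expands results back to reads.
#'
#' @param inserts Named character vector of insert sequences.
#' @param amp A [ReferenceAmplicon-class].
#' @param scheme A [scoringScheme()].
#' @return List with `alignments` (data frame: `read`, `score`, `refStart`,
#'   `cigar`, `aligned`) and `events` (data frame: `read`, `kind`, `cdsPos`,
#'   `ref`, `alt` for aligned reads only).
#' @export
alignReads <- function(inserts, amp, scheme = scoringScheme()) {
  uq <- unique(unname(inserts))
  res <- lapply(uq, function(s) semiglobalAlign(s, amp, scheme))
  idx <- match(unname(inserts), uq)
  alignments <- data.frame(
    read = names(inserts),
    score = vapply(res, `[[`, numeric(1), "score")[idx],
    refStart = vapply(res, `[[`, numeric(1), "ref_start")[idx],
    cigar = vapply(res, `[[`, character(1), "cigar")[idx],
    aligned = vapply(res, `[[`, logical(1), "aligned")[idx])
  evUq <- lapply(seq_along(uq), function(k) {
    if (!res[[k]]$aligned) return(NULL)
    df <- .eventsDF(res[[k]], uq[k], amp)
    if (nrow(df)) df$uq <- k
    df
  })
  evUq <- do.call(rbind, evUq[!vapply(evUq, is.null, logical(1))])
  events <- if (!is.null(evUq) && nrow(evUq)) {
    reps <- lapply(seq_len(nrow(evUq)), function(r) which(idx == evUq$uq[r]))
    data.frame(read = names(inserts)[unlist(reps)],
               kind = rep(evUq$kind, lengths(reps)),
               cdsPos = rep(evUq$cdsPos, lengths(reps)),
               ref = rep(evUq$ref, lengths(reps)),
               alt = rep(evUq$alt, lengths(reps)))
  } else data.frame(read = character(0), kind = character(0),
                    cdsPos = integer(0), ref = character(0),
                    alt = character(0))
  list(alignments = alignments, events = events)
}

#' Dump alignments as a SAM-style TSV
#'
#' @param alignments Alignment data frame from [alignReads()].
#' @param ampName Reference name to record.
#' @param path Output file.
#' @export
writeAlignmentsTSV <- function(alignments, ampName, path) {
  df <- data.frame(read = alignments$read, ref = ampName,
                   pos = alignments$refStart + 1L,
                   cigar = alignments$cigar, score = alignments$score,
                   aligned = alignments$aligned)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
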