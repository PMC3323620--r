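#' Caller configuration
#'
#' Operating point of the count-based caller: minimum depth for a confident
#' call (the assay's nominal 500x), the per-base background error
#' probability of the null model, the per-site tail bound, the calling mode
#' and the sensitivity goal used for limits of detection.
#'
#' @param minDepth Minimum depth for `detected = TRUE` (default 500).
#' @param backgroundError Per-base null error probability `e` (default
#'   0.002, matching the simulator's default substitution rate).
#' @param alpha Per-site null tail bound (default 0.001).
#' @param mode `"targeted"` (hotspots only, no multiplicity correction) or
#'   `"discovery"` (all positions, Bonferroni over interrogated sites).
#' @param z Normal quantile for Wilson confidence intervals (1.96 = 95%).
#' @param sensitivityGoal Detection probability required of the limit of
#'   detection (default 0.95).
#' @param insertionFlank Bases of reference flank a read must span on each
#'   side of an insertion anchor to count in the insertion denominator,
#'   keeping insertion and substitution RMAs comparable (default 12).
#' @return An object of class `CallConfig`.
#' @export
callConfig <- function(minDepth = 500L, backgroundError = 0.002,
                       alpha = 0.001, mode = c("targeted", "discovery"),
                       z = 1.96, sensitivityGoal = 0.95,
                       insertionFlank = 12L) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, backgroundError >= 0,
            backgroundError < 0.5, minDepth >= 1L, z > 0,
            sensitivityGoal > 0, sensitivityGoal < 1)
  structure(list(minDepth = as.integer(minDepth),
                 backgroundError = backgroundError, alpha = alpha,
                 mode = mode, z = z, sensitivityGoal = sensitivityGoal,
                 insertionFlank = as.integer(insertionFlank)),
            class = "CallConfig")
}

#' @title Per-amplicon pileup of aligned events
#'
#' @description Tallied evidence from one sample's aligned reads against one
#' amplicon: per-read reference spans (run-length compressed) and counts of
#' each distinct substitution, insertion (keyed by left-normalized anchor
#' and inserted sequence) and deletion event.
#'
#' @slot refName Amplicon name.
#' @slot cdsStart 1-based CDS coordinate of the amplicon's first base.
#' @slot refLength Amplicon length.
#' @slot nReads Number of aligned reads contributing.
#' @slot spans Data frame `start`, `end` (1-based local), `n`.
#' @slot subs Data frame `cdsPos`, `ref`, `alt`, `count`.
#' @slot ins Data frame `cdsPos` (anchor), `alt`, `count`.
#' @slot dels Data frame `cdsPos` (anchor), `ref`, `count`.
#' @export
setClass("AmpliconPileup",
  representation(refName = "character", cdsStart = "integer",
                 refLength = "integer", nReads = "integer",
                 spans = "data.frame", subs = "data.frame",
                 ins = "data.frame", dels = "data.frame"))

setMethod("show", "AmpliconPileup", function(object) {
  cat("AmpliconPileup on", object@refName, "\n",
      " ", object@nReads, "aligned reads;",
      nrow(object@subs), "distinct substitutions,",
      nrow(object@ins), "insertions,", nrow(object@dels), "deletions\n")
})

#' Build a pileup from batch alignments
#'
#' Each aligned read contributes one reference span and its extracted
#' events; unaligned reads are excluded.
#'
#' @param aligned Result of [alignReads()] (one amplicon per call; mixing
#'   amplicons is a configuration error caught upstream).
#' @param amp The [ReferenceAmplicon-class] aligned against.
#' @return An [AmpliconPileup-class].
#' @export
buildPileup <- function(aligned, amp) {
  al <- aligned$alignments[aligned$alignments$aligned, , drop = FALSE]
  ev <- aligned$events
  spanLen <- vapply(al$cigar, function(cg) {
    p <- .parseCigar(cg); sum(p$len[p$op != "I"])
  }, integer(1), USE.NAMES = FALSE)
  spans <- data.frame(start = al$refStart + 1L,
                      end = al$refStart + spanLen)
  spans <- stats::aggregate(list(n = rep(1L, nrow(spans))),
                            spans, FUN = sum)
  cnt <- function(df, cols) {
    if (nrow(df) == 0L)
      return(cbind(df[cols], data.frame(count = integer(0))))
    agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                            df[cols], FUN = sum)
    agg
  }
  subs <- cnt(ev[ev$kind == "substitution", , drop = FALSE],
              c("cdsPos", "ref", "alt"))
  ins <- cnt(ev[ev$kind == "insertion", , drop = FALSE], c("cdsPos", "alt"))
  dels <- cnt(ev[ev$kind == "deletion", , drop = FALSE], c("cdsPos", "ref"))
  new("AmpliconPileup", refName = ampliconName(amp),
      cdsStart = cdsStart(amp), refLength = nchar(ampliconSeq(amp)),
      nReads = nrow(al), spans = spans, subs = subs, ins = ins, dels = dels)
}

#' @describeIn AmpliconPileup-class read depth over a CDS interval: number
#'   of aligned reads whose reference span covers `[cdsFrom, cdsTo]`.
#' @param x An `AmpliconPileup`.
#' @param cdsFrom,cdsTo 1-based CDS interval (default a single position).
#' @export
depthAt <- function(x, cdsFrom, cdsTo = cdsFrom) {
  a <- cdsFrom - x@cdsStart + 1L
  b <- cdsTo - x@cdsStart + 1L
  sum(x@spans$n[x@spans$start <= a & x@spans$end >= b])
}

#' Relative mutation abundance
#'
#' The proportion of sequence reads that contain the mutation.
#'
#' @param altCount Reads carrying the variant.
#' @param depth Reads covering the position.
#' @return `altCount / depth`.
#' @examples
#' computeRMA(27, 200)  # 0.135
#' @export
computeRMA <- function(altCount, depth) {
  if (any(depth <= 0)) stop("undefined RMA: depth must be > 0")
  stopifnot(all(altCount >= 0), all(altCount <= depth))
  altCount / depth
}

#' Wilson score interval for a proportion
#'
#' @param altCount Successes.
#' @param depth Trials (> 0).
#' @param z Normal quantile (1.96 = 95%).
#' @return Named numeric vector `low`, `high` (or a two-column matrix for
#'   vector input).
#' @examples
#' wilsonCI(5, 500)
#' @export
wilsonCI <- function(altCount, depth, z = 1.96) {
  stopifnot(all(depth > 0))
  p <- altCount / depth
  denom <- 1 + z^2 / depth
  centre <- (p + z^2 / (2 * depth)) / denom
  half <- z * sqrt(p * (1 - p) / depth + z^2 / (4 * depth^2)) / denom
  if (length(p) == 1L) c(low = max(0, centre - half),
                         high = min(1, centre + half))
  else cbind(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Exact-binomial detection threshold
#'
#' Smallest alternate-read count `c` whose probability under the
#' background-error null `Binomial(depth, e)` satisfies
#' `P[X >= c] <= alpha / nSites` (exact tail, no normal approximation).
#'
#' @param depth Read depth (>= 1).
#' @param e Per-base background error probability.
#' @param alpha Per-site tail bound.
#' @param nSites Bonferroni factor: 1 in targeted mode, the number of
#'   interrogated sites in discovery mode.
#' @return Integer threshold count.
#' @examples
#' detectionThreshold(500, 0.002, 0.01)    # 5
#' detectionThreshold(1000, 0.002, 0.001)  # 9
#' @export
detectionThreshold <- function(depth, e, alpha, nSites = 1L) {
  stopifnot(depth >= 1L, nSites >= 1L)
  bound <- alpha / nSites
  if (bound >= 1) stop("configuration error: alpha/nSites must be < 1")
  if (e == 0) return(1L)
  cc <- 0L
  while (pbinom(cc - 1L, depth, e, lower.tail = FALSE) > bound) cc <- cc + 1L
  cc
}

#' Limit of detection at a given depth
#'
#' Smallest true mutant fraction (on a grid of 1e-4) detected with
#' probability at least `sensitivityGoal` by the exact-binomial rule of
#' [detectionThreshold()]. With defaults (e = 0.002, alpha = 0.001, 95%
#' sensitivity) the LOD at 1000x is about 1.4%, inside the assay's stated
#' 1-2% operating window.
#'
#' @param depth Read depth.
#' @param config A [callConfig()].
#' @param nSites Bonferroni factor passed to [detectionThreshold()].
#' @return Smallest detectable true fraction.
#' @examples
#' estimateLOD(1000)  # ~0.014
#' @export
estimateLOD <- function(depth, config = callConfig(), nSites = 1L) {
  cc <- detectionThreshold(depth, config$backgroundError, config$alpha,
                           nSites)
  grid <- seq(1e-4, 1, by = 1e-4)
  power <- pbinom(cc - 1L, depth, grid, lower.tail = FALSE)
  grid[which(power >= config$sensitivityGoal)[1]]
}

# detected insertion events matching a hotspot: an insertion's equivalent
# placement interval (left-normalized anchor .. right-shifted anchor + 1)
# must contain the hotspot position
.insertionPlacementRange <- function(amp, cdsAnchor, seq) {
  s <- ampliconSeq(amp)
  jL <- cdsAnchor - cdsStart(amp) + 1L
  j <- jL; ins <- seq
  repeat {
    nxt <- j + 1L
    if (nxt > nchar(s) || substr(s, nxt, nxt) != substr(ins, 1L, 1L)) break
    ins <- paste0(substr(ins, 2L, nchar(ins)), substr(s, nxt, nxt))
    j <- nxt
  }
  c(localToCds(amp, max(1L, jL)) - (jL < 1L), localToCds(amp, j) + 1L)
}

#' Call variants from a pileup
#'
#' In targeted mode, evaluates every observed substitution at a hotspot
#' position and every insertion event whose equivalent-placement interval
#' covers a hotspot anchor. In discovery mode, evaluates every observed
#' non-reference event, Bonferroni-correcting the detection threshold over
#' all interrogated reference positions. A variant is `detected` when its
#' supporting read count reaches the exact-binomial threshold and depth
#' reaches `minDepth`; hotspot calls below `minDepth` are reported with a
#' `lowDepth` flag rather than dropped.
#'
#' @param pileup An [AmpliconPileup-class].
#' @param amp The matching [ReferenceAmplicon-class].
#' @param config A [callConfig()].
#' @param code Genetic code for consequence annotation.
#' @return Data frame with one row per evaluated variant: descriptor fields,
#'   `altCount`, `depth`, `rma`, `ciLow`, `ciHigh`, `thresholdCount`,
#'   `detected`, `lowDepth`, `label` (protein consequence), `synonymous`.
#' @export
callVariants <- function(pileup, amp, config = callConfig(),
                         code = geneticCode()) {
  stopifnot(is(pileup, "AmpliconPileup"))
  if (pileup@refName != ampliconName(amp))
    stop("configuration error: pileup was built against ", pileup@refName)
  targeted <- config$mode == "targeted"
  nSites <- if (targeted) 1L else pileup@refLength
  subs <- pileup@subs
  ins <- pileup@ins
  if (targeted) {
    subs <- subs[subs$cdsPos %in% hotspots(amp), , drop = FALSE]
    if (nrow(ins)) {
      keep <- vapply(seq_len(nrow(ins)), function(k) {
        rng <- .insertionPlacementRange(amp, ins$cdsPos[k], ins$alt[k])
        any(hotspots(amp) >= rng[1] & hotspots(amp) <= rng[2])
      }, logical(1))
      ins <- ins[keep, , drop = FALSE]
    }
  }
  rows <- list()
  addRow <- function(kind, cdsPos, ref, alt, altCount, depth) {
    if (depth == 0L) return()
    thr <- detectionThreshold(depth, config$backgroundError, config$alpha,
                              nSites)
    rma <- computeRMA(altCount, depth)
    ci <- wilsonCI(altCount, depth, config$z)
    v <- switch(kind,
                substitution = variantSubstitution(cdsPos, ref, alt),
                insertion = variantInsertion(cdsPos, alt))
    cons <- tryCatch(annotateVariant(amp, v, code), error = function(e) NULL)
    rows[[length(rows) + 1L]] <<- data.frame(
      refName = pileup@refName, kind = kind, cdsPos = cdsPos,
      ref = ref, alt = alt, altCount = altCount, depth = depth,
      rma = rma, ciLow = unname(ci["low"]), ciHigh = unname(ci["high"]),
      thresholdCount = thr,
      detected = altCount >= thr && depth >= config$minDepth,
      lowDepth = depth < config$minDepth,
      label = if (is.null(cons)) NA_character_ else consequenceLabel(cons),
      synonymous = if (is.null(cons)) NA else isSynonymous(cons))
  }
  if (nrow(subs))
    for (k in seq_len(nrow(subs)))
      addRow("substitution", subs$cdsPos[k], subs$ref[k], subs$alt[k],
             subs$count[k], depthAt(pileup, subs$cdsPos[k]))
  if (nrow(ins))
    for (k in seq_len(nrow(ins))) {
      f <- config$insertionFlank
      d <- depthAt(pileup, max(cdsStart(amp), ins$cdsPos[k] - f + 1L),
                   min(cdsEnd(amp), ins$cdsPos[k] + f))
      addRow("insertion", ins$cdsPos[k], "", ins$alt[k], ins$count[k], d)
    }
  if (!targeted && nrow(pileup@dels))
    for (k in seq_len(nrow(pileup@dels))) {
      dd <- pileup@dels
      d <- depthAt(pileup, dd$cdsPos[k],
                   min(cdsEnd(amp), dd$cdsPos[k] + nchar(dd$ref[k])))
      if (d == 0L) next
      thr <- detectionThreshold(d, config$backgroundError, config$alpha,
                                nSites)
      ci <- wilsonCI(dd$count[k], d, config$z)
      rows[[length(rows) + 1L]] <- data.frame(
        refName = pileup@refName, kind = "deletion", cdsPos = dd$cdsPos[k],
        ref = dd$ref[k], alt = "", altCount = dd$count[k], depth = d,
        rma = computeRMA(dd$count[k], d), ciLow = unname(ci["low"]),
        ciHigh = unname(ci["high"]), thresholdCount = thr,
        detected = dd$count[k] >= thr && d >= config$minDepth,
        lowDepth = d < config$minDepth,
        label = NA_character_, synonymous = NA)
    }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(refName = character(0), kind = character(0),
                  cdsPos = integer(0), ref = character(0),
                  alt = character(0), altCount = integer(0),
                  depth = integer(0), rma = numeric(0), ciLow = numeric(0),
                  ciHigh = numeric(0), thresholdCount = integer(0),
                  detected = logical(0), lowDepth = logical(0),
                  label = character(0), synonymous = logical(0))
}

#' Combine replicate calls
#'
#' Independent PCR + sequencing replicates confirm a mutation when it is
#' detected in every replicate; the pooled RMA uses summed counts.
#'
#' @param callList List of call data frames (one per replicate) from
#'   [callVariants()].
#' @param config A [callConfig()].
#' @return Data frame keyed by variant with per-replicate RMAs, pooled RMA
#'   and a `confirmed` flag.
#' @export
combineReplicates <- function(callList, config = callConfig()) {
  stopifnot(length(callList) >= 1L)
  keyed <- lapply(callList, function(df) {
    df$key <- paste(df$kind, df$cdsPos, df$ref, df$alt, sep = ":")
    df
  })
  keys <- unique(unlist(lapply(keyed, `[[`, "key")))
  do.call(rbind, lapply(keys, function(k) {
    hits <- lapply(keyed, function(df) df[df$key == k, , drop = FALSE])
    present <- vapply(hits, nrow, integer(1)) > 0L
    alt <- sum(vapply(hits[present], function(h) h$altCount[1], numeric(1)))
    dep <- sum(vapply(hits[present], function(h) h$depth[1], numeric(1)))
    ex <- hits[present][[1]]
    data.frame(kind = ex$kind[1], cdsPos = ex$cdsPos[1], ref = ex$ref[1],
               alt = ex$alt[1], label = ex$label[1],
               rmaPerReplicate = paste(
                 vapply(hits, function(h)
                   if (nrow(h)) sprintf("%.4f", h$rma[1]) else "NA",
                   character(1)), collapse = ","),
               pooledRMA = alt / dep,
               confirmed = all(present) &&
                 all(vapply(hits, function(h) isTRUE(h$detected[1]),
                            logical(1))))
  }))
}

#' Write calls as minimal VCF 4.2
#'
#' CHROM is the amplicon name and POS the CDS coordinate. Substitutions are
#' written directly; insertions in the usual anchored form (REF = anchor
#' base, ALT = anchor + inserted sequence). INFO carries DP, AD, RMA,
#' DETECTED and CONSEQ.
#'
#' @param calls Call data frame from [callVariants()].
#' @param amp The [ReferenceAmplicon-class] the calls refer to.
#' @param path Output VCF file.
#' @export
writeCallsVCF <- function(calls, amp, path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", ampliconName(amp), ",length=",
                  nchar(ampliconSeq(amp)), ">"),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alternate read count\">",
           "##INFO=<ID=RMA,Number=1,Type=Float,Description=\"Relative mutation abundance\">",
           "##INFO=<ID=DETECTED,Number=1,Type=Integer,Description=\"Detection decision\">",
           "##INFO=<ID=CONSEQ,Number=1,Type=String,Description=\"Protein consequence\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  s <- ampliconSeq(amp)
  for (k in seq_len(nrow(calls))) {
    cl <- calls[k, ]
    if (cl$kind == "substitution") {
      pos <- cl$cdsPos; ref <- cl$ref; alt <- cl$alt
    } else if (cl$kind == "insertion") {
      i <- cdsToLocal(amp, cl$cdsPos)
      pos <- cl$cdsPos; ref <- substr(s, i, i)
      alt <- paste0(ref, cl$alt)
    } else {
      i <- cdsToLocal(amp, cl$cdsPos)
      pos <- cl$cdsPos
      ref <- substr(s, i, i + nchar(cl$ref))
      alt <- substr(s, i, i)
    }
    info <- sprintf("DP=%d;AD=%d;RMA=%.6g;DETECTED=%d;CONSEQ=%s",
                    cl$depth, cl$altCount, cl$rma, as.integer(cl$detected),
                    if (is.na(cl$label)) "." else cl$label)
    body <- c(body, paste(ampliconName(amp), pos, ".", ref, alt, ".",
                          "PASS", info, sep = "\t"))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read back a calls VCF
#'
#' @param path VCF written by [writeCallsVCF()].
#' @return Data frame `chrom`, `cdsPos`, `ref`, `alt`, `depth`, `altCount`,
#'   `rma`, `detected`, `label`.
#' @export
readCallsVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  getInfo <- function(info, key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    sub(paste0(key, "="), "", m)
  }
  data.frame(chrom = fix$CHROM, cdsPos = as.integer(fix$POS),
             ref = fix$REF, alt = fix$ALT,
             depth = as.integer(getInfo(fix$INFO, "DP")),
             altCount = as.integer(getInfo(fix$INFO, "AD")),
             rma = as.numeric(getInfo(fix$INFO, "RMA")),
             detected = getInfo(fix$INFO, "DETECTED") == "1",
             label = getInfo(fix$INFO, "CONSEQ"))
}
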