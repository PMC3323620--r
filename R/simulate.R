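#' Pyrosequencing-style error model
#'
#' Per-base substitution errors plus homopolymer-run length errors, the two
#' dominant error modes of flow-based pyrosequencing. A homopolymer run of
#' length \eqn{L \ge 2} gains or loses one base with probability
#' `homopolymerIndelRate * (L - 1)`. Rates of zero reproduce templates
#' exactly. Defaults are calibrated so that the default calling pipeline's
#' limit of detection lands in the 1-2% window at 500-1000x depth.
#'
#' @param subRate Per-base substitution probability.
#' @param homopolymerIndelRate Per-run scaling of the +/-1 length-error
#'   probability.
#' @return An object of class `ErrorModel` (a validated list).
#' @examples
#' errorModel()            # defaults: 0.002 / 0.001
#' errorModel(0, 0)        # error-free
#' @export
errorModel <- function(subRate = 0.002, homopolymerIndelRate = 0.001) {
  stopifnot(subRate >= 0, subRate <= 1,
            homopolymerIndelRate >= 0, homopolymerIndelRate <= 1)
  structure(list(subRate = subRate,
                 homopolymerIndelRate = homopolymerIndelRate),
            class = "ErrorModel")
}

#' Simulation configuration
#'
#' Universal tag sequences flanking every amplicon insert (added in the
#' second PCR round together with the sample barcode), the constant quality
#' symbol of emitted reads, and the master seed. The same seed and sample
#' specifications yield byte-identical output; each sample draws from its
#' own generator stream derived from `(seed, sampleId)`, so per-sample
#' results do not depend on simulation order.
#'
#' @param seed Integer master seed.
#' @param forwardTag,reverseTag Universal tag sequences.
#' @param qualityChar Constant Phred+33 symbol for emitted reads
#'   (default `"I"`, Q40; the caller is count-based and ignores qualities).
#' @return An object of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      forwardTag = "GCCTCCCTCGCGCCATCAG",
                      reverseTag = "GCCTTGCCAGCCCGCTCAG",
                      qualityChar = "I") {
  stopifnot(!grepl("[^ACGT]", forwardTag), !grepl("[^ACGT]", reverseTag),
            nchar(qualityChar) == 1L)
  structure(list(seed = as.integer(seed), forwardTag = forwardTag,
                 reverseTag = reverseTag, qualityChar = qualityChar),
            class = "SimConfig")
}

#' Built-in sample barcodes
#'
#' A fixed panel of 24 10-bp barcodes with pairwise Hamming distance >= 3
#' and no homopolymer run longer than 3.
#'
#' @param n Number of barcodes requested (<= 24).
#' @return Character vector of `n` barcodes.
#' @export
ampliconBarcodes <- function(n = 24L) {
  bc <- c("CATCCTCAGA", "ATGTCAATAT", "CCGTTCCTGT", "AGACATACGC",
          "ATCCGCAATT", "CCACTCTGAT", "AGTATGGCCC", "GCCAAGAAGA",
          "TTATTAAATG", "ACTGACCTTC", "TGGCGTAAGG", "CTCGAAGTTG",
          "AACTAGTATT", "GGTCGATCAC", "TGCTCCAGAG", "ATAGCGAGCT",
          "GTCGAAATAC", "AACCTCTGTT", "TCGCTTGGGC", "GGATCTGGTG",
          "CTCAGCTCGT", "AGTGGCCCGC", "GCGGTCCATA", "CTCGAAGCCT")
  stopifnot(n >= 1L, n <= length(bc))
  bc[seq_len(n)]
}

#' Per-sample simulation specification
#'
#' @param sampleId Sample identifier.
#' @param barcode 10-base sample barcode.
#' @param amplicon Name of the reference amplicon sequenced for this sample.
#' @param variant A [VariantDescriptor-class] carried by mutant reads, or
#'   `NULL` for wild type.
#' @param trueFraction True mutant allele fraction in `[0, 1]`; must be 0
#'   when `variant` is `NULL`.
#' @param depth Number of reads to emit (>= 1); 500x is the assay's nominal
#'   coverage.
#' @return An object of class `SampleSpec`.
#' @export
sampleSpec <- function(sampleId, barcode, amplicon, variant = NULL,
                       trueFraction = 0, depth = 500L) {
  stopifnot(nchar(barcode) == 10L, !grepl("[^ACGT]", barcode),
            depth >= 1L, trueFraction >= 0, trueFraction <= 1,
            is.null(variant) || is(variant, "VariantDescriptor"))
  if (is.null(variant) && trueFraction > 0)
    stop("trueFraction > 0 requires a variant")
  structure(list(sampleId = as.character(sampleId), barcode = barcode,
                 amplicon = amplicon, variant = variant,
                 trueFraction = trueFraction, depth = as.integer(depth)),
            class = "SampleSpec")
}

# deterministic 31-bit stream seed from (master seed, sample id)
.sampleSeed <- function(seed, sampleId) {
  h <- 0
  for (k in utf8ToInt(sampleId)) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Build the full read template for a sample
#'
#' Layout: `barcode + forwardTag + insert + reverseTag`, where the insert is
#' the reference amplicon or, for mutant templates, the amplicon with the
#' sample's variant spliced in.
#'
#' @param amp A [ReferenceAmplicon-class].
#' @param spec A [sampleSpec()].
#' @param cfg A [simConfig()].
#' @param mutant Emit the variant-spliced insert?
#' @return DNA string.
#' @export
makeTemplate <- function(amp, spec, cfg, mutant = FALSE) {
  insert <- if (mutant) {
    if (is.null(spec$variant)) stop("mutant template requested without variant")
    spliceVariant(amp, spec$variant)
  } else ampliconSeq(amp)
  paste0(spec$barcode, cfg$forwardTag, insert, cfg$reverseTag)
}

#' Apply sequencing errors to reads
#'
#' Substitution errors are drawn independently per base; then each
#' homopolymer run of length >= 2 in the substituted read is lengthened or
#' shortened by one base (equiprobably) with probability
#' `homopolymerIndelRate * (runLength - 1)`. Uses the current RNG state.
#'
#' @param reads Character vector of DNA strings.
#' @param err An [errorModel()].
#' @return Character vector of mutated reads.
#' @export
applyErrors <- function(reads, err) {
  stopifnot(inherits(err, "ErrorModel"))
  if (err$subRate == 0 && err$homopolymerIndelRate == 0) return(reads)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(reads, "")
  if (err$subRate > 0) {
    lens <- lengths(chars)
    flat <- unlist(chars, use.names = FALSE)
    hit <- which(runif(length(flat)) < err$subRate)
    if (length(hit)) {
      # substitute with one of the three other bases, uniformly
      repl <- vapply(flat[hit],
                     function(b) sample(setdiff(bases, b), 1L), character(1),
                     USE.NAMES = FALSE)
      flat[hit] <- repl
      chars <- split(flat, rep.int(seq_along(lens), lens))
    }
  }
  if (err$homopolymerIndelRate > 0) {
    chars <- lapply(chars, function(v) {
      r <- rle(v)
      long <- which(r$lengths >= 2L)
      if (length(long)) {
        p <- pmin(1, err$homopolymerIndelRate * (r$lengths[long] - 1L))
        ev <- long[runif(length(long)) < p]
        if (length(ev)) {
          delta <- sample(c(-1L, 1L), length(ev), replace = TRUE)
          r$lengths[ev] <- pmax(1L, r$lengths[ev] + delta)
          v <- inverse.rle(r)
        }
      }
      v
    })
  }
  vapply(chars, paste, character(1), collapse = "")
}

#' Simulate one sample's read batch
#'
#' Emits exactly `spec$depth` reads. Each read is independently drawn mutant
#' with probability `spec$trueFraction`, built from the corresponding
#' template and passed through [applyErrors()]. The returned truth sidecar
#' records the per-read allele.
#'
#' @param spec A [sampleSpec()].
#' @param amp The sample's [ReferenceAmplicon-class].
#' @param err An [errorModel()].
#' @param cfg A [simConfig()]; the sample's RNG stream is derived from
#'   `cfg$seed` and `spec$sampleId`.
#' @return List with `reads` (named character vector) and `truth`
#'   (data frame `read`, `sample`, `mutant`).
#' @export
simulateSample <- function(spec, amp, err = errorModel(), cfg = simConfig()) {
  stopifnot(inherits(spec, "SampleSpec"))
  if (!is.null(spec$variant))      # validates range against the amplicon
    invisible(spliceVariant(amp, spec$variant))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.sampleSeed(cfg$seed, spec$sampleId))
  wt <- makeTemplate(amp, spec, cfg, mutant = FALSE)
  mut <- if (!is.null(spec$variant)) makeTemplate(amp, spec, cfg, mutant = TRUE)
  isMut <- if (spec$trueFraction > 0)
    runif(spec$depth) < spec$trueFraction else rep(FALSE, spec$depth)
  templates <- rep(wt, spec$depth)
  if (!is.null(mut)) templates[isMut] <- mut
  reads <- applyErrors(templates, err)
  ids <- sprintf("%s_read%05d", spec$sampleId, seq_len(spec$depth))
  names(reads) <- ids
  list(reads = reads,
       truth = data.frame(read = ids, sample = spec$sampleId,
                          mutant = isMut))
}

#' Simulate a full sequencing run and write it to disk
#'
#' Simulates every sample, then writes a single Phred+33 FASTQ, a sample
#' sheet TSV (`sample_id`, `barcode`, `amplicon`) and a truth TSV with the
#' per-sample true fractions and per-read alleles. Output is byte-identical
#' for identical seeds and specifications.
#'
#' @param specs List of [sampleSpec()] objects.
#' @param amps Named list of [ReferenceAmplicon-class] objects.
#' @param err An [errorModel()].
#' @param cfg A [simConfig()].
#' @param dir Output directory (created if needed); `NULL` keeps everything
#'   in memory.
#' @return List with `reads`, `truth`, `sheet` and (if `dir` given) `paths`.
#' @export
simulateRun <- function(specs, amps, err = errorModel(), cfg = simConfig(),
                        dir = NULL) {
  stopifnot(length(specs) > 0)
  batches <- lapply(specs, function(sp) {
    amp <- amps[[sp$amplicon]]
    if (is.null(amp)) stop("unknown amplicon '", sp$amplicon, "'")
    simulateSample(sp, amp, err, cfg)
  })
  reads <- unlist(lapply(batches, `[[`, "reads"))
  truth <- do.call(rbind, lapply(batches, `[[`, "truth"))
  truth$true_fraction <- vapply(truth$sample, function(s)
    specs[[match(s, vapply(specs, `[[`, "", "sampleId"))]]$trueFraction,
    numeric(1))
  sheet <- data.frame(
    sample_id = vapply(specs, `[[`, "", "sampleId"),
    barcode = vapply(specs, `[[`, "", "barcode"),
    amplicon = vapply(specs, `[[`, "", "amplicon"))
  out <- list(reads = reads, truth = truth, sheet = sheet)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fq <- file.path(dir, "reads.fastq")
    writeFastq(reads, fq, qualityChar = cfg$qualityChar)
    ss <- file.path(dir, "sample_sheet.tsv")
    write.table(sheet, ss, sep = "\t", quote = FALSE, row.names = FALSE)
    tt <- file.path(dir, "truth.tsv")
    write.table(truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- c(fastq = fq, sheet = ss, truth = tt)
  }
  out
}

#' Write reads as Sanger FASTQ (Phred+33)
#'
#' @param reads Named character vector of DNA strings.
#' @param path Output FASTQ file.
#' @param qualityChar Constant quality symbol.
#' @export
writeFastq <- function(reads, path, qualityChar = "I") {
  seqs <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(strrep(qualityChar,
                                         nchar(as.character(reads))))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file as a named character vector
#'
#' @param path FASTQ file (Phred+33).
#' @return Named character vector of read sequences.
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
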