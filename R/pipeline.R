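#' Variant descriptor for a named allele
#'
#' Maps the cohort's allele labels to their cDNA-level events: `V600E` =
#' c.1799 T>A, `T599A` = c.1795 A>G, `600DLAT` = 12-nt in-frame insertion
#' after c.1797.
#'
#' @param label Allele label (`"V600E"`, `"T599A"`, `"600DLAT"` or `"wt"`).
#' @return A [VariantDescriptor-class], or `NULL` for `"wt"`.
#' @export
alleleVariant <- function(label) {
  switch(label,
         V600E = variantSubstitution(1799, "T", "A"),
         T599A = variantSubstitution(1795, "A", "G"),
         `600DLAT` = variantInsertion(1797, "GATCTAGCTACA"),
         wt = NULL,
         stop("unknown allele label '", label, "'"))
}

#' Sample specifications for a granuloma cohort simulation
#'
#' Builds one [sampleSpec()] per patient in the compartment table, using
#' each patient's first available granuloma fraction (total gDNA, else
#' CD1a+ gDNA) as the true mutant fraction; wild-type patients simulate at
#' fraction 0. All samples draw the exon-15 amplicon and a barcode from the
#' built-in panel.
#'
#' @param tab Compartment table, see [lchCompartments()].
#' @param depth Reads per sample.
#' @return List of [sampleSpec()] objects named by patient.
#' @export
granulomaSampleSpecs <- function(tab = lchCompartments(), depth = 1000L) {
  patients <- unique(tab$patient)
  bcs <- ampliconBarcodes(length(patients))
  specs <- lapply(seq_along(patients), function(i) {
    p <- patients[i]
    rows <- tab[tab$patient == p &
                tab$compartment %in% c("granuloma_total_gDNA", "CD1a_gDNA"), ,
                drop = FALSE]
    rows <- rows[order(match(rows$compartment,
                             c("granuloma_total_gDNA", "CD1a_gDNA"))), ,
                 drop = FALSE]
    mut <- rows[rows$allele != "wt", , drop = FALSE]
    if (nrow(mut)) {
      sampleSpec(paste0("patient", p), bcs[i], "BRAF_ex15",
                 variant = alleleVariant(mut$allele[1]),
                 trueFraction = mut$rma_percent[1] / 100, depth = depth)
    } else {
      sampleSpec(paste0("patient", p), bcs[i], "BRAF_ex15",
                 trueFraction = 0, depth = depth)
    }
  })
  names(specs) <- paste0("patient", patients)
  specs
}

#' Run the demultiplex-align-call pipeline
#'
#' Demultiplexes a read set against a sample sheet, trims barcodes and
#' universal tags, aligns each sample's inserts to its amplicon, builds
#' pileups and calls variants. A failure in one sample is logged and
#' skipped; it never aborts the remaining samples.
#'
#' @param reads Named character vector of reads, or a FASTQ path.
#' @param sheet A [sampleSheet()] (or sample-sheet TSV path).
#' @param amps Named list of [ReferenceAmplicon-class] objects.
#' @param cfg A [simConfig()] (supplies the universal tag sequences).
#' @param config A [callConfig()].
#' @param scheme A [scoringScheme()].
#' @param maxMismatch Barcode mismatch tolerance for [demultiplex()].
#' @param outDir Optional output directory for `demux_stats.tsv`,
#'   `calls.tsv`, per-sample VCFs and a run manifest.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return List of class `pipelineResult`: `calls` (per-sample call data
#'   frames), `demuxStats`, `trimStats`, `failures` (named character).
#' @export
runPipeline <- function(reads, sheet, amps = brafAmplicons(),
                        cfg = simConfig(), config = callConfig(),
                        scheme = scoringScheme(), maxMismatch = 1L,
                        outDir = NULL, seed = NA_integer_) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- readFastq(reads)
  if (is.character(sheet) && length(sheet) == 1L && file.exists(sheet))
    sheet <- readSampleSheet(sheet)
  missingAmps <- setdiff(unique(sheet$amplicon), names(amps))
  if (length(missingAmps))
    stop("startup error: no reference for amplicon(s) ",
         paste(missingAmps, collapse = ", "))
  dm <- demultiplex(reads, sheet, maxMismatch)
  calls <- list()
  failures <- character(0)
  trimStats <- list()
  for (k in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[k]
    amp <- amps[[sheet$amplicon[k]]]
    res <- tryCatch({
      tr <- trimReads(dm$perSample[[sid]], cfg)
      al <- alignReads(tr$inserts, amp, scheme)
      pp <- buildPileup(al, amp)
      list(calls = callVariants(pp, amp, config),
           trim = data.frame(sample_id = sid,
                             assigned = length(dm$perSample[[sid]]),
                             dropped = length(tr$dropped),
                             noReverseTag = sum(tr$noReverseTag),
                             aligned = pp@nReads))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[sid] <- conditionMessage(res)
      message("sample ", sid, " failed: ", conditionMessage(res))
    } else {
      calls[[sid]] <- res$calls
      trimStats[[sid]] <- res$trim
    }
  }
  trimStats <- do.call(rbind, trimStats)
  out <- structure(list(calls = calls, demuxStats = dm$stats,
                        trimStats = trimStats, failures = failures),
                   class = "pipelineResult")
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(dm$stats, file.path(outDir, "demux_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    allCalls <- do.call(rbind, lapply(names(calls), function(s)
      if (nrow(calls[[s]])) cbind(sample = s, calls[[s]])))
    if (is.null(allCalls))
      allCalls <- data.frame(sample = character(0))
    write.table(allCalls, file.path(outDir, "calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (s in names(calls))
      if (nrow(calls[[s]]))
        writeCallsVCF(calls[[s]],
                      amps[[sheet$amplicon[match(s, sheet$sample_id)]]],
                      file.path(outDir, paste0(s, ".vcf")))
    writeLines(c(paste0("package=rafamp ",
                        as.character(utils::packageVersion("rafamp"))),
                 paste0("seed=", seed),
                 paste0("samples=", nrow(sheet)),
                 paste0("mode=", config$mode),
                 paste0("alpha=", config$alpha),
                 paste0("background_error=", config$backgroundError),
                 paste0("min_depth=", config$minDepth)),
               file.path(outDir, "manifest.txt"))
  }
  out
}

#' @export
print.pipelineResult <- function(x, ...) {
  det <- vapply(x$calls, function(df) any(df$detected), logical(1))
  cat("pipelineResult:", length(x$calls), "samples,",
      sum(det), "with a detected variant,",
      length(x$failures), "failed\n")
  invisible(x)
}

#' Detected calls per sample
#'
#' @param result A [runPipeline()] result.
#' @return Data frame of detected calls with a `sample` column (zero rows
#'   when nothing was detected).
#' @export
detectedCalls <- function(result) {
  out <- lapply(names(result$calls), function(s) {
    df <- result$calls[[s]]
    df <- df[df$detected, , drop = FALSE]
    if (nrow(df)) cbind(sample = s, df)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out)) do.call(rbind, out)
  else data.frame(sample = character(0))
}
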