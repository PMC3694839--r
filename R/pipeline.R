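# Orchestration: configuration presets, the end-to-end driver and report
# emission in the two experimental designs (structural-RNA transcriptome
# mode and mRNA genome mode).

#' Pipeline configuration
#'
#' Two presets mirror the two experimental designs: \code{"structural-rna"}
#' (transcriptome mode against unique mature tRNA/rRNA sequences, duplicate
#' filter off) and \code{"mrna"} (genome mode, duplicate filter on). All
#' thresholds are overridable.
#'
#' @param preset "mrna" or "structural-rna".
#' @param mode overrides the preset's alignment mode.
#' @param align \code{\link{bs_align_params}}.
#' @param min_quality Phred gate for counted positions (default 20).
#' @param unconverted_threshold read-level unconverted-C cutoff (default 3).
#' @param p_threshold significance gate (default 0.01).
#' @param spacing close-site discard distance in nt (default 10).
#' @param context_window collapse context width in nt (default 31).
#' @param thresholds classification band edges in percent (default
#'   c(10, 20, 50)).
#' @param motif consensus \code{\link{motif_pattern}}.
#' @param motif_min_coverage anchor coverage for the motif scan (default 5;
#'   3 is the looser published alternative).
#' @param seed seed for multimapper assignment and any other randomness.
#' @return list of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(preset = c("mrna", "structural-rna"), mode = NULL,
                            align = bs_align_params(), min_quality = 20L,
                            unconverted_threshold = 3L, p_threshold = 0.01,
                            spacing = 10L, context_window = 31L,
                            thresholds = c(10, 20, 50),
                            motif = motif_pattern(), motif_min_coverage = 5L,
                            seed = 1L) {
  preset <- match.arg(preset)
  mode <- mode %||% if (preset == "mrna") "genome" else "transcriptome"
  stopifnot(min_quality > 0L, unconverted_threshold > 0L, p_threshold > 0,
            spacing > 0L, context_window > 0L, all(thresholds > 0))
  align$seed <- as.integer(seed)
  structure(list(preset = preset, mode = mode, align = align,
                 min_quality = as.integer(min_quality),
                 unconverted_threshold = as.integer(unconverted_threshold),
                 p_threshold = p_threshold, spacing = as.integer(spacing),
                 context_window = as.integer(context_window),
                 thresholds = thresholds, motif = motif,
                 motif_min_coverage = as.integer(motif_min_coverage),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full m5C detection pipeline
#'
#' Reference conversion, bisulfite alignment (with iterative trimming and
#' seeded multimapper assignment), artifact filters, quality-gated pileup,
#' exact conversion test, spacing discard, context collapapse, classification,
#' coverage summary and (genome mode, when coding features are annotated)
#' the consensus-motif enrichment analysis. Any stage failure aborts with
#' the stage name; partially written outputs are removed.
#'
#' @param refs original \code{ReferenceSet}.
#' @param reads read table (id, seq, qual) or FASTQ path.
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir optional directory for TSV/BED/log outputs.
#' @return report list: alignments, align_log, conversion_rate, sites,
#'   calls, coverage, motif (or NULL), log.
#' @export
run_pipeline <- function(refs, reads, config = pipeline_config(),
                         out_dir = NULL) {
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      for (f in written) if (file.exists(f)) unlink(f)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.character(reads) && length(reads) == 1L)
    reads <- stage("read-input", read_fastq(reads))
  conv <- stage("reference-prep", convert_reference(refs, config$mode))
  ares <- stage("alignment", bs_align(reads, conv, config$align))
  rate <- stage("conversion-rate", conversion_rate(ares$alignments, refs))
  mc <- stage("methylation-calling",
              call_methylation(ares$alignments, refs, config$mode,
                               min_quality = config$min_quality,
                               p_threshold = config$p_threshold,
                               spacing = config$spacing,
                               context_window = config$context_window,
                               unconverted_threshold = config$unconverted_threshold,
                               thresholds = config$thresholds))
  cov <- if (nrow(refs$features))
    stage("coverage-summary", coverage_summary(ares$alignments, refs$features))
  else NULL
  motif <- NULL
  cds <- refs$features[refs$features$biotype == "CDS", , drop = FALSE]
  if (config$mode == "genome" && nrow(cds) > 0L && nrow(mc$sites) > 0L) {
    motif <- stage("motif-analysis", {
      occ <- scan_motif(refs, cds, config$motif, mc$sites,
                        config$motif_min_coverage)
      ctl <- build_control_set(refs, cds, mc$sites, config$motif_min_coverage)
      enr <- if (nrow(occ) && nrow(ctl)) enrichment_summary(occ, ctl) else NULL
      list(occurrences = occ, controls = ctl, enrichment = enr)
    })
  }
  log <- c(list(seed = config$seed, mode = config$mode,
                n_reads = nrow(reads),
                conversion_rate = rate),
           ares$log, mc$log)
  report <- list(alignments = ares$alignments, unmapped = ares$unmapped,
                 conversion_rate = rate, sites = mc$sites, calls = mc$calls,
                 coverage = cov, motif = motif, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stage("write-outputs", {
      f <- file.path(out_dir, "calls.tsv")
      written <<- c(written, f)
      utils::write.table(report_table3_style(mc$calls), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      f <- file.path(out_dir, "calls.bed")
      written <<- c(written, f)
      write_calls_bed(mc$calls, f)
      f <- file.path(out_dir, "sites.tsv")
      written <<- c(written, f)
      utils::write.table(mc$sites, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      if (!is.null(cov)) {
        f <- file.path(out_dir, "coverage_summary.tsv")
        written <<- c(written, f)
        utils::write.table(cov$per_feature, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
      if (!is.null(motif) && !is.null(motif$enrichment)) {
        f <- file.path(out_dir, "motif_enrichment.tsv")
        written <<- c(written, f)
        utils::write.table(motif$enrichment, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
      f <- file.path(out_dir, "run_log.tsv")
      written <<- c(written, f)
      utils::write.table(
        data.frame(key = names(log),
                   value = vapply(log, function(x) paste(format(x), collapse = ","),
                                  character(1))),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }
  report
}

#' Format calls in the published mRNA-table layout
#'
#' Columns: locus, position, strand, p (three significant figures), coverage
#' n, unconverted k, level (one decimal) -- then the same three counts for an
#' optional second replicate (NA when absent) -- and a description. Rows are
#' sorted by first-replicate level, descending.
#'
#' @param calls call table (rname, pos, strand, n, k, level, p).
#' @param replicate optional second-replicate call table, matched on
#'   (rname, pos, strand).
#' @param descriptions optional named character vector keyed by
#'   "rname:pos".
#' @return data.frame in the report layout.
#' @export
report_table3_style <- function(calls, replicate = NULL, descriptions = NULL) {
  cols <- c("locus", "position", "strand", "p_value", "n_rep1", "k_rep1",
            "level_rep1", "n_rep2", "k_rep2", "level_rep2", "description")
  if (nrow(calls) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols))
    return(out)
  }
  calls <- data.table::as.data.table(calls)
  out <- data.table::data.table(
    locus = calls$rname, position = calls$pos, strand = calls$strand,
    p_value = signif(calls$p, 3), n_rep1 = calls$n, k_rep1 = calls$k,
    level_rep1 = round(calls$level, 1))
  if (!is.null(replicate)) {
    rep2 <- data.table::as.data.table(replicate)[
      , .(locus = rname, position = pos, strand,
          n_rep2 = n, k_rep2 = k, level_rep2 = round(methylation_level(k, n), 1))]
    out <- merge(out, rep2, by = c("locus", "position", "strand"), all.x = TRUE)
  } else {
    out[, `:=`(n_rep2 = NA_integer_, k_rep2 = NA_integer_,
               level_rep2 = NA_real_)]
  }
  key <- paste0(out$locus, ":", out$position)
  out[, description := if (!is.null(descriptions))
    unname(descriptions[key]) else NA_character_]
  data.table::setorder(out, -level_rep1)
  data.table::setcolorder(out, cols)
  as.data.frame(out)
}

#' Write calls as BED6 with the methylation level in the score field
#' @param calls call table.
#' @param path output BED path.
#' @export
write_calls_bed <- function(calls, path) {
  if (nrow(calls) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- paste(calls$rname, calls$pos - 1L, calls$pos,
                 paste0("m5C_", seq_len(nrow(calls))),
                 round(calls$level, 1), calls$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
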