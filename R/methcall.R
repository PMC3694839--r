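# Per-cytosine methylation quantification: artifact filters, pileup with a
# base-quality gate, the exact conversion test, spacing and sequence-context
# collapsing, classification, and library-level summaries.

# Expanded per-(alignment x cytosine-site) table. One row per reference
# cytosine (on the alignment's resolved transcript strand) covered by each
# alignment: aidx, qname, rname, pos, strand, state ("U" unconverted /
# "C" converted / "N" other base), q (Phred score of the read base).
conv_state_table <- function(aln, refs) {
  if (nrow(aln) == 0L)
    return(data.table::data.table(aidx = integer(), qname = character(),
                                  rname = character(), pos = integer(),
                                  strand = character(), state = character(),
                                  q = integer()))
  aln <- data.table::as.data.table(aln)
  aln[, aidx := .I]
  site_cache <- new.env(parent = emptyenv())
  sites_for <- function(r, strand) {
    key <- paste0(r, strand)
    if (!is.null(site_cache[[key]])) return(site_cache[[key]])
    ch <- if (strand == "+") "C" else "G"
    m <- gregexpr(ch, refs$seqs[[r]], fixed = TRUE)[[1]]
    v <- if (m[1] == -1L) integer(0) else as.integer(m)
    site_cache[[key]] <- v
    v
  }
  parts <- list()
  grps <- unique(aln[, .(rname, strand)])
  for (g in seq_len(nrow(grps))) {
    r <- grps$rname[g]; s <- grps$strand[g]
    sp <- sites_for(r, s)
    sub <- aln[rname == r & strand == s]
    if (length(sp) == 0L || nrow(sub) == 0L) next
    lo <- findInterval(sub$pos - 1L, sp) + 1L
    hi <- findInterval(sub$end, sp)
    cnt <- pmax(hi - lo + 1L, 0L)
    if (sum(cnt) == 0L) next
    rows <- rep(seq_len(nrow(sub)), cnt)
    site_pos <- sp[sequence(cnt, from = lo)]
    off <- site_pos - sub$pos[rows] + 1L
    base <- substring(sub$seq[rows], off, off)
    qch <- substring(sub$qual[rows], off, off)
    q <- as.integer(charToRaw(paste0(qch, collapse = ""))) - 33L
    state <- if (s == "+") {
      ifelse(base == "C", "U", ifelse(base == "T", "C", "N"))
    } else {
      ifelse(base == "G", "U", ifelse(base == "A", "C", "N"))
    }
    parts[[length(parts) + 1L]] <- data.table::data.table(
      aidx = sub$aidx[rows], qname = sub$qname[rows], rname = r,
      pos = site_pos, strand = s, state = state, q = q)
  }
  if (length(parts) == 0L)
    return(conv_state_table(aln[0L], refs))
  data.table::rbindlist(parts)
}

#' Remove PCR duplicates (genome mode)
#'
#' Reads with identical full as-sequenced sequence strings are considered a
#' single read; the first by reference coordinate, then read id, is retained.
#' In transcriptome mode the input is returned unchanged, since for highly
#' expressed structural RNAs identical reads reflect depth, not PCR
#' amplification.
#'
#' @param aln alignment table.
#' @param mode "genome" or "transcriptome".
#' @return filtered alignment table; attribute \code{n_removed} logs the count.
#' @export
filter_duplicates <- function(aln, mode = c("genome", "transcriptome")) {
  mode <- match.arg(mode)
  if (mode == "transcriptome" || nrow(aln) == 0L) {
    attr(aln, "n_removed") <- 0L
    return(aln)
  }
  aln <- data.table::as.data.table(aln)
  data.table::setorder(aln, rname, pos, qname)
  keep <- !duplicated(aln$orig_seq)
  out <- aln[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Remove reads with too many unconverted cytosines
#'
#' Stretches of unconverted Cs in a single read typically reflect a molecule
#' that escaped full bisulfite exposure rather than genuine methylation.
#' Reads whose conversion-state vector holds \code{threshold} or more
#' unconverted cytosines (counted on the resolved transcript strand, among
#' bases passing the quality gate) are eliminated.
#'
#' @param aln alignment table.
#' @param refs original \code{ReferenceSet}.
#' @param threshold minimum number of unconverted Cs that disqualifies a
#'   read (default 3).
#' @param min_quality Phred gate; only bases with quality strictly above this
#'   count (default 20).
#' @return filtered alignment table with attribute \code{n_removed}.
#' @export
filter_unconverted_reads <- function(aln, refs, threshold = 3L, min_quality = 20L) {
  if (nrow(aln) == 0L) {
    attr(aln, "n_removed") <- 0L
    return(aln)
  }
  aln <- data.table::as.data.table(aln)
  aln[, aidx := .I]
  cst <- conv_state_table(aln, refs)
  bad <- cst[state == "U" & q > min_quality, .N, by = aidx][N >= threshold, aidx]
  out <- aln[!aidx %in% bad][, aidx := NULL]
  attr(out, "n_removed") <- length(bad)
  out
}

#' Per-cytosine pileup with a base-quality gate
#'
#' For every reference cytosine (plus strand) or guanine (a minus-strand
#' cytosine) covered by at least one read, tallies coverage \code{n} and
#' unconverted count \code{k} over read bases with Phred quality strictly
#' above \code{min_quality}. Bases that are neither the retained nor the
#' converted form (sequencing errors) contribute to neither tally. Strand is
#' taken from each read's resolved transcript strand.
#'
#' @param aln filtered alignment table.
#' @param refs original \code{ReferenceSet}.
#' @param min_quality Phred gate (default 20).
#' @return data.table with rname, pos, strand, n, k.
#' @export
pileup <- function(aln, refs, min_quality = 20L) {
  cst <- conv_state_table(aln, refs)
  cst <- cst[q > min_quality & state != "N"]
  if (nrow(cst) == 0L)
    return(data.table::data.table(rname = character(), pos = integer(),
                                  strand = character(), n = integer(),
                                  k = integer()))
  out <- cst[, .(n = .N, k = sum(state == "U")), by = .(rname, pos, strand)]
  data.table::setorder(out, rname, pos, strand)
  out
}

#' Methylation level of a site
#'
#' The proportion (percent) of qualifying reads in which the cytosine was not
#' converted: \code{100 * k / n}.
#'
#' @param k unconverted read count.
#' @param n total qualifying coverage (must be >= 1).
#' @return percent in [0, 100]; vectorised.
#' @export
methylation_level <- function(k, n) {
  if (any(n < 1L)) stop("n must be >= 1")
  if (any(k < 0L | k > n)) stop("k must satisfy 0 <= k <= n")
  100 * k / n
}

#' Exact test of non-conversion against a fully converted null
#'
#' Two-sided Fisher's exact test on the 2x2 table [[k, n-k], [0, n]]: the
#' observed sample of n reads with k unconverted cytosines against an
#' all-converted pseudo-sample of equal depth. The two-sided p-value sums
#' hypergeometric probabilities not exceeding that of the observed table
#' (minimum-likelihood rule). A one-sided variant is available.
#'
#' @param k unconverted count(s).
#' @param n coverage(s), n >= 1.
#' @param alternative "two.sided" (default) or "greater".
#' @return p-value(s) in (0, 1]; vectorised over k, n.
#' @export
fisher_conversion_test <- function(k, n, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (any(n < 1L) || any(k < 0L) || any(k > n)) stop("invalid counts: need 0 <= k <= n, n >= 1")
  one <- function(k, n) {
    if (alternative == "greater")
      return(stats::phyper(k - 1L, n, n, k, lower.tail = FALSE))
    pr <- stats::dhyper(0:k, n, n, k)
    sum(pr[pr <= pr[k + 1L] * (1 + 1e-7)])
  }
  mapply(one, as.integer(k), as.integer(n))
}

#' Discard pairs of close methylation sites
#'
#' A methylation call within \code{distance} nucleotides of another call on
#' the same reference (either strand) is discarded; both members of a close
#' pair are removed. Clustered calls typically reflect local conversion
#' artifacts rather than independent methylation.
#'
#' @param calls data.table of calls with rname, pos.
#' @param distance maximum centre-to-centre distance that triggers removal
#'   (default 10; a pair at distance \code{distance + 1} is retained).
#' @return filtered calls with attribute \code{n_removed}.
#' @export
spacing_filter <- function(calls, distance = 10L) {
  if (nrow(calls) == 0L) {
    attr(calls, "n_removed") <- 0L
    return(calls)
  }
  calls <- data.table::as.data.table(calls)
  drop <- logical(nrow(calls))
  for (r in unique(calls$rname)) {
    i <- which(calls$rname == r)
    o <- i[order(calls$pos[i])]
    if (length(o) < 2L) next
    d <- diff(calls$pos[o])
    close <- d <= distance
    drop[o[c(close, FALSE)]] <- TRUE
    drop[o[c(FALSE, close)]] <- TRUE
  }
  out <- calls[!drop]
  attr(out, "n_removed") <- sum(drop)
  out
}

# strand-oriented flanking context around sites; flags truncation at edges
site_context <- function(refs, rname, pos, strand, flank = 15L) {
  len <- nchar(refs$seqs)[match(rname, names(refs$seqs))]
  from <- pmax(1L, pos - flank)
  to <- pmin(len, pos + flank)
  ctx <- substring(refs$seqs[match(rname, names(refs$seqs))], from, to)
  minus <- strand == "-"
  if (any(minus)) ctx[minus] <- rc(ctx[minus])
  data.table::data.table(context = ctx, edge = from != pos - flank | to != pos + flank)
}

#' Collapse calls sharing an identical sequence context
#'
#' Genes present in multiple identical copies yield repeated calls with the
#' same flanking sequence. Significant calls sharing an identical
#' \code{window}-nt strand-oriented context centred on the site are collapsed
#' into a single call whose n and k are the sums over the parents, with the
#' level and p-value recalculated from the cumulative counts. Contexts
#' truncated by a sequence edge are grouped by the available context and
#' flagged.
#'
#' @param calls significant calls (rname, pos, strand, n, k).
#' @param refs original \code{ReferenceSet}.
#' @param window context width in nt (odd; default 31, site at centre).
#' @return collapsed calls with parents recorded.
#' @export
collapse_by_context <- function(calls, refs, window = 31L) {
  stopifnot(window %% 2L == 1L)
  if (nrow(calls) == 0L) {
    out <- data.table::as.data.table(calls)
    out[, `:=`(context = character(), edge = logical(), n_parents = integer(),
               parents = character(), level = numeric(), p = numeric())]
    return(out)
  }
  calls <- data.table::as.data.table(calls)
  flank <- (window - 1L) %/% 2L
  ctx <- site_context(refs, calls$rname, calls$pos, calls$strand, flank)
  calls[, `:=`(context = ctx$context, edge = ctx$edge)]
  data.table::setorder(calls, rname, pos, strand)
  out <- calls[, .(rname = rname[1L], pos = pos[1L], strand = strand[1L],
                   n = sum(n), k = sum(k), n_parents = .N,
                   parents = paste(rname, pos, strand, sep = ":", collapse = ";"),
                   edge = any(edge)),
               by = context]
  out[, level := methylation_level(k, n)]
  out[, p := fisher_conversion_test(k, n)]
  data.table::setcolorder(out, c("rname", "pos", "strand", "n", "k", "level",
                                 "p", "context", "edge", "n_parents", "parents"))
  out[]
}

#' Classify calls into methylation-level bands
#'
#' Default bands (edges inclusive upward): <10, 10-20, 20-50 and >=50
#' percent.
#'
#' @param calls calls with a \code{level} column.
#' @param thresholds ascending band edges in percent (default c(10, 20, 50)).
#' @return calls with a \code{class} column added.
#' @export
classify_calls <- function(calls, thresholds = c(10, 20, 50)) {
  stopifnot(!is.unsorted(thresholds))
  labs <- c(paste0("<", thresholds[1], "%"),
            if (length(thresholds) > 1L)
              paste0(thresholds[-length(thresholds)], "-", thresholds[-1], "%"),
            paste0(">=", thresholds[length(thresholds)], "%"))
  calls <- data.table::as.data.table(calls)
  calls[, class := labs[findInterval(level, thresholds) + 1L]]
  calls[]
}

#' Global cytosine conversion rate of a library
#'
#' Percent of sequenced reference-cytosine positions (on each read's resolved
#' strand) converted to T, computed on raw alignments prior to any filtering
#' and without a quality gate.
#'
#' @param aln raw (pre-filter) alignment table.
#' @param refs original \code{ReferenceSet}.
#' @return percent, or NA (with a warning) if no cytosines were observed.
#' @export
conversion_rate <- function(aln, refs) {
  cst <- conv_state_table(aln, refs)
  conv <- sum(cst$state == "C")
  unconv <- sum(cst$state == "U")
  if (conv + unconv == 0L) {
    warning("no cytosines observed; conversion rate undefined")
    return(NA_real_)
  }
  100 * conv / (conv + unconv)
}

#' Per-feature coverage summary
#'
#' Mean per-base read coverage for every annotated feature, the count of
#' features exceeding mean coverage 5 (strict), and the percent of features
#' covered.
#'
#' @param aln alignment table.
#' @param features feature data.frame (feature_id, seqid, start, end, strand,
#'   biotype).
#' @param min_mean strict mean-coverage cutoff (default 5).
#' @return list with \code{per_feature}, \code{by_biotype}, \code{n_features},
#'   \code{n_pass} and \code{pct_covered} (rounded percent).
#' @export
coverage_summary <- function(aln, features, min_mean = 5) {
  features <- data.table::as.data.table(features)
  aln <- data.table::as.data.table(aln)
  mean_cov <- numeric(nrow(features))
  for (i in seq_len(nrow(features))) {
    f <- features[i]
    sub <- aln[rname == f$seqid & pos <= f$end & end >= f$start]
    flen <- f$end - f$start + 1L
    mean_cov[i] <- if (nrow(sub) == 0L) 0 else
      sum(pmin(sub$end, f$end) - pmax(sub$pos, f$start) + 1L) / flen
  }
  per <- data.table::data.table(feature_id = features$feature_id,
                                biotype = features$biotype,
                                length = features$end - features$start + 1L,
                                mean_coverage = mean_cov,
                                pass = mean_cov > min_mean)
  by_bio <- per[, .(n = .N, n_pass = sum(pass),
                    pct_covered = round(100 * sum(pass) / .N)), by = biotype]
  list(per_feature = per, by_biotype = by_bio,
       n_features = nrow(per), n_pass = sum(per$pass),
       pct_covered = round(100 * sum(per$pass) / nrow(per)))
}

#' Spike-in conversion QC
#'
#' Aligns a library against the spike templates alone (transcriptome mode),
#' applies the standard read filters, and reports the non-conversion
#' percentage per spike overall and specifically at the embedded consensus
#' motif's cytosine. An unmethylated spike carrying the consensus verifies
#' that the motif is not intrinsically bisulfite-resistant.
#'
#' @param reads read table (id, seq, qual).
#' @param spike_refs \code{ReferenceSet} of spike templates; motif anchor
#'   positions may be supplied via \code{anchors} or an \code{anchors}
#'   attribute on \code{spike_refs}, else the default consensus is scanned.
#' @param anchors optional data.frame (rname, pos) of motif anchor Cs.
#' @param align_params \code{\link{bs_align_params}}.
#' @param min_quality Phred gate for the pileup (default 20).
#' @param unconverted_threshold read filter threshold (default 3).
#' @return data.table, one row per spike template.
#' @export
spike_qc <- function(reads, spike_refs, anchors = NULL,
                     align_params = bs_align_params(), min_quality = 20L,
                     unconverted_threshold = 3L) {
  if (is.null(anchors)) anchors <- attr(spike_refs, "anchors")
  if (is.null(anchors)) {
    pat <- motif_pattern()
    anchors <- data.table::rbindlist(lapply(names(spike_refs$seqs), function(r) {
      m <- Biostrings::matchPattern(pat$pattern,
                                    Biostrings::DNAString(spike_refs$seqs[[r]]),
                                    fixed = FALSE)
      data.table::data.table(rname = r,
                             pos = Biostrings::start(m) + pat$anchor - 1L)
    }))
  }
  anchors <- data.table::as.data.table(anchors)
  conv <- convert_reference(spike_refs, "transcriptome")
  res <- bs_align(reads, conv, align_params)
  aln <- res$alignments
  out <- data.table::data.table(spike = names(spike_refs$seqs))
  if (nrow(aln) == 0L) {
    warning("no reads mapped to the spike templates")
    out[, `:=`(n_reads = 0L, pct_nonconversion = NA_real_,
               motif_pos = NA_integer_, motif_n = NA_integer_,
               motif_k = NA_integer_, motif_pct_nonconversion = NA_real_)]
    return(out)
  }
  aln <- filter_unconverted_reads(aln, spike_refs, unconverted_threshold,
                                  min_quality)
  pu <- pileup(aln, spike_refs, min_quality)
  per <- pu[, .(n = sum(n), k = sum(k)), by = rname]
  out <- merge(out, aln[, .(n_reads = .N), by = .(spike = rname)],
               by = "spike", all.x = TRUE)
  out <- merge(out, per[, .(spike = rname,
                            pct_nonconversion = 100 * k / n)],
               by = "spike", all.x = TRUE)
  mo <- merge(anchors, pu, by = c("rname", "pos"), all.x = TRUE)
  mo <- mo[strand == "+" | is.na(strand)]
  mo <- mo[, .(motif_pos = pos[1L], motif_n = n[1L], motif_k = k[1L]),
           by = .(spike = rname)]
  out <- merge(out, mo, by = "spike", all.x = TRUE)
  out[, motif_pct_nonconversion := 100 * motif_k / motif_n]
  out[is.na(n_reads), n_reads := 0L]
  out[]
}

#' One-stop methylation calling from filtered-or-raw alignments
#'
#' Applies the artifact filters (duplicate removal in genome mode, the
#' unconverted-read filter), builds the quality-gated pileup, assigns each
#' site its methylation level and exact-test p-value, gates at
#' \code{p_threshold}, discards close site pairs, collapses identical
#' sequence contexts, and classifies the surviving calls.
#'
#' @param aln alignment table from \code{\link{bs_align}} or
#'   \code{\link{import_sam}}.
#' @param refs original \code{ReferenceSet}.
#' @param mode "genome" or "transcriptome" (controls the duplicate filter).
#' @param min_quality Phred gate (default 20).
#' @param p_threshold significance gate (default 0.01).
#' @param spacing close-pair distance (default 10).
#' @param context_window collapse context width (default 31).
#' @param unconverted_threshold read filter threshold (default 3).
#' @param thresholds classification band edges (default c(10, 20, 50)).
#' @param dedup whether to apply the duplicate filter; defaults to genome
#'   mode only. At very high transcript coverage identical reads mostly
#'   reflect depth rather than PCR, so the filter can be disabled
#'   explicitly even in genome mode.
#' @return list with \code{sites} (all covered cytosines with level and p),
#'   \code{calls} (final collapsed, classified calls) and \code{log}
#'   (per-filter removal counts).
#' @export
call_methylation <- function(aln, refs, mode = c("genome", "transcriptome"),
                             min_quality = 20L, p_threshold = 0.01,
                             spacing = 10L, context_window = 31L,
                             unconverted_threshold = 3L,
                             thresholds = c(10, 20, 50),
                             dedup = (mode == "genome")) {
  mode <- match.arg(mode)
  force(dedup)
  a1 <- filter_duplicates(aln, if (dedup) "genome" else "transcriptome")
  n_dup <- attr(a1, "n_removed")
  a2 <- filter_unconverted_reads(a1, refs, unconverted_threshold, min_quality)
  n_unconv <- attr(a2, "n_removed")
  sites <- pileup(a2, refs, min_quality)
  if (nrow(sites)) {
    sites[, level := methylation_level(k, n)]
    sites[, p := fisher_conversion_test(k, n)]
  } else {
    sites[, `:=`(level = numeric(), p = numeric())]
  }
  sig <- sites[p < p_threshold]
  sig2 <- spacing_filter(sig, spacing)
  n_spaced <- attr(sig2, "n_removed")
  calls <- collapse_by_context(sig2, refs, context_window)
  calls <- classify_calls(calls, thresholds)
  list(sites = sites, calls = calls,
       log = list(n_alignments_in = nrow(aln),
                  n_duplicates_removed = n_dup,
                  n_unconverted_removed = n_unconv,
                  n_sites = nrow(sites),
                  n_significant = nrow(sig),
                  n_spacing_removed = n_spaced,
                  n_calls = nrow(calls)))
}
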