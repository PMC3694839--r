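#' Alignment parameters for the built-in bisulfite aligner
#'
#' @param k seed k-mer length for exact seeding (default 12).
#' @param max_mismatches maximum mismatches on the converted (three-letter)
#'   alphabet for a placement to be retained (default 2).
#' @param min_length shortest read length at which an alignment attempt is
#'   made; iterative trimming stops before any attempt below this (default 35).
#' @param trim_step bases removed from the 3' end per trimming round
#'   (default 2).
#' @param seed RNG seed for random assignment of multi-mapping reads.
#' @return list of class \code{bs_align_params}.
#' @export
bs_align_params <- function(k = 12L, max_mismatches = 2L, min_length = 35L,
                            trim_step = 2L, seed = 1L) {
  stopifnot(k >= 4L, max_mismatches >= 0L, min_length > k, trim_step >= 1L)
  structure(list(k = as.integer(k), max_mismatches = as.integer(max_mismatches),
                 min_length = as.integer(min_length),
                 trim_step = as.integer(trim_step), seed = as.integer(seed)),
            class = "bs_align_params")
}

#' Build (or fetch cached) k-mer seed index for a converted reference
#' @keywords internal
.bs_index <- function(conv, k) {
  key <- paste0("k", k)
  if (!is.null(conv$cache[[key]])) return(conv$cache[[key]])
  build <- function(strs) {
    parts <- lapply(seq_along(strs), function(i) {
      s <- strs[[i]]
      n <- nchar(s)
      if (n < k) return(NULL)
      st <- seq_len(n - k + 1L)
      data.table::data.table(kmer = substring(s, st, st + k - 1L),
                             rec = i, pos = st)
    })
    dt <- data.table::rbindlist(parts)
    data.table::setkey(dt, kmer)
    dt
  }
  idx <- list(plus = build(conv$plus),
              minus = if (conv$mode == "genome") build(conv$minus) else NULL)
  conv$cache[[key]] <- idx
  idx
}

# Align a batch of equal-length reads (no trimming). reads_dt needs columns
# idx, seq, qual; returns candidate placements with mismatch counts.
.align_batch <- function(reads_dt, conv, params) {
  L <- nchar(reads_dt$seq[1])
  k <- params$k
  stopifnot(all(nchar(reads_dt$seq) == L), L >= params$min_length)
  idx <- .bs_index(conv, k)
  rec_len <- nchar(conv$plus)
  fwd <- reads_dt$seq
  rev <- rc(fwd)
  combos <- list(list(fam = "plus", orient = "F", q = conv_ct(fwd)),
                 list(fam = "plus", orient = "R", q = conv_ct(rev)))
  if (conv$mode == "genome")
    combos <- c(combos,
                list(list(fam = "minus", orient = "F", q = conv_ga(fwd)),
                     list(fam = "minus", orient = "R", q = conv_ga(rev))))
  ofs <- seq(1L, L - k + 1L, by = k)
  ofs <- unique(c(ofs[seq_len(min(3L, length(ofs)))], L - k + 1L))
  hits <- list()
  for (cb in combos) {
    fam_idx <- idx[[cb$fam]]
    if (is.null(fam_idx) || nrow(fam_idx) == 0L) next
    seeds <- data.table::rbindlist(lapply(ofs, function(o)
      data.table::data.table(qrow = seq_len(nrow(reads_dt)), ofs = o,
                             kmer = substring(cb$q, o, o + k - 1L))))
    cand <- fam_idx[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(cand) == 0L) next
    cand[, start := pos - ofs + 1L]
    cand <- cand[start >= 1L & start + L - 1L <= rec_len[rec]]
    cand <- unique(cand[, .(qrow, rec, start)])
    if (nrow(cand) == 0L) next
    fam_str <- if (cb$fam == "plus") conv$plus else conv$minus
    tstr <- substring(fam_str[cand$rec], cand$start, cand$start + L - 1L)
    cand[, mm := hamming_pairs(cb$q[qrow], tstr, L)]
    cand <- cand[mm <= params$max_mismatches]
    if (nrow(cand) == 0L) next
    cand[, `:=`(strand = if (cb$fam == "plus") "+" else "-", orient = cb$orient)]
    hits[[length(hits) + 1L]] <- cand
  }
  if (length(hits) == 0L) return(data.table::data.table())
  all <- data.table::rbindlist(hits)
  # keep only equal-best placements per read
  all[, best := min(mm), by = qrow]
  all <- all[mm == best][, best := NULL]
  ids <- names(conv$plus)
  out <- data.table::data.table(
    qname = reads_dt$id[all$qrow],
    rname = ids[all$rec],
    pos = all$start,
    end = all$start + L - 1L,
    strand = all$strand,
    orient = all$orient,
    mm = all$mm,
    len = L,
    orig_seq = reads_dt$seq[all$qrow],
    orig_qual = reads_dt$qual[all$qrow])
  out[, seq := ifelse(orient == "F", orig_seq, NA_character_)]
  if (any(out$orient == "R")) out[orient == "R", seq := rc(orig_seq)]
  out[, qual := ifelse(orient == "F", orig_qual, NA_character_)]
  if (any(out$orient == "R")) out[orient == "R", qual := str_rev(orig_qual)]
  out
}

#' Align one bisulfite read against a converted reference
#'
#' Three-letter alignment: the read is fully converted (C->T and, for the
#' opposite library strand, G->A) before matching, so conversion status never
#' penalises placement. Candidates are found by exact k-mer seeding followed
#' by ungapped verification on the converted alphabet; all placements tied at
#' the best (lowest) mismatch count are returned.
#'
#' @param read list or one-row data.frame with \code{id}, \code{seq},
#'   \code{qual} (Phred+33 string, same length as seq).
#' @param conv a \code{ConvertedReference}.
#' @param params \code{\link{bs_align_params}}.
#' @return data.table of candidate placements (possibly empty), one row per
#'   equal-best placement, with the read carried in reference orientation.
#' @export
align_read <- function(read, conv, params = bs_align_params()) {
  if (nchar(read$seq) != nchar(read$qual))
    stop("sequence and quality lengths differ for read ", read$id)
  if (nchar(read$seq) < params$min_length) {
    out <- data.table::data.table()
    attr(out, "reason") <- "too_short"
    return(out)
  }
  .align_batch(data.table::data.table(idx = 1L, id = read$id,
                                      seq = toupper(read$seq), qual = read$qual),
               conv, params)
}

#' Iteratively 3'-trim and realign a read
#'
#' A read failing to align at its full length is trimmed by
#' \code{params$trim_step} bases from its 3' end and realigned, repeatedly,
#' as long as the trimmed length is at least \code{params$min_length}; the
#' first successful attempt's candidates are returned. Quality strings are
#' trimmed in lockstep.
#'
#' @inheritParams align_read
#' @return list with \code{alignments} (candidates of the first successful
#'   attempt, or empty), \code{attempted_lengths}, and \code{final_length}.
#' @export
iterative_trim_align <- function(read, conv, params = bs_align_params()) {
  L <- nchar(read$seq)
  attempted <- integer(0)
  while (L >= params$min_length) {
    attempted <- c(attempted, L)
    cand <- align_read(list(id = read$id,
                            seq = substr(read$seq, 1L, L),
                            qual = substr(read$qual, 1L, L)),
                      conv, params)
    if (nrow(cand) > 0L)
      return(list(alignments = cand, attempted_lengths = attempted,
                  final_length = L))
    L <- L - params$trim_step
  }
  list(alignments = data.table::data.table(), attempted_lengths = attempted,
       final_length = if (length(attempted)) attempted[length(attempted)] else nchar(read$seq))
}

#' Randomly assign multi-mapping reads to a single placement
#'
#' Among the equal-best placements of each read, exactly one is chosen
#' uniformly at random from a seeded generator; candidates are pre-sorted by
#' reference id, strand and coordinate so the choice is deterministic for a
#' fixed seed. The pre-assignment multiplicity is recorded in \code{nmap}.
#'
#' @param cands data.table of candidate placements (from the aligner), any
#'   number of reads.
#' @param seed integer RNG seed.
#' @return data.table with one placement per read.
#' @export
assign_multimappers <- function(cands, seed = 1L) {
  if (nrow(cands) == 0L) return(cands)
  cands <- data.table::copy(cands)
  data.table::setorder(cands, qname, rname, strand, pos, orient)
  cands[, nmap := .N, by = qname]
  pick <- with_seed(seed,
    cands[, .(row = .I[sample.int(.N, 1L)]), by = qname]$row)
  cands[sort(pick)]
}

#' Full bisulfite alignment of a read set
#'
#' Batch driver: aligns every read at full length, iteratively 3'-trims
#' failures (never attempting below \code{params$min_length}), and resolves
#' multi-mappers by seeded random assignment.
#'
#' @param reads data.frame with columns \code{id}, \code{seq}, \code{qual}.
#' @param conv a \code{ConvertedReference}.
#' @param params \code{\link{bs_align_params}}.
#' @return list with \code{alignments} (one row per mapped read),
#'   \code{unmapped} (qname, reason, final_length) and \code{log} counts.
#' @export
bs_align <- function(reads, conv, params = bs_align_params()) {
  reads <- data.table::as.data.table(reads)
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) == 0L) stop("empty read set")
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence/quality length mismatch")
  reads[, seq := toupper(seq)]
  short <- reads[nchar(seq) < params$min_length]
  active <- reads[nchar(seq) >= params$min_length]
  active[, cur_seq := seq]
  active[, cur_qual := qual]
  cand_all <- list()
  unmapped <- list()
  if (nrow(short) > 0L)
    unmapped[[1]] <- data.table::data.table(qname = short$id, reason = "too_short",
                                            final_length = nchar(short$seq))
  while (nrow(active) > 0L) {
    lens <- sort(unique(nchar(active$cur_seq)), decreasing = TRUE)
    done_ids <- character(0)
    for (L in lens) {
      grp <- active[nchar(cur_seq) == L]
      cand <- .align_batch(
        data.table::data.table(idx = seq_len(nrow(grp)), id = grp$id,
                               seq = grp$cur_seq, qual = grp$cur_qual),
        conv, params)
      if (nrow(cand) > 0L) {
        cand_all[[length(cand_all) + 1L]] <- cand
        done_ids <- c(done_ids, unique(cand$qname))
      }
    }
    active <- active[!id %in% done_ids]
    if (nrow(active) == 0L) break
    # trim survivors and retry; retire reads that would fall below the floor
    active[, `:=`(cur_seq = substr(cur_seq, 1L, nchar(cur_seq) - params$trim_step),
                  cur_qual = substr(cur_qual, 1L, nchar(cur_qual) - params$trim_step))]
    fail <- active[nchar(cur_seq) < params$min_length]
    if (nrow(fail) > 0L) {
      unmapped[[length(unmapped) + 1L]] <-
        data.table::data.table(qname = fail$id, reason = "no_alignment",
                               final_length = nchar(fail$cur_seq) + params$trim_step)
      active <- active[nchar(cur_seq) >= params$min_length]
    }
  }
  cands <- if (length(cand_all)) data.table::rbindlist(cand_all) else data.table::data.table()
  aln <- assign_multimappers(cands, params$seed)
  un <- if (length(unmapped)) data.table::rbindlist(unmapped) else
    data.table::data.table(qname = character(), reason = character(),
                           final_length = integer())
  list(alignments = aln, unmapped = un,
       log = list(n_input = nrow(reads),
                  n_mapped = if (nrow(aln)) length(unique(aln$qname)) else 0L,
                  n_unmapped = nrow(un),
                  n_multimapped = if (nrow(aln)) sum(aln$nmap > 1L) else 0L))
}

#' Read a FASTQ file into the aligner's read table
#' @param path FASTQ path (uncompressed or gzipped).
#' @return data.frame with columns id, seq, qual.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Write a read table to FASTQ
#' @param reads data.frame with id, seq, qual.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}
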