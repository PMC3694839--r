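# Independent helper implementations used as oracles. These deliberately do
# not call package internals: sequence handling is done with base string
# operations so that cross-checks stay independent of the code under test.

o_revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

o_ct <- function(x) chartr("C", "T", x)
o_ga <- function(x) chartr("G", "A", x)

# construct a bisulfite read from a reference region with chosen retained
# (methylated/unconverted) cytosines; `keep` holds genomic positions whose
# sense-strand C stays a C. All other sense Cs convert.
bis_read <- function(refs, rec, start, len, tstrand = "+", keep = integer(),
                     sequenced_sense = TRUE, id = "r1", qual_char = "I") {
  region <- substring(refs$seqs[[rec]], start, start + len - 1L)
  sense <- if (tstrand == "+") region else o_revcomp(region)
  off <- if (tstrand == "+") keep - start + 1L else (start + len - 1L) - keep + 1L
  ch <- strsplit(sense, "")[[1]]
  stopifnot(all(ch[off] == "C"))
  conv <- which(ch == "C" & !(seq_along(ch) %in% off))
  ch[conv] <- "T"
  bis <- paste(ch, collapse = "")
  seqd <- if (sequenced_sense) bis else o_revcomp(bis)
  list(id = id, seq = seqd, qual = strrep(qual_char, len))
}

# brute-force bisulfite aligner: all offsets, both strand conversions, both
# read orientations, Hamming distance on the converted alphabet; returns all
# equal-best placements with mismatches <= max_mm.
brute_align <- function(read_seq, refs, mode = "genome", max_mm = 2L) {
  len <- nchar(read_seq)
  hits <- list()
  for (rec in names(refs$seqs)) {
    P <- refs$seqs[[rec]]
    n <- nchar(P)
    if (n < len) next
    targets <- list(list(strand = "+", t = o_ct(P)))
    if (mode == "genome")
      targets <- c(targets, list(list(strand = "-", t = o_ga(P))))
    starts <- seq_len(n - len + 1L)
    idx <- outer(seq_len(len) - 1L, starts, "+")
    for (tg in targets) {
      tch <- strsplit(tg$t, "")[[1]]
      M <- matrix(tch[idx], nrow = len)
      for (orient in c("F", "R")) {
        O <- if (orient == "F") read_seq else o_revcomp(read_seq)
        q <- if (tg$strand == "+") o_ct(O) else o_ga(O)
        qch <- strsplit(q, "")[[1]]
        mm <- colSums(M != qch)
        ok <- which(mm <= max_mm)
        if (length(ok))
          hits[[length(hits) + 1L]] <- data.frame(
            rname = rec, pos = starts[ok], strand = tg$strand,
            orient = orient, mm = mm[ok], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(rname = character(), pos = integer(),
                      strand = character(), orient = character(),
                      mm = integer(), stringsAsFactors = FALSE))
  all <- do.call(rbind, hits)
  all[all$mm == min(all$mm), , drop = FALSE]
}

# deterministic random genome for fixtures (helper-local RNG; does not
# disturb the session RNG state)
random_genome <- function(n, seed, gc = 0.4) {
  r <- local({
    set.seed(seed)
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  })
  paste(r, collapse = "")
}

# one-row gene feature helper
feat <- function(id, seqid, start, end, strand = "+", biotype = "CDS") {
  data.frame(feature_id = id, seqid = seqid, start = start, end = end,
             strand = strand, biotype = biotype, stringsAsFactors = FALSE)
}
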