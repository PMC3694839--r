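# SAM interchange for the built-in aligner: minimal emission (11 mandatory
# columns + tags) and import of external alignments through Rsamtools.

# Per-alignment conversion-state string in reference orientation:
# "U" unconverted C, "C" converted C, "N" non-C/T base at a C site,
# "." neutral (non-cytosine) position. Strand decides which reference base
# is the cytosine (plus-strand C or minus-strand C, i.e. a plus-strand G).
conv_state_strings <- function(aln, refs) {
  if (nrow(aln) == 0L) return(character(0))
  out <- character(nrow(aln))
  for (L in unique(aln$len)) {
    i <- which(aln$len == L)
    rstr <- substring(refs$seqs[aln$rname[i]], aln$pos[i], aln$pos[i] + L - 1L)
    rmat <- matrix(charToRaw(paste0(rstr, collapse = "")), nrow = L)
    qmat <- matrix(charToRaw(paste0(aln$seq[i], collapse = "")), nrow = L)
    smat <- matrix(".", nrow = L, ncol = length(i))
    plus <- aln$strand[i] == "+"
    tgt <- matrix(FALSE, nrow = L, ncol = length(i))
    tgt[, plus] <- rmat[, plus, drop = FALSE] == charToRaw("C")
    tgt[, !plus] <- rmat[, !plus, drop = FALSE] == charToRaw("G")
    un <- matrix(FALSE, nrow = L, ncol = length(i))
    cv <- un
    un[, plus] <- qmat[, plus, drop = FALSE] == charToRaw("C")
    cv[, plus] <- qmat[, plus, drop = FALSE] == charToRaw("T")
    un[, !plus] <- qmat[, !plus, drop = FALSE] == charToRaw("G")
    cv[, !plus] <- qmat[, !plus, drop = FALSE] == charToRaw("A")
    smat[tgt & un] <- "U"
    smat[tgt & cv] <- "C"
    smat[tgt & !un & !cv] <- "N"
    out[i] <- apply(smat, 2L, paste0, collapse = "")
  }
  out
}

#' Write alignments as minimal SAM
#'
#' Emits the 11 mandatory columns plus tags: \code{XM:i} converted-alphabet
#' mismatches, \code{XS:A} transcript strand, \code{NH:i} pre-assignment
#' multiplicity and \code{XC:Z} the per-base conversion-state vector
#' (U = unconverted C, C = converted C, N = other base at a C site,
#' . = neutral). SEQ/QUAL are stored in reference orientation with FLAG 16
#' set for reads sequenced antisense to the reference.
#'
#' @param aln alignment table from \code{\link{bs_align}}.
#' @param refs the original (unconverted) \code{ReferenceSet}.
#' @param path output SAM path.
#' @export
write_sam <- function(aln, refs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(refs$seqs), "\tLN:", nchar(refs$seqs)),
           "@PG\tID:m5Cpipe\tPN:m5Cpipe")
  if (nrow(aln) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  states <- conv_state_strings(aln, refs)
  rows <- paste(aln$qname,
                ifelse(aln$orient == "R", 16L, 0L),
                aln$rname, aln$pos, 255L, paste0(aln$len, "M"),
                "*", 0L, 0L, aln$seq, aln$qual,
                paste0("XM:i:", aln$mm),
                paste0("XS:A:", aln$strand),
                paste0("NH:i:", aln$nmap %||% 1L),
                paste0("XC:Z:", states),
                sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Import external alignments from SAM
#'
#' Reads a SAM file (through Rsamtools/htslib), skips unmapped, secondary,
#' supplementary and gapped records with counts logged, and reconstructs the
#' per-base conversion state by comparing read bases to the original
#' reference at reference-C (plus strand) or reference-G (minus strand)
#' positions. The transcript strand is taken from an \code{XS:A} tag when
#' present, otherwise inferred as the strand whose converted-alphabet
#' mismatch count is lower.
#'
#' @param path SAM file path.
#' @param refs the original \code{ReferenceSet} the records address.
#' @return list with \code{alignments} (the aligner's table layout) and
#'   \code{log} (skipped-record counts).
#' @export
import_sam <- function(path, refs) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    tag = c("XS", "NH", "XM"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n_total <- length(b$qname)
  flag <- b$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  simple <- !is.na(b$cigar) & grepl("^[0-9]+M$", b$cigar)
  keep <- !unmapped & !secondary & simple
  log <- list(n_records = n_total, n_unmapped = sum(unmapped),
              n_secondary = sum(secondary & !unmapped),
              n_gapped = sum(!simple & !unmapped & !secondary))
  if (!any(keep))
    return(list(alignments = data.table::data.table(), log = log))
  rname <- as.character(b$rname)[keep]
  bad <- setdiff(unique(rname), names(refs$seqs))
  if (length(bad))
    stop("reference name(s) not in reference set: ", paste(bad, collapse = ", "))
  seqs <- as.character(b$seq)[keep]
  quals <- as.character(b$qual)[keep]
  orient <- ifelse(bitwAnd(flag[keep], 16L) > 0L, "R", "F")
  len <- nchar(seqs)
  pos <- b$pos[keep]
  aln <- data.table::data.table(
    qname = b$qname[keep], rname = rname, pos = pos, end = pos + len - 1L,
    strand = NA_character_, orient = orient, mm = NA_integer_, len = len,
    seq = seqs, qual = quals)
  aln[, orig_seq := ifelse(orient == "F", seq, NA_character_)]
  if (any(orient == "R")) aln[orient == "R", orig_seq := rc(seq)]
  aln[, orig_qual := ifelse(orient == "F", qual, NA_character_)]
  if (any(orient == "R")) aln[orient == "R", orig_qual := str_rev(qual)]
  nh <- b$tag$NH
  aln[, nmap := if (!is.null(nh)) ifelse(is.na(nh[keep]), 1L, nh[keep]) else 1L]
  # strand: tag if present, else conversion-consistency inference
  xs <- b$tag$XS
  if (!is.null(xs)) aln[, strand := as.character(xs[keep])]
  need <- which(is.na(aln$strand))
  if (length(need)) {
    rstr <- substring(refs$seqs[aln$rname[need]], aln$pos[need], aln$end[need])
    mm_ct <- hamming_pairs_var(conv_ct(aln$seq[need]), conv_ct(rstr), aln$len[need])
    mm_ga <- hamming_pairs_var(conv_ga(aln$seq[need]), conv_ga(rstr), aln$len[need])
    aln[need, strand := ifelse(mm_ct <= mm_ga, "+", "-")]
  }
  # converted-alphabet mismatch count on the resolved strand
  rstr <- substring(refs$seqs[aln$rname], aln$pos, aln$end)
  plus <- aln$strand == "+"
  mmv <- integer(nrow(aln))
  if (any(plus))
    mmv[plus] <- hamming_pairs_var(conv_ct(aln$seq[plus]), conv_ct(rstr[plus]),
                                   aln$len[plus])
  if (any(!plus))
    mmv[!plus] <- hamming_pairs_var(conv_ga(aln$seq[!plus]), conv_ga(rstr[!plus]),
                                    aln$len[!plus])
  data.table::set(aln, j = "mm", value = mmv)
  list(alignments = aln, log = log)
}

# hamming_pairs over possibly mixed widths (grouped internally)
hamming_pairs_var <- function(a, b, width) {
  out <- integer(length(a))
  for (L in unique(width)) {
    i <- which(width == L)
    out[i] <- hamming_pairs(a[i], b[i], L)
  }
  out
}
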