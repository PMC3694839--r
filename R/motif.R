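# Consensus-motif scanning and methylation-stratified enrichment against a
# mismatch-constrained control set, plus position-frequency-matrix consensus
# derivation from site flanks.

#' Define a consensus motif pattern
#'
#' The default is the 8-nt consensus AUCGANGU (DNA form ATCGANGT) with the
#' interrogated cytosine at position 3. The alternative spelling with
#' explicit degenerate positions, AUCG-A/U-G/U-G-U/G, is available as the
#' preset \code{"loose"} (DNA IUPAC form ATCGWKGK).
#'
#' @param pattern IUPAC string on the coding (sense) strand, DNA alphabet.
#' @param anchor 1-based index of the interrogated C within the pattern.
#' @param preset "default" (ATCGANGT) or "loose" (ATCGWKGK); ignored when
#'   \code{pattern} is given.
#' @return list of class \code{MotifPattern}.
#' @export
motif_pattern <- function(pattern = NULL, anchor = 3L,
                          preset = c("default", "loose")) {
  preset <- match.arg(preset)
  if (is.null(pattern))
    pattern <- if (preset == "default") "ATCGANGT" else "ATCGWKGK"
  pattern <- toupper(pattern)
  iupac <- Biostrings::IUPAC_CODE_MAP
  if (!all(strsplit(pattern, "")[[1]] %in% names(iupac)))
    stop("invalid IUPAC symbol in pattern")
  if (substr(pattern, anchor, anchor) != "C")
    stop("pattern must have its anchor C at the declared offset")
  structure(list(pattern = pattern, anchor = as.integer(anchor)),
            class = "MotifPattern")
}

# genomic coordinate of a position measured along a gene's sense strand
sense_to_genomic <- function(gene, offset) {
  if (gene$strand == "+") gene$start + offset - 1L else gene$end - offset + 1L
}

#' Scan coding genes for consensus-motif occurrences
#'
#' Finds all pattern matches (IUPAC semantics) on the coding strand of the
#' annotated genes, keeps those whose anchor cytosine is covered by at least
#' \code{min_coverage} qualifying reads, and annotates each with its
#' methylation level from the pileup (regardless of p-value). Hits are
#' deduplicated by genomic anchor position.
#'
#' @param refs original \code{ReferenceSet} (genome).
#' @param features gene features (sense-strand annotation); defaults to
#'   \code{refs$features}.
#' @param pattern a \code{\link{motif_pattern}}.
#' @param pile pileup table from \code{\link{pileup}}.
#' @param min_coverage minimum anchor coverage (default 5).
#' @return data.table of occurrences: gene, rname, pos, strand, flank, n, k,
#'   level.
#' @export
scan_motif <- function(refs, features = NULL, pattern = motif_pattern(),
                       pile, min_coverage = 5L) {
  features <- data.table::as.data.table(features %||% refs$features)
  if (nrow(features) == 0L) stop("no gene features to scan")
  plen <- nchar(pattern$pattern)
  occ <- list()
  for (i in seq_len(nrow(features))) {
    g <- features[i]
    gs <- substring(refs$seqs[[g$seqid]], g$start, g$end)
    if (g$strand == "-") gs <- rc(gs)
    m <- Biostrings::matchPattern(pattern$pattern, Biostrings::DNAString(gs),
                                  fixed = FALSE)
    if (length(m) == 0L) next
    st <- Biostrings::start(m)
    occ[[length(occ) + 1L]] <- data.table::data.table(
      gene = g$feature_id, rname = g$seqid,
      pos = vapply(st + pattern$anchor - 1L,
                   function(o) sense_to_genomic(g, o), integer(1)),
      strand = g$strand,
      flank = substring(gs, st, st + plen - 1L))
  }
  if (length(occ) == 0L)
    return(data.table::data.table(gene = character(), rname = character(),
                                  pos = integer(), strand = character(),
                                  flank = character(), n = integer(),
                                  k = integer(), level = numeric()))
  occ <- data.table::rbindlist(occ)
  occ <- occ[!duplicated(paste(rname, pos, strand))]
  occ <- merge(occ, pile, by = c("rname", "pos", "strand"))
  occ <- occ[n >= min_coverage]
  occ[, level := methylation_level(k, n)]
  data.table::setorder(occ, rname, pos)
  occ[]
}

#' Build the non-motif control site set
#'
#' Covered cytosines on the coding strand of annotated genes whose context
#' violates the consensus at all three informative offsets: a C at position
#' 0 with position -2 not an A, -1 not a T, and +1 not a G (sense
#' orientation). By construction this set is disjoint from the motif
#' occurrences.
#'
#' @inheritParams scan_motif
#' @return data.table of control sites with coverage and level.
#' @export
build_control_set <- function(refs, features = NULL, pile, min_coverage = 5L) {
  features <- data.table::as.data.table(features %||% refs$features)
  if (nrow(features) == 0L) stop("no gene features")
  ctl <- list()
  for (i in seq_len(nrow(features))) {
    g <- features[i]
    gs <- substring(refs$seqs[[g$seqid]], g$start, g$end)
    if (g$strand == "-") gs <- rc(gs)
    ch <- strsplit(gs, "")[[1]]
    cpos <- which(ch == "C")
    cpos <- cpos[cpos >= 3L & cpos <= length(ch) - 1L]
    if (length(cpos) == 0L) next
    ok <- ch[cpos - 2L] != "A" & ch[cpos - 1L] != "T" & ch[cpos + 1L] != "G"
    cpos <- cpos[ok]
    if (length(cpos) == 0L) next
    ctl[[length(ctl) + 1L]] <- data.table::data.table(
      gene = g$feature_id, rname = g$seqid,
      pos = vapply(cpos, function(o) sense_to_genomic(g, o), integer(1)),
      strand = g$strand)
  }
  if (length(ctl) == 0L)
    return(data.table::data.table(gene = character(), rname = character(),
                                  pos = integer(), strand = character(),
                                  n = integer(), k = integer(),
                                  level = numeric()))
  ctl <- data.table::rbindlist(ctl)
  ctl <- ctl[!duplicated(paste(rname, pos, strand))]
  ctl <- merge(ctl, pile, by = c("rname", "pos", "strand"))
  ctl <- ctl[n >= min_coverage]
  ctl[, level := methylation_level(k, n)]
  data.table::setorder(ctl, rname, pos)
  ctl[]
}

#' Methylation enrichment of motif sites over controls
#'
#' For each level cut, the fraction of sites methylated above it (strictly)
#' in the motif set versus the control set, with a two-sided Fisher's exact
#' comparison of the two fractions.
#'
#' @param occurrences motif occurrence table (\code{\link{scan_motif}}).
#' @param controls control site table (\code{\link{build_control_set}}).
#' @param level_cuts percent cuts (default c(10, 20)).
#' @return data.table, one row per cut: counts, percentages and Fisher p.
#' @export
enrichment_summary <- function(occurrences, controls, level_cuts = c(10, 20)) {
  if (nrow(occurrences) == 0L || nrow(controls) == 0L)
    stop("both the motif and the control set must be nonempty")
  data.table::rbindlist(lapply(level_cuts, function(cut) {
    am <- sum(occurrences$level > cut)
    ac <- sum(controls$level > cut)
    nm <- nrow(occurrences)
    nc <- nrow(controls)
    p <- stats::fisher.test(matrix(c(am, nm - am, ac, nc - ac), nrow = 2L))$p.value
    data.table::data.table(cut = cut, n_motif = nm, n_motif_above = am,
                           pct_motif = 100 * am / nm,
                           n_control = nc, n_control_above = ac,
                           pct_control = 100 * ac / nc,
                           fisher_p = p)
  }))
}

#' Position frequency matrix and consensus from aligned site flanks
#'
#' Per-position base frequencies over equal-length flanks aligned on the
#' anchor cytosine. The consensus calls a fixed base when it reaches 90
#' percent frequency, a two-base IUPAC degenerate symbol when two bases
#' jointly reach 90 percent, and N otherwise.
#'
#' @param flanks character vector of equal-length flanking sequences.
#' @param threshold consensus frequency threshold (default 0.9).
#' @return list with \code{pfm} (4 x L frequency matrix) and
#'   \code{consensus}.
#' @export
build_pfm <- function(flanks, threshold = 0.9) {
  if (length(flanks) == 0L) stop("no flanks")
  L <- nchar(flanks[1])
  if (any(nchar(flanks) != L)) stop("flanks must have equal lengths")
  mat <- matrix(unlist(strsplit(toupper(flanks), "")), nrow = L)
  bases <- c("A", "C", "G", "T")
  pfm <- vapply(seq_len(L), function(j)
    vapply(bases, function(b) mean(mat[j, ] == b), numeric(1)),
    numeric(4))
  rownames(pfm) <- bases
  two_code <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")
  consensus <- vapply(seq_len(L), function(j) {
    f <- sort(pfm[, j], decreasing = TRUE)
    if (f[1] >= threshold) return(names(f)[1])
    if (f[1] + f[2] >= threshold) {
      key <- paste(sort(names(f)[1:2]), collapse = "")
      return(unname(two_code[key]))
    }
    "N"
  }, character(1))
  list(pfm = pfm, consensus = paste(consensus, collapse = ""))
}
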