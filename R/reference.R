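#' Build a reference set from sequences and gene features
#'
#' A \code{ReferenceSet} bundles nucleotide sequences (chromosomes in genome
#' mode, mature transcripts in transcriptome mode) with strand-aware gene
#' features. Sequences may contain only A/C/G/T/N. Coordinates are 1-based
#' inclusive throughout the user-facing API.
#'
#' @param sequences named character vector or \code{DNAStringSet}.
#' @param features \code{data.frame} with columns \code{feature_id},
#'   \code{seqid}, \code{start}, \code{end}, \code{strand} ("+"/"-") and
#'   \code{biotype} (e.g. "CDS", "tRNA", "rRNA"). May be \code{NULL}.
#' @return an object of class \code{ReferenceSet}.
#' @export
reference_set <- function(sequences, features = NULL) {
  if (inherits(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  if (!is.character(sequences) || length(sequences) == 0L)
    stop("'sequences' must be a nonempty named character vector or DNAStringSet")
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == "") || anyDuplicated(ids))
    stop("sequence records must carry unique nonempty names")
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0L))
    stop("empty sequence in record(s): ",
         paste(ids[nchar(sequences) == 0L], collapse = ", "))
  bad <- !grepl("^[ACGTN]+$", sequences)
  if (any(bad))
    stop("non-nucleotide characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  if (is.null(features)) {
    features <- data.frame(feature_id = character(), seqid = character(),
                           start = integer(), end = integer(),
                           strand = character(), biotype = character(),
                           stringsAsFactors = FALSE)
  } else {
    features <- as.data.frame(features)
    need <- c("feature_id", "seqid", "start", "end", "strand", "biotype")
    miss <- setdiff(need, names(features))
    if (length(miss)) stop("features missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(features$feature_id)) stop("feature identifiers must be unique")
    if (!all(features$seqid %in% ids))
      stop("feature seqid(s) not in reference: ",
           paste(setdiff(features$seqid, ids), collapse = ", "))
    len <- nchar(sequences)[match(features$seqid, ids)]
    if (any(features$start < 1L | features$end > len | features$start > features$end))
      stop("feature interval(s) outside their sequence")
    if (!all(features$strand %in% c("+", "-")))
      stop("feature strand must be '+' or '-'")
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
  }
  structure(list(seqs = sequences, features = features), class = "ReferenceSet")
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat("ReferenceSet:", length(x$seqs), "record(s),",
      nrow(x$features), "feature(s);",
      "total length", sum(nchar(x$seqs)), "nt\n")
  invisible(x)
}

#' In-silico bisulfite conversion of a reference
#'
#' Produces, for every record, the plus-strand conversion (every C replaced by
#' T: the image of a fully converted unmethylated plus-strand molecule) and
#' the minus-strand conversion (every G replaced by A, representing C-to-T
#' conversion on the reverse strand). Both retain the source coordinates, so
#' the provenance map from converted to original coordinates is the identity
#' on position with a strand tag (see \code{\link{provenance_map}}).
#'
#' @param refs a \code{ReferenceSet}.
#' @param mode "genome" (whole chromosomes, both strands alignable) or
#'   "transcriptome" (mature sense transcripts; only the plus conversion is
#'   used as an alignment target, though both are stored).
#' @return an object of class \code{ConvertedReference}.
#' @export
convert_reference <- function(refs, mode = c("genome", "transcriptome")) {
  mode <- match.arg(mode)
  if (!inherits(refs, "ReferenceSet")) refs <- reference_set(refs)
  structure(list(refs = refs,
                 plus = conv_ct(refs$seqs),
                 minus = conv_ga(refs$seqs),
                 mode = mode,
                 cache = new.env(parent = emptyenv())),
            class = "ConvertedReference")
}

#' @export
print.ConvertedReference <- function(x, ...) {
  cat("ConvertedReference (", x$mode, " mode): ", length(x$plus),
      " record(s)\n", sep = "")
  invisible(x)
}

#' Coordinate provenance of a converted reference
#'
#' @param conv a \code{ConvertedReference}.
#' @param record record id (defaults to the first record).
#' @return data.frame mapping each converted coordinate of both strand
#'   conversions back to the original coordinate and strand.
#' @export
provenance_map <- function(conv, record = names(conv$plus)[1]) {
  stopifnot(inherits(conv, "ConvertedReference"), record %in% names(conv$plus))
  L <- nchar(conv$plus[[record]])
  data.frame(record = record,
             conversion = rep(c("plus", "minus"), each = L),
             converted_pos = rep(seq_len(L), 2L),
             original_pos = rep(seq_len(L), 2L),
             strand = rep(c("+", "-"), each = L),
             stringsAsFactors = FALSE)
}

#' Collapse tRNA/rRNA gene copies into a unique-sequence transcript database
#'
#' Multi-copy structural RNA genes dilute read coverage when each copy is a
#' separate alignment target. This builds the transcriptome-mode reference:
#' exact-duplicate sequences are collapsed to a single record (tRNAs), and one
#' representative is retained per rRNA species, while membership lists record
#' every source gene so calls can be attributed to all copies.
#'
#' @param tRNAs \code{ReferenceSet} of mature tRNA sequences (may be NULL).
#' @param rRNAs \code{ReferenceSet} of rRNA sequences (may be NULL).
#' @param rRNA_species optional character vector, parallel to the rRNA
#'   records, naming the species (e.g. "16S") of each copy; defaults to
#'   collapsing identical sequences like the tRNAs.
#' @return a \code{ReferenceSet} with attribute \code{membership}: a named
#'   list mapping each retained record to the ids of all source copies.
#' @export
build_transcript_db <- function(tRNAs = NULL, rRNAs = NULL, rRNA_species = NULL) {
  collapse <- function(seqs, key) {
    keep <- !duplicated(key)
    membership <- split(names(seqs), key)[unique(key)]
    names(membership) <- names(seqs)[keep]
    list(seqs = seqs[keep], membership = membership)
  }
  out_seqs <- character(0)
  membership <- list()
  biotype <- character(0)
  if (!is.null(tRNAs)) {
    ct <- collapse(tRNAs$seqs, unname(tRNAs$seqs))
    out_seqs <- c(out_seqs, ct$seqs)
    membership <- c(membership, ct$membership)
    biotype <- c(biotype, rep("tRNA", length(ct$seqs)))
  }
  if (!is.null(rRNAs)) {
    key <- if (is.null(rRNA_species)) unname(rRNAs$seqs) else as.character(rRNA_species)
    if (length(key) != length(rRNAs$seqs))
      stop("rRNA_species must be parallel to the rRNA records")
    cr <- collapse(rRNAs$seqs, key)
    out_seqs <- c(out_seqs, cr$seqs)
    membership <- c(membership, cr$membership)
    biotype <- c(biotype, rep("rRNA", length(cr$seqs)))
  }
  if (length(out_seqs) == 0L) stop("no input sequences")
  feats <- data.frame(feature_id = names(out_seqs), seqid = names(out_seqs),
                      start = 1L, end = nchar(out_seqs), strand = "+",
                      biotype = biotype, stringsAsFactors = FALSE)
  db <- reference_set(out_seqs, feats)
  attr(db, "membership") <- membership
  db
}

#' Read a reference set from FASTA (+ optional GFF3/BED features)
#' @param fasta path to a FASTA file.
#' @param gff optional path to a GFF3 file of gene features.
#' @return a \code{ReferenceSet}.
#' @export
read_reference <- function(fasta, gff = NULL) {
  seqs <- as.character(Biostrings::readDNAStringSet(fasta))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  features <- NULL
  if (!is.null(gff)) {
    gr <- rtracklayer::import(gff)
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
      paste0("feat", seq_along(gr))
    features <- data.frame(
      feature_id = ids,
      seqid = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      biotype = if (!is.null(gr$type)) as.character(gr$type) else "CDS",
      stringsAsFactors = FALSE)
  }
  reference_set(seqs, features)
}

#' Write a reference set to FASTA (and its features to GFF3)
#' @param refs a \code{ReferenceSet}.
#' @param fasta output FASTA path.
#' @param gff optional output GFF3 path for the features.
#' @export
write_reference <- function(refs, fasta, gff = NULL) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs$seqs), fasta)
  if (!is.null(gff) && nrow(refs$features)) {
    f <- refs$features
    gr <- GenomicRanges::GRanges(f$seqid,
                                 IRanges::IRanges(f$start, f$end),
                                 strand = f$strand,
                                 type = f$biotype, ID = f$feature_id)
    # rtracklayer warns about absent CDS phase; phase is not modelled here
    suppressWarnings(rtracklayer::export(gr, gff, format = "gff3"))
  }
  invisible(fasta)
}

#' Write a converted reference as FASTA with a provenance sidecar
#' @param conv a \code{ConvertedReference}.
#' @param fasta output FASTA path (both strand conversions, suffixed ids).
#' @param provenance_tsv optional TSV path for the coordinate back-map.
#' @export
write_converted_reference <- function(conv, fasta, provenance_tsv = NULL) {
  seqs <- c(stats::setNames(conv$plus, paste0(names(conv$plus), "|CT")),
            stats::setNames(conv$minus, paste0(names(conv$minus), "|GA")))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  if (!is.null(provenance_tsv)) {
    pm <- do.call(rbind, lapply(names(conv$plus), function(r) provenance_map(conv, r)))
    utils::write.table(pm, provenance_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}
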