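# Synthetic-data generator: annotated genomes bearing planted m5C sites,
# bisulfite reads with a molecule-level conversion-failure model, spike-in
# templates, and RIP fragment libraries -- all with ground-truth tables so
# every pipeline stage can be checked against known answers.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the pipeline targets: 40-nt reads,
#' about 98.5 percent conversion of unmethylated cytosines, a small fraction
#' of molecules that escape full bisulfite exposure (the artifact motivating
#' the unconverted-read filter), PCR duplicates, and a Phred-quality model
#' with a small fraction of sub-20 bases to exercise the quality gate.
#'
#' @param genome_length genome size in nt (default 50000).
#' @param n_genes number of protein-coding gene features (default 40).
#' @param gene_length min/max gene length (default c(600, 1500)).
#' @param n_structural number of short tRNA-like features (default 0).
#' @param structural_length length of structural features (default 75).
#' @param gc genomic GC content (default 0.38, archaeal-like).
#' @param n_sites number of planted methylated sites (default 20).
#' @param stoichiometry true per-site methylation stoichiometries, recycled
#'   to \code{n_sites} (default c(0.25, 0.5, 0.9, 1.0)).
#' @param motif_frac fraction of planted sites embedded in the consensus
#'   motif (default 0.5).
#' @param conversion per-C conversion probability of unmethylated cytosines
#'   in normally exposed molecules (default 0.985).
#' @param fail_frac fraction of molecules with whole-molecule conversion
#'   failure (default 0.02).
#' @param fail_conversion conversion probability within failed molecules
#'   (default 0.2).
#' @param read_length read length in nt (default 40).
#' @param coverage target mean per-base coverage of transcripts (default 100).
#' @param error_rate per-base sequencing substitution rate (default 0.002).
#' @param dup_rate PCR duplication rate per molecule (default 0.02).
#' @param qual_mean,qual_sd Phred quality model for ordinary bases
#'   (default 38, 2; clipped to at least 21).
#' @param qual_sub20_frac fraction of bases drawn sub-20 (default 0.01).
#' @param spike_conversion conversion probability used for spike libraries
#'   (default 0.994).
#' @param spike_coverage target coverage for spike libraries (default 10000).
#' @param rip_fragment RIP fragment length in nt (default 100).
#' @param rip_coverage per-library RIP coverage (default 50).
#' @param seed RNG seed (mandatory).
#' @return list of class \code{SimConfig}.
#' @export
sim_config <- function(genome_length = 50000L, n_genes = 40L,
                       gene_length = c(600L, 1500L), n_structural = 0L,
                       structural_length = 75L, gc = 0.38, n_sites = 20L,
                       stoichiometry = c(0.25, 0.5, 0.9, 1.0),
                       motif_frac = 0.5, conversion = 0.985,
                       fail_frac = 0.02, fail_conversion = 0.2,
                       read_length = 40L, coverage = 100,
                       error_rate = 0.002, dup_rate = 0.02,
                       qual_mean = 38, qual_sd = 2, qual_sub20_frac = 0.01,
                       spike_conversion = 0.994, spike_coverage = 10000,
                       rip_fragment = 100L, rip_coverage = 50, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- as.list(environment())
  probs <- c(gc, conversion, fail_frac, fail_conversion, error_rate,
             dup_rate, qual_sub20_frac, motif_frac, spike_conversion,
             stoichiometry)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  structure(cfg, class = "SimConfig")
}

# sequential placement of non-overlapping features with random gaps
.place_features <- function(L, n, len_range, min_gap = 20L, max_gap = 120L,
                            prefix = "gene", biotype = "CDS", rng_strand = TRUE) {
  out <- list()
  cursor <- 1L
  for (i in seq_len(n)) {
    gap <- sample(min_gap:max_gap, 1L)
    len <- if (len_range[1] == len_range[2]) len_range[1] else
      sample(len_range[1]:len_range[2], 1L)
    start <- cursor + gap
    if (start + len - 1L > L) break
    out[[i]] <- data.frame(feature_id = sprintf("%s%03d", prefix, i),
                           start = start, end = start + len - 1L,
                           strand = if (rng_strand) sample(c("+", "-"), 1L) else "+",
                           biotype = biotype, stringsAsFactors = FALSE)
    cursor <- start + len
  }
  do.call(rbind, out)
}

#' Simulate an annotated genome with planted m5C sites
#'
#' Generates a random nucleotide genome carrying non-overlapping gene
#' features on both strands and plants methylated sites inside genes on the
#' sense strand. Motif-embedded sites have the consensus ATCGANGT written
#' around them (anchor C at motif position 3, sense orientation); other
#' planted sites sit at an ordinary cytosine. Planted sites are kept at
#' least 50 nt apart and 30 nt from gene ends.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{refs} (a \code{ReferenceSet}) and \code{truth}
#'   (list with \code{sites} and the config).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(cfg$seed, {
    bases <- c("A", "C", "G", "T")
    pb <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
    gch <- sample(bases, cfg$genome_length, replace = TRUE, prob = pb)
    feats <- .place_features(cfg$genome_length, cfg$n_genes, cfg$gene_length)
    if (is.null(feats) || nrow(feats) < cfg$n_genes)
      stop("genome too short to place the requested genes")
    if (cfg$n_structural > 0L) {
      used <- max(feats$end)
      st <- .place_features(cfg$genome_length - used, cfg$n_structural,
                            rep(cfg$structural_length, 2L),
                            prefix = "trna", biotype = "tRNA")
      if (!is.null(st)) {
        st$start <- st$start + used
        st$end <- st$end + used
        feats <- rbind(feats, st)
      }
    }
    feats <- data.frame(feature_id = feats$feature_id, seqid = "chr1",
                        start = feats$start, end = feats$end,
                        strand = feats$strand, biotype = feats$biotype,
                        stringsAsFactors = FALSE)
    sites <- NULL
    if (cfg$n_sites > 0L) {
      genes <- feats[feats$biotype == "CDS", ]
      if (cfg$n_sites > nrow(genes))
        stop("more planted sites than genes; one site per gene is planted")
      pick <- sort(sample(nrow(genes), cfg$n_sites))
      stoich <- rep_len(cfg$stoichiometry, cfg$n_sites)
      n_motif <- round(cfg$motif_frac * cfg$n_sites)
      is_motif <- sample(rep_len(c(rep(TRUE, n_motif),
                                   rep(FALSE, cfg$n_sites - n_motif)),
                                 cfg$n_sites))
      rows <- list()
      for (i in seq_len(cfg$n_sites)) {
        g <- genes[pick[i], ]
        glen <- g$end - g$start + 1L
        off <- sample(30:(glen - 30L), 1L)
        pos <- sense_to_genomic(g, off)
        if (is_motif[i]) {
          motif <- strsplit(paste0("ATCGA", sample(bases, 1L), "GT"), "")[[1]]
          if (g$strand == "+") gch[(pos - 2L):(pos + 5L)] <- motif
          else gch[(pos - 5L):(pos + 2L)] <- rev(chartr("ACGT", "TGCA", motif))
        } else {
          gch[pos] <- if (g$strand == "+") "C" else "G"
        }
        rows[[i]] <- data.frame(site_id = sprintf("site%02d", i),
                                rname = "chr1", pos = pos, strand = g$strand,
                                gene = g$feature_id, sense_offset = off,
                                stoichiometry = stoich[i], motif = is_motif[i],
                                stringsAsFactors = FALSE)
      }
      sites <- do.call(rbind, rows)
    } else {
      sites <- data.frame(site_id = character(), rname = character(),
                          pos = integer(), strand = character(),
                          gene = character(), sense_offset = integer(),
                          stoichiometry = numeric(), motif = logical(),
                          stringsAsFactors = FALSE)
    }
    genome <- paste0(gch, collapse = "")
    refs <- reference_set(c(chr1 = genome), feats)
    list(refs = refs, truth = list(sites = sites, config = cfg))
  })
}

#' Simulate bisulfite-converted reads with ground truth
#'
#' Transcript fragments are drawn from the sense strand of every annotated
#' feature at the configured coverage. Each molecule is flagged a
#' conversion failure with probability \code{fail_frac}; every unmethylated
#' cytosine then converts with the molecule's conversion probability
#' (\code{conversion}, or \code{fail_conversion} inside failed molecules).
#' A planted site's cytosine is methylated per molecule with its true
#' stoichiometry, and methylated cytosines never convert. Sequencing errors,
#' Phred qualities, random read orientation (the library is non-directional)
#' and PCR duplicates are then applied, and every outcome is logged in the
#' truth table.
#'
#' @param refs \code{ReferenceSet} from \code{\link{simulate_genome}}.
#' @param truth its truth list (planted sites).
#' @param cfg the \code{\link{sim_config}}.
#' @param seed RNG seed; defaults to \code{cfg$seed + 1}.
#' @return list with \code{reads} (id, seq, qual) and \code{truth_reads}
#'   (per-read provenance: source placement, failure/duplicate flags,
#'   unconverted-C count).
#' @export
simulate_bisulfite_reads <- function(refs, truth, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$coverage <= 0) stop("coverage must be positive")
  feats <- refs$features
  rl <- cfg$read_length
  feats <- feats[feats$end - feats$start + 1L >= rl, , drop = FALSE]
  if (nrow(feats) == 0L) stop("no feature long enough to yield reads")
  with_seed(seed, {
    sense <- character(nrow(feats))
    for (i in seq_len(nrow(feats))) {
      s <- substring(refs$seqs[[feats$seqid[i]]], feats$start[i], feats$end[i])
      sense[i] <- if (feats$strand[i] == "-") rc(s) else s
    }
    flen <- nchar(sense)
    nmol_per <- pmax(1L, as.integer(round(cfg$coverage * flen / rl)))
    gene_idx <- rep(seq_len(nrow(feats)), nmol_per)
    nmol <- length(gene_idx)
    start <- as.integer(floor(stats::runif(nmol) * (flen[gene_idx] - rl + 1))) + 1L
    frag <- substring(sense[gene_idx], start, start + rl - 1L)
    m <- matrix(unlist(strsplit(frag, ""), use.names = FALSE), nrow = rl)
    fail <- stats::runif(nmol) < cfg$fail_frac
    pconv <- ifelse(fail, cfg$fail_conversion, cfg$conversion)
    cmask <- m == "C"
    u <- matrix(stats::runif(rl * nmol), nrow = rl)
    converted <- cmask & (u < rep(pconv, each = rl))
    # planted sites: methylated molecules retain their C unconditionally
    sites <- truth$sites
    if (!is.null(sites) && nrow(sites) > 0L) {
      fid <- match(sites$gene, feats$feature_id)
      for (s in seq_len(nrow(sites))) {
        gi <- fid[s]
        if (is.na(gi)) next
        o <- sites$sense_offset[s]
        mols <- which(gene_idx == gi & start <= o & start + rl - 1L >= o)
        if (length(mols) == 0L) next
        meth <- mols[stats::runif(length(mols)) < sites$stoichiometry[s]]
        converted[cbind(o - start[meth] + 1L, meth)] <- FALSE
      }
    }
    m[converted] <- "T"
    n_unconv <- as.integer(colSums(cmask & !converted))
    n_c <- as.integer(colSums(cmask))
    # sequencing errors
    bases <- c("A", "C", "G", "T")
    err <- which(stats::runif(rl * nmol) < cfg$error_rate)
    if (length(err))
      m[err] <- bases[(match(m[err], bases) - 1L +
                         sample(3L, length(err), replace = TRUE)) %% 4L + 1L]
    # qualities
    q <- as.integer(round(stats::rnorm(rl * nmol, cfg$qual_mean, cfg$qual_sd)))
    q <- pmin(pmax(q, 21L), 41L)
    low <- which(stats::runif(rl * nmol) < cfg$qual_sub20_frac)
    if (length(low)) q[low] <- sample(3:19, length(low), replace = TRUE)
    qm <- matrix(rawToChar(as.raw(q + 33L), multiple = TRUE), nrow = rl)
    seqs <- do.call(paste0, lapply(seq_len(rl), function(i) m[i, ]))
    quals <- do.call(paste0, lapply(seq_len(rl), function(i) qm[i, ]))
    # non-directional library: half the reads are sequenced antisense
    flip <- stats::runif(nmol) < 0.5
    if (any(flip)) {
      seqs[flip] <- rc(seqs[flip])
      quals[flip] <- str_rev(quals[flip])
    }
    ids <- sprintf("r%07d", seq_len(nmol))
    g <- feats[gene_idx, ]
    gstart <- ifelse(g$strand == "+", g$start + start - 1L,
                     g$end - start - rl + 2L)
    tr <- data.table::data.table(
      read_id = ids, gene = g$feature_id, rname = g$seqid,
      genomic_start = as.integer(gstart), genomic_end = as.integer(gstart) + rl - 1L,
      strand = g$strand, sense_start = start, antisense = flip,
      fail = fail, dup = FALSE, n_c = n_c, n_unconverted = n_unconv)
    reads <- data.table::data.table(id = ids, seq = seqs, qual = quals)
    # PCR duplicates: identical copies appended under new ids
    dup <- which(stats::runif(nmol) < cfg$dup_rate)
    if (length(dup)) {
      dreads <- reads[dup]
      dreads[, id := paste0(id, "_dup")]
      dtr <- tr[dup]
      dtr[, `:=`(read_id = paste0(read_id, "_dup"), dup = TRUE)]
      reads <- rbind(reads, dreads)
      tr <- rbind(tr, dtr)
    }
    list(reads = reads, truth_reads = tr)
  })
}

#' Simulate unmethylated spike-in templates and their reads
#'
#' Two ~200-nt templates, each embedding one common representation of the
#' consensus (ATCGAGGT and ATCGAAGG), with reads generated entirely
#' unmethylated at \code{cfg$spike_conversion}. The anchor cytosine
#' positions are recorded in the \code{anchors} attribute of the returned
#' reference set.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param seed RNG seed; defaults to \code{cfg$seed + 2}.
#' @return list with \code{refs} (spike \code{ReferenceSet} with anchors),
#'   \code{reads} and \code{truth_reads}.
#' @export
simulate_spikes <- function(cfg, seed = cfg$seed + 2L) {
  stopifnot(inherits(cfg, "SimConfig"))
  variants <- c(spike1 = "ATCGAGGT", spike2 = "ATCGAAGG")
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    pat <- motif_pattern()
    make_template <- function(variant) {
      repeat {
        ch <- sample(bases, 200L, replace = TRUE)
        ch[96:103] <- strsplit(variant, "")[[1]]
        s <- paste0(ch, collapse = "")
        hits <- Biostrings::matchPattern(pat$pattern, Biostrings::DNAString(s),
                                         fixed = FALSE)
        n_expected <- if (grepl("GT$", variant)) 1L else 0L
        if (length(hits) == n_expected) return(s)
      }
    }
    seqs <- vapply(variants, make_template, character(1))
    feats <- data.frame(feature_id = names(seqs), seqid = names(seqs),
                        start = 1L, end = nchar(seqs), strand = "+",
                        biotype = "spike", stringsAsFactors = FALSE)
    refs <- reference_set(seqs, feats)
    attr(refs, "anchors") <- data.frame(rname = names(seqs), pos = 98L,
                                        stringsAsFactors = FALSE)
    spike_cfg <- cfg
    spike_cfg$conversion <- cfg$spike_conversion
    spike_cfg$coverage <- cfg$spike_coverage
    class(spike_cfg) <- "SimConfig"
    sim <- simulate_bisulfite_reads(refs, list(sites = NULL), spike_cfg,
                                    seed = seed + 1L)
    list(refs = refs, reads = sim$reads, truth_reads = sim$truth_reads)
  })
}

#' Simulate RIP-seq fragment libraries (IP, control-IP, input)
#'
#' Unconverted ~100-nt transcript fragments. In the IP library, fragments
#' overlapping a planted site are sampled \code{enrichment_factor}-fold more
#' often, scaled by the site's stoichiometry (sampling weight
#' 1 + (factor - 1) * stoichiometry); control-IP and input libraries are
#' sampled uniformly.
#'
#' @param refs simulated genome \code{ReferenceSet}.
#' @param truth its truth list (needs at least one planted site).
#' @param enrichment_factor IP enrichment at fully methylated sites
#'   (default 20).
#' @param cfg the \code{\link{sim_config}}.
#' @param seed RNG seed; defaults to \code{cfg$seed + 3}.
#' @return named list of libraries (IP, control_IP, input), each with
#'   \code{reads} and \code{placements} (rname, pos, end, gene).
#' @export
simulate_rip_library <- function(refs, truth, enrichment_factor = 20, cfg,
                                 seed = cfg$seed + 3L) {
  stopifnot(inherits(cfg, "SimConfig"))
  sites <- truth$sites
  if (is.null(sites) || nrow(sites) == 0L)
    stop("RIP simulation needs at least one planted site")
  fl <- cfg$rip_fragment
  feats <- refs$features
  feats <- feats[feats$end - feats$start + 1L >= fl, , drop = FALSE]
  with_seed(seed, {
    make_lib <- function(weighted, label) {
      nfrag_per <- pmax(1L, as.integer(round(
        cfg$rip_coverage * (feats$end - feats$start + 1L) / fl)))
      gene_idx <- rep(seq_len(nrow(feats)), nfrag_per)
      glen <- feats$end[gene_idx] - feats$start[gene_idx] + 1L
      # candidate pool: uniform fragment starts (genomic, plus orientation)
      pos <- feats$start[gene_idx] +
        as.integer(floor(stats::runif(length(gene_idx)) * (glen - fl + 1)))
      end <- pos + fl - 1L
      if (weighted) {
        w <- rep(1, length(pos))
        for (s in seq_len(nrow(sites))) {
          hit <- pos <= sites$pos[s] & end >= sites$pos[s]
          ws <- 1 + (enrichment_factor - 1) * sites$stoichiometry[s]
          w[hit] <- pmax(w[hit], ws)
        }
        keep <- sample(length(pos), length(pos), replace = TRUE, prob = w)
      } else {
        keep <- seq_along(pos)
      }
      pl <- data.table::data.table(
        id = sprintf("%s_f%06d", label, seq_along(keep)),
        rname = feats$seqid[gene_idx[keep]], pos = pos[keep], end = end[keep],
        gene = feats$feature_id[gene_idx[keep]])
      seqs <- substring(refs$seqs[pl$rname], pl$pos, pl$end)
      reads <- data.table::data.table(id = pl$id, seq = seqs,
                                      qual = strrep("I", fl))
      list(reads = reads, placements = pl)
    }
    list(IP = make_lib(TRUE, "ip"),
         control_IP = make_lib(FALSE, "ctl"),
         input = make_lib(FALSE, "inp"))
  })
}
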