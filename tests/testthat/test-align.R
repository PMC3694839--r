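make_fixture_genome <- function(seed = 101, n = 2000) {
  reference_set(c(chr1 = random_genome(n, seed = seed)))
}

test_that("a perfect three-letter match aligns with the right conversion state", {
  refs <- make_fixture_genome()
  conv <- convert_reference(refs, "genome")
  # pick a window containing at least one C
  start <- regexpr("C", substring(refs$seqs[[1]], 100, 1900)) + 99L
  start <- max(101L, start - 10L)
  cpos <- start + which(strsplit(substring(refs$seqs[[1]], start, start + 39L),
                                 "")[[1]] == "C")[1] - 1L
  rd <- bis_read(refs, "chr1", start, 40L, keep = integer())  # C sequenced as T
  aln <- align_read(rd, conv)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$pos, start)
  expect_equal(aln$mm, 0L)
  expect_equal(aln$strand, "+")
  st <- m5Cpipe:::conv_state_strings(aln, refs)
  expect_equal(substr(st, cpos - start + 1L, cpos - start + 1L), "C")  # converted

  rd2 <- bis_read(refs, "chr1", start, 40L, keep = cpos)  # C retained
  aln2 <- align_read(rd2, conv)
  expect_equal(nrow(aln2), 1L)
  expect_equal(aln2$mm, 0L)
  st2 <- m5Cpipe:::conv_state_strings(aln2, refs)
  expect_equal(substr(st2, cpos - start + 1L, cpos - start + 1L), "U")  # unconverted
})

test_that("a read from a duplicated segment yields two equal-score candidates", {
  seg <- random_genome(60, seed = 5)
  g <- paste0(random_genome(400, seed = 6), seg, random_genome(300, seed = 8),
              seg, random_genome(240, seed = 9))
  refs <- reference_set(c(chr1 = g))
  conv <- convert_reference(refs, "genome")
  rd <- bis_read(refs, "chr1", 401L, 40L)
  aln <- align_read(rd, conv)
  expect_equal(nrow(aln), 2L)
  expect_setequal(aln$pos, c(401L, 761L))
  expect_equal(unique(aln$mm), 0L)
  # cross-check against the exhaustive oracle
  oracle <- brute_align(rd$seq, refs)
  expect_equal(nrow(oracle), 2L)
  expect_setequal(paste(aln$pos, aln$strand), paste(oracle$pos, oracle$strand))
})

test_that("iterative trimming retries at 38 then 36 as tail mismatches allow", {
  refs <- make_fixture_genome(seed = 77)
  conv <- convert_reference(refs, "genome")
  rd <- bis_read(refs, "chr1", 500L, 40L)
  ch <- strsplit(rd$seq, "")[[1]]
  # corrupt 3 of the last 4 bases (substitutions chosen to stay mismatched
  # on the converted alphabet)
  for (i in c(37L, 38L, 39L)) ch[i] <- setdiff(c("A", "G"), ch[i])[1]
  rd$seq <- paste(ch, collapse = "")
  # mismatch-free matching: attempts enumerate 40, 38, 36 and succeed at 36
  res <- iterative_trim_align(rd, conv, bs_align_params(max_mismatches = 0L))
  expect_equal(res$attempted_lengths, c(40L, 38L, 36L))
  expect_equal(res$final_length, 36L)
  expect_gte(nrow(res$alignments), 1L)
  expect_true(500L %in% res$alignments$pos)
  # with 2 mismatches tolerated, one trim already leaves an acceptable tail
  res2 <- iterative_trim_align(rd, conv, bs_align_params(max_mismatches = 2L))
  expect_equal(res2$attempted_lengths, c(40L, 38L))
  expect_true(500L %in% res2$alignments$pos)
  expect_false(any(res2$alignments$mm[res2$alignments$pos == 500L] > 2L))

  # a clean read aligns at full length, no trimming
  rd2 <- bis_read(refs, "chr1", 700L, 40L)
  res3 <- iterative_trim_align(rd2, conv)
  expect_equal(res3$attempted_lengths, 40L)
})

test_that("the 35-nt floor stops trimming before any shorter attempt", {
  refs <- make_fixture_genome(seed = 13)
  conv <- convert_reference(refs, "genome")
  rd <- list(id = "junk", seq = strrep("ACGTAGGTA", 4L), qual = strrep("I", 36L))
  res <- iterative_trim_align(rd, conv)
  expect_equal(nrow(res$alignments), 0L)
  expect_equal(res$attempted_lengths, 36L)  # 34 < 35: never attempted
  expect_equal(res$final_length, 36L)
})

test_that("multimapper assignment is uniform, seeded and deterministic", {
  cands <- data.table::data.table(
    qname = "r1", rname = "chr1", pos = c(100L, 900L), end = c(139L, 939L),
    strand = "+", orient = "F", mm = 0L, len = 40L,
    orig_seq = "A", orig_qual = "I", seq = "A", qual = "I")
  one <- assign_multimappers(cands[1], seed = 99)
  expect_equal(one$pos, 100L)
  picks <- vapply(1:10000, function(s) assign_multimappers(cands, seed = s)$pos,
                  integer(1))
  frac <- mean(picks == 100L)
  expect_gt(frac, 0.48)
  expect_lt(frac, 0.52)
  expect_equal(assign_multimappers(cands, seed = 42)$pos,
               assign_multimappers(cands, seed = 42)$pos)
  expect_equal(unique(vapply(1:5, function(i)
    assign_multimappers(cands, seed = 7)$pos, integer(1))) |> length(), 1L)
})

test_that("converting any read C to T never changes placement or score", {
  refs <- make_fixture_genome(seed = 21)
  conv <- convert_reference(refs, "genome")
  allc <- 300L + which(strsplit(substring(refs$seqs[[1]], 300, 339),
                                "")[[1]] == "C") - 1L
  expect_gte(length(allc), 2L)
  # retain every other C so the originating strand is unambiguous
  rd <- bis_read(refs, "chr1", 300L, 40L,
                 keep = allc[seq(1L, length(allc), by = 2L)])
  base_aln <- align_read(rd, conv)
  cpos <- which(strsplit(rd$seq, "")[[1]] == "C")
  expect_gt(length(cpos), 0L)
  for (i in cpos) {
    mut <- rd
    substr(mut$seq, i, i) <- "T"
    aln <- align_read(mut, conv)
    expect_equal(aln$pos, base_aln$pos)
    expect_equal(aln$mm, base_aln$mm)
    expect_equal(aln$strand, base_aln$strand)
  }
})

test_that("the seeded aligner matches the brute-force oracle on random reads", {
  cfg <- sim_config(genome_length = 3000L, n_genes = 3L,
                    gene_length = c(600L, 900L), n_sites = 0L,
                    coverage = 1, error_rate = 0.01, fail_frac = 0,
                    dup_rate = 0, qual_sub20_frac = 0, seed = 404)
  g <- simulate_genome(cfg)
  sim <- simulate_bisulfite_reads(g$refs, g$truth, cfg)
  conv <- convert_reference(g$refs, "genome")
  reads <- head(sim$reads, 30L)
  for (i in seq_len(nrow(reads))) {
    rd <- as.list(reads[i])
    aln <- align_read(rd, conv)
    oracle <- brute_align(rd$seq, g$refs)
    expect_equal(nrow(aln), nrow(oracle))
    if (nrow(oracle)) {
      expect_setequal(paste(aln$rname, aln$pos, aln$strand, aln$orient),
                      paste(oracle$rname, oracle$pos, oracle$strand,
                            oracle$orient))
      expect_equal(sort(aln$mm), sort(oracle$mm))
    }
  }
})

test_that("batch alignment accounts for every read exactly once", {
  cfg <- sim_config(genome_length = 4000L, n_genes = 4L,
                    gene_length = c(500L, 800L), n_sites = 2L,
                    stoichiometry = 1, coverage = 5, seed = 31)
  g <- simulate_genome(cfg)
  sim <- simulate_bisulfite_reads(g$refs, g$truth, cfg)
  conv <- convert_reference(g$refs, "genome")
  res <- bs_align(sim$reads, conv, bs_align_params(seed = 31))
  expect_equal(res$log$n_mapped + res$log$n_unmapped, nrow(sim$reads))
  expect_equal(nrow(res$alignments), res$log$n_mapped)
  expect_false(any(duplicated(res$alignments$qname)))
})

test_that("short reads are reported unmapped with a reason", {
  refs <- make_fixture_genome(seed = 3)
  conv <- convert_reference(refs, "genome")
  reads <- data.frame(id = c("short1", "ok1"),
                      seq = c(substring(refs$seqs[[1]], 10, 39),
                              substring(refs$seqs[[1]], 100, 139)),
                      qual = c(strrep("I", 30), strrep("I", 40)))
  reads$seq <- o_ct(reads$seq)
  res <- bs_align(reads, conv)
  expect_equal(res$unmapped$qname, "short1")
  expect_equal(res$unmapped$reason, "too_short")
  expect_equal(res$alignments$qname, "ok1")
})
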