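# Fixture: a genome with one gene and hand-built alignments whose conversion
# states are fully controlled through bis_read().
mk_aln <- function(refs, conv, reads) {
  res <- bs_align(reads, conv, bs_align_params(seed = 1))
  expect_equal(res$log$n_unmapped, 0L)
  res$alignments
}

test_that("exact conversion test reproduces hand-enumerated hypergeometrics", {
  # independent oracle: explicit enumeration with choose()
  oracle <- function(k, n) {
    pr <- vapply(0:k, function(x)
      choose(n, x) * choose(n, k - x) / choose(2 * n, k), numeric(1))
    sum(pr[pr <= pr[k + 1] * (1 + 1e-7)])
  }
  for (n in c(1:15, 30, 45, 60)) {
    ks <- unique(round(seq(0, n, length.out = 8)))
    for (k in ks) {
      expect_equal(fisher_conversion_test(k, n), oracle(k, n),
                   tolerance = 1e-12)
      # cross-check against the reference implementation in base R
      expect_equal(fisher_conversion_test(k, n),
                   stats::fisher.test(matrix(c(k, 0L, n - k, n), 2L))$p.value,
                   tolerance = 1e-9)
    }
  }
})

test_that("exact test is strictly decreasing in k and 1 for the null table", {
  for (n in c(5L, 20L, 60L)) {
    p <- fisher_conversion_test(1:n, n)
    expect_true(all(diff(p) < 0))
    expect_equal(fisher_conversion_test(0L, n), 1.0)
  }
  expect_error(fisher_conversion_test(5, 4), "invalid")
})

test_that("methylation level is 100*k/n with bounds enforced", {
  expect_equal(round(methylation_level(17, 30), 1), 56.7)
  expect_equal(round(methylation_level(179, 500), 1), 35.8)
  expect_equal(methylation_level(0, 50), 0)
  expect_error(methylation_level(1, 0), "n must")
  expect_error(methylation_level(5, 4), "k must")
})

test_that("duplicate filter keeps one representative per sequence, genome mode only", {
  refs <- reference_set(c(chr1 = random_genome(800, seed = 12)))
  conv <- convert_reference(refs, "genome")
  one <- bis_read(refs, "chr1", 100L, 40L, id = "a1")
  other <- bis_read(refs, "chr1", 300L, 40L, id = "b1")
  reads <- do.call(rbind, c(
    lapply(1:5, function(i) as.data.frame(modifyList(one, list(id = paste0("a", i))))),
    list(as.data.frame(other))))
  aln <- mk_aln(refs, conv, reads)
  f <- filter_duplicates(aln, "genome")
  expect_equal(nrow(f), 2L)
  expect_equal(attr(f, "n_removed"), 4L)
  ft <- filter_duplicates(aln, "transcriptome")
  expect_equal(nrow(ft), nrow(aln))
  expect_equal(attr(ft, "n_removed"), 0L)
})

test_that("duplicate filter collapses 17 planted duplicate pairs out of 100 reads", {
  refs <- reference_set(c(chr1 = random_genome(6000, seed = 31)))
  conv <- convert_reference(refs, "genome")
  base <- lapply(1:83, function(i)
    as.data.frame(bis_read(refs, "chr1", 40L + 70L * (i - 1L), 40L,
                           id = paste0("u", i))))
  dups <- lapply(1:17, function(i) {
    d <- base[[i]]
    d$id <- paste0("d", i)
    d
  })
  aln <- mk_aln(refs, conv, do.call(rbind, c(base, dups)))
  f <- filter_duplicates(aln, "genome")
  expect_equal(nrow(f), 83L)  # hash-set oracle: unique sequences survive
  expect_equal(attr(f, "n_removed"), 17L)
})

test_that("unconverted-read filter removes at >=3 retained Cs, boundary at 2", {
  refs <- reference_set(c(chr1 = random_genome(900, seed = 44)))
  conv <- convert_reference(refs, "genome")
  win <- substring(refs$seqs[[1]], 200, 239)
  cpos <- 200L + which(strsplit(win, "")[[1]] == "C") - 1L
  expect_gte(length(cpos), 3L)
  reads <- rbind(
    as.data.frame(bis_read(refs, "chr1", 200L, 40L, keep = cpos[1:2], id = "two")),
    as.data.frame(bis_read(refs, "chr1", 200L, 40L, keep = cpos[1:3], id = "three")))
  aln <- mk_aln(refs, conv, reads)
  f <- filter_unconverted_reads(aln, refs)
  expect_equal(f$qname, "two")
  expect_equal(attr(f, "n_removed"), 1L)
})

test_that("pileup honours counts and the quality gate", {
  refs <- reference_set(c(chr1 = random_genome(700, seed = 91)))
  conv <- convert_reference(refs, "genome")
  win <- substring(refs$seqs[[1]], 150, 189)
  cpos <- 150L + which(strsplit(win, "")[[1]] == "C") - 1L
  site <- cpos[1]
  reads <- do.call(rbind, lapply(1:10, function(i)
    as.data.frame(bis_read(refs, "chr1", 150L, 40L,
                           keep = if (i <= 7) site else integer(),
                           id = paste0("r", i)))))
  aln <- mk_aln(refs, conv, reads)
  pu <- pileup(aln, refs)
  got <- pu[pos == site]
  expect_equal(got$n, 10L)   # printed worked example: n=10, k=7
  expect_equal(got$k, 7L)
  expect_equal(round(methylation_level(got$k, got$n), 1), 70.0)
  expect_equal(signif(fisher_conversion_test(got$k, got$n), 4), 0.003096)

  # drop 3 of the unconverted bases below the quality gate (Q15)
  aln2 <- data.table::copy(aln)
  off <- site - 150L + 1L
  for (i in 1:3) substr(aln2$qual[aln2$qname == paste0("r", i)], off, off) <- "0"
  pu2 <- pileup(aln2, refs)
  got2 <- pu2[pos == site]
  expect_equal(got2$n, 7L)
  expect_equal(got2$k, 4L)
})

test_that("pileup equals a per-column brute-force recount on simulated data", {
  cfg <- sim_config(genome_length = 3000L, n_genes = 3L,
                    gene_length = c(400L, 700L), n_sites = 2L,
                    stoichiometry = c(0.5, 1), coverage = 8,
                    dup_rate = 0, seed = 77)
  g <- simulate_genome(cfg)
  sim <- simulate_bisulfite_reads(g$refs, g$truth, cfg)
  conv <- convert_reference(g$refs, "genome")
  aln <- bs_align(sim$reads, conv, bs_align_params(seed = 77))$alignments
  pu <- pileup(aln, g$refs, min_quality = 20L)
  gch <- strsplit(g$refs$seqs[[1]], "")[[1]]
  # oracle: loop alignments, tally every covered C by string inspection
  tally <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(aln))) {
    rch <- strsplit(aln$seq[i], "")[[1]]
    qch <- utf8ToInt(aln$qual[i]) - 33L
    for (j in seq_along(rch)) {
      gp <- aln$pos[i] + j - 1L
      refb <- gch[gp]
      want <- if (aln$strand[i] == "+") c("C", "T") else c("G", "A")
      if (refb != want[1] || qch[j] <= 20L) next
      if (!(rch[j] %in% want)) next
      key <- paste0(gp, aln$strand[i])
      old <- tally[[key]] %||% c(0L, 0L)
      tally[[key]] <- old + c(1L, as.integer(rch[j] == want[1]))
    }
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  expect_equal(nrow(pu), length(ls(tally)))
  for (r in seq_len(nrow(pu))) {
    key <- paste0(pu$pos[r], pu$strand[r])
    expect_equal(unname(tally[[key]]), c(pu$n[r], pu$k[r]))
  }
})

test_that("duplicate and unconverted filters commute on the final pileup", {
  cfg <- sim_config(genome_length = 2500L, n_genes = 2L,
                    gene_length = c(500L, 700L), n_sites = 1L,
                    stoichiometry = 1, coverage = 15, fail_frac = 0.1,
                    seed = 19)
  g <- simulate_genome(cfg)
  sim <- simulate_bisulfite_reads(g$refs, g$truth, cfg)
  conv <- convert_reference(g$refs, "genome")
  aln <- bs_align(sim$reads, conv, bs_align_params(seed = 19))$alignments
  ab <- filter_unconverted_reads(filter_duplicates(aln, "genome"), g$refs)
  ba <- filter_duplicates(filter_unconverted_reads(aln, g$refs), "genome")
  pa <- pileup(ab, g$refs)
  pb <- pileup(ba, g$refs)
  data.table::setorder(pa, rname, pos, strand)
  data.table::setorder(pb, rname, pos, strand)
  expect_equal(pa, pb)
})

test_that("spacing filter removes both members of close pairs, boundary 11 nt", {
  calls <- data.table::data.table(
    rname = "chr1", pos = c(100L, 105L, 300L, 311L, 500L),
    strand = "+", n = 10L, k = 5L)
  f <- spacing_filter(calls, 10L)
  expect_setequal(f$pos, c(300L, 311L, 500L))
  expect_equal(attr(f, "n_removed"), 2L)
})

test_that("spacing filter agrees with an all-pairs brute-force oracle", {
  set.seed(8)
  for (rep in 1:20) {
    pos <- sort(sample(1:400, 25))
    calls <- data.table::data.table(rname = "chrZ", pos = pos, strand = "+",
                                    n = 5L, k = 2L)
    f <- spacing_filter(calls, 10L)
    drop <- vapply(seq_along(pos), function(i)
      any(abs(pos[-i] - pos[i]) <= 10L), logical(1))
    expect_setequal(f$pos, pos[!drop])
  }
})

test_that("context collapse merges identical gene copies and recomputes stats", {
  seg <- random_genome(200, seed = 3)
  g <- paste0(random_genome(100, seed = 1), seg,
              random_genome(150, seed = 2), seg, random_genome(80, seed = 4))
  refs <- reference_set(c(chr1 = g))
  # the same site inside both copies of the repeated segment
  soff <- which(strsplit(seg, "")[[1]] == "C")[5]
  p1 <- 100L + soff
  p2 <- 100L + 200L + 150L + soff
  calls <- data.table::data.table(rname = "chr1", pos = c(p1, p2),
                                  strand = "+", n = c(28L, 28L),
                                  k = c(26L, 26L))
  col <- collapse_by_context(calls, refs)
  expect_equal(nrow(col), 1L)
  expect_equal(col$n, 56L)   # 52/56 reporting convention for merged copies
  expect_equal(col$k, 52L)
  expect_equal(col$n_parents, 2L)
  expect_equal(col$level, methylation_level(52, 56))
  expect_equal(col$p, fisher_conversion_test(52, 56))

  # unique contexts pass through unchanged
  calls2 <- data.table::data.table(rname = "chr1", pos = c(p1, p1 + 40L),
                                   strand = "+", n = c(10L, 20L), k = c(5L, 9L))
  col2 <- collapse_by_context(calls2, refs)
  expect_equal(nrow(col2), 2L)
  expect_equal(sum(col2$n), sum(calls2$n))  # collapse conserves reads
})

test_that("collapse groups random duplicated contexts like a context-map oracle", {
  seg <- random_genome(400, seed = 21)
  g <- paste0(seg, random_genome(60, seed = 22), seg)
  refs <- reference_set(c(chr1 = g))
  cp <- which(strsplit(seg, "")[[1]] == "C")
  cp <- cp[cp > 15 & cp < 385]
  set.seed(99)
  pick <- sample(cp, 8)
  calls <- data.table::data.table(
    rname = "chr1",
    pos = c(pick, pick + 400L + 60L),
    strand = "+",
    n = sample(20:40, 16, replace = TRUE))
  calls[, k := as.integer(pmin(n, 15L))]
  col <- collapse_by_context(calls, refs)
  ctx <- m5Cpipe:::site_context(refs, calls$rname, calls$pos, calls$strand)$context
  oracle_n <- tapply(calls$n, ctx, sum)
  expect_equal(nrow(col), length(oracle_n))
  expect_equal(sort(as.integer(oracle_n)), sort(col$n))
  expect_equal(sum(col$n), sum(calls$n))
})

test_that("classification bands are inclusive upward", {
  calls <- data.table::data.table(level = c(56.7, 35.8, 50.0, 10.0, 9.9, 20.0))
  got <- classify_calls(calls)$class
  expect_equal(got, c(">=50%", "20-50%", ">=50%", "10-20%", "<10%", "20-50%"))
})

test_that("conversion rate hits the configured simulator probability", {
  cfg <- sim_config(genome_length = 4000L, n_genes = 4L,
                    gene_length = c(600L, 900L), n_sites = 0L,
                    conversion = 0.985, fail_frac = 0, coverage = 40,
                    error_rate = 0, dup_rate = 0, qual_sub20_frac = 0,
                    seed = 55)
  g <- simulate_genome(cfg)
  sim <- simulate_bisulfite_reads(g$refs, g$truth, cfg)
  conv <- convert_reference(g$refs, "genome")
  aln <- bs_align(sim$reads, conv, bs_align_params(seed = 55))$alignments
  rate <- conversion_rate(aln, g$refs)
  expect_gt(rate, 98.3)
  expect_lt(rate, 98.7)

  # degenerate extremes
  refs <- reference_set(c(chr1 = random_genome(500, seed = 2)))
  cv <- convert_reference(refs, "genome")
  cpos <- 100L + which(strsplit(substring(refs$seqs[[1]], 100, 139),
                                "")[[1]] == "C") - 1L
  all_kept <- mk_aln(refs, cv, as.data.frame(
    bis_read(refs, "chr1", 100L, 40L, keep = cpos)))
  expect_equal(conversion_rate(all_kept, refs), 0)
  all_conv <- mk_aln(refs, cv, as.data.frame(bis_read(refs, "chr1", 100L, 40L)))
  expect_equal(conversion_rate(all_conv, refs), 100)
})

test_that("coverage summary applies the strict mean-coverage cutoff", {
  feats <- feat("g1", "chr1", 1L, 100L)
  aln <- data.table::data.table(rname = "chr1",
                                pos = rep(c(1L, 51L), each = 5L))
  aln[, end := pos + 49L]
  cs <- coverage_summary(aln, feats)
  expect_equal(cs$per_feature$mean_coverage, 5.0)
  expect_equal(cs$n_pass, 0L)  # > 5 is strict
})

test_that("coverage summary percent matches the published tRNA arithmetic", {
  feats <- do.call(rbind, lapply(1:187, function(i)
    feat(paste0("t", i), "chr1", 1000L * i, 1000L * i + 9L, biotype = "tRNA")))
  covered <- lapply(1:153, function(i)
    data.table::data.table(rname = "chr1",
                           pos = rep(1000L * i, 6L), end = rep(1000L * i + 9L, 6L)))
  aln <- data.table::rbindlist(covered)
  cs <- coverage_summary(aln, feats)
  expect_equal(cs$n_pass, 153L)
  expect_equal(cs$pct_covered, 82)
})

test_that("end-to-end calling flags planted sites and not background", {
  cfg <- sim_config(genome_length = 6000L, n_genes = 6L,
                    gene_length = c(500L, 900L), n_sites = 3L,
                    stoichiometry = c(0.6, 0.9, 1), coverage = 40, seed = 5)
  g <- simulate_genome(cfg)
  sim <- simulate_bisulfite_reads(g$refs, g$truth, cfg)
  conv <- convert_reference(g$refs, "genome")
  aln <- bs_align(sim$reads, conv, bs_align_params(seed = 5))$alignments
  mc <- call_methylation(aln, g$refs, "genome")
  tr <- g$truth$sites
  found <- merge(data.table::as.data.table(tr),
                 mc$calls[, .(rname, pos, strand, level, p)],
                 by = c("rname", "pos", "strand"))
  expect_equal(nrow(found), 3L)
  expect_true(all(found$p < 0.01))
  # coarse per-site agreement: binomial noise at n ~ 35 is several points
  expect_true(all(abs(found$level - 100 * found$stoichiometry) < 20))
})
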