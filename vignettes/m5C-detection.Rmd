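---
title: "Detecting m5C in RNA from bisulfite sequencing: methods and design"
author: "m5Cpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting m5C in RNA from bisulfite sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m5Cpipe)
```

## The measurement model

Bisulfite deaminates unmethylated cytidine to uridine; 5-methylcytidine
(m5C) resists. After reverse transcription and sequencing, an unmethylated
reference cytosine is read as T in almost every read, while a methylated one
is read as C in a fraction of reads proportional to the fraction of
transcript molecules carrying the modification. Two quantities summarise a
site with coverage $n$ and unconverted count $k$:

* the **methylation level** $100\,k/n$, a direct estimate of stoichiometry;
* an exact test of non-conversion: a two-sided Fisher's exact test on the
  table $[[k, n-k], [0, n]]$, i.e. the observed sample against an
  all-converted pseudo-sample of equal depth. The two-sided p-value sums
  hypergeometric probabilities not exceeding that of the observed table.
  This construction was validated against independently enumerated
  hypergeometric sums and against `fisher.test()` across $n \le 60$.

Because conversion is incomplete (realistic libraries convert ~98–99% of
unmethylated Cs), the expected level at an unmethylated site is about
1–2%, not 0, and a deeply covered unmethylated site can reach a tiny
p-value at a trivial level. Calling therefore combines the significance
gate (p < 0.01) with level bands; the <10% band is reported but treated as
unreliable (see Limitations).

## Alignment

Reads are aligned with three-letter matching: the read is fully converted
(C→T, and G→A for the opposite library strand) and compared against the
correspondingly converted reference, so conversion status never penalises
placement. The library is non-directional, so each read is tried in four
states ({C→T, G→A} conversion × {forward, reverse-complement}); the winning
state fixes the transcript strand used for conversion-state calls.

The built-in aligner seeds candidate placements with exact 12-mers at three
disjoint offsets plus the final read position, then verifies each candidate
ungapped on the converted alphabet, keeping placements within
`max_mismatches` (default 2) and returning all equal-best ones. Three
disjoint 12-mers guarantee that any placement with at most two mismatches
is seeded for reads of 36 nt or longer; the package's test suite verifies
exact equivalence with a brute-force all-offset aligner on kilobase-scale
genomes. Reads failing at full length are trimmed by 2 nt from the 3' end
and retried while at least 35 nt long (the floor is checked before the
attempt, so a 36-nt read that fails is never re-tried at 34). Multi-mapping
reads are assigned to one equal-best placement uniformly at random from a
seeded generator, with candidates pre-sorted by reference, strand and
coordinate so runs are reproducible; the pre-assignment multiplicity is
kept on the surviving record. External alignments can be imported from SAM,
with conversion states reconstructed against the original reference.

Two reference modes exist. *Genome* mode aligns against whole chromosomes,
both strands. *Transcriptome* mode aligns against unique mature tRNA/rRNA
sequences (`build_transcript_db()` collapses identical gene copies and
keeps one representative per rRNA species, recording membership), which
prevents dilution of reads across identical copies and avoids losing reads
across processing boundaries such as excised introns.

## Artifact filters

1. **PCR duplicates** (genome mode): reads with identical full sequence
   strings count once; the representative is the first by coordinate, then
   read id. The filter is keyed on the sequence string, not the mapping
   coordinate. It is off in transcriptome mode: for highly expressed
   structural RNAs identical reads overwhelmingly reflect depth, not PCR.
   The same reasoning applies to any analysis at very high per-gene
   coverage, which is why `call_methylation()` exposes `dedup` explicitly:
   in the package's own 100× recovery benchmark the filter removed ~16× more
   reads than the number of true planted duplicates and biased high
   stoichiometries downward by several points, so that benchmark disables
   it.
2. **Conversion failures**: reads with ≥3 unconverted cytosines are
   eliminated — stretches of retained Cs typically mark molecules that
   escaped full bisulfite exposure. The count is taken on the read's
   resolved strand and only over bases passing the quality gate, so that
   quality failures cannot mask a molecule-level artifact.
3. **Base quality**: only bases with Phred quality strictly above 20 are
   counted in pileups.

After significance gating, sites within 10 nt of another site on the same
reference are discarded (both members of a close pair — clustered calls
typically share one artifactual molecule). Significant calls sharing an
identical 31-nt strand-oriented context are collapsed into one call with
$n$ and $k$ summed and the level and p-value recomputed — this merges calls
from identical gene copies; contexts truncated at sequence edges are
grouped by the available context and flagged.

The global **conversion rate** (the percentage of sequenced reference-C
positions converted) is computed on raw alignments before any filtering and
without the quality gate, so it reflects the library, not the pipeline.

## Consensus motif analysis

`scan_motif()` finds IUPAC-pattern occurrences (default ATCGANGT, anchor C
at position 3; RNA form AUCGANGU) on the coding strand of annotated genes,
keeps anchors covered by at least `min_coverage` reads (default 5; the
looser historical alternative of 3 is a config choice), deduplicates by
genomic anchor, and annotates levels regardless of p-value.
`build_control_set()` collects covered cytosines whose context violates the
consensus at the three informative offsets (−2 ≠ A, −1 ≠ T, +1 ≠ G), which
makes it provably disjoint from the motif set. `enrichment_summary()`
compares the fraction of sites methylated above each level cut between the
two sets with a two-sided Fisher's exact test. `build_pfm()` derives a
position frequency matrix and a consensus string from aligned flanks: a
base fixed at ≥90% frequency is called, two bases jointly ≥90% give the
IUPAC two-base code, anything else is N.

## Comparative statistics

Site positions are mapped to $[0,1]$ along the gene's sense strand with a
$(L-1)$ denominator so both ends are attainable (the convention is a
package choice; either convention changes positions by under half a
percent for typical genes). Location shifts between site sets use the
Welch t statistic computed from first principles; level comparisons use the
Mann–Whitney U with midranks, exact enumeration when both groups have ≤8
observations and the tie- and continuity-corrected normal approximation
otherwise. Both are cross-checked against the base-R implementations in the
test suite. The normal approximation is accurate away from extreme tails;
for decisions at very small p with small samples the exact path applies.

## Spike-in QC

Unmethylated transcripts carrying the consensus motif, mixed into a
library, verify that the motif is not intrinsically bisulfite-resistant.
`spike_qc()` aligns a library against the spike templates alone
(transcriptome mode), applies the standard filters, and reports overall and
motif-anchor non-conversion per spike. The simulator's spike libraries use
conversion 0.994 and anchor coverage 10,000×, chosen so that the expected
anchor non-conversion (0.6%) is estimated with a binomial standard error
near 0.08 points — small against the ±0.3-point agreement the QC is meant
to demonstrate.

## RIP-seq cross-validation

Antibody pulldown of fragmented RNA gives coverage peaks at modified
regions with ~100 bp resolution. `normalize_and_enrich()` rescales each
library so its median over the displayed feature equals the IP library's
median and expresses per-base fold enrichment relative to that median
(scale-invariant by construction; a zero median falls back to the mean with
a warning). `flag_sites()` supports a candidate when the IP fold
enrichment within ±50 nt exceeds `min_fold` (default 5, conservative
relative to the 10–35-fold peaks the assay can produce) in the IP but in no
control library. The simulator draws ~100-nt fragments with IP sampling
weight $1 + (f-1)\,s$ for fragments overlapping a site of stoichiometry
$s$ at enrichment factor $f$; its RIP benchmark plants fully methylated
sites, matching the strongly methylated rRNA/mRNA sites such pulldowns are
used to confirm.

## The synthetic-data generator

`sim_config()` fixes the study conditions: 40-nt reads, conversion
probability 0.985 per unmethylated C, a 2% fraction of molecules with
whole-molecule conversion failure (conversion 0.2 within them — the
molecule-level model matches the artifact mechanism of insufficient
bisulfite exposure), sequencing error 0.002, PCR duplication 2%, Phred
qualities centred at 38 with 1% of bases below 20, and an archaeal-like GC
of 0.38. Planted sites sit inside genes on the sense strand, at least
50 nt apart and 30 nt from gene ends; motif-embedded sites have ATCGANGT
written around them. Methylation is drawn per molecule at the site's true
stoichiometry and methylated Cs never convert. Every outcome — placement,
failure flag, duplicate flag, per-molecule unconverted count — is logged in
truth tables, so each filter's behaviour can be checked against ground
truth.

What the simulator does not emulate: RNA secondary-structure-dependent
conversion resistance, polyA selection, reverse-transcriptase stalling at
bulky modifications, DNA contamination, and expression variation between
genes (all features draw coverage proportional to length). Passing tests
therefore demonstrate the pipeline's correctness under the stated noise
model, not robustness to every artifact of real libraries.

## Benchmark design and problem sizes

The end-to-end recovery benchmark uses a 50-kb genome, 40 genes, 100×
coverage, and 20 planted sites at stoichiometries {0.25, 0.5, 0.9, 1.0}
allocated 4/8/4/4. The allocation weights the 0.5 group because it is the
hardest to calibrate: binomial noise at $s=0.5$ and $n\approx100$ is
~5 points per site, so the benchmark checks calibration of the group mean
(within ±5 points of truth) rather than each site individually — a per-site
±5-point check would fail for a perfect estimator most of the time at this
depth. Site-level *detection* (p < 0.01 for every site with $s \ge 0.5$) is
checked per site, since those p-values sit many orders of magnitude below
the gate. The false-positive check requires fewer than 1 in 1000
unmethylated covered cytosines to receive a significant >50% call.

The filter benchmark uses total-failure molecules (conversion 0), for which
≥5 cytosines per read guarantees detectability by the ≥3-unconverted rule;
partially converting failure molecules (the generation default, 0.2) are
exercised separately, where roughly 2% of reads fall to the filter as
expected. Other fixture sizes (2–20 kb genomes, coverages 2–40×) were
chosen to keep the full suite under a minute on one core while leaving
every stochastic margin at three or more standard errors.

## Numerical choices and degenerate inputs

* p-values are computed with `dhyper()` sums using a $1+10^{-7}$ relative
  guard when comparing probabilities for the minimum-likelihood rule.
* Levels are reported to one decimal and p-values to three significant
  figures in the report layout; internal values are never rounded.
* Sites with $n = 0$ are never emitted (rather than emitted with a
  sentinel); a library with no observed cytosines yields an NA conversion
  rate with a warning.
* N reference bases pass through conversion unchanged and are excluded
  from all cytosine tallies; read bases that are neither the retained nor
  the converted form (sequencing errors) count toward neither $n$ nor $k$.
* Classification bands are inclusive upward (a level of exactly 50.0% is
  ≥50%; 10.0% is 10–20%).
* All randomness (multimapper assignment, every simulator draw) flows from
  explicit integer seeds through private RNG streams that do not disturb
  the session RNG.

## Limitations

Bisulfite resistance is not specific to m5C: 3-methylcytidine,
N4-methylcytidine, N4,2′-O-dimethylcytidine and N4-acetyl variants also
block conversion, so calls are "putative m5C" and orthogonal evidence
(antibody pulldown, here; or chemistry-independent methods) is needed for
identity. Sites methylated below ~10% are indistinguishable from residual
artifacts at realistic conversion rates and are intentionally not rescued.
Stoichiometry estimates inherit any reverse-transcription bias against
heavily modified molecules; the simulator does not model that bias, so
real-data levels should be read as lower-bound-flavoured estimates.
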