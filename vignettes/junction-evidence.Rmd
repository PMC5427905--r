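---
title: "Quantifying splice-junction evidence for VEGFA isoforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying splice-junction evidence for VEGFA isoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegfsplice)
```

## The question and the model

VEGFA produces a family of isoforms by alternative splicing. The canonical
isoforms (VEGFA~121~, VEGFA~165~, VEGFA~189~, ...) differ in which of exons
5--7 they retain, but all end in the same terminal exon, entered through the
proximal acceptor we call **8a**. A second family, VEGFA~xxx~b, has been
proposed: it would enter the terminal exon 66 coding bases further
downstream, at a distal acceptor (**8b**), producing proteins with a
different C-terminus. Genomically, 8b begins immediately after 8a ends —
the canonical terminal exon is the contiguous `8a + 8b` block, and an
"8b-spliced" transcript is one that skips 8a entirely.

Whether 8b-spliced transcripts exist is an evidence-counting problem over
sequencing reads. `vegfsplice` implements the two complementary
quantification routes such a question needs, plus the statistics to
interpret a zero:

1. **Exact junction-probe scanning** (`build_probes()`, `scan_reads()`).
   For a junction joining donor exon $d$ to acceptor exon $a$, the probe is
   the last $k$ bases of $d$ concatenated with the first $k$ bases of $a$
   ($k = 11$ by default, 22-base probes). A read supports the junction iff
   it contains the probe exactly (either strand). Exact containment of a
   22-mer is strict: it requires at least $k$ correct bases on *each* side
   of the splice, which is what makes this route immune to the
   short-overhang artifact described below.
2. **Splice-junction table extraction** (`parse_sj_file()`,
   `annotate_sj_records()`). Spliced aligners summarise discovered introns
   in a 9-column table; the package extracts records whose intron falls
   entirely inside the locus window, names those matching a junction
   catalog, labels the rest `novel:first-last`, and normalises per million
   reads or per billion aligned bases.

The two routes are deliberately redundant. On simulated data with perfect
reads and well-anchored junctions they must agree read-for-read, and the
test suite asserts exactly that (probe-scan hits = ambiguity-aware
assignments = simulator truth).

## The short-overhang misalignment artifact

The last 3 bases of exon 7 (our exon 7b) are identical to the last 3 bases
of exon 8a. A read that covers the final $s \le 3$ bases of exon 8a and
runs into 8b is therefore consistent with two placements: contiguous within
the terminal exon (the truth, for canonical transcripts), or spliced from
7b to 8b with a donor overhang of $s$. An aligner guided by an annotation
containing the 7b-8b junction can prefer the spliced interpretation and
report phantom 8b evidence.

`assign_batch()` reproduces this mechanism explicitly. Candidate placements
for each read are exact substring matches against (a) the genomic locus,
(b) each transcript (which handles donor overhangs that run through
upstream exons), and (c) a genomic window across each annotated junction
boundary — route (c) is what an annotation provides an aligner, and is
available even for junctions no transcript supports. Two policies resolve
the candidates:

* **naive** — accepts any spliced candidate with overhangs $\ge$ a fixed
  minimum (default 1) and prefers annotated spliced placements over
  contiguous ones. This is a deliberate, documented emulation of
  annotation-guided aligner behaviour, not a model of any specific
  aligner's scoring.
* **ambiguity_aware** — prefers contiguous placements, and accepts a
  spliced candidate only if its donor overhang exceeds the shared terminal
  suffix between the donor exon and the exon abutting the acceptor
  (`junction_overhang_requirements()`; the acceptor side is handled
  symmetrically with shared prefixes, which costs nothing and
  generalises). Ties between junctions after filtering are reported
  `ambiguous`, never resolved arbitrarily.

Shared terminal sequence is always *computed* from the locus
(`shared_terminal_ambiguity()`), never assumed to be 3: the value 3 is a
property of the sequence, engineered into the synthetic locus and verified
by the tests. Junction assignments whose donor overhang lies within the
shared length carry an `artifact` flag, and summaries render them in
brackets next to the clean count (`"0 (24)"` style) so that phantom
evidence is visible but never mixed with real evidence.

## Detection limits and ratios

Observing zero 8b reads is informative only relative to depth.
`one_read_proportion(n)` reports $100/n$ percent — what a single 8b read
would have represented among $n$ canonical-junction reads — with headline
rounding to one significant figure. `zero_hit_upper_bound(n)` reports a
formal upper bound: the exact solution of $(1-p)^n = 1 - c$ at confidence
$c$ (default 95%), alongside the rule-of-three approximation $3/n$. The
one-read statistic is an informal "unlikely to exceed" argument; both are
reported, clearly labelled, because they answer slightly different
questions.

`isoform_ratio()` computes per-sample ratios of junction counts (default
5-8a : 7b-8a, which separates the diffusible VEGFA~121~ fraction from the
matrix-bound isoforms), excluding and logging samples with a zero
denominator, and `cross_dataset_r2()` measures reproducibility of the
ratio vector between two independent datasets as squared Pearson
correlation.

## The synthetic locus and read simulator

All tests run on a generated locus (`make_toy_locus()`), a scaled-down
structural mirror of the real one: the same fourteen exons with the same
contiguity pattern (1a|1b, 6a|6b|6c, 7a|7b, 8a|8b adjacent), exons of
24--400 bases (7b and 8a keep their real lengths, 35 and 66; 8b is 400
bases so a 100-base read fits inside it), introns of 120--400 bases, total
span about 3 kb so that exhaustive substring oracles over the whole locus
run in milliseconds. The generator:

* engineers the shared terminal suffix between 7b and 8a to be **exactly**
  the requested value (default 3) — equality is forced, and the next
  upstream base is forced to differ;
* rejection-samples until every flank-11 probe is unique (absent from the
  genome on both strands, present in transcripts only across its own
  junction) and no other exon pair shares a terminal suffix or initial
  prefix of 11 or more bases. Random 3-kb sequences satisfy these
  constraints almost always, so the bounded retry loop (100 attempts)
  exists for safety, not because rejection is common.

`simulate_reads()` draws reads by transcript weight, uniform start, random
strand, and iid substitutions at a configurable rate, recording per-read
truth: source transcript, window, strand, and every splice junction the
window spans with its donor/acceptor overhangs. Because start positions
are uniform, the expected number of reads spanning a junction with at
least $k$ bases on each side is $n\,(L_r - 2k + 1)/(L_t - L_r + 1)$ reads
for a transcript of length $L_t$ and read length $L_r$ — the closed form
the recovery tests check against, and the basis for choosing mixture
weights that hit a target share of junction-spanning reads.

`simulate_amplicon_reads()` apportions reads to templates
deterministically (largest-remainder rounding of $n \times$ weight) so the
recorded truth proportions equal the requested mixture exactly; only the
read order and the error layer are random. Mixture sampling error would
otherwise be confounded with classification error in recovery tests.

What the simulator does **not** model, by design: indels (the analyses are
exact-match based, so indels would conflate scanner misses with simulator
artifacts), PCR duplicates, GC bias, quality decay, or chimeric reads.
Passing tests therefore demonstrate correctness of the counting and
assignment logic under substitution noise, not robustness to every
real-library pathology; on real data the probe-scan route additionally
loses any junction read carrying a sequencing error inside the 22-mer,
which is why per-run normalisation matters there.

## Numerical and interface choices

* **Coordinates** are 1-based inclusive throughout, matching the exon
  coordinate table the default catalog ships (`vegfa_exon_catalog()`,
  hg19); BED export converts to 0-based half-open.
* **Flank default 11** (22-base probes), configurable and validated
  against exon lengths: exon 5 (30 bases) caps the flank at 30 for its
  junctions, exon 6b (18) at 18. Flanks must exceed the largest shared
  terminal suffix for probes to be junction-specific; the audit
  (`probe_cross_match_audit()`) verifies this rather than trusting it.
* **Matching is exact** — no mismatches in probes, placements, or primer
  sites. A read is counted once per probe no matter how often the probe
  occurs in it; a read matching several probes counts once for each, with
  a warning. Reads containing `N` never match.
* **Per-million denominators** count all scanned reads, matched or not;
  mates count as two reads. SJ-window containment requires the whole
  intron inside the window, boundaries inclusive.
* **Priming** is exact and must be unique; zero sites or multiple sites
  raise classed conditions (`vegfsplice_no_product`,
  `vegfsplice_nonunique_priming`) rather than guessing. The reverse primer
  is interpreted 5'→3' on the antisense strand, so predicted products
  include both primer footprints.
* Putative first exons with unknown start coordinates (1B, 1C, 1D) are
  omitted from the default catalog; user catalogs can add them via
  `load_exon_catalog()`. The exported functions are the package interface;
  no shell wrapper is provided because every operation is a small
  composable R call.

## Problem sizes in the test suite

The shipped tests exercise the full pipeline at sizes chosen to make
binomial checks meaningful while keeping the suite quick: specificity and
spike-in recovery at 200,000 reads (error rates 0 and 0.005; spike at
0.1% of junction-spanning reads, recovered within 3 binomial standard
deviations), artifact reproduction at 10,000 reads, the cross-module
equality oracle at 6,000 reads over two seeds, and ratio reproducibility
as 20 replicates of 14 simulated tissue pairs with roughly 2,000
junction-spanning reads per dataset, requiring median $R^2 > 0.8$. All
randomness flows through explicit integer seeds; rerunning any test
reproduces its numbers bit-for-bit.

## Known limitations

* The spliced-assignment layer is not an aligner: it has no mismatch
  tolerance, no indel handling, no multimapping model, and its naive mode
  is a mechanism demonstration, not a reimplementation of any published
  tool.
* SJ tables and raw reads are the two supported evidence sources; BAM
  parsing of spliced alignments is future work.
* The real-genome mode (supplying an hg19 window as the
  `locus_reference`) is supported but not exercised by the shipped tests,
  which are self-contained by design; product sizes and shared-suffix
  values quoted for the real locus are then recomputed, not assumed.
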