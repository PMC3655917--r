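---
title: "Comparing viral metagenome libraries: models and methods"
author: "virolib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing viral metagenome libraries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virolib)
```

## The problem

Viral community samples routinely yield nanograms of DNA or less, so
sequencing libraries are built with adaptor-mediated PCR amplification and
under platform-specific constraints. Every one of these choices — input DNA
mass, number of amplification cycles, sequencing platform, transposon-based
versus ligation-based preparation — can distort the composition of the
resulting metagenome. `virolib` implements the comparative analyses used to
quantify such distortions between replicate libraries and between
treatments, together with a library-preparation simulator that provides
ground truth for every analysis stage.

The unit of comparison is a per-library *profile*: the distribution of
per-read mean %G+C, the duplication-level spectrum, or the hit-frequency
vector over protein clusters. Profiles are compared by pairwise Pearson
correlation, clustered by UPGMA on `d = 1 - r`, and internal nodes receive
ordinary bootstrap support.

## The simulator

`generate_community()` draws genomes with i.i.d. bases at a controlled G+C
fraction (`P(G) = P(C) = gc/2`). This is deliberately the simplest
composition model that supports GC-profile work: the analyses operate on
per-read mean %G+C, which depends on base composition, not on realistic
genome architecture (genes, repeats, codon structure are absent and are not
needed for these analyses — see Limitations).

`simulate_fragments()` models shearing and size selection: fragment origins
are proportional to abundance × genome length, lengths are
Normal(`fragment_len_mean`, `fragment_len_sd`) clamped to the genome, starts
uniform.

`amplify_pool()` encodes the two bias mechanisms attributed to library
amplification:

* a Gaussian amplification efficiency in fragment G+C,
  `eff(gc) = exp(-strength * (gc - optimum)^2 / width^2)`, applied per cycle
  as the probability that each existing copy duplicates; and
* outright loss of low-GC fragments before cycling, with probability
  `low_gc_loss * max(0, optimum - gc)`.

The literature describes both effects qualitatively (inhibition by high-GC
secondary structure, loss of low-GC fragments during heated steps) without a
quantitative magnitude, so the functional form and its parameters are this
package's own model and are fully configurable; `strength = 0` and
`low_gc_loss = 0` recover unbiased amplification exactly. Copies are tracked
as per-fragment counts rather than materialised molecules, which is
observationally equivalent for every downstream statistic and keeps 15-18
cycle simulations cheap.

`sequence_pool()` draws reads with replacement proportionally to copy
number. Read length and quality follow platform presets with defaults taken
from typical raw-read summaries: Illumina 100 bp paired-end at PHRED ~34,
unamplified 454 at 408 ± 11 bp / ~32.5, linker-amplified 454 at 377 ± 15 bp
/ ~32.8 with 15 cycles, Ion Torrent at 105 ± 5 bp / ~16.3 with 5 cycles.
The per-base quality model is a deterministic linear PHRED decay floored at
2; preset decay defaults are 0 so a preset's mean quality equals its
nominal value, and decay is exposed as a tunable. Substitution errors occur
at `10^(-q/10)` per base. On-instrument amplification (emPCR, bridge) and
platform indel/homopolymer error modes are deliberately not modelled.

Adapter contamination prepends the adapter motif at the 5' end of a random
`adapter_rate` fraction of reads, displacing the 3' end so read length is
unchanged. The motif is injected *after* error simulation — contaminated
reads carry the exact motif — which makes the equivalence between discarded
reads and truth-tagged reads deterministic and testable.

Every read carries truth tags: source genome, source fragment, whether its
fragment was drawn at least twice (the read is then a PCR/resampling
duplicate), the pre-error sequence, and adapter status. All stages take
explicit seeds; no global random state is used, and identical seeds
reproduce a library byte-for-byte.

## Quality control

Two regimes mirror per-platform practice:

* **whole-read filtering** (`filter_whole_reads()`), for long-read
  platforms: keep a read iff mean PHRED ≥ `min_mean_quality` (default 20)
  and length ≥ `min_length` (default 50 bp). The cited pipelines state no
  universal numeric thresholds, so the defaults are configurable and logged
  in the run manifest.
* **two-sided trimming** (`trim_reads()`), for short-read platforms: a read
  is reduced to its longest contiguous run of bases with PHRED ≥
  `quality_threshold` (default 20), leftmost run on ties. This is the
  deterministic interpretation of threshold-based 5'/3' trimming; the
  probabilistic segment-score variant used by some trimmers is out of
  scope.

Adapter removal (`remove_adapter_reads()`) uses discard semantics — a read
containing an exact, forward-orientation occurrence of the motif (≥ 8 bp) is
dropped entirely — and applies to forward mates and unpaired reads only.
Length filtering keeps reads of exactly the minimum length ("under 50 bp"
removes 49 bp, keeps 50 bp). The reported failed fraction aggregates all
removal causes into one number per library.

## %G+C profiling

Because read lengths differ several-fold across platforms, only the first
50 bp of each read enter the G+C statistics: `read_mean_gc()` computes
`100 * (G+C) / min(window, length)` with ambiguous bases counting in the
denominator only (an N lowers a read's %G+C; the count of such reads is
available, and the rule is this package's documented choice). Profiles bin
reads into fifty 2%-wide bins, half-open `[2k, 2k+2)` with the top bin
closed — the boundary rule is ours, stated here because only "2% bins" is
conventionally specified. Reads shorter than the window after QC are
excluded from profiling rather than profiled on fewer bases, consistent
with the 50 bp QC floor. Reference genomes are tiled into non-overlapping
50 bp windows (`fragment_reference()`) so genome composition can be drawn
on the same axes.

## Correlation, UPGMA and bootstrap support

`pearson_matrix()` computes ordinary product-moment correlations between
profiles, with an explicit error naming any zero-variance library.
Distances are `d = 1 - r` — the source analyses state that distances were
derived from the correlation values without giving the formula, so the
standard transform is used and stated. `upgma()` merges the closest pair,
defines inter-cluster distance as the unweighted mean of all original
member-pair distances, and places a merge at height `d/2`; ties break on
the lexicographically smallest pair of cluster-minimum ids, making results
independent of input order. The implementation is checked against
average-linkage `hclust` on hundreds of random matrices.

`bootstrap_support()` resamples profile *positions* (GC bins or protein
clusters) with replacement, 100 replicates by default, and scores each
internal node by the percentage of replicate trees containing the same leaf
set. These are ordinary bootstrap proportions (BP%), not multiscale/AU
p-values; reports label them accordingly. The display threshold of 60% is
presentation only — all supports are written to the Newick output.

## Duplicate analyses

The duplication-level spectrum (`duplicate_spectrum()`) groups raw,
pre-QC reads by exact identity of their first 50 bp; a group of size *k*
contributes *k* reads to level `min(k, 10)`. Groups of exactly 10 are
placed in the top (">= 10-fold") level — the boundary is ambiguous in
conventional usage and is fixed and documented here.

Artificial duplicates (`detect_artificial()`) follow the
identical-start / >95%-identity definition: greedy incremental clustering
with the longest read as seed, joining a read to the first cluster whose
seed shares an identical first 20 bp (configurable; the anchor length
balances specificity against early-cycle sequencing error, as the
definition itself does not quantify "identical starts") and exceeds the
identity threshold over the aligned span. The threshold is strict (a 95.0%
pair does **not** join) but exact matches always join, so full-identity
detection degenerates to exact duplicate grouping. Substitution identity is
positionwise matches over the overlap; indel mode uses a banded (width 4)
edit distance. The contract is this definition, not bit-for-bit parity with
any external clustering tool. Natural duplication is reported as
`max(0, total - artificial)`.

## Protein-cluster profiling

Reads are length-normalised to exactly 100 bp (shorter reads dropped,
longer truncated) so platforms contribute equal information, then recruited
to a protein-cluster reference by exact peptide 4-mer seeds across all six
reading frames; a read is assigned to the cluster sharing the most distinct
seeds in its best frame, requiring at least `min_seeds = 2` (one shared
4-mer is too easily spurious), ties to the smallest cluster id. This
deterministic matcher is a self-contained stand-in for an external
translated homology search; externally produced read-to-cluster hit tables
can be imported in the same TSV schema instead (`read_hit_table()`), and no
parity with any aligner's scoring or with real mapped-fraction percentages
is claimed. The comparison axis is the hit-frequency table of the most
abundant clusters across all libraries (`top_pc_table()`, default top
1500 — effectively all clusters at desk scale).

A real protein-cluster database cannot be bundled; `synthetic_pc_db()`
derives single-representative clusters from gene-sized windows of the
simulated genomes, labelled synthetic throughout.

## Assembly metrics

`assembly_stats()` reports contig count, total size, maximum contig and
N50, where N50 is the length at which the cumulative sum of
descending-sorted contig lengths first reaches half the total — N50
conventions differ between tools, so the rule is stated and tested against
a brute-force oracle. Total size counts sequence as written, including Ns.
Assembly itself is out of scope; reads/bp-assembled are computed from an
optional placement table and reported as unknown otherwise.

## Orchestration

`run_pipeline()` composes the stages over a library manifest (QC →
profiles → duplicates → protein clusters → clustering → assembly metrics),
analysing forward and reverse mates as separate libraries. Degenerate
manifests produce distinct diagnostics; with fewer than two libraries the
comparison stages are skipped with a warning. `write_bundle()` emits TSV
matrices, Newick trees and a JSON run manifest with fixed numeric
formatting; by default no wall-clock timestamp is recorded, so a seeded run
is reproducible to identical file checksums (set `record_timestamp = TRUE`
to include one).

## Problem sizes and what the tests show

The validation suite runs entirely on simulated data at desk scale, chosen
as the smallest sizes at which the compared quantities stabilise: the
clustering analyses use 2 treatments × 2 replicates at 50,000 reads over a
12-genome, 30-60% G+C community; duplicate recovery uses 10,000 reads at
PHRED 30 (1e-3 per-base error) over a 2 Mb community; protein-cluster
replication uses 25,000 reads against 40 synthetic clusters over genomes
with geometrically decaying abundances. Under these conditions replicate
GC profiles correlate above 0.99 and co-cluster with 100% bootstrap
support, GC-biased amplification separates treatments sharply, planted
duplicates are recovered with ≈96% sensitivity at ≈0.5% false positives,
and replicate protein-cluster vectors correlate near 0.96-0.98 — lower
than the GC-profile correlations, as expected when forty features are
resolved instead of a 50-bin histogram.

Passing these tests shows the machinery is correct and well-calibrated on
data whose generating process is known. It does not show that real
libraries behave like the simulator: real viral metagenomes have gene- and
repeat-structured genomes, platform-specific indel errors, contaminating
cellular DNA, and amplification chemistry whose GC response need not be
Gaussian. The simulator's bias strength is a free parameter — no published
quantitative magnitude exists to pin it — so analyses of real data should
treat the simulated effect sizes as illustrative only.

## Known limitations

* Substitution-only error model; no homopolymer or indel errors, so
  platform-specific artefacts of pyrosequencing-type chemistry are absent.
* No paired-end re-synchronisation after QC; mates are analysed as
  separate libraries.
* The duplicate detector's greedy clustering is order-dependent by design
  (longest-first, deterministic); it is a definition-faithful detector, not
  a reimplementation of any specific tool's heuristics.
* `n_reads` counts both mates in paired mode and must be even there.
* Fragments shorter than the nominal read length yield shorter reads
  (clamped), which the length-normalisation step then drops from
  protein-cluster mapping.
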