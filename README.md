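# virolib

Comparative analysis of shotgun viral metagenome libraries across
library-preparation treatments, with a ground-truth simulator.

## The problem

Viral community samples often yield nanograms of DNA or less, forcing
adaptor-mediated PCR amplification before sequencing and raising the
question every low-input study must answer: *do my library-preparation
choices (input DNA amount, amplification cycles, platform) change what the
metagenome looks like?* `virolib` is for researchers running or evaluating
such experiments. It implements the standard battery of library-comparison
analyses:

- **%G+C profiling** — per-read mean %G+C over the first 50 bp, binned into
  fifty 2%-wide bins, so libraries with very different read lengths are
  compared on equal footing;
- **duplicate analyses** — duplication-level spectra over the starting
  50 bp (levels 1–9 and ≥10), plus *artificial*-duplicate detection by the
  identical-start / >95%-identity rule, and the natural = total − artificial
  decomposition;
- **functional profiling** — six-frame translated k-mer recruitment of
  length-normalised (100 bp) reads to a protein-cluster reference, compared
  through the hit frequencies of the most abundant clusters;
- **assembly metrics** — N50 (cumulative ≥ half-total rule), maximum
  contig, total size, reads/bp assembled;
- **comparison machinery** — pairwise Pearson *r* between library profiles,
  UPGMA clustering of *d* = 1 − *r*, and bootstrap support (BP%) per node
  from resampling profile positions (100 replicates by default);
- **QC** — whole-read filtering (mean PHRED, length) for long-read
  platforms and two-sided longest-run trimming for short-read platforms,
  discard-mode adapter removal, 50 bp length floor.

A library-preparation **simulator** generates toy viral communities and
sequencing libraries with explicit ground truth (source fragment per read,
PCR duplicates, adapter contamination), including GC-dependent
amplification bias per cycle, `eff(gc) = exp(−strength·(gc−optimum)²/width²)`,
and loss of low-GC fragments. Platform presets follow typical raw-read
models (Illumina 100 bp PE / PHRED ~34; 454 at 408±11 bp; linker-amplified
454 at 377±15 bp; Ion Torrent at 105±5 bp / PHRED ~16).

## Worked example

Simulate two treatments (no amplification vs 12 cycles with a strong
GC-bias) × two replicates from one community, then compare their %G+C
profiles:

```r
library(virolib)

com <- generate_community(community_config(
  n_genomes = 12, genome_length = 30000,
  gc_target = seq(0.30, 0.60, length.out = 12), seed = 101))
unamp <- platform_preset("illumina", amp_cycles = 0L)
amp   <- platform_preset("illumina", amp_cycles = 12L,
                         gc_bias = list(optimum = 0.65, width = 0.15, strength = 1.2),
                         low_gc_loss = 1)
libs <- list(U_A = unamp, U_B = unamp, A_A = amp, A_B = amp)
profs <- profile_matrix(lapply(names(libs), function(id)
  profile_library(simulate_library(com, libs[[id]], 40000, 50000,
                                   seed = match(id, names(libs)) + 110,
                                   library_id = id), library_id = id)))
round(pearson_matrix(profs), 4)
#>        U_A    U_B    A_A    A_B
#> U_A 1.0000 0.9982 0.3453 0.3301
#> U_B 0.9982 1.0000 0.3519 0.3361
#> A_A 0.3453 0.3519 1.0000 0.9968
#> A_B 0.3301 0.3361 0.9968 1.0000

boot <- bootstrap_support(profs, n_boot = 100, seed = 5)
to_newick(boot$tree, supports = boot$supports)
#> "((U_A:0.00088826,U_B:0.00088826)100:0.328693,(A_A:0.00158539,A_B:0.00158539)100:0.327996)100;"
```

Replicates correlate at *r* > 0.99 and co-cluster with 100% bootstrap
support, while the GC-biased amplification treatment separates sharply
(between-treatment *r* ≈ 0.33): amplification bias, not replication noise,
dominates the comparison. The same machinery runs on duplicate spectra and
protein-cluster frequencies, and `run_pipeline()` orchestrates all stages
over a manifest TSV (see `analysis/` for the numbered end-to-end drivers,
which write their tables under `results/`).

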