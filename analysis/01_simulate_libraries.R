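#!/usr/bin/env Rscript
# Simulate the library-preparation experiment: one shared viral community
# sequenced under two treatments (no amplification vs 12 cycles of GC-biased
# amplification), two replicates each, 50,000 reads per library.
#
# Writes FASTQs, truth tables, contig fixtures and the library manifest under
# results/simulated/.

suppressPackageStartupMessages(library(virolib))

outdir <- "results/simulated"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

# A 12-genome community spanning 30-60% G+C — wide enough that a GC-dependent
# amplification efficiency visibly reshapes the read GC distribution.
com <- generate_community(community_config(
  n_genomes = 12, genome_length = 30000,
  gc_target = seq(0.30, 0.60, length.out = 12), seed = 101))
write_fasta(com$genomes, file.path(outdir, "community.fasta"))

unamp <- platform_preset("illumina", amp_cycles = 0L)
amp <- platform_preset("illumina", amp_cycles = 12L,
                       gc_bias = list(optimum = 0.65, width = 0.15, strength = 1.2),
                       low_gc_loss = 1)
protos <- list(U_A = unamp, U_B = unamp, A_A = amp, A_B = amp)

rows <- list()
for (i in seq_along(protos)) {
  id <- names(protos)[i]
  rd <- simulate_library(com, protos[[i]], n_fragments = 40000, n_reads = 50000,
                         seed = 110 + i, library_id = id)
  fq <- file.path(outdir, paste0(id, ".fastq"))
  write_fastq(rd[rd$pair == "F", ], fq)              # analyses run per mate
  write_truth_table(rd, file.path(outdir, paste0(id, "_truth.tsv")))
  ctg <- file.path(outdir, paste0(id, "_contigs.fasta"))
  write_fasta(simulate_contigs(com, n_contigs = 40, seed = 150 + i), ctg)
  rows[[i]] <- data.frame(
    library_id = id, fastq = fq, platform_style = "short-paired",
    input_dna_ng = protos[[i]]$input_dna_ng, amp_cycles = protos[[i]]$amp_cycles,
    replicate = sub("^.*_", "", id), mate = "F", contigs = ctg)
  message(sprintf("%s: %d cycles -> %d forward reads, %.1f%% truth-tagged duplicates",
                  id, protos[[i]]$amp_cycles, sum(rd$pair == "F"),
                  100 * mean(rd$is_pcr_duplicate)))
}
manifest <- do.call(rbind, rows)
write.table(manifest, file.path(outdir, "manifest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("manifest written to ", file.path(outdir, "manifest.tsv"))
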