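# Shared fixtures: tiny communities, protocols and oracle helpers.
# All randomness is seeded so every test is reproducible.

tiny_community <- function(n = 3, len = 5000, gc = 0.45, abundance = NULL,
                           seed = 42) {
  generate_community(community_config(n, len, gc_target = gc,
                                      abundance = abundance, seed = seed))
}

plain_protocol <- function(...) {
  args <- utils::modifyList(
    list(platform_style = "short-single", amp_cycles = 0L,
         read_len_fixed = 100L, mean_quality = 40, quality_decay = 0,
         fragment_len_mean = 300, fragment_len_sd = 50, paired = FALSE),
    list(...))
  do.call(library_protocol, args)
}

# quality string from integer PHRED scores
phred_string <- function(scores) intToUtf8(scores + 33L)

# independent trimming oracle: check every (i, j) window and keep the longest
# one whose bases all pass the threshold (first found of maximal length, i.e.
# leftmost on ties)
trim_oracle <- function(scores, threshold) {
  n <- length(scores)
  best <- c(0L, 0L)
  best_len <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(scores[i:j] >= threshold) && (j - i + 1L) > best_len) {
        best_len <- j - i + 1L
        best <- c(i, j)
      }
    }
  }
  best
}

# leaf-cluster sets implied by an hclust merge matrix (UPGMA oracle support)
hclust_cluster_sets <- function(hc) {
  n <- nrow(hc$merge) + 1L
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    grab <- function(x) if (x < 0) hc$labels[-x] else sets[[x]]
    sets[[k]] <- sort(c(grab(hc$merge[k, 1]), grab(hc$merge[k, 2])))
  }
  sets
}

# random symmetric distance matrix with labelled rows, continuous (tie-free)
random_distance_matrix <- function(n, labels = LETTERS[seq_len(n)]) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 1)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# standard-code reverse translation with one fixed codon per amino acid
reverse_translate <- function(peptide) {
  codon <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
             Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
             L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
             S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT",
             "*" = "TAA")
  paste(codon[strsplit(peptide, "")[[1]]], collapse = "")
}

# a 4-library manifest (2 treatments x 2 replicates) with FASTQs on disk:
# unamplified versus GC-biased amplification from one shared community
make_test_manifest <- function(dir, n_reads = 1200, with_contigs = FALSE,
                               seed_base = 120) {
  com <- generate_community(community_config(
    6, 20000, gc_target = seq(0.32, 0.58, length.out = 6), seed = seed_base))
  unamp <- platform_preset("illumina", amp_cycles = 0L)
  amp <- platform_preset("illumina", amp_cycles = 10L,
                         gc_bias = list(optimum = 0.62, width = 0.15, strength = 1.2),
                         low_gc_loss = 1)
  protos <- list(U_A = unamp, U_B = unamp, A_A = amp, A_B = amp)
  rows <- list()
  for (i in seq_along(protos)) {
    id <- names(protos)[i]
    rd <- simulate_library(com, protos[[i]], 5000, n_reads,
                           seed = seed_base + i, library_id = id)
    fq <- file.path(dir, paste0(id, ".fastq"))
    write_fastq(rd[rd$pair == "F", ], fq)
    contigs <- ""
    if (with_contigs) {
      contigs <- file.path(dir, paste0(id, "_contigs.fasta"))
      write_fasta(simulate_contigs(com, 15, seed = seed_base + 50 + i), contigs)
    }
    rows[[i]] <- tibble::tibble(
      library_id = id, fastq = fq, platform_style = "short-paired",
      input_dna_ng = 1000, amp_cycles = protos[[i]]$amp_cycles,
      replicate = sub("^.*_", "", id), mate = "F", contigs = contigs)
  }
  list(manifest = do.call(rbind, rows), community = com)
}

# deterministic pseudo-random DNA for hand-built read sets
random_dna <- function(n, len, seed = 1) {
  withr::with_seed(seed,
    vapply(seq_len(n),
           function(i) paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
           character(1)))
}
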