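test_that("community generation is seeded, GC-controlled and validated", {
  cfg <- community_config(2, 50000, gc_target = 0.5, seed = 7)
  com1 <- generate_community(cfg)
  com2 <- generate_community(cfg)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(com1$genomes, f1); write_fasta(com2$genomes, f2)
  expect_identical(readLines(f1), readLines(f2))

  gc <- as.numeric(Biostrings::letterFrequency(com1$genomes, "GC")) /
    Biostrings::width(com1$genomes)
  expect_true(all(gc >= 0.48 & gc <= 0.52))

  expect_error(community_config(0, 1000), "n_genomes")
  expect_error(community_config(2, 50), "genome_length")
  expect_error(community_config(2, 1000, gc_target = 1.0), "gc_target")
  expect_error(community_config(2, 1000, abundance = c(0.7, 0.2)), "abundance")
})

test_that("fragment origins follow abundance weights and the length model", {
  com1 <- tiny_community(n = 1, len = 5000)
  fr <- simulate_fragments(com1, plain_protocol(), 500, seed = 1)
  expect_setequal(unique(fr$genome_id), "genome_001")

  com2 <- tiny_community(n = 2, len = 5000, abundance = c(0.9, 0.1), seed = 5)
  fr2 <- simulate_fragments(com2, plain_protocol(), 10000, seed = 2)
  n1 <- sum(fr2$genome_id == "genome_001")
  ci <- qbinom(c(0.005, 0.995), 10000, 0.9)  # binomial 99% CI oracle
  expect_gte(n1, ci[1]); expect_lte(n1, ci[2])

  fr3 <- simulate_fragments(com1, plain_protocol(fragment_len_sd = 0), 200, seed = 3)
  expect_true(all(fr3$length == 300L))
  expect_true(all(nchar(fr3$sequence) == 300L))
  expect_error(simulate_fragments(com1, plain_protocol(), 0), "n_fragments")
})

test_that("amplification is identity at 0 cycles and unbiased when strength is 0", {
  com <- tiny_community(n = 4, len = 20000, gc = c(0.3, 0.4, 0.5, 0.6), seed = 9)
  proto0 <- plain_protocol(amp_cycles = 0L)
  fr <- simulate_fragments(com, proto0, 10000, seed = 4)
  expect_identical(amplify_pool(fr, proto0, seed = 1), fr)

  proto5 <- plain_protocol(amp_cycles = 5L,
                           gc_bias = list(optimum = 0.5, width = 0.15, strength = 0))
  pool <- amplify_pool(fr, proto5, seed = 5)
  expect_identical(pool$fragment_id, fr$fragment_id)  # no loss either
  # copy-weighted GC distribution matches the input distribution
  draw <- withr::with_seed(6, sample(pool$gc, 10000, replace = TRUE, prob = pool$copies))
  ks <- suppressWarnings(stats::ks.test(draw, fr$gc))
  expect_gt(ks$p.value, 0.01)
})

test_that("GC-favoured fragments amplify more under strong bias", {
  frags <- tibble::tibble(
    fragment_id = sprintf("f%04d", 1:2000),
    genome_id = "g", start = 1L, length = 100L,
    sequence = strrep("A", 100),
    gc = rep(c(0.3, 0.5), each = 1000), copies = 1)
  proto <- plain_protocol(amp_cycles = 6L,
                          gc_bias = list(optimum = 0.5, width = 0.1, strength = 25))
  pool <- amplify_pool(frags, proto, seed = 11)
  mean_copies <- tapply(pool$copies, pool$gc, mean)
  expect_gt(mean_copies[["0.5"]], mean_copies[["0.3"]])
})

test_that("sequencing emits fixed-length mate pairs with truth tags intact", {
  com <- tiny_community(n = 2, len = 8000, seed = 12)
  proto <- platform_preset("illumina", amp_cycles = 0L)
  fr <- simulate_fragments(com, proto, 2000, seed = 13)
  rd <- sequence_pool(fr, proto, 1000, seed = 14, library_id = "pe")
  expect_true(all(nchar(rd$sequence) == 100L))
  expect_equal(as.integer(table(rd$pair)[c("F", "R")]), c(500L, 500L))
  expect_true(all(rd$source_fragment_id %in% fr$fragment_id))
  expect_true(all(rd$source_genome_id %in% names(com$genomes)))
  # a flagged duplicate always shares its fragment with another read
  dup_frags <- rd$source_fragment_id[rd$is_pcr_duplicate]
  expect_true(all(table(rd$source_fragment_id)[unique(dup_frags)] >= 2))
  expect_error(sequence_pool(fr[0, ], proto, 10), "empty")
})

test_that("base-call error rate follows the quality model", {
  com <- tiny_community(n = 1, len = 20000, seed = 15)
  proto <- plain_protocol(mean_quality = 40, quality_decay = 0)
  fr <- simulate_fragments(com, proto, 5000, seed = 16)
  rd <- sequence_pool(fr, proto, 10000, seed = 17)  # 1e6 sequenced bases
  mism <- mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                 rd$sequence, rd$pre_error_sequence, USE.NAMES = FALSE)
  n_bases <- sum(nchar(rd$sequence))
  expect_equal(n_bases, 1e6)
  expected <- n_bases * 1e-4
  tol <- 3 * sqrt(n_bases * 1e-4)  # 3-sigma binomial
  expect_lt(abs(sum(mism) - expected), tol)
})

test_that("adapter contamination hits the configured rate", {
  com <- tiny_community(n = 1, len = 20000, seed = 18)
  proto <- plain_protocol(adapter_rate = 0.4, adapter_motif = "ACGTACGTTGCATGCATTGG")
  fr <- simulate_fragments(com, proto, 5000, seed = 19)
  rd <- sequence_pool(fr, proto, 10000, seed = 20)
  frac <- mean(startsWith(rd$sequence, proto$adapter_motif))
  expect_gte(frac, 0.37); expect_lte(frac, 0.43)
  expect_identical(startsWith(rd$sequence, proto$adapter_motif) & rd$has_adapter,
                   rd$has_adapter)
})

test_that("identical seeds reproduce a library byte-for-byte", {
  com <- tiny_community(n = 2, len = 6000, seed = 21)
  proto <- plain_protocol(adapter_rate = 0.1, amp_cycles = 4L)
  r1 <- simulate_library(com, proto, 1000, 800, seed = 22, library_id = "x")
  r2 <- simulate_library(com, proto, 1000, 800, seed = 22, library_id = "x")
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(r1, f1); write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # round-trip through FASTQ preserves sequences and qualities
  back <- read_fastq(f1)
  expect_identical(back$sequence, r1$sequence)
  expect_identical(back$quality, r1$quality)
})

test_that("duplicate load grows with amplification cycles", {
  com <- tiny_community(n = 3, len = 20000, gc = c(0.35, 0.45, 0.55), seed = 23)
  dup_frac <- vapply(c(0L, 4L, 8L, 12L), function(cyc) {
    proto <- plain_protocol(amp_cycles = cyc,
                            gc_bias = list(optimum = 0.45, width = 0.15, strength = 0.8))
    rd <- simulate_library(com, proto, 10000, 4000, seed = 24, library_id = "m")
    mean(rd$is_pcr_duplicate)
  }, numeric(1))
  expect_true(all(diff(dup_frac) >= 0))
})

test_that("bias-free amplification leaves the sequenced GC profile unchanged", {
  com <- generate_community(community_config(
    8, 30000, gc_target = seq(0.3, 0.6, length.out = 8), seed = 25))
  base <- plain_protocol(amp_cycles = 0L)
  amp <- plain_protocol(amp_cycles = 5L,
                        gc_bias = list(optimum = 0.5, width = 0.15, strength = 0))
  r0 <- simulate_library(com, base, 40000, 50000, seed = 26, library_id = "c0")
  r5 <- simulate_library(com, amp, 40000, 50000, seed = 27, library_id = "c5")
  p0 <- profile_library(r0)$bin_freqs
  p5 <- profile_library(r5)$bin_freqs
  expect_gt(cor(p0, p5), 0.99)
})
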