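test_that("duplication spectrum counts prefix groups into 10 levels", {
  distinct <- random_dna(100, 60, seed = 81)
  s <- duplicate_spectrum(distinct)
  expect_equal(unname(s$level_freqs[1]), 1)
  expect_equal(s$total_duplicate_fraction, 0)

  tenfold <- c(rep(distinct[1], 10), distinct[2:91])
  s2 <- duplicate_spectrum(tenfold)
  expect_equal(unname(s2$level_freqs[["10+"]]), 0.10)
  expect_equal(s2$total_duplicate_fraction, 0.10)
  expect_equal(s2$high_freq_fraction, 0.10)
  expect_equal(sum(s2$level_freqs), 1)

  # the prefix rule: identical first 50 bp counts as duplicate even if the
  # reads differ later
  a <- paste0(strrep("ACGTT", 10), strrep("G", 20))
  b <- paste0(strrep("ACGTT", 10), strrep("C", 20))
  s3 <- duplicate_spectrum(c(a, b))
  expect_equal(s3$total_duplicate_fraction, 1)
})

test_that("spectrum frequencies reconstruct the exact group counts", {
  withr::with_seed(82, {
    base <- random_dna(30, 55, seed = 83)
    reads <- sample(base, 400, replace = TRUE)
  })
  s <- duplicate_spectrum(reads)
  expect_equal(sum(s$level_freqs) * 400, 400)
  tab <- table(table(substr(reads, 1, 50)))
  manual_level1 <- if ("1" %in% names(tab)) as.integer(tab[["1"]]) else 0L
  expect_equal(unname(s$level_freqs[1]) * 400, manual_level1)
})

test_that("identity threshold is strict: 96% joins, 94% (and 95%) do not", {
  base <- random_dna(1, 100, seed = 84)
  mutate_at <- function(s, pos) {
    for (p in pos) {
      old <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    s
  }
  pair96 <- read_set(c("s", "q96"), c(base, mutate_at(base, c(30, 45, 60, 75))))
  expect_equal(detect_artificial(pair96)$artificial_fraction, 1)

  pair94 <- read_set(c("s", "q94"), c(base, mutate_at(base, c(30, 40, 50, 60, 70, 80))))
  expect_equal(detect_artificial(pair94)$artificial_fraction, 0)

  pair95 <- read_set(c("s", "q95"), c(base, mutate_at(base, c(30, 40, 50, 60, 75))))
  expect_equal(detect_artificial(pair95)$artificial_fraction, 0)  # > is strict

  # but reads differing only inside the anchor never co-cluster
  pair_anchor <- read_set(c("s", "qa"), c(base, mutate_at(base, c(5))))
  expect_equal(detect_artificial(pair_anchor)$artificial_fraction, 0)
})

test_that("full-identity detection reduces to exact duplicate grouping", {
  withr::with_seed(85, {
    base <- random_dna(40, 80, seed = 86)
    seqs <- sample(base, 200, replace = TRUE)
  })
  reads <- read_set(sprintf("r%03d", seq_along(seqs)), seqs)
  det <- detect_artificial(reads, start_anchor = 80, identity = 1.0)
  # oracle: hash-based exact grouping
  exact_frac <- mean(table(seqs)[seqs] >= 2)
  expect_equal(det$artificial_fraction, exact_frac)
  sizes_det <- sort(lengths(det$clusters))
  expect_equal(sizes_det, sort(unname(as.integer(table(seqs)))))
})

test_that("lowering the identity threshold never decreases the artificial fraction", {
  com <- tiny_community(n = 2, len = 20000, seed = 87)
  proto <- plain_protocol(amp_cycles = 5L, mean_quality = 25,
                          gc_bias = list(optimum = 0.45, width = 0.15, strength = 0.5))
  rd <- simulate_library(com, proto, 1500, 1500, seed = 88)
  fracs <- vapply(c(0.99, 0.97, 0.95, 0.90, 0.80), function(thr)
    detect_artificial(rd, identity = thr)$artificial_fraction, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("indel mode absorbs a 1-base slip that substitution mode rejects", {
  base <- random_dna(1, 100, seed = 89)
  slipped <- substr(paste0(substr(base, 1, 50), "A", substr(base, 51, 100)), 1, 100)
  pair <- read_set(c("s", "slip"), c(base, slipped))
  expect_equal(detect_artificial(pair, mode = "substitution")$artificial_fraction, 0)
  expect_equal(detect_artificial(pair, mode = "indel")$artificial_fraction, 1)
})

test_that("banded edit distance agrees with the unrestricted oracle", {
  withr::with_seed(90, {
    for (i in 1:50) {
      a <- random_dna(1, sample(20:60, 1), seed = 900 + i)
      # mutate/indel a into b with a few edits (inside the band)
      b <- a
      for (k in seq_len(sample(0:3, 1))) {
        p <- sample(nchar(b), 1)
        op <- sample(c("sub", "ins", "del"), 1)
        b <- switch(op,
          sub = { substr(b, p, p) <- sample(c("A", "C", "G", "T"), 1); b },
          ins = paste0(substr(b, 1, p), sample(c("A", "C", "G", "T"), 1),
                       substr(b, p + 1, nchar(b))),
          del = paste0(substr(b, 1, p - 1), substr(b, p + 1, nchar(b))))
      }
      expect_equal(virolib:::banded_edit_distance(a, b, band = 4L),
                   as.integer(utils::adist(a, b)))
    }
  })
})

test_that("natural duplicates are the excess over detected artificial ones", {
  seqs <- c(rep(random_dna(1, 60, seed = 91), 3), random_dna(7, 60, seed = 92))
  reads <- read_set(sprintf("r%02d", 1:10), seqs)
  spec <- duplicate_spectrum(reads)
  det <- detect_artificial(reads)
  dec <- natural_minus_artificial(spec, det)
  expect_equal(dec$natural_fraction, 0)  # all duplicates detected as artificial

  # constructed decomposition: total 0.30, artificial 0.25 -> natural 0.05
  fake_spec <- spec; fake_spec$total_duplicate_fraction <- 0.30
  fake_det <- det; fake_det$artificial_fraction <- 0.25
  expect_equal(natural_minus_artificial(fake_spec, fake_det)$natural_fraction, 0.05)

  short <- duplicate_spectrum(reads[1:5, ])
  expect_error(natural_minus_artificial(short, det), "different read sets")
})

test_that("empty input yields an empty cluster set", {
  det <- detect_artificial(read_set(character(), character(), character()))
  expect_length(det$clusters, 0)
  expect_equal(det$artificial_fraction, 0)
})
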