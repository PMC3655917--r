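test_that("length normalisation yields only exact 100 bp reads", {
  reads <- read_set(c("long", "short", "exact", "mid"),
                    c(strrep("ACGT", 90), strrep("A", 99), strrep("G", 100),
                      strrep("C", 150)))
  norm <- normalize_reads_for_pc(reads)
  expect_setequal(norm$id, c("long", "exact", "mid"))
  expect_true(all(nchar(norm$sequence) == 100))
  expect_identical(norm$sequence[norm$id == "long"], strrep("ACGT", 25))
})

test_that("six-frame translation follows the standard code", {
  expect_equal(translate_six_frames("ATG")[["F1"]], "M")
  expect_equal(translate_six_frames("TAA")[["F1"]], "*")
  expect_equal(translate_six_frames("ATGAAATAA")[["F1"]], "MK*")
  s <- "ATGGCCTTTAGGCAT"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(translate_six_frames(s)[["R1"]], translate_six_frames(rc)[["F1"]])
  # partial trailing codons are dropped; N becomes X
  expect_equal(translate_six_frames("ATGAA")[["F1"]], "M")
  expect_equal(translate_six_frames("ATNGGG")[["F1"]], "XG")
  expect_error(translate_six_frames("AT"), ">= 3")
})

test_that("reads recruit to the cluster whose peptide they encode", {
  withr::with_seed(101, {
    aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    peptides <- vapply(1:10, function(i)
      paste(sample(aa, 60, replace = TRUE), collapse = ""), character(1))
  })
  db <- pc_db(setNames(peptides, sprintf("PC_%04d", 1:10)))

  # a read encoding an exact 30-aa substring of PC_0007's representative
  target <- substr(peptides[7], 11, 40)
  read_seq <- substr(paste0(reverse_translate(target), strrep("A", 10)), 1, 100)
  expect_identical(map_read_to_pc(read_seq, db), "PC_0007")

  # poly-A read: its frames share no 4-mers with the db
  expect_true(is.na(map_read_to_pc(strrep("A", 100), db)))

  # seed-count tie between two identical clusters: smaller id wins
  db_tie <- pc_db(setNames(c(peptides[1], peptides[1]), c("PC_B", "PC_A")))
  read1 <- substr(paste0(reverse_translate(substr(peptides[1], 1, 30)),
                         strrep("A", 10)), 1, 100)
  expect_identical(map_read_to_pc(read1, db_tie), "PC_A")

  # min_seeds gate: a single shared 4-mer is not enough by default
  lone <- paste0(substr(target, 1, 4), strrep("W", 29))
  db_lone <- pc_db(c(PC_X = lone))
  expect_true(is.na(map_read_to_pc(read_seq, db_lone)))
  expect_identical(map_read_to_pc(read_seq, db_lone, min_seeds = 1L), "PC_X")
})

test_that("mapping is deterministic and blind to bases beyond 100 bp", {
  com <- tiny_community(n = 2, len = 20000, seed = 102)
  db <- synthetic_pc_db(com, n_clusters = 20, seed = 103)
  proto <- plain_protocol(read_len_fixed = 150L)
  rd <- simulate_library(com, proto, 3000, 500, seed = 104)
  rd <- rd[nchar(rd$sequence) == 150L, ]  # fragments shorter than the read model
  a1 <- map_read_to_pc(normalize_reads_for_pc(rd), db)
  a2 <- map_read_to_pc(normalize_reads_for_pc(rd), db)
  expect_identical(a1, a2)
  # appending bases beyond 100 never changes an assignment
  extended <- rd
  extended$sequence <- paste0(extended$sequence, strrep("G", 30))
  extended$quality <- paste0(extended$quality, strrep("I", 30))
  a3 <- map_read_to_pc(normalize_reads_for_pc(extended), db)
  expect_identical(a1$cluster_id, a3$cluster_id)
})

test_that("top-cluster table ranks by summed hits and normalises per library", {
  hits <- tibble::tibble(
    library_id = c("L1", "L1", "L1", "L2", "L2"),
    cluster_id = c("PC_a", "PC_b", "PC_c", "PC_a", "PC_c"),
    hits = c(5L, 1L, 4L, 5L, 6L))
  top2 <- top_pc_table(hits, n_top = 2)
  expect_equal(top2$clusters, c("PC_a", "PC_c"))  # totals 10 and 10, ties by id
  expect_equal(top2$frequencies["L1", "PC_a"], 0.5)
  expect_equal(top2$frequencies["L2", "PC_c"], 6 / 11)

  all3 <- top_pc_table(hits, n_top = 10)
  expect_equal(ncol(all3$frequencies), 3)

  solo <- top_pc_table(tibble::tibble(library_id = "L", cluster_id = "PC_z",
                                      hits = 7L))
  expect_equal(unname(solo$frequencies[1, 1]), 1)
  expect_error(top_pc_table(hits[0, ]), "no protein-cluster hits")
})

test_that("hit tables round-trip through the TSV interchange schema", {
  hits <- tibble::tibble(library_id = c("L1", "L2"),
                         cluster_id = c("PC_a", "PC_b"), hits = c(3L, 9L))
  path <- tempfile(fileext = ".tsv")
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_hit_table(path)
  expect_equal(as.data.frame(back), as.data.frame(hits))
})

test_that("replicate cluster profiles correlate better than altered communities", {
  ab <- 0.6^(0:5); ab <- ab / sum(ab)
  com <- generate_community(community_config(
    6, 30000, gc_target = seq(0.38, 0.52, length.out = 6), abundance = ab,
    seed = 105))
  db <- synthetic_pc_db(com, n_clusters = 24, seed = 106)
  proto <- plain_protocol(mean_quality = 35)
  mk <- function(seed, id)
    map_library_to_pc(simulate_library(com, proto, 40000, 8000, seed = seed,
                                       library_id = id), db, library_id = id)
  h1 <- mk(107, "rep1"); h2 <- mk(108, "rep2")
  v <- top_pc_table(list(h1, h2))$frequencies
  expect_gt(cor(v["rep1", ], v["rep2", ]), 0.8)

  # permuting community structure pulls the correlation down
  com_perm <- generate_community(community_config(
    6, 30000, gc_target = seq(0.38, 0.52, length.out = 6), abundance = rev(ab),
    seed = 105))
  h3 <- map_library_to_pc(simulate_library(com_perm, proto, 40000, 8000,
                                           seed = 109, library_id = "perm"),
                          db, library_id = "perm")
  v3 <- top_pc_table(list(h1, h2, h3))$frequencies
  expect_lt(cor(v3["rep1", ], v3["perm", ]), cor(v3["rep1", ], v3["rep2", ]))
})
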