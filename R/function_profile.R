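# Functional profiling: length-normalised reads are recruited to a
# protein-cluster reference by exact translated k-mer seed matching, and the
# per-library hit frequencies of the top-N clusters feed the comparison
# machinery. The seed matcher is a deterministic, self-contained stand-in for
# an external homology search; externally produced read->cluster hit tables
# can be imported in the same TSV schema via read_hit_table().

#' Protein-cluster reference database
#'
#' @param x a data frame with columns `cluster_id` and `peptide` (one row per
#'   representative; clusters may have several), or a named character vector
#'   of peptides (names = cluster ids, repeated names allowed). Peptides use
#'   the 20-letter amino-acid alphabet plus X and `*` (stop).
#' @return A `pc_db`: tibble with columns `cluster_id`, `peptide`.
#' @export
pc_db <- function(x) {
  if (is.character(x)) x <- tibble(cluster_id = names(x), peptide = unname(x))
  x <- as_tibble(x)[, c("cluster_id", "peptide")]
  if (nrow(x) == 0L) stop("empty protein-cluster database")
  x$peptide <- toupper(x$peptide)
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", x$peptide)))
    stop("peptides must use the 20-letter alphabet plus X/*")
  structure(x, class = c("pc_db", class(x)))
}

#' Read a protein-cluster database from FASTA
#'
#' The first whitespace-delimited token of each header is the cluster id;
#' repeated ids contribute multiple representatives to one cluster.
#'
#' @param path FASTA file of representative peptides.
#' @return A [pc_db()].
#' @export
read_pc_db <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "[ \t]"), `[`, character(1), 1L)
  pc_db(tibble(cluster_id = ids, peptide = as.character(aa)))
}

#' Length-normalise reads for protein-cluster mapping
#'
#' Removes reads under `target_len` bp and truncates longer reads to their
#' first `target_len` bp, so every mapped read contributes the same sequence
#' length regardless of platform.
#'
#' @param reads a read tibble.
#' @param target_len normalised read length in bp (default 100).
#' @return Read tibble in which every sequence is exactly `target_len` bp.
#' @export
normalize_reads_for_pc <- function(reads, target_len = 100L) {
  keep <- reads[nchar(reads$sequence) >= target_len, , drop = FALSE]
  keep$sequence <- substr(keep$sequence, 1L, target_len)
  keep$quality <- substr(keep$quality, 1L, target_len)
  keep
}

#' Six-frame translation
#'
#' Translates frames +1..+3 of the sequence and +1..+3 of its reverse
#' complement under the standard genetic code; stop codons are emitted as
#' `*`, fuzzy codons (containing N) as `X`, and trailing partial codons are
#' dropped.
#'
#' @param sequence a single nucleotide sequence of length >= 3.
#' @return Named character vector of 6 peptides (`F1 F2 F3 R1 R2 R3`); a
#'   frame too short to hold one codon gives `""`.
#' @examples
#' translate_six_frames("ATGAAATAA")[["F1"]]  # "MK*"
#' @export
translate_six_frames <- function(sequence) {
  if (length(sequence) != 1L || nchar(sequence) < 3L)
    stop("sequence must be a single string of length >= 3")
  fwd <- Biostrings::DNAString(toupper(sequence))
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, f) {
    L <- length(s)
    w <- ((L - f + 1L) %/% 3L) * 3L
    if (w < 3L) return("")
    as.character(Biostrings::translate(Biostrings::subseq(s, f, f + w - 1L),
                                       if.fuzzy.codon = "X"))
  }
  c(F1 = one(fwd, 1L), F2 = one(fwd, 2L), F3 = one(fwd, 3L),
    R1 = one(rev, 1L), R2 = one(rev, 2L), R3 = one(rev, 3L))
}

# distinct k-mers of one peptide string
peptide_kmers <- function(p, k) {
  L <- nchar(p)
  if (L < k) return(character(0))
  unique(substring(p, 1:(L - k + 1L), k:L))
}

# kmer -> cluster_id index over all representatives, distinct pairs
pc_db_index <- function(db, k) {
  lst <- lapply(seq_len(nrow(db)), function(i) peptide_kmers(db$peptide[i], k))
  dt <- data.table::data.table(
    cluster_id = rep(db$cluster_id, lengths(lst)),
    kmer = unlist(lst, use.names = FALSE))
  unique(dt)
}

#' Map reads to protein clusters by translated k-mer seeds
#'
#' For each of a read's six frame peptides, the number of distinct peptide
#' `seed_k`-mers shared with each cluster's representatives is counted; the
#' read's score for a cluster is the best frame's count. The read is assigned
#' to the highest-scoring cluster if its score is >= `min_seeds` (ties go to
#' the lexicographically smallest cluster id), otherwise to none. Mapping is
#' fully deterministic.
#'
#' @param reads a read tibble of length-normalised reads (see
#'   [normalize_reads_for_pc()]); also accepts a single sequence string.
#' @param db a [pc_db()].
#' @param seed_k peptide k-mer size (default 4).
#' @param min_seeds minimum shared distinct k-mers to accept an assignment.
#' @return Tibble with `read_id`, `cluster_id` (`NA` for unmapped) and
#'   `n_seeds`; for a single sequence, the cluster id (or `NA`).
#' @export
map_read_to_pc <- function(reads, db, seed_k = 4L, min_seeds = 2L) {
  single <- is.character(reads)
  if (single) reads <- read_set("query", reads)
  if (!inherits(db, "pc_db")) db <- pc_db(db)
  if (nrow(db) == 0L) stop("empty protein-cluster database")
  res <- map_reads_internal(reads, db, seed_k, min_seeds)
  if (single) res$cluster_id[1] else res
}

map_reads_internal <- function(reads, db, seed_k, min_seeds) {
  n <- nrow(reads)
  empty <- tibble(read_id = reads$id, cluster_id = NA_character_,
                  n_seeds = 0L)
  if (n == 0L) return(empty)
  idx <- pc_db_index(db, seed_k)
  if (nrow(idx) == 0L) return(empty)

  # vectorised six-frame translation across all reads
  fwd <- Biostrings::DNAStringSet(toupper(reads$sequence))
  rev <- Biostrings::reverseComplement(fwd)
  widths <- Biostrings::width(fwd)
  frame_pep <- function(strand, f) {
    w <- ((widths - f + 1L) %/% 3L) * 3L
    ok <- w >= 3L
    out <- character(length(w))
    if (any(ok)) {
      sub <- Biostrings::subseq(strand[ok], start = f, width = w[ok])
      out[ok] <- as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
    }
    out
  }
  peps <- c(lapply(1:3, function(f) frame_pep(fwd, f)),
            lapply(1:3, function(f) frame_pep(rev, f)))

  # read x frame distinct k-mers, joined against the db index
  pieces <- lapply(seq_along(peps), function(fr) {
    km <- lapply(peps[[fr]], peptide_kmers, k = seed_k)
    data.table::data.table(read = rep(seq_len(n), lengths(km)),
                           frame = fr,
                           kmer = unlist(km, use.names = FALSE))
  })
  rk <- data.table::rbindlist(pieces)
  if (nrow(rk) == 0L) return(empty)
  hits <- merge(rk, idx, by = "kmer", allow.cartesian = TRUE)
  if (nrow(hits) == 0L) return(empty)
  counts <- hits[, list(n_seeds = data.table::uniqueN(kmer)),
                 by = c("read", "frame", "cluster_id")]
  best_frame <- counts[, list(n_seeds = max(n_seeds)), by = c("read", "cluster_id")]
  data.table::setorder(best_frame, read, -n_seeds, cluster_id)
  top <- best_frame[!duplicated(read)]
  top <- top[top$n_seeds >= min_seeds]
  out <- empty
  out$cluster_id[top$read] <- top$cluster_id
  out$n_seeds[top$read] <- top$n_seeds
  out
}

#' Map one library and tally cluster hits
#'
#' Length-normalises the reads, maps them, and returns per-cluster hit
#' counts plus the mapped fraction.
#'
#' @inheritParams map_read_to_pc
#' @param library_id label for the output.
#' @param target_len length-normalisation target in bp.
#' @return List with `hits` (tibble: `library_id`, `cluster_id`, `hits`),
#'   `n_reads` (reads entering normalisation), `n_normalized`, `n_mapped`
#'   and `mapped_fraction` (of normalised reads).
#' @export
map_library_to_pc <- function(reads, db, seed_k = 4L, min_seeds = 2L,
                              library_id = "lib", target_len = 100L) {
  norm <- normalize_reads_for_pc(reads, target_len)
  asg <- map_read_to_pc(norm, db, seed_k = seed_k, min_seeds = min_seeds)
  mapped <- asg[!is.na(asg$cluster_id), , drop = FALSE]
  tab <- table(mapped$cluster_id)
  list(library_id = library_id,
       hits = tibble(library_id = rep(library_id, length(tab)),
                     cluster_id = names(tab), hits = as.integer(tab)),
       n_reads = nrow(reads), n_normalized = nrow(norm),
       n_mapped = nrow(mapped),
       mapped_fraction = if (nrow(norm)) nrow(mapped) / nrow(norm) else 0)
}

#' Read an externally produced hit table
#'
#' Accepts the TSV schema `library_id, cluster_id, hits` so users who ran a
#' real homology search can feed its results into [top_pc_table()].
#'
#' @param path TSV file.
#' @return Tibble with those columns.
#' @export
read_hit_table <- function(path) {
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Hit-frequency table of the most abundant protein clusters
#'
#' Ranks clusters by total hits summed across libraries (ties by cluster id),
#' keeps the top `n_top`, and converts hits to frequencies per library
#' (hits / mapped reads in that library).
#'
#' @param hit_tables list of [map_library_to_pc()] results, or a single
#'   tibble `library_id, cluster_id, hits` (in which case mapped counts are
#'   the per-library hit sums).
#' @param n_top clusters to retain (default 1500; effectively
#'   `min(n_top, clusters present)`).
#' @return A `pc_hit_table`: list with `frequencies` (libraries x clusters
#'   matrix), `clusters` (retained ids in rank order), `mapped_fraction`
#'   (named per-library vector, `NA` when unknown) and `n_top`.
#' @export
top_pc_table <- function(hit_tables, n_top = 1500L) {
  if (is.data.frame(hit_tables)) {
    hits <- as_tibble(hit_tables)
    mapped <- tapply(hits$hits, hits$library_id, sum)
    mapped_fraction <- setNames(rep(NA_real_, length(mapped)), names(mapped))
  } else {
    hits <- do.call(rbind, lapply(hit_tables, `[[`, "hits"))
    mapped <- vapply(hit_tables, `[[`, numeric(1), "n_mapped")
    names(mapped) <- vapply(hit_tables, `[[`, character(1), "library_id")
    mf <- vapply(hit_tables, `[[`, numeric(1), "mapped_fraction")
    mapped_fraction <- setNames(mf, names(mapped))
  }
  if (is.null(hits) || nrow(hits) == 0L || sum(hits$hits) == 0)
    stop("no protein-cluster hits to tabulate")
  totals <- tapply(hits$hits, hits$cluster_id, sum)
  rank <- order(-totals, names(totals))
  keep <- names(totals)[rank][seq_len(min(n_top, length(totals)))]
  libs <- sort(unique(hits$library_id))
  freq <- matrix(0, nrow = length(libs), ncol = length(keep),
                 dimnames = list(libs, keep))
  sub <- hits[hits$cluster_id %in% keep, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    freq[sub$library_id[i], sub$cluster_id[i]] <-
      sub$hits[i] / mapped[[sub$library_id[i]]]
  }
  structure(list(frequencies = freq, clusters = keep,
                 mapped_fraction = mapped_fraction[libs], n_top = n_top),
            class = "pc_hit_table")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
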