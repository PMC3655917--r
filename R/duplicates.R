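# Duplicate analyses. The duplication-level spectrum groups raw reads by
# exact identity of their first 50 bp and bins group sizes 1-9 and >=10;
# artificial duplicates (amplification/instrument artifacts) are detected by
# greedy identical-start / >95%-identity clustering, and the natural level is
# the remainder.

#' Duplication-level spectrum over read prefixes
#'
#' Groups reads by exact identity of their first `prefix` bases (reads
#' shorter than `prefix` group by their full sequence). A group of size `k`
#' contributes `k` reads to level `min(k, 10)`; frequencies are normalised to
#' the total read count. Intended to run on raw (pre-QC) reads.
#'
#' @param reads a read tibble or a character vector of sequences.
#' @param prefix bp of the read start compared (default 50).
#' @param library_id label stored on the spectrum.
#' @return A `duplicate_spectrum`: list with `library_id`, `level_freqs`
#'   (10 frequencies, levels 1-9 and `"10+"`, summing to 1),
#'   `total_duplicate_fraction` (reads in groups of size >= 2),
#'   `high_freq_fraction` (reads in groups of size >= 10) and `n_reads`.
#' @export
duplicate_spectrum <- function(reads, prefix = 50L, library_id = "lib") {
  sequence <- if (is.character(reads)) reads else reads$sequence
  if (length(sequence) == 0L) stop("no reads given")
  key <- substr(sequence, 1L, prefix)
  tab <- table(key)
  k <- as.integer(tab[key])
  level <- pmin(k, 10L)
  level_freqs <- tabulate(level, nbins = 10L) / length(k)
  names(level_freqs) <- c(as.character(1:9), "10+")
  structure(list(library_id = library_id, level_freqs = level_freqs,
                 total_duplicate_fraction = mean(k >= 2L),
                 high_freq_fraction = mean(k >= 10L),
                 n_reads = length(k)),
            class = "duplicate_spectrum")
}

#' @export
print.duplicate_spectrum <- function(x, ...) {
  cat(sprintf(
    "Duplicate spectrum '%s': %d reads, %.1f%% duplicated (%.2f%% at >=10-fold)\n",
    x$library_id, x$n_reads, 100 * x$total_duplicate_fraction,
    100 * x$high_freq_fraction))
  invisible(x)
}

# pairwise identity over the aligned span
pair_identity <- function(a, b, mode, band = 4L) {
  la <- nchar(a); lb <- nchar(b)
  overlap <- min(la, lb)
  if (overlap == 0L) return(0)
  if (mode == "substitution") {
    av <- utf8ToInt(substr(a, 1L, overlap))
    bv <- utf8ToInt(substr(b, 1L, overlap))
    sum(av == bv) / overlap
  } else {
    1 - banded_edit_distance(a, b, band) / overlap
  }
}

# banded Levenshtein distance (band width `band` around the diagonal)
banded_edit_distance <- function(a, b, band = 4L) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  n <- length(av); m <- length(bv)
  if (abs(n - m) > band) return(abs(n - m) + band)  # outside the band: lower bound
  inf <- n + m
  prev <- c(0L, seq_len(m))
  prev[seq_len(m) > band] <- inf
  for (i in seq_len(n)) {
    cur <- rep(inf, m + 1L)
    lo <- max(1L, i - band); hi <- min(m, i + band)
    if (lo == 1L) cur[1L] <- i
    for (j in lo:hi) {
      cost <- if (av[i] == bv[j]) 0L else 1L
      cur[j + 1L] <- min(prev[j] + cost, prev[j + 1L] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Detect artificial duplicates by identical-start / identity clustering
#'
#' Greedy incremental clustering: reads are visited in order of decreasing
#' length (ties by id); each read joins the first existing cluster whose seed
#' (its first, longest read) shares an identical first
#' `min(start_anchor, read length)` bases **and** whose global identity over
#' the aligned span exceeds `identity`; otherwise the read seeds a new
#' cluster. Exact full-length matches always join. Identity is
#' matches/overlap in `"substitution"` mode, or `1 - edit_distance/overlap`
#' (banded, width 4) in `"indel"` mode. Reads in clusters of size >= 2 are
#' the artificial duplicates.
#'
#' @param reads a read tibble.
#' @param start_anchor bp of the identical start (default 20).
#' @param identity strict lower bound on pairwise identity, in `(0, 1]`.
#' @param mode `"substitution"` or `"indel"`.
#' @return A `duplicate_clusters`: list with `clusters` (list of read-id
#'   vectors, in creation order), `membership` (tibble: `read_id`,
#'   `cluster_id`), `artificial_fraction` and `n_reads`. Empty input gives an
#'   empty cluster set.
#' @export
detect_artificial <- function(reads, start_anchor = 20L, identity = 0.95,
                              mode = c("substitution", "indel")) {
  mode <- match.arg(mode)
  if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]")
  if (start_anchor < 1) stop("start_anchor must be >= 1")
  n <- nrow(reads)
  if (n == 0L) {
    return(structure(list(clusters = list(),
                          membership = tibble(read_id = character(),
                                              cluster_id = integer()),
                          artificial_fraction = 0, n_reads = 0L),
                     class = "duplicate_clusters"))
  }
  ord <- order(-nchar(reads$sequence), reads$id)
  seqs <- reads$sequence[ord]
  ids <- reads$id[ord]
  lens <- nchar(seqs)

  # clusters are only reachable through an identical anchor with the seed, so
  # bucket candidate seeds by anchor prefix
  seed_seq <- character(0)
  assignment <- integer(n)
  buckets <- new.env(parent = emptyenv())
  n_clusters <- 0L

  for (i in seq_len(n)) {
    anchor_len <- min(start_anchor, lens[i])
    key <- substr(seqs[i], 1L, start_anchor)  # full read when shorter
    cand <- if (lens[i] >= start_anchor) {
      get0(key, envir = buckets, ifnotfound = integer(0))
    } else {
      # short read: any cluster whose seed starts with the whole read
      which(substr(seed_seq, 1L, anchor_len) == seqs[i])
    }
    joined <- 0L
    for (cl in cand) {
      if (lens[i] >= start_anchor &&
          substr(seed_seq[cl], 1L, anchor_len) != substr(seqs[i], 1L, anchor_len))
        next
      iden <- pair_identity(seed_seq[cl], seqs[i], mode)
      if (iden > identity || iden >= 1) { joined <- cl; break }
    }
    if (joined) {
      assignment[i] <- joined
    } else {
      n_clusters <- n_clusters + 1L
      assignment[i] <- n_clusters
      seed_seq[n_clusters] <- seqs[i]
      if (lens[i] >= start_anchor) {
        assign(key, c(get0(key, envir = buckets, ifnotfound = integer(0)), n_clusters),
               envir = buckets)
      }
    }
  }

  clusters <- split(ids, assignment)
  clusters <- clusters[order(as.integer(names(clusters)))]
  names(clusters) <- NULL
  sizes <- lengths(clusters)
  structure(list(clusters = clusters,
                 membership = tibble(read_id = ids, cluster_id = assignment),
                 artificial_fraction = sum(sizes[sizes >= 2L]) / n,
                 n_reads = n),
            class = "duplicate_clusters")
}

#' Natural duplicate level as total minus artificial
#'
#' @param spectrum a [duplicate_spectrum()] of a read set.
#' @param clusters a [detect_artificial()] result over the same read set.
#' @return List with `total_fraction`, `artificial_fraction` and
#'   `natural_fraction = max(0, total - artificial)`.
#' @export
natural_minus_artificial <- function(spectrum, clusters) {
  if (spectrum$n_reads != clusters$n_reads)
    stop("spectrum and clusters describe different read sets (",
         spectrum$n_reads, " vs ", clusters$n_reads, " reads)")
  list(library_id = spectrum$library_id,
       total_fraction = spectrum$total_duplicate_fraction,
       artificial_fraction = clusters$artificial_fraction,
       natural_fraction = max(0, spectrum$total_duplicate_fraction -
                                clusters$artificial_fraction))
}
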