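# Two QC regimes are implemented, matching common practice per platform:
# whole-read filtering (mean-quality + length) for long-read data, and
# two-sided quality trimming (longest run of bases above a PHRED threshold)
# for short-read data, plus discard-mode adapter removal and a minimum-length
# filter.

#' QC parameters
#'
#' @param mode `"filter"` (whole-read filtering) or `"trim"` (two-sided
#'   quality trimming).
#' @param quality_threshold per-base PHRED threshold used by the trimmer.
#' @param min_mean_quality mean-PHRED threshold used by the whole-read filter.
#' @param min_length minimum read length kept, in bp; reads *under* this
#'   length are removed (a read of exactly `min_length` bp is kept).
#' @param adapter_motif adapter sequence (>= 8 bp) for discard-mode removal,
#'   or `NULL` to skip.
#' @return A `qc_params` list.
#' @export
qc_params <- function(mode = c("filter", "trim"), quality_threshold = 20,
                      min_mean_quality = 20, min_length = 50L,
                      adapter_motif = NULL) {
  mode <- match.arg(mode)
  if (min_length < 1) stop("min_length must be >= 1")
  if (quality_threshold < 0 || min_mean_quality < 0) stop("thresholds must be >= 0")
  structure(list(mode = mode, quality_threshold = quality_threshold,
                 min_mean_quality = min_mean_quality,
                 min_length = as.integer(min_length),
                 adapter_motif = adapter_motif),
            class = "qc_params")
}

#' Whole-read quality filtering
#'
#' Keeps a read iff its mean PHRED score is >= `min_mean_quality` and its
#' length is >= `min_length`; reports the aggregate failed fraction.
#'
#' @param reads a read tibble.
#' @param params a [qc_params()] (mode `"filter"`).
#' @param min_mean_quality,min_length override `params` when given.
#' @return List with `reads` (kept) and `summary` (tibble: `reads_in`,
#'   `reads_out`, `failed_fraction`). Empty input gives failed fraction 0.
#' @export
filter_whole_reads <- function(reads, params = qc_params("filter"),
                               min_mean_quality = params$min_mean_quality,
                               min_length = params$min_length) {
  n_in <- nrow(reads)
  if (n_in == 0L) {
    return(list(reads = reads,
                summary = tibble(reads_in = 0L, reads_out = 0L, failed_fraction = 0)))
  }
  keep <- read_mean_quality(reads) >= min_mean_quality &
    nchar(reads$sequence) >= min_length
  out <- reads[keep, , drop = FALSE]
  list(reads = out,
       summary = tibble(reads_in = n_in, reads_out = nrow(out),
                        failed_fraction = 1 - nrow(out) / n_in))
}

# longest contiguous run of scores >= threshold; leftmost on ties;
# returns c(start, end), c(0, 0) when no base passes
longest_quality_run <- function(quality, threshold) {
  qv <- phred_scores(quality)
  if (length(qv) == 0L) return(c(0L, 0L))
  r <- rle(qv >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values)
  if (!length(good)) return(c(0L, 0L))
  best <- good[which.max(r$lengths[good])]  # which.max is leftmost on ties
  c(starts[best], ends[best])
}

#' Two-sided quality trimming
#'
#' Each read is reduced to its longest contiguous run of bases whose PHRED
#' score is >= `quality_threshold` (leftmost run on ties), removing suspect
#' regions from both the 5' and 3' ends. A read with no passing base becomes
#' empty (length 0) and can be removed downstream with [drop_short_reads()].
#'
#' @param reads a read tibble.
#' @param params a [qc_params()] (mode `"trim"`).
#' @param quality_threshold override of `params$quality_threshold`.
#' @return The read tibble with trimmed `sequence`/`quality`.
#' @examples
#' r <- read_set("a", "ACGTACGT", intToUtf8(c(10, 10, 30, 30, 30, 10, 30, 30) + 33))
#' trim_reads(r, quality_threshold = 20)$sequence  # "GTA" (bases 3-5)
#' @export
trim_reads <- function(reads, params = qc_params("trim"),
                       quality_threshold = params$quality_threshold) {
  if (nrow(reads) == 0L) return(reads)
  span <- vapply(reads$quality, longest_quality_run, integer(2),
                 threshold = quality_threshold, USE.NAMES = FALSE)
  reads$sequence <- substr(reads$sequence, span[1L, ], span[2L, ])
  reads$quality <- substr(reads$quality, span[1L, ], span[2L, ])
  reads
}

#' Discard reads containing an adapter motif
#'
#' Reads containing an exact forward-orientation occurrence of the motif are
#' discarded entirely (clipper discard mode). Only forward mates and unpaired
#' reads are eligible; reverse mates are always retained.
#'
#' @param reads a read tibble.
#' @param motif adapter sequence, length >= 8.
#' @return The kept reads.
#' @export
remove_adapter_reads <- function(reads, motif) {
  if (is.null(motif) || nchar(motif) < 8)
    stop("adapter motif must be at least 8 bases")
  drop <- reads$pair %in% c("F", "U") &
    grepl(toupper(motif), reads$sequence, fixed = TRUE)
  reads[!drop, , drop = FALSE]
}

#' Remove reads under a minimum length
#'
#' @param reads a read tibble.
#' @param min_length bp; reads shorter than this are removed (a read of
#'   exactly `min_length` is kept).
#' @return The kept reads.
#' @export
drop_short_reads <- function(reads, min_length = 50L) {
  if (min_length < 1) stop("min_length must be >= 1")
  reads[nchar(reads$sequence) >= min_length, , drop = FALSE]
}

#' Run one library through QC
#'
#' Applies, in order: adapter discard (if a motif is configured), the
#' mode-specific step (whole-read filter or two-sided trim), and the
#' minimum-length filter. The reported failed fraction aggregates reads
#' removed by all causes.
#'
#' @param reads a read tibble.
#' @param params a [qc_params()].
#' @param library_id label copied into the summary.
#' @return List with `reads` and `summary` (tibble: `library_id`, `reads_in`,
#'   `reads_out`, `failed_fraction`).
#' @export
qc_library <- function(reads, params, library_id = "lib") {
  n_in <- nrow(reads)
  out <- reads
  if (!is.null(params$adapter_motif))
    out <- remove_adapter_reads(out, params$adapter_motif)
  if (params$mode == "filter") {
    out <- filter_whole_reads(out, params)$reads
  } else {
    out <- trim_reads(out, params)
  }
  out <- drop_short_reads(out, params$min_length)
  list(reads = out,
       summary = tibble(library_id = library_id, reads_in = n_in,
                        reads_out = nrow(out),
                        failed_fraction = if (n_in) 1 - nrow(out) / n_in else 0))
}
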