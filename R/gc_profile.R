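# %G+C profiling. The unit of analysis is the per-read mean %G+C over the
# first 50 bp — using a fixed window normalises for the large read-length
# differences across platforms — binned into fifty 2%-wide bins.

#' Mean \%G+C of the first bases of a sequence
#'
#' Computes `100 * (G+C count) / min(window, length)` over the first
#' `min(window, length)` bases, case-insensitively. Ambiguous bases (N) count
#' in the denominator but never as G+C, so they lower the read's \%G+C.
#'
#' @param sequence character vector of nucleotide sequences.
#' @param window window size in bp (default 50).
#' @return Numeric vector of percentages in `[0, 100]`.
#' @examples
#' read_mean_gc(c(strrep("G", 50), paste0("GCGC", strrep("A", 46))))  # 100, 8
#' @export
read_mean_gc <- function(sequence, window = 50L) {
  if (length(sequence) == 0L) stop("no sequences given")
  if (any(nchar(sequence) == 0L)) stop("empty sequence")
  head50 <- Biostrings::DNAStringSet(toupper(substr(sequence, 1L, window)))
  gc <- as.numeric(Biostrings::letterFrequency(head50, "GC"))
  100 * gc / Biostrings::width(head50)
}

#' Bin per-read \%G+C into a 50-bin, 2\%-wide profile
#'
#' Bins are half-open `[0,2), [2,4), ..., [96,98)` with the top bin `[98,100]`
#' closed, so a 100\% G+C read falls in bin 50. Reads shorter than `window`
#' are excluded from profiling (consistent with a 50 bp minimum-length QC
#' rule) and counted in `n_excluded`.
#'
#' @param reads a read tibble or a character vector of sequences.
#' @param window bp window for [read_mean_gc()].
#' @param library_id label stored on the profile.
#' @return A `gc_profile`: list with `library_id`, `bin_freqs` (50
#'   frequencies summing to 1), `n_reads`, `n_excluded`.
#' @export
profile_library <- function(reads, window = 50L, library_id = "lib") {
  sequence <- if (is.character(reads)) reads else reads$sequence
  if (length(sequence) == 0L) stop("zero reads: cannot profile")
  long_enough <- nchar(sequence) >= window
  sequence <- sequence[long_enough]
  if (length(sequence) == 0L)
    stop("zero reads of length >= ", window, ": cannot profile")
  gc <- read_mean_gc(sequence, window)
  bin <- pmin(floor(gc / 2), 49) + 1L
  freqs <- tabulate(bin, nbins = 50L) / length(gc)
  names(freqs) <- sprintf("[%d,%d)", seq(0, 98, 2), seq(2, 100, 2))
  names(freqs)[50] <- "[98,100]"
  structure(list(library_id = library_id, bin_freqs = freqs,
                 n_reads = length(gc), n_excluded = sum(!long_enough)),
            class = "gc_profile")
}

#' @export
print.gc_profile <- function(x, ...) {
  cat(sprintf("GC profile '%s': %d reads (%d excluded), modal bin %s\n",
              x$library_id, x$n_reads, x$n_excluded,
              names(x$bin_freqs)[which.max(x$bin_freqs)]))
  invisible(x)
}

#' Cut a reference genome into non-overlapping 50 bp windows
#'
#' Tiles `floor(L / window)` fragments from position 1; any trailing
#' remainder shorter than `window` is discarded. The fragment profile puts
#' genome \%G+C on the same footing as read \%G+C.
#'
#' @param genome a single sequence (character or `DNAString`).
#' @param window fragment width in bp.
#' @param library_id label for the returned profile.
#' @return List with `fragments` (character vector) and `profile`
#'   (a `gc_profile`).
#' @export
fragment_reference <- function(genome, window = 50L, library_id = "reference") {
  genome <- toupper(as.character(genome))
  L <- nchar(genome)
  if (L < window) stop("genome shorter than one window (", window, " bp)")
  n <- L %/% window
  starts <- (seq_len(n) - 1L) * window + 1L
  fragments <- substring(genome, starts, starts + window - 1L)
  list(fragments = fragments,
       profile = profile_library(fragments, window = window, library_id = library_id))
}

#' Collect profiles into a libraries x bins matrix
#'
#' @param profiles list of `gc_profile` objects (or any objects with
#'   `library_id` and a numeric frequency vector under `bin_freqs`).
#' @return Numeric matrix, one row per library, ready for [pearson_matrix()].
#' @export
profile_matrix <- function(profiles) {
  mat <- do.call(rbind, lapply(profiles, function(p) p$bin_freqs))
  rownames(mat) <- vapply(profiles, function(p) p$library_id, character(1))
  mat
}
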