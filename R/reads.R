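#' Read sets
#'
#' Reads are carried through the pipeline as a plain tibble with one row per
#' read and columns:
#' \describe{
#'   \item{id}{unique read identifier}
#'   \item{sequence}{nucleotide string (A/C/G/T/N, upper case)}
#'   \item{quality}{per-base PHRED scores encoded Sanger-style (PHRED+33)}
#'   \item{pair}{one of \code{"F"} (forward mate), \code{"R"} (reverse mate),
#'     \code{"U"} (unpaired)}
#' }
#' Simulated reads add truth columns (see [sequence_pool()]). All analysis
#' functions accept any tibble/data.frame with at least these columns.
#'
#' @param id,sequence,quality,pair column vectors, recycled to a common length.
#' @return A tibble with the columns above.
#' @examples
#' read_set("r1", "ACGT", "IIII")
#' @export
read_set <- function(id, sequence, quality = NULL, pair = "U") {
  sequence <- toupper(as.character(sequence))
  if (is.null(quality)) {
    quality <- vapply(nchar(sequence), function(n) strrep("I", n), character(1))
  }
  stopifnot(all(nchar(sequence) == nchar(quality)))
  tibble(
    id = as.character(id), sequence = sequence,
    quality = as.character(quality), pair = as.character(pair)
  )
}

#' Decode a PHRED+33 quality string to integer scores
#'
#' @param quality a single quality string.
#' @return Integer vector of per-base PHRED scores.
#' @export
phred_scores <- function(quality) {
  if (nchar(quality) == 0L) return(integer(0))
  utf8ToInt(quality) - 33L
}

#' Per-read mean PHRED quality
#'
#' @param reads a read tibble (see [read_set()]).
#' @return Numeric vector of mean PHRED scores (NaN for zero-length reads).
#' @export
read_mean_quality <- function(reads) {
  vapply(reads$quality,
         function(q) if (nchar(q)) mean(utf8ToInt(q)) - 33 else NaN,
         numeric(1), USE.NAMES = FALSE)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ file (Sanger PHRED+33, uncompressed or gzipped).
#' @param pair mate label to assign to every read (\code{"F"}, \code{"R"} or
#'   \code{"U"}); FASTQ carries no mate column of its own.
#' @return A read tibble.
#' @export
read_fastq <- function(path, pair = "U") {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- vapply(strsplit(names(x), "[ \t]"), `[`, character(1), 1L)
  read_set(
    id = ids,
    sequence = as.character(x),
    quality = as.character(S4Vectors::mcols(x)$qualities),
    pair = pair
  )
}

#' Write a read tibble to FASTQ (Sanger PHRED+33)
#'
#' @param reads a read tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Write named sequences to FASTA
#'
#' @param sequences a named character vector or `DNAStringSet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (!methods::is(sequences, "XStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}
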