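# Assembly summary statistics. De novo assembly itself is out of scope —
# metrics are computed on contigs produced elsewhere (or on fixture contigs
# from the simulator).

#' Assembly summary statistics
#'
#' N50 is the length of the contig at which the cumulative length of contigs,
#' sorted in descending order, first reaches at least half the total assembly
#' size. Total assembly size counts sequence length as written (including any
#' N characters).
#'
#' @param contigs contig lengths (numeric vector), sequences (character
#'   vector) or a `DNAStringSet`; at least one contig.
#' @param placements optional read-placement data frame with columns
#'   `read_id`, `contig_id` and optionally `read_length`; when absent the
#'   reads/bp-assembled fields are `NA` (unknown).
#' @param library_id label copied into the result.
#' @return An `assembly_stats` tibble row: `library_id`, `n_contigs`,
#'   `total_bp`, `max_contig_bp`, `n50_bp`, `reads_assembled`,
#'   `bp_assembled`.
#' @examples
#' assembly_stats(c(4000, 3000, 3000, 2000, 2000, 2000))$n50_bp  # 3000
#' @export
assembly_stats <- function(contigs, placements = NULL, library_id = "lib") {
  if (methods::is(contigs, "XStringSet")) contigs <- Biostrings::width(contigs)
  if (is.character(contigs)) contigs <- nchar(contigs)
  contigs <- as.numeric(contigs)
  if (length(contigs) == 0L) stop("empty contig set")
  if (any(contigs <= 0)) stop("contig lengths must be positive")
  s <- sort(contigs, decreasing = TRUE)
  n50 <- s[which(cumsum(s) >= sum(s) / 2)[1]]
  reads_assembled <- NA_integer_
  bp_assembled <- NA_real_
  if (!is.null(placements)) {
    stopifnot(all(c("read_id", "contig_id") %in% names(placements)))
    reads_assembled <- length(unique(placements$read_id))
    if ("read_length" %in% names(placements))
      bp_assembled <- sum(placements$read_length[!duplicated(placements$read_id)])
  }
  tibble(library_id = library_id, n_contigs = length(contigs),
         total_bp = sum(s), max_contig_bp = s[1], n50_bp = n50,
         reads_assembled = reads_assembled, bp_assembled = bp_assembled)
}

#' Read contigs from FASTA and summarise the assembly
#'
#' @param path contig FASTA file.
#' @param placements optional placement TSV path (`read_id`, `contig_id`[,
#'   `read_length`]).
#' @inheritParams assembly_stats
#' @return As [assembly_stats()].
#' @export
assembly_stats_fasta <- function(path, placements = NULL, library_id = "lib") {
  contigs <- Biostrings::readDNAStringSet(path)
  pl <- if (!is.null(placements)) read.delim(placements, stringsAsFactors = FALSE)
  assembly_stats(contigs, pl, library_id = library_id)
}

#' Simulate fixture contigs from a community
#'
#' Draws contig lengths log-normally around `mean_len` and extracts each
#' contig as a substring of a community genome — enough structure to exercise
#' the assembly-metrics stage with known inputs.
#'
#' @param community a `community`.
#' @param n_contigs number of contigs.
#' @param mean_len,sd_log log-normal length model (bp).
#' @param seed integer seed.
#' @return A named `DNAStringSet` of contigs.
#' @export
simulate_contigs <- function(community, n_contigs = 50L, mean_len = 2000,
                             sd_log = 0.6, seed = 1L) {
  glen <- Biostrings::width(community$genomes)
  withr::with_seed(seed, {
    len <- pmax(100L, as.integer(round(stats::rlnorm(n_contigs, log(mean_len), sd_log))))
    gidx <- sample.int(length(glen), n_contigs, replace = TRUE,
                       prob = community$abundance)
    len <- pmin(len, glen[gidx])
    start <- floor(runif(n_contigs) * (glen[gidx] - len + 1)) + 1L
    ctg <- Biostrings::subseq(community$genomes[gidx], start = start, width = len)
    names(ctg) <- sprintf("contig_%04d", seq_len(n_contigs))
    ctg
  })
}
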