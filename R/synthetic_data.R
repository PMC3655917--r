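# Library-preparation simulator. Every downstream stage (QC, GC profiling,
# duplicate analysis, protein-cluster recruitment, clustering) is validated
# against the ground truth this module records: which genome and sheared
# fragment each read came from, whether its fragment was drawn more than once
# (a PCR/resampling duplicate), and whether an adapter was injected.

#' Describe a toy viral community
#'
#' @param n_genomes number of genomes (>= 1).
#' @param genome_length genome length in bp (>= 100); scalar or per-genome.
#' @param gc_target per-genome G+C fraction, strictly inside (0, 1); scalar or
#'   per-genome vector.
#' @param abundance relative abundances (summing to 1 within 1e-9); defaults to
#'   uniform.
#' @param seed integer seed; all community randomness derives from it.
#' @return A `community_config` list.
#' @export
community_config <- function(n_genomes, genome_length, gc_target = 0.45,
                             abundance = NULL, seed = 1L) {
  if (length(n_genomes) != 1L || is.na(n_genomes) || n_genomes < 1)
    stop("invalid config: n_genomes must be >= 1")
  n_genomes <- as.integer(n_genomes)
  genome_length <- as.integer(rep_len(genome_length, n_genomes))
  if (any(genome_length < 100))
    stop("invalid config: genome_length must be >= 100")
  gc_target <- rep_len(gc_target, n_genomes)
  if (any(gc_target <= 0 | gc_target >= 1))
    stop("invalid config: gc_target must lie strictly in (0, 1)")
  if (is.null(abundance)) abundance <- rep(1 / n_genomes, n_genomes)
  if (length(abundance) != n_genomes || any(abundance < 0) ||
      abs(sum(abundance) - 1) > 1e-9)
    stop("invalid config: abundance must be non-negative and sum to 1")
  structure(list(n_genomes = n_genomes, genome_length = genome_length,
                 gc_target = gc_target, abundance = abundance,
                 seed = as.integer(seed)),
            class = "community_config")
}

#' Generate a community of random genomes
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc_target/2 and
#' P(A) = P(T) = (1 - gc_target)/2 — the simplest composition model that gives
#' each genome a controlled mean \%G+C.
#'
#' @param config a [community_config()].
#' @return A `community` list with elements `genomes` (named
#'   `DNAStringSet`), `abundance`, `gc_target` and `config`. Identical configs
#'   (including seed) give byte-identical genomes.
#' @examples
#' com <- generate_community(community_config(2, 1000, gc_target = 0.4, seed = 7))
#' Biostrings::width(com$genomes)
#' @export
generate_community <- function(config) {
  if (!inherits(config, "community_config")) config <- do.call(community_config, config)
  genomes <- withr::with_seed(config$seed, {
    vapply(seq_len(config$n_genomes), function(i) {
      gc <- config$gc_target[i]
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      paste(sample(names(p), config$genome_length[i], replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
  })
  gs <- Biostrings::DNAStringSet(genomes)
  names(gs) <- sprintf("genome_%03d", seq_len(config$n_genomes))
  structure(list(genomes = gs, abundance = config$abundance,
                 gc_target = config$gc_target, config = config),
            class = "community")
}

#' Describe one library-preparation treatment
#'
#' Captures the knobs compared across treatments: input DNA mass, number of
#' adaptor-mediated amplification cycles, a GC-dependent amplification
#' efficiency (Gaussian in fragment G+C fraction), loss of low-GC fragments,
#' fragment size selection, the platform read-length/quality model, and
#' adapter contamination. Platform presets are available via
#' [platform_preset()].
#'
#' @param platform_style one of `"short-paired"`, `"long-single"`,
#'   `"short-single"`.
#' @param input_dna_ng input DNA mass in ng (bookkeeping; carried into
#'   manifests).
#' @param amp_cycles number of library amplification cycles (>= 0). Excludes
#'   on-instrument emPCR/bridge amplification, which is not modelled.
#' @param gc_bias list with `optimum` (GC fraction of maximal amplification
#'   efficiency), `width` (> 0, Gaussian width in GC fraction) and `strength`
#'   (>= 0; 0 disables bias). Per cycle a fragment duplicates with probability
#'   `exp(-strength * (gc - optimum)^2 / width^2)`.
#' @param low_gc_loss >= 0; before cycling a fragment is discarded with
#'   probability `low_gc_loss * max(0, optimum - gc)` (models loss of low-GC
#'   fragments during size selection/heating).
#' @param fragment_len_mean,fragment_len_sd sheared fragment length model (bp).
#' @param read_len_mean,read_len_sd platform read length model (bp), used when
#'   `read_len_fixed` is `NA`.
#' @param read_len_fixed fixed read length in bp, or `NA`.
#' @param mean_quality PHRED quality at the first base.
#' @param quality_decay linear per-base PHRED decline along the read; scores
#'   are floored at 2.
#' @param adapter_motif adapter sequence injected at the 5' end of
#'   contaminated reads.
#' @param adapter_rate fraction of reads carrying the adapter, in `[0, 1]`.
#' @param paired emit mate pairs from the two fragment ends?
#' @param seed default seed for [simulate_library()].
#' @return A `library_protocol` list.
#' @export
library_protocol <- function(platform_style = c("short-paired", "long-single", "short-single"),
                             input_dna_ng = 1000, amp_cycles = 0L,
                             gc_bias = list(optimum = 0.5, width = 0.15, strength = 0),
                             low_gc_loss = 0,
                             fragment_len_mean = 300, fragment_len_sd = 60,
                             read_len_mean = 100, read_len_sd = 0,
                             read_len_fixed = NA_integer_,
                             mean_quality = 34, quality_decay = 0,
                             adapter_motif = "AGATCGGAAGAGCACACG", adapter_rate = 0,
                             paired = (platform_style == "short-paired"),
                             seed = 1L) {
  platform_style <- match.arg(platform_style)
  if (amp_cycles < 0) stop("amp_cycles must be >= 0")
  if (adapter_rate < 0 || adapter_rate > 1) stop("adapter_rate must be in [0, 1]")
  if (fragment_len_mean <= 0 || read_len_mean <= 0 ||
      (!is.na(read_len_fixed) && read_len_fixed <= 0))
    stop("length parameters must be positive")
  stopifnot(is.list(gc_bias), all(c("optimum", "width", "strength") %in% names(gc_bias)))
  if (gc_bias$width <= 0) stop("gc_bias$width must be > 0")
  if (gc_bias$strength < 0 || low_gc_loss < 0)
    stop("gc_bias$strength and low_gc_loss must be >= 0")
  structure(list(platform_style = platform_style, input_dna_ng = input_dna_ng,
                 amp_cycles = as.integer(amp_cycles), gc_bias = gc_bias,
                 low_gc_loss = low_gc_loss,
                 fragment_len_mean = fragment_len_mean, fragment_len_sd = fragment_len_sd,
                 read_len_mean = read_len_mean, read_len_sd = read_len_sd,
                 read_len_fixed = read_len_fixed,
                 mean_quality = mean_quality, quality_decay = quality_decay,
                 adapter_motif = toupper(adapter_motif), adapter_rate = adapter_rate,
                 paired = isTRUE(paired), seed = as.integer(seed)),
            class = "library_protocol")
}

#' Platform presets for the read models of common sequencers
#'
#' Read length and quality defaults follow the raw-read summaries typical of
#' each platform: 100 bp paired-end Illumina at PHRED ~34; unamplified 454 at
#' 408 +/- 11 bp, PHRED ~32.5; linker-amplified (LA) 454 at 377 +/- 15 bp,
#' PHRED ~32.8 with 15 cycles; Ion Torrent at 105 +/- 5 bp, PHRED ~16.3 with 5
#' cycles. Every field can be overridden via `...`.
#'
#' @param name one of `"illumina"`, `"454"`, `"454-la"`, `"ion-torrent"`.
#' @param ... overrides passed to [library_protocol()].
#' @return A `library_protocol`.
#' @examples
#' platform_preset("ion-torrent", amp_cycles = 10L)
#' @export
platform_preset <- function(name = c("illumina", "454", "454-la", "ion-torrent"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "illumina" = list(platform_style = "short-paired", input_dna_ng = 1000,
                      amp_cycles = 14L, fragment_len_mean = 450, fragment_len_sd = 75,
                      read_len_fixed = 100L, mean_quality = 34.2, paired = TRUE),
    "454" = list(platform_style = "long-single", input_dna_ng = 1500,
                 amp_cycles = 0L, fragment_len_mean = 700, fragment_len_sd = 120,
                 read_len_mean = 408, read_len_sd = 11, mean_quality = 32.5,
                 paired = FALSE),
    "454-la" = list(platform_style = "long-single", input_dna_ng = 10,
                    amp_cycles = 15L, fragment_len_mean = 650, fragment_len_sd = 110,
                    read_len_mean = 377, read_len_sd = 15, mean_quality = 32.8,
                    paired = FALSE),
    "ion-torrent" = list(platform_style = "short-single", input_dna_ng = 1000,
                         amp_cycles = 5L, fragment_len_mean = 250, fragment_len_sd = 40,
                         read_len_mean = 105, read_len_sd = 5, mean_quality = 16.3,
                         paired = FALSE))
  do.call(library_protocol, utils::modifyList(base, list(...)))
}

#' Shear genomes into a fragment pool
#'
#' Fragment origins are sampled with probability proportional to
#' abundance x genome length; fragment lengths are Normal(mean, sd), rounded,
#' and clamped to `[1, genome length]`; start positions are uniform.
#'
#' @param community a `community` from [generate_community()].
#' @param protocol a [library_protocol()] (supplies the length model).
#' @param n_fragments number of fragments (>= 1).
#' @param seed integer seed.
#' @return Tibble with `fragment_id`, `genome_id`, `start`, `length`,
#'   `sequence`, `gc` (fraction) and `copies` (all 1 before amplification).
#' @export
simulate_fragments <- function(community, protocol, n_fragments, seed = protocol$seed) {
  if (!inherits(community, "community")) stop("community must come from generate_community()")
  if (length(community$genomes) == 0L) stop("empty genome set")
  if (n_fragments < 1) stop("n_fragments must be >= 1")
  n_fragments <- as.integer(n_fragments)
  glen <- Biostrings::width(community$genomes)
  w <- community$abundance * glen
  withr::with_seed(seed, {
    gidx <- sample.int(length(glen), n_fragments, replace = TRUE, prob = w)
    len <- round(rnorm(n_fragments, protocol$fragment_len_mean, protocol$fragment_len_sd))
    len <- pmax(1L, pmin(as.integer(len), glen[gidx]))
    start <- floor(runif(n_fragments) * (glen[gidx] - len + 1)) + 1L
    seqs <- as.character(Biostrings::subseq(community$genomes[gidx], start = start,
                                            width = len))
    frs <- Biostrings::DNAStringSet(seqs)
    gc <- as.numeric(Biostrings::letterFrequency(frs, "GC")) / len
    tibble(fragment_id = sprintf("frag_%07d", seq_len(n_fragments)),
           genome_id = names(community$genomes)[gidx],
           start = as.integer(start), length = as.integer(len),
           sequence = unname(seqs), gc = gc, copies = 1)
  })
}

# per-cycle duplication probability: Gaussian in fragment GC
gc_efficiency <- function(gc, bias) {
  clamp01(exp(-bias$strength * (gc - bias$optimum)^2 / bias$width^2))
}

#' Amplify a fragment pool with GC-dependent efficiency
#'
#' Encodes the two bias mechanisms attributed to adaptor-mediated library
#' amplification: reduced amplification efficiency away from a GC optimum
#' (high-GC secondary-structure inhibition when the optimum sits low, or the
#' converse), and outright loss of low-GC fragments before cycling. Copies are
#' tracked as per-fragment counts; each cycle adds
#' `Binomial(copies, eff(gc))` new copies. With `amp_cycles = 0` the pool is
#' returned unchanged.
#'
#' @param fragments fragment tibble from [simulate_fragments()].
#' @param protocol a [library_protocol()].
#' @param seed integer seed.
#' @return The fragment tibble with updated `copies`; fragments lost to the
#'   low-GC discard step are removed.
#' @export
amplify_pool <- function(fragments, protocol, seed = protocol$seed) {
  if (protocol$amp_cycles == 0L) return(fragments)
  bias <- protocol$gc_bias
  withr::with_seed(seed, {
    p_loss <- clamp01(protocol$low_gc_loss * pmax(0, bias$optimum - fragments$gc))
    keep <- runif(nrow(fragments)) >= p_loss
    pool <- fragments[keep, , drop = FALSE]
    if (nrow(pool) == 0L) stop("amplification discarded every fragment")
    eff <- gc_efficiency(pool$gc, bias)
    copies <- pool$copies
    for (cycle in seq_len(protocol$amp_cycles)) {
      copies <- copies + rbinom(length(copies), size = copies, prob = eff)
    }
    pool$copies <- copies
    pool
  })
}

# deterministic per-position PHRED model: linear decay floored at 2
position_quality <- function(protocol, max_len) {
  pmin(60L, pmax(2L, as.integer(round(protocol$mean_quality -
                                        protocol$quality_decay * (seq_len(max_len) - 1)))))
}

#' Sequence reads from an (amplified) fragment pool
#'
#' Fragments are drawn with replacement with probability proportional to their
#' copy number; unpaired reads come from the 5' end, paired mode emits a
#' forward read from the 5' end and a reverse-complemented read from the 3'
#' end of each drawn fragment. Per-base substitution errors occur at rate
#' `10^(-q/10)` under the position-dependent quality model; `adapter_rate` of
#' reads have the adapter motif injected at the 5' end (after error
#' simulation, displacing the read 3' end so read length is unchanged).
#'
#' @param pool fragment tibble (from [simulate_fragments()] or
#'   [amplify_pool()]).
#' @param protocol a [library_protocol()].
#' @param n_reads total reads to emit (must be even in paired mode).
#' @param seed integer seed.
#' @param library_id prefix for read ids.
#' @return Read tibble (see [read_set()]) with truth columns
#'   `source_genome_id`, `source_fragment_id`, `is_pcr_duplicate` (fragment
#'   drawn >= 2 times), `pre_error_sequence` (fragment-derived sequence before
#'   errors and adapter) and `has_adapter`.
#' @export
sequence_pool <- function(pool, protocol, n_reads, seed = protocol$seed,
                          library_id = "lib") {
  if (nrow(pool) == 0L) stop("empty fragment pool")
  if (n_reads < 1) stop("n_reads must be >= 1")
  n_reads <- as.integer(n_reads)
  paired <- protocol$paired
  if (paired && n_reads %% 2L != 0L) stop("paired mode needs an even n_reads")
  n_draw <- if (paired) n_reads %/% 2L else n_reads

  withr::with_seed(seed, {
    fidx <- sample.int(nrow(pool), n_draw, replace = TRUE, prob = pool$copies)
    dup_fragment <- duplicated(fidx) | duplicated(fidx, fromLast = TRUE)
    flen <- pool$length[fidx]

    rlen <- function(n) {
      if (!is.na(protocol$read_len_fixed)) rep(as.integer(protocol$read_len_fixed), n)
      else pmax(1L, as.integer(round(rnorm(n, protocol$read_len_mean, protocol$read_len_sd))))
    }

    if (paired) {
      lf <- pmin(rlen(n_draw), flen)
      lr <- pmin(rlen(n_draw), flen)
      fwd <- substr(pool$sequence[fidx], 1L, lf)
      rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
        substr(pool$sequence[fidx], flen - lr + 1L, flen))))
      seqs <- c(fwd, rev)
      pair <- rep(c("F", "R"), each = n_draw)
      base <- sprintf("%s_r%06d", library_id, rep(seq_len(n_draw), 2L))
      ids <- paste0(base, "/", rep(c("1", "2"), each = n_draw))
      fidx2 <- rep(fidx, 2L)
      dup2 <- rep(dup_fragment, 2L)
    } else {
      lu <- pmin(rlen(n_draw), flen)
      seqs <- substr(pool$sequence[fidx], 1L, lu)
      pair <- rep("U", n_draw)
      ids <- sprintf("%s_r%06d", library_id, seq_len(n_draw))
      fidx2 <- fidx
      dup2 <- dup_fragment
    }

    pre_error <- seqs
    len <- nchar(seqs)
    qpos <- position_quality(protocol, max(len))
    # vectorised substitution errors across all bases of all reads
    pos <- sequence(len)
    ridx <- rep.int(seq_along(len), len)
    perr <- 10^(-qpos[pos] / 10)
    hit <- which(runif(length(pos)) < perr)
    if (length(hit)) {
      subs <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
      pick <- sample.int(3L, length(hit), replace = TRUE)
      for (k in seq_along(hit)) {
        i <- ridx[hit[k]]; j <- pos[hit[k]]
        orig <- substr(seqs[i], j, j)
        alt <- subs[orig]
        if (!is.na(alt)) substr(seqs[i], j, j) <- substr(alt, pick[k], pick[k])
      }
    }

    has_adapter <- runif(length(seqs)) < protocol$adapter_rate
    if (any(has_adapter)) {
      seqs[has_adapter] <- substr(paste0(protocol$adapter_motif, seqs[has_adapter]),
                                  1L, len[has_adapter])
    }

    qfull <- intToUtf8(qpos + 33L)
    quality <- substr(rep(qfull, length(len)), 1L, len)

    out <- read_set(ids, seqs, quality, pair)
    out$source_genome_id <- pool$genome_id[fidx2]
    out$source_fragment_id <- pool$fragment_id[fidx2]
    out$is_pcr_duplicate <- dup2
    out$pre_error_sequence <- pre_error
    out$has_adapter <- has_adapter
    out
  })
}

#' Simulate one library end to end
#'
#' Convenience wrapper: shear, amplify, sequence. Stage seeds are derived
#' deterministically from `seed` so one integer reproduces the library.
#'
#' @inheritParams sequence_pool
#' @param community a `community`.
#' @param n_fragments size of the sheared fragment pool.
#' @return As [sequence_pool()].
#' @export
simulate_library <- function(community, protocol, n_fragments, n_reads,
                             seed = protocol$seed, library_id = "lib") {
  seed <- as.integer(seed)
  frags <- simulate_fragments(community, protocol, n_fragments, seed = seed)
  pool <- amplify_pool(frags, protocol, seed = (seed + 1013L) %% .Machine$integer.max)
  sequence_pool(pool, protocol, n_reads, seed = (seed + 2027L) %% .Machine$integer.max,
                library_id = library_id)
}

#' Write the simulation truth table
#'
#' @param reads simulated read tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(reads, path) {
  stopifnot(all(c("source_genome_id", "source_fragment_id", "is_pcr_duplicate") %in%
                  names(reads)))
  truth <- reads[, c("id", "source_genome_id", "source_fragment_id",
                     "is_pcr_duplicate", "has_adapter")]
  names(truth)[1] <- "read_id"
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a synthetic protein-cluster reference from community genomes
#'
#' Picks non-overlapping gene-sized windows on the forward strand of each
#' genome and translates them in frame +1; each window becomes one
#' single-representative cluster. Reads simulated from the same genomes then
#' recruit to these clusters, giving the functional-profiling stage a
#' ground-truth reference. Labelled synthetic: it stands in for a real marine
#' virus protein-cluster database, which cannot be bundled.
#'
#' @param community a `community`.
#' @param n_clusters clusters to derive (spread across genomes).
#' @param gene_len gene window length in bp (multiple of 3).
#' @param seed integer seed.
#' @return A `pc_db` (see [pc_db()]).
#' @export
synthetic_pc_db <- function(community, n_clusters = 100, gene_len = 300, seed = 1L) {
  stopifnot(gene_len %% 3 == 0)
  glen <- Biostrings::width(community$genomes)
  per <- diff(round(seq(0, n_clusters, length.out = length(glen) + 1)))
  withr::with_seed(seed, {
    rows <- list()
    k <- 0L
    for (g in seq_along(glen)) {
      ng <- per[g]
      if (ng == 0L) next
      max_start <- glen[g] - gene_len + 1L
      starts <- sort(sample.int(max_start, ng))
      dna <- Biostrings::DNAStringSet(substring(as.character(community$genomes[[g]]),
                                                starts, starts + gene_len - 1L))
      pep <- as.character(Biostrings::translate(dna, if.fuzzy.codon = "X"))
      for (j in seq_len(ng)) {
        k <- k + 1L
        rows[[k]] <- tibble(cluster_id = sprintf("PC_%04d", k), peptide = pep[j],
                            genome_id = names(community$genomes)[g],
                            start = starts[j])
      }
    }
    db <- do.call(rbind, rows)
    pc_db(db[, c("cluster_id", "peptide")])
  })
}
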