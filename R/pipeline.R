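# Orchestration: run every comparison stage across a manifest of libraries
# and write the full output bundle (correlation tables, bootstrapped
# dendrograms, duplicate spectra, protein-cluster tables, assembly stats)
# plus a reproducibility manifest.

#' Read a library manifest
#'
#' A manifest TSV has one row per library with columns `library_id`, `fastq`,
#' `platform_style` (`short-paired`/`long-single`/`short-single`),
#' `input_dna_ng`, `amp_cycles`, `replicate` and `mate` (`F`/`R`/`U`);
#' optional columns `qc_mode` (`filter`/`trim`) and `contigs` (FASTA path).
#'
#' @param path manifest TSV path.
#' @return A manifest tibble.
#' @export
read_manifest <- function(path) {
  m <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  validate_manifest(m)
  m
}

validate_manifest <- function(manifest) {
  required <- c("library_id", "fastq", "platform_style", "mate")
  missing <- setdiff(required, names(manifest))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(manifest$library_id))
    stop("manifest library ids must be unique")
  gone <- !file.exists(manifest$fastq)
  if (any(gone))
    stop("FASTQ not found: ", paste(manifest$fastq[gone], collapse = ", "))
  invisible(manifest)
}

#' Pipeline configuration
#'
#' @param gc_window bp window for \%G+C profiling.
#' @param qc_trim_threshold PHRED threshold of the trimmer (short-read
#'   platforms).
#' @param qc_min_mean_quality mean-PHRED threshold of the whole-read filter
#'   (long-read platforms).
#' @param qc_min_length minimum read length kept after QC.
#' @param adapter_motif adapter for discard-mode removal, or `NULL`.
#' @param dup_prefix,dup_anchor,dup_identity,dup_mode duplicate-analysis
#'   parameters (see [duplicate_spectrum()] and [detect_artificial()]).
#' @param detect_artificial run artificial-duplicate clustering per library?
#' @param pc_db a [pc_db()] (or path to its FASTA) enabling the
#'   protein-cluster stage, or `NULL` to skip it.
#' @param pc_top clusters retained in the hit table.
#' @param n_boot bootstrap replicates for dendrogram support.
#' @param support_display minimum BP\% shown when printing (all supports are
#'   always written to the Newick files; the threshold is presentation only).
#' @param seed integer seed for the bootstrap.
#' @param record_timestamp write a wall-clock timestamp into the run
#'   manifest? Off by default so identical runs produce byte-identical
#'   bundles.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(gc_window = 50L, qc_trim_threshold = 20,
                            qc_min_mean_quality = 20, qc_min_length = 50L,
                            adapter_motif = NULL,
                            dup_prefix = 50L, dup_anchor = 20L,
                            dup_identity = 0.95, dup_mode = "substitution",
                            detect_artificial = TRUE,
                            pc_db = NULL, pc_top = 1500L,
                            n_boot = 100L, support_display = 60,
                            seed = 1L, record_timestamp = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

qc_mode_for <- function(platform_style, qc_mode = NA) {
  if (!is.na(qc_mode) && nzchar(qc_mode)) return(qc_mode)
  # trimming for short-read data whose errors localise within the read;
  # whole-read filtering for the long-read platforms
  if (platform_style == "long-single" || platform_style == "short-single")
    "filter" else "trim"
}

#' Run the full library comparison
#'
#' Stages, in order, per library: FASTQ input, duplicate spectrum on raw
#' reads, QC (adapter discard, trim or filter, length floor), \%G+C profile
#' of QC-ed reads, optional artificial-duplicate clustering and
#' protein-cluster mapping, optional assembly statistics. Across libraries:
#' Pearson correlation matrices and bootstrapped UPGMA dendrograms for the
#' \%G+C profiles, the duplicate-level spectra and (when a database is
#' configured) the top-cluster hit frequencies. With fewer than two libraries
#' the comparison stages are skipped with a warning; clustering needs at
#' least three.
#'
#' @param manifest a manifest tibble (see [read_manifest()]).
#' @param config a [pipeline_config()].
#' @return A `pipeline_bundle` list: `per_library` (per-library results),
#'   `qc_summary`, `comparisons` (per analysis axis: `r`, `boot`),
#'   `assembly`, `pc_table`, `run_manifest`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config()) {
  validate_manifest(manifest)
  n_lib <- nrow(manifest)
  if (n_lib < 1) stop("empty manifest")

  db <- config$pc_db
  if (is.character(db)) db <- read_pc_db(db)

  per_library <- vector("list", n_lib)
  names(per_library) <- manifest$library_id
  qc_rows <- vector("list", n_lib)

  for (i in seq_len(n_lib)) {
    lib <- manifest$library_id[i]
    reads <- read_fastq(manifest$fastq[i], pair = manifest$mate[i])
    if (nrow(reads) == 0L) stop("malformed or empty FASTQ: ", manifest$fastq[i])

    spectrum <- duplicate_spectrum(reads, prefix = config$dup_prefix,
                                   library_id = lib)
    clusters <- NULL
    if (isTRUE(config$detect_artificial)) {
      clusters <- detect_artificial(reads, start_anchor = config$dup_anchor,
                                    identity = config$dup_identity,
                                    mode = config$dup_mode)
    }

    mode <- qc_mode_for(manifest$platform_style[i],
                        if ("qc_mode" %in% names(manifest)) manifest$qc_mode[i] else NA)
    params <- qc_params(mode = mode,
                        quality_threshold = config$qc_trim_threshold,
                        min_mean_quality = config$qc_min_mean_quality,
                        min_length = config$qc_min_length,
                        adapter_motif = config$adapter_motif)
    qc <- qc_library(reads, params, library_id = lib)
    qc_rows[[i]] <- qc$summary

    profile <- profile_library(qc$reads, window = config$gc_window,
                               library_id = lib)

    pc <- NULL
    if (!is.null(db)) {
      pc <- map_library_to_pc(qc$reads, db, library_id = lib)
    }

    per_library[[i]] <- list(
      library_id = lib, n_raw = nrow(reads), qc = qc$summary,
      gc_profile = profile, duplicate_spectrum = spectrum,
      artificial = clusters,
      decomposition = if (!is.null(clusters))
        natural_minus_artificial(spectrum, clusters),
      pc = pc)
  }

  comparisons <- list()
  pc_table <- NULL
  if (n_lib < 2) {
    warning("fewer than two libraries: comparison stages skipped")
  } else {
    gc_mat <- profile_matrix(lapply(per_library, `[[`, "gc_profile"))
    dup_mat <- do.call(rbind, lapply(per_library, function(p)
      p$duplicate_spectrum$level_freqs))
    rownames(dup_mat) <- manifest$library_id
    comparisons$gc <- compare_axis(gc_mat, config)
    comparisons$duplicates <- compare_axis(dup_mat, config)
    if (!is.null(db)) {
      pc_table <- top_pc_table(lapply(per_library, `[[`, "pc"),
                               n_top = config$pc_top)
      comparisons$pc <- compare_axis(pc_table$frequencies, config)
    }
  }

  assembly <- NULL
  if ("contigs" %in% names(manifest) && any(nzchar(manifest$contigs))) {
    rows <- lapply(which(nzchar(manifest$contigs)), function(i)
      assembly_stats_fasta(manifest$contigs[i],
                           library_id = manifest$library_id[i]))
    assembly <- do.call(rbind, rows)
  }

  run_manifest <- list(
    tool = "virolib", version = as.character(utils::packageVersion("virolib")),
    seed = config$seed, n_boot = config$n_boot,
    gc_window = config$gc_window,
    dup_params = list(prefix = config$dup_prefix, anchor = config$dup_anchor,
                      identity = config$dup_identity, mode = config$dup_mode),
    qc_params = list(trim_threshold = config$qc_trim_threshold,
                     min_mean_quality = config$qc_min_mean_quality,
                     min_length = config$qc_min_length),
    libraries = manifest$library_id,
    timestamp = if (isTRUE(config$record_timestamp))
      format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z") else NULL)

  structure(list(per_library = per_library,
                 qc_summary = do.call(rbind, qc_rows),
                 comparisons = comparisons, pc_table = pc_table,
                 assembly = assembly, run_manifest = run_manifest,
                 manifest = manifest),
            class = "pipeline_bundle")
}

# correlation + (if >= 3 libraries) bootstrapped UPGMA for one analysis axis
compare_axis <- function(mat, config) {
  r <- pearson_matrix(mat)
  boot <- if (nrow(mat) >= 3)
    bootstrap_support(mat, n_boot = config$n_boot, seed = config$seed)
  list(r = r, boot = boot)
}

fmt_num <- function(x) sprintf("%.8g", x)

write_tsv_fixed <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(library_id = rownames(m),
                   apply(m, 2, fmt_num, simplify = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a pipeline bundle to disk
#'
#' Emits, under `outdir`: `qc_summary.tsv`, `gc_profiles.tsv` (long format:
#' `library_id`, `bin_low`, `bin_high`, `frequency`),
#' `duplicate_spectra.tsv`, `duplicate_summary.tsv`, correlation matrices and
#' Newick dendrograms per comparison axis (`<axis>_correlation.tsv`,
#' `<axis>_dendrogram.nwk`, supports as internal node labels),
#' `pc_table.tsv`, `assembly_stats.tsv` and `run_manifest.json`. Numeric
#' output uses fixed significant-digit formatting so repeated runs are
#' byte-identical.
#'
#' @param bundle a `pipeline_bundle` from [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)

  write_tsv_fixed(bundle$qc_summary, p("qc_summary.tsv"))

  gc_long <- do.call(rbind, lapply(bundle$per_library, function(pl) {
    f <- pl$gc_profile$bin_freqs
    data.frame(library_id = pl$library_id, bin_low = seq(0, 98, 2),
               bin_high = seq(2, 100, 2), frequency = f,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  write_tsv_fixed(gc_long, p("gc_profiles.tsv"))

  dup_long <- do.call(rbind, lapply(bundle$per_library, function(pl) {
    s <- pl$duplicate_spectrum
    data.frame(library_id = pl$library_id, level = names(s$level_freqs),
               frequency = unname(s$level_freqs), stringsAsFactors = FALSE)
  }))
  write_tsv_fixed(dup_long, p("duplicate_spectra.tsv"))

  dup_sum <- do.call(rbind, lapply(bundle$per_library, function(pl) {
    d <- pl$decomposition
    data.frame(library_id = pl$library_id,
               total_duplicate_fraction = pl$duplicate_spectrum$total_duplicate_fraction,
               high_freq_fraction = pl$duplicate_spectrum$high_freq_fraction,
               artificial_fraction = if (!is.null(d)) d$artificial_fraction else NA,
               natural_fraction = if (!is.null(d)) d$natural_fraction else NA,
               stringsAsFactors = FALSE)
  }))
  write_tsv_fixed(dup_sum, p("duplicate_summary.tsv"))

  for (axis in names(bundle$comparisons)) {
    cmp <- bundle$comparisons[[axis]]
    write_matrix_tsv(cmp$r, p(paste0(axis, "_correlation.tsv")))
    if (!is.null(cmp$boot)) {
      writeLines(to_newick(cmp$boot$tree, supports = cmp$boot$supports),
                 p(paste0(axis, "_dendrogram.nwk")))
    }
  }

  if (!is.null(bundle$pc_table))
    write_matrix_tsv(bundle$pc_table$frequencies, p("pc_table.tsv"))
  if (!is.null(bundle$assembly))
    write_tsv_fixed(bundle$assembly, p("assembly_stats.tsv"))

  jsonlite::write_json(bundle$run_manifest, p("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
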