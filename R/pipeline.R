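#' Run the full per-sample profiling pipeline
#'
#' Executes the workflow stages in their canonical order: quality/length
#' filtering with low-complexity masking, host-read elimination, seeded
#' subsampling to the analysis depth (subsampling precedes classification so
#' no alignment work is wasted), best-hit classification with even tie
#' allocation, and composition with the minor-taxon "Others" rule. Per-stage
#' read counts are recorded so they reconcile across stages. When `out_dir`
#' is given, a stats TSV (run-statistics schema), a profile TSV and a Krona
#' text file are written; reruns with the same inputs and seed produce
#' byte-identical files.
#'
#' @param reads Read tibble or path to a FASTQ file.
#' @param refdb A [reference_db()] tibble.
#' @param tree A `taxonomy` object.
#' @param region `"V1-9"` or `"V3-4"` (sets the length window).
#' @param sample_id Sample label used in outputs.
#' @param min_q Mean-quality threshold (default 7).
#' @param window Optional [region_window()] override.
#' @param host_refs Optional host reference tibble for [screen_host()];
#'   NULL skips host screening.
#' @param subsample_n Analysis depth (default 3000); NULL disables
#'   subsampling.
#' @param seed Integer seed (drives subsampling).
#' @param min_score_frac Classification threshold (default 0.4).
#' @param rank Reporting rank (default `"species"`).
#' @param others_threshold Minor-taxon cutoff (default 0.01).
#' @param alignments Optional PAF tibble for external-mapper mode.
#' @param scheme A [scoring_scheme()].
#' @param out_dir Optional output directory for TSV/Krona files.
#' @return A `vagitax_run` object: list with `sample_id`, `filter`
#'   (`filter_result`), `n_host`, `n_analyzed`, `assignments`, `profile`
#'   (full, at `rank`), `profile_grouped` (after the Others rule), `shannon`
#'   (on the un-grouped profile), and `stats` (one-row tibble of per-stage
#'   counts).
#' @export
run_sample <- function(reads, refdb, tree, region = "V1-9",
                       sample_id = "sample", min_q = 7, window = NULL,
                       host_refs = NULL, subsample_n = 3000L, seed = 1L,
                       min_score_frac = 0.4, rank = "species",
                       others_threshold = 0.01, alignments = NULL,
                       scheme = scoring_scheme(), out_dir = NULL) {
  if (is.character(reads) && length(reads) == 1L) {
    reads <- read_fastq(reads)
  }
  check_reads(reads)
  window <- window %||% region_window(region)
  lens <- nchar(reads$seq)

  fr <- filter_reads(reads, window = window, min_q = min_q)
  if (fr$n_kept == 0L) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_run_stats(empty_run_stats(sample_id, region, fr, lens),
                      file.path(out_dir, paste0(sample_id, "_stats.tsv")))
    }
    abort(sprintf("Sample '%s': no reads survive filtering.", sample_id),
          class = "vagitax_empty_pool")
  }

  scr <- if (is.null(host_refs)) {
    list(host = fr$kept[0, ], non_host = fr$kept)
  } else {
    screen_host(fr$kept, host_refs, scheme = scheme)
  }
  pool <- scr$non_host
  if (!is.null(subsample_n) && nrow(pool) > subsample_n) {
    pool <- subsample_reads(pool, n = subsample_n,
                            seed = derive_seed(seed, 4L))
  }
  assignments <- classify_batch(pool, refdb, tree,
                                min_score_frac = min_score_frac,
                                scheme = scheme, alignments = alignments)
  prof <- composition(assignments, tree, rank = rank, sample_id = sample_id)
  grouped <- apply_minor_grouping(prof, threshold = others_threshold)

  stats <- tibble(
    sample = sample_id, region = region,
    pass_reads = fr$n_input, filtered_reads = fr$n_kept,
    retention_pct = retention_percent(fr),
    min_bp = min(lens), avg_bp = round(mean(lens), 1), max_bp = max(lens),
    filtered_avg_bp = round(mean(nchar(fr$kept$seq)), 1),
    host_reads = nrow(scr$host), analyzed_reads = nrow(pool),
    classified_reads = sum(assignments$outcome == "classified" &
                             !duplicated(assignments$read_id)),
    seed = seed)

  res <- structure(list(
    sample_id = sample_id, filter = fr, n_host = nrow(scr$host),
    n_analyzed = nrow(pool), assignments = assignments,
    profile = prof, profile_grouped = grouped,
    shannon = shannon(prof), stats = stats
  ), class = "vagitax_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_stats(stats, file.path(out_dir, paste0(sample_id, "_stats.tsv")))
    write_profile(grouped, file.path(out_dir, paste0(sample_id, "_profile.tsv")))
    write_krona(prof, tree, file.path(out_dir, paste0(sample_id, "_krona.txt")))
  }
  res
}

write_run_stats <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

empty_run_stats <- function(sample_id, region, fr, lens) {
  tibble(sample = sample_id, region = region, pass_reads = fr$n_input,
         filtered_reads = 0L,
         retention_pct = if (fr$n_input > 0) 0 else NA_real_,
         min_bp = if (length(lens)) min(lens) else NA_integer_,
         avg_bp = if (length(lens)) round(mean(lens), 1) else NA_real_,
         max_bp = if (length(lens)) max(lens) else NA_integer_,
         filtered_avg_bp = NA_real_, host_reads = NA_integer_,
         analyzed_reads = 0L, classified_reads = 0L, seed = NA_integer_)
}

#' @export
print.vagitax_run <- function(x, ...) {
  cat(sprintf("<vagitax_run> %s: %d reads in, %d analyzed, H = %.3f\n",
              x$sample_id, x$filter$n_input, x$n_analyzed, x$shannon))
  print(x$profile_grouped)
  invisible(x)
}

#' Run a cohort of samples and ordinate them
#'
#' Runs [run_sample()] per sample, assembles the species-rank profiles into
#' a long table, computes the pairwise weighted UniFrac matrix on the given
#' phylogeny and embeds it with [pcoa()]. Bins that are not tree leaves
#' (`"unclassified"`, `"Others"`) are dropped with renormalisation before
#' UniFrac, since the phylogeny carries no placement for them.
#'
#' @param samples Named list of read tibbles (or FASTQ paths); names are the
#'   sample ids.
#' @param refdb,tree See [run_sample()].
#' @param phylo A rooted [ape::phylo] whose tips are the reference taxon
#'   ids at the reporting rank.
#' @param normalized Normalized UniFrac (default TRUE).
#' @param n_axes PCoA axes (default 2).
#' @param ... Passed to [run_sample()].
#' @return A list: `runs` (per-sample `vagitax_run`s), `profiles` (long
#'   tibble), `distances` (matrix), `ordination` (`vagitax_pcoa`).
#' @export
run_cohort <- function(samples, refdb, tree, phylo, normalized = TRUE,
                       n_axes = 2L, ...) {
  if (length(samples) < 2L) abort("A cohort needs at least 2 samples.")
  ids <- names(samples) %||% paste0("sample", seq_along(samples))
  runs <- purrr::imap(stats::setNames(samples, ids), function(rd, id) {
    run_sample(rd, refdb, tree, sample_id = id, ...)
  })
  profiles <- purrr::imap(runs, function(r, id) {
    dplyr::mutate(as_tibble(r$profile), sample_id = id)
  }) |> dplyr::bind_rows()
  on_tree <- profiles |>
    dplyr::filter(.data$taxon_id %in% phylo$tip.label) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(fraction = .data$fraction / sum(.data$fraction)) |>
    dplyr::ungroup()
  dm <- distance_matrix(on_tree, phylo, normalized = normalized)
  list(runs = runs, profiles = profiles, distances = dm,
       ordination = pcoa(dm, n_axes = n_axes))
}
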