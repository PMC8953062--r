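#' Per-sample taxonomic composition
#'
#' Sums the fractional assignment weights per taxon, rolls them up to the
#' requested rank, and divides by the total weight of all reads handed in
#' (classified plus unclassified, unless `include_unclassified = FALSE`).
#' Unclassified reads are kept as their own labelled bin so composition
#' fractions always sum to 1.
#'
#' @param assignments Assignment tibble from [classify_batch()].
#' @param tree A `taxonomy` object.
#' @param rank Rank to report at (default `"species"`).
#' @param sample_id Optional sample label stored in the result.
#' @param include_unclassified Keep unclassified reads in the denominator and
#'   as an `"unclassified"` bin (default TRUE).
#' @return A `tax_profile` tibble: columns `taxon_id`, `taxon`, `fraction`,
#'   with attributes `sample_id` and `n_reads_used`.
#' @export
composition <- function(assignments, tree, rank = "species",
                        sample_id = NULL, include_unclassified = TRUE) {
  check_taxonomy(tree)
  stopifnot(all(c("read_id", "outcome", "taxon_id", "weight") %in%
                  names(assignments)))
  cls <- assignments[assignments$outcome == "classified", , drop = FALSE]
  n_uncls <- length(unique(
    assignments$read_id[assignments$outcome == "unclassified"]))
  n_cls <- length(unique(cls$read_id))
  if (n_cls == 0L) {
    warn("No classified reads: profile is entirely unclassified.")
    out <- tibble(taxon_id = "unclassified", taxon = "unclassified",
                  fraction = 1)
    return(new_tax_profile(out, sample_id, n_uncls))
  }
  counts <- cls |>
    dplyr::group_by(.data$taxon_id) |>
    dplyr::summarise(count = sum(.data$weight), .groups = "drop")
  rolled <- rollup(counts, tree, rank)
  total <- sum(rolled$count) + if (include_unclassified) n_uncls else 0
  out <- tibble(taxon_id = rolled$taxon_id, taxon = rolled$name,
                fraction = rolled$count / total)
  if (include_unclassified && n_uncls > 0L) {
    out <- dplyr::bind_rows(out, tibble(
      taxon_id = "unclassified", taxon = "unclassified",
      fraction = n_uncls / total))
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$fraction))
  new_tax_profile(out, sample_id, n_cls + if (include_unclassified) n_uncls else 0L)
}

new_tax_profile <- function(tbl, sample_id, n_reads_used) {
  attr(tbl, "sample_id") <- sample_id
  attr(tbl, "n_reads_used") <- n_reads_used
  class(tbl) <- c("tax_profile", class(tbl))
  tbl
}

#' Merge minor taxa into "Others"
#'
#' Taxa with a fraction strictly below `threshold` are pooled into an
#' `"Others"` bin (the "assignment of less than 1%" display rule); a taxon at
#' exactly the threshold is retained. The `"unclassified"` bin is never
#' merged. Total mass is conserved.
#'
#' @param profile A `tax_profile` tibble.
#' @param threshold Minor-taxon cutoff as a fraction (default 0.01).
#' @return A `tax_profile` tibble with at most one `"Others"` row.
#' @export
apply_minor_grouping <- function(profile, threshold = 0.01) {
  stopifnot(all(c("taxon_id", "taxon", "fraction") %in% names(profile)))
  minor <- profile$fraction < threshold & profile$taxon_id != "unclassified"
  if (!any(minor)) return(profile)
  kept <- profile[!minor, , drop = FALSE]
  others <- tibble(taxon_id = "Others", taxon = "Others",
                   fraction = sum(profile$fraction[minor]))
  out <- dplyr::bind_rows(kept, others)
  new_tax_profile(out, attr(profile, "sample_id"),
                  attr(profile, "n_reads_used"))
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * ln(p_i))` over all bins with positive fraction, natural
#' log, computed over the profile exactly as handed in (pass the un-grouped
#' species-rank profile unless you want the display bins to enter the sum).
#'
#' @param profile A `tax_profile` tibble (or any tibble with `fraction`).
#' @return The Shannon index (>= 0).
#' @export
shannon <- function(profile) {
  p <- profile$fraction
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Nugent-score category
#'
#' Sums the three Gram-stain morphotype subscores — Lactobacillus (0–4),
#' Gardnerella (0–4), Mobiluncus (0–2) — and maps the total to the standard
#' diagnostic bands: 0–3 healthy, 4–6 intermediate, 7+ bacterial vaginosis.
#'
#' @param lactobacillus,gardnerella,mobiluncus Integer subscores (vectors
#'   recycle together).
#' @return Character vector: `"healthy"`, `"intermediate"` or `"BV"`.
#' @export
nugent_category <- function(lactobacillus, gardnerella, mobiluncus) {
  if (any(lactobacillus < 0 | lactobacillus > 4)) {
    abort("Lactobacillus subscore must be in 0-4.")
  }
  if (any(gardnerella < 0 | gardnerella > 4)) {
    abort("Gardnerella subscore must be in 0-4.")
  }
  if (any(mobiluncus < 0 | mobiluncus > 2)) {
    abort("Mobiluncus subscore must be in 0-2.")
  }
  total <- lactobacillus + gardnerella + mobiluncus
  dplyr::case_when(total <= 3 ~ "healthy",
                   total <= 6 ~ "intermediate",
                   TRUE ~ "BV")
}

#' Predicted minutes to accumulate a target read count
#'
#' Uses the median per-session filtered read count as the sequencing yield:
#' `rate = median(filtered_counts) / session_minutes`, returning
#' `round(target_reads / rate)`. With the study's 18 full-length lavage
#' filtered counts over a 90-minute session this predicts 3000 reads in
#' about 8 minutes.
#'
#' @param filtered_counts Integer vector of per-sample filtered read counts.
#' @param session_minutes Sequencing session length in minutes (default 90).
#' @param target_reads Read target (default 3000).
#' @return Predicted minutes, rounded to the nearest integer.
#' @export
time_to_reads <- function(filtered_counts, session_minutes = 90,
                          target_reads = 3000) {
  if (length(filtered_counts) == 0L) abort("Need at least one count.")
  if (session_minutes <= 0) abort("session_minutes must be positive.")
  med <- stats::median(filtered_counts)
  if (med == 0) abort("Median filtered count is zero; rate undefined.")
  rate <- med / session_minutes
  round(target_reads / rate)
}

#' Bundled per-sample nanopore run statistics
#'
#' The published per-sample MinION run statistics of an 18-subject vaginal
#' microbiome study (22 full-length V1–9 samples, of which 18 lavage and 4
#' swab, plus 6 V3–4 samples): pass reads, filtered reads (1300–1950 bp for
#' V1–9, 350–600 bp for V3–4, mean quality >= 7) and read-length summaries.
#' Used as the worked example for [retention_percent()] and
#' [time_to_reads()].
#'
#' @return A tibble with columns `sample`, `sample_type`, `region`,
#'   `pass_reads`, `filtered_reads`, `min_bp`, `avg_bp`, `max_bp`,
#'   `filtered_avg_bp`.
#' @export
minion_run_stats <- function() {
  path <- system.file("extdata", "minion_run_stats.tsv", package = "vagitax",
                      mustWork = TRUE)
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Write a profile in Krona two-column text format
#'
#' One line per taxon: count, then the tab-separated root-to-taxon lineage
#' names — the plain-text input consumed by hierarchical composition
#' viewers. `Others`/`unclassified` bins are written as single-field
#' lineages.
#'
#' @param profile A `tax_profile` tibble.
#' @param tree A `taxonomy` object (for lineage names).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_krona <- function(profile, tree, path) {
  check_taxonomy(tree)
  n <- attr(profile, "n_reads_used") %||% 1L
  lines <- vapply(seq_len(nrow(profile)), function(i) {
    id <- profile$taxon_id[i]
    lin <- if (id %in% tree$nodes$taxon_id) {
      paste(lineage(tree, id)$name, collapse = "\t")
    } else {
      profile$taxon[i]
    }
    sprintf("%.6g\t%s", profile$fraction[i] * n, lin)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a profile as TSV
#'
#' @param profile A `tax_profile` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
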