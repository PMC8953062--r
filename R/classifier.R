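#' Alignment scoring scheme
#'
#' Affine-gap local alignment parameters. Defaults (match +2, mismatch -4,
#' gap open -4, gap extend -2) follow the minimap2-style convention where a
#' gap of length L costs `|gap_open| + (L - 1) * |gap_extend|`.
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (<= 0).
#' @param gap_open Penalty for the first base of a gap (<= 0).
#' @param gap_extend Penalty for each further gap base (<= 0).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -4L, gap_open = -4L,
                           gap_extend = -2L) {
  if (match <= 0 || mismatch > 0 || gap_open > 0 || gap_extend > 0) {
    abort("match must be positive; penalties must be <= 0.")
  }
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' Best local alignment score of a query against a target
#'
#' Smith–Waterman with affine gaps, evaluated on both strands (the query and
#' its reverse complement); the larger score is returned. `N` never matches
#' anything. The score is a stand-in for an external long-read mapper's
#' alignment score when no precomputed alignments are supplied.
#'
#' @param query,target Non-empty DNA strings.
#' @param scheme A [scoring_scheme()].
#' @param both_strands Evaluate the reverse complement too (default TRUE).
#' @return A non-negative integer score.
#' @export
local_align_score <- function(query, target, scheme = scoring_scheme(),
                              both_strands = TRUE) {
  stopifnot(is.character(query), is.character(target),
            nchar(query) > 0, nchar(target) > 0)
  fwd <- sw_score_cpp(query, target, scheme$match, -scheme$mismatch,
                      -scheme$gap_open, -scheme$gap_extend)
  if (!both_strands) return(fwd)
  rev <- sw_score_cpp(revcomp(query), target, scheme$match, -scheme$mismatch,
                      -scheme$gap_open, -scheme$gap_extend)
  max(fwd, rev)
}

#' Reference panel constructor
#'
#' @param refs Tibble with columns `ref_id`, `seq`, `taxon_id`.
#' @param tree Optional `taxonomy` object; when given, every `taxon_id` must
#'   be present in it.
#' @return The validated tibble (invisibly classed `reference_db`).
#' @export
reference_db <- function(refs, tree = NULL) {
  stopifnot(is.data.frame(refs),
            all(c("ref_id", "seq", "taxon_id") %in% names(refs)))
  if (any(nchar(refs$seq) == 0L)) abort("Reference sequences must be non-empty.")
  if (anyDuplicated(refs$ref_id)) abort("Duplicate ref_id in reference panel.")
  if (!is.null(tree)) {
    check_taxonomy(tree)
    missing <- setdiff(refs$taxon_id, tree$nodes$taxon_id)
    if (length(missing) > 0L) {
      abort(paste0("Reference taxa absent from taxonomy: ",
                   paste(missing, collapse = ", ")))
    }
  }
  refs <- as_tibble(refs)
  class(refs) <- c("reference_db", class(refs))
  refs
}

# minimizer sketches for every reference, cached on the tibble
ref_sketches <- function(refdb, k = 15L, w = 10L) {
  lapply(refdb$seq, minimizer_keys_cpp, k = k, w = w)
}

#' Screen out host-derived reads
#'
#' A read is flagged as host when its best local alignment score against any
#' host reference reaches `min_host_score_frac` of the read's perfect-match
#' score (`match * read length`). Host elimination runs before bacterial
#' classification, mirroring the pipeline order of read processing.
#'
#' @param reads Read tibble.
#' @param host_refs Tibble with `ref_id`, `seq` (a host reference panel), or
#'   NULL/empty for no screening.
#' @param min_host_score_frac Fraction of the perfect-match score required to
#'   call a read host (default 0.7: demands a near-full-length, high-identity
#'   host hit).
#' @param scheme A [scoring_scheme()].
#' @return A list with read tibbles `host` and `non_host`, both preserving
#'   input order.
#' @export
screen_host <- function(reads, host_refs = NULL, min_host_score_frac = 0.7,
                        scheme = scoring_scheme()) {
  check_reads(reads)
  if (min_host_score_frac <= 0 || min_host_score_frac > 1) {
    abort("min_host_score_frac must be in (0, 1].")
  }
  if (is.null(host_refs) || nrow(host_refs) == 0L) {
    warn("Empty host reference panel: no reads screened as host.")
    return(list(host = reads[0, ], non_host = reads))
  }
  is_host <- vapply(seq_len(nrow(reads)), function(i) {
    thr <- min_host_score_frac * scheme$match * nchar(reads$seq[i])
    for (h in host_refs$seq) {
      if (local_align_score(reads$seq[i], h, scheme) >= thr) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(host = reads[is_host, , drop = FALSE],
       non_host = reads[!is_host, , drop = FALSE])
}

#' Classify reads by best hit with even tie allocation
#'
#' The computational core of the workflow. For every read a score per
#' DISTINCT taxon is computed as the maximum over that taxon's references
#' (so redundant references for one taxon never absorb tie mass, and
#' strain-level references collapse to their taxon before selection). A read
#' is `classified` when the top per-taxon score reaches `min_score_frac`
#' of the read's perfect-match score; its unit weight is then split evenly,
#' `1/k` to each of the `k` taxa tying for the top score. Otherwise it is
#' `unclassified`.
#'
#' Two scoring modes:
#' * built-in (default): a shared-minimizer prescreen (canonical k = 15,
#'   window 10) picks up to `n_candidates` references per read (pruned by
#'   `min_shared_frac`), which are then scored by affine local alignment.
#'   The read's strand is determined once, against the top prescreen
#'   candidate on both strands; the remaining candidates are scored on the
#'   winning strand. A read sharing zero minimizers with every reference is
#'   `unclassified` without alignment.
#' * external: pass `alignments` (a PAF tibble from [read_paf()]); scores
#'   come from the `score` column and no built-in alignment runs.
#'
#' Score ties are exact for integer built-in scores; external scores are
#' compared with a 1e-9 tolerance.
#'
#' @param reads Read tibble.
#' @param refdb A [reference_db()] tibble.
#' @param tree A `taxonomy` object covering the reference taxa.
#' @param min_score_frac Classification threshold as a fraction of the
#'   perfect-match score (default 0.4: permissive for 10–15% nanopore error,
#'   strict enough to reject random sequence).
#' @param scheme A [scoring_scheme()] (built-in mode).
#' @param alignments Optional PAF tibble for external-mapper mode.
#' @param n_candidates Maximum prescreen candidates per read (default 20).
#' @param min_shared_frac Prescreen prune: candidates must share at least
#'   this fraction of the top candidate's shared-minimizer count (default
#'   0.25). At realistic 16S divergences same-genus references share nearly
#'   the full count while unrelated genera share well under a quarter, so
#'   the prune discards only references that could not win the best-hit
#'   selection; set to 0 to score all `n_candidates`.
#' @param keep_scores Attach the per-(read, reference) score table as
#'   attribute `"scores"` (built-in mode only).
#' @return A tidy assignment tibble: one row per (read, taxon) weight with
#'   columns `read_id`, `outcome` (`classified`/`unclassified`), `taxon_id`,
#'   `weight`, `best_score`; unclassified reads carry one row with NA taxon
#'   and weight.
#' @export
classify_batch <- function(reads, refdb, tree, min_score_frac = 0.4,
                           scheme = scoring_scheme(), alignments = NULL,
                           n_candidates = 20L, min_shared_frac = 0.25,
                           keep_scores = FALSE) {
  check_reads(reads)
  check_taxonomy(tree)
  if (nrow(refdb) == 0L) abort("Empty reference panel.")
  taxon_of <- stats::setNames(refdb$taxon_id, refdb$ref_id)

  if (!is.null(alignments)) {
    unknown <- setdiff(unique(alignments$query_id), reads$read_id)
    if (length(unknown) > 0L) {
      abort(sprintf("Alignment references unknown read '%s'.", unknown[1]))
    }
    unknown_ref <- setdiff(unique(alignments$target_id), refdb$ref_id)
    if (length(unknown_ref) > 0L) {
      abort(sprintf("Alignment references unknown reference '%s'.",
                    unknown_ref[1]))
    }
    score_tbl <- alignments |>
      dplyr::group_by(read_id = .data$query_id, ref_id = .data$target_id) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop")
    tie_tol <- 1e-9
  } else {
    sketches <- ref_sketches(refdb)
    m <- scheme$match; mm <- -scheme$mismatch
    go <- -scheme$gap_open; ge <- -scheme$gap_extend
    rows <- vector("list", nrow(reads))
    for (i in seq_len(nrow(reads))) {
      keys <- minimizer_keys_cpp(reads$seq[i], 15L, 10L)
      shared <- vapply(sketches, shared_count_cpp, integer(1), a = keys)
      if (all(shared == 0L)) next
      cand <- order(shared, decreasing = TRUE)[seq_len(min(n_candidates,
                                                           nrow(refdb)))]
      cand <- cand[shared[cand] >= max(shared) * min_shared_frac &
                     shared[cand] > 0L]
      # orient the read once: both strands against the top candidate, the
      # winning strand for the rest (a read has one true orientation, and
      # strand score differences dwarf inter-reference differences)
      fwd_seq <- reads$seq[i]
      rev_seq <- revcomp(fwd_seq)
      s_fwd <- sw_score_cpp(fwd_seq, refdb$seq[cand[1]], m, mm, go, ge)
      s_rev <- sw_score_cpp(rev_seq, refdb$seq[cand[1]], m, mm, go, ge)
      oriented <- if (s_fwd >= s_rev) fwd_seq else rev_seq
      scores <- c(max(s_fwd, s_rev),
                  vapply(cand[-1], function(j) {
                    sw_score_cpp(oriented, refdb$seq[j], m, mm, go, ge)
                  }, integer(1)))
      rows[[i]] <- tibble(read_id = reads$read_id[i],
                          ref_id = refdb$ref_id[cand],
                          score = as.numeric(scores))
    }
    score_tbl <- dplyr::bind_rows(rows)
    tie_tol <- 0
  }

  read_len <- stats::setNames(nchar(reads$seq), reads$read_id)
  assignments <- if (nrow(score_tbl) == 0L) {
    tibble(read_id = character(), outcome = character(),
           taxon_id = character(), weight = numeric(), best_score = numeric())
  } else {
    score_tbl |>
      dplyr::mutate(taxon_id = unname(taxon_of[.data$ref_id])) |>
      dplyr::group_by(.data$read_id, .data$taxon_id) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop_last") |>
      dplyr::filter(.data$score >= max(.data$score) - tie_tol) |>
      dplyr::mutate(weight = 1 / dplyr::n(), best_score = max(.data$score)) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$best_score >=
                      min_score_frac * scheme$match * read_len[.data$read_id]) |>
      dplyr::mutate(outcome = "classified") |>
      dplyr::select("read_id", "outcome", "taxon_id", "weight", "best_score")
  }
  missing <- setdiff(reads$read_id, assignments$read_id)
  if (length(missing) > 0L) {
    assignments <- dplyr::bind_rows(
      assignments,
      tibble(read_id = missing, outcome = "unclassified",
             taxon_id = NA_character_, weight = NA_real_,
             best_score = NA_real_))
  }
  out <- assignments[order(match(assignments$read_id, reads$read_id)), ]
  if (keep_scores && is.null(alignments)) attr(out, "scores") <- score_tbl
  out
}

#' Classify a single read
#'
#' Convenience wrapper over [classify_batch()] for one read.
#'
#' @inheritParams classify_batch
#' @param read A one-row read tibble, or a list with `read_id`, `seq`, `qual`.
#' @return A one-read assignment tibble (possibly several weight rows).
#' @export
classify_read <- function(read, refdb, tree, min_score_frac = 0.4,
                          scheme = scoring_scheme()) {
  if (!is.data.frame(read)) read <- as_tibble(read[c("read_id", "seq", "qual")])
  classify_batch(read, refdb, tree, min_score_frac = min_score_frac,
                 scheme = scheme)
}
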