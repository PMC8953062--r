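#' Built-in 16S amplification primer sets
#'
#' The two inner-primer pairs of the four-primer amplification strategy,
#' each carrying a shared anchor tail used by the barcoding outer primers:
#' * `V1-9` (full length, ~1.6 kb product): forward core
#'   `AGRGTTYGATYMTGGCTCAG`, reverse core `GGYTACCTTGTTACGACTT`;
#' * `V3-4` (~0.4 kb product): forward core `CCTACGGGNGGCWGCAG`, reverse
#'   core `GGACTACHVGGGTWTCTAAT`.
#' Forward anchor `TTTCTGTTGGTGCTGATATTGC`, reverse anchor
#' `ACTTGCCTGTCGCTCTATCTTC` for both sets.
#'
#' @param name `"V1-9"` or `"V3-4"` (case-insensitive).
#' @return A `primer_set` list: `name`, `fwd_core`, `rev_core`, `fwd_anchor`,
#'   `rev_anchor`.
#' @export
primer_set <- function(name = c("V1-9", "V3-4")) {
  name <- match.arg(toupper(name), c("V1-9", "V3-4"))
  cores <- list(
    `V1-9` = c(fwd = "AGRGTTYGATYMTGGCTCAG", rev = "GGYTACCTTGTTACGACTT"),
    `V3-4` = c(fwd = "CCTACGGGNGGCWGCAG", rev = "GGACTACHVGGGTWTCTAAT"))
  structure(list(
    name = name,
    fwd_core = unname(cores[[name]]["fwd"]),
    rev_core = unname(cores[[name]]["rev"]),
    fwd_anchor = "TTTCTGTTGGTGCTGATATTGC",
    rev_anchor = "ACTTGCCTGTCGCTCTATCTTC"
  ), class = "primer_set")
}

#' Does an IUPAC primer base match a template base?
#'
#' @param primer_base Single IUPAC nucleotide code (e.g. `"R"`, `"N"`).
#' @param template_base Single concrete base, one of A/C/G/T.
#' @return TRUE iff the template base belongs to the code's set (R = \{A,G\},
#'   Y = \{C,T\}, M = \{A,C\}, W = \{A,T\}, H = \{A,C,T\}, V = \{A,C,G\},
#'   N = \{A,C,G,T\}, ...).
#' @export
iupac_matches <- function(primer_base, template_base) {
  primer_base <- toupper(primer_base)
  template_base <- toupper(template_base)
  map <- Biostrings::IUPAC_CODE_MAP
  if (!primer_base %in% names(map)) {
    abort(sprintf("Invalid IUPAC code '%s'.", primer_base))
  }
  if (!template_base %in% DNA_BASES) {
    abort(sprintf("Template base must be one of A/C/G/T, got '%s'.",
                  template_base))
  }
  grepl(template_base, map[[primer_base]], fixed = TRUE)
}

#' In-silico PCR with degenerate primers
#'
#' Matches the forward primer core on the plus strand and the reverse core as
#' its reverse complement downstream, allowing up to `max_mismatch`
#' mismatches per primer; IUPAC-degenerate agreement never counts as a
#' mismatch. For each forward site only the minimal-length pairing is
#' emitted (PCR favours the shortest product), products are reported sorted
#' by position, and overlapping duplicates are dropped. Spans are 0-based
#' half-open on the template.
#'
#' @param templates Tibble with `seq_id` and `seq` (e.g. from
#'   [read_fasta()]), or a single named character vector.
#' @param primers A [primer_set()].
#' @param max_mismatch Mismatches tolerated per primer (default 3).
#' @param with_anchors Prepend the forward anchor and append the reverse
#'   complement of the reverse anchor to the product sequence (default
#'   FALSE); the span always refers to the template-matched part.
#' @return Tibble with `template_id`, `start`, `end` (0-based half-open),
#'   `length` (product sequence length, anchors included when requested),
#'   `product_seq`, `includes_anchors`.
#' @export
in_silico_pcr <- function(templates, primers = primer_set("V1-9"),
                          max_mismatch = 3L, with_anchors = FALSE) {
  if (!is.data.frame(templates)) {
    templates <- tibble(seq_id = names(templates) %||%
                          paste0("template", seq_along(templates)),
                        seq = unname(templates))
  }
  out <- vector("list", nrow(templates))
  rev_rc <- revcomp(primers$rev_core)
  for (i in seq_len(nrow(templates))) {
    subj <- Biostrings::DNAString(templates$seq[i])
    fwd_hits <- Biostrings::matchPattern(
      Biostrings::DNAString(primers$fwd_core), subj,
      max.mismatch = max_mismatch, fixed = FALSE)
    rev_hits <- Biostrings::matchPattern(
      Biostrings::DNAString(rev_rc), subj,
      max.mismatch = max_mismatch, fixed = FALSE)
    if (length(fwd_hits) == 0L || length(rev_hits) == 0L) next
    f_start <- Biostrings::start(fwd_hits)   # 1-based
    f_end <- Biostrings::end(fwd_hits)
    r_end <- Biostrings::end(rev_hits)
    rows <- list()
    for (k in seq_along(f_start)) {
      cand <- r_end[r_end > f_end[k]]
      if (length(cand) == 0L) next
      stop1 <- min(cand)                      # minimal-length pairing
      rows[[length(rows) + 1L]] <- c(f_start[k], stop1)
    }
    if (length(rows) == 0L) next
    spans <- unique(do.call(rbind, rows))
    # drop products nested inside an earlier (shorter-started) product
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    keep <- rep(TRUE, nrow(spans))
    for (k in seq_len(nrow(spans))[-1]) {
      if (any(spans[seq_len(k - 1), 2][keep[seq_len(k - 1)]] >= spans[k, 2])) {
        keep[k] <- FALSE
      }
    }
    spans <- spans[keep, , drop = FALSE]
    seqs <- substring(templates$seq[i], spans[, 1], spans[, 2])
    if (with_anchors) {
      seqs <- paste0(primers$fwd_anchor, seqs, revcomp(primers$rev_anchor))
    }
    out[[i]] <- tibble(
      template_id = templates$seq_id[i],
      start = spans[, 1] - 1L,              # back to 0-based half-open
      end = spans[, 2],
      length = nchar(seqs),
      product_seq = seqs,
      includes_anchors = with_anchors)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(template_id = character(), start = integer(),
                  end = integer(), length = integer(),
                  product_seq = character(), includes_anchors = logical())
  }
  res
}
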