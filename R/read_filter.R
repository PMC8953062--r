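#' Amplicon length window for a 16S region
#'
#' The defaults are the study windows for the two amplicon targets:
#' 1300–1950 bp for the full-length V1–9 amplicon and 350–600 bp for the
#' V3–4 amplicon, both closed intervals.
#'
#' @param region `"V1-9"` or `"V3-4"` (case-insensitive; `"v1-9"` works).
#' @param min_len,max_len Optional overrides of the window bounds (bp).
#' @return A list with `region`, `min_len`, `max_len`.
#' @export
region_window <- function(region = c("V1-9", "V3-4"),
                          min_len = NULL, max_len = NULL) {
  region <- toupper(region)
  region <- match.arg(region, c("V1-9", "V3-4"))
  defaults <- list(`V1-9` = c(1300L, 1950L), `V3-4` = c(350L, 600L))
  w <- defaults[[region]]
  min_len <- as.integer(min_len %||% w[1])
  max_len <- as.integer(max_len %||% w[2])
  if (min_len <= 0L || min_len > max_len) {
    abort("Need 0 < min_len <= max_len.")
  }
  list(region = region, min_len = min_len, max_len = max_len)
}

#' Mean read quality by error-probability averaging
#'
#' The per-read quality is `-10 * log10(mean(10^(-q_i / 10)))`, i.e. the
#' Phred transform of the average per-base error probability — the
#' convention the basecaller's pass/fail split uses, not the arithmetic mean
#' of the Phred scores (which is always an upper bound, by Jensen's
#' inequality).
#'
#' @param qual Character vector of Phred+33 quality strings.
#' @return Numeric vector of mean qualities, one per read.
#' @export
mean_read_quality <- function(qual) {
  stopifnot(is.character(qual))
  if (any(nchar(qual) == 0L)) {
    abort("Mean quality of an empty read is undefined.")
  }
  vapply(qual, function(qs) {
    q <- phred_to_int(qs)
    -10 * log10(mean(10^(-q / 10)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Mask low-complexity (tandem repeat) regions with N
#'
#' A simplified greedy tandem masker: any run consisting of a repeated unit
#' of period 1–10 covering at least `min_run` bases is replaced by `N`.
#' Output length always equals input length; only `N` is ever introduced.
#'
#' @param seq Character vector of DNA strings.
#' @param min_run Minimum repeat-run length in bases to mask (default 15).
#' @param max_period Largest repeat unit length considered (default 10).
#' @return Character vector of masked sequences.
#' @export
mask_low_complexity <- function(seq, min_run = 15L, max_period = 10L) {
  stopifnot(is.character(seq))
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n == 0L) return(s)
    mask <- rep(FALSE, n)
    for (p in seq_len(max_period)) {
      # at least ceiling(min_run / p) unit copies => run >= min_run
      reps <- max(ceiling(min_run / p) - 1L, 1L)
      pat <- sprintf("([ACGTN]{%d})\\1{%d,}", p, reps)
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (m[1] != -1L) {
        len <- attr(m, "match.length")
        for (k in seq_along(m)) {
          if (len[k] >= min_run) mask[m[k]:(m[k] + len[k] - 1L)] <- TRUE
        }
      }
    }
    if (!any(mask)) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[mask] <- "N"
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Quality, length and complexity filter
#'
#' Keeps reads with mean quality (error-probability averaged) at least
#' `min_q`, length inside the closed region window, and post-masking `N`
#' fraction below `mask_discard_fraction`. Rejection categories are counted
#' with fixed precedence quality -> length -> mask so the counts are
#' deterministic and always partition the input. Kept reads are returned
#' with their low-complexity regions masked.
#'
#' @param reads Read tibble (`read_id`, `seq`, `qual`).
#' @param window A [region_window()].
#' @param min_q Minimum mean read quality (default 7, the basecaller pass
#'   threshold).
#' @param mask_discard_fraction Discard a read whose masked (`N`) fraction
#'   reaches this value (default 0.9: such a read carries no taxonomic
#'   signal).
#' @param mask_min_run Minimum tandem-run length passed to
#'   [mask_low_complexity()].
#' @return A `filter_result` object: list with `kept` (masked read tibble)
#'   and counts `n_input`, `n_kept`, `n_fail_quality`, `n_fail_length`,
#'   `n_fail_masked`.
#' @export
filter_reads <- function(reads, window = region_window("V1-9"), min_q = 7,
                         mask_discard_fraction = 0.9, mask_min_run = 15L) {
  check_reads(reads)
  n_input <- nrow(reads)
  if (n_input == 0L) {
    return(new_filter_result(reads, n_input, 0L, 0L, 0L))
  }
  q_ok <- mean_read_quality(reads$qual) >= min_q
  len <- nchar(reads$seq)
  l_ok <- len >= window$min_len & len <= window$max_len
  surv <- reads[q_ok & l_ok, , drop = FALSE]
  masked <- mask_low_complexity(surv$seq, min_run = mask_min_run)
  n_frac <- stringr::str_count(masked, "N") / pmax(nchar(masked), 1L)
  m_ok <- n_frac < mask_discard_fraction
  kept <- surv
  kept$seq <- masked
  kept <- kept[m_ok, , drop = FALSE]
  new_filter_result(
    kept,
    n_input = n_input,
    n_fail_quality = sum(!q_ok),
    n_fail_length = sum(q_ok & !l_ok),
    n_fail_masked = sum(!m_ok)
  )
}

new_filter_result <- function(kept, n_input, n_fail_quality, n_fail_length,
                              n_fail_masked) {
  structure(list(
    kept = kept,
    n_input = as.integer(n_input),
    n_kept = nrow(kept),
    n_fail_quality = as.integer(n_fail_quality),
    n_fail_length = as.integer(n_fail_length),
    n_fail_masked = as.integer(n_fail_masked)
  ), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf(
    "<filter_result> %d in -> %d kept (%.1f%%); fail: quality %d, length %d, mask %d\n",
    x$n_input, x$n_kept, if (x$n_input > 0) 100 * x$n_kept / x$n_input else 0,
    x$n_fail_quality, x$n_fail_length, x$n_fail_masked))
  invisible(x)
}

#' @rdname filter_reads
#' @param x A `filter_result`.
#' @param ... Unused.
#' @export
glance.filter_result <- function(x, ...) {
  tibble(n_input = x$n_input, n_kept = x$n_kept,
         n_fail_quality = x$n_fail_quality,
         n_fail_length = x$n_fail_length,
         n_fail_masked = x$n_fail_masked,
         retention_pct = if (x$n_input > 0) retention_percent(x) else NA_real_)
}

#' Retention percentage of a filter result
#'
#' `100 * n_kept / n_input`, rounded to one decimal — the parenthesised
#' percentage convention of per-sample sequencing run statistics.
#'
#' @param result A `filter_result`, or a list with `n_kept` and `n_input`.
#' @return Percentage rounded to 1 decimal place.
#' @export
retention_percent <- function(result) {
  if (is.null(result$n_input) || result$n_input == 0) {
    abort("Retention is undefined for zero input reads.")
  }
  round(100 * result$n_kept / result$n_input, 1)
}

#' Seeded uniform subsampling of reads
#'
#' Draws exactly `n` reads uniformly without replacement (in draw order);
#' identical seeds give identical selections. If the pool is smaller than
#' `n`, all reads are returned with a warning.
#'
#' @param reads Read tibble.
#' @param n Number of reads to draw (default 3000, the per-sample analysis
#'   depth).
#' @param seed Integer seed.
#' @return Read tibble with `min(n, nrow(reads))` rows.
#' @export
subsample_reads <- function(reads, n = 3000L, seed = 1L) {
  check_reads(reads)
  if (n < 0L) abort("n must be non-negative.")
  pool <- nrow(reads)
  if (pool < n) {
    warn(sprintf("Pool of %d reads is smaller than requested n = %d; returning all.",
                 pool, n))
    return(reads)
  }
  idx <- withr::with_seed(seed, sample.int(pool, n))
  reads[idx, , drop = FALSE]
}
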