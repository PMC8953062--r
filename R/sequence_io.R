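#' Read a 4-line FASTQ file into a read tibble
#'
#' Reads Phred+33 FASTQ (the nanopore convention; Phred+64 input is rejected,
#' not auto-detected) into the package's read table: one row per read with the
#' quality string kept in its encoded form. Multi-line FASTQ is not accepted.
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return A tibble with columns `read_id`, `seq` (uppercase DNA) and `qual`
#'   (Phred+33 quality string, same width as `seq`).
#' @seealso [write_fastq()], [qual_scores()]
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(tibble(read_id = character(), seq = character(), qual = character()))
  }
  if (length(lines) %% 4L != 0L) {
    abort(sprintf(
      "Truncated FASTQ record: file ends at line %d (records are 4 lines).",
      length(lines)))
  }
  idx <- seq(1L, length(lines), by = 4L)
  headers <- lines[idx]
  bad <- which(!startsWith(headers, "@"))
  if (length(bad) > 0L) {
    abort(sprintf("Malformed FASTQ header at line %d: expected '@'.",
                  idx[bad[1]]))
  }
  read_id <- sub("\\s.*$", "", substring(headers, 2L))
  seq <- toupper(lines[idx + 1L])
  qual <- lines[idx + 3L]
  mism <- which(nchar(seq) != nchar(qual))
  if (length(mism) > 0L) {
    abort(sprintf(
      "Read '%s' (record %d): sequence length %d != quality length %d.",
      read_id[mism[1]], mism[1], nchar(seq[mism[1]]), nchar(qual[mism[1]])))
  }
  qrange <- range(utf8ToInt(paste(qual, collapse = "")))
  if (length(qual) > 0L && nchar(qual[1]) > 0L &&
      (qrange[1] < 33L || qrange[2] > 126L)) {
    abort("Quality characters outside the Phred+33 printable range.")
  }
  if (anyDuplicated(read_id)) {
    abort(sprintf("Duplicate read id in FASTQ: '%s'.",
                  read_id[duplicated(read_id)][1]))
  }
  tibble(read_id = read_id, seq = seq, qual = qual)
}

#' Write a read tibble as Phred+33 FASTQ
#'
#' @param reads Tibble with `read_id`, `seq`, `qual` columns (as produced by
#'   [read_fastq()] or [simulate_reads()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_reads(reads)
  qc <- utf8ToInt(paste(reads$qual, collapse = ""))
  if (length(qc) > 0L && (min(qc) < 33L || max(qc) > 126L)) {
    abort("Unencodable quality: Phred scores must lie in [0, 93] (Phred+33).")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    out <- rbind(paste0("@", reads$read_id), reads$seq, "+", reads$qual)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param qual Character vector of Phred+33 quality strings.
#' @return A list of integer vectors, one per input string.
#' @export
qual_scores <- function(qual) {
  lapply(qual, phred_to_int)
}

check_reads <- function(reads) {
  if (!is.data.frame(reads) ||
      !all(c("read_id", "seq", "qual") %in% names(reads))) {
    abort("`reads` must be a data frame with read_id, seq and qual columns.")
  }
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    abort("seq and qual must have equal widths for every read.")
  }
  invisible(reads)
}

#' Read a FASTA file into a sequence tibble
#'
#' Multi-line FASTA is accepted (references are commonly wrapped).
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `seq_id` and `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(seq_id = sub("\\s.*$", "", names(x)), seq = as.character(x))
}

#' Write a sequence tibble as FASTA
#'
#' @param seqs Tibble with `seq_id` and `seq` columns; an optional `desc`
#'   column is appended to the header line.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs$seq)
  names(x) <- if ("desc" %in% names(seqs)) {
    paste(seqs$seq_id, seqs$desc)
  } else {
    seqs$seq_id
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# PAF -----------------------------------------------------------------------

#' Read a PAF alignment file
#'
#' Parses the 12 mandatory tab-separated PAF columns plus optional SAM-style
#' typed tags. The alignment score is taken from the `AS:i` tag when present
#' and falls back to the residue-match count (column 10) otherwise — minimap2
#' emits its alignment score as `AS` while residue matches are the documented
#' mandatory-column fallback. Coordinates stay 0-based half-open, as in PAF.
#'
#' @param path Path to a PAF file.
#' @return Tibble with columns `query_id`, `query_len`, `query_start`,
#'   `query_end`, `strand`, `target_id`, `target_len`, `target_start`,
#'   `target_end`, `n_match`, `aln_len`, `mapq`, `score` and `score_source`
#'   (`"AS"` or `"n_match"`).
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) abort(paste0("PAF file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_paf())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 12L)) {
    abort(sprintf("PAF parse error at line %d: %d columns (12 required).",
                  which(nfield < 12L)[1], nfield[which(nfield < 12L)[1]]))
  }
  int_cols <- c(2L, 3L, 4L, 7L, 8L, 9L, 10L, 11L, 12L)
  mat <- t(vapply(parts, function(p) p[1:12], character(12)))
  ints <- suppressWarnings(
    matrix(as.integer(mat[, int_cols, drop = FALSE]), ncol = length(int_cols)))
  if (anyNA(ints)) {
    bad <- which(apply(is.na(ints), 1, any))[1]
    abort(sprintf("PAF parse error at line %d: non-integer coordinate field.",
                  bad))
  }
  if (any(!mat[, 5] %in% c("+", "-"))) {
    abort(sprintf("PAF parse error at line %d: strand must be '+' or '-'.",
                  which(!mat[, 5] %in% c("+", "-"))[1]))
  }
  as_score <- vapply(parts, function(p) {
    if (length(p) <= 12L) return(NA_integer_)
    tag <- grep("^AS:i:", p[-(1:12)], value = TRUE)
    if (length(tag) == 0L) NA_integer_ else as.integer(sub("^AS:i:", "", tag[1]))
  }, integer(1))
  tibble(
    query_id = mat[, 1], query_len = ints[, 1],
    query_start = ints[, 2], query_end = ints[, 3],
    strand = mat[, 5],
    target_id = mat[, 6], target_len = ints[, 4],
    target_start = ints[, 5], target_end = ints[, 6],
    n_match = ints[, 7], aln_len = ints[, 8], mapq = ints[, 9],
    score = ifelse(is.na(as_score), ints[, 7], as_score),
    score_source = ifelse(is.na(as_score), "n_match", "AS")
  )
}

empty_paf <- function() {
  tibble(
    query_id = character(), query_len = integer(),
    query_start = integer(), query_end = integer(), strand = character(),
    target_id = character(), target_len = integer(),
    target_start = integer(), target_end = integer(),
    n_match = integer(), aln_len = integer(), mapq = integer(),
    score = integer(), score_source = character()
  )
}

#' Write an alignment tibble as PAF
#'
#' The score is emitted as an `AS:i` tag so a round trip through [read_paf()]
#' preserves it.
#'
#' @param hits Alignment tibble in the column layout of [read_paf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(hits, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\tAS:i:%d",
                   hits$query_id, hits$query_len, hits$query_start,
                   hits$query_end, hits$strand, hits$target_id,
                   hits$target_len, hits$target_start, hits$target_end,
                   hits$n_match, hits$aln_len, hits$mapq,
                   as.integer(round(hits$score)))
  writeLines(lines, path)
  invisible(path)
}

# Newick --------------------------------------------------------------------

#' Parse a rooted Newick string
#'
#' Thin wrapper over [ape::read.tree()] that enforces the invariants the rest
#' of the package relies on: a single rooted tree, unique leaf labels,
#' non-negative branch lengths (missing lengths default to 0).
#'
#' @param text A Newick string.
#' @return An [ape::phylo] object.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL)
  if (is.null(tr)) abort("Newick parse error (unbalanced or malformed input).")
  if (inherits(tr, "multiPhylo")) abort("Expected a single Newick tree.")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (any(tr$edge.length < 0)) abort("Negative branch length in Newick input.")
  if (anyDuplicated(tr$tip.label)) abort("Duplicate leaf labels in Newick input.")
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree An [ape::phylo] object.
#' @return A Newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

# NCBI-style taxonomy dumps -------------------------------------------------

#' Load an NCBI-style taxonomy from nodes/names dump tables
#'
#' Accepts the pipe-delimited, whitespace-tolerant `nodes.dmp`/`names.dmp`
#' dialect (`id | parent | rank ...`; `id | name | unique | class`). When a
#' name class column is present only "scientific name" rows are used;
#' otherwise the first name per taxon wins.
#'
#' @param nodes_path Path to the nodes table.
#' @param names_path Path to the names table.
#' @return A `taxonomy` object (see [taxonomy_tree()]).
#' @export
load_taxonomy <- function(nodes_path, names_path) {
  parse_dmp <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lapply(strsplit(lines, "|", fixed = TRUE), trimws)
  }
  nodes_raw <- parse_dmp(nodes_path)
  if (any(lengths(nodes_raw) < 3L)) {
    abort("nodes table: each row needs at least id | parent | rank.")
  }
  names_raw <- parse_dmp(names_path)
  if (any(lengths(names_raw) < 2L)) {
    abort("names table: each row needs at least id | name.")
  }
  nm_id <- vapply(names_raw, `[`, character(1), 1L)
  nm_name <- vapply(names_raw, `[`, character(1), 2L)
  nm_class <- vapply(names_raw, function(x) {
    if (length(x) >= 4L) x[4L] else NA_character_
  }, character(1))
  keep <- is.na(nm_class) | nm_class == "scientific name"
  nm_id <- nm_id[keep]; nm_name <- nm_name[keep]
  nm_first <- !duplicated(nm_id)
  name_map <- stats::setNames(nm_name[nm_first], nm_id[nm_first])

  nodes <- tibble(
    taxon_id = vapply(nodes_raw, `[`, character(1), 1L),
    parent_id = vapply(nodes_raw, `[`, character(1), 2L),
    rank = vapply(nodes_raw, `[`, character(1), 3L)
  )
  nodes$name <- unname(name_map[nodes$taxon_id])
  if (anyNA(nodes$name)) {
    abort(sprintf("Taxon %s has no name in the names table.",
                  nodes$taxon_id[is.na(nodes$name)][1]))
  }
  taxonomy_tree(nodes)
}
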