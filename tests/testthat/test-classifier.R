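test_that("local alignment scores match identity and strand expectations", {
  s <- random_dna(100, seed = 1)
  expect_equal(local_align_score(s, s), 200)
  expect_equal(local_align_score(revcomp(s), s), 200)
  # N matches nothing
  expect_equal(local_align_score("NNNN", "NNNN"), 0)
})

test_that("compiled aligner agrees with the brute-force DP oracle", {
  for (k in 1:20) {
    q <- random_dna(60, seed = 2 * k)
    t <- withr::with_seed(2 * k + 1, {
      # mutate the query so alignments are non-trivial
      ch <- strsplit(q, "")[[1]]
      idx <- sample(60, 12)
      ch[idx] <- sample(c("A", "C", "G", "T"), 12, replace = TRUE)
      paste(ch, collapse = "")
    })
    expect_equal(local_align_score(q, t, both_strands = FALSE),
                 dp_local_score(q, t))
  }
  # and under a non-default scheme
  sch <- scoring_scheme(3L, -2L, -5L, -1L)
  q <- random_dna(60, seed = 99); t <- random_dna(60, seed = 100)
  expect_equal(local_align_score(q, t, sch, both_strands = FALSE),
               dp_local_score(q, t, 3, -2, -5, -1))
})

test_that("host screening flags verbatim host copies and passes 16S reads", {
  host <- tibble::tibble(ref_id = "chrH",
                         seq = random_dna(3000, seed = 42))
  host_read <- make_read("h1", substr(host$seq, 501, 2000), q = 12)
  bact_read <- make_read("b1", fix10()$refdb$seq[1], q = 12)
  reads <- dplyr::bind_rows(host_read, bact_read)
  scr <- screen_host(reads, host)
  expect_equal(scr$host$read_id, "h1")
  expect_equal(scr$non_host$read_id, "b1")

  expect_warning(scr0 <- screen_host(reads, NULL), "host")
  expect_equal(nrow(scr0$host), 0L)
  expect_equal(scr0$non_host, reads)

  empty <- screen_host(reads[0, ], host)
  expect_equal(nrow(empty$host), 0L)
  expect_equal(nrow(empty$non_host), 0L)
})

test_that("ties split evenly and per-taxon max precedes tie detection", {
  fx <- fix10()
  seq1 <- fx$refdb$seq[1]
  # two taxa with identical references -> exact tie, 0.5 each
  tax <- fx$taxonomy
  refs <- reference_db(tibble::tibble(
    ref_id = c("rA", "rB"), seq = c(seq1, seq1),
    taxon_id = c("s01_1", "s02_1")), tax)
  a <- classify_batch(make_read("r", seq1, 12), refs, tax)
  expect_equal(sort(a$taxon_id), c("s01_1", "s02_1"))
  expect_equal(a$weight, c(0.5, 0.5))
  expect_equal(sum(a$weight), 1)

  # adding a duplicate reference for one taxon must not shift tie mass
  refs_dup <- reference_db(tibble::tibble(
    ref_id = c("rA", "rA2", "rB"), seq = c(seq1, seq1, seq1),
    taxon_id = c("s01_1", "s01_1", "s02_1")), tax)
  a2 <- classify_batch(make_read("r", seq1, 12), refs_dup, tax)
  expect_equal(dplyr::arrange(a2, taxon_id)$weight,
               dplyr::arrange(a, taxon_id)$weight)

  # unique maximum takes the whole weight
  refs_uni <- reference_db(tibble::tibble(
    ref_id = c("rA", "rB"), seq = c(seq1, fx$refdb$seq[2]),
    taxon_id = c("s01_1", "s02_1")), tax)
  a3 <- classify_batch(make_read("r", seq1, 12), refs_uni, tax)
  expect_equal(a3$taxon_id, "s01_1")
  expect_equal(a3$weight, 1)
})

test_that("weights of every classified read sum to one", {
  fx <- fix10()
  sim <- sim_small()
  a <- classify_batch(sim$reads[1:30, ], fx$refdb, fx$taxonomy)
  sums <- a |>
    dplyr::filter(outcome == "classified") |>
    dplyr::group_by(read_id) |>
    dplyr::summarise(w = sum(weight))
  expect_true(all(abs(sums$w - 1) < 1e-12))
})

test_that("raising the score threshold only shrinks the classified set", {
  fx <- fix10()
  reads <- sim_small()$reads[1:20, ]
  classified_at <- function(frac) {
    a <- classify_batch(reads, fx$refdb, fx$taxonomy, min_score_frac = frac)
    unique(a$read_id[a$outcome == "classified"])
  }
  sets <- lapply(c(0.2, 0.4, 0.8, 1.01), classified_at)
  for (k in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[k + 1]] %in% sets[[k]]))
  }
  expect_equal(length(sets[[4]]), 0L)  # nothing beats a perfect score + 1%
})

test_that("simulated reads are assigned to their source species", {
  fx <- fix10()
  sim <- simulate_reads(fx$refdb, c(s01_1 = 1), n_reads = 200,
                        region = "V1-9", seed = 5)
  a <- classify_batch(sim$reads, fx$refdb, fx$taxonomy)
  cls <- a[a$outcome == "classified", ]
  expect_gt(length(unique(cls$read_id)) / 200, 0.95)
  on_target <- sum(cls$weight[cls$taxon_id == "s01_1"]) / sum(cls$weight)
  expect_gt(on_target, 0.95)
})

test_that("external-mapper mode mirrors PAF best hits and validates ids", {
  fx <- fix10()
  reads <- sim_small()$reads[1:15, ]
  builtin <- classify_batch(reads, fx$refdb, fx$taxonomy, keep_scores = TRUE)
  scores <- attr(builtin, "scores")
  # fabricate a PAF carrying exactly the built-in scores
  hits <- scores |>
    dplyr::mutate(
      query_len = nchar(reads$seq[match(read_id, reads$read_id)]),
      target_len = nchar(fx$refdb$seq[match(ref_id, fx$refdb$ref_id)])) |>
    dplyr::transmute(
      query_id = read_id, query_len, query_start = 0L, query_end = query_len,
      strand = "+", target_id = ref_id, target_len, target_start = 0L,
      target_end = target_len,
      n_match = as.integer(score %/% 2), aln_len = query_len, mapq = 60L,
      score = score)
  fp <- withr::local_tempfile(fileext = ".paf")
  write_paf(hits, fp)
  external <- classify_batch(reads, fx$refdb, fx$taxonomy,
                             alignments = read_paf(fp))
  expect_equal(
    dplyr::arrange(as.data.frame(external), read_id, taxon_id),
    dplyr::arrange(as.data.frame(builtin), read_id, taxon_id),
    ignore_attr = TRUE)

  bad <- hits
  bad$query_id[1] <- "ghost"
  expect_error(
    classify_batch(reads, fx$refdb, fx$taxonomy, alignments = bad),
    "ghost")
})
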