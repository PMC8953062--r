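test_that("fixture generation is deterministic with the stated cardinality", {
  fx <- fix10()
  expect_equal(nrow(fx$refdb), 10L)
  expect_equal(sum(fx$taxonomy$nodes$rank == "genus"), 10L)
  expect_equal(sum(fx$taxonomy$nodes$rank == "species"), 10L)
  expect_equal(length(fx$tree$tip.label), 10L)
  expect_setequal(fx$tree$tip.label,
                  fx$taxonomy$nodes$taxon_id[fx$taxonomy$nodes$rank == "species"])

  again <- make_reference_fixture(n_genera = 10, species_per_genus = 1,
                                  seed = 1)
  expect_identical(again$refdb$seq, fx$refdb$seq)

  other <- make_reference_fixture(n_genera = 10, species_per_genus = 1,
                                  seed = 99)
  expect_false(identical(other$refdb$seq, fx$refdb$seq))

  expect_error(make_reference_fixture(inter_genus_div = 0.01,
                                      intra_genus_div = 0.02), "intra")
})

test_that("realized divergences track the generator targets", {
  fx <- fix10()
  # pairwise inter-genus divergence ~ 0.15 within +/- 3 points
  divs <- c()
  for (i in 1:4) {
    for (j in (i + 1):5) {
      divs <- c(divs, str_divergence(fx$refdb$seq[i], fx$refdb$seq[j]))
    }
  }
  expect_true(all(abs(divs - 0.15) < 0.03))

  # intra-genus divergence ~ 0.02
  fm <- fix_multi()
  sp_g1 <- fm$refdb$seq[fm$refdb$taxon_id %in% c("s01_1", "s01_2")]
  expect_lt(abs(str_divergence(sp_g1[1], sp_g1[2]) - 2 * 0.02), 0.02)
})

test_that("every fixture species yields exactly one product per region", {
  fx <- fix_multi()
  templates <- tibble::tibble(seq_id = fx$refdb$ref_id, seq = fx$refdb$seq)
  for (region in c("V1-9", "V3-4")) {
    prods <- in_silico_pcr(templates, primer_set(region))
    expect_equal(sort(prods$template_id), sort(fx$refdb$ref_id))
  }
})

test_that("the confusable pair is V3-4-identical but V1-9-distinct", {
  cp <- confusable()
  templates <- tibble::tibble(seq_id = cp$refdb$ref_id, seq = cp$refdb$seq)
  v34 <- in_silico_pcr(templates, primer_set("V3-4"))
  expect_equal(nrow(v34), 2L)
  expect_identical(v34$product_seq[1], v34$product_seq[2])

  v19 <- in_silico_pcr(templates, primer_set("V1-9"))
  expect_equal(nrow(v19), 2L)
  expect_gte(str_divergence(v19$product_seq[1], v19$product_seq[2]), 0.05)
})

test_that("error-free V3-4 reads split evenly; V1-9 reads resolve the species", {
  cp <- confusable()
  nofail <- error_model(p_sub = 0, p_ins = 0, p_del = 0)
  v34 <- simulate_reads(cp$refdb, c(s01_1 = 1), n_reads = 10,
                        region = "V3-4", model = nofail, seed = 3)
  a34 <- classify_batch(v34$reads, cp$refdb, cp$taxonomy)
  w <- a34 |>
    dplyr::filter(outcome == "classified") |>
    dplyr::group_by(taxon_id) |>
    dplyr::summarise(w = sum(weight) / 10)
  expect_equal(sort(w$taxon_id), c("s01_1", "s01_2"))
  expect_equal(w$w, c(0.5, 0.5))

  v19 <- simulate_reads(cp$refdb, c(s01_1 = 1), n_reads = 10,
                        region = "V1-9", model = nofail, seed = 4)
  a19 <- classify_batch(v19$reads, cp$refdb, cp$taxonomy)
  cls <- a19[a19$outcome == "classified", ]
  expect_equal(unique(cls$taxon_id), "s01_1")
  expect_true(all(cls$weight == 1))
})

test_that("the no-error model reproduces amplicons exactly with zero truth", {
  fx <- fix10()
  nofail <- error_model(p_sub = 0, p_ins = 0, p_del = 0)
  sim <- simulate_reads(fx$refdb, c(s03_1 = 1), n_reads = 5,
                        region = "V1-9", model = nofail, seed = 6)
  amp <- in_silico_pcr(
    tibble::tibble(seq_id = "r", seq = fx$refdb$seq[fx$refdb$taxon_id == "s03_1"]),
    primer_set("V1-9"), with_anchors = TRUE)$product_seq
  fwd <- ifelse(sim$truth$strand == "-", revcomp(sim$reads$seq), sim$reads$seq)
  expect_true(all(fwd == amp))
  expect_true(all(sim$truth$n_sub == 0 & sim$truth$n_ins == 0 &
                    sim$truth$n_del == 0))
})

test_that("simulation matches its sampling and error-rate targets", {
  fx <- fix10()
  sim <- simulate_reads(fx$refdb, uniform10(), n_reads = 3000,
                        region = "V1-9", seed = 1)
  counts <- table(sim$truth$taxon_id)
  # binomial: 300 +/- 4 * sqrt(3000 * 0.1 * 0.9) ~ 300 +/- 66
  expect_true(all(abs(counts - 300) <= 4 * sqrt(3000 * 0.1 * 0.9)))

  # realized substitution rate ~ p_sub +/- 0.005 (template length 1578)
  rate <- sum(sim$truth$n_sub) / (3000 * 1578)
  expect_lt(abs(rate - 0.03), 0.005)

  # full determinism under the same seed
  again <- simulate_reads(fx$refdb, uniform10(), n_reads = 50,
                          region = "V1-9", seed = 42)
  again2 <- simulate_reads(fx$refdb, uniform10(), n_reads = 50,
                           region = "V1-9", seed = 42)
  expect_identical(again$reads, again2$reads)
  expect_identical(again$truth, again2$truth)

  expect_error(simulate_reads(fx$refdb, c(s01_1 = 0.5), 10, seed = 1), "sum")
  expect_error(simulate_reads(fx$refdb, c(ghost = 1), 10, seed = 1), "ghost")
})

test_that("error-position qualities are drawn lower than match qualities", {
  fx <- fix10()
  sim <- simulate_reads(fx$refdb, c(s01_1 = 1), n_reads = 30,
                        region = "V3-4", seed = 13)
  q <- unlist(qual_scores(sim$reads$qual))
  # a mixture of Q14 matches and Q8 errors: mean must sit between, nearer 14
  expect_gt(mean(q), 11)
  expect_lt(mean(q), 15)
  # reads pass the default quality filter
  expect_true(all(mean_read_quality(sim$reads$qual) > 7))
})
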