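two_leaf_tree <- function() parse_newick("(A:1,B:1):0;")

prof <- function(taxa, frac) tibble::tibble(taxon_id = taxa, fraction = frac)

random_profile <- function(tree, seed) {
  withr::with_seed(seed, {
    p <- runif(length(tree$tip.label))
    prof(tree$tip.label, p / sum(p))
  })
}

test_that("weighted UniFrac matches hand computations on two-leaf trees", {
  tr <- two_leaf_tree()
  pa <- prof(c("A", "B"), c(1, 0))
  pb <- prof(c("A", "B"), c(0, 1))
  expect_equal(weighted_unifrac(tr, pa, pa), 0)
  expect_equal(weighted_unifrac(tr, pa, pb, normalized = FALSE), 2)
  expect_equal(weighted_unifrac(tr, pa, pb, normalized = TRUE), 1)
  # intermediate mixture: raw = 1*|1-0.5| + 1*|0-0.5| = 1
  pc <- prof(c("A", "B"), c(0.5, 0.5))
  expect_equal(weighted_unifrac(tr, pa, pc, normalized = FALSE), 1)

  expect_error(weighted_unifrac(tr, prof("Z", 1), pa), "Z")
})

test_that("weighted UniFrac is a pseudometric on fixture profiles", {
  tree <- fix_multi()$tree
  profs <- lapply(1:6, random_profile, tree = tree)
  for (i in 1:5) {
    expect_equal(weighted_unifrac(tree, profs[[i]], profs[[i]]), 0)
    for (j in (i + 1):6) {
      dij <- weighted_unifrac(tree, profs[[i]], profs[[j]], normalized = FALSE)
      dji <- weighted_unifrac(tree, profs[[j]], profs[[i]], normalized = FALSE)
      expect_equal(dij, dji)
      expect_gte(dij, 0)
    }
  }
  # triangle inequality for the raw variant over all triples
  dm <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    if (i != j) dm[i, j] <- weighted_unifrac(tree, profs[[i]], profs[[j]],
                                             normalized = FALSE)
  }
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
  }
})

test_that("weighted UniFrac agrees with an independent implementation", {
  skip_if_not_installed("phyloseq")
  # random binary tree (the reference implementation requires a resolved
  # rooted tree without a root edge)
  tree <- withr::with_seed(31, ape::rtree(10))
  for (seed in 1:4) {
    pa <- random_profile(tree, seed)
    pb <- random_profile(tree, seed + 50)
    otu <- rbind(A = pa$fraction, B = pb$fraction)
    colnames(otu) <- pa$taxon_id
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(otu, taxa_are_rows = FALSE), tree)
    ref <- as.numeric(phyloseq::UniFrac(ps, weighted = TRUE,
                                        normalized = TRUE))
    expect_equal(weighted_unifrac(tree, pa, pb, normalized = TRUE), ref,
                 tolerance = 1e-8)
    ref_raw <- as.numeric(phyloseq::UniFrac(ps, weighted = TRUE,
                                            normalized = FALSE))
    expect_equal(weighted_unifrac(tree, pa, pb, normalized = FALSE), ref_raw,
                 tolerance = 1e-8)
  }
})

test_that("distance matrices are consistent with per-pair calls", {
  tree <- fix10()$tree
  profs <- dplyr::bind_rows(lapply(1:4, function(s) {
    dplyr::mutate(random_profile(tree, s), sample_id = paste0("p", s))
  }))
  dm <- distance_matrix(profs, tree)
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), stats::setNames(rep(0, 4), paste0("p", 1:4)))
  p1 <- profs[profs$sample_id == "p1", ]
  p3 <- profs[profs$sample_id == "p3", ]
  expect_equal(dm["p1", "p3"], weighted_unifrac(tree, p1, p3))

  # duplicated composition gives a zero off-diagonal entry
  dup <- dplyr::bind_rows(profs,
                          dplyr::mutate(p1, sample_id = "p1_copy"))
  dm2 <- distance_matrix(dup, tree)
  expect_equal(dm2["p1", "p1_copy"], 0)

  expect_error(distance_matrix(p1, tree), "at least 2")
})

test_that("PCoA re-embeds distances and orders axes by eigenvalue", {
  # all-zero distances -> all-zero coordinates
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(res0 <- pcoa(z), "axes")
  expect_true(all(abs(as.matrix(res0$coordinates[, -1])) < 1e-10))

  # equilateral triangle: recovered pairwise distances all 1
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  res <- pcoa(d3, n_axes = 2)
  co <- as.matrix(res$coordinates[, -1])
  expect_equal(as.numeric(dist(co)), rep(1, 3), tolerance = 1e-9)

  # Euclidean input distances are recovered up to rigid motion
  pts <- withr::with_seed(4, matrix(rnorm(16), ncol = 2))
  dmat <- as.matrix(dist(pts))
  dimnames(dmat) <- list(paste0("x", 1:8), paste0("x", 1:8))
  res2 <- pcoa(dmat, n_axes = 2)
  rec <- as.matrix(dist(as.matrix(res2$coordinates[, -1])))
  expect_equal(unname(rec), unname(dmat), tolerance = 1e-8)
  expect_true(all(diff(res2$eigenvalues) <= 1e-9))
  expect_equal(sum(res2$proportion_explained), 1, tolerance = 1e-9)

  # agreement with classical scaling in stats::cmdscale
  ref <- stats::cmdscale(dmat, k = 2, eig = TRUE)
  expect_equal(abs(as.matrix(res2$coordinates[, -1])), abs(ref$points),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("tidy and glance summarise a PCoA result", {
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  res <- pcoa(d3)
  td <- tidy(res)
  expect_equal(nrow(td), 6L)
  expect_setequal(names(td), c("sample_id", "axis", "coordinate"))
  gl <- glance(res)
  expect_equal(gl$n_samples, 3L)
})

test_that("paired multinomial resamples cluster together in UniFrac space", {
  tree <- fix10()$tree
  tips <- tree$tip.label
  # four distinct underlying compositions, each dominated by another taxon
  base <- lapply(1:4, function(k) {
    p <- rep(0.02, 10); p[k] <- 1 - 0.02 * 9
    stats::setNames(p, tips)
  })
  profs <- dplyr::bind_rows(lapply(1:4, function(k) {
    dplyr::bind_rows(lapply(1:2, function(r) {
      cnt <- withr::with_seed(10 * k + r,
                              stats::rmultinom(1, 3000, base[[k]])[, 1])
      tibble::tibble(sample_id = sprintf("c%d_rep%d", k, r),
                     taxon_id = tips, fraction = cnt / 3000)
    }))
  }))
  dm <- distance_matrix(profs, tree)
  for (k in 1:4) {
    a <- sprintf("c%d_rep1", k); b <- sprintf("c%d_rep2", k)
    within <- dm[a, b]
    between <- dm[a, setdiff(colnames(dm), c(a, b))]
    expect_true(all(within < between))
  }
})
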