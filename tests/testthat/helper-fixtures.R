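# Shared fixtures and independent oracles for the test suite.

# Independent brute-force affine-gap local alignment DP (full matrices,
# plain R). Kept deliberately separate from the package's compiled kernel so
# the two routes can disagree. Gap of length L costs gap_open + (L-1)*gap_extend.
dp_local_score <- function(query, target, match = 2, mismatch = -4,
                           gap_open = -4, gap_extend = -2) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  t <- strsplit(target, "", fixed = TRUE)[[1]]
  m <- length(q); n <- length(t)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)  # gap in query (horizontal)
  F <- matrix(NEG, m + 1, n + 1)  # gap in target (vertical)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open, E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open, F[i - 1, j] + gap_extend)
      s <- if (q[i - 1] == t[j - 1] && q[i - 1] %in% c("A", "C", "G", "T"))
        match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# percent of differing positions between two equal-length strings
str_divergence <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca != cb)
}

# memoised standard fixtures (built once per test run)
.fixture_cache <- new.env(parent = emptyenv())

fix10 <- function() {
  if (is.null(.fixture_cache$fix10)) {
    .fixture_cache$fix10 <- make_reference_fixture(
      n_genera = 10, species_per_genus = 1, seed = 1)
  }
  .fixture_cache$fix10
}

fix_multi <- function() {
  if (is.null(.fixture_cache$fix_multi)) {
    .fixture_cache$fix_multi <- make_reference_fixture(
      n_genera = 4, species_per_genus = 3, seed = 2)
  }
  .fixture_cache$fix_multi
}

confusable <- function() {
  if (is.null(.fixture_cache$confusable)) {
    .fixture_cache$confusable <- make_v34_confusable_pair(seed = 1)
  }
  .fixture_cache$confusable
}

uniform10 <- function() {
  fx <- fix10()
  stats::setNames(rep(0.1, 10), fx$refdb$taxon_id)
}

# small simulated batch shared by several tests
sim_small <- function() {
  if (is.null(.fixture_cache$sim_small)) {
    .fixture_cache$sim_small <- simulate_reads(
      fix10()$refdb, uniform10(), n_reads = 60, region = "V1-9", seed = 11)
  }
  .fixture_cache$sim_small
}

make_read <- function(id, seq, q = 20L) {
  tibble::tibble(read_id = id, seq = seq,
                 qual = strrep(intToUtf8(q + 33L), nchar(seq)))
}
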