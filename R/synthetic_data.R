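# Fixture geometry: 1550-bp 16S-like references with the primer cores
# embedded at fixed canonical positions (1-based):
#   V1-9 fwd  11..30    V3-4 fwd  331..347
#   V3-4 rev (rc) 776..795    V1-9 rev (rc) 1526..1544
# giving a 1534-bp V1-9 product and a 465-bp V3-4 product, both inside their
# filter windows. Mutations during fixture generation avoid the primer spans
# so every species stays amplifiable (a deliberate unrealism, documented).
FIXTURE_LEN <- 1550L
FIXTURE_PRIMER_SPANS <- rbind(c(11L, 30L), c(331L, 347L),
                              c(776L, 795L), c(1526L, 1544L))
FIXTURE_V34_SPAN <- c(331L, 795L)

resolve_iupac <- function(core) {
  map <- Biostrings::IUPAC_CODE_MAP
  ch <- strsplit(core, "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(b) {
    opts <- strsplit(map[[b]], "", fixed = TRUE)[[1]]
    sample(opts, 1)
  }, character(1)), collapse = "")
}

fixture_backbone <- function() {
  base <- paste(sample(DNA_BASES, FIXTURE_LEN, replace = TRUE), collapse = "")
  v19 <- primer_set("V1-9"); v34 <- primer_set("V3-4")
  inserts <- list(resolve_iupac(v19$fwd_core), resolve_iupac(v34$fwd_core),
                  revcomp(resolve_iupac(v34$rev_core)),
                  revcomp(resolve_iupac(v19$rev_core)))
  ch <- strsplit(base, "", fixed = TRUE)[[1]]
  for (k in seq_len(nrow(FIXTURE_PRIMER_SPANS))) {
    span <- FIXTURE_PRIMER_SPANS[k, ]
    ch[span[1]:span[2]] <- strsplit(inserts[[k]], "", fixed = TRUE)[[1]]
  }
  paste(ch, collapse = "")
}

mutable_positions <- function(exclude_extra = NULL) {
  pos <- seq_len(FIXTURE_LEN)
  for (k in seq_len(nrow(FIXTURE_PRIMER_SPANS))) {
    span <- FIXTURE_PRIMER_SPANS[k, ]
    pos <- setdiff(pos, span[1]:span[2])
  }
  if (!is.null(exclude_extra)) pos <- setdiff(pos, exclude_extra)
  pos
}

mutate_sequence <- function(seq, n_mut, positions = mutable_positions()) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  sel <- sample(positions, min(n_mut, length(positions)))
  ch[sel] <- vapply(ch[sel], function(b) sample(setdiff(DNA_BASES, b), 1),
                    character(1))
  paste(ch, collapse = "")
}

#' Generate a reference panel, taxonomy and tree with controlled divergence
#'
#' Builds a desk-scale stand-in for a genome reference panel: one ancestral
#' 16S-like 1550-bp sequence, one genus branch per genus, and species within
#' a genus at `intra_genus_div` from the genus sequence. Genus-branch
#' lengths are chosen so that the realized pairwise divergence between
#' species of *different* genera is approximately `inter_genus_div`. Every
#' species embeds realizations of both the V1–9 and V3–4 primer cores at
#' canonical positions, so in-silico PCR always yields exactly one product
#' per region. The taxonomy is root -> genus -> species and the phylogeny's
#' branch lengths equal the divergence generated along each branch (so
#' root-to-tip depth is `inter_genus_div / 2`). Fully deterministic under a
#' fixed seed.
#'
#' @param n_genera Number of genera (default 10, a mock-community
#'   cardinality).
#' @param species_per_genus Species per genus (default 1).
#' @param seed Integer seed.
#' @param inter_genus_div Target pairwise divergence between genera
#'   (default 0.15).
#' @param intra_genus_div Divergence between congeneric species
#'   (default 0.02).
#' @return A list: `refdb` ([reference_db()] tibble), `taxonomy`
#'   (`taxonomy` object), `tree` ([ape::phylo] with species taxon ids as tip
#'   labels).
#' @export
make_reference_fixture <- function(n_genera = 10L, species_per_genus = 1L,
                                   seed = 1L, inter_genus_div = 0.15,
                                   intra_genus_div = 0.02) {
  if (inter_genus_div <= 0 || inter_genus_div >= 0.5 ||
      intra_genus_div <= 0 || intra_genus_div >= 0.5 ||
      inter_genus_div / 2 <= intra_genus_div) {
    abort("Need 0 < intra_genus_div < inter_genus_div / 2 < 0.25.")
  }
  withr::with_seed(derive_seed(seed, 1L), {
    ancestor <- fixture_backbone()
    # genus-branch mutation count discounts the two intra-genus branches so
    # that realized pairwise divergence between species of different genera
    # lands on inter_genus_div
    n_inter <- round((inter_genus_div / 2 - intra_genus_div) * FIXTURE_LEN)
    n_intra <- round(intra_genus_div * FIXTURE_LEN)
    nodes <- list(tibble(taxon_id = "root", parent_id = "root",
                         rank = "no rank", name = "root"))
    refs <- list()
    tip_labels <- list()
    for (g in seq_len(n_genera)) {
      gid <- sprintf("g%02d", g)
      gname <- sprintf("Genus_%02d", g)
      gseq <- mutate_sequence(ancestor, n_inter)
      nodes[[length(nodes) + 1L]] <- tibble(
        taxon_id = gid, parent_id = "root", rank = "genus", name = gname)
      stips <- character(species_per_genus)
      for (s in seq_len(species_per_genus)) {
        sid <- sprintf("s%02d_%d", g, s)
        sseq <- mutate_sequence(gseq, n_intra)
        nodes[[length(nodes) + 1L]] <- tibble(
          taxon_id = sid, parent_id = gid, rank = "species",
          name = sprintf("%s species_%d", gname, s))
        refs[[length(refs) + 1L]] <- tibble(
          ref_id = paste0("ref_", sid), seq = sseq, taxon_id = sid)
        stips[s] <- sprintf("%s:%g", sid, intra_genus_div)
      }
      tip_labels[[g]] <- sprintf("(%s):%g", paste(stips, collapse = ","),
                                 inter_genus_div / 2 - intra_genus_div)
    }
    newick <- sprintf("(%s):0;", paste(unlist(tip_labels), collapse = ","))
    tax <- taxonomy_tree(dplyr::bind_rows(nodes))
    list(refdb = reference_db(dplyr::bind_rows(refs), tax),
         taxonomy = tax,
         tree = parse_newick(newick))
  })
}

#' Generate a species pair indistinguishable over V3–4 but not over V1–9
#'
#' Two congeneric species whose sequences are identical across the whole
#' V3–4 amplicon span but diverge at >= 5% of the remaining V1–9 amplicon
#' positions — the construction behind the short-amplicon ambiguity: V3–4
#' reads tie between the two species (and are split 0.5/0.5 by the
#' classifier), while V1–9 reads resolve the true species.
#'
#' @param seed Integer seed.
#' @return A list like [make_reference_fixture()]: `refdb`, `taxonomy`,
#'   `tree` (tips `s01_1`, `s01_2`).
#' @export
make_v34_confusable_pair <- function(seed = 1L) {
  withr::with_seed(derive_seed(seed, 2L), {
    base <- fixture_backbone()
    # mutate only outside the V3-4 amplicon span (and outside primer cores)
    eligible <- mutable_positions(
      exclude_extra = FIXTURE_V34_SPAN[1]:FIXTURE_V34_SPAN[2])
    n_mut <- ceiling(0.08 * length(eligible))
    sp2 <- mutate_sequence(base, n_mut, positions = eligible)
    nodes <- tibble(
      taxon_id = c("root", "g01", "s01_1", "s01_2"),
      parent_id = c("root", "root", "g01", "g01"),
      rank = c("no rank", "genus", "species", "species"),
      name = c("root", "Genus_01", "Genus_01 species_1",
               "Genus_01 species_2"))
    tax <- taxonomy_tree(nodes)
    refs <- tibble(ref_id = c("ref_s01_1", "ref_s01_2"),
                   seq = c(base, sp2),
                   taxon_id = c("s01_1", "s01_2"))
    list(refdb = reference_db(refs, tax), taxonomy = tax,
         tree = parse_newick("((s01_1:0.05,s01_2:0.05):0.1):0;"))
  })
}

#' Nanopore-style error model
#'
#' Per-base substitution/insertion/deletion probabilities and the Phred
#' means used when emitting qualities (error positions get lower means than
#' match positions). Defaults (0.03, 0.02, 0.03, Q14, Q8) give ~8% total
#' error, a realistic figure for basecalled long amplicon reads.
#'
#' @param p_sub,p_ins,p_del Per-base event probabilities, each in \[0, 1),
#'   jointly < 0.5.
#' @param quality_mean_match,quality_mean_error Phred means for emitted
#'   qualities at match and error positions.
#' @return An `error_model` list.
#' @export
error_model <- function(p_sub = 0.03, p_ins = 0.02, p_del = 0.03,
                        quality_mean_match = 14, quality_mean_error = 8) {
  if (any(c(p_sub, p_ins, p_del) < 0) || any(c(p_sub, p_ins, p_del) >= 1) ||
      p_sub + p_ins + p_del >= 0.5) {
    abort("Error probabilities must be in [0, 1) and sum to < 0.5.")
  }
  structure(list(p_sub = p_sub, p_ins = p_ins, p_del = p_del,
                 quality_mean_match = quality_mean_match,
                 quality_mean_error = quality_mean_error),
            class = "error_model")
}

#' Simulate nanopore-style amplicon reads with ground truth
#'
#' Draws each read's source taxon from `abundances`, takes that species'
#' region amplicon (anchors included, as on real amplicon reads) as the
#' template, applies substitution/insertion/deletion errors base by base,
#' emits qualities with lower means at error positions, flips half the reads
#' to the reverse strand, and records per-read ground truth. Deterministic
#' under a fixed seed; the seed is sub-derived per stage so earlier fixture
#' stages are never perturbed.
#'
#' @param refdb A [reference_db()] tibble with fixture species.
#' @param abundances Tibble with `taxon_id` and `fraction` (summing to 1),
#'   or a named numeric vector.
#' @param n_reads Number of reads to simulate.
#' @param region `"V1-9"` or `"V3-4"`.
#' @param model An [error_model()].
#' @param seed Integer seed.
#' @return A list: `reads` (read tibble) and `truth` (tibble `read_id`,
#'   `taxon_id`, `n_sub`, `n_ins`, `n_del`, `strand`).
#' @export
simulate_reads <- function(refdb, abundances, n_reads = 3000L,
                           region = "V1-9", model = error_model(),
                           seed = 1L) {
  if (!is.data.frame(abundances)) {
    abundances <- tibble(taxon_id = names(abundances),
                         fraction = unname(abundances))
  }
  stopifnot(all(c("taxon_id", "fraction") %in% names(abundances)))
  if (abs(sum(abundances$fraction) - 1) > 1e-6) {
    abort("Abundances must sum to 1.")
  }
  missing <- setdiff(abundances$taxon_id, refdb$taxon_id)
  if (length(missing) > 0L) {
    abort(paste0("Taxa absent from the reference panel: ",
                 paste(missing, collapse = ", ")))
  }
  primers <- primer_set(region)
  amp_of <- vapply(abundances$taxon_id, function(tid) {
    ref <- refdb[refdb$taxon_id == tid, , drop = FALSE][1, ]
    prods <- in_silico_pcr(tibble(seq_id = ref$ref_id, seq = ref$seq),
                           primers, with_anchors = TRUE)
    if (nrow(prods) == 0L) {
      abort(sprintf("No %s amplicon for taxon '%s'.", region, tid))
    }
    prods$product_seq[1]
  }, character(1))

  withr::with_seed(derive_seed(seed, 3L), {
    src <- sample(abundances$taxon_id, n_reads, replace = TRUE,
                  prob = abundances$fraction)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    reads <- vector("list", n_reads)
    truth <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      tmpl <- strsplit(amp_of[[src[i]]], "", fixed = TRUE)[[1]]
      L <- length(tmpl)
      u <- stats::runif(L)
      is_del <- u < model$p_del
      is_sub <- !is_del & u < model$p_del + model$p_sub
      is_ins <- stats::runif(L) < model$p_ins
      out_base <- tmpl
      out_base[is_sub] <- vapply(tmpl[is_sub], function(b) {
        sample(setdiff(DNA_BASES, b), 1)
      }, character(1))
      base_err <- is_sub
      pieces <- as.list(out_base)
      err_flags <- as.list(base_err)
      ins_at <- which(is_ins)
      for (j in ins_at) {
        pieces[[j]] <- c(pieces[[j]], sample(DNA_BASES, 1))
        err_flags[[j]] <- c(err_flags[[j]], TRUE)
      }
      keep <- !is_del
      seq_chars <- unlist(pieces[keep], use.names = FALSE)
      errs <- unlist(err_flags[keep], use.names = FALSE)
      n_out <- length(seq_chars)
      mu <- ifelse(errs, model$quality_mean_error, model$quality_mean_match)
      q <- pmin(pmax(round(stats::rnorm(n_out, mu, 3)), 1L), 41L)
      sq <- paste(seq_chars, collapse = "")
      qs <- int_to_phred(as.integer(q))
      if (strand[i] == "-") {
        sq <- revcomp(sq)
        qs <- paste(rev(strsplit(qs, "", fixed = TRUE)[[1]]), collapse = "")
      }
      reads[[i]] <- tibble(read_id = sprintf("sim_%05d", i),
                           seq = sq, qual = qs)
      truth[[i]] <- tibble(read_id = sprintf("sim_%05d", i),
                           taxon_id = src[i],
                           n_sub = sum(is_sub), n_ins = sum(is_ins & keep),
                           n_del = sum(is_del), strand = strand[i])
    }
    list(reads = dplyr::bind_rows(reads), truth = dplyr::bind_rows(truth))
  })
}
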