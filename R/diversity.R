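#' Weighted UniFrac distance between two sample profiles
#'
#' Raw weighted UniFrac is the branch-length-weighted sum
#' `sum_b l_b * |P_A(b) - P_B(b)|`, where `P_X(b)` is the fraction of sample
#' X descending from branch `b`. The normalized variant divides by
#' `sum_j d_j * (p_Aj + p_Bj)` with `d_j` the root-to-leaf path length,
#' bounding the distance in \[0, 1\] and making values comparable across
#' trees.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths; profile taxa
#'   must be tip labels.
#' @param profile_a,profile_b Tibbles with `taxon_id` (or `taxon`) and
#'   `fraction`; bins not on the tree (e.g. `"unclassified"`, `"Others"`)
#'   must be removed or renormalised by the caller first — an unknown taxon
#'   is an error, not a silent drop.
#' @param normalized Use the normalized variant (default TRUE).
#' @return A non-negative number (in \[0, 1\] when normalized).
#' @export
weighted_unifrac <- function(tree, profile_a, profile_b, normalized = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  ma <- profile_masses(tree, profile_a)
  mb <- profile_masses(tree, profile_b)

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  acc_a <- numeric(nnode); acc_b <- numeric(nnode)
  acc_a[seq_len(ntip)] <- ma
  acc_b[seq_len(ntip)] <- mb
  tr <- ape::reorder.phylo(tree, "postorder")
  raw <- 0
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    raw <- raw + tr$edge.length[e] * abs(acc_a[child] - acc_b[child])
    acc_a[parent] <- acc_a[parent] + acc_a[child]
    acc_b[parent] <- acc_b[parent] + acc_b[child]
  }
  if (!normalized) return(raw)
  depth <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
  denom <- sum(depth * (ma + mb))
  if (denom == 0) return(0)
  raw / denom
}

# map a profile onto tip masses, renormalised to sum 1 over tree tips
profile_masses <- function(tree, profile) {
  key <- if ("taxon_id" %in% names(profile)) "taxon_id" else "taxon"
  taxa <- profile[[key]]
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0L) {
    abort(paste0("Profile taxa absent from the tree: ",
                 paste(missing, collapse = ", "),
                 ". Drop or remap non-leaf bins before computing UniFrac."))
  }
  m <- numeric(length(tree$tip.label))
  idx <- match(taxa, tree$tip.label)
  m[idx] <- profile$fraction
  s <- sum(m)
  if (s <= 0) abort("Profile has zero total mass on the tree.")
  m / s
}

#' Pairwise weighted UniFrac distance matrix
#'
#' @param profiles Long tibble with columns `sample_id`, `taxon_id` (or
#'   `taxon`) and `fraction`.
#' @param tree A rooted [ape::phylo] tree.
#' @param normalized Use the normalized UniFrac variant (default TRUE).
#' @return A symmetric labelled matrix with zero diagonal.
#' @export
distance_matrix <- function(profiles, tree, normalized = TRUE) {
  stopifnot(is.data.frame(profiles), "sample_id" %in% names(profiles))
  ids <- unique(profiles$sample_id)
  if (length(ids) < 2L) abort("Need at least 2 samples for a distance matrix.")
  split_profiles <- split(profiles, profiles$sample_id)[ids]
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- weighted_unifrac(
        tree, split_profiles[[i]], split_profiles[[j]], normalized = normalized)
    }
  }
  attr(d, "metric") <- if (normalized) "weighted UniFrac (normalized)" else
    "weighted UniFrac (raw)"
  d
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centres the squared distance matrix (`B = -J D^2 J / 2`),
#' eigendecomposes it, and scales eigenvectors by the square root of their
#' (non-negative) eigenvalues. Negative eigenvalues — a signature of
#' non-Euclidean distances — are reported but clamped to zero for coordinate
#' scaling and excluded from the proportion-explained denominator.
#'
#' @param dm Symmetric distance matrix with sample labels.
#' @param n_axes Number of axes to return (default 2); more axes than the
#'   matrix supports triggers a warning and returns the available ones.
#' @return A `vagitax_pcoa` object: `coordinates` (tibble, `sample_id` +
#'   `axis1..axisK`), `eigenvalues` (all, non-increasing) and
#'   `proportion_explained` per returned axis.
#' @export
pcoa <- function(dm, n_axes = 2L) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (max(abs(dm - t(dm))) > 1e-8) abort("Distance matrix must be symmetric.")
  n <- nrow(dm)
  labels <- rownames(dm) %||% paste0("sample", seq_len(n))
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (dm^2) %*% J
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE)
  eig <- ev$values
  pos <- pmax(eig, 0)
  n_avail <- if (max(pos) > 0) sum(pos > max(pos) * 1e-12) else 0L
  if (n_axes > max(n_avail, 1L)) {
    warn(sprintf("Only %d positive axes available (%d requested).",
                 n_avail, n_axes))
  }
  n_axes <- min(n_axes, max(n_avail, 1L))
  coords <- ev$vectors[, seq_len(n_axes), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(n_axes)]), n_axes)
  colnames(coords) <- paste0("axis", seq_len(n_axes))
  denom <- sum(pos)
  prop <- if (denom > 0) pos[seq_len(n_axes)] / denom else rep(0, n_axes)
  structure(list(
    coordinates = dplyr::bind_cols(tibble(sample_id = labels),
                                   as_tibble(coords)),
    eigenvalues = eig,
    proportion_explained = prop
  ), class = "vagitax_pcoa")
}

#' @export
print.vagitax_pcoa <- function(x, ...) {
  cat(sprintf("<pcoa> %d samples, %d axes; proportion explained: %s\n",
              nrow(x$coordinates), length(x$proportion_explained),
              paste(sprintf("%.1f%%", 100 * x$proportion_explained),
                    collapse = ", ")))
  invisible(x)
}

#' Tidy PCoA coordinates
#'
#' @param x A `vagitax_pcoa` object.
#' @param ... Unused.
#' @return Long tibble: `sample_id`, `axis`, `coordinate`.
#' @export
tidy.vagitax_pcoa <- function(x, ...) {
  tidyr::pivot_longer(x$coordinates, -"sample_id",
                      names_to = "axis", values_to = "coordinate")
}

#' One-row PCoA summary
#'
#' @param x A `vagitax_pcoa` object.
#' @param ... Unused.
#' @return Tibble with sample/axis counts, the leading proportions explained
#'   and the count of negative eigenvalues.
#' @export
glance.vagitax_pcoa <- function(x, ...) {
  tibble(n_samples = nrow(x$coordinates),
         n_axes = length(x$proportion_explained),
         prop_axis1 = x$proportion_explained[1],
         prop_axis2 = if (length(x$proportion_explained) >= 2)
           x$proportion_explained[2] else NA_real_,
         n_negative_eigenvalues = sum(x$eigenvalues < 0))
}

#' Write a labelled distance matrix as TSV
#'
#' @param dm Distance matrix from [distance_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  utils::write.table(dm, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Write PCoA coordinates as TSV
#'
#' @param res A `vagitax_pcoa` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pcoa <- function(res, path) {
  hdr <- paste0("# eigenvalues: ",
                paste(signif(res$eigenvalues, 6), collapse = "\t"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(res$coordinates), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
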