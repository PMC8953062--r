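#' Construct a taxonomy tree from a node table
#'
#' Validates an NCBI-style node table (every parent present, one self-parented
#' root, no cycles, no duplicate ids) and returns a `taxonomy` object used by
#' lineage/LCA/roll-up operations and the classifier.
#'
#' @param nodes Tibble with columns `taxon_id`, `parent_id`, `rank`, `name`
#'   (all character).
#' @return An object of class `taxonomy`: the node tibble plus the detected
#'   `root_id`.
#' @examples
#' tax <- taxonomy_tree(tibble::tibble(
#'   taxon_id = c("1", "g1", "s1"),
#'   parent_id = c("1", "1", "g1"),
#'   rank = c("no rank", "genus", "species"),
#'   name = c("root", "Genus one", "Genus one species one")))
#' lineage(tax, "s1")
#' @export
taxonomy_tree <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("taxon_id", "parent_id", "rank", "name") %in% names(nodes)))
  nodes <- as_tibble(nodes)
  nodes$taxon_id <- as.character(nodes$taxon_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  if (anyDuplicated(nodes$taxon_id)) {
    abort(sprintf("Duplicate taxon_id: '%s'.",
                  nodes$taxon_id[duplicated(nodes$taxon_id)][1]))
  }
  orphans <- setdiff(nodes$parent_id, nodes$taxon_id)
  if (length(orphans) > 0L) {
    abort(paste0("Orphan parent_id(s) not present as nodes: ",
                 paste(orphans, collapse = ", ")))
  }
  root <- nodes$taxon_id[nodes$taxon_id == nodes$parent_id]
  if (length(root) != 1L) {
    abort(sprintf("Expected exactly one self-parented root, found %d.",
                  length(root)))
  }
  parent <- stats::setNames(nodes$parent_id, nodes$taxon_id)
  # cycle / reachability check: every node must reach the root
  for (id in nodes$taxon_id) {
    seen <- character(0)
    cur <- id
    while (cur != root) {
      if (cur %in% seen) abort(sprintf("Cycle in taxonomy at '%s'.", cur))
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  structure(list(nodes = nodes, root_id = root,
                 parent = parent,
                 rank = stats::setNames(nodes$rank, nodes$taxon_id),
                 name = stats::setNames(nodes$name, nodes$taxon_id)),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %d nodes, root '%s'; ranks: %s\n",
              nrow(x$nodes), x$root_id,
              paste(sort(unique(x$nodes$rank)), collapse = ", ")))
  invisible(x)
}

#' @export
as_tibble.taxonomy <- function(x, ...) x$nodes

check_taxonomy <- function(tree) {
  if (!inherits(tree, "taxonomy")) abort("`tree` must be a taxonomy object.")
  invisible(tree)
}

#' Root-to-node lineage
#'
#' @param tree A `taxonomy` object.
#' @param id A taxon id present in the tree.
#' @return Tibble with one row per lineage step, root first: `taxon_id`,
#'   `rank`, `name`.
#' @export
lineage <- function(tree, id) {
  check_taxonomy(tree)
  id <- as.character(id)
  if (!id %in% names(tree$parent)) abort(sprintf("Unknown taxon id '%s'.", id))
  path <- id
  cur <- id
  while (cur != tree$root_id) {
    cur <- tree$parent[[cur]]
    path <- c(cur, path)
  }
  tibble(taxon_id = path,
         rank = unname(tree$rank[path]),
         name = unname(tree$name[path]))
}

#' Lowest common ancestor of a set of taxa
#'
#' @param tree A `taxonomy` object.
#' @param ids Non-empty character vector of taxon ids.
#' @return The taxon id of the deepest node ancestral to every input id (an
#'   id is its own ancestor, so `lca(tree, x)` is `x`).
#' @export
lca <- function(tree, ids) {
  check_taxonomy(tree)
  ids <- unique(as.character(ids))
  if (length(ids) == 0L) abort("lca of an empty taxon set is undefined.")
  paths <- lapply(ids, function(id) lineage(tree, id)$taxon_id)
  common <- Reduce(function(a, b) {
    n <- min(length(a), length(b))
    k <- which(a[seq_len(n)] != b[seq_len(n)])
    if (length(k) == 0L) a[seq_len(n)] else a[seq_len(k[1] - 1L)]
  }, paths)
  common[length(common)]
}

#' Roll fractional taxon counts up to a rank
#'
#' Each count is re-assigned to the nearest ancestor (including the taxon
#' itself) carrying the requested rank label; "no rank" nodes are walked
#' through transparently. Taxa with no ancestor at that rank accumulate under
#' the reserved id `"unranked"`. Fractional counts from tie-splitting pass
#' through unchanged, so total mass is conserved exactly.
#'
#' @param counts Tibble with columns `taxon_id` and `count` (fractional
#'   counts allowed).
#' @param tree A `taxonomy` object.
#' @param rank Rank label to roll up to (e.g. `"genus"`, `"species"`).
#' @return Tibble with columns `taxon_id`, `name`, `count`, one row per
#'   taxon at the requested rank (plus an `"unranked"` row if needed).
#' @export
rollup <- function(counts, tree, rank) {
  check_taxonomy(tree)
  stopifnot(is.data.frame(counts),
            all(c("taxon_id", "count") %in% names(counts)))
  if (!rank %in% tree$nodes$rank) {
    abort(sprintf("Rank '%s' does not occur in this taxonomy.", rank))
  }
  target_of <- function(id) {
    cur <- as.character(id)
    if (!cur %in% names(tree$parent)) {
      abort(sprintf("Unknown taxon id '%s' in counts.", cur))
    }
    repeat {
      if (tree$rank[[cur]] == rank) return(cur)
      if (cur == tree$root_id) return("unranked")
      cur <- tree$parent[[cur]]
    }
  }
  mapped <- unname(vapply(counts$taxon_id, target_of, character(1)))
  out <- tibble(taxon_id = mapped, count = counts$count) |>
    dplyr::group_by(.data$taxon_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  out$name <- ifelse(out$taxon_id == "unranked", "unranked",
                     unname(tree$name[out$taxon_id]))
  out[, c("taxon_id", "name", "count")]
}

#' Export lineages of a set of taxa as a tibble (TSV-ready)
#'
#' @param tree A `taxonomy` object.
#' @param ids Taxon ids; defaults to all nodes.
#' @return Tibble with `taxon_id`, `rank`, `name`, `parent_chain`
#'   (root-to-parent names joined by `";"`).
#' @export
lineage_table <- function(tree, ids = NULL) {
  check_taxonomy(tree)
  ids <- ids %||% tree$nodes$taxon_id
  rows <- lapply(ids, function(id) {
    lin <- lineage(tree, id)
    tibble(taxon_id = id,
           rank = tree$rank[[id]],
           name = tree$name[[id]],
           parent_chain = paste(lin$name[-nrow(lin)], collapse = ";"))
  })
  dplyr::bind_rows(rows)
}
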