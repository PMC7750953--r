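# Community structure over the bipartite miRNA/tissue x gene-set association
# graph: binarise signed enrichment results at strict FDR/ES thresholds, then
# agglomerative (fast-greedy, Clauset-Newman-Moore) modularity maximisation
# over the graph whose two node kinds are miRNA/tissue profiles and gene sets.

#' Binarise enrichment results into an association matrix
#'
#' A miRNA/tissue profile is associated with a gene set when the enrichment is
#' highly significant and strongly positive: `FDR < fdr_thresh` and
#' `ES > es_thresh`, both strict.
#'
#' @param results Output of [target_enrichment()] (needs `mirna`, `tissue`,
#'   `gene_set`, `ES`, `FDR`).
#' @param fdr_thresh Strict FDR cut-off; default 0.001.
#' @param es_thresh Strict ES cut-off; default 0.65.
#' @return A tibble with columns `profile` (`"<mirna>|<tissue>"`), `gene_set`
#'   and binary `associated`.
#' @export
binarize <- function(results, fdr_thresh = 0.001, es_thresh = 0.65) {
  stopifnot(all(c("mirna", "tissue", "gene_set", "ES", "FDR") %in% names(results)))
  results |>
    mutate(profile = paste(.data$mirna, .data$tissue, sep = "|"),
           associated = as.integer(.data$FDR < fdr_thresh & .data$ES > es_thresh)) |>
    select("profile", "gene_set", "associated")
}

# internal: association tibble -> igraph bipartite graph over the 1-cells,
# nodes added in lexicographic order so fast-greedy merges are deterministic
assoc_to_graph <- function(assoc) {
  ones <- filter(assoc, .data$associated == 1)
  if (nrow(ones) == 0) abort("association matrix has no edges")
  profiles <- sort(unique(ones$profile))
  sets <- sort(unique(ones$gene_set))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(profiles), name = profiles, kind = "profile")
  g <- igraph::add_vertices(g, length(sets), name = sets, kind = "gene_set")
  edges <- rbind(ones$profile, ones$gene_set)
  igraph::add_edges(g, as.vector(edges))
}

#' Detect communities in the association graph
#'
#' Builds the bipartite graph with one edge per association (all-zero rows and
#' columns drop out by construction) and clusters its nodes — miRNA/tissue
#' profiles and gene sets together — by fast-greedy modularity maximisation.
#'
#' @param assoc Output of [binarize()].
#' @param seed Unused by the deterministic merge order; retained for API
#'   symmetry with the stochastic operations.
#' @return An object of class `puma_communities`: membership tibble
#'   (`node`, `kind`, `community`) plus the partition modularity `Q`.
#' @export
detect_communities <- function(assoc, seed = 1) {
  g <- assoc_to_graph(assoc)
  cl <- igraph::cluster_fast_greedy(g)
  # cut the merge dendrogram at its maximum-modularity step ourselves: the
  # stored membership can miss a tail merge that still improves Q
  membership <- igraph::cut_at(cl, steps = which.max(cl$modularity) - 1L)
  structure(list(
    membership = tibble(node = igraph::V(g)$name,
                        kind = igraph::V(g)$kind,
                        community = as.integer(membership)),
    modularity = igraph::modularity(g, membership),
    graph = g
  ), class = "puma_communities")
}

#' @export
print.puma_communities <- function(x, ...) {
  cat(sprintf("<puma_communities> %d nodes in %d communities, Q = %.4f\n",
              nrow(x$membership), length(unique(x$membership$community)),
              x$modularity))
  invisible(x)
}

#' @export
tidy.puma_communities <- function(x, ...) x$membership

#' @export
glance.puma_communities <- function(x, ...) {
  tibble(n_nodes = nrow(x$membership),
         n_communities = length(unique(x$membership$community)),
         modularity = x$modularity)
}

#' Jaccard index between two sets
#'
#' @param a,b Vectors treated as sets.
#' @return `|a intersect b| / |a union b|`; `NA` if both sets are empty.
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Compare community partitions from two collections
#'
#' Restricts each partition to communities containing at least
#' `min_gene_sets` gene-set nodes, then reports the Jaccard index over node
#' sets for every community pair, flagging each first-partition community's
#' best match.
#'
#' @param a,b `puma_communities` objects over a shared node universe.
#' @param min_gene_sets Minimum number of gene-set nodes for a community to be
#'   compared; default 5.
#' @return Tibble with `community_a`, `community_b`, `jaccard`, `best_match`.
#' @export
compare_partitions <- function(a, b, min_gene_sets = 5) {
  keep_comms <- function(p) {
    counts <- p$membership |>
      filter(.data$kind == "gene_set") |>
      dplyr::count(.data$community)
    keep <- counts$community[counts$n >= min_gene_sets]
    split(p$membership$node[p$membership$community %in% keep],
          p$membership$community[p$membership$community %in% keep])
  }
  ca <- keep_comms(a)
  cb <- keep_comms(b)
  if (length(ca) == 0 || length(cb) == 0) {
    return(tibble(community_a = integer(), community_b = integer(),
                  jaccard = double(), best_match = logical()))
  }
  grid <- tidyr::expand_grid(community_a = names(ca), community_b = names(cb))
  grid$jaccard <- purrr::map2_dbl(grid$community_a, grid$community_b,
                                  function(i, j) jaccard(ca[[i]], cb[[j]]))
  grid |>
    group_by(.data$community_a) |>
    mutate(best_match = .data$jaccard == max(.data$jaccard)) |>
    ungroup() |>
    mutate(community_a = as.integer(.data$community_a),
           community_b = as.integer(.data$community_b))
}

#' Plot community sizes by node kind
#'
#' @param object A `puma_communities` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.puma_communities <- function(object, ...) {
  ggplot2::ggplot(object$membership,
                  ggplot2::aes(x = factor(.data$community), fill = .data$kind)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "community", y = "nodes", fill = NULL,
                  title = sprintf("Q = %.3f", object$modularity)) +
    ggplot2::theme_minimal()
}
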