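#' Collect per-tissue network fits into one long edge table
#'
#' @param fits Named list of `puma_fit` objects (names are tissue labels), all
#'   fitted on the same regulator/gene universe.
#' @return A tibble with columns `regulator`, `gene`, `tissue`, `weight`.
#' @export
collect_networks <- function(fits) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    abort("collect_networks: fits must be a named list (names = tissue labels)")
  }
  ref <- fits[[1]]
  for (f in fits) {
    if (!identical(f$regulators, ref$regulators) || !identical(f$genes, ref$genes)) {
      abort("collect_networks: all fits must share the regulator/gene universe")
    }
  }
  purrr::imap(fits, function(f, tis) {
    out <- matrix_to_edges(f$weights)
    out$tissue <- tis
    out
  }) |>
    bind_rows() |>
    select("regulator", "gene", "tissue", "weight")
}

# internal: type-7 (linear interpolation) quartiles -> IQR, the pinned
# convention for every specificity score in the package
iqr7 <- function(x) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Tissue-specificity scores for network edges
#'
#' For each edge and tissue, the deviation of the edge weight from its median
#' across all tissues, in units of the cross-tissue interquartile range:
#' \deqn{s_{ij}(t) = \frac{w_{ij}(t) - \mathrm{med}(w_{ij})}{\mathrm{IQR}(w_{ij})}}
#' An edge whose weight is identical in every tissue has IQR 0 and gets score
#' 0: by definition it is not specific to any tissue.  Quartiles use linear
#' interpolation between order statistics (R's default type-7 convention).
#'
#' @param networks Long edge table with columns `regulator`, `gene`, `tissue`,
#'   `weight` (see [collect_networks()]).  At least 3 tissues, and every edge
#'   present in every tissue.
#' @return The input tibble with a `score` column added.
#' @export
edge_specificity <- function(networks) {
  stopifnot(all(c("regulator", "gene", "tissue", "weight") %in% names(networks)))
  tissues <- unique(networks$tissue)
  if (length(tissues) < 3) {
    abort("edge_specificity: at least 3 tissues are required for median/IQR scores")
  }
  # dense reshape: edges x tissues
  wide <- networks |>
    tidyr::pivot_wider(id_cols = c("regulator", "gene"),
                       names_from = "tissue", values_from = "weight")
  Wmat <- as.matrix(wide[, tissues, drop = FALSE])
  if (anyNA(Wmat)) abort("edge_specificity: networks differ in their edge sets across tissues")
  med <- apply(Wmat, 1, median)
  iqr <- apply(Wmat, 1, iqr7)
  S <- (Wmat - med) / ifelse(iqr == 0, Inf, iqr)  # IQR 0 -> score 0
  scores <- wide[, c("regulator", "gene")]
  scores <- bind_rows(purrr::map(seq_along(tissues), function(k) {
    out <- scores
    out$tissue <- tissues[k]
    out$score <- unname(S[, k])
    out
  }))
  networks |>
    left_join(scores, by = c("regulator", "gene", "tissue"))
}

#' Edge multiplicity across tissues
#'
#' The number of tissues an edge is specific to: the count of tissues in which
#' its specificity score strictly exceeds the threshold,
#' \eqn{m_{ij} = \sum_t [s_{ij}(t) > 2]} at the default threshold.
#'
#' @param scores Output of [edge_specificity()].
#' @param threshold Specificity cut-off; default 2.
#' @return Tibble with columns `regulator`, `gene`, `multiplicity`.
#' @export
multiplicity <- function(scores, threshold = 2) {
  stopifnot("score" %in% names(scores))
  scores |>
    group_by(.data$regulator, .data$gene) |>
    summarise(multiplicity = sum(.data$score > threshold), .groups = "drop")
}

#' Tissue-specificity of miRNA expression
#'
#' Compares the median expression of each miRNA gene within a tissue to the
#' median and IQR of its expression pooled over the samples of all tissues:
#' \deqn{s_p(t) = \frac{\mathrm{med}(e_p(t)) - \mathrm{med}(e_p(\mathrm{all}))}{\mathrm{IQR}(e_p(\mathrm{all}))}}
#' A pooled IQR of 0 yields score 0.
#'
#' @param expression_by_tissue Named list of expression inputs (one per
#'   tissue; see [compute_coexpression()] for accepted forms).
#' @param mirna Character vector of miRNA gene IDs; each must be present in
#'   every tissue's expression matrix.
#' @return Tibble with columns `mirna`, `tissue`, `score`.
#' @export
expression_specificity <- function(expression_by_tissue, mirna) {
  if (is.null(names(expression_by_tissue))) {
    abort("expression_specificity: expression_by_tissue must be a named list")
  }
  mats <- purrr::map(expression_by_tissue, as_expression_matrix)
  for (tis in names(mats)) {
    missing <- setdiff(mirna, rownames(mats[[tis]]))
    if (length(missing)) {
      abort(paste0("expression_specificity: miRNA(s) absent from tissue '", tis,
                   "': ", paste(missing, collapse = ", ")))
    }
  }
  purrr::map(mirna, function(p) {
    pooled <- unlist(purrr::map(mats, function(M) M[p, ]), use.names = FALSE)
    med_all <- median(pooled)
    iqr_all <- iqr7(pooled)
    tibble(
      mirna = p,
      tissue = names(mats),
      score = unname(purrr::map_dbl(mats, function(M) {
        if (iqr_all == 0) 0 else (median(M[p, ]) - med_all) / iqr_all
      }))
    )
  }) |> bind_rows()
}

#' Classify edges by their support in two priors
#'
#' Edges present (non-zero) in both priors are `canonical`, absent from both
#' are `non-canonical`, and present in exactly one are `different`
#' (inconsistent between the prediction resources).
#'
#' @param prior_a,prior_b Edge-list data frames (`regulator`, `gene`,
#'   `weight`) over the same regulator/gene universe.
#' @return Tibble with one row per regulator-gene pair of the full grid:
#'   `regulator`, `gene`, `class`.
#' @export
classify_edges <- function(prior_a, prior_b) {
  A <- edges_to_matrix(prior_a)
  B <- edges_to_matrix(prior_b,
                       regulators = unique(as.character(prior_b$regulator)),
                       genes = unique(as.character(prior_b$gene)))
  if (!setequal(rownames(A), rownames(B)) || !setequal(colnames(A), colnames(B))) {
    abort("classify_edges: priors are defined on different regulator/gene universes")
  }
  B <- B[rownames(A), colnames(A), drop = FALSE]
  cls <- matrix("different", nrow(A), ncol(A))
  cls[A != 0 & B != 0] <- "canonical"
  cls[A == 0 & B == 0] <- "non-canonical"
  out <- matrix_to_edges(A, value = "weight_a")
  out$class <- as.vector(cls)
  select(out, "regulator", "gene", "class")
}

#' Overlap between two prior networks
#'
#' Jaccard index over the non-zero edge sets, and Pearson correlation over the
#' full vectorised weight grids.
#'
#' @inheritParams classify_edges
#' @return One-row tibble: `jaccard`, `pearson`.
#' @export
prior_overlap <- function(prior_a, prior_b) {
  A <- edges_to_matrix(prior_a)
  B <- edges_to_matrix(prior_b,
                       regulators = unique(as.character(prior_b$regulator)),
                       genes = unique(as.character(prior_b$gene)))
  if (!setequal(rownames(A), rownames(B)) || !setequal(colnames(A), colnames(B))) {
    abort("prior_overlap: priors are defined on different regulator/gene universes")
  }
  B <- B[rownames(A), colnames(A), drop = FALSE]
  inter <- sum(A != 0 & B != 0)
  uni <- sum(A != 0 | B != 0)
  r <- if (sd(as.vector(A)) == 0 || sd(as.vector(B)) == 0) NA_real_ else
    cor(as.vector(A), as.vector(B))
  tibble(jaccard = if (uni == 0) NA_real_ else inter / uni, pearson = r)
}

#' Compare tissue-specificity scores between two network collections
#'
#' Pearson correlation of edge specificity scores between two collections
#' (e.g. networks built on two different target-prediction priors), per tissue
#' and optionally stratified by edge class.
#'
#' @param scores_a,scores_b Outputs of [edge_specificity()] over the same
#'   edges and tissues.
#' @param classes Optional output of [classify_edges()]; when given,
#'   correlations are additionally reported per (tissue, class).
#' @return Tibble with columns `tissue`, `class` (`"all"` when unstratified),
#'   `r`, `n_edges`.  A zero-variance score vector yields `r = NA`.
#' @export
compare_collections <- function(scores_a, scores_b, classes = NULL) {
  joined <- inner_join(
    select(scores_a, "regulator", "gene", "tissue", score_a = "score"),
    select(scores_b, "regulator", "gene", "tissue", score_b = "score"),
    by = c("regulator", "gene", "tissue"))
  if (nrow(joined) == 0) abort("compare_collections: no shared (edge, tissue) pairs")
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }
  all_cls <- joined |>
    group_by(.data$tissue) |>
    summarise(class = "all", r = safe_cor(.data$score_a, .data$score_b),
              n_edges = n(), .groups = "drop")
  if (is.null(classes)) return(all_cls)
  by_cls <- joined |>
    inner_join(classes, by = c("regulator", "gene")) |>
    group_by(.data$tissue, .data$class) |>
    summarise(r = safe_cor(.data$score_a, .data$score_b),
              n_edges = n(), .groups = "drop")
  bind_rows(all_cls, by_cls) |> arrange(.data$tissue)
}

#' Plot per-tissue specificity-score distributions
#'
#' @param scores Output of [edge_specificity()].
#' @param threshold Specificity cut-off drawn as a reference line; default 2.
#' @return A ggplot object.
#' @export
plot_specificity <- function(scores, threshold = 2) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$tissue, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed", colour = "red") +
    ggplot2::labs(y = "tissue-specificity score", x = NULL) +
    ggplot2::theme_minimal()
}
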