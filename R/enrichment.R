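# Pre-ranked GSEA on tissue-specific targeting profiles.
#
# The enrichment statistic is the classic weighted Kolmogorov-Smirnov running
# sum (weight exponent 1): walking down the ranked profile, the sum increases
# by |score|/sum(|score| in set) at members and decreases by 1/(n - k)
# elsewhere; ES is the maximum deviation from zero, signed.  The null is built
# from seeded random gene-label permutations; FDR follows the standard
# normalised-ES (NES) pooling procedure, with Benjamini-Hochberg on the
# permutation p-values available as a fallback.

# internal: ES from hit positions in the ranked list.  The running sum only
# attains its extremes at a hit or immediately before one, so O(k) suffices.
es_from_positions <- function(absw, pos, n) {
  k <- length(pos)
  w <- absw[pos]
  tot <- sum(w)
  inc <- if (tot > 0) w / tot else rep(1 / k, k)   # all-zero scores: flat walk
  miss_inc <- if (n > k) 1 / (n - k) else 0
  cumhit <- cumsum(inc)
  miss_cnt <- pos - seq_len(k)                     # misses seen before hit j
  s_at <- cumhit - miss_cnt * miss_inc
  s_before <- c(0, cumhit[-k]) - miss_cnt * miss_inc
  maxdev <- max(s_at)
  mindev <- min(0, s_before)
  if (maxdev >= -mindev) maxdev else mindev
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path Path to a GMT file (gzip accepted).
#' @return A named list of character vectors; descriptions are kept in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    abort(sprintf("read_gmt: line %d has fewer than 3 fields", bad[1]))
  }
  sets <- purrr::map(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- purrr::map_chr(fields, 1)
  if (anyDuplicated(names(sets))) {
    abort("read_gmt: duplicate gene-set names")
  }
  attr(sets, "description") <- purrr::map_chr(fields, 2)
  sets
}

#' Pre-ranked gene set enrichment on one targeting profile
#'
#' Ranks the profile (ties broken by a seeded random permutation), computes
#' the weighted KS enrichment score for every gene set and a permutation null
#' by random gene-label permutations, and derives permutation p-values, NES
#' and FDR.  The signed score is \eqn{-\log_{10}(\mathrm{FDR})\cdot
#' \mathrm{sign}(ES)}, with FDR floored at `1/(nperm + 1)` (the resolution of
#' the permutation null) before taking the log.
#'
#' @param profile Data frame with columns `gene` and `score` (one score per
#'   gene; e.g. one miRNA's tissue-specificity scores over all genes).
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param nperm Number of gene-label permutations; default 1000.
#' @param seed Seed for tie-breaking and the permutation null.
#' @param min_size,max_size Bounds on gene-set size after restriction to the
#'   profiled genes; defaults 15 and 500.
#' @param fdr_method `"gsea"` (NES pooling, default) or `"bh"`
#'   (Benjamini-Hochberg on the permutation p-values).
#' @return A tibble with one row per retained gene set: `gene_set`, `size`,
#'   `ES`, `NES`, `p_perm`, `FDR`, `signed_score`.
#' @export
preranked_gsea <- function(profile, gene_sets, nperm = 1000, seed = 1,
                           min_size = 15, max_size = 500,
                           fdr_method = c("gsea", "bh")) {
  fdr_method <- match.arg(fdr_method)
  stopifnot(all(c("gene", "score") %in% names(profile)))
  genes <- as.character(profile$gene)
  score <- as.numeric(profile$score)
  if (anyDuplicated(genes)) abort("preranked_gsea: duplicate genes in profile")
  if (any(!is.finite(score))) abort("preranked_gsea: profile scores must be finite")
  n <- length(genes)

  sets <- purrr::map(gene_sets, function(s) intersect(s, genes))
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  sets <- sets[keep]
  if (length(sets) == 0) {
    warn("preranked_gsea: no gene set within size bounds after filtering")
    return(tibble(gene_set = character(), size = integer(), ES = double(),
                  NES = double(), p_perm = double(), FDR = double(),
                  signed_score = double()))
  }

  res <- with_seed(seed, {
    tie_break <- sample.int(n)                       # D-style seeded tie-break
    ord <- order(-score, tie_break)
    ranked_genes <- genes[ord]
    absw <- abs(score[ord])
    rank_of <- match(seq_len(n), ord)                # gene index -> rank

    pos_list <- purrr::map(sets, function(s) {
      sort(rank_of[match(s, genes)])
    })
    es_obs <- purrr::map_dbl(pos_list, es_from_positions, absw = absw, n = n)

    null_es <- matrix(NA_real_, length(sets), nperm)
    for (b in seq_len(nperm)) {
      perm <- sample.int(n)                          # gene-label permutation
      for (j in seq_along(pos_list)) {
        null_es[j, b] <- es_from_positions(absw, sort(perm[pos_list[[j]]]), n)
      }
    }
    list(es = es_obs, null = null_es)
  })
  es <- unname(res$es)
  null_es <- res$null

  p_perm <- purrr::map_dbl(seq_along(es), function(j) {
    nu <- null_es[j, ]
    if (es[j] >= 0) (1 + sum(nu >= es[j])) / (1 + sum(nu >= 0))
    else (1 + sum(nu <= es[j])) / (1 + sum(nu < 0))
  })

  # NES: normalise by the mean magnitude of same-sign null ES, per set
  pos_mean <- purrr::map_dbl(seq_along(es), function(j) {
    v <- null_es[j, ][null_es[j, ] >= 0]; if (length(v)) mean(v) else NA_real_
  })
  neg_mean <- purrr::map_dbl(seq_along(es), function(j) {
    v <- null_es[j, ][null_es[j, ] < 0]; if (length(v)) mean(abs(v)) else NA_real_
  })
  norm_one <- function(e, pm, nm) {
    if (e >= 0) { if (is.na(pm) || pm == 0) 0 else e / pm }
    else { if (is.na(nm) || nm == 0) 0 else e / nm }
  }
  nes <- purrr::map_dbl(seq_along(es), function(j) norm_one(es[j], pos_mean[j], neg_mean[j]))

  if (fdr_method == "bh") {
    fdr <- p.adjust(p_perm, method = "BH")
  } else {
    null_nes <- null_es
    for (j in seq_along(es)) {
      nu <- null_es[j, ]
      null_nes[j, ] <- ifelse(
        nu >= 0,
        if (is.na(pos_mean[j]) || pos_mean[j] == 0) 0 else nu / pos_mean[j],
        if (is.na(neg_mean[j]) || neg_mean[j] == 0) 0 else nu / neg_mean[j])
    }
    pool <- as.vector(null_nes)
    pool_pos <- pool[pool >= 0]
    pool_neg <- pool[pool < 0]
    obs_pos <- nes[nes >= 0]
    obs_neg <- nes[nes < 0]
    fdr <- purrr::map_dbl(nes, function(v) {
      if (v >= 0) {
        num <- if (length(pool_pos)) mean(pool_pos >= v) else 0
        den <- if (length(obs_pos)) mean(obs_pos >= v) else 1
      } else {
        num <- if (length(pool_neg)) mean(pool_neg <= v) else 0
        den <- if (length(obs_neg)) mean(obs_neg <= v) else 1
      }
      if (den == 0) 1 else min(1, num / den)
    })
  }

  floor_ <- 1 / (nperm + 1)
  tibble(
    gene_set = names(sets),
    size = lengths(sets),
    ES = es,
    NES = nes,
    p_perm = p_perm,
    FDR = fdr,
    signed_score = -log10(pmax(fdr, floor_)) * sign(es)
  )
}

#' Enrichment over every miRNA/tissue targeting profile of a collection
#'
#' Extracts, for each regulator and tissue, the targeting profile (that
#' regulator's tissue-specificity scores over all genes) and runs
#' [preranked_gsea()] on it.
#'
#' @param scores Output of [edge_specificity()].
#' @param gene_sets Named list of gene sets (see [read_gmt()]).
#' @param ... Passed to [preranked_gsea()] (`nperm`, `seed`, size bounds,
#'   `fdr_method`).
#' @return A tibble of [preranked_gsea()] results with `mirna` and `tissue`
#'   columns prepended.
#' @export
target_enrichment <- function(scores, gene_sets, ...) {
  stopifnot(all(c("regulator", "gene", "tissue", "score") %in% names(scores)))
  combos <- distinct(scores, .data$regulator, .data$tissue)
  purrr::map2(combos$regulator, combos$tissue, function(reg, tis) {
    prof <- scores |>
      filter(.data$regulator == reg, .data$tissue == tis) |>
      select("gene", "score")
    res <- preranked_gsea(prof, gene_sets, ...)
    if (nrow(res)) { res$mirna <- reg; res$tissue <- tis }
    res
  }) |>
    bind_rows() |>
    select("mirna", "tissue", dplyr::everything())
}

#' Signed enrichment-score matrix
#'
#' Recomputes the signed score \eqn{-\log_{10}(\max(\mathrm{FDR},
#' \mathrm{floor}))\cdot\mathrm{sign}(ES)} from a results table and pivots it
#' into a (miRNA/tissue) x gene-set matrix.
#'
#' @param results Output of [target_enrichment()] (needs `mirna`, `tissue`,
#'   `gene_set`, `ES`, `FDR`).
#' @param floor Lower cap applied to FDR before the log; default `1e-16`
#'   guards exact zeros when results were produced outside [preranked_gsea()].
#' @return A wide tibble: `mirna`, `tissue`, then one column per gene set.
#' @export
signed_score_matrix <- function(results, floor = 1e-16) {
  stopifnot(all(c("mirna", "tissue", "gene_set", "ES", "FDR") %in% names(results)))
  results |>
    mutate(signed_score = -log10(pmax(.data$FDR, floor)) * sign(.data$ES)) |>
    tidyr::pivot_wider(id_cols = c("mirna", "tissue"),
                       names_from = "gene_set", values_from = "signed_score")
}

#' Similarity of enrichment profiles between two collections
#'
#' Pearson correlation, per miRNA/tissue pair, of the signed enrichment
#' scores across gene sets between two result sets (e.g. networks built on
#' two different priors).
#'
#' @param results_a,results_b Outputs of [target_enrichment()] over the same
#'   gene sets.
#' @return Tibble with `mirna`, `tissue`, `r`, `p`, `n_sets`; `r` is `NA`
#'   where a score vector has zero variance.
#' @export
profile_similarity <- function(results_a, results_b) {
  joined <- inner_join(
    select(results_a, "mirna", "tissue", "gene_set", a = "signed_score"),
    select(results_b, "mirna", "tissue", "gene_set", b = "signed_score"),
    by = c("mirna", "tissue", "gene_set"))
  if (nrow(joined) == 0) abort("profile_similarity: no shared (profile, gene set) pairs")
  joined |>
    group_by(.data$mirna, .data$tissue) |>
    summarise(
      r = if (sd(.data$a) == 0 || sd(.data$b) == 0) NA_real_ else cor(.data$a, .data$b),
      p = if (sd(.data$a) == 0 || sd(.data$b) == 0) NA_real_ else
        cor.test(.data$a, .data$b)$p.value,
      n_sets = n(), .groups = "drop")
}

#' Cross-tissue null of enrichment-profile correlations
#'
#' Builds the negative-control distribution: Pearson correlations of signed
#' enrichment scores between profiles from *different* tissues within one
#' collection.  Under tissue-specific regulation these correlations centre
#' at zero.
#'
#' @param results Output of [target_enrichment()].
#' @param max_pairs Cap on the number of mismatched-tissue pairs (seeded
#'   subsample beyond it); default 2000.
#' @param seed Seed for the subsample.
#' @return Tibble with `mirna_a`, `tissue_a`, `mirna_b`, `tissue_b`, `r`.
#' @export
cross_tissue_null <- function(results, max_pairs = 2000, seed = 1) {
  wide <- tidyr::pivot_wider(results, id_cols = c("mirna", "tissue"),
                             names_from = "gene_set", values_from = "signed_score")
  M <- as.matrix(wide[, -(1:2), drop = FALSE])
  ids <- wide[, c("mirna", "tissue")]
  np <- nrow(M)
  pairs <- which(outer(ids$tissue, ids$tissue, "!=") & upper.tri(matrix(0, np, np)),
                 arr.ind = TRUE)
  if (nrow(pairs) == 0) abort("cross_tissue_null: need profiles from at least 2 tissues")
  if (nrow(pairs) > max_pairs) {
    pairs <- with_seed(seed, pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE])
  }
  r <- purrr::map_dbl(seq_len(nrow(pairs)), function(k) {
    x <- M[pairs[k, 1], ]; y <- M[pairs[k, 2], ]
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  })
  tibble(mirna_a = ids$mirna[pairs[, 1]], tissue_a = ids$tissue[pairs[, 1]],
         mirna_b = ids$mirna[pairs[, 2]], tissue_b = ids$tissue[pairs[, 2]],
         r = r)
}

#' Volcano-style plot of enrichment results
#'
#' @param results Output of [preranked_gsea()] or [target_enrichment()].
#' @param fdr_thresh Reference FDR level; default 0.05.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, fdr_thresh = 0.05) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$ES, y = -log10(pmax(.data$FDR, 1e-16)))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(fdr_thresh), linetype = "dashed") +
    ggplot2::labs(x = "enrichment score (ES)", y = "-log10 FDR") +
    ggplot2::theme_minimal()
}
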