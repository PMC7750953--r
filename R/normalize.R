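#' Z-score normalisation of a network matrix
#'
#' Standardises a weight matrix the way the PANDA/PUMA message-passing
#' framework expects its inputs: every entry is replaced by the average of its
#' within-row and within-column z-score, scaled by \eqn{1/\sqrt{2}}, so that
#' the result remains approximately standard normal when rows and columns are.
#' Rows or columns with zero variance contribute the whole-matrix z-score
#' instead, which keeps the output finite on degenerate (e.g. all-constant-row)
#' priors.
#'
#' @param M A finite numeric matrix.
#' @return A numeric matrix of the same dimension (dimnames preserved).
#' @examples
#' normalize_network(matrix(c(0, 1, 1, 0), 2, 2))
#' @export
normalize_network <- function(M) {
  if (!is.matrix(M)) M <- as.matrix(M)
  storage.mode(M) <- "double"
  if (any(!is.finite(M))) abort("normalize_network: input contains non-finite values")
  overall_sd <- sd(as.vector(M))
  if (overall_sd == 0) {
    abort("normalize_network: matrix is constant, no variance anywhere")
  }
  z0 <- (M - mean(M)) / overall_sd

  row_mu <- rowMeans(M)
  row_sd <- apply(M, 1, sd)
  zr <- (M - row_mu) / row_sd          # row-wise z-scores (sample sd)
  bad_r <- row_sd == 0 | !is.finite(row_sd)
  if (any(bad_r)) zr[bad_r, ] <- z0[bad_r, ]

  col_mu <- colMeans(M)
  col_sd <- apply(M, 2, sd)
  zc <- sweep(sweep(M, 2, col_mu), 2, col_sd, "/")
  bad_c <- col_sd == 0 | !is.finite(col_sd)
  if (any(bad_c)) zc[, bad_c] <- z0[, bad_c]

  (zr + zc) / sqrt(2)
}

#' Continuous Tanimoto similarity between row profiles
#'
#' The matching kernel of the message-passing framework:
#' \deqn{T(x, y) = \frac{x \cdot y}{\sqrt{\|x\|^2 + \|y\|^2 - |x \cdot y|}}}
#' computed for every pair of a row of `X` against a row of `Y`.  It behaves
#' like a continuous Jaccard/Tanimoto overlap for z-score-like profiles.  A
#' pair of all-zero vectors carries no agreement signal and is defined as 0.
#'
#' @param X Numeric matrix, `a` rows by `k` columns.
#' @param Y Numeric matrix, `b` rows by `k` columns (same `k`).
#' @return An `a` by `b` matrix of similarities.
#' @export
tanimoto <- function(X, Y) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1)
  if (ncol(X) != ncol(Y)) {
    abort(sprintf("tanimoto: inner dimensions differ (%d vs %d)", ncol(X), ncol(Y)))
  }
  dot <- tcrossprod(X, Y)
  nx <- rowSums(X^2)
  ny <- rowSums(Y^2)
  den2 <- outer(nx, ny, "+") - abs(dot)
  out <- dot / sqrt(den2)
  out[den2 <= 0] <- 0  # both profiles zero: no signal
  out
}

#' Gene-gene co-expression network from an expression matrix
#'
#' Pearson correlation between gene expression profiles across samples.  Genes
#' with zero variance get correlation 0 to every other gene (and 1 with
#' themselves): a flat profile is uninformative, not perfectly coherent.
#'
#' @param expression A data frame whose first column is the gene ID and whose
#'   remaining columns are per-sample expression values, or a numeric matrix
#'   (genes in rows, rownames = gene IDs).  At least 3 samples are required.
#' @return A symmetric genes-by-genes correlation matrix with unit diagonal.
#' @export
compute_coexpression <- function(expression) {
  E <- as_expression_matrix(expression)
  if (ncol(E) < 3) {
    abort(sprintf("compute_coexpression: %d sample(s); at least 3 are required",
                  ncol(E)))
  }
  C <- suppressWarnings(cor(t(E)))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  C
}
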