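#' Align prior, expression and cooperativity inputs on shared IDs
#'
#' Restricts the regulatory prior to the genes that have expression data
#' (regulatory evidence is only usable where co-expression can be computed)
#' and puts every input in one consistent ordering: prior columns, expression
#' rows and the co-expression network share the gene order; prior rows and the
#' cooperativity network share the regulator order.  A missing cooperativity
#' network defaults to the identity, the natural prior for regulators with no
#' known cooperation (the usual situation for miRNA-only runs).
#'
#' @param prior Edge-list data frame with columns `regulator`, `gene`,
#'   `weight`.  Zero-weight rows are legitimate and pin IDs into the universe.
#' @param expression Expression input (see [compute_coexpression()]).
#' @param cooperativity Optional square numeric matrix with regulator IDs as
#'   dimnames, or `NULL` for the identity default.
#' @param mirna Character vector of regulator IDs to flag as miRNAs, or `NULL`
#'   to flag all regulators.
#' @return A list with elements `prior` (m x n matrix), `expression`
#'   (n x q matrix), `cooperativity` (m x m matrix), `mirna_mask` (logical m),
#'   `regulators`, `genes`.
#' @export
align_inputs <- function(prior, expression, cooperativity = NULL, mirna = NULL) {
  stopifnot(all(c("regulator", "gene", "weight") %in% names(prior)))
  W <- edges_to_matrix(prior)
  if (any(!is.finite(W))) abort("align_inputs: prior weights must be finite")
  E <- as_expression_matrix(expression)

  genes <- intersect(colnames(W), rownames(E))  # prior order, restricted
  if (length(genes) < 2) {
    abort(paste0(
      "align_inputs: fewer than 2 genes shared between prior and expression.\n",
      "  prior genes: ", paste(head(colnames(W), 5), collapse = ", "),
      if (ncol(W) > 5) ", ..." else "", "\n",
      "  expression genes: ", paste(head(rownames(E), 5), collapse = ", "),
      if (nrow(E) > 5) ", ..." else ""))
  }
  regulators <- rownames(W)
  W <- W[, genes, drop = FALSE]
  E <- E[genes, , drop = FALSE]

  if (is.null(cooperativity)) {
    P <- diag(length(regulators))
    dimnames(P) <- list(regulators, regulators)
  } else {
    P <- as.matrix(cooperativity)
    if (is.null(rownames(P))) abort("align_inputs: cooperativity needs regulator dimnames")
    missing <- setdiff(regulators, rownames(P))
    if (length(missing)) {
      abort(paste0("align_inputs: regulators absent from cooperativity: ",
                   paste(missing, collapse = ", ")))
    }
    P <- P[regulators, regulators, drop = FALSE]
    if (max(abs(P - t(P))) > 1e-8) abort("align_inputs: cooperativity must be symmetric")
  }

  mask <- if (is.null(mirna)) rep(TRUE, length(regulators)) else regulators %in% mirna
  list(prior = W, expression = E, cooperativity = P,
       mirna_mask = mask, regulators = regulators, genes = genes)
}

# internal: diagonal replacement after a similarity update -- self-similarity
# would otherwise dominate the cooperativity / co-expression updates.  Each
# diagonal entry becomes the row's standard deviation (excluding the
# diagonal) times the matrix dimension times exp(2 * alpha * step); the
# exponential growth over iterations progressively damps the similarity
# messages and is what drives the scheme to convergence.
replace_diagonal <- function(M, alpha, step) {
  k <- nrow(M)
  off <- M
  diag(off) <- NA
  row_sd <- apply(off, 1, sd, na.rm = TRUE)
  diag(M) <- row_sd * k * exp(2 * alpha * step)
  M
}

#' One message-passing update of the PUMA state
#'
#' Performs a single iteration of the PANDA-style message passing with the
#' miRNA modification.  Responsibility compares each regulator's cooperativity
#' profile to each gene's regulator profile; availability compares each
#' regulator's target profile to each gene's co-expression profile.  The
#' network moves a step of size `alpha` towards their average; cooperativity
#' and co-expression then move towards the updated network's self-similarity,
#' except that rows and columns of the cooperativity matrix belonging to
#' flagged miRNAs are reset to their initial values every iteration — miRNA
#' cooperativity is data we do not have, so it is never learnt.
#'
#' All matrices are assumed to be already normalised ([normalize_network()]).
#'
#' @param state List with elements `W` (m x n network), `P` (m x m
#'   cooperativity), `C` (n x n co-expression), `P0` (initial cooperativity),
#'   `mirna_mask` (logical m), `alpha` (step size in (0, 1]), and optionally
#'   `step` (0-based iteration counter used by the diagonal damping; default
#'   0, incremented on return).
#' @return The updated state, with the convergence statistic `h` (mean
#'   absolute difference between the network and its message-based candidate,
#'   computed before the step) added and `step` incremented.
#' @export
message_passing_step <- function(state) {
  W <- state$W; P <- state$P; C <- state$C
  alpha <- state$alpha
  mask <- state$mirna_mask
  step <- state$step %||% 0

  R <- tanimoto(P, t(W))        # responsibility: m x n
  A <- tanimoto(W, C)           # availability:  m x n (C symmetric)
  What <- (R + A) / 2
  h <- mean(abs(W - What))
  W <- (1 - alpha) * W + alpha * What

  Pup <- replace_diagonal(tanimoto(W, W), alpha, step)
  P <- (1 - alpha) * P + alpha * Pup
  if (any(mask)) {              # the miRNA modification
    P[mask, ] <- state$P0[mask, ]
    P[, mask] <- state$P0[, mask]
  }

  Cup <- replace_diagonal(tanimoto(t(W), t(W)), alpha, step)
  C <- (1 - alpha) * C + alpha * Cup

  for (nm in c("W", "P", "C")) {
    M <- get(nm)
    if (any(!is.finite(M))) {
      abort(sprintf("message passing produced non-finite values in %s", nm))
    }
  }
  state$W <- W; state$P <- P; state$C <- C; state$h <- h
  state$step <- step + 1
  state
}

#' Infer a miRNA-target regulatory network by message passing
#'
#' Runs the PUMA algorithm: the target-prediction prior, the target-gene
#' co-expression network and the regulator cooperativity network are z-score
#' normalised and then iteratively reconciled by message passing until the
#' mean absolute update `h` falls below `tol`.  For regulators flagged as
#' miRNAs the cooperativity matrix is pinned to its initial value at every
#' iteration; with no flagged regulators the engine is exactly PANDA.  Edge
#' weights in the result are on a z-score-like scale: large positive values
#' mark well-supported regulator-gene interactions, including interactions
#' absent from the prior but supported by co-expression ("learnt" edges).
#'
#' @inheritParams align_inputs
#' @param mode `"puma"` (default) or `"panda"`.  In PANDA mode the miRNA
#'   reset is disabled regardless of `mirna`.
#' @param alpha Update step size in (0, 1]; default 0.1.
#' @param tol Convergence threshold on `h`; default 1e-3.
#' @param max_iter Maximum number of iterations; default 200.  With
#'   `max_iter = 0` the normalised prior is returned unchanged.
#' @return An object of class `puma_fit`; see [tidy.puma_fit()] and
#'   [glance.puma_fit()].
#' @examples
#' sim <- simulate_regulatory_data(simulate_config(m = 6, n = 15, tissues = 1,
#'                                                 samples = 20, seed = 1))
#' fit <- run_puma(sim$prior_a, sim$expression[[1]])
#' glance(fit)
#' @export
run_puma <- function(prior, expression, cooperativity = NULL, mirna = NULL,
                     mode = c("puma", "panda"), alpha = 0.1, tol = 1e-3,
                     max_iter = 200L) {
  mode <- match.arg(mode)
  if (!(alpha > 0 && alpha <= 1)) abort("alpha must be in (0, 1]")
  if (!(tol > 0)) abort("tol must be positive")
  if (max_iter < 0) abort("max_iter must be non-negative")

  al <- align_inputs(prior, expression, cooperativity, mirna)
  mask <- if (mode == "panda") rep(FALSE, length(al$regulators)) else al$mirna_mask

  W <- normalize_network(al$prior)
  P0 <- normalize_network(al$cooperativity)
  C0 <- normalize_network(compute_coexpression(al$expression))

  state <- list(W = W, P = P0, C = C0, P0 = P0,
                mirna_mask = mask, alpha = alpha, step = 0)
  h_trace <- numeric(0)
  p_drift <- numeric(0)   # max |P - P0| over miRNA rows/cols, per iteration
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    state <- message_passing_step(state)
    iter <- iter + 1L
    h_trace[iter] <- state$h
    p_drift[iter] <- if (any(mask)) {
      max(abs(state$P[mask, , drop = FALSE] - state$P0[mask, , drop = FALSE]),
          abs(state$P[, mask, drop = FALSE] - state$P0[, mask, drop = FALSE]))
    } else 0
    if (state$h < tol) { converged <- TRUE; break }
  }
  if (!converged && max_iter > 0) {
    warn(sprintf("PUMA did not converge in %d iterations (final h = %.3g)",
                 max_iter, state$h))
  }

  structure(list(
    weights = state$W,
    regulators = al$regulators,
    genes = al$genes,
    mirna_mask = al$mirna_mask,
    prior = al$prior,
    mode = mode,
    alpha = alpha, tol = tol, max_iter = max_iter,
    iterations = iter,
    converged = converged || max_iter == 0,
    final_h = if (iter > 0) state$h else NA_real_,
    h_trace = h_trace,
    p_drift = p_drift
  ), class = "puma_fit")
}

#' @export
print.puma_fit <- function(x, ...) {
  cat(sprintf("<puma_fit> %s mode: %d regulators x %d genes\n",
              x$mode, length(x$regulators), length(x$genes)))
  cat(sprintf("  %d iteration(s), %s (final h = %s, tol = %g)\n",
              x$iterations,
              if (x$converged) "converged" else "NOT converged",
              format(x$final_h, digits = 4), x$tol))
  invisible(x)
}

#' Tidy a fitted PUMA network into an edge tibble
#'
#' @param x A `puma_fit`.
#' @param ... Unused.
#' @return A tibble with one row per regulator-gene edge: `regulator`, `gene`,
#'   `weight` (refined, z-score-like) and `prior` (the aligned input prior
#'   weight).
#' @export
tidy.puma_fit <- function(x, ...) {
  out <- matrix_to_edges(x$weights)
  out$prior <- as.vector(x$prior)
  out
}

#' One-row summary of a PUMA run
#'
#' @param x A `puma_fit`.
#' @param ... Unused.
#' @return A one-row tibble: mode, dimensions, iterations, convergence flag,
#'   final `h`, `alpha` and `tol`.
#' @export
glance.puma_fit <- function(x, ...) {
  tibble(mode = x$mode,
         n_regulators = length(x$regulators),
         n_genes = length(x$genes),
         iterations = x$iterations,
         converged = x$converged,
         final_h = x$final_h,
         alpha = x$alpha,
         tol = x$tol)
}

#' Plot the weight distribution of a fitted network by prior support
#'
#' Refined edge weights, split by whether the edge was present (non-zero) in
#' the prior.  A fit that has learnt from co-expression shows the
#' prior-supported distribution shifted right of the prior-absent one, with a
#' high-weight tail among prior-absent edges where new targets were learnt.
#'
#' @param object A `puma_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.puma_fit <- function(object, ...) {
  df <- tidy(object)
  df$prior_support <- ifelse(df$prior != 0, "in prior", "not in prior")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, fill = .data$prior_support)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "edge weight (z-score-like)", fill = NULL,
                  title = "Refined edge weights by prior support") +
    ggplot2::theme_minimal()
}
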