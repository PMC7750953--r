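# Independent, deliberately naive reference implementations used to check the
# package's vectorised code.  Everything here is element-wise loops or direct
# textbook formulas; none of it calls package internals.

oracle_tanimoto_pair <- function(x, y) {
  d <- sum(x * y)
  den2 <- sum(x^2) + sum(y^2) - abs(d)
  if (den2 <= 0) return(0)
  d / sqrt(den2)
}

oracle_tanimoto <- function(X, Y) {
  out <- matrix(NA_real_, nrow(X), nrow(Y))
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(Y))) {
    out[i, j] <- oracle_tanimoto_pair(X[i, ], Y[j, ])
  }
  out
}

oracle_normalize <- function(M) {
  mu <- mean(M); s <- sd(as.vector(M))
  out <- matrix(NA_real_, nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    ri <- M[i, ]; cj <- M[, j]
    zr <- if (sd(ri) > 0) (M[i, j] - mean(ri)) / sd(ri) else (M[i, j] - mu) / s
    zc <- if (sd(cj) > 0) (M[i, j] - mean(cj)) / sd(cj) else (M[i, j] - mu) / s
    out[i, j] <- (zr + zc) / sqrt(2)
  }
  out
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# linear-interpolation quantile of sorted data at probability p
oracle_quantile <- function(x, p) {
  xs <- unname(sort(x))
  n <- length(xs)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  hi <- min(ceiling(h) + 1, n)
  xs[lo] + (h - (lo - 1)) * (xs[hi] - xs[lo])
}

oracle_iqr <- function(x) oracle_quantile(x, 0.75) - oracle_quantile(x, 0.25)

oracle_specificity <- function(w) {
  iqr <- oracle_iqr(w)
  if (iqr == 0) return(rep(0, length(w)))
  (w - oracle_quantile(w, 0.5)) / iqr
}

# full running-sum GSEA walk: ranked_scores descending, member logical along
# the ranking; returns the signed maximum deviation
oracle_es <- function(ranked_scores, member) {
  n <- length(ranked_scores)
  k <- sum(member)
  w <- abs(ranked_scores)
  tot <- sum(w[member])
  s <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (member[i]) {
      s <- s + (if (tot > 0) w[i] / tot else 1 / k)
    } else {
      s <- s - 1 / (n - k)
    }
    if (abs(s) > abs(best)) best <- s
  }
  best
}

# modularity of a partition on an undirected simple graph given as an edge
# data frame (from, to) over node names
oracle_modularity <- function(edges, membership) {
  nodes <- names(membership)
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(edges))) {
    A[edges$from[e], edges$to[e]] <- 1
    A[edges$to[e], edges$from[e]] <- 1
  }
  deg <- rowSums(A)
  two_m <- sum(deg)
  q <- 0
  for (i in nodes) for (j in nodes) {
    if (membership[[i]] == membership[[j]]) {
      q <- q + A[i, j] - deg[[i]] * deg[[j]] / two_m
    }
  }
  q / two_m
}

# enumerate all set partitions of n items as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxg) {
    i <- length(prefix) + 1
    if (i > n) { out[[length(out) + 1]] <<- prefix; return(invisible()) }
    for (g in 0:(maxg + 1)) rec(c(prefix, g), max(maxg, g))
  }
  rec(integer(0), -1L)
  out
}

# best modularity over every partition of the graph's nodes (n <= 8 or so)
brute_force_modularity <- function(edges, nodes) {
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(edges))) {
    A[edges$from[e], edges$to[e]] <- 1
    A[edges$to[e], edges$from[e]] <- 1
  }
  deg <- rowSums(A)
  two_m <- sum(deg)
  B <- A - outer(deg, deg) / two_m
  best <- -Inf
  for (p in all_partitions(length(nodes))) {
    same <- outer(p, p, "==")
    best <- max(best, sum(B * same) / two_m)
  }
  best
}

oracle_auroc <- function(w, labels) {
  pos <- w[as.logical(labels)]
  neg <- w[!as.logical(labels)]
  u <- 0
  for (p in pos) for (q in neg) {
    u <- u + (p > q) + 0.5 * (p == q)
  }
  u / (length(pos) * length(neg))
}

# one full message-passing step by direct per-cell loops, independent of the
# package's matrix algebra
oracle_step <- function(W, P, C, P0, mask, alpha, step = 0) {
  m <- nrow(W); n <- ncol(W)
  R <- matrix(NA_real_, m, n)
  A <- matrix(NA_real_, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    R[i, j] <- oracle_tanimoto_pair(P[i, ], W[, j])
    A[i, j] <- oracle_tanimoto_pair(W[i, ], C[, j])
  }
  What <- (R + A) / 2
  h <- mean(abs(W - What))
  Wn <- (1 - alpha) * W + alpha * What

  upd_diag <- function(M) {
    k <- nrow(M)
    for (i in seq_len(k)) {
      M[i, i] <- sd(M[i, -i]) * k * exp(2 * alpha * step)
    }
    M
  }
  Pup <- upd_diag(oracle_tanimoto(Wn, Wn))
  Pn <- (1 - alpha) * P + alpha * Pup
  Pn[mask, ] <- P0[mask, ]
  Pn[, mask] <- P0[, mask]
  Cup <- upd_diag(oracle_tanimoto(t(Wn), t(Wn)))
  Cn <- (1 - alpha) * C + alpha * Cup
  list(W = Wn, P = Pn, C = Cn, h = h)
}

# small fixture builders ------------------------------------------------------

rand_matrix <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(rnorm(nr * nc), nr, nc)
}

# a tiny aligned prior/expression pair for engine tests
tiny_instance <- function(m = 4, n = 6, q = 12, seed = 42) {
  set.seed(seed)
  regs <- sprintf("R%d", seq_len(m))
  gens <- sprintf("G%d", seq_len(n))
  prior <- expand.grid(regulator = regs, gene = gens,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  prior$weight <- rbinom(nrow(prior), 1, 0.4)
  E <- matrix(rnorm(n * q), n, q, dimnames = list(gens, sprintf("s%d", seq_len(q))))
  expr <- data.frame(gene = gens, E, check.names = FALSE)
  list(prior = tibble::as_tibble(prior), expression = tibble::as_tibble(expr))
}
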