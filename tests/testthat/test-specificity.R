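# tissue-specificity scores, multiplicities, edge classes and collection
# comparisons against direct median/IQR oracles

make_collection <- function(W_by_tissue) {
  purrr::imap_dfr(W_by_tissue, function(W, tis) {
    out <- expand.grid(regulator = rownames(W), gene = colnames(W),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out$tissue <- tis
    out$weight <- as.vector(W)
    out
  })
}

one_edge_collection <- function(w) {
  Ws <- lapply(seq_along(w), function(t) {
    matrix(w[t], 1, 1, dimnames = list("r1", "g1"))
  })
  names(Ws) <- paste0("t", seq_along(w))
  make_collection(Ws)
}

test_that("edge specificity equals the sort-and-interpolate quantile oracle", {
  w <- c(1, 2, 3, 4, 10)
  sc <- edge_specificity(one_edge_collection(w))
  expect_equal(sc$score, oracle_specificity(w), tolerance = 1e-12)
  expect_equal(sc$score[5], (10 - 3) / oracle_iqr(w), tolerance = 1e-12)

  set.seed(31)
  for (rep in 1:5) {
    w <- rnorm(7)
    sc <- edge_specificity(one_edge_collection(w))
    expect_equal(sc$score, oracle_specificity(w), tolerance = 1e-12)
  }
})

test_that("constant and median-valued weights get specificity zero", {
  sc <- edge_specificity(one_edge_collection(rep(2.5, 4)))
  expect_true(all(sc$score == 0))

  w <- c(1, 2, 3)   # middle tissue sits at the median
  sc <- edge_specificity(one_edge_collection(w))
  expect_equal(sc$score[2], 0)
})

test_that("specificity scores are invariant to affine weight transforms", {
  set.seed(8)
  Ws <- lapply(1:4, function(t) {
    matrix(rnorm(6), 2, 3, dimnames = list(c("r1", "r2"), c("g1", "g2", "g3")))
  })
  names(Ws) <- paste0("t", 1:4)
  base <- edge_specificity(make_collection(Ws))
  shifted <- edge_specificity(make_collection(
    lapply(Ws, function(W) 3.7 * W + 11)))
  expect_equal(base$score, shifted$score, tolerance = 1e-10)
})

test_that("multiplicity counts strict threshold exceedances", {
  sc <- one_edge_collection(c(2.5, 0.1, -1, 3.0))
  sc$score <- sc$weight                      # inject known scores directly
  expect_equal(multiplicity(sc)$multiplicity, 2L)
  sc$score <- c(2, 1.9, -5, 0)               # boundary: 2 is not > 2
  expect_equal(multiplicity(sc)$multiplicity, 0L)

  # conservation: multiplicity equals the edge-wise recount
  set.seed(12)
  Ws <- lapply(1:5, function(t)
    matrix(rnorm(8, sd = 3), 2, 4,
           dimnames = list(c("r1", "r2"), paste0("g", 1:4))))
  names(Ws) <- paste0("t", 1:5)
  sc <- edge_specificity(make_collection(Ws))
  mult <- multiplicity(sc, threshold = 2)
  recount <- tapply(sc$score > 2, paste(sc$regulator, sc$gene), sum)
  expect_equal(mult$multiplicity,
               as.integer(recount[paste(mult$regulator, mult$gene)]),
               ignore_attr = TRUE)
})

test_that("expression specificity matches a from-scratch median/IQR oracle", {
  set.seed(77)
  mk <- function(mu) {
    E <- matrix(rnorm(3 * 8, mean = mu), 3, 8,
                dimnames = list(c("m1", "m2", "g1"), paste0("s", 1:8)))
    E
  }
  tissues <- list(ta = mk(0), tb = mk(1), tc = mk(3))
  sc <- expression_specificity(tissues, c("m1", "m2"))
  for (p in c("m1", "m2")) {
    pooled <- unlist(lapply(tissues, function(E) E[p, ]))
    for (tis in names(tissues)) {
      expected <- (oracle_quantile(tissues[[tis]][p, ], 0.5) -
                     oracle_quantile(pooled, 0.5)) / oracle_iqr(pooled)
      got <- sc$score[sc$mirna == p & sc$tissue == tis]
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
  # tissue-restricted expression scores positive in its tissue
  only_tb <- list(ta = mk(0), tb = mk(5), tc = mk(0))
  sc2 <- expression_specificity(only_tb, "m1")
  expect_gt(sc2$score[sc2$tissue == "tb"], 0)

  expect_error(expression_specificity(tissues, "nope"), "nope")
})

test_that("edges are classified canonical / non-canonical / different", {
  grid <- expand.grid(regulator = c("r1", "r2"), gene = c("g1", "g2"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  a <- transform(grid, weight = c(1, 0, 1, 0))
  b <- transform(grid, weight = c(1, 0, 0, 1))
  cls <- classify_edges(a, b)
  lookup <- function(r, g) cls$class[cls$regulator == r & cls$gene == g]
  expect_equal(lookup("r1", "g1"), "canonical")
  expect_equal(lookup("r2", "g1"), "non-canonical")
  expect_equal(lookup("r1", "g2"), "different")
  expect_equal(lookup("r2", "g2"), "different")
  expect_equal(nrow(cls), 4L)  # classes partition the grid
})

test_that("prior overlap reports Jaccard and Pearson", {
  grid <- expand.grid(regulator = "r1", gene = paste0("g", 1:4),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  a <- transform(grid, weight = c(1, 1, 1, 0))
  b <- transform(grid, weight = c(0, 1, 1, 1))
  ov <- prior_overlap(a, b)
  expect_equal(ov$jaccard, 0.5)              # {g1,g2,g3} vs {g2,g3,g4}
  expect_equal(ov$pearson, oracle_pearson(a$weight, b$weight), tolerance = 1e-12)
})

test_that("collection comparison recovers perfect, inverted and oracle correlations", {
  set.seed(41)
  Ws <- lapply(1:3, function(t)
    matrix(rnorm(12), 3, 4, dimnames = list(paste0("r", 1:3), paste0("g", 1:4))))
  names(Ws) <- paste0("t", 1:3)
  sa <- edge_specificity(make_collection(Ws))
  expect_equal(compare_collections(sa, sa)$r, rep(1, 3), tolerance = 1e-12)

  sb <- sa; sb$score <- -sb$score
  expect_equal(compare_collections(sa, sb)$r, rep(-1, 3), tolerance = 1e-12)

  sc <- sa; set.seed(42); sc$score <- rnorm(nrow(sc))
  cmp <- compare_collections(sa, sc)
  for (tis in cmp$tissue) {
    x <- sa$score[sa$tissue == tis]
    y <- sc$score[sc$tissue == tis]
    expect_equal(cmp$r[cmp$tissue == tis], oracle_pearson(x, y), tolerance = 1e-12)
  }

  # stratification by class keeps per-tissue totals
  classes <- classify_edges(
    transform(expand.grid(regulator = paste0("r", 1:3), gene = paste0("g", 1:4),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
              weight = rep(c(1, 0), 6)),
    transform(expand.grid(regulator = paste0("r", 1:3), gene = paste0("g", 1:4),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
              weight = rep(c(1, 1, 0), 4)))
  cmp2 <- compare_collections(sa, sc, classes)
  per_tissue <- subset(cmp2, class != "all")
  expect_equal(sum(per_tissue$n_edges), 3 * 12)
})

test_that("edge specificity needs at least 3 tissues and consistent edge sets", {
  coll <- one_edge_collection(c(1, 2))
  expect_error(edge_specificity(coll), "at least 3 tissues")
  set.seed(3)
  Ws <- lapply(1:3, function(t)
    matrix(rnorm(4), 2, 2, dimnames = list(c("r1", "r2"), c("g1", "g2"))))
  names(Ws) <- paste0("t", 1:3)
  coll4 <- make_collection(Ws)
  # one edge missing from one tissue: inconsistent edge sets
  expect_error(edge_specificity(coll4[-2, ]), "edge sets")
})
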