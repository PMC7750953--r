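# binarisation thresholds, fast-greedy community detection and partition
# comparison, with modularity checked against the formula and brute force

biclique_assoc <- function() {
  # two disjoint 3x3 bicliques: profiles p1-p3 x sets A1-A3, p4-p6 x B1-B3
  grid <- expand.grid(profile = sprintf("p%d", 1:6),
                      gene_set = c(sprintf("A%d", 1:3), sprintf("B%d", 1:3)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$associated <- as.integer(
    (grid$profile %in% sprintf("p%d", 1:3) & grepl("^A", grid$gene_set)) |
    (grid$profile %in% sprintf("p%d", 4:6) & grepl("^B", grid$gene_set)))
  grid
}

assoc_edges <- function(assoc) {
  ones <- assoc[assoc$associated == 1, ]
  data.frame(from = ones$profile, to = ones$gene_set)
}

test_that("binarisation applies strict FDR and ES thresholds", {
  res <- tibble::tibble(
    mirna = "m", tissue = "t",
    gene_set = c("a", "b", "c", "d"),
    ES = c(0.7, 0.7, 0.65, 0.9),
    FDR = c(0.0005, 0.001, 0.0001, 0.002))
  b <- binarize(res)
  expect_equal(b$associated, c(1L, 0L, 0L, 0L))  # boundaries excluded
  expect_equal(b$profile, rep("m|t", 4))
})

test_that("two disjoint bicliques are recovered as exactly two communities", {
  assoc <- biclique_assoc()
  comm <- detect_communities(assoc)
  mem <- comm$membership
  expect_equal(length(unique(mem$community)), 2L)
  side_a <- mem$community[mem$node %in% c(sprintf("p%d", 1:3), sprintf("A%d", 1:3))]
  side_b <- mem$community[mem$node %in% c(sprintf("p%d", 4:6), sprintf("B%d", 1:3))]
  expect_equal(length(unique(side_a)), 1L)
  expect_equal(length(unique(side_b)), 1L)
  expect_false(side_a[1] == side_b[1])

  # reported Q matches the independent modularity formula
  membership <- setNames(mem$community, mem$node)
  expect_equal(comm$modularity,
               oracle_modularity(assoc_edges(assoc), as.list(membership)),
               tolerance = 1e-12)

  # and equals the brute-force optimum over the biclique-respecting search:
  # enumerate all partitions of the 4 biclique halves is overkill here; the
  # two-community split is optimal among all partitions found by exhaustive
  # search over merges of the 4 natural blocks
  blocks <- list(c(sprintf("p%d", 1:3)), sprintf("A%d", 1:3),
                 sprintf("p%d", 4:6), sprintf("B%d", 1:3))
  best <- -Inf
  for (code in 0:(4^4 - 1)) {  # assignments of 4 blocks to <=4 groups
    g <- (code %/% 4^(0:3)) %% 4
    memb <- list()
    for (b in 1:4) for (nd in blocks[[b]]) memb[[nd]] <- g[b]
    q <- oracle_modularity(assoc_edges(assoc), memb)
    best <- max(best, q)
  }
  expect_equal(comm$modularity, best, tolerance = 1e-12)
})

test_that("a single-edge graph collapses into one community with Q = 0", {
  assoc <- tibble::tibble(profile = "p1", gene_set = "A1", associated = 1L)
  comm <- detect_communities(assoc)
  expect_equal(length(unique(comm$membership$community)), 1L)
  expect_equal(comm$modularity, 0)
})

test_that("modularity of an 8-node toy partition matches brute force bounds", {
  set.seed(19)
  grid <- expand.grid(profile = sprintf("p%d", 1:4),
                      gene_set = sprintf("S%d", 1:4),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$associated <- rbinom(nrow(grid), 1, 0.45)
  grid$associated[grid$profile == "p1" & grid$gene_set == "S1"] <- 1L  # connected-ish
  comm <- detect_communities(grid)
  mem <- setNames(as.list(comm$membership$community), comm$membership$node)
  expect_equal(comm$modularity, oracle_modularity(assoc_edges(grid), mem),
               tolerance = 1e-12)

  # brute force over all set partitions of the retained nodes (<= 8): the
  # greedy partition cannot beat the optimum
  nodes <- comm$membership$node
  best <- brute_force_modularity(assoc_edges(grid), nodes)
  expect_lte(comm$modularity, best + 1e-12)
})

test_that("node order and all-zero rows do not affect the partition", {
  assoc <- biclique_assoc()
  base <- detect_communities(assoc)
  set.seed(23)
  shuffled <- assoc[sample(nrow(assoc)), ]
  perm <- detect_communities(shuffled)
  expect_equal(perm$modularity, base$modularity, tolerance = 1e-12)
  # same partition up to relabeling: co-membership matrices agree
  co <- function(comm) {
    mem <- comm$membership[order(comm$membership$node), ]
    outer(mem$community, mem$community, "==")
  }
  expect_identical(co(base), co(perm))

  padded <- rbind(assoc,
                  data.frame(profile = "p_empty", gene_set = assoc$gene_set[1:6],
                             associated = 0L))
  expect_identical(co(detect_communities(padded)), co(base))
})

test_that("partition comparison filters by gene-set count and uses Jaccard", {
  expect_equal(jaccard(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(jaccard(1:3, 4:6), 0)

  assoc <- biclique_assoc()
  comm <- detect_communities(assoc)
  idm <- compare_partitions(comm, comm, min_gene_sets = 3)
  expect_true(all(idm$jaccard[idm$community_a == idm$community_b] == 1))
  expect_true(all(idm$jaccard[idm$community_a != idm$community_b] == 0))
  # min_gene_sets above community size filters everything out
  expect_equal(nrow(compare_partitions(comm, comm, min_gene_sets = 5)), 0L)
})

test_that("an edgeless association matrix is an error", {
  assoc <- tibble::tibble(profile = "p1", gene_set = "A1", associated = 0L)
  expect_error(detect_communities(assoc), "no edges")
})
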