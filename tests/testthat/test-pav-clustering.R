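test_that("PAV distances match direct counting", {
  m <- matrix(c(1L, 1L, 0L, 0L,
                1L, 0L, 1L, 0L,
                1L, 1L, 0L, 0L), nrow = 4,
              dimnames = list(sprintf("g%d", 1:4), c("x", "y", "z")))
  pav <- pav_matrix(m)
  dh <- pav_distance(pav, "hamming")
  dj <- pav_distance(pav, "jaccard")
  expect_equal(dh["x", "y"], 0.5)
  expect_equal(dj["x", "y"], 2 / 3)
  expect_equal(dh["x", "z"], 0)          # identical rows
  expect_equal(unname(diag(dh)), rep(0, 3))
  expect_identical(dh, t(dh))

  # complementary accessions are at hamming distance 1
  m2 <- matrix(c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L), nrow = 4,
               dimnames = list(sprintf("g%d", 1:4), c("p", "q")))
  expect_equal(pav_distance(pav_matrix(m2), "hamming")["p", "q"], 1)

  # hamming satisfies the triangle inequality
  set.seed(13)
  m3 <- matrix(rbinom(200, 1, 0.5), 20, 10,
               dimnames = list(sprintf("g%02d", 1:20),
                               sprintf("a%02d", 1:10)))
  d3 <- pav_distance(pav_matrix(m3), "hamming")
  for (i in 1:10) {
    trip <- sample(10, 3)
    expect_lte(d3[trip[1], trip[2]],
               d3[trip[1], trip[3]] + d3[trip[3], trip[2]] + 1e-12)
  }

  # empty union under jaccard: distance 0 with a warning
  m4 <- matrix(c(1L, 0L, 0L), nrow = 1,
               dimnames = list("g1", c("u", "v", "w")))
  expect_warning(d4 <- pav_distance(pav_matrix(m4), "jaccard"),
                 "empty")
  expect_equal(d4["v", "w"], 0)
})

test_that("neighbor joining is exact on additive distances", {
  # ((A:1,B:2):1,(C:3,D:4)) as a distance matrix
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_identical(rf_distance(tr, truth), 0L)
  # branch lengths reproduce the metric exactly
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[LETTERS[1:4],
                                                    LETTERS[1:4]],
               d, tolerance = 1e-12)

  # three taxa: closed-form resolution
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighbor_joining(d3)
  cp <- as.matrix(ape::cophenetic.phylo(tr3))[c("A", "B", "C"),
                                              c("A", "B", "C")]
  expect_equal(cp, d3, tolerance = 1e-12)

  asym <- d
  asym[1, 2] <- 99
  expect_error(neighbor_joining(asym), "symmetric")
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining recovers random trees from their metrics", {
  set.seed(14)
  for (i in 1:30) {
    n <- sample(8:20, 1)
    true_tree <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    d <- as.matrix(ape::cophenetic.phylo(true_tree))
    got <- neighbor_joining(d)
    expect_identical(rf_distance(got, ape::unroot(true_tree)), 0L)
  }
})

test_that("split extraction and RF distance agree with phangorn", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    t1 <- ape::unroot(ape::rtree(n))
    t2 <- ape::unroot(ape::rtree(n))
    t2$tip.label <- t1$tip.label[sample(n)]
    expect_identical(rf_distance(t1, t1), 0L)
    expect_equal(rf_distance(t1, t2),
                 as.integer(phangorn::RF.dist(t1, t2)))
  }
  # star vs resolved: RF equals the resolved tree's internal split count
  res <- ape::unroot(ape::rtree(5))
  star <- ape::read.tree(text = paste0("(", paste(res$tip.label,
                                                  collapse = ","), ");"))
  expect_identical(rf_distance(star, res), length(tree_splits(res)))
})

test_that("bootstrap supports are deterministic and bounded", {
  st <- small_study()
  bs1 <- bootstrap_support(st$pav, n_reps = 25, seed = 8)
  bs2 <- bootstrap_support(st$pav, n_reps = 25, seed = 8)
  expect_identical(bs1$split_support, bs2$split_support)
  expect_true(all(bs1$split_support >= 0 & bs1$split_support <= 100))

  one <- bootstrap_support(st$pav, n_reps = 1, seed = 9)
  expect_true(all(one$split_support %in% c(0, 100)))

  # clades separated by many fixed differences get strong support
  cr <- clade_recovery(bs1$tree, st$truth$clade_map)
  expect_true(all(cr$monophyletic))
  clade_keys <- vapply(split(names(st$truth$clade_map),
                             st$truth$clade_map), function(m) {
    anchor <- sort(bs1$tree$tip.label)[1]
    side <- if (anchor %in% m) setdiff(bs1$tree$tip.label, m) else m
    paste(sort(side), collapse = "|")
  }, character(1))
  expect_true(all(bs1$split_support[clade_keys] >= 90))
})

test_that("clade recovery flags broken monophyly", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,(b2:1,a3:1):1):1);")
  cm <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B")
  cr <- clade_recovery(tr, cm)
  expect_false(cr$monophyletic[["A"]])
  expect_false(cr$monophyletic[["B"]])
  expect_error(clade_recovery(tr, cm[-1]), "without clade")
})

test_that("PCA satisfies the spectral identities", {
  st <- small_study()
  pav <- st$pav
  n_acc <- length(accession_ids(pav))
  pc <- pav_pca(pav, n_components = n_acc - 1)
  x <- t(pav$presence)
  xc <- scale(x, center = TRUE, scale = FALSE)

  # full reconstruction of the centered matrix
  recon <- pc$scores %*% t(pc$loadings)
  expect_lt(max(abs(recon - xc)), 1e-9)
  # explained variance sums to the total column variance
  expect_equal(sum(pc$explained_variance), 1, tolerance = 1e-9)
  expect_equal(pc$total_variance, sum(apply(xc, 2, var)),
               tolerance = 1e-9)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(pc$loadings))) {
    expect_gte(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }

  # identical accessions land on identical coordinates
  m <- st$pav$presence
  m2 <- cbind(m, clone = m[, 1])
  pc2 <- pav_pca(pav_matrix(m2), 2)
  expect_equal(pc2$scores[1, ], pc2$scores["clone", ])

  # rank-1 pattern explains everything on one axis
  r1 <- outer(rep(1L, 10), c(1L, 1L, 0L, 0L))
  dimnames(r1) <- list(sprintf("g%02d", 1:10), sprintf("a%d", 1:4))
  pcr <- pav_pca(pav_matrix(r1), 1)
  expect_equal(pcr$explained_variance[1], 1, tolerance = 1e-12)

  expect_error(pav_pca(pav, n_components = 10000), "exceeds")
})

test_that("newick io round-trips topology, lengths and supports", {
  tmp <- withr::local_tempfile(fileext = ".nwk")
  tr <- ape::read.tree(text = "(A:1,B:2,(C:3,D:4):1.5);")
  write_newick(tr, tmp)
  back <- read_newick(tmp)
  expect_identical(rf_distance(tr, back), 0L)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)

  st <- small_study()
  bs <- bootstrap_support(st$pav, n_reps = 10, seed = 3)
  write_newick(bs$tree, tmp)
  back2 <- read_newick(tmp)
  expect_identical(rf_distance(bs$tree, back2), 0L)
  expect_setequal(setdiff(back2$node.label, ""),
                  setdiff(bs$tree$node.label, ""))

  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:2;", bad)
  expect_error(read_newick(bad))
})
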