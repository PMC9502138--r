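block_matrix <- function() {
  # two blocks of identical rows: within-block distance 0, between 1
  binary_term_matrix(matrix(
    c(1, 1, 0, 0,
      1, 1, 0, 0,
      1, 1, 0, 0,
      0, 0, 1, 1,
      0, 0, 1, 1,
      0, 0, 1, 1), 6, 4, byrow = TRUE,
    dimnames = list(paste0("e", 1:6), c("a", "b", "c", "d"))))
}

test_that("jaccard distances match hand computations", {
  m <- binary_term_matrix(matrix(c(1, 0, 1, 1, 0, 1), 2, 3,
                                 dimnames = list(c("A", "B"),
                                                 c("t1", "t2", "t3"))))
  d <- as.matrix(distance_matrix(m, "jaccard"))
  expect_equal(d["A", "B"], 1 - 1 / 3, tolerance = 1e-12)

  ident <- build_matrix(list(A = "x", B = "x"))
  expect_equal(as.matrix(distance_matrix(ident))["A", "B"], 0)

  disjoint <- build_matrix(list(A = "x", B = "y"))
  expect_equal(as.matrix(distance_matrix(disjoint))["A", "B"], 1)

  zeros <- binary_term_matrix(matrix(c(1, 0, 0), 3, 1,
                                     dimnames = list(c("A", "B", "C"), "t")))
  dz <- as.matrix(distance_matrix(zeros))
  expect_equal(dz["B", "C"], 0)  # two all-zero rows: distance defined as 0
  expect_equal(dz["A", "B"], 1)

  expect_error(distance_matrix(build_matrix(list(A = "x"))),
               class = "litsim_validation_error")
})

test_that("pca scores are exact principal-component projections", {
  m <- binary_term_matrix(matrix(c(1, 0, 0, 1), 2, 2,
                                 dimnames = list(c("A", "B"), c("x", "y"))))
  e <- reduce_dimensions(m, "pca", d = 1)
  expect_equal(sort(unname(e[, 1])), c(-sqrt(0.5), sqrt(0.5)),
               tolerance = 1e-12)

  dup <- binary_term_matrix(matrix(
    c(1, 1, 0, 1, 1, 0, 0, 1, 1), 3, 3, byrow = TRUE,
    dimnames = list(c("A", "B", "C"), c("x", "y", "z"))))
  e <- reduce_dimensions(dup, "pca", d = 2)
  expect_equal(dim(e), c(3L, 2L))
  expect_equal(unname(e["A", ]), unname(e["B", ]))  # equal rows map equally
})

test_that("stochastic embeddings have the right shape and are seeded", {
  set.seed(99)
  m <- build_matrix(stats::setNames(
    lapply(1:12, function(i) sample(letters, 8)), paste0("e", 1:12)))
  for (method in c("tsne", "umap")) {
    e1 <- reduce_dimensions(m, method, d = 2, seed = 7)
    e2 <- reduce_dimensions(m, method, d = 2, seed = 7)
    expect_equal(dim(e1), c(12L, 2L))
    expect_true(all(is.finite(e1)))
    expect_identical(unclass(e1), unclass(e2))
  }
  expect_error(reduce_dimensions(m, "tsne", perplexity = 12),
               class = "litsim_validation_error")
})

test_that("hierarchical clustering recovers ideal blocks and cuts monotonely", {
  m <- block_matrix()
  d <- distance_matrix(m)
  for (linkage in c("ward", "average", "complete")) {
    p <- cluster_hierarchical(d, k = 2, linkage = linkage)
    expect_equal(unname(p[1:3]), rep(p[["e1"]], 3))
    expect_equal(unname(p[4:6]), rep(p[["e4"]], 3))
    expect_equal(length(unique(p)), 2L)
  }
  expect_equal(length(unique(cluster_hierarchical(d, k = 1))), 1L)
  expect_equal(length(unique(cluster_hierarchical(d, k = 6))), 6L)
  expect_error(cluster_hierarchical(d, k = 0),
               class = "litsim_validation_error")
  expect_error(cluster_hierarchical(d, k = 7),
               class = "litsim_validation_error")

  # cutting at k refines cutting at k - 1 along the merge tree
  for (k in 3:6) {
    coarse <- cluster_hierarchical(d, k = k - 1)
    fine <- cluster_hierarchical(d, k = k)
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
  }
})

test_that("k-means separates far clouds and is seed-deterministic", {
  coords <- rbind(matrix(rnorm(8, 0, 0.05), 4, 2),
                  matrix(rnorm(8, 10, 0.05), 4, 2))
  rownames(coords) <- paste0("e", 1:8)
  emb <- structure(coords, method = "pca", seed = 1L,
                   class = c("litsim_embedding", "matrix", "array"))
  p <- cluster_kmeans(emb, k = 2, seed = 5)
  expect_equal(length(unique(p[1:4])), 1L)
  expect_equal(length(unique(p[5:8])), 1L)
  expect_false(p[["e1"]] == p[["e5"]])
  expect_identical(p, cluster_kmeans(emb, k = 2, seed = 5))
  singletons <- cluster_kmeans(emb, k = 8, seed = 5)
  expect_equal(length(unique(singletons)), 8L)
})

test_that("adjusted Rand index worked examples hold", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # degenerate conventions
  expect_equal(adjusted_rand_index(1:5, 1:5), 1)
  expect_equal(adjusted_rand_index(rep(1, 5), rep("x", 5)), 1)
  # label types do not matter
  expect_equal(adjusted_rand_index(c("a", "a", "b", "b"), c(9, 9, 4, 4)), 1)
  expect_error(adjusted_rand_index(c(a = 1, b = 1), c(b = 1, c = 1)),
               class = "litsim_validation_error")
  expect_error(adjusted_rand_index(1:3, 1:4),
               class = "litsim_validation_error")
})

test_that("ARI matches the brute-force pair oracle on random partitions", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    p <- sample(1:4, n, replace = TRUE)
    q <- sample(1:4, n, replace = TRUE)
    expect_equal(adjusted_rand_index(p, q), ari_pair_oracle(p, q),
                 tolerance = 1e-12)
  }
})

test_that("ARI agrees with an independent library implementation", {
  skip_if_not_installed("mclust")
  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    p <- sample(1:5, n, replace = TRUE)
    q <- sample(1:5, n, replace = TRUE)
    expect_equal(adjusted_rand_index(p, q),
                 mclust::adjustedRandIndex(p, q), tolerance = 1e-12)
  }
})

test_that("top terms per cluster rank by within-cluster presence", {
  m <- binary_term_matrix(matrix(c(1, 1, 0, 1, 0, 1), 2, 3, byrow = TRUE,
                                 dimnames = list(c("A", "B"),
                                                 c("a", "b", "c"))))
  p <- stats::setNames(c(1L, 1L), c("A", "B"))
  # column presence counts 2, 1, 1: top-1 is "a"
  expect_equal(top_terms_per_cluster(m, p, n = 1), list(`1` = "a"))
  expect_equal(top_terms_per_cluster(m, p, n = 0), list(`1` = character()))

  q <- stats::setNames(c(1L, 2L), c("A", "B"))
  # singleton clusters report their own row's terms, lexicographic on ties
  expect_equal(top_terms_per_cluster(m, q, n = 5),
               list(`1` = c("a", "b"), `2` = c("a", "c")))
})

test_that("suggest_k finds the true block count by silhouette", {
  m <- block_matrix()
  expect_equal(suggest_k(distance_matrix(m), 2:4), 2L)

  three <- build_matrix(list(
    a1 = c("p", "q"), a2 = c("p", "q"), a3 = c("p", "q"),
    b1 = c("r", "s"), b2 = c("r", "s"), b3 = c("r", "s"),
    c1 = c("t", "u"), c2 = c("t", "u"), c3 = c("t", "u")))
  expect_equal(suggest_k(distance_matrix(three), 2:5), 3L)
  expect_error(suggest_k(distance_matrix(three), integer()),
               class = "litsim_validation_error")
  expect_error(suggest_k(distance_matrix(three), 2:9),
               class = "litsim_validation_error")
})
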