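#' Pairwise distances between entity term profiles
#'
#' Jaccard distance of two binary rows is `1 - |intersection| / |union|`;
#' the distance between two all-zero rows is defined as 0 so that entities
#' without usable text stay together rather than becoming maximally distant
#' from everything.
#'
#' @param matrix a [binary_term_matrix()] with at least two entities.
#' @param metric `"jaccard"` or `"euclidean"`.
#' @return A [stats::dist] object labelled with the entity identifiers.
#' @export
distance_matrix <- function(matrix, metric = c("jaccard", "euclidean")) {
  metric <- match.arg(metric)
  if (nrow(matrix) < 2) stop_validation("need at least 2 entities")
  m <- unclass(matrix)
  if (metric == "euclidean") return(stats::dist(m, method = "euclidean"))
  inter <- tcrossprod(m)
  rs <- rowSums(m)
  un <- outer(rs, rs, "+") - inter
  d <- 1 - inter / un
  d[un == 0] <- 0
  diag(d) <- 0
  stats::as.dist(d)
}

#' Embed the binary matrix in 2 or 3 dimensions
#'
#' PCA (the deterministic default) projects the centered rows onto the
#' leading principal components; t-SNE and UMAP are available for non-linear
#' structure and are reproducible bit-for-bit given `seed`.
#'
#' @param matrix a [binary_term_matrix()].
#' @param method `"pca"`, `"tsne"` or `"umap"`.
#' @param d embedding dimension (1, 2 or 3; reports use 2).
#' @param seed integer seed controlling the stochastic methods.
#' @param perplexity t-SNE perplexity; default `min(30, (n - 2) / 3)`. Must
#'   satisfy `3 * perplexity <= n - 2`.
#' @param n_neighbors UMAP neighborhood size (capped at `n - 1`).
#' @return A `litsim_embedding`: an `n x d` coordinate matrix with entity
#'   identifiers as row names and attributes `method` and `seed`.
#' @export
reduce_dimensions <- function(matrix, method = c("pca", "tsne", "umap"),
                              d = 2L, seed = 1L, perplexity = NULL,
                              n_neighbors = 15L) {
  method <- match.arg(method)
  n <- nrow(matrix)
  if (!d %in% c(1L, 2L, 3L)) stop_validation("d must be 1, 2 or 3")
  if (d > min(n, max(1L, ncol(matrix)))) {
    stop_validation("d exceeds the matrix rank bound min(entities, terms)")
  }
  if (method %in% c("tsne", "umap") && n < 3) {
    stop_validation(sprintf("%s needs at least 3 entities", method))
  }
  m <- unclass(matrix)
  storage.mode(m) <- "double"
  coords <- switch(method,
    pca = {
      p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
      scores <- p$x
      if (ncol(scores) < d) {  # rank-deficient input: pad constant axes
        scores <- cbind(scores, matrix(0, n, d - ncol(scores)))
      }
      scores[, seq_len(d), drop = FALSE]
    },
    tsne = {
      if (is.null(perplexity)) perplexity <- max(1, min(30, (n - 2) / 3))
      if (3 * perplexity > n - 1) {
        stop_validation(sprintf(
          "perplexity %.1f too large for %d entities; need 3*perplexity <= n-1 (try <= %.1f)",
          perplexity, n, (n - 1) / 3))
      }
      set.seed(seed)
      Rtsne::Rtsne(m, dims = d, perplexity = perplexity,
                   check_duplicates = FALSE, pca = TRUE,
                   max_iter = 500)$Y
    },
    umap = {
      set.seed(seed)
      uwot::umap(m, n_components = d,
                 n_neighbors = min(n_neighbors, n - 1),
                 n_threads = 1, n_sgd_threads = 0)
    })
  dimnames(coords) <- list(rownames(matrix), paste0("dim", seq_len(d)))
  structure(coords, method = method, seed = seed,
            class = c("litsim_embedding", class(matrix())))
}

#' Hierarchical clustering of entities
#'
#' Agglomerative clustering of the distance matrix, cut at `k` clusters.
#' `"ward"` uses the squared-distance Ward convention (`hclust`'s
#' `"ward.D2"`). The merge tree is attached for dendrogram export.
#'
#' @param dist a [stats::dist] from [distance_matrix()].
#' @param k number of clusters, `1 <= k <= n`.
#' @param linkage `"ward"`, `"average"` or `"complete"`.
#' @return A named integer vector of cluster labels (names are entity
#'   identifiers) with the `hclust` tree as attribute `"tree"`.
#' @export
cluster_hierarchical <- function(dist, k, linkage = c("ward", "average",
                                                      "complete")) {
  linkage <- match.arg(linkage)
  n <- attr(dist, "Size")
  if (k < 1 || k > n) stop_validation(sprintf("k must be in [1, %d]", n))
  method <- c(ward = "ward.D2", average = "average",
              complete = "complete")[[linkage]]
  tree <- stats::hclust(dist, method = method)
  labels <- stats::cutree(tree, k = k)
  structure(labels, tree = tree)
}

#' k-means clustering of an embedding
#'
#' Lloyd-style k-means on the embedding coordinates with a fixed number of
#' random restarts (best within-cluster sum of squares kept); deterministic
#' given `seed`.
#'
#' @param embedding a `litsim_embedding` from [reduce_dimensions()].
#' @param k number of clusters.
#' @param seed integer seed.
#' @param nstart number of random restarts.
#' @return Named integer vector of cluster labels.
#' @export
cluster_kmeans <- function(embedding, k, seed = 1L, nstart = 25L) {
  n <- nrow(embedding)
  if (k < 1 || k > n) stop_validation(sprintf("k must be in [1, %d]", n))
  if (k == n) {  # all singletons, inertia 0 (stats::kmeans refuses k = n)
    return(stats::setNames(seq_len(n), rownames(embedding)))
  }
  set.seed(seed)
  fit <- stats::kmeans(unclass(embedding), centers = k, nstart = nstart,
                       iter.max = 100L)
  stats::setNames(fit$cluster, rownames(embedding))
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance: with contingency counts
#' \eqn{n_{ij}}, row sums \eqn{a_i}, column sums \eqn{b_j} and \eqn{n}
#' entities,
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}{\tfrac12\left[\sum_i
#'   \binom{a_i}{2} + \sum_j \binom{b_j}{2}\right] - E}, \quad
#'   E = \sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2} / \binom{n}{2}.}
#' It is invariant under label renaming, equals 1 iff the partitions are
#' identical up to relabeling, and is about 0 for random agreement. The
#' degenerate cases (both partitions all singletons, or both one single
#' cluster) are defined as 1.
#'
#' @param p,q partitions over the same entities in the same order: label
#'   vectors (any atomic type), named with entity identifiers or unnamed.
#'   When both are named, the names must match.
#' @return The ARI, a number `<= 1`.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same partition
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
adjusted_rand_index <- function(p, q) {
  if (length(p) != length(q)) {
    stop_validation("partitions must cover the same entities")
  }
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q))) {
    stop_validation("partitions are over different entity lists")
  }
  n <- length(p)
  tab <- table(as.character(p), as.character(q))
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}

#' Most frequent terms per cluster
#'
#' For each cluster, ranks terms by within-cluster presence count (how many
#' of the cluster's entities selected the term), ties broken
#' lexicographically, and returns the top `n` terms actually present.
#'
#' @param matrix a [binary_term_matrix()].
#' @param partition named label vector over the same entities.
#' @param n number of terms per cluster.
#' @return Named list mapping cluster label -> character vector of terms.
#' @export
top_terms_per_cluster <- function(matrix, partition, n = 10L) {
  if (length(partition) != nrow(matrix) ||
      (!is.null(names(partition)) &&
       !identical(names(partition), rownames(matrix)))) {
    stop_validation("partition and matrix cover different entities")
  }
  out <- lapply(split(seq_len(nrow(matrix)), partition), function(idx) {
    counts <- colSums(matrix[idx, , drop = FALSE])
    counts <- counts[counts > 0]
    ord <- order(-counts, names(counts), method = "radix")
    utils::head(names(counts)[ord], n)
  })
  out
}

#' Suggest a cluster count by silhouette
#'
#' Cuts the hierarchical tree at each candidate `k` and returns the `k`
#' maximizing the mean silhouette width; ties go to the smallest `k`.
#'
#' @param dist a [stats::dist].
#' @param k_range integer vector of candidate cluster counts, each within
#'   `[2, n - 1]`.
#' @param linkage passed to [cluster_hierarchical()].
#' @return The selected `k`.
#' @export
suggest_k <- function(dist, k_range, linkage = "ward") {
  n <- attr(dist, "Size")
  if (!length(k_range)) stop_validation("k_range is empty")
  if (any(k_range < 2 | k_range > n - 1)) {
    stop_validation(sprintf("k_range must lie within [2, %d]", n - 1))
  }
  scores <- vapply(k_range, function(k) {
    labels <- cluster_hierarchical(dist, k = k, linkage = linkage)
    mean(cluster::silhouette(as.integer(factor(labels)), dist)[, "sil_width"])
  }, numeric(1))
  k_range[which.max(scores)]
}
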