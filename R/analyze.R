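#' Analyze a binary term matrix and write a static report
#'
#' The downstream analysis stage: embeds the matrix in two dimensions,
#' clusters the entities, summarizes each cluster's discriminating terms
#' and, when a grouping variable is supplied, quantifies the agreement
#' between the text-derived clusters and the grouping with the adjusted
#' Rand index. Results are written as a directory of static artifacts:
#' \describe{
#'   \item{`labels.tsv`}{entity, cluster label, grouping label (if any) and
#'     an `ALL_ZERO` flag for entities whose term profile is empty (they are
#'     kept, not dropped, so partitions stay aligned).}
#'   \item{`embedding.tsv`}{entity coordinates.}
#'   \item{`cluster_terms.tsv`}{per-cluster top terms with presence counts.}
#'   \item{`ari.txt`}{the ARI against the grouping variable (only written
#'     when one is supplied).}
#'   \item{`embedding.png`, `dendrogram.png`}{scatter plot colored by
#'     grouping (or cluster), and the hierarchical merge tree.}
#' }
#'
#' @param matrix a [binary_term_matrix()].
#' @param meta optional [entity_table()] carrying grouping columns.
#' @param group_col name of the grouping column in `meta` to compare
#'   against.
#' @param reduce embedding method (see [reduce_dimensions()]).
#' @param metric distance metric (see [distance_matrix()]).
#' @param cluster `"hclust"` (hierarchical on the distance matrix) or
#'   `"kmeans"` (on the embedding).
#' @param k number of clusters, or `"auto"`: the number of distinct grouping
#'   labels when a grouping is supplied, otherwise the silhouette-selected k
#'   over `2..min(10, n - 1)` (see [suggest_k()]).
#' @param seed integer seed for the stochastic steps.
#' @param n_terms top terms reported per cluster.
#' @param outdir report directory (created if needed); `NULL` skips writing.
#' @return (invisibly) a list with `labels`, `embedding`, `ari` (or `NA`),
#'   `k`, `grouping` and `cluster_terms`.
#' @export
analyze_matrix <- function(matrix, meta = NULL, group_col = NULL,
                           reduce = c("pca", "tsne", "umap"),
                           metric = c("jaccard", "euclidean"),
                           cluster = c("hclust", "kmeans"), k = "auto",
                           seed = 7L, n_terms = 10L, outdir = NULL) {
  reduce <- match.arg(reduce)
  metric <- match.arg(metric)
  cluster <- match.arg(cluster)
  n <- nrow(matrix)
  if (n < 2) stop_validation("need at least 2 entities to analyze")

  grouping <- NULL
  if (!is.null(group_col)) {
    if (is.null(meta)) stop_validation("group_col given without meta table")
    if (!group_col %in% names(meta)) {
      stop_validation(sprintf("grouping column '%s' not in meta table",
                              group_col))
    }
    idx <- match(rownames(matrix), meta$entity_id)
    if (anyNA(idx)) {
      stop_validation(sprintf("entities missing from meta table: %s",
        paste(rownames(matrix)[is.na(idx)], collapse = ", ")))
    }
    grouping <- stats::setNames(meta[[group_col]][idx], rownames(matrix))
  }

  if (identical(k, "auto")) {
    k <- if (!is.null(grouping)) {
      length(unique(grouping))
    } else {
      suggest_k(distance_matrix(matrix, metric),
                2:max(2, min(10, n - 1)))
    }
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1 || k > n) {
    stop_validation(sprintf("k must be in [1, %d]", n))
  }

  d <- distance_matrix(matrix, metric)
  embedding <- reduce_dimensions(matrix, method = reduce, d = 2L, seed = seed)
  partition <- if (cluster == "hclust") {
    cluster_hierarchical(d, k = k)
  } else {
    cluster_kmeans(embedding, k = k, seed = seed)
  }
  ari <- if (!is.null(grouping)) {
    adjusted_rand_index(partition, grouping)
  } else NA_real_
  terms <- top_terms_per_cluster(matrix, partition, n = n_terms)
  zero_row <- rowSums(matrix) == 0

  res <- list(labels = partition, embedding = embedding, ari = ari, k = k,
              grouping = grouping, cluster_terms = terms,
              zero_row = zero_row)
  if (!is.null(outdir)) write_report(res, matrix, outdir)
  invisible(res)
}

write_report <- function(res, matrix, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  labels <- data.frame(ID = rownames(matrix),
                       CLUSTER = as.integer(res$labels),
                       stringsAsFactors = FALSE)
  if (!is.null(res$grouping)) labels$GROUP <- unname(res$grouping)
  labels$ALL_ZERO <- ifelse(res$zero_row, "1", "0")
  write_tsv_strict(labels, file.path(outdir, "labels.tsv"))

  emb <- data.frame(ID = rownames(res$embedding),
                    unclass(res$embedding)[, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(emb, file.path(outdir, "embedding.tsv"))

  ct <- do.call(rbind, lapply(names(res$cluster_terms), function(cl) {
    t <- res$cluster_terms[[cl]]
    if (!length(t)) return(NULL)
    data.frame(CLUSTER = cl, RANK = seq_along(t), TERM = t,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ct)) {
    ct <- data.frame(CLUSTER = character(), RANK = integer(),
                     TERM = character())
  }
  write_tsv_strict(ct, file.path(outdir, "cluster_terms.tsv"))

  if (!is.na(res$ari)) {
    writeLines(format(res$ari, digits = 15), file.path(outdir, "ari.txt"))
  }

  plot_df <- data.frame(dim1 = res$embedding[, 1], dim2 = res$embedding[, 2],
                        color = if (!is.null(res$grouping)) {
                          unname(res$grouping)
                        } else as.character(res$labels))
  p <- ggplot2::ggplot(plot_df, ggplot2::aes(dim1, dim2, color = color)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(color = if (!is.null(res$grouping)) "group" else "cluster",
                  x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
  suppressMessages(ggplot2::ggsave(file.path(outdir, "embedding.png"), p,
                                   width = 6, height = 5, dpi = 150))

  tree <- attr(res$labels, "tree")
  if (!is.null(tree)) {
    grDevices::png(file.path(outdir, "dendrogram.png"),
                   width = 900, height = 600)
    plot(tree, hang = -1, main = "", sub = "", xlab = "", cex = 0.8)
    grDevices::dev.off()
  }
  invisible(NULL)
}
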