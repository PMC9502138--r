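#' Specification of a topic-structured synthetic corpus
#'
#' Describes a corpus with `k_topics` latent topics. Each topic has a
#' characteristic vocabulary of `topic_vocab_size` words, pairwise disjoint
#' across topics and disjoint from a shared noise vocabulary of
#' `shared_vocab_size` words. Each of the `k_topics * entities_per_topic`
#' entities is assigned to one topic and receives `docs_per_entity`
#' documents of `words_per_doc` words drawn i.i.d.: with probability
#' `noise_fraction` uniformly from the shared vocabulary, otherwise
#' uniformly from the entity's topic vocabulary. The topic assignments are
#' the ground-truth partition, standing in for an expert-curated grouping.
#'
#' @param k_topics number of latent topics (>= 1).
#' @param entities_per_topic entities assigned to each topic (>= 1).
#' @param topic_vocab_size characteristic words per topic (>= 1).
#' @param shared_vocab_size shared noise words (>= 0; >= 1 when
#'   `noise_fraction` is 1).
#' @param docs_per_entity documents per entity (>= 1).
#' @param words_per_doc words per document (>= 1).
#' @param noise_fraction probability in `[0, 1]` that a word is drawn from
#'   the shared vocabulary.
#' @param seed integer seed; the corpus is deterministic given the spec.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(k_topics = 4L, entities_per_topic = 10L,
                        topic_vocab_size = 30L, shared_vocab_size = 100L,
                        docs_per_entity = 20L, words_per_doc = 50L,
                        noise_fraction = 0.3, seed = 1L) {
  spec <- list(k_topics = as.integer(k_topics),
               entities_per_topic = as.integer(entities_per_topic),
               topic_vocab_size = as.integer(topic_vocab_size),
               shared_vocab_size = as.integer(shared_vocab_size),
               docs_per_entity = as.integer(docs_per_entity),
               words_per_doc = as.integer(words_per_doc),
               noise_fraction = as.numeric(noise_fraction),
               seed = as.integer(seed))
  counts <- spec[c("k_topics", "entities_per_topic", "topic_vocab_size",
                   "docs_per_entity", "words_per_doc")]
  if (any(unlist(counts) < 1L)) {
    stop_validation("all corpus counts must be >= 1")
  }
  if (spec$shared_vocab_size < 0L) {
    stop_validation("shared_vocab_size must be >= 0")
  }
  if (spec$noise_fraction < 0 || spec$noise_fraction > 1) {
    stop_validation("noise_fraction must lie in [0, 1]")
  }
  if (spec$noise_fraction == 1 && spec$shared_vocab_size < 1L) {
    stop_validation("noise_fraction = 1 requires shared_vocab_size >= 1")
  }
  structure(spec, class = "corpus_spec")
}

# Pronounceable nonsense words (alternating consonant/vowel syllables, >= 6
# letters, no digits, screened against the stopword list) so the default
# tokenization passes every synthetic word through unchanged.
synthetic_words <- function(n) {
  consonants <- strsplit("bcdfghjklmnprstvwz", "")[[1]]
  vowels <- strsplit("aeiou", "")[[1]]
  words <- character(0)
  while (length(words) < n) {
    batch <- replicate(max(2L * (n - length(words)), 16L), paste0(
      paste0(sample(consonants, 3, replace = TRUE),
             sample(vowels, 3, replace = TRUE), collapse = "")))
    words <- unique(c(words, setdiff(batch, STOPWORDS_EN)))
  }
  words[seq_len(n)]
}

#' Generate a synthetic corpus with known ground truth
#'
#' @param spec a [corpus_spec()].
#' @return A list with elements `table` (an [entity_table()] whose texts are
#'   the sampled documents and whose `CATEGORY` grouping column holds the
#'   topic assignment) and `truth` (the ground-truth partition: named topic
#'   labels in table order).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  n_entities <- spec$k_topics * spec$entities_per_topic
  vocab <- synthetic_words(spec$k_topics * spec$topic_vocab_size +
                             spec$shared_vocab_size)
  topic_vocab <- split(utils::head(vocab, spec$k_topics * spec$topic_vocab_size),
                       rep(seq_len(spec$k_topics), each = spec$topic_vocab_size))
  shared_vocab <- utils::tail(vocab, spec$shared_vocab_size)
  topic_of <- rep(seq_len(spec$k_topics), each = spec$entities_per_topic)
  ids <- sprintf("entity_%0*d", nchar(n_entities), seq_len(n_entities))
  texts <- lapply(seq_len(n_entities), function(i) {
    own <- topic_vocab[[topic_of[i]]]
    vapply(seq_len(spec$docs_per_entity), function(j) {
      from_shared <- stats::runif(spec$words_per_doc) < spec$noise_fraction
      words <- character(spec$words_per_doc)
      if (any(!from_shared)) {
        words[!from_shared] <- sample(own, sum(!from_shared), replace = TRUE)
      }
      if (any(from_shared)) {
        words[from_shared] <- sample(shared_vocab, sum(from_shared),
                                     replace = TRUE)
      }
      paste(words, collapse = " ")
    }, character(1))
  })
  topic_label <- sprintf("topic_%d", topic_of)
  table <- entity_table(ids,
                        grouping = data.frame(CATEGORY = topic_label,
                                              stringsAsFactors = FALSE),
                        texts = texts)
  list(table = table,
       truth = stats::setNames(topic_label, ids),
       topic_vocabularies = topic_vocab,
       shared_vocabulary = shared_vocab)
}

#' Topic-recovery experiment
#'
#' Runs the full offline pipeline on a synthetic corpus and measures how
#' well text-derived clusters recover the ground-truth topics: generate the
#' corpus, build the binary word matrix, cluster hierarchically at
#' `k = k_topics`, and return the adjusted Rand index against the truth.
#' This mirrors, at desk scale, validating literature-derived gene clusters
#' against expert-curated disorder categories.
#'
#' @param spec a [corpus_spec()].
#' @param n_top top words kept per entity.
#' @param metric distance metric (see [distance_matrix()]).
#' @param linkage linkage (see [cluster_hierarchical()]).
#' @param options a [tokenization_options()].
#' @return The ARI between recovered clusters and ground-truth topics.
#' @export
recovery_experiment <- function(spec, n_top = 50L, metric = "jaccard",
                                linkage = "ward",
                                options = tokenization_options()) {
  corpus <- generate_corpus(spec)
  if (spec$k_topics * spec$entities_per_topic == 1L) return(1)
  mat <- text_to_wordmatrix(corpus$table, n_top = n_top, options = options)
  if (spec$k_topics == 1L) {
    # a single topic is the one-cluster degenerate case
    labels <- stats::setNames(rep(1L, nrow(mat)), rownames(mat))
  } else {
    d <- distance_matrix(mat, metric = metric)
    labels <- cluster_hierarchical(d, k = spec$k_topics, linkage = linkage)
  }
  adjusted_rand_index(labels, corpus$truth[rownames(mat)])
}
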