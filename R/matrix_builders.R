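#' Count vocabulary terms for one entity
#'
#' Tokenizes all of an entity's collected texts and sums raw token
#' occurrences across them. With `exclude_self` enabled (the default), any
#' token that also appears in the tokenized form of the entity's identifier
#' or query is removed before counting.
#'
#' @param entity_id the entity's identifier.
#' @param texts character vector of the entity's texts.
#' @param query the entity's query (`NA` when absent); only used for
#'   self-token exclusion.
#' @param options a [tokenization_options()].
#' @return Named integer vector of strictly positive counts (possibly empty).
#' @export
count_terms <- function(entity_id, texts, query = NA_character_,
                        options = tokenization_options()) {
  tokens <- unlist(lapply(texts, tokenize, options = options),
                   use.names = FALSE)
  if (isTRUE(options$exclude_self)) {
    self <- tokenize(paste(entity_id, if (!is.na(query)) query else ""),
                     options)
    tokens <- tokens[!tokens %in% self]
  }
  if (!length(tokens)) return(integer())
  counts <- table(tokens)
  stats::setNames(as.integer(counts), names(counts))
}

#' Count concept-annotation terms for one entity
#'
#' Counts normalized PubTator concepts over the annotations belonging to the
#' entity's PMIDs. Counting is per-document presence: a concept mentioned
#' five times within one abstract contributes 1 for that abstract (concept
#' annotations repeat heavily within an abstract and would otherwise
#' dominate the frequency ranks).
#'
#' @param pmids the entity's PMIDs.
#' @param annotations data frame from [fetch_annotations()] (already
#'   category-filtered).
#' @param by_id passed to [normalize_concepts()].
#' @return Named integer vector of counts: number of the entity's abstracts
#'   in which each concept occurs.
#' @export
count_concepts <- function(pmids, annotations, by_id = TRUE) {
  ann <- annotations[annotations$pmid %in% pmids, , drop = FALSE]
  if (!nrow(ann)) return(integer())
  term <- normalize_concepts(ann, by_id = by_id)
  per_doc <- unique(data.frame(pmid = ann$pmid, term = term,
                               stringsAsFactors = FALSE))
  counts <- table(per_doc$term)
  stats::setNames(as.integer(counts), names(counts))
}

#' Select an entity's most frequent terms
#'
#' Returns the `n_top` highest-count terms, ties broken lexicographically;
#' when the vocabulary is smaller than `n_top`, all terms are returned.
#'
#' @param counts named integer vector of term counts.
#' @param n_top number of terms to keep (>= 0).
#' @return Character vector of selected terms, highest count first.
#' @export
select_top_terms <- function(counts, n_top) {
  if (n_top < 0) stop_validation("n_top must be non-negative")
  if (!length(counts) || n_top == 0) return(character())
  ord <- order(-as.integer(counts), names(counts), method = "radix")
  utils::head(names(counts)[ord], n_top)
}

#' Assemble the binary term matrix from per-entity term selections
#'
#' The term set is the sorted union of all selected terms; cell `(e, t)` is 1
#' iff `t` is in entity `e`'s selection. Entities with empty selections
#' become all-zero rows (and are kept, so partitions stay aligned); the
#' construction guarantees no all-zero term column exists.
#'
#' @param selections named list mapping entity identifier -> character vector
#'   of selected terms.
#' @return A [binary_term_matrix()].
#' @export
build_matrix <- function(selections) {
  ids <- names(selections)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop_validation("selections must be a uniquely named list")
  }
  terms <- sort(unique(unlist(selections, use.names = FALSE)))
  cells <- matrix(0L, length(ids), length(terms),
                  dimnames = list(ids, terms))
  for (i in seq_along(ids)) {
    cells[i, match(unique(selections[[i]]), terms)] <- 1L
  }
  binary_term_matrix(cells)
}

#' Entity texts to binary word matrix
#'
#' The word pipeline: for every entity in the table, tokenize and count its
#' collected texts ([count_terms()]), keep the `n_top` most frequent words
#' ([select_top_terms()]), and assemble the entity-by-term presence matrix
#' ([build_matrix()]).
#'
#' @param table an [entity_table()] with texts.
#' @param n_top number of top words kept per entity (default 50).
#' @param options a [tokenization_options()].
#' @return A [binary_term_matrix()].
#' @export
text_to_wordmatrix <- function(table, n_top = 50L,
                               options = tokenization_options()) {
  stopifnot(inherits(table, "entity_table"))
  selections <- lapply(seq_len(nrow(table)), function(i) {
    counts <- count_terms(table$entity_id[i], table$texts[[i]],
                          table$query[i], options)
    select_top_terms(counts, n_top)
  })
  names(selections) <- table$entity_id
  build_matrix(selections)
}

#' Entity PMIDs to binary concept matrix
#'
#' The concept pipeline: fetches PubTator annotations for all PMIDs in the
#' table, counts per-entity concept presence ([count_concepts()]), keeps the
#' `n_top` most frequent concepts per entity and assembles the matrix.
#'
#' @param table an [entity_table()] with PMIDs.
#' @param categories concept categories to extract (see
#'   [fetch_annotations()]).
#' @param transport a [transports] function.
#' @param by_id normalize concepts by identifier (see
#'   [normalize_concepts()])?
#' @param n_top number of top concepts kept per entity (default 50).
#' @return A [binary_term_matrix()].
#' @export
pmids_to_pubtator_matrix <- function(table, categories, transport,
                                     by_id = TRUE, n_top = 50L) {
  stopifnot(inherits(table, "entity_table"))
  all_pmids <- unique(unlist(table$pmids, use.names = FALSE))
  annotations <- fetch_annotations(all_pmids, categories, transport)
  selections <- lapply(table$pmids, function(p) {
    select_top_terms(count_concepts(p, annotations, by_id = by_id), n_top)
  })
  names(selections) <- table$entity_id
  build_matrix(selections)
}
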