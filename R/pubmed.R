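#' Search PubMed for PMIDs matching a query
#'
#' Runs an ESearch query (PubMed's own keyword search rules and syntax apply)
#' and returns up to `max_n` PMIDs in the service's return order. Paging is
#' handled internally; the result is deduplicated preserving order. With
#' `max_n = 0` no request is made.
#'
#' @param query a non-empty PubMed query string.
#' @param max_n maximum number of PMIDs to return.
#' @param transport a [transports] function.
#' @param page_size ESearch `retmax` per request.
#' @return Character vector of PMIDs.
#' @export
search_pmids <- function(query, max_n, transport, page_size = 500L) {
  if (!is.character(query) || length(query) != 1L || !nzchar(query)) {
    stop_validation("query must be a non-empty string")
  }
  if (max_n < 0) stop_validation("max_n must be non-negative")
  if (max_n == 0) return(character())
  ids <- character()
  retstart <- 0L
  repeat {
    payload <- transport("esearch", list(
      term = query, retstart = retstart,
      retmax = min(page_size, max_n - length(ids))))
    page <- parse_esearch(payload)
    ids <- c(ids, page$ids)
    retstart <- retstart + length(page$ids)
    if (length(ids) >= max_n || retstart >= page$count || !length(page$ids)) break
  }
  ids <- ids[!duplicated(ids)]
  utils::head(ids, max_n)
}

parse_esearch <- function(payload) {
  doc <- tryCatch(xml2::read_xml(payload),
                  error = function(e) stop_parse(sprintf(
                    "malformed ESearch payload: %s", conditionMessage(e))))
  list(
    count = as.integer(xml2::xml_text(xml2::xml_find_first(doc, ".//Count"))),
    ids = xml2::xml_text(xml2::xml_find_all(doc, ".//IdList/Id"))
  )
}

#' Fetch abstracts for a list of PMIDs
#'
#' EFetch requests are batched (at most 200 PMIDs per call). The result has
#' one row per input PMID that has an abstract, in input order; PMIDs whose
#' citation lacks an abstract (common for old records) are dropped with a
#' logged skip. Markup is stripped and whitespace collapsed, and the article
#' title is prepended to the abstract body unless `include_title = FALSE`.
#'
#' @param pmids character vector of PMIDs (digits only).
#' @param transport a [transports] function.
#' @param include_title prepend the article title to the abstract text?
#' @return Data frame with columns `pmid` and `text`.
#' @export
fetch_abstracts <- function(pmids, transport, include_title = TRUE) {
  pmids <- clean_pmids(pmids)
  if (!length(pmids)) return(data.frame(pmid = character(), text = character()))
  batches <- split(pmids, ceiling(seq_along(pmids) / 200))
  recs <- do.call(rbind, lapply(batches, function(batch) {
    payload <- tryCatch(
      transport("efetch", list(id = paste(batch, collapse = ","))),
      error = function(e) {
        if (inherits(e, "litsim_retrieval_error")) {
          stop_retrieval(sprintf("abstract fetch failed for batch [%s]: %s",
                                 paste(batch, collapse = ","),
                                 conditionMessage(e)))
        }
        stop(e)
      })
    parse_efetch(payload)
  }))
  rownames(recs) <- NULL
  recs <- recs[match(pmids, recs$pmid), , drop = FALSE]
  recs <- recs[!is.na(recs$pmid), , drop = FALSE]
  have <- !is.na(recs$abstract) & nzchar(recs$abstract)
  skipped <- setdiff(pmids, recs$pmid[have])
  if (length(skipped)) {
    message(sprintf("skipping %d PMID(s) without an abstract: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  recs <- recs[have, , drop = FALSE]
  text <- if (include_title) {
    trimws(paste(recs$title, recs$abstract))
  } else recs$abstract
  data.frame(pmid = recs$pmid, text = text, stringsAsFactors = FALSE)
}

parse_efetch <- function(payload) {
  doc <- tryCatch(xml2::read_xml(payload),
                  error = function(e) stop_parse(sprintf(
                    "malformed EFetch payload: %s", conditionMessage(e))))
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  collapse_ws <- function(x) trimws(gsub("\\s+", " ", x))
  df <- lapply(arts, function(a) {
    abs_nodes <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    data.frame(
      pmid = xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID")),
      title = collapse_ws(xml2::xml_text(
        xml2::xml_find_first(a, ".//Article/ArticleTitle"))),
      abstract = if (length(abs_nodes)) {
        collapse_ws(paste(xml2::xml_text(abs_nodes), collapse = " "))
      } else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, df)
  if (is.null(out)) {
    out <- data.frame(pmid = character(), title = character(),
                      abstract = character(), stringsAsFactors = FALSE)
  }
  out$title[is.na(out$title)] <- ""
  out
}

#' Populate an entity table from PubMed queries
#'
#' Runs each record's query through [search_pmids()]. With `mode = "pmids"`
#' the hits fill the record's `pmids`; with `mode = "abstracts"` the hits are
#' additionally passed through [fetch_abstracts()] and the abstracts are
#' appended to the record's `texts` (pre-existing custom texts are kept, and
#' the searched PMIDs are recorded too, so a downstream concept-annotation
#' stage does not need to re-search). Records whose query returns nothing are
#' kept unchanged with a logged warning.
#'
#' @param table an [entity_table()]; every record must have a query.
#' @param mode `"pmids"` or `"abstracts"`.
#' @param max_n maximum PMIDs per entity.
#' @param transport a [transports] function.
#' @param include_title passed to [fetch_abstracts()].
#' @return A new [entity_table()]; the input is not modified.
#' @export
populate_by_queries <- function(table, mode = c("pmids", "abstracts"),
                                max_n = 100L, transport,
                                include_title = TRUE) {
  stopifnot(inherits(table, "entity_table"))
  mode <- match.arg(mode)
  missing_q <- table$entity_id[is.na(table$query)]
  if (length(missing_q)) {
    stop_validation(sprintf("entities without a query: %s",
                            paste(missing_q, collapse = ", ")))
  }
  pmids <- table$pmids
  texts <- table$texts
  for (i in seq_len(nrow(table))) {
    hits <- search_pmids(table$query[i], max_n, transport)
    if (!length(hits)) {
      message(sprintf("query for entity '%s' returned no PMIDs",
                      table$entity_id[i]))
      next
    }
    pmids[[i]] <- hits
    if (mode == "abstracts") {
      fetched <- fetch_abstracts(hits, transport, include_title)
      texts[[i]] <- c(texts[[i]], fetched$text)
    }
  }
  entity_table(table$entity_id,
               grouping = table[, grouping_columns(table), drop = FALSE],
               query = table$query, pmids = pmids, texts = texts)
}

#' Fetch abstracts for pre-curated PMIDs
#'
#' For every record that has PMIDs, fetches the corresponding abstracts and
#' appends them to the record's `texts`; custom text already present is
#' preserved, so it is analyzed in addition to the collected abstracts.
#' Records without PMIDs are left unchanged.
#'
#' @inheritParams populate_by_queries
#' @return A new [entity_table()].
#' @export
populate_abstracts_by_pmids <- function(table, transport, include_title = TRUE) {
  stopifnot(inherits(table, "entity_table"))
  if (!any(lengths(table$pmids) > 0)) {
    stop_validation("no record has PMIDs to fetch abstracts for")
  }
  texts <- table$texts
  for (i in seq_len(nrow(table))) {
    if (!length(table$pmids[[i]])) next
    fetched <- fetch_abstracts(table$pmids[[i]], transport, include_title)
    texts[[i]] <- c(texts[[i]], fetched$text)
  }
  entity_table(table$entity_id,
               grouping = table[, grouping_columns(table), drop = FALSE],
               query = table$query, pmids = table$pmids, texts = texts)
}
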