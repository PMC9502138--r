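#' Transports: pluggable request executors for the retrieval clients
#'
#' A transport is a function `(endpoint, params) -> character payload` for the
#' endpoints `"esearch"` (PubMed ESearch), `"efetch"` (PubMed EFetch, abstract
#' XML) and `"pubtator"` (PubTator concept annotations). The retrieval clients
#' are written against this contract only, so a fixture transport that replays
#' packaged payloads makes the whole retrieval layer deterministic and
#' network-free, while the live transport talks to the NCBI services.
#'
#' @name transports
NULL

#' Fixture transport: replay packaged payloads
#'
#' Reads a fixture directory and renders, on request, the same wire formats
#' the live services return (E-utilities XML, PubTator tab-separated format),
#' so the payload parsers are exercised identically offline. The directory
#' may contain:
#' \describe{
#'   \item{`queries.json`}{object mapping query string -> array of PMIDs, in
#'     relevance order (the full hit list; paging is emulated).}
#'   \item{`abstracts.json`}{object mapping PMID -> `{title, abstract}`; an
#'     empty/absent abstract renders a citation without an abstract body.}
#'   \item{`annotations.tsv`}{columns `pmid`, `type`, `concept_id`, `mention`
#'     (PubTator concept types, e.g. `Gene`, `Disease`).}
#' }
#'
#' @param dir fixture directory.
#' @return A transport function.
#' @export
fixture_transport <- function(dir) {
  if (!dir.exists(dir)) stop_input_format(sprintf("no fixture directory: %s", dir))
  read_json_if <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) jsonlite::read_json(p) else list()
  }
  queries <- read_json_if("queries.json")
  abstracts <- read_json_if("abstracts.json")
  ann_path <- file.path(dir, "annotations.tsv")
  annotations <- if (file.exists(ann_path)) read_tsv_strict(ann_path) else
    data.frame(pmid = character(), type = character(),
               concept_id = character(), mention = character())

  function(endpoint, params) {
    switch(endpoint,
      esearch = {
        hits <- unlist(queries[[params$term]]) %||% character()
        retstart <- params$retstart %||% 0L
        retmax <- params$retmax %||% 20L
        page <- hits[seq_along(hits) > retstart][seq_len(min(retmax, max(0, length(hits) - retstart)))]
        id_nodes <- if (length(page)) {
          paste0("<Id>", page, "</Id>", collapse = "")
        } else ""
        paste0("<eSearchResult><Count>", length(hits), "</Count>",
               "<RetStart>", retstart, "</RetStart><IdList>",
               id_nodes, "</IdList></eSearchResult>")
      },
      efetch = {
        ids <- strsplit(params$id, ",", fixed = TRUE)[[1]]
        arts <- vapply(ids, function(id) {
          rec <- abstracts[[id]]
          if (is.null(rec)) return("")
          abs_node <- if (!is.null(rec$abstract) && nzchar(rec$abstract)) {
            paste0("<Abstract><AbstractText>", xml_escape(rec$abstract),
                   "</AbstractText></Abstract>")
          } else ""
          paste0("<PubmedArticle><MedlineCitation><PMID>", id, "</PMID>",
                 "<Article><ArticleTitle>", xml_escape(rec$title %||% ""),
                 "</ArticleTitle>", abs_node,
                 "</Article></MedlineCitation></PubmedArticle>")
        }, character(1))
        paste0("<PubmedArticleSet>", paste0(arts, collapse = ""),
               "</PubmedArticleSet>")
      },
      pubtator = {
        ids <- strsplit(params$pmids, ",", fixed = TRUE)[[1]]
        rows <- annotations[annotations$pmid %in% ids, , drop = FALSE]
        if (!nrow(rows)) return("")
        paste0(paste(rows$pmid, "0", "1", rows$mention, rows$type,
                     rows$concept_id, sep = "\t"), collapse = "\n")
      },
      stop_validation(sprintf("unknown endpoint: %s", endpoint))
    )
  }
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Live transport: NCBI E-utilities and PubTator over HTTP
#'
#' Enforces the NCBI rate limit (3 requests/second without an API key, 10
#' with one) and retries transient failures up to three times with
#' exponential backoff. Requires network access.
#'
#' @param api_key optional NCBI API key.
#' @param retries number of retries on failure.
#' @return A transport function.
#' @export
live_transport <- function(api_key = NULL, retries = 3L) {
  min_gap <- if (is.null(api_key)) 1 / 3 else 1 / 10
  last <- 0
  eutils <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"
  pubtator <- "https://www.ncbi.nlm.nih.gov/research/pubtator-api/publications/export/pubtator"

  http_get <- function(full_url) {
    wait <- min_gap - (as.numeric(Sys.time()) - last)
    if (wait > 0) Sys.sleep(wait)
    last <<- as.numeric(Sys.time())
    for (attempt in seq_len(retries + 1L)) {
      res <- tryCatch({
        con <- url(full_url, open = "rb")
        on.exit(close(con), add = TRUE)
        paste(readLines(con, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
      }, error = function(e) e)
      if (!inherits(res, "error")) return(res)
      if (attempt <= retries) Sys.sleep(2 ^ (attempt - 1))
    }
    stop_retrieval(sprintf("request failed after %d retries: %s",
                           retries, full_url))
  }

  function(endpoint, params) {
    if (!is.null(api_key)) params$api_key <- api_key
    qs <- paste(names(params),
                vapply(params, function(v) utils::URLencode(as.character(v),
                                                            reserved = TRUE),
                       character(1)),
                sep = "=", collapse = "&")
    switch(endpoint,
      esearch = http_get(paste0(eutils, "/esearch.fcgi?db=pubmed&", qs)),
      efetch = http_get(paste0(eutils, "/efetch.fcgi?db=pubmed&retmode=xml&rettype=abstract&", qs)),
      pubtator = http_get(paste0(pubtator, "?", qs)),
      stop_validation(sprintf("unknown endpoint: %s", endpoint))
    )
  }
}
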