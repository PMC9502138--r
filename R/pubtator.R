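PUBTATOR_CATEGORIES <- c("gene", "disease", "chemical", "mutation",
                         "species", "cellline")

# PubTator concept types -> our category vocabulary
pubtator_type_to_category <- function(type) {
  key <- gsub("[^a-z]", "", tolower(type))
  out <- c(gene = "gene", disease = "disease", chemical = "chemical",
           mutation = "mutation", dnamutation = "mutation",
           proteinmutation = "mutation", snp = "mutation",
           species = "species", cellline = "cellline")[key]
  unname(out)
}

#' Fetch PubTator concept annotations for a list of PMIDs
#'
#' Retrieves pre-computed concept annotations (genes, diseases, chemicals,
#' mutations, species, cell lines) for the given PMIDs, batching requests at
#' 100 PMIDs per call, and keeps only the requested categories. PMIDs unknown
#' to the service simply yield no annotations and a logged skip.
#'
#' @param pmids character vector of PMIDs.
#' @param categories non-empty subset of
#'   `c("gene","disease","chemical","mutation","species","cellline")`.
#' @param transport a [transports] function.
#' @return Data frame with columns `pmid`, `category`, `concept_id` (`NA`
#'   when the mention is not normalized to an identifier) and `mention`.
#' @export
fetch_annotations <- function(pmids, categories, transport) {
  categories <- unique(as.character(categories))
  bad <- setdiff(categories, PUBTATOR_CATEGORIES)
  if (!length(categories) || length(bad)) {
    stop_validation(sprintf(
      "invalid annotation categor%s: %s; valid names are %s",
      if (length(bad) == 1) "y" else "ies",
      paste(bad, collapse = ", "),
      paste(PUBTATOR_CATEGORIES, collapse = ", ")))
  }
  pmids <- clean_pmids(pmids)
  empty <- data.frame(pmid = character(), category = character(),
                      concept_id = character(), mention = character(),
                      stringsAsFactors = FALSE)
  if (!length(pmids)) return(empty)
  batches <- split(pmids, ceiling(seq_along(pmids) / 100))
  ann <- do.call(rbind, lapply(batches, function(batch) {
    payload <- tryCatch(
      transport("pubtator", list(pmids = paste(batch, collapse = ","))),
      error = function(e) {
        if (inherits(e, "litsim_retrieval_error")) {
          stop_retrieval(sprintf("annotation fetch failed for batch [%s]: %s",
                                 paste(batch, collapse = ","),
                                 conditionMessage(e)))
        }
        stop(e)
      })
    parse_pubtator(payload)
  }))
  if (is.null(ann)) ann <- empty
  rownames(ann) <- NULL
  unseen <- setdiff(pmids, unique(ann$pmid))
  if (length(unseen)) {
    message(sprintf("no annotations returned for %d PMID(s): %s",
                    length(unseen), paste(unseen, collapse = ", ")))
  }
  ann[ann$category %in% categories, , drop = FALSE]
}

# PubTator tab-separated export: title/abstract lines use "pmid|t|..." and
# "pmid|a|..."; annotation lines are pmid \t start \t end \t mention \t type
# [\t concept_id]. Unrecognized concept types are dropped.
parse_pubtator <- function(payload) {
  lines <- strsplit(payload %||% "", "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines) & !grepl("^[0-9]+\\|[ta]\\|", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- lengths(fields) >= 5
  if (any(!keep) && length(lines[!keep])) {
    stop_parse(sprintf("malformed annotation line: %s", lines[!keep][1]))
  }
  fields <- fields[keep]
  if (!length(fields)) {
    return(data.frame(pmid = character(), category = character(),
                      concept_id = character(), mention = character(),
                      stringsAsFactors = FALSE))
  }
  concept_id <- vapply(fields, function(f) {
    if (length(f) >= 6 && nzchar(f[6]) && f[6] != "-") f[6] else NA_character_
  }, character(1))
  out <- data.frame(
    pmid = vapply(fields, `[[`, character(1), 1),
    category = pubtator_type_to_category(vapply(fields, `[[`, character(1), 5)),
    concept_id = concept_id,
    mention = vapply(fields, `[[`, character(1), 4),
    stringsAsFactors = FALSE)
  out[!is.na(out$category), , drop = FALSE]
}

#' Normalize concept annotations into matrix terms
#'
#' With `by_id = TRUE` (the default) an annotation becomes
#' `"<category>:<concept_id>"`, which merges synonymous mentions of one
#' concept (e.g. "heat shock protein" and "HSP"); annotations without an
#' identifier fall back to the text form. With `by_id = FALSE` the verbatim
#' mention is used, lowercased with whitespace collapsed.
#'
#' @param annotations data frame as returned by [fetch_annotations()].
#' @param by_id normalize by concept identifier?
#' @return Character vector of terms, one per annotation row.
#' @export
normalize_concepts <- function(annotations, by_id = TRUE) {
  text_form <- trimws(gsub("\\s+", " ", tolower(annotations$mention)))
  if (!by_id) return(text_form)
  has_id <- !is.na(annotations$concept_id)
  ifelse(has_id, paste0(annotations$category, ":", annotations$concept_id),
         text_form)
}
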