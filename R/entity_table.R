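#' Entity tables
#'
#' An entity table holds one record per biomedical entity: a unique
#' identifier, optional categorical grouping labels (e.g. an expert-curated
#' disorder category), an optional PubMed query, an ordered list of PMIDs and
#' an ordered list of free texts (abstracts and/or custom notes). It is the
#' object that flows through the text-collection stages of the pipeline.
#'
#' Internally it is a data frame with list-columns `pmids` and `texts`, one
#' character column per grouping variable, and an attribute
#' `grouping_columns` recording which columns are grouping variables.
#'
#' @param entity_id character vector of unique, non-empty identifiers.
#' @param grouping `NULL` or a data frame (one row per entity) of categorical
#'   grouping columns.
#' @param query character vector of PubMed queries (`NA` when absent).
#' @param pmids list of character vectors of PMIDs (digits only; duplicates
#'   within one record are dropped, first occurrence kept).
#' @param texts list of character vectors of free texts.
#' @return An `entity_table`.
#' @examples
#' entity_table(c("SCN1A", "KCNQ4"),
#'              grouping = data.frame(CATEGORY = c("epilepsy", "deafness")),
#'              query = c("SCN1A AND epilepsy", "KCNQ4"))
#' @export
entity_table <- function(entity_id, grouping = NULL, query = NA_character_,
                         pmids = NULL, texts = NULL) {
  entity_id <- as.character(entity_id)
  n <- length(entity_id)
  if (any(is.na(entity_id) | !nzchar(entity_id))) {
    stop_validation("entity identifiers must be non-empty")
  }
  dup <- unique(entity_id[duplicated(entity_id)])
  if (length(dup)) {
    stop_validation(sprintf("duplicate entity identifiers: %s",
                            paste(dup, collapse = ", ")))
  }
  if (is.null(grouping)) grouping <- data.frame(row.names = seq_len(n))
  grouping <- as.data.frame(grouping, stringsAsFactors = FALSE)
  if (n > 0 && nrow(grouping) != n) {
    stop_validation("grouping must have one row per entity")
  }
  for (gc in names(grouping)) {
    grouping[[gc]] <- as.character(grouping[[gc]])
    grouping[[gc]][is.na(grouping[[gc]])] <- ""
  }
  query <- rep_len(as.character(query), n)
  query[!is.na(query) & !nzchar(query)] <- NA_character_
  if (is.null(pmids)) pmids <- rep(list(character()), n)
  if (is.null(texts)) texts <- rep(list(character()), n)
  pmids <- lapply(pmids, clean_pmids)
  texts <- lapply(texts, function(x) as.character(x[!is.na(x) & nzchar(x)]))
  tab <- data.frame(entity_id = entity_id, stringsAsFactors = FALSE)
  for (gc in names(grouping)) tab[[gc]] <- grouping[[gc]]
  tab$query <- query
  tab$pmids <- pmids
  tab$texts <- texts
  structure(tab,
            grouping_columns = names(grouping),
            class = c("entity_table", "data.frame"))
}

clean_pmids <- function(x) {
  x <- as.character(x)
  x <- x[!is.na(x) & nzchar(x)]
  bad <- x[!grepl("^[0-9]+$", x)]
  if (length(bad)) {
    stop_validation(sprintf("PMIDs must contain only digits; offending: %s",
                            paste(unique(bad), collapse = ", ")))
  }
  x[!duplicated(x)]
}

#' @export
print.entity_table <- function(x, ...) {
  cat(sprintf("<entity_table> %d entities", nrow(x)))
  gc <- grouping_columns(x)
  if (length(gc)) cat(sprintf(", grouping: %s", paste(gc, collapse = ", ")))
  cat(sprintf(", %d with PMIDs, %d with texts\n",
              sum(lengths(x$pmids) > 0), sum(lengths(x$texts) > 0)))
  invisible(x)
}

#' @rdname entity_table
#' @param table an `entity_table`.
#' @export
entity_ids <- function(table) table$entity_id

#' @rdname entity_table
#' @export
grouping_columns <- function(table) attr(table, "grouping_columns") %||% character()

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an entity table from TSV
#'
#' The on-disk dialect is a UTF-8, tab-delimited file with a header row: an
#' `ID` column, any declared grouping columns, an optional query column, and
#' runs of `PMID_1..PMID_n` / `ABSTRACT_1..ABSTRACT_n` columns which are
#' gathered left-to-right into each record's ordered lists (empty cells are
#' skipped, so entities may have different literature depth).
#'
#' @param path path to a TSV file.
#' @param query_column name of the query column. Defaults to `"QUERY"`, which
#'   is simply ignored when absent; naming any other column that is missing is
#'   an error.
#' @param pmid_prefix,text_prefix column-name prefixes gathered into the
#'   `pmids` / `texts` lists.
#' @param grouping_columns character vector of grouping column names; each
#'   must be present in the file.
#' @return An [entity_table()].
#' @export
read_entity_table <- function(path, query_column = "QUERY",
                              pmid_prefix = "PMID_",
                              text_prefix = "ABSTRACT_",
                              grouping_columns = character()) {
  query_declared <- !missing(query_column) && !is.null(query_column)
  raw <- read_tsv_strict(path)
  if (!"ID" %in% names(raw)) {
    stop_input_format(sprintf("'%s' has no 'ID' column", path))
  }
  missing_gc <- setdiff(grouping_columns, names(raw))
  if (length(missing_gc)) {
    stop_validation(sprintf("declared grouping column(s) absent: %s",
                            paste(missing_gc, collapse = ", ")))
  }
  dup <- unique(raw$ID[duplicated(raw$ID)])
  if (length(dup)) {
    stop_validation(sprintf("duplicate entity identifiers: %s",
                            paste(dup, collapse = ", ")))
  }
  query <- NA_character_
  if (!is.null(query_column) && query_column %in% names(raw)) {
    query <- raw[[query_column]]
  } else if (query_declared && !is.null(query_column)) {
    stop_validation(sprintf("declared query column absent: %s", query_column))
  }
  gather <- function(prefix) {
    cols <- names(raw)[startsWith(names(raw), prefix)]
    if (!length(cols)) return(rep(list(character()), nrow(raw)))
    lapply(seq_len(nrow(raw)), function(i) {
      v <- unlist(raw[i, cols], use.names = FALSE)
      v[!is.na(v) & nzchar(v)]
    })
  }
  entity_table(raw$ID,
               grouping = raw[, grouping_columns, drop = FALSE],
               query = query,
               pmids = gather(pmid_prefix),
               texts = gather(text_prefix))
}

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop_input_format(sprintf("file not found: %s", path))
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, fileEncoding = "UTF-8",
                    stringsAsFactors = FALSE)
}

#' Write an entity table to TSV
#'
#' Inverse of [read_entity_table()]: PMIDs are emitted as columns
#' `PMID_1..PMID_n` and texts as `ABSTRACT_1..ABSTRACT_n`, where `n` is the
#' table-wide maximum list length; a `QUERY` column is written only when at
#' least one record has a query. Reading the file back yields an equal table.
#'
#' @param table an [entity_table()].
#' @param path output path.
#' @export
write_entity_table <- function(table, path) {
  stopifnot(inherits(table, "entity_table"))
  out <- data.frame(ID = table$entity_id, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (gc in grouping_columns(table)) out[[gc]] <- table[[gc]]
  if (any(!is.na(table$query))) {
    q <- table$query
    q[is.na(q)] <- ""
    out$QUERY <- q
  }
  pad_cols <- function(lst, prefix) {
    w <- if (length(lst)) max(lengths(lst)) else 0L
    for (j in seq_len(w)) {
      out[[paste0(prefix, j)]] <<- vapply(lst, function(v) {
        if (length(v) >= j) v[[j]] else ""
      }, character(1))
    }
  }
  pad_cols(table$pmids, "PMID_")
  pad_cols(table$texts, "ABSTRACT_")
  write_tsv_strict(out, path)
}

write_tsv_strict <- function(df, path) {
  ok <- tryCatch({
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(litsim_error(sprintf("cannot write '%s': %s", path,
                              conditionMessage(ok)), "litsim_io_error"))
  }
  invisible(NULL)
}
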