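#' Binary term matrices
#'
#' The pipeline's central object: an entities-by-terms presence/absence
#' matrix. Cell `(e, t)` is 1 iff term `t` is among entity `e`'s selected
#' vocabulary. Term columns are kept sorted lexicographically, every term
#' column contains at least one 1 (a term exists only because some entity
#' selected it), and rows of entities with no usable text may be all zero.
#'
#' @param cells numeric/integer matrix of 0/1 values with entity identifiers
#'   as row names and terms as column names.
#' @return A `binary_term_matrix` (an integer matrix subclass).
#' @export
binary_term_matrix <- function(cells) {
  cells <- as.matrix(cells)
  if (is.null(rownames(cells))) stop_validation("cells must have entity row names")
  if (ncol(cells) > 0 && is.null(colnames(cells))) {
    stop_validation("cells must have term column names")
  }
  ids <- rownames(cells)
  if (anyDuplicated(ids)) stop_validation("entity identifiers must be unique")
  terms <- colnames(cells)
  if (anyDuplicated(terms)) stop_validation("terms must be unique")
  storage.mode(cells) <- "integer"
  if (length(cells) && !all(cells %in% c(0L, 1L))) {
    stop_validation("matrix cells must be 0 or 1")
  }
  if (ncol(cells) > 0) {
    cells <- cells[, order(terms), drop = FALSE]
    empty <- colnames(cells)[colSums(cells) == 0 & nrow(cells) > 0]
    if (length(empty)) {
      stop_validation(sprintf("term column(s) with no selecting entity: %s",
                              paste(empty, collapse = ", ")))
    }
  }
  structure(cells, class = c("binary_term_matrix", class(matrix())))
}

#' @export
print.binary_term_matrix <- function(x, ...) {
  cat(sprintf("<binary_term_matrix> %d entities x %d terms, density %.3f\n",
              nrow(x), ncol(x),
              if (length(x)) mean(x) else NA_real_))
  invisible(x)
}

#' Read / write a binary term matrix as TSV
#'
#' The file has a leading `ID` column of entity identifiers; the remaining
#' header fields are terms and the cells are 0/1. Writing sorts term columns
#' lexicographically, and `read_term_matrix(write_term_matrix(m))` is the
#' identity.
#'
#' @param path path to a TSV file.
#' @return A [binary_term_matrix()].
#' @export
read_term_matrix <- function(path) {
  raw <- read_tsv_strict(path)
  if (!length(names(raw)) || names(raw)[1] != "ID") {
    stop_input_format(sprintf("'%s' must start with an 'ID' column", path))
  }
  terms <- names(raw)[-1]
  cells <- matrix(0L, nrow(raw), length(terms),
                  dimnames = list(raw$ID, terms))
  for (j in seq_along(terms)) {
    v <- raw[[j + 1]]
    bad <- which(!v %in% c("0", "1"))
    if (length(bad)) {
      stop_validation(sprintf(
        "non-binary cell '%s' at row %d (entity %s), column '%s'",
        v[bad[1]], bad[1], raw$ID[bad[1]], terms[j]))
    }
    cells[, j] <- as.integer(v)
  }
  binary_term_matrix(cells)
}

#' @rdname read_term_matrix
#' @param matrix a [binary_term_matrix()].
#' @export
write_term_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "binary_term_matrix"))
  out <- data.frame(ID = rownames(matrix), stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (t in colnames(matrix)) out[[t]] <- matrix[, t]
  write_tsv_strict(out, path)
}
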