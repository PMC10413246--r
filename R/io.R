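#' Read / write the standard claims tables
#'
#' Events: `person_id, date, code, setting`; registry: `person_id,
#' birth_year, sex, is_case, index_date, match_id`. Dates are ISO-8601 in
#' the files and `Date` in memory.
#'
#' @param x table to write.
#' @param path CSV file path.
#' @return `read_*` return `data.table`s; `write_*` return `path` invisibly.
#' @name claims_io
NULL

#' @rdname claims_io
#' @export
write_events <- function(x, path) {
  fwrite(as.data.table(x)[, .(person_id, date, code, setting)], path)
  invisible(path)
}

#' @rdname claims_io
#' @export
read_events <- function(path) {
  ev <- fread(path, colClasses = list(character = c("person_id", "code", "setting")))
  ev[, date := as_date(date)]
  ev[]
}

#' @rdname claims_io
#' @export
write_registry <- function(x, path) {
  fwrite(as.data.table(x)[, .(person_id, birth_year, sex, is_case, index_date,
                              match_id)], path)
  invisible(path)
}

#' @rdname claims_io
#' @export
read_registry <- function(path) {
  reg <- fread(path, colClasses = list(character = c("person_id", "sex", "match_id")))
  reg[, `:=`(index_date = as_date(index_date), is_case = as.logical(is_case))]
  reg[]
}

#' Write a feature matrix as MatrixMarket coordinate text plus label files
#'
#' `<stem>.mtx` holds the sparse binary matrix; `<stem>_rows.txt` the person
#' ids; `<stem>_cols.csv` the tokens and their feature groups.
#'
#' @param fm a `feature_matrix`.
#' @param stem path stem (no extension).
#' @return paths of the three files, invisibly.
#' @export
write_feature_matrix <- function(fm, stem) {
  paths <- paste0(stem, c(".mtx", "_rows.txt", "_cols.csv"))
  Matrix::writeMM(as(fm$X, "generalMatrix"), paths[1])
  writeLines(rownames(fm$X), paths[2])
  fwrite(data.table(token = names(fm$groups), group = unname(fm$groups)), paths[3])
  invisible(paths)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(stem) {
  ## readMM yields a pattern (ng) matrix for 0/1 input; coerce to numeric
  X <- as(Matrix::readMM(paste0(stem, ".mtx")) * 1, "CsparseMatrix")
  rows <- readLines(paste0(stem, "_rows.txt"))
  cols <- fread(paste0(stem, "_cols.csv"))
  dimnames(X) <- list(rows, cols$token)
  structure(list(X = X, groups = setNames(cols$group, cols$token)),
            class = "feature_matrix")
}
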