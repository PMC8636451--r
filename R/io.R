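#' Read a response matrix from CSV
#'
#' Expects a header row of item labels and one row of 0/1 cells per person;
#' column order is taken as administration order.  An optional first column
#' named `person` (or `id`) supplies person labels.
#'
#' @param path CSV file.
#' @return Validated integer response matrix with person row names.
#' @export
read_response_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop(sprintf("empty or unreadable response file: %s", path),
                                          call. = FALSE))
  if (nrow(df) == 0 || ncol(df) == 0) stop("empty response file", call. = FALSE)
  idcol <- which(tolower(names(df)) %in% c("person", "id", "person_id"))
  ids <- if (length(idcol)) as.character(df[[idcol[1]]]) else NULL
  if (length(idcol)) df <- df[, -idcol[1], drop = FALSE]
  X <- validate_responses(df)
  if (!is.null(ids)) rownames(X) <- ids
  X
}

#' Write a response matrix to CSV
#'
#' @param X response matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(X, path) {
  X <- validate_responses(X)
  write.csv(as.data.frame(X), path, row.names = FALSE)
  invisible(path)
}

#' Read a weight matrix from CSV
#'
#' By default the file is item-major (one row per item, one column per
#' operation, header row of operation labels).  Printed weight matrices are
#' often transposed (operations in rows); set `transposed = TRUE` to read
#' that dialect — the flag is explicit, the orientation is never guessed.
#' An optional first column named `operation` or `item` supplies labels.
#'
#' @param path CSV file.
#' @param transposed is the file operation-major?
#' @return Validated J x M weight matrix.
#' @export
read_weight_matrix <- function(path, transposed = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0 || ncol(df) == 0) stop("empty weight file", call. = FALSE)
  lab <- which(tolower(names(df)) %in% c("operation", "item", "label"))
  labs <- if (length(lab)) as.character(df[[lab[1]]]) else NULL
  if (length(lab)) df <- df[, -lab[1], drop = FALSE]
  W <- as.matrix(df)
  if (transposed) {
    itemlabs <- colnames(W)
    W <- t(W)
    colnames(W) <- labs %||% paste0("op", seq_len(ncol(W)))
    rownames(W) <- if (!is.null(itemlabs) && !any(itemlabs == ""))
      paste0("item", itemlabs) else paste0("item", seq_len(nrow(W)))
  }
  validate_weights(W)
}

#' Write a weight matrix to CSV (item-major)
#'
#' @param W weight matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_weight_matrix <- function(W, path) {
  W <- validate_weights(W)
  write.csv(as.data.frame(W), path, row.names = FALSE)
  invisible(path)
}
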