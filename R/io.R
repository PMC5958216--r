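# CSV round-trips with a one-line provenance comment.

write_with_provenance <- function(df, file, provenance = "") {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", provenance), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write / read item parameters as headered CSV
#'
#' @param params an \code{\link{item_params}} object.
#' @param file path.
#' @param provenance one-line comment (e.g. seed or condition id).
#' @return The file path (write) or an \code{\link{item_params}} (read).
#' @export
write_item_params <- function(params, file, provenance = "") {
  write_with_provenance(as.data.frame(params), file, provenance)
}

#' @rdname write_item_params
#' @export
read_item_params <- function(file) {
  df <- utils::read.csv(file, comment.char = "#")
  item_params(df$slipping, df$guessing)
}

#' Write / read a response or profile matrix as headered CSV
#'
#' Examinees are rows. Column names are preserved; a one-line \code{#}
#' comment records provenance.
#'
#' @param x binary matrix (responses or attribute profiles).
#' @param file path.
#' @param provenance one-line comment.
#' @return The file path (write) or an integer matrix (read).
#' @export
write_binary_matrix <- function(x, file, provenance = "") {
  write_with_provenance(as.data.frame(x), file, provenance)
}

#' @rdname write_binary_matrix
#' @export
read_binary_matrix <- function(file) {
  m <- as.matrix(utils::read.csv(file, comment.char = "#"))
  storage.mode(m) <- "integer"
  m
}
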