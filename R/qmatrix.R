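#' Construct a Q-matrix
#'
#' A Q-matrix is the binary item-by-attribute loading structure of a
#' cognitive diagnostic model: entry \eqn{q_{jk} = 1} means item \eqn{j}
#' requires attribute \eqn{k}. Every item must require at least one
#' attribute.
#'
#' @param entries J x K matrix (or object coercible to one) of 0/1 entries.
#' @param item_ids optional item identifiers (default \code{1:J}).
#' @param attribute_ids optional attribute identifiers (default \code{1:K}).
#' @return An object of class \code{"qmatrix"}: the binary matrix with
#'   \code{dimnames} set from the ids.
#' @examples
#' q <- qmatrix(rbind(c(1, 0), c(0, 1), c(1, 1)))
#' item_complexity(q)
#' @export
qmatrix <- function(entries, item_ids = NULL, attribute_ids = NULL) {
  m <- as.matrix(entries)
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L)))
    stop("Q-matrix entries must all be 0 or 1")
  if (nrow(m) < 1L || ncol(m) < 1L)
    stop("Q-matrix must have at least one item and one attribute")
  rs <- rowSums(m)
  if (any(rs == 0L))
    stop("every item must require at least one attribute (all-zero Q row: ",
         paste(which(rs == 0L), collapse = ", "), ")")
  if (is.null(item_ids)) item_ids <- seq_len(nrow(m))
  if (is.null(attribute_ids)) attribute_ids <- seq_len(ncol(m))
  dimnames(m) <- list(item = as.character(item_ids),
                      attribute = as.character(attribute_ids))
  class(m) <- c("qmatrix", "matrix")
  m
}

#' @export
print.qmatrix <- function(x, ...) {
  cat("Q-matrix:", nrow(x), "items x", ncol(x), "attributes\n")
  print(unclass(x))
  invisible(x)
}

#' Number of attributes measured by each item
#'
#' @param q a \code{\link{qmatrix}}.
#' @return Integer vector of Q-matrix row sums.
#' @export
item_complexity <- function(q) {
  stopifnot(inherits(q, "qmatrix"))
  as.integer(rowSums(q))
}

#' Item complexity stratum
#'
#' Items are grouped into the two strata used throughout the study
#' summaries: those measuring two or fewer attributes and those measuring
#' three or more.
#'
#' @param q a \code{\link{qmatrix}}.
#' @return Factor of length J with levels \code{"2_or_fewer"} and
#'   \code{"3_or_more"}.
#' @export
complexity_stratum <- function(q) {
  factor(ifelse(item_complexity(q) <= 2L, "2_or_fewer", "3_or_more"),
         levels = c("2_or_fewer", "3_or_more"))
}

#' Write / read a Q-matrix as headered CSV
#'
#' Items are rows, attributes columns. A one-line \code{#} comment records
#' provenance (free text, e.g. a seed or condition id).
#'
#' @param q a \code{\link{qmatrix}}.
#' @param file path to write to / read from.
#' @param provenance one-line character comment stored atop the file.
#' @return \code{write_qmatrix} returns \code{file} invisibly;
#'   \code{read_qmatrix} returns a \code{\link{qmatrix}}.
#' @export
write_qmatrix <- function(q, file, provenance = "") {
  stopifnot(inherits(q, "qmatrix"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", provenance), con)
  df <- data.frame(item = rownames(q), unclass(q), check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_qmatrix
#' @export
read_qmatrix <- function(file) {
  df <- utils::read.csv(file, comment.char = "#", check.names = FALSE)
  qmatrix(df[, -1, drop = FALSE], item_ids = df[[1]],
          attribute_ids = colnames(df)[-1])
}
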