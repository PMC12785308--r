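#' Rater-by-case correctness matrix
#'
#' The central data structure of the analysis: one row per rater, one column
#' per case, cells `1` (correct), `0` (incorrect) or `NA` (case not
#' evaluated by that rater). Each rater carries a group label
#' (e.g. resident, board_certified, expert, or an AI model name).
#'
#' @param ratings integer/numeric matrix of 0/1/NA cells; row names are rater
#'   ids, column names case ids (defaults are generated when absent).
#' @param groups character vector of group labels, one per rater.
#' @return a matrix of class `correctness_matrix` with a `groups` attribute.
#' @export
correctness_matrix <- function(ratings, groups) {
  ratings <- as.matrix(ratings)
  if (!all(ratings %in% c(0, 1, NA)))
    stop("cells must be 0, 1 or NA", call. = FALSE)
  if (length(groups) != nrow(ratings))
    stop("`groups` must have one label per rater (row)", call. = FALSE)
  storage.mode(ratings) <- "integer"
  if (is.null(rownames(ratings)))
    rownames(ratings) <- paste0("rater", seq_len(nrow(ratings)))
  if (is.null(colnames(ratings)))
    colnames(ratings) <- paste0("case", seq_len(ncol(ratings)))
  attr(ratings, "groups") <- stats::setNames(as.character(groups), rownames(ratings))
  class(ratings) <- c("correctness_matrix", class(ratings))
  ratings
}

#' @rdname correctness_matrix
#' @param x a `correctness_matrix`.
#' @export
matrix_groups <- function(x) attr(x, "groups")

#' @export
print.correctness_matrix <- function(x, ...) {
  cat(sprintf("<correctness_matrix: %d raters x %d cases, %d missing cells>\n",
              nrow(x), ncol(x), sum(is.na(x))))
  g <- matrix_groups(x)
  cat("groups:", paste(sprintf("%s(%d)", unique(g), table(g)[unique(g)]),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a correctness matrix as CSV
#'
#' Plain-text round trip: one row per rater with columns `rater_id`, `group`,
#' then one column per case. Missing cells are written as empty fields.
#'
#' @param x a [correctness_matrix()].
#' @param path CSV file path.
#' @export
write_matrix_csv <- function(x, path) {
  df <- data.frame(rater_id = rownames(x), group = matrix_groups(x),
                   unclass(x), check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("rater_id", "group")), drop = FALSE])
  rownames(m) <- df$rater_id
  correctness_matrix(m, df$group)
}
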