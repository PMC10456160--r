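#' Construct a response matrix of integer item scores
#'
#' The raw input of every screening or simulation pipeline: an
#' `N x J` matrix of integer item responses together with the declared
#' category range of every item (e.g. 0/1 for binary items, 1..5 for a
#' five-point Likert format). The declared range matters: the extremeness
#' index rescales the item mean by it, and the observed range
#' underestimates the scale whenever an extreme category goes unused.
#'
#' Rows containing missing values are removed (listwise deletion) with a
#' message reporting the count; pairwise deletion is deliberately not
#' offered because it can itself induce an indefinite correlation matrix.
#'
#' @param data integer matrix or data frame, one row per respondent, one
#'   column per item.
#' @param categories declared category ranges: either a length-2 vector
#'   `c(min_code, max_code)` shared by all items, or a `J x 2` matrix /
#'   list of length-2 vectors, one per item. When `NULL`, the observed
#'   per-item range is used and a warning is issued.
#' @param item_labels optional character vector of item names; defaults to
#'   column names or `item1..itemJ`.
#'
#' @return An object of class `response_matrix`: a list with elements
#'   `data` (integer matrix), `categories` (`J x 2` matrix with columns
#'   `min_code`, `max_code`), `n_respondents`, `item_labels`,
#'   `n_dropped_rows`.
#' @export
#' @examples
#' x <- matrix(c(0, 1, 1, 0, 1, 1), ncol = 2)
#' rm <- response_matrix(x, categories = c(0, 1))
#' rm$n_respondents
response_matrix <- function(data, categories = NULL, item_labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("response data must be numeric integer codes")
  if (ncol(data) < 2L) stop("at least 2 items are required")

  n_dropped <- 0L
  if (anyNA(data)) {
    keep <- stats::complete.cases(data)
    n_dropped <- sum(!keep)
    message(sprintf("listwise deletion: dropped %d row(s) with missing values",
                    n_dropped))
    data <- data[keep, , drop = FALSE]
  }
  if (nrow(data) < 2L) stop("at least 2 respondents are required")
  if (any(data != round(data))) {
    bad <- which(data != round(data), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer response at row %d, column %d",
                 bad[1L], bad[2L]))
  }
  storage.mode(data) <- "integer"
  J <- ncol(data)

  if (is.null(item_labels)) {
    item_labels <- colnames(data)
    if (is.null(item_labels)) item_labels <- paste0("item", seq_len(J))
  }
  if (length(item_labels) != J) stop("item_labels length must equal J")
  colnames(data) <- item_labels

  if (is.null(categories)) {
    warning("no category ranges declared; using the observed per-item range",
            call. = FALSE)
    cat_mat <- cbind(apply(data, 2L, min), apply(data, 2L, max))
  } else if (is.list(categories)) {
    if (length(categories) != J) stop("categories list must have one entry per item")
    cat_mat <- do.call(rbind, lapply(categories, function(z) as.integer(z[1:2])))
  } else if (is.matrix(categories)) {
    if (nrow(categories) != J || ncol(categories) != 2L)
      stop("categories matrix must be J x 2")
    cat_mat <- categories
  } else {
    if (length(categories) != 2L)
      stop("categories must be c(min_code, max_code) or per-item ranges")
    cat_mat <- matrix(rep(as.integer(categories), each = J), ncol = 2L)
  }
  storage.mode(cat_mat) <- "integer"
  colnames(cat_mat) <- c("min_code", "max_code")
  rownames(cat_mat) <- item_labels

  if (any(cat_mat[, 2L] - cat_mat[, 1L] < 1L))
    stop("every item needs at least 2 categories (max_code - min_code >= 1)")
  for (j in seq_len(J)) {
    out_of_range <- data[, j] < cat_mat[j, 1L] | data[, j] > cat_mat[j, 2L]
    if (any(out_of_range)) {
      i <- which(out_of_range)[1L]
      stop(sprintf(
        "value %d at row %d of item '%s' outside declared range %d..%d",
        data[i, j], i, item_labels[j], cat_mat[j, 1L], cat_mat[j, 2L]))
    }
  }

  structure(
    list(data = data, categories = cat_mat,
         n_respondents = nrow(data), item_labels = item_labels,
         n_dropped_rows = n_dropped),
    class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Response matrix: %d respondents x %d items\n",
              x$n_respondents, length(x$item_labels)))
  rng <- apply(x$categories, 1L, function(z) paste0(z[1L], "..", z[2L]))
  cat("Items:", paste0(x$item_labels, " [", rng, "]", collapse = ", "), "\n")
  invisible(x)
}

# internal: subset rows (bootstrap / split-half) keeping declared ranges
rm_subset_rows <- function(rm, idx) {
  structure(
    list(data = rm$data[idx, , drop = FALSE], categories = rm$categories,
         n_respondents = length(idx), item_labels = rm$item_labels,
         n_dropped_rows = 0L),
    class = "response_matrix")
}
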