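#' Paired ordinal contingency table
#'
#' Square count matrix of paired category ratings at two occasions. Rows index
#' the occasion-1 category, columns the occasion-2 category, both in increasing
#' order of the (shared) ordered category set, with higher categories meaning
#' better health. This is the object all Svensson measures consume.
#'
#' @param counts square non-negative integer matrix; `counts[i, j]` is the
#'   number of subjects rated in category `i` at occasion 1 and `j` at
#'   occasion 2.
#' @param categories ordered vector of unique category labels, one per
#'   row/column of `counts`. Defaults to the rownames of `counts`, or
#'   `1..C` when absent.
#' @return An object of class `paired_table`: a list with elements `counts`
#'   (named matrix), `categories` and `n` (total pair count).
#' @seealso [build_paired_table()] to tally a table from raw paired ratings.
#' @export
#' @examples
#' paired_table(matrix(c(2, 1, 1, 2), 2, 2), categories = c("worse", "better"))
paired_table <- function(counts, categories = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("'counts' must be a square matrix")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must contain non-negative integers")
  C <- nrow(counts)
  if (C < 2)
    stop("at least two ordered categories are required")
  if (is.null(categories)) {
    categories <- if (!is.null(rownames(counts))) rownames(counts) else seq_len(C)
  }
  if (length(categories) != C)
    stop("'categories' must have one label per row of 'counts'")
  if (anyDuplicated(categories))
    stop("category labels must be unique")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(occasion1 = as.character(categories),
                           occasion2 = as.character(categories))
  structure(list(counts = counts, categories = categories, n = sum(counts)),
            class = "paired_table")
}

#' Tally a paired table from raw paired ratings
#'
#' @param occasion1,occasion2 vectors of equal length holding the category
#'   rated at each occasion; pairs with a missing value at either occasion are
#'   dropped (complete-case).
#' @param categories ordered category set; defaults to the sorted unique
#'   values observed across both occasions. Categories never observed are
#'   retained as zero rows/columns when supplied explicitly.
#' @return A [paired_table()].
#' @export
#' @examples
#' build_paired_table(c(1, 2), c(1, 2), categories = 1:3)
build_paired_table <- function(occasion1, occasion2, categories = NULL) {
  if (length(occasion1) != length(occasion2))
    stop("'occasion1' and 'occasion2' must have the same length")
  keep <- !(is.na(occasion1) | is.na(occasion2))
  occasion1 <- occasion1[keep]
  occasion2 <- occasion2[keep]
  if (length(occasion1) == 0L)
    stop("no complete pairs")
  if (is.null(categories))
    categories <- sort(unique(c(occasion1, occasion2)))
  bad <- setdiff(unique(c(occasion1, occasion2)), categories)
  if (length(bad))
    stop("rating(s) outside the category set: ", paste(bad, collapse = ", "))
  f1 <- factor(occasion1, levels = categories)
  f2 <- factor(occasion2, levels = categories)
  counts <- matrix(table(f1, f2), length(categories), length(categories))
  paired_table(counts, categories)
}

#' @export
print.paired_table <- function(x, ...) {
  cat(sprintf("Paired ordinal table: %d categories, n = %d pairs\n",
              length(x$categories), as.integer(x$n)))
  print(x$counts)
  invisible(x)
}

#' Marginal distributions of a paired table
#'
#' Relative frequencies of each category at the two occasions, with their
#' cumulative distributions. These marginals are all that the relative
#' position and relative concentration measures depend on.
#'
#' @param table a [paired_table()] with `n >= 1`.
#' @return An object of class `marginal_pair`: list with `p1`, `p2`
#'   (probability vectors, row and column sums over `n`) and `F1`, `F2`
#'   (their cumulative sums, so `F(C) = 1`; `F(0) = 0` is implicit).
#' @export
marginal_distributions <- function(table) {
  stopifnot(inherits(table, "paired_table"))
  if (table$n < 1)
    stop("table is empty")
  p1 <- rowSums(table$counts) / table$n
  p2 <- colSums(table$counts) / table$n
  structure(list(p1 = p1, p2 = p2, F1 = cumsum(p1), F2 = cumsum(p2)),
            class = "marginal_pair")
}

#' ROC points of the cumulative marginal distributions
#'
#' The curve of occasion-2 versus occasion-1 cumulative marginal frequencies.
#' Identical marginals put every point on the identity diagonal; a bow away
#' from the diagonal indicates a systematic change in position of the ratings.
#'
#' @param table a [paired_table()].
#' @return data frame with columns `category` (NA for the origin), `cum1`,
#'   `cum2`; `C + 1` rows from (0, 0) to (1, 1).
#' @export
roc_points <- function(table) {
  m <- marginal_distributions(table)
  data.frame(category = c(NA, as.character(table$categories)),
             cum1 = c(0, m$F1),
             cum2 = c(0, m$F2),
             stringsAsFactors = FALSE, row.names = NULL)
}
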