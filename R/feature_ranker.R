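# F-score feature screening: score every column, sort, keep the top N.

#' Binary F-score of one feature
#'
#' The classical filter score used by libsvm-style feature selection:
#' \deqn{F = \frac{(\bar x^{+} - \bar x)^2 + (\bar x^{-} - \bar x)^2}
#'                {s^2_{+} + s^2_{-}}}
#' with class means \eqn{\bar x^{\pm}}, overall mean \eqn{\bar x} and the
#' unbiased (n - 1 denominator) within-class sample variances. A zero
#' denominator yields `Inf` when the numerator is positive (a constant,
#' perfectly separating feature) and 0 otherwise.
#'
#' @param x Numeric vector, the feature's value per sample.
#' @param y Logical (or 0/1) vector: `TRUE` marks the positive class. Both
#'   classes need at least two samples.
#' @return A non-negative score (possibly `Inf`).
#' @export
fscore_binary <- function(x, y) {
  y <- as.logical(y)
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos < 2L || n_neg < 2L) {
    stop("both classes need at least 2 samples (got ", n_pos, " / ", n_neg,
         ")", call. = FALSE)
  }
  m_pos <- mean(x[y])
  m_neg <- mean(x[!y])
  m <- mean(x)
  num <- (m_pos - m)^2 + (m_neg - m)^2
  den <- stats::var(x[y]) + stats::var(x[!y])
  if (den == 0) {
    if (num > 0) Inf else 0
  } else {
    num / den
  }
}

#' Multiclass F-scores for a feature matrix
#'
#' Each feature's score is the maximum over classes of the one-vs-rest
#' binary F-score, so a feature diagnostic for any single location ranks
#' high. Rows are locative instances: a protein with k locations appears as
#' k rows, one per true class.
#'
#' @param X Numeric matrix (instances x features) with column names.
#' @param labels Class index (or name) per row; at least two classes.
#' @return A `loc_ranking`: tibble with columns `column`, `score`,
#'   `position` (original column position), sorted by descending score with
#'   ties broken by ascending position; `Inf` scores sort above all finite
#'   scores. The per-class one-vs-rest score matrix is attached as attribute
#'   `"per_class"` for audit.
#' @export
fscore_multiclass <- function(X, labels) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  labels <- as.vector(labels)
  if (length(labels) != nrow(X)) {
    stop("`labels` must have one entry per row of `X`", call. = FALSE)
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  per_class <- vapply(classes, function(cl) {
    y <- labels == cl
    apply(X, 2L, fscore_binary, y = y)
  }, numeric(ncol(X)))
  colnames(per_class) <- as.character(classes)
  scores <- apply(per_class, 1L, max)
  ranking <- tibble::tibble(column = colnames(X),
                            score = unname(scores),
                            position = seq_len(ncol(X))) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$position)
  structure(ranking, class = c("loc_ranking", class(ranking)),
            per_class = per_class)
}

#' Select the top-N ranked features
#'
#' @param ranking A `loc_ranking`.
#' @param n Number of columns to keep, `1 <= n <= nrow(ranking)`.
#' @return Character vector: the first `n` column names in ranking order.
#' @export
select_top <- function(ranking, n) {
  stopifnot(inherits(ranking, "loc_ranking"))
  n <- as.integer(n)
  if (n < 1L || n > nrow(ranking)) {
    stop("`n` must be between 1 and ", nrow(ranking), call. = FALSE)
  }
  ranking$column[seq_len(n)]
}

#' Rank the features of a featurized dataset
#'
#' Convenience wrapper: expands the dataset into locative instances,
#' replicates the corresponding feature rows, and calls
#' [fscore_multiclass()].
#'
#' @param dataset A `loc_dataset`.
#' @param X Feature matrix from [featurize_dataset()] (rownames =
#'   accessions).
#' @return A `loc_ranking`.
#' @export
rank_features <- function(dataset, X) {
  inst <- locative_instances(dataset)
  fscore_multiclass(X[inst$accession, , drop = FALSE], inst$class)
}

#' Write / read a feature ranking as TSV
#'
#' Two columns, `column<TAB>score`, in descending score order (the
#' `.fscore`-style audit file).
#'
#' @param ranking A `loc_ranking`.
#' @param path Output (or input) path.
#' @return `path` invisibly; `read_ranking()` returns a `loc_ranking`
#'   (without the per-class attribute).
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "loc_ranking"))
  writeLines(c("column\tscore",
               paste(ranking$column,
                     formatC(ranking$score, digits = 17, format = "g"),
                     sep = "\t")),
             path)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  raw <- read_tsv_lines(path, comment = "#")
  body <- raw$fields[-1]
  ranking <- tibble::tibble(
    column = vapply(body, `[`, character(1), 1L),
    score = as.numeric(vapply(body, `[`, character(1), 2L)),
    position = seq_along(body))
  structure(ranking, class = c("loc_ranking", class(ranking)))
}
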