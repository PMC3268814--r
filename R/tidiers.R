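# broom-style tidy()/glance() methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pair-classifier table of an ensemble
#'
#' @param x An `ovo_ensemble`.
#' @param ... Unused.
#' @return A tibble with one row per pair task: `t`, `i`, `j`,
#'   `location_i`, `location_j`, `algo`, `loo_knn`, `loo_svm`.
#' @method tidy ovo_ensemble
#' @export
tidy.ovo_ensemble <- function(x, ...) {
  x$pairs |>
    dplyr::mutate(location_i = x$scheme[.data$i],
                  location_j = x$scheme[.data$j],
                  .after = "j")
}

#' One-row summary of an ensemble
#'
#' @param x An `ovo_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble: `n_locations`, `n_tasks`, `n_svm`, `n_knn`,
#'   `n_features`, `knn_k`, `svm_c`, `svm_gamma`.
#' @method glance ovo_ensemble
#' @export
glance.ovo_ensemble <- function(x, ...) {
  tibble::tibble(n_locations = length(x$scheme),
                 n_tasks = nrow(x$pairs),
                 n_svm = sum(x$pairs$algo == "svm"),
                 n_knn = sum(x$pairs$algo == "knn"),
                 n_features = length(x$columns),
                 knn_k = x$config$knn_k,
                 svm_c = x$config$svm_c,
                 svm_gamma = x$config$svm_gamma)
}

#' Tidy the per-class metrics of an evaluation report
#'
#' @param x A `loc_report`.
#' @param ... Unused.
#' @return The per-class tibble (`location`, `n`, `correct`, `accuracy`,
#'   `tp`, `fp`, `tn`, `fn`, `mcc`).
#' @method tidy loc_report
#' @export
tidy.loc_report <- function(x, ...) x$per_class

#' One-row summary of an evaluation report
#'
#' @param x A `loc_report`.
#' @param ... Unused.
#' @return A one-row tibble: `oa`, `absolute_true`, `n_locative`,
#'   `n_distinct`.
#' @method glance loc_report
#' @export
glance.loc_report <- function(x, ...) {
  tibble::tibble(oa = x$oa,
                 absolute_true = x$absolute_true,
                 n_locative = x$n_locative,
                 n_distinct = x$n_distinct)
}

#' Tidy a feature ranking
#'
#' @param x A `loc_ranking`.
#' @param ... Unused.
#' @return The ranking as a plain tibble (`column`, `score`, `position`).
#' @method tidy loc_ranking
#' @export
tidy.loc_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
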