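# Jackknife evaluation and the metric suite: per-class accuracy, overall
# locative accuracy, absolute-true accuracy and per-class Matthews
# correlation.

# Align a truth tibble (accession, locations list) with a prediction
# tibble (accession, predicted list); error on missing predictions.
align_truth_pred <- function(truth, predictions) {
  missing <- setdiff(truth$accession, predictions$accession)
  if (length(missing) > 0L) {
    stop("missing prediction(s) for: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  idx <- match(truth$accession, predictions$accession)
  list(truth = truth$locations,
       pred = predictions$predicted[idx],
       accession = truth$accession)
}

#' Overall locative accuracy and per-class correct counts
#'
#' A locative instance (protein p, location i) counts as correct iff i is
#' in p's predicted set. The overall accuracy OA is the number of correct
#' locative instances over the total number of locative instances N.
#'
#' @param truth Tibble with `accession` and `locations` (list column of
#'   true location names).
#' @param predictions Tibble with `accession` and `predicted` (list
#'   column), e.g. from [predict.ovo_ensemble()].
#' @param scheme A `loc_scheme`.
#' @return A list with `per_class` (tibble: `location`, `n`, `correct`,
#'   `accuracy`), `oa`, and `n_locative`.
#' @export
locative_scores <- function(truth, predictions, scheme) {
  al <- align_truth_pred(truth, predictions)
  inst <- tibble::tibble(
    location = unlist(al$truth),
    correct = unlist(mapply(function(tr, pr) tr %in% pr, al$truth, al$pred,
                            SIMPLIFY = FALSE)))
  per_class <- inst |>
    dplyr::mutate(location = factor(.data$location, levels = scheme)) |>
    dplyr::group_by(.data$location, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(), correct = sum(.data$correct),
                     .groups = "drop") |>
    dplyr::mutate(location = as.character(.data$location),
                  accuracy = ifelse(.data$n > 0, .data$correct / .data$n,
                                    NA_real_))
  list(per_class = per_class,
       oa = sum(per_class$correct) / nrow(inst),
       n_locative = nrow(inst))
}

#' Absolute-true accuracy
#'
#' The fraction of distinct proteins whose predicted location set equals
#' the true location set exactly (a superset or subset does not count).
#'
#' @inheritParams locative_scores
#' @return Accuracy in [0, 1].
#' @export
absolute_true <- function(truth, predictions) {
  al <- align_truth_pred(truth, predictions)
  exact <- mapply(function(tr, pr) setequal(tr, pr), al$truth, al$pred)
  mean(exact)
}

#' Per-class Matthews correlation coefficient
#'
#' One-vs-rest counting over distinct proteins: for class i, TP are
#' proteins with i in both the true and predicted sets, FP with i predicted
#' only, FN with i true only, TN with i in neither.
#' \eqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}};
#' a zero factor in the denominator yields MCC = 0 by convention.
#'
#' @inheritParams locative_scores
#' @return A tibble with columns `location`, `tp`, `fp`, `tn`, `fn`, `mcc`.
#' @export
mcc_per_class <- function(truth, predictions, scheme) {
  al <- align_truth_pred(truth, predictions)
  purrr::map_dfr(scheme, function(loc) {
    in_true <- vapply(al$truth, function(s) loc %in% s, logical(1))
    in_pred <- vapply(al$pred, function(s) loc %in% s, logical(1))
    tp <- sum(in_true & in_pred)
    fp <- sum(!in_true & in_pred)
    fn <- sum(in_true & !in_pred)
    tn <- sum(!in_true & !in_pred)
    denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
    tibble::tibble(location = loc, tp = tp, fp = fp, tn = tn, fn = fn,
                   mcc = mcc)
  })
}

#' Full evaluation report
#'
#' Combines per-class accuracy, per-class MCC, overall locative accuracy
#' and absolute-true accuracy into a single report object.
#'
#' @inheritParams locative_scores
#' @return An object of class `loc_report`: list with `per_class` (tibble:
#'   `location`, `n`, `correct`, `accuracy`, `tp`, `fp`, `tn`, `fn`,
#'   `mcc`), `oa`, `absolute_true`, `n_locative`, `n_distinct`. Classes
#'   with no locative instance have `accuracy = NA` (reported as absent,
#'   not zero).
#' @export
evaluation_report <- function(truth, predictions, scheme) {
  ls <- locative_scores(truth, predictions, scheme)
  mcc <- mcc_per_class(truth, predictions, scheme)
  per_class <- dplyr::left_join(ls$per_class, mcc, by = "location")
  structure(
    list(per_class = per_class,
         oa = ls$oa,
         absolute_true = absolute_true(truth, predictions),
         n_locative = ls$n_locative,
         n_distinct = nrow(truth)),
    class = "loc_report")
}

#' @export
print.loc_report <- function(x, ...) {
  cat("<loc_report> ", x$n_distinct, " proteins / ", x$n_locative,
      " locative instances\n", sep = "")
  cat(sprintf("overall locative accuracy: %.2f%%\n", 100 * x$oa))
  cat(sprintf("absolute-true accuracy:    %.2f%%\n", 100 * x$absolute_true))
  print(x$per_class, ...)
  invisible(x)
}

#' Serialize / restore an evaluation report
#'
#' `write_report_json()` round-trips the full report losslessly;
#' `write_report_tsv()` writes a per-location table (location, accuracy %,
#' MCC) with overall and absolute-true accuracy footer rows.
#'
#' @param report A `loc_report`.
#' @param path Output (input) path.
#' @return `path` invisibly; `read_report_json()` returns the
#'   `loc_report`.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "loc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$per_class <- tibble::as_tibble(raw$per_class)
  structure(raw, class = "loc_report")
}

#' @rdname write_report_json
#' @export
write_report_tsv <- function(report, path) {
  stopifnot(inherits(report, "loc_report"))
  pc <- report$per_class
  lines <- c("location\taccuracy_pct\tmcc",
             paste(pc$location,
                   ifelse(is.na(pc$accuracy), "-",
                          sprintf("%.2f", 100 * pc$accuracy)),
                   sprintf("%.4f", pc$mcc),
                   sep = "\t"),
             sprintf("Overall accuracy\t%.2f\t-", 100 * report$oa),
             sprintf("Absolute true\t%.2f\t-", 100 * report$absolute_true))
  writeLines(lines, path)
  invisible(path)
}

#' Jackknife (leave-one-out) evaluation of the ensemble pipeline
#'
#' Each protein is removed in turn (all of its locative instances), the
#' pair models are rebuilt on the remainder, and the held-out protein is
#' predicted. Only the pair tasks in which the held-out protein
#' participates differ from the full-data models, so the untouched tasks
#' reuse the full-data fits — the result is identical to refitting every
#' task in every fold. The feature ranking is frozen globally by default;
#' `rank_per_fold = TRUE` re-ranks inside each training fold for a
#' leakage-free protocol.
#'
#' @param dataset A `loc_dataset` in which every class has at least 3
#'   members.
#' @param X Feature matrix from [featurize_dataset()].
#' @param ranking A `loc_ranking` computed on the full data (ignored when
#'   `rank_per_fold = TRUE`).
#' @param top_n Number of features retained.
#' @param config A `classifier_config`.
#' @param rank_per_fold Recompute the F-score ranking inside each fold.
#' @param select Per-pair KNN/SVM selection (as in [train_ensemble()]).
#' @return A list with `predictions` (tibble as from
#'   [predict.ovo_ensemble()]) and `report` (a `loc_report`).
#' @export
jackknife <- function(dataset, X, ranking = NULL, top_n = 45L,
                      config = classifier_config(), rank_per_fold = FALSE,
                      select = TRUE) {
  stopifnot(inherits(dataset, "loc_dataset"))
  recs <- dataset$records
  inst <- locative_instances(dataset)
  counts <- table(factor(inst$class, levels = seq_along(dataset$scheme)))
  if (any(counts < 3L)) {
    stop("jackknife needs >= 3 members per class; degenerate: ",
         paste(dataset$scheme[counts < 3L], collapse = ", "), call. = FALSE)
  }
  m <- length(dataset$scheme)
  pairs <- enumerate_pairs(m)
  if (!rank_per_fold) {
    if (is.null(ranking)) ranking <- rank_features(dataset, X)
    columns <- select_top(ranking, min(top_n, nrow(ranking)))
    Xs <- X[, columns, drop = FALSE]
    # full-data pair models, reused for folds that do not touch them
    full_models <- lapply(seq_len(nrow(pairs)), function(t) {
      ts <- pair_training_set(inst, Xs, pairs$i[t], pairs$j[t])
      fit_pair_model(ts$x, ts$y, config, select = select)
    })
  }
  preds <- vector("list", nrow(recs))
  for (h in seq_len(nrow(recs))) {
    held <- recs$accession[h]
    fold_inst <- inst[inst$accession != held, ]
    if (rank_per_fold) {
      fold_ds <- dataset
      fold_ds$records <- recs[-h, ]
      fold_rank <- rank_features(fold_ds, X[-h, , drop = FALSE])
      columns <- select_top(fold_rank, min(top_n, nrow(fold_rank)))
      Xs_fold <- X[, columns, drop = FALSE]
    } else {
      Xs_fold <- Xs
    }
    held_classes <- inst$class[inst$accession == held]
    models <- vector("list", nrow(pairs))
    for (t in seq_len(nrow(pairs))) {
      touched <- rank_per_fold ||
        pairs$i[t] %in% held_classes || pairs$j[t] %in% held_classes
      if (!touched) {
        models[[t]] <- full_models[[t]]
      } else {
        ts <- pair_training_set(fold_inst, Xs_fold, pairs$i[t], pairs$j[t])
        tab <- table(ts$y)
        if (length(tab) < 2L || any(tab < 2L)) {
          stop("fold for '", held, "': pair (", pairs$i[t], ",", pairs$j[t],
               ") untrainable", call. = FALSE)
        }
        models[[t]] <- fit_pair_model(ts$x, ts$y, config, select = select)
      }
    }
    ass <- vapply(seq_len(nrow(pairs)), function(t) {
      as.integer(predict_pair(models[[t]], Xs_fold[held, ]))
    }, integer(1))
    s <- vote(ass, m, pairs)
    cls <- which(s == max(s))
    preds[[h]] <- tibble::tibble(
      accession = held,
      predicted = list(dataset$scheme[cls]),
      classes = list(cls),
      scores = list(s))
  }
  predictions <- dplyr::bind_rows(preds)
  truth <- recs[, c("accession", "locations")]
  list(predictions = predictions,
       report = evaluation_report(truth, predictions, dataset$scheme))
}

#' Grid search over SVM parameters and top-N
#'
#' Evaluates the overall locative accuracy over the Cartesian grid of
#' (C, gamma, top-N) and returns the best cell; ties are resolved toward
#' smaller C, then smaller gamma, then smaller N. The default objective
#' uses k-fold cross-validation over proteins; `method = "jackknife"` runs
#' the full leave-one-out protocol instead. The default grids cover the
#' tuned operating point (C = 2, gamma = 0.125, N = 45).
#'
#' @param dataset A `loc_dataset`.
#' @param X Feature matrix.
#' @param c_grid,gamma_grid,topn_grid Non-empty numeric grids.
#' @param knn_k KNN neighbourhood size (held fixed).
#' @param method `"cv"` (k-fold over proteins) or `"jackknife"`.
#' @param folds Fold count for `method = "cv"`.
#' @param select Per-pair algorithm selection inside each evaluation.
#' @param seed Integer seed for the fold assignment.
#' @return A list with `best` (one-row tibble: `c`, `gamma`, `top_n`,
#'   `oa`) and `table` (the full grid with accuracies).
#' @export
grid_search <- function(dataset, X,
                        c_grid = 2^c(-5, -1, 1, 3, 9),
                        gamma_grid = c(0.03125, 0.125, 0.5),
                        topn_grid = c(10, 25, 45),
                        knn_k = 5L,
                        method = c("cv", "jackknife"),
                        folds = 5L, select = FALSE, seed = 1L) {
  method <- match.arg(method)
  if (length(c_grid) == 0L || length(gamma_grid) == 0L ||
      length(topn_grid) == 0L) {
    stop("parameter grids must be non-empty", call. = FALSE)
  }
  ranking <- rank_features(dataset, X)
  grid <- tidyr::expand_grid(c = sort(c_grid), gamma = sort(gamma_grid),
                             top_n = sort(topn_grid))
  oa <- vapply(seq_len(nrow(grid)), function(g) {
    config <- classifier_config(knn_k = knn_k, svm_c = grid$c[g],
                                svm_gamma = grid$gamma[g])
    if (method == "jackknife") {
      jackknife(dataset, X, ranking, grid$top_n[g], config,
                select = select)$report$oa
    } else {
      cv_oa(dataset, X, ranking, grid$top_n[g], config, folds, select, seed)
    }
  }, numeric(1))
  grid$oa <- oa
  best <- grid |>
    dplyr::arrange(dplyr::desc(.data$oa), .data$c, .data$gamma,
                   .data$top_n) |>
    dplyr::slice(1L)
  list(best = best, table = grid)
}

# k-fold cross-validated overall locative accuracy (folds over distinct
# proteins, deterministic given the seed).
cv_oa <- function(dataset, X, ranking, top_n, config, folds, select, seed) {
  recs <- dataset$records
  n <- nrow(recs)
  folds <- min(folds, n)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  all_preds <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    ds_tr <- dataset
    ds_tr$records <- recs[tr, ]
    ds_tr$n_distinct <- length(tr)
    ds_tr$n_locative <- sum(lengths(recs$locations[tr]))
    model <- train_ensemble(ds_tr, X[tr, , drop = FALSE], ranking,
                            top_n, config, select = select)
    all_preds[[f]] <- stats::predict(model, X[te, , drop = FALSE])
  }
  predictions <- dplyr::bind_rows(all_preds)
  truth <- recs[, c("accession", "locations")]
  locative_scores(truth, predictions, dataset$scheme)$oa
}
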