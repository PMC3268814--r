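# One-versus-one ensemble: pair enumeration, the KNN and RBF-SVM binary
# learners, per-pair algorithm selection by leave-one-out accuracy, and
# vote fusion with multi-label ties.

#' Classifier configuration
#'
#' Defaults follow the tuned operating point of the method: `knn_k = 5`
#' neighbours, SVM cost `C = 2` and RBF kernel width `gamma = 0.125`.
#'
#' @param knn_k Positive odd integer, the KNN neighbourhood size.
#' @param svm_c Positive SVM cost.
#' @param svm_gamma Positive RBF kernel parameter.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(knn_k = 5L, svm_c = 2, svm_gamma = 0.125) {
  knn_k <- as.integer(knn_k)
  if (knn_k < 1L || knn_k %% 2L == 0L) {
    stop("`knn_k` must be a positive odd integer", call. = FALSE)
  }
  if (svm_c <= 0 || svm_gamma <= 0) {
    stop("`svm_c` and `svm_gamma` must be positive", call. = FALSE)
  }
  structure(list(knn_k = knn_k, svm_c = svm_c, svm_gamma = svm_gamma),
            class = "classifier_config")
}

#' Enumerate the one-versus-one class pairs
#'
#' The M(M-1)/2 binary tasks in lexicographic order
#' (1,2), (1,3), ..., (1,M), (2,3), ..., (M-1,M), with 1-based task index
#' `t`. A 14-class scheme yields 91 tasks.
#'
#' @param m Class count, at least 2.
#' @return A tibble with columns `t`, `i`, `j` (`i < j`).
#' @export
enumerate_pairs <- function(m) {
  m <- as.integer(m)
  if (m < 2L) stop("need at least 2 classes", call. = FALSE)
  pairs <- utils::combn(m, 2L)
  tibble::tibble(t = seq_len(ncol(pairs)),
                 i = pairs[1L, ],
                 j = pairs[2L, ])
}

#' k-nearest-neighbour prediction
#'
#' Euclidean distance on the given columns. Fully deterministic: distance
#' ties are broken by the lower training-row index; a tied majority vote is
#' broken in favour of the tied label whose best-ranked neighbour is
#' nearest.
#'
#' @param train_x Numeric training matrix.
#' @param train_y Label per training row.
#' @param query Numeric vector (one query) or matrix of queries.
#' @param k Neighbourhood size; clamped to the training size.
#' @return The predicted label (or vector of labels for a query matrix).
#' @export
knn_predict <- function(train_x, train_y, query, k = 5L) {
  if (is.null(dim(train_x))) train_x <- matrix(train_x, ncol = 1L)
  if (nrow(train_x) == 0L) stop("empty training set", call. = FALSE)
  if (is.null(dim(query))) query <- matrix(query, ncol = ncol(train_x))
  k <- min(as.integer(k), nrow(train_x))
  out <- vapply(seq_len(nrow(query)), function(q) {
    d2 <- colSums((t(train_x) - query[q, ])^2)
    ord <- order(d2, seq_along(d2))   # distance ties -> lower row index
    nn <- ord[seq_len(k)]
    votes <- table(train_y[nn])
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) == 1L) {
      winners
    } else {
      # tie: the tied label seen earliest in the neighbour ranking wins
      as.character(train_y[nn][match(TRUE, train_y[nn] %in% winners)])
    }
  }, character(1))
  if (is.numeric(train_y)) out <- as.numeric(out)
  out
}

#' Train a soft-margin RBF-kernel SVM
#'
#' Thin wrapper over the libsvm binding in \pkg{e1071}
#' (C-classification, radial kernel, no rescaling: all retained features
#' already lie in [0, 1] by construction).
#'
#' @param train_x Numeric training matrix.
#' @param train_y Label per row; both labels must be present.
#' @param c_cost Cost parameter C.
#' @param gamma RBF kernel parameter.
#' @return A fitted `e1071::svm` model.
#' @export
train_svm <- function(train_x, train_y, c_cost = 2, gamma = 0.125) {
  if (is.null(dim(train_x))) train_x <- matrix(train_x, ncol = 1L)
  if (length(unique(train_y)) < 2L) {
    stop("SVM training needs both labels present", call. = FALSE)
  }
  e1071::svm(train_x, factor(train_y), type = "C-classification",
             kernel = "radial", cost = c_cost, gamma = gamma,
             scale = FALSE)
}

svm_predict <- function(model, query) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  lev <- as.character(stats::predict(model, query))
  lev
}

#' Leave-one-out accuracy of a binary learner on a pair task
#'
#' Each instance is held out in turn, the learner is refit on the rest, and
#' the held-out instance is predicted; accuracy is the fraction of correct
#' predictions, (T_i + T_j) / (n_i + n_j).
#'
#' @param train_x Numeric matrix of the task's instances.
#' @param train_y Label per row (two labels, each with at least 2
#'   instances).
#' @param algo `"knn"` or `"svm"`.
#' @param config A `classifier_config`.
#' @return Accuracy in [0, 1].
#' @export
loo_accuracy <- function(train_x, train_y, algo = c("knn", "svm"),
                         config = classifier_config()) {
  algo <- match.arg(algo)
  if (is.null(dim(train_x))) train_x <- matrix(train_x, ncol = 1L)
  tab <- table(train_y)
  if (length(tab) != 2L || any(tab < 2L)) {
    stop("pair task needs two classes with >= 2 instances each",
         call. = FALSE)
  }
  n <- nrow(train_x)
  correct <- vapply(seq_len(n), function(h) {
    x_tr <- train_x[-h, , drop = FALSE]
    y_tr <- train_y[-h]
    pred <- if (algo == "knn") {
      knn_predict(x_tr, y_tr, train_x[h, ], config$knn_k)
    } else {
      if (length(unique(y_tr)) < 2L) return(FALSE)
      svm_predict(train_svm(x_tr, y_tr, config$svm_c, config$svm_gamma),
                  train_x[h, ])
    }
    as.character(pred) == as.character(train_y[h])
  }, logical(1))
  mean(correct)
}

# Fit one binary model for a pair task: run leave-one-out selection between
# KNN and SVM, keep the winner (ties go to SVM), record both accuracies.
fit_pair_model <- function(train_x, train_y, config, select = TRUE) {
  loo_knn <- loo_accuracy(train_x, train_y, "knn", config)
  loo_svm <- loo_accuracy(train_x, train_y, "svm", config)
  algo <- if (select && loo_knn > loo_svm) "knn" else "svm"
  model <- list(algo = algo,
                loo_knn = loo_knn,
                loo_svm = loo_svm,
                x = train_x,
                y = as.character(train_y),
                config = config)
  if (algo == "svm") {
    model$svm <- train_svm(train_x, train_y, config$svm_c, config$svm_gamma)
  }
  structure(model, class = "ovo_binary_model")
}

predict_pair <- function(model, query) {
  if (model$algo == "knn") {
    knn_predict(model$x, model$y, query, model$config$knn_k)
  } else {
    svm_predict(model$svm, query)
  }
}

#' Select the better of KNN and SVM for one pair task
#'
#' Computes leave-one-out accuracy for both learners on the task's
#' instances and keeps the one with the higher accuracy; ties are resolved
#' in favour of the SVM. Both accuracies are recorded in the returned
#' model.
#'
#' @inheritParams loo_accuracy
#' @return An `ovo_binary_model` with elements `algo`, `loo_knn`,
#'   `loo_svm`.
#' @export
select_algorithm <- function(train_x, train_y, config = classifier_config()) {
  fit_pair_model(train_x, train_y, config, select = TRUE)
}

# Assemble per-pair training sets from locative instances: instances of the
# two classes, minus proteins that belong to BOTH classes of the pair
# (their label for this task would be contradictory).
pair_training_set <- function(inst, X, i, j) {
  acc_i <- inst$accession[inst$class == i]
  acc_j <- inst$accession[inst$class == j]
  dual <- intersect(acc_i, acc_j)
  acc_i <- setdiff(acc_i, dual)
  acc_j <- setdiff(acc_j, dual)
  list(x = X[c(acc_i, acc_j), , drop = FALSE],
       y = c(rep(i, length(acc_i)), rep(j, length(acc_j))),
       accession = c(acc_i, acc_j),
       n_dual = length(dual))
}

#' Train the one-versus-one KNN-SVM ensemble
#'
#' One binary model per class pair, trained on the locative instances of
#' the two classes (proteins annotated to both classes of a pair are
#' excluded from that pair's training set). For each pair the algorithm
#' (KNN or SVM) with the higher leave-one-out accuracy is selected.
#'
#' @param dataset A `loc_dataset`.
#' @param X Feature matrix from [featurize_dataset()].
#' @param ranking A `loc_ranking` (frozen), or `NULL` to skip selection and
#'   use all columns.
#' @param top_n Number of top-ranked features to retain (default 45);
#'   ignored when `ranking` is `NULL`.
#' @param config A `classifier_config`.
#' @param select When `FALSE`, skip the leave-one-out comparison and use
#'   the SVM for every pair (used by the tuner).
#' @return An object of class `ovo_ensemble`: scheme, frozen feature
#'   column set, pair table with chosen algorithms and both leave-one-out
#'   accuracies, fitted binary models, and the featurization parameters
#'   needed to predict new records.
#' @export
train_ensemble <- function(dataset, X, ranking = NULL, top_n = 45L,
                           config = classifier_config(), select = TRUE) {
  stopifnot(inherits(dataset, "loc_dataset"))
  m <- length(dataset$scheme)
  pairs <- enumerate_pairs(m)
  columns <- if (is.null(ranking)) colnames(X) else {
    select_top(ranking, min(top_n, nrow(ranking)))
  }
  Xs <- X[, columns, drop = FALSE]
  inst <- locative_instances(dataset)
  models <- vector("list", nrow(pairs))
  for (t in seq_len(nrow(pairs))) {
    ts <- pair_training_set(inst, Xs, pairs$i[t], pairs$j[t])
    tab <- table(ts$y)
    if (length(tab) < 2L || any(tab < 2L)) {
      stop("pair (", dataset$scheme[pairs$i[t]], ", ",
           dataset$scheme[pairs$j[t]], ") is not trainable: needs >= 2 ",
           "single-membership instances per class", call. = FALSE)
    }
    models[[t]] <- fit_pair_model(ts$x, ts$y, config, select = select)
  }
  pairs$algo <- vapply(models, `[[`, character(1), "algo")
  pairs$loo_knn <- vapply(models, `[[`, numeric(1), "loo_knn")
  pairs$loo_svm <- vapply(models, `[[`, numeric(1), "loo_svm")
  structure(
    list(scheme = dataset$scheme,
         columns = columns,
         pairs = pairs,
         models = models,
         config = config,
         map = attr(X, "map"),
         scales = attr(X, "scales"),
         lambda = attr(X, "lambda"),
         w = attr(X, "w")),
    class = "ovo_ensemble")
}

#' @export
print.ovo_ensemble <- function(x, ...) {
  cat("<ovo_ensemble> ", length(x$scheme), " locations, ", nrow(x$pairs),
      " pair classifiers (", sum(x$pairs$algo == "svm"), " svm / ",
      sum(x$pairs$algo == "knn"), " knn), ", length(x$columns),
      " features\n", sep = "")
  invisible(x)
}

#' Fuse pairwise assignments into a voting tally
#'
#' The voting score of class j is the number of binary classifiers that
#' assigned the query to j; over all M(M-1)/2 tasks the scores sum to
#' M(M-1)/2 and each score is at most M-1.
#'
#' @param assignments Integer vector: the class voted by each task, in task
#'   order.
#' @param m Class count.
#' @param pairs Optional pair table from [enumerate_pairs()]; when given,
#'   each assignment is checked to be one of its task's two classes.
#' @return Integer vector `S` of length `m`.
#' @export
vote <- function(assignments, m, pairs = NULL) {
  m <- as.integer(m)
  assignments <- as.integer(assignments)
  if (!is.null(pairs)) {
    stopifnot(length(assignments) == nrow(pairs))
    ok <- assignments == pairs$i | assignments == pairs$j
    if (!all(ok)) {
      stop("assignment for task ", pairs$t[which(!ok)[1]],
           " is outside its class pair", call. = FALSE)
    }
  }
  if (any(assignments < 1L | assignments > m)) {
    stop("assignments must be class indices in 1..", m, call. = FALSE)
  }
  tabulate(assignments, nbins = m)
}

#' Predict subcellular locations for feature vectors
#'
#' Runs every pair classifier, fuses the votes, and returns the classes
#' attaining the maximal voting score: a tie yields a multi-location
#' prediction.
#'
#' @param object An `ovo_ensemble`.
#' @param newdata Numeric feature matrix (rows = query proteins) covering
#'   the ensemble's feature columns, or a `loc_dataset` whose records are
#'   featurized with the ensemble's frozen map, scales and parameters.
#' @param ... Unused.
#' @return A tibble with columns `accession`, `predicted` (list of location
#'   names), `classes` (list of class indices) and `scores` (list of
#'   integer voting tallies of length M).
#' @export
predict.ovo_ensemble <- function(object, newdata, ...) {
  if (inherits(newdata, "loc_dataset")) {
    newdata <- featurize_dataset(newdata, map = object$map,
                                 scales = object$scales,
                                 lambda = object$lambda, w = object$w)
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  missing_cols <- setdiff(object$columns, colnames(newdata))
  if (length(missing_cols) > 0L) {
    stop("newdata lacks feature column(s): ",
         paste(utils::head(missing_cols, 3), collapse = ", "), call. = FALSE)
  }
  Xq <- newdata[, object$columns, drop = FALSE]
  m <- length(object$scheme)
  n_task <- nrow(object$pairs)
  # assignments: n_query x n_task matrix of voted class indices
  ass <- vapply(seq_len(n_task), function(t) {
    as.integer(predict_pair(object$models[[t]], Xq))
  }, integer(nrow(Xq)))
  if (nrow(Xq) == 1L) ass <- matrix(ass, nrow = 1L)
  acc <- rownames(Xq)
  if (is.null(acc)) acc <- paste0("query_", seq_len(nrow(Xq)))
  res <- lapply(seq_len(nrow(Xq)), function(q) {
    s <- vote(ass[q, ], m, object$pairs)
    cls <- which(s == max(s))
    list(classes = cls, scores = s)
  })
  tibble::tibble(
    accession = acc,
    predicted = lapply(res, function(r) object$scheme[r$classes]),
    classes = lapply(res, `[[`, "classes"),
    scores = lapply(res, `[[`, "scores"))
}

#' Write predictions as TSV
#'
#' Format: `accession<TAB>loc1;loc2<TAB>S_1,...,S_M`.
#'
#' @param predictions Tibble from [predict.ovo_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  lines <- vapply(seq_len(nrow(predictions)), function(q) {
    paste(predictions$accession[q],
          paste(predictions$predicted[[q]], collapse = ";"),
          paste(predictions$scores[[q]], collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
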