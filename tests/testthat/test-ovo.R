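test_that("pair enumeration is lexicographic with M(M-1)/2 tasks", {
  p14 <- enumerate_pairs(14)
  expect_equal(nrow(p14), 91L)
  expect_equal(p14$t, 1:91)
  p2 <- enumerate_pairs(2)
  expect_equal(p2[1, ], tibble::tibble(t = 1L, i = 1L, j = 2L))
  p5 <- enumerate_pairs(5)
  expect_equal(nrow(p5), 10L)
  expect_equal(p5$i[1:4], rep(1L, 4))
  expect_equal(p5$j[1:4], 2:5)
  expect_true(all(p5$i < p5$j))
  expect_error(enumerate_pairs(1), "at least 2")
})

test_that("KNN predicts by majority with deterministic tie-breaking", {
  train <- matrix(c(0, 1, 10), ncol = 1)
  y <- c("A", "A", "B")
  expect_equal(knn_predict(train, y, 0.5, k = 1), "A")
  expect_equal(knn_predict(train, y, 0.5, k = 3), "A")
  # distance tie between rows 1 (A) and 3 (B): lower index wins at k = 1
  train2 <- matrix(c(0, 5, 10), ncol = 1)
  expect_equal(knn_predict(train2, c("A", "C", "B"), 5, k = 1), "C")
  expect_equal(knn_predict(matrix(c(0, 2), ncol = 1), c("A", "B"), 1, k = 1),
               "A")
  expect_error(knn_predict(matrix(numeric(0), ncol = 1), character(0), 1),
               "empty")
})

test_that("KNN agrees with the exhaustive distance-sort oracle", {
  set.seed(91)
  train <- matrix(rnorm(250), ncol = 5)
  y <- sample(1:3, 50, replace = TRUE)
  queries <- matrix(rnorm(100), ncol = 5)
  for (q in 1:20) {
    expect_equal(as.character(knn_predict(train, y, queries[q, ], k = 5)),
                 bf_knn(train, y, queries[q, ], k = 5))
  }
})

test_that("SVM training separates easy data and survives conflicts", {
  x <- matrix(c(-1, -1.1, 1, 1.1), ncol = 1)
  y <- c("i", "i", "j", "j")
  m <- train_svm(x, y, c_cost = 2, gamma = 0.125)
  expect_equal(as.character(predict(m, x)), y)
  # duplicated conflicting points: no crash, some label returned
  xc <- matrix(c(0, 0, 1, 1.5), ncol = 1)
  mc <- train_svm(xc, c("i", "j", "i", "j"), 2, 0.125)
  expect_true(all(as.character(predict(mc, xc)) %in% c("i", "j")))
  # XOR-style points are fit exactly by the RBF kernel at default params
  xx <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2)
  yy <- c("i", "j", "j", "i")
  mx <- train_svm(xx, yy, 2, 0.125)
  expect_equal(as.character(predict(mx, xx)), yy)
  expect_error(train_svm(x, rep("i", 4), 2, 0.125), "both labels")
})

test_that("leave-one-out accuracy matches explicit per-fold refits", {
  set.seed(101)
  x <- matrix(c(0, 0.2, 0.4, 5, 5.2, 5.4), ncol = 1)
  y <- rep(c(1L, 2L), each = 3)
  cfg <- classifier_config(knn_k = 1L)
  expect_equal(loo_accuracy(x, y, "knn", cfg), 1.0)
  # independent enumeration of the 6 held-out predictions
  for (algo in c("knn", "svm")) {
    manual <- mean(vapply(1:6, function(h) {
      if (algo == "knn") {
        pred <- knn_predict(x[-h, , drop = FALSE], y[-h], x[h, ], k = 1)
      } else {
        pred <- predict(train_svm(x[-h, , drop = FALSE], y[-h], 2, 0.125),
                        matrix(x[h, ], 1))
      }
      as.character(pred) == as.character(y[h])
    }, logical(1)))
    expect_equal(loo_accuracy(x, y, algo, cfg), manual)
  }
  expect_error(loo_accuracy(x[1:3, , drop = FALSE], y[1:3], "knn", cfg),
               "two classes")
})

test_that("LOO accuracy on shuffled labels hovers near chance", {
  set.seed(111)
  clouds <- make_clouds(n_per_class = 100, p = 2, sep = 0)
  y <- sample(clouds$y)
  acc <- loo_accuracy(clouds$x, y, "knn", classifier_config(knn_k = 5L))
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)
})

test_that("algorithm selection keeps the higher LOO accuracy, ties to SVM", {
  set.seed(121)
  clouds <- make_clouds(n_per_class = 8, p = 3, sep = 8)
  model <- select_algorithm(clouds$x, clouds$y)
  expect_s3_class(model, "ovo_binary_model")
  expect_equal(model$loo_knn, 1.0)
  expect_equal(model$loo_svm, 1.0)
  expect_equal(model$algo, "svm")   # tie rule
  chosen <- max(model$loo_knn, model$loo_svm)
  expect_equal(if (model$algo == "knn") model$loo_knn else model$loo_svm,
               chosen)
})

test_that("vote tallies reproduce the five-class worked example", {
  s <- vote(c(2, 1, 4, 5, 2, 2, 5, 3, 5, 4), m = 5, pairs = enumerate_pairs(5))
  expect_equal(s, c(1L, 3L, 1L, 2L, 3L))
  expect_equal(which(s == max(s)), c(2L, 5L))
  # M=3: both tasks that include class 1 vote for it (its maximal tally M-1)
  expect_equal(vote(c(1, 1, 2), 3, enumerate_pairs(3)), c(2L, 1L, 0L))
  expect_error(vote(c(3, 1, 1), 3, enumerate_pairs(3)), "outside")
})

test_that("vote conservation holds for random assignments", {
  set.seed(131)
  for (m in c(3, 5, 8)) {
    pairs <- enumerate_pairs(m)
    for (r in 1:20) {
      pick <- ifelse(runif(nrow(pairs)) < 0.5, pairs$i, pairs$j)
      s <- vote(pick, m, pairs)
      expect_equal(sum(s), m * (m - 1) / 2)
      expect_true(all(s <= m - 1))
    }
  }
})

test_that("the trained ensemble predicts separable fixtures and ties multi-label", {
  fx <- make_separable_fixture(m = 3, n = 8, seed = 5)
  model <- train_ensemble(fx$dataset, fx$X, fx$ranking, top_n = 30)
  expect_equal(nrow(model$pairs), 3L)
  expect_true(all(model$pairs$algo %in% c("knn", "svm")))
  pr <- predict(model, fx$X)
  # predicted set is non-empty and all members share the maximal score
  for (q in seq_len(nrow(pr))) {
    s <- pr$scores[[q]]
    expect_equal(sum(s), 3L)
    expect_gt(length(pr$classes[[q]]), 0L)
    expect_true(all(s[pr$classes[[q]]] == max(s)))
  }
})

test_that("a two-class ensemble reduces to its single binary model", {
  fx <- make_separable_fixture(m = 2, n = 8, seed = 9)
  model <- train_ensemble(fx$dataset, fx$X, fx$ranking, top_n = 20)
  expect_equal(nrow(model$pairs), 1L)
  pr <- predict(model, fx$X)
  bm <- model$models[[1]]
  direct <- as.integer(if (bm$algo == "knn") {
    knn_predict(bm$x, bm$y, fx$X[, model$columns], bm$config$knn_k)
  } else {
    as.character(predict(bm$svm, fx$X[, model$columns]))
  })
  expect_equal(unlist(pr$classes), direct, ignore_attr = TRUE)
})

test_that("retraining with the identical fixture is deterministic", {
  fx <- make_separable_fixture(m = 3, n = 6, seed = 13)
  m1 <- train_ensemble(fx$dataset, fx$X, fx$ranking, top_n = 25)
  m2 <- train_ensemble(fx$dataset, fx$X, fx$ranking, top_n = 25)
  expect_equal(tidy(m1), tidy(m2))
  expect_equal(predict(m1, fx$X), predict(m2, fx$X))
})

test_that("dual-membership proteins are excluded from their pair's training", {
  fx <- make_separable_fixture(m = 3, n = 10, seed = 17,
                               multi_label_fraction = 0.3)
  inst <- locative_instances(fx$dataset)
  dual <- inst |>
    dplyr::group_by(accession) |>
    dplyr::filter(dplyr::n() > 1)
  expect_gt(nrow(dual), 0L)
  model <- train_ensemble(fx$dataset, fx$X, fx$ranking, top_n = 30)
  pair_of <- function(i, j) which(model$pairs$i == i & model$pairs$j == j)
  a <- dual$accession[1]
  cls <- sort(inst$class[inst$accession == a])
  t <- pair_of(cls[1], cls[2])
  expect_false(a %in% rownames(model$models[[t]]$x))
})

test_that("ensemble bundles round-trip through the text serialization", {
  fx <- make_separable_fixture(m = 3, n = 6, seed = 23)
  model <- train_ensemble(fx$dataset, fx$X, fx$ranking, top_n = 20)
  dir <- withr::local_tempdir()
  save_ensemble(model, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_ensemble(dir)
  expect_equal(back$columns, model$columns)
  expect_equal(tidy(back)[c("t", "i", "j", "algo")],
               tidy(model)[c("t", "i", "j", "algo")])
  expect_equal(predict(back, fx$X), predict(model, fx$X))
})
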