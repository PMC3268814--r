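scheme3 <- location_scheme(c("Cytoplasm", "Membrane", "Nucleus"))

pred_tbl <- function(acc, sets) {
  tibble::tibble(accession = acc, predicted = sets)
}

truth_tbl <- function(acc, sets) {
  tibble::tibble(accession = acc, locations = sets)
}

test_that("locative scoring counts instances against predicted sets", {
  truth <- truth_tbl(c("A", "B"),
                     list(c("Cytoplasm", "Nucleus"), "Membrane"))
  preds <- pred_tbl(c("A", "B"), list("Cytoplasm", "Membrane"))
  ls <- locative_scores(truth, preds, scheme3)
  expect_equal(ls$n_locative, 3L)
  expect_equal(ls$oa, 2 / 3)
  perfect <- pred_tbl(c("A", "B"),
                      list(c("Nucleus", "Cytoplasm", "Membrane"), "Membrane"))
  expect_equal(locative_scores(truth, perfect, scheme3)$oa, 1.0)
  expect_error(locative_scores(truth, preds[1, ], scheme3), "missing")
})

test_that("locative scoring matches exhaustive instance enumeration", {
  set.seed(141)
  for (r in 1:10) {
    acc <- sprintf("P%d", 1:6)
    truth <- truth_tbl(acc, lapply(1:6, function(i) {
      sample(scheme3, sample(1:2, 1))
    }))
    preds <- pred_tbl(acc, lapply(1:6, function(i) {
      sample(scheme3, sample(1:2, 1))
    }))
    got <- locative_scores(truth, preds, scheme3)
    manual <- 0
    total <- 0
    for (i in 1:6) {
      for (loc in truth$locations[[i]]) {
        total <- total + 1
        manual <- manual + (loc %in% preds$predicted[[i]])
      }
    }
    expect_equal(got$oa, manual / total)
    expect_lte(sum(got$per_class$correct), got$n_locative)
  }
})

test_that("absolute-true accuracy requires exact set equality", {
  truth <- truth_tbl(c("A", "B", "C"),
                     list("Cytoplasm", c("Membrane", "Nucleus"), "Nucleus"))
  preds <- pred_tbl(c("A", "B", "C"),
                    list(c("Cytoplasm", "Membrane"),       # superset: wrong
                         c("Nucleus", "Membrane"),         # same set: right
                         "Nucleus"))
  expect_equal(absolute_true(truth, preds), 2 / 3)
  expect_equal(absolute_true(truth, pred_tbl(truth$accession,
                                             truth$locations)), 1.0)
  # the superset prediction is locative-correct despite not being exact
  ls <- locative_scores(truth[1, ], preds[1, ], scheme3)
  expect_equal(ls$oa, 1.0)
})

test_that("absolute-true equals overall accuracy on single-location data", {
  set.seed(151)
  for (r in 1:10) {
    acc <- sprintf("P%d", 1:8)
    truth <- truth_tbl(acc, as.list(sample(scheme3, 8, replace = TRUE)))
    preds <- pred_tbl(acc, as.list(sample(scheme3, 8, replace = TRUE)))
    expect_identical(absolute_true(truth, preds),
                     locative_scores(truth, preds, scheme3)$oa)
  }
})

test_that("per-class MCC follows the one-vs-rest contingency formula", {
  # TP=2, TN=2, FP=1, FN=1 for Nucleus: (2*2 - 1*1) / sqrt(3*3*3*3) = 1/3
  truth <- truth_tbl(sprintf("P%d", 1:6),
                     list("Nucleus", "Nucleus", "Nucleus",
                          "Cytoplasm", "Cytoplasm", "Cytoplasm"))
  preds <- pred_tbl(sprintf("P%d", 1:6),
                    list("Nucleus", "Nucleus", "Cytoplasm",
                         "Nucleus", "Cytoplasm", "Cytoplasm"))
  mcc <- mcc_per_class(truth, preds, scheme3)
  nuc <- mcc[mcc$location == "Nucleus", ]
  expect_equal(c(nuc$tp, nuc$tn, nuc$fp, nuc$fn), c(2, 2, 1, 1))
  expect_equal(nuc$mcc, 1 / 3)
  # never-true, never-predicted class: 0 by the zero-factor convention
  expect_equal(mcc[mcc$location == "Membrane", ]$mcc, 0)
  # perfect predictions give MCC 1 for represented classes
  perfect <- mcc_per_class(truth, pred_tbl(truth$accession, truth$locations),
                           scheme3)
  expect_equal(perfect$mcc[perfect$location != "Membrane"], c(1, 1))
})

test_that("MCC is symmetric under swapping (TP,FP) with (TN,FN)", {
  mcc_of <- function(tp, fp, tn, fn) {
    denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  }
  set.seed(161)
  for (r in 1:20) {
    cnt <- sample(0:8, 4, replace = TRUE)
    expect_equal(mcc_of(cnt[1], cnt[2], cnt[3], cnt[4]),
                 mcc_of(cnt[3], cnt[4], cnt[1], cnt[2]))
  }
})

test_that("evaluation reports assemble and round-trip as JSON", {
  truth <- truth_tbl(c("A", "B"), list("Nucleus", c("Cytoplasm", "Membrane")))
  preds <- pred_tbl(c("A", "B"), list("Nucleus", "Cytoplasm"))
  rep <- evaluation_report(truth, preds, scheme3)
  expect_equal(rep$oa, 2 / 3)
  expect_equal(rep$absolute_true, 1 / 2)
  expect_equal(rep$n_distinct, 2L)
  expect_true(all(rep$per_class$accuracy >= 0 & rep$per_class$accuracy <= 1,
                  na.rm = TRUE))
  tf <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, tf)
  back <- read_report_json(tf)
  expect_equal(back$oa, rep$oa)
  expect_equal(back$per_class, rep$per_class)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(rep, tsv)
  expect_equal(length(readLines(tsv)), 1 + 3 + 2)
})

test_that("glance and tidy expose the report metrics", {
  truth <- truth_tbl(c("A", "B"), list("Nucleus", "Cytoplasm"))
  rep <- evaluation_report(truth, pred_tbl(truth$accession, truth$locations),
                           scheme3)
  g <- glance(rep)
  expect_equal(g$oa, 1)
  expect_equal(g$absolute_true, 1)
  expect_equal(nrow(tidy(rep)), 3L)
})

test_that("jackknife recovers a separable two-class fixture", {
  fx <- make_separable_fixture(m = 2, n = 10, seed = 31)
  jk <- jackknife(fx$dataset, fx$X, fx$ranking, top_n = 20)
  expect_equal(jk$report$oa, 1.0)
  expect_equal(jk$report$absolute_true, jk$report$oa)
  expect_equal(nrow(jk$predictions), fx$dataset$n_distinct)
})

test_that("jackknife on permuted labels scores near chance", {
  fx <- make_separable_fixture(m = 2, n = 20, seed = 37)
  ds <- fx$dataset
  set.seed(41)
  perm <- sample(nrow(ds$records))
  ds$records$locations <- ds$records$locations[perm]
  jk <- jackknife(ds, fx$X, rank_features(ds, fx$X), top_n = 20)
  expect_gt(jk$report$oa, 0.5 - 0.15)
  expect_lt(jk$report$oa, 0.5 + 0.15)
})

test_that("jackknife refuses degenerate classes", {
  suppressWarnings(ds <- make_dataset(
    acc = c("A1", "A2", "A3", "A4"),
    seq = replicate(4, random_sequence(20)),
    locs = list("N", "N", "N", "C"),
    go = as.list(sprintf("GO:000000%d", 1:4))))
  X <- featurize_dataset(ds, lambda = 2)
  expect_error(jackknife(ds, X), ">= 3 members")
})

test_that("grid search returns the argmax cell with deterministic ties", {
  fx <- make_separable_fixture(m = 2, n = 8, seed = 43)
  gs <- grid_search(fx$dataset, fx$X, c_grid = c(1, 2),
                    gamma_grid = c(0.125, 0.5), topn_grid = 15,
                    folds = 4, seed = 7)
  expect_equal(nrow(gs$table), 4L)
  # oracle: independent rerun of every cell
  ranking <- rank_features(fx$dataset, fx$X)
  for (g in seq_len(nrow(gs$table))) {
    oa <- ovoloc:::cv_oa(fx$dataset, fx$X, ranking, 15,
                         classifier_config(svm_c = gs$table$c[g],
                                           svm_gamma = gs$table$gamma[g]),
                         folds = 4, select = FALSE, seed = 7)
    expect_equal(gs$table$oa[g], oa)
  }
  best_oa <- max(gs$table$oa)
  cands <- gs$table[gs$table$oa == best_oa, ]
  cands <- cands[order(cands$c, cands$gamma, cands$top_n), ]
  expect_equal(gs$best$c, cands$c[1])
  expect_equal(gs$best$gamma, cands$gamma[1])
  # single-point grid returns that point
  gs1 <- grid_search(fx$dataset, fx$X, c_grid = 2, gamma_grid = 0.125,
                     topn_grid = 10, folds = 3, seed = 7)
  expect_equal(gs1$best[, c("c", "gamma", "top_n")],
               tibble::tibble(c = 2, gamma = 0.125, top_n = 10))
  expect_error(grid_search(fx$dataset, fx$X, c_grid = numeric(0)),
               "non-empty")
})
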