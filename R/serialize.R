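# Portable on-disk model bundle: a directory holding manifest.json (scheme,
# pair table, per-task algorithm and leave-one-out accuracies, config) plus
# one numeric TSV of training vectors per task. SVM decision functions are
# re-derived deterministically from the stored training data on load, so
# the bundle stays plain text and backend-version independent.

#' Save an ensemble model bundle
#'
#' @param model An `ovo_ensemble`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(model, dir) {
  stopifnot(inherits(model, "ovo_ensemble"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(
    scheme = as.character(model$scheme),
    columns = model$columns,
    config = unclass(model$config),
    lambda = model$lambda,
    w = model$w,
    pairs = as.data.frame(model$pairs))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$map)) {
    write_compress_map(model$map, file.path(dir, "go_compress_map.tsv"))
  }
  if (!is.null(model$scales)) {
    writeLines(c("residue\th1\th2",
                 paste(aa_alphabet(),
                       formatC(model$scales$h1, digits = 17, format = "g"),
                       formatC(model$scales$h2, digits = 17, format = "g"),
                       sep = "\t")),
               file.path(dir, "scales_standardized.tsv"))
  }
  for (t in seq_along(model$models)) {
    bm <- model$models[[t]]
    tab <- cbind(label = bm$y,
                 as.data.frame(bm$x, check.names = FALSE))
    utils::write.table(tab, file.path(dir, sprintf("task_%03d.tsv", t)),
                       sep = "\t", quote = FALSE, row.names = TRUE,
                       col.names = NA)
  }
  invisible(dir)
}

#' Load an ensemble model bundle
#'
#' @param dir Directory written by [save_ensemble()].
#' @return An `ovo_ensemble`. SVM tasks are refit from their stored
#'   training vectors with the stored parameters (deterministic given the
#'   data), so predictions match the saved model exactly.
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  config <- classifier_config(manifest$config$knn_k,
                              manifest$config$svm_c,
                              manifest$config$svm_gamma)
  pairs <- tibble::as_tibble(manifest$pairs)
  models <- lapply(seq_len(nrow(pairs)), function(t) {
    tab <- utils::read.table(file.path(dir, sprintf("task_%03d.tsv", t)),
                             sep = "\t", header = TRUE, row.names = 1L,
                             check.names = FALSE)
    x <- as.matrix(tab[, -1, drop = FALSE])
    y <- as.character(tab[[1]])
    model <- list(algo = pairs$algo[t],
                  loo_knn = pairs$loo_knn[t],
                  loo_svm = pairs$loo_svm[t],
                  x = x, y = y, config = config)
    if (model$algo == "svm") {
      model$svm <- train_svm(x, y, config$svm_c, config$svm_gamma)
    }
    structure(model, class = "ovo_binary_model")
  })
  map_path <- file.path(dir, "go_compress_map.tsv")
  map <- if (file.exists(map_path)) read_compress_map(map_path) else NULL
  scales_path <- file.path(dir, "scales_standardized.tsv")
  scales <- NULL
  if (file.exists(scales_path)) {
    raw <- read_tsv_lines(scales_path)
    body <- raw$fields[-1]
    h1 <- as.numeric(vapply(body, `[`, character(1), 2L))
    h2 <- as.numeric(vapply(body, `[`, character(1), 3L))
    names(h1) <- names(h2) <- vapply(body, `[`, character(1), 1L)
    scales <- structure(list(h1 = h1[aa_alphabet()], h2 = h2[aa_alphabet()]),
                        class = "hydro_scales")
  }
  structure(
    list(scheme = location_scheme(manifest$scheme),
         columns = manifest$columns,
         pairs = pairs,
         models = models,
         config = config,
         map = map,
         scales = scales,
         lambda = manifest$lambda,
         w = manifest$w),
    class = "ovo_ensemble")
}
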