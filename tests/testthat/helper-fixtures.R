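# Shared fixture builders and independent brute-force oracles.

# Build a tiny deterministic dataset directly from vectors (no files).
# Tiny fixtures legitimately trigger the degenerate-class warning, which is
# under test only where asserted explicitly.
make_dataset <- function(acc, seq, locs, go, quiet = TRUE) {
  seqs <- tibble::tibble(accession = acc, sequence = seq)
  labels <- tibble::tibble(accession = acc, locations = locs)
  anns <- tibble::tibble(accession = acc, go_terms = go)
  if (quiet) {
    withCallingHandlers(
      assemble_dataset(seqs, labels, anns),
      warning = function(w) {
        if (grepl("fewer than 2 records", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  } else {
    assemble_dataset(seqs, labels, anns)
  }
}

random_sequence <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}

# Brute-force oracle for the sequence-order correlation factors: naive
# nested loops over the definition.
bf_sequence_order <- function(sequence, scales, lambda) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  tau <- numeric(2 * lambda)
  for (k in seq_len(lambda)) {
    s1 <- 0
    s2 <- 0
    for (i in seq_len(L - k)) {
      s1 <- s1 + scales$h1[[chars[i]]] * scales$h1[[chars[i + k]]]
      s2 <- s2 + scales$h2[[chars[i]]] * scales$h2[[chars[i + k]]]
    }
    tau[2 * k - 1] <- s1 / (L - k)
    tau[2 * k] <- s2 / (L - k)
  }
  tau
}

# Brute-force binary F-score straight off the formula.
bf_fscore <- function(x, y) {
  xp <- x[y]
  xn <- x[!y]
  num <- (mean(xp) - mean(x))^2 + (mean(xn) - mean(x))^2
  den <- sum((xp - mean(xp))^2) / (length(xp) - 1) +
    sum((xn - mean(xn))^2) / (length(xn) - 1)
  if (den == 0) {
    if (num > 0) Inf else 0
  } else {
    num / den
  }
}

# Brute-force KNN by exhaustive distance sort (same tie rules, written
# independently: full sort, then sequential majority count).
bf_knn <- function(train_x, train_y, query, k) {
  d <- sqrt(rowSums(sweep(train_x, 2, query)^2))
  perm <- order(d, seq_along(d))
  lab <- as.character(train_y[perm][seq_len(k)])
  counts <- sort(table(lab), decreasing = TRUE)
  top <- names(counts)[counts == counts[1]]
  if (length(top) == 1) return(top)
  lab[lab %in% top][1]
}

# Two well-separated Gaussian clouds in `p` dimensions.
make_clouds <- function(n_per_class = 10, p = 3, sep = 6) {
  x <- rbind(matrix(stats::rnorm(n_per_class * p), ncol = p),
             matrix(stats::rnorm(n_per_class * p, mean = sep), ncol = p))
  y <- rep(c(1L, 2L), each = n_per_class)
  list(x = x, y = y)
}

# A small well-separated dataset + features, reused by ensemble tests.
make_separable_fixture <- function(m = 3, n = 8, seed = 1,
                                   multi_label_fraction = 0) {
  cfg <- sim_config(m = m, n_per_class = n,
                    multi_label_fraction = multi_label_fraction,
                    class_signal = 1, seq_length = c(120L, 200L),
                    seed = seed)
  ds <- simulate_dataset(cfg)
  X <- featurize_dataset(ds, lambda = 5)
  list(dataset = ds, X = X, ranking = rank_features(ds, X))
}
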