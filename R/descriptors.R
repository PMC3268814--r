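# Sequence-derived feature blocks: amino-acid composition, the 400
# dipeptide frequencies, and the amphiphilic sequence-order correlation
# factors (AmPseAAC).

#' Load and standardize hydropathy scales
#'
#' Reads a 20-row TSV with columns `residue`, `hydrophobicity`,
#' `hydrophilicity` and standardizes each scale to mean 0 and population
#' standard deviation 1 over the 20 residues. The packaged default is the
#' classical pseudo-amino-acid-composition pairing: the Tanford-style
#' hydrophobicity index and the Hopp-Woods hydrophilicity index. Any
#' user-supplied 20-row table with the same columns can be used instead.
#'
#' @param path Path to the scales TSV; defaults to the packaged table.
#' @return An object of class `hydro_scales`: a list with named 20-vectors
#'   `h1` (hydrophobicity) and `h2` (hydrophilicity), both standardized.
#' @export
load_hydro_scales <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hydro_scales.tsv", package = "ovoloc")
  }
  raw <- read_tsv_lines(path, comment = "#")
  fields <- raw$fields
  header <- fields[[1]]
  if (!identical(header[1:3], c("residue", "hydrophobicity", "hydrophilicity"))) {
    stop("scales TSV must have columns residue, hydrophobicity, hydrophilicity",
         call. = FALSE)
  }
  body <- fields[-1]
  res <- vapply(body, `[`, character(1), 1L)
  h1 <- as.numeric(vapply(body, `[`, character(1), 2L))
  h2 <- as.numeric(vapply(body, `[`, character(1), 3L))
  if (!setequal(res, aa_alphabet()) || length(res) != 20L) {
    stop("scales TSV must cover exactly the 20 standard residues",
         call. = FALSE)
  }
  names(h1) <- res
  names(h2) <- res
  std <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  h1 <- std(h1)[aa_alphabet()]
  h2 <- std(h2)[aa_alphabet()]
  for (x in list(h1, h2)) {
    stopifnot(abs(mean(x)) < 1e-9,
              abs(sqrt(mean((x - mean(x))^2)) - 1) < 1e-9)
  }
  structure(list(h1 = h1, h2 = h2), class = "hydro_scales")
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

#' Amino-acid composition
#'
#' @param sequence Normalized protein sequence.
#' @return Named 20-vector of residue frequencies (`aac_A` .. `aac_Y`),
#'   summing to 1.
#' @export
amino_acid_composition <- function(sequence) {
  chars <- seq_chars(sequence)
  if (length(chars) == 0L) stop("empty sequence", call. = FALSE)
  counts <- table(factor(chars, levels = aa_alphabet()))
  v <- as.numeric(counts) / length(chars)
  names(v) <- paste0("aac_", aa_alphabet())
  v
}

#' Dipeptide composition
#'
#' Frequencies of the 400 ordered adjacent residue pairs: component (a, b)
#' is the count of occurrences of `ab` divided by L - 1.
#'
#' @param sequence Normalized protein sequence of length at least 2.
#' @return Named 400-vector (`dip_AA`, `dip_AC`, ..., `dip_YY`) summing
#'   to 1.
#' @export
dipeptide_composition <- function(sequence) {
  chars <- seq_chars(sequence)
  L <- length(chars)
  if (L < 2L) stop("dipeptide composition needs a sequence of length >= 2",
                   call. = FALSE)
  pairs <- paste0(chars[-L], chars[-1])
  lev <- as.vector(t(outer(aa_alphabet(), aa_alphabet(), paste0)))
  counts <- table(factor(pairs, levels = lev))
  v <- as.numeric(counts) / (L - 1)
  names(v) <- paste0("dip_", lev)
  v
}

#' Amphiphilic sequence-order correlation factors
#'
#' For each correlation rank k = 1..lambda, two factors are computed along
#' the sequence: the rank-k autocorrelation of the standardized
#' hydrophobicity values and the rank-k autocorrelation of the standardized
#' hydrophilicity values,
#' \deqn{\tau_{2k-1} = \frac{1}{L-k}\sum_{i=1}^{L-k} H_1(R_i) H_1(R_{i+k}),
#'       \quad
#'       \tau_{2k}   = \frac{1}{L-k}\sum_{i=1}^{L-k} H_2(R_i) H_2(R_{i+k}).}
#' Hydrophobicity occupies the odd positions and hydrophilicity the even
#' positions of the returned vector.
#'
#' @param sequence Normalized protein sequence.
#' @param scales A `hydro_scales` object.
#' @param lambda Number of correlation ranks; must be smaller than the
#'   sequence length.
#' @return Named numeric vector of length `2 * lambda`
#'   (`tau_1` .. `tau_<2*lambda>`); empty for `lambda = 0`.
#' @export
sequence_order_factors <- function(sequence, scales, lambda) {
  stopifnot(inherits(scales, "hydro_scales"))
  lambda <- as.integer(lambda)
  if (lambda < 0L) stop("`lambda` must be >= 0", call. = FALSE)
  chars <- seq_chars(sequence)
  L <- length(chars)
  if (lambda >= L) {
    stop("lambda (", lambda, ") must be smaller than the sequence length (",
         L, ") for sequence ", substr(sequence, 1, 12), "...", call. = FALSE)
  }
  if (lambda == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  h1 <- scales$h1[chars]
  h2 <- scales$h2[chars]
  tau <- numeric(2L * lambda)
  for (k in seq_len(lambda)) {
    idx <- seq_len(L - k)
    tau[2L * k - 1L] <- sum(h1[idx] * h1[idx + k]) / (L - k)
    tau[2L * k] <- sum(h2[idx] * h2[idx + k]) / (L - k)
  }
  names(tau) <- paste0("tau_", seq_len(2L * lambda))
  tau
}

#' Amphiphilic pseudo amino acid composition
#'
#' Joint normalization of the raw residue frequencies f and the weighted
#' sequence-order factors tau:
#' \deqn{p_u = \frac{f_u}{\sum f + w \sum \tau} \ (u \le 20), \qquad
#'       p_{20+j} = \frac{w \tau_j}{\sum f + w \sum \tau} \ (1 \le j \le
#'       2\lambda),}
#' so all 20 + 2 lambda components sum to 1. With `lambda = 0` the vector
#' reduces exactly to the amino-acid composition.
#'
#' @inheritParams sequence_order_factors
#' @param w Positive weight of the pseudo components relative to the
#'   composition (default 0.5).
#' @return Named numeric vector of length `20 + 2 * lambda`
#'   (`aac_*` then `tau_*` blocks).
#' @export
ampseaac <- function(sequence, scales, lambda = 25L, w = 0.5) {
  if (w <= 0) stop("`w` must be positive", call. = FALSE)
  f <- amino_acid_composition(sequence)
  tau <- sequence_order_factors(sequence, scales, lambda)
  denom <- sum(f) + w * sum(tau)
  if (denom <= 0) {
    stop("AmPseAAC denominator is not positive (sum of correlation factors ",
         "too negative); use a smaller weight `w`", call. = FALSE)
  }
  c(f / denom, (w * tau) / denom)
}

#' Feature-space layout
#'
#' @param map A `go_compress_map` (or `NULL` for no GO block).
#' @param lambda Number of correlation ranks.
#' @return Character vector of the full column layout
#'   `[go | aac | tau | dip]`.
#' @export
feature_space <- function(map, lambda = 25L) {
  go_nm <- if (is.null(map)) character(0) else go_block_names(map)
  lev <- as.vector(t(outer(aa_alphabet(), aa_alphabet(), paste0)))
  nm <- c(go_nm,
          paste0("aac_", aa_alphabet()),
          if (lambda > 0L) paste0("tau_", seq_len(2L * lambda)),
          paste0("dip_", lev))
  if (anyDuplicated(nm)) stop("duplicate feature column names", call. = FALSE)
  nm
}

#' Featurize one protein record
#'
#' Concatenates the binary GO block, the amphiphilic pseudo amino acid
#' composition and the 400 dipeptide frequencies, in that order.
#'
#' @param record One row of a `loc_dataset` records tibble (or a list with
#'   `sequence` and `go_terms`).
#' @param map A `go_compress_map`.
#' @param scales A `hydro_scales`.
#' @param lambda,w AmPseAAC parameters.
#' @return Named numeric vector of length `D + 20 + 2*lambda + 400`.
#' @export
featurize <- function(record, map, scales, lambda = 25L, w = 0.5) {
  go <- encode_go(unlist(record$go_terms), map)
  seqv <- if (is.data.frame(record)) record$sequence[[1]] else record$sequence
  c(go, ampseaac(seqv, scales, lambda, w), dipeptide_composition(seqv))
}

#' Featurize a whole dataset
#'
#' Builds the feature matrix for every distinct protein in the dataset.
#' `lambda` is validated against the shortest sequence and clamped (with a
#' warning) to `min(length) - 1` when too large.
#'
#' @param dataset A `loc_dataset`.
#' @param map A `go_compress_map`; defaults to [build_compress_map()] on the
#'   dataset.
#' @param scales A `hydro_scales`; defaults to the packaged scales.
#' @param lambda,w AmPseAAC parameters.
#' @return A numeric matrix, one row per record (rownames = accessions),
#'   with the `feature_space()` column layout and attributes `map`,
#'   `scales`, `lambda`, `w`.
#' @export
featurize_dataset <- function(dataset, map = NULL, scales = NULL,
                              lambda = 25L, w = 0.5) {
  stopifnot(inherits(dataset, "loc_dataset"))
  if (is.null(map)) map <- build_compress_map(dataset)
  if (is.null(scales)) scales <- load_hydro_scales()
  min_len <- min(nchar(dataset$records$sequence))
  lambda <- as.integer(lambda)
  if (lambda >= min_len) {
    warning("lambda = ", lambda, " is not smaller than the shortest ",
            "sequence (", min_len, "); clamped to ", min_len - 1L,
            call. = FALSE)
    lambda <- min_len - 1L
  }
  rows <- lapply(seq_len(nrow(dataset$records)), function(i) {
    featurize(dataset$records[i, ], map, scales, lambda, w)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- dataset$records$accession
  colnames(X) <- feature_space(map, lambda)
  attr(X, "map") <- map
  attr(X, "scales") <- scales
  attr(X, "lambda") <- lambda
  attr(X, "w") <- w
  X
}
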