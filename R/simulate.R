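# Deterministic synthetic-corpus generator. The fixture emulates the
# structure of the benchmark corpora the method targets: class-biased
# residue compositions, class-specific GO-term blocks, and a configurable
# fraction of multi-location proteins. GO ids are drawn from a reserved
# synthetic range (GO:9000000+) so they can never collide with real
# ontology ids in user data.

#' Synthetic corpus configuration
#'
#' @param m Class count.
#' @param n_per_class Proteins whose primary location is each class.
#' @param multi_label_fraction Probability, in [0, 1), that a protein is
#'   assigned a second location (uniform over the other classes).
#' @param seq_length Length-2 integer range of sequence lengths.
#' @param go_vocab_size Total synthetic GO vocabulary size; the first
#'   `m * go_block_size` ids form the per-class private blocks and the rest
#'   are a shared noise pool.
#' @param go_block_size Private GO ids per class.
#' @param go_terms_per_protein Length-2 range: how many of its class-block
#'   terms a signal-carrying protein draws.
#' @param class_signal Probability, in [0, 1], that a protein carries its
#'   class's private GO terms and composition bias; non-carriers get only
#'   noise terms and the uniform composition.
#' @param noise_terms Length-2 range of uniform noise-pool terms per
#'   protein.
#' @param seed Mandatory integer seed; there is no implicit entropy.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m = 5L, n_per_class = 20L,
                       multi_label_fraction = 0.1,
                       seq_length = c(120L, 400L),
                       go_vocab_size = 100L,
                       go_block_size = 8L,
                       go_terms_per_protein = c(3L, 6L),
                       class_signal = 0.95,
                       noise_terms = c(1L, 3L),
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  m <- as.integer(m)
  stopifnot(m >= 2L, n_per_class >= 1L,
            multi_label_fraction >= 0, multi_label_fraction < 1,
            length(seq_length) == 2L, seq_length[1] >= 2L,
            seq_length[1] <= seq_length[2],
            length(go_terms_per_protein) == 2L,
            go_terms_per_protein[1] <= go_terms_per_protein[2],
            length(noise_terms) == 2L, noise_terms[1] <= noise_terms[2],
            class_signal >= 0, class_signal <= 1,
            go_block_size >= 1L)
  if (m * go_block_size >= go_vocab_size) {
    stop("`go_vocab_size` must exceed m * go_block_size (need a noise pool)",
         call. = FALSE)
  }
  if (go_terms_per_protein[2] > go_block_size) {
    stop("`go_terms_per_protein` cannot exceed `go_block_size`",
         call. = FALSE)
  }
  structure(list(m = m, n_per_class = as.integer(n_per_class),
                 multi_label_fraction = multi_label_fraction,
                 seq_length = as.integer(seq_length),
                 go_vocab_size = as.integer(go_vocab_size),
                 go_block_size = as.integer(go_block_size),
                 go_terms_per_protein = as.integer(go_terms_per_protein),
                 class_signal = class_signal,
                 noise_terms = as.integer(noise_terms),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Class-biased residue sampling weights: uniform base plus a strong boost
# on a 4-residue subset that rotates with the class index.
class_composition <- function(class, m) {
  w <- rep(1, 20)
  boost <- ((class - 1L) * 4L + 0:3) %% 20L + 1L
  w[boost] <- w[boost] + 4
  w / sum(w)
}

sim_go_vocab <- function(config) {
  sprintf("GO:%07d", 9000000L + seq_len(config$go_vocab_size) - 1L)
}

# Draw the GO terms and sequence fragment contributed by one class.
sim_class_draw <- function(class, config, vocab) {
  blocks <- config$go_block_size
  block_ids <- vocab[(class - 1L) * blocks + seq_len(blocks)]
  noise_pool <- vocab[(config$m * blocks + 1L):config$go_vocab_size]
  carries <- stats::runif(1) < config$class_signal
  terms <- character(0)
  if (carries) {
    # carriers always bear the class's core term (the compartment
    # annotation shared across the class, as in real GOA corpora) plus a
    # random draw of the other block terms
    n_block <- sample(config$go_terms_per_protein[1]:
                      config$go_terms_per_protein[2], 1L)
    terms <- c(block_ids[1], sample(block_ids[-1], n_block - 1L))
  }
  n_noise <- sample(config$noise_terms[1]:config$noise_terms[2], 1L)
  if (n_noise > 0L) terms <- c(terms, sample(noise_pool, n_noise))
  probs <- if (carries) class_composition(class, config$m) else rep(0.05, 20)
  list(terms = unique(terms), probs = probs)
}

#' Simulate a synthetic localization corpus in memory
#'
#' Generates proteins per class: each draws residues from a class-biased
#' composition and carries its class's private GO-term block with
#' probability `class_signal`, plus uniform noise terms; a
#' `multi_label_fraction` of proteins take the union of two classes'
#' generators and both locations. Fully deterministic given the seed.
#'
#' @param config A `sim_config`.
#' @return A list with tibbles `seqs` (`accession`, `sequence`), `labels`
#'   (`accession`, `locations`, with the `loc_scheme` attached) and
#'   `annotations` (`accession`, `go_terms`).
#' @export
simulate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    vocab <- sim_go_vocab(config)
    scheme <- location_scheme(sprintf("Loc%02d", seq_len(config$m)))
    acc <- character(0)
    seqs <- character(0)
    locs <- list()
    gos <- list()
    idx <- 0L
    for (cl in seq_len(config$m)) {
      for (p in seq_len(config$n_per_class)) {
        idx <- idx + 1L
        classes <- cl
        if (stats::runif(1) < config$multi_label_fraction) {
          classes <- c(cl, sample(setdiff(seq_len(config$m), cl), 1L))
        }
        draws <- lapply(classes, sim_class_draw, config = config,
                        vocab = vocab)
        probs <- Reduce(`+`, lapply(draws, `[[`, "probs")) / length(draws)
        L <- sample(config$seq_length[1]:config$seq_length[2], 1L)
        acc[idx] <- sprintf("SYN%05d", idx)
        seqs[idx] <- paste(sample(aa_alphabet(), L, replace = TRUE,
                                  prob = probs), collapse = "")
        locs[[idx]] <- scheme[sort(classes)]
        gos[[idx]] <- sort(unique(unlist(lapply(draws, `[[`, "terms"))))
      }
    }
    labels <- tibble::tibble(accession = acc, locations = locs)
    attr(labels, "scheme") <- scheme
    list(seqs = tibble::tibble(accession = acc, sequence = seqs),
         labels = labels,
         annotations = tibble::tibble(accession = acc, go_terms = gos))
  })
}

#' Write a simulated corpus to FASTA / TSV files
#'
#' Serializes [simulate_corpus()] output to the three on-disk formats the
#' readers consume; byte-identical outputs for equal seeds.
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths (`fasta`, `labels`,
#'   `go`), invisibly.
#' @export
write_sim_corpus <- function(config, dir) {
  corpus <- simulate_corpus(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "corpus.fasta"),
             labels = file.path(dir, "labels.tsv"),
             go = file.path(dir, "go.tsv"))
  write_fasta(corpus$seqs, paths[["fasta"]])
  writeLines(paste(corpus$labels$accession,
                   vapply(corpus$labels$locations, paste,
                          character(1), collapse = ";"),
                   sep = "\t"),
             paths[["labels"]])
  writeLines(paste(corpus$annotations$accession,
                   vapply(corpus$annotations$go_terms, paste,
                          character(1), collapse = ";"),
                   sep = "\t"),
             paths[["go"]])
  invisible(paths)
}

#' Simulate and assemble a ready-to-use dataset
#'
#' @param config A `sim_config`.
#' @return A `loc_dataset`.
#' @export
simulate_dataset <- function(config) {
  corpus <- simulate_corpus(config)
  assemble_dataset(corpus$seqs, corpus$labels, corpus$annotations)
}
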