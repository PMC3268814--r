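# Reading and validating the three input formats (FASTA sequences, GO
# annotations, location labels) and assembling them into a dataset of
# protein records.

#' The 20-letter amino-acid alphabet
#'
#' Standard one-letter residue codes in the canonical order used for the
#' composition and dipeptide feature blocks.
#'
#' @format A character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Ambiguity / non-standard residue codes remapped to a canonical residue.
# B (Asx) -> D, Z (Glx) -> E, J (Xle) -> L, X (unknown) -> A,
# U (Sec) -> C, O (Pyl) -> K.
ambiguity_map <- c(B = "D", Z = "E", J = "L", X = "A", U = "C", O = "K")

#' Normalize a protein sequence
#'
#' Uppercases the sequence and remaps the ambiguity codes B, Z, J, X, U, O
#' onto canonical residues (Asx to D, Glx to E, Xle to L, unknown to A,
#' selenocysteine to C, pyrrolysine to K) with a warning. Any other
#' character is an error.
#'
#' @param sequence Character scalar, the residue sequence.
#' @param accession Identifier used in error and warning messages.
#' @return The normalized sequence over the 20-letter alphabet.
#' @export
normalize_sequence <- function(sequence, accession = "<unnamed>") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("`sequence` must be a single string (", accession, ")", call. = FALSE)
  }
  s <- toupper(gsub("[\\s*-]", "", sequence, perl = TRUE))
  if (nchar(s) == 0L) {
    stop("empty sequence for accession '", accession, "'", call. = FALSE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  amb <- chars %in% names(ambiguity_map)
  if (any(amb)) {
    warning("accession '", accession, "': remapped ambiguity codes ",
            paste(sort(unique(chars[amb])), collapse = ","),
            call. = FALSE)
    chars[amb] <- ambiguity_map[chars[amb]]
  }
  bad <- setdiff(unique(chars), aa_alphabet())
  if (length(bad) > 0L) {
    stop("accession '", accession, "': invalid residue code(s) ",
         paste(bad, collapse = ","), call. = FALSE)
  }
  paste(chars, collapse = "")
}

# Extract the accession from a FASTA header: first whitespace-delimited
# token, with UniProt 'sp|ACC|NAME' / 'tr|ACC|NAME' wrappers unwrapped.
parse_accession <- function(header) {
  token <- stringr::str_split_i(stringr::str_trim(header), "\\s+", 1L)
  parts <- strsplit(token, "|", fixed = TRUE)[[1]]
  if (length(parts) >= 2L && parts[1] %in% c("sp", "tr")) parts[2] else token
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file. Headers start with `>`; the accession is
#'   the first whitespace-delimited token, with UniProt `sp|ACC|NAME` headers
#'   unwrapped to `ACC`. Wrapped sequence lines are joined and uppercased.
#' @param normalize If `TRUE` (default) sequences are passed through
#'   [normalize_sequence()].
#' @return A tibble with columns `accession` and `sequence`, in file order.
#' @export
read_fasta <- function(path, normalize = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  acc <- vapply(names(set), parse_accession, character(1), USE.NAMES = FALSE)
  seqs <- toupper(as.character(set))
  empty <- which(nchar(seqs) == 0L)
  if (length(empty) > 0L) {
    stop("empty sequence for accession '", acc[empty[1]], "' in ", path,
         call. = FALSE)
  }
  if (normalize) {
    seqs <- mapply(normalize_sequence, seqs, acc, USE.NAMES = FALSE)
  }
  tibble::tibble(accession = acc, sequence = unname(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs A data frame with columns `accession` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(all(c("accession", "sequence") %in% names(seqs)))
  set <- Biostrings::BStringSet(seqs$sequence)
  names(set) <- seqs$accession
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

go_id_regex <- "^GO:[0-9]{7}$"

# Split a ';'-separated GO term field, validate, de-duplicate.
parse_go_field <- function(field, line_no) {
  terms <- stringr::str_trim(strsplit(field, ";", fixed = TRUE)[[1]])
  terms <- terms[nchar(terms) > 0L]
  bad <- terms[!grepl(go_id_regex, terms)]
  if (length(bad) > 0L) {
    stop("malformed GO id '", bad[1], "' at line ", line_no, call. = FALSE)
  }
  unique(terms)
}

# Read a 2-or-more column TSV as raw lines, skipping comments and blanks,
# keeping original line numbers for error reporting.
read_tsv_lines <- function(path, comment = "#") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!startsWith(lines, comment) & nchar(trimws(lines)) > 0L)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE), line_no = keep)
}

#' Read protein-to-GO-term annotations
#'
#' Two dialects are supported: `"tsv"` is a two-column file
#' `accession<TAB>GO:NNNNNNN;GO:NNNNNNN;...` with `#` comment lines; `"gaf"`
#' is GAF 2.x, in which `!` comment lines are skipped and only columns 2
#' (accession) and 5 (GO id) are used.
#'
#' @param path Path to the annotation file.
#' @param dialect `"tsv"` or `"gaf"`.
#' @return A tibble with columns `accession` and `go_terms` (a list column of
#'   de-duplicated GO id character vectors). Accessions absent from the file
#'   are simply absent from the result.
#' @export
read_go_annotations <- function(path, dialect = c("tsv", "gaf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    raw <- read_tsv_lines(path, comment = "#")
    acc <- character(0)
    terms <- list()
    for (idx in seq_along(raw$fields)) {
      f <- raw$fields[[idx]]
      if (length(f) < 2L) {
        stop("expected 2 tab-separated columns at line ", raw$line_no[idx],
             " of ", path, call. = FALSE)
      }
      acc[idx] <- f[1]
      terms[[idx]] <- parse_go_field(f[2], raw$line_no[idx])
    }
  } else {
    raw <- read_tsv_lines(path, comment = "!")
    acc <- character(0)
    terms <- list()
    for (idx in seq_along(raw$fields)) {
      f <- raw$fields[[idx]]
      if (length(f) < 5L) {
        stop("GAF line ", raw$line_no[idx], " has fewer than 5 columns",
             call. = FALSE)
      }
      acc[idx] <- f[2]
      terms[[idx]] <- parse_go_field(f[5], raw$line_no[idx])
    }
  }
  tibble::tibble(accession = acc, go_terms = terms) |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      go_terms = list(unique(unlist(.data$go_terms))), .groups = "drop")
}

#' Construct a location scheme
#'
#' A location scheme is the ordered list of the M distinct subcellular
#' location class names; its order defines the stable 1..M class indices
#' used by the one-versus-one pair enumeration and the voting scores.
#'
#' @param locations Character vector of class names (duplicates removed,
#'   order of first appearance kept) or a list of per-protein location sets,
#'   in which case the induced scheme is the lexicographic sort of the
#'   distinct names.
#' @return A character vector of class `loc_scheme`.
#' @export
location_scheme <- function(locations) {
  if (is.list(locations)) {
    classes <- sort(unique(unlist(locations)))
  } else {
    classes <- unique(as.character(locations))
  }
  if (length(classes) == 0L) stop("empty location scheme", call. = FALSE)
  structure(classes, class = "loc_scheme")
}

#' Map location names to 1-based class indices
#'
#' @param locations Character vector of location names.
#' @param scheme A `loc_scheme`.
#' @return Integer class indices in `1..length(scheme)`.
#' @export
class_index <- function(locations, scheme) {
  idx <- match(locations, scheme)
  if (anyNA(idx)) {
    stop("location(s) not in scheme: ",
         paste(unique(locations[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Read protein-to-location labels
#'
#' @param path Two-column TSV `accession<TAB>loc1;loc2;...`; `#` lines are
#'   comments.
#' @param scheme Optional `loc_scheme`. When supplied, any location name not
#'   in the scheme is an error; when omitted, a scheme is induced from the
#'   distinct names in lexicographic order.
#' @return A tibble with columns `accession` and `locations` (list column),
#'   with the scheme attached as attribute `"scheme"`.
#' @export
read_location_labels <- function(path, scheme = NULL) {
  raw <- read_tsv_lines(path, comment = "#")
  acc <- character(0)
  locs <- list()
  for (idx in seq_along(raw$fields)) {
    f <- raw$fields[[idx]]
    if (length(f) < 2L) {
      stop("expected 2 tab-separated columns at line ", raw$line_no[idx],
           " of ", path, call. = FALSE)
    }
    acc[idx] <- f[1]
    ll <- stringr::str_trim(strsplit(f[2], ";", fixed = TRUE)[[1]])
    ll <- unique(ll[nchar(ll) > 0L])
    if (length(ll) == 0L) {
      stop("no locations at line ", raw$line_no[idx], " of ", path,
           call. = FALSE)
    }
    locs[[idx]] <- ll
  }
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in ", path, ": ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(scheme)) {
    scheme <- location_scheme(locs)
  } else {
    unknown <- setdiff(unique(unlist(locs)), scheme)
    if (length(unknown) > 0L) {
      stop("unknown location(s) not in scheme: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  out <- tibble::tibble(accession = acc, locations = locs)
  attr(out, "scheme") <- scheme
  out
}

#' Assemble a validated localization dataset
#'
#' Joins sequences, location labels and GO annotations on accession.
#' Proteins without any GO annotation are excluded (they cannot be encoded
#' in the GO block) and reported in `$dropped`. A protein with k locations
#' contributes k locative instances, so the locative count `n_locative` can
#' exceed the distinct-protein count `n_distinct`.
#'
#' @param seqs Tibble from [read_fasta()].
#' @param labels Tibble from [read_location_labels()] (or any data frame with
#'   `accession` and a `locations` list column).
#' @param annotations Tibble from [read_go_annotations()].
#' @param scheme Optional `loc_scheme`; defaults to the one attached to
#'   `labels`, or is induced from the labels.
#' @return An object of class `loc_dataset`: a list with `records` (tibble
#'   with columns `accession`, `sequence`, `go_terms`, `locations`),
#'   `scheme`, `n_locative`, `n_distinct`, `dropped` (accessions excluded for
#'   lacking GO terms) and `degenerate_classes` (classes with fewer than two
#'   records, for which leave-one-out evaluation is degenerate).
#' @export
assemble_dataset <- function(seqs, labels, annotations, scheme = NULL) {
  if (is.null(scheme)) scheme <- attr(labels, "scheme")
  if (is.null(scheme)) scheme <- location_scheme(labels$locations)
  missing_seq <- setdiff(labels$accession, seqs$accession)
  if (length(missing_seq) > 0L) {
    stop("labeled accession(s) without a sequence: ",
         paste(utils::head(missing_seq, 5), collapse = ", "), call. = FALSE)
  }
  recs <- labels |>
    dplyr::inner_join(seqs, by = "accession") |>
    dplyr::left_join(annotations, by = "accession")
  no_go <- vapply(recs$go_terms, function(g) is.null(g) || length(g) == 0L,
                  logical(1))
  dropped <- recs$accession[no_go]
  recs <- recs[!no_go, c("accession", "sequence", "go_terms", "locations")]
  if (nrow(recs) == 0L) {
    stop("no proteins left after removing entries without GO terms",
         call. = FALSE)
  }
  # validate locations against the scheme
  class_index(unlist(recs$locations), scheme)
  per_class <- table(factor(unlist(recs$locations), levels = scheme))
  degenerate <- names(per_class)[per_class < 2L]
  if (length(degenerate) > 0L) {
    warning("class(es) with fewer than 2 records (jackknife degenerate): ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  structure(
    list(records = recs,
         scheme = scheme,
         n_locative = sum(lengths(recs$locations)),
         n_distinct = nrow(recs),
         dropped = dropped,
         degenerate_classes = degenerate),
    class = "loc_dataset")
}

#' @export
print.loc_dataset <- function(x, ...) {
  cat("<loc_dataset> ", x$n_distinct, " proteins, ", x$n_locative,
      " locative instances, ", length(x$scheme), " locations\n", sep = "")
  cat("locations: ", paste(x$scheme, collapse = ", "), "\n", sep = "")
  if (length(x$dropped) > 0L) {
    cat("dropped (no GO terms): ", length(x$dropped), "\n", sep = "")
  }
  invisible(x)
}

#' Expand a dataset into locative instances
#'
#' @param dataset A `loc_dataset`.
#' @return A tibble with one row per (protein, location) pair: columns
#'   `accession`, `location`, `class` (1-based index into the scheme).
#' @export
locative_instances <- function(dataset) {
  stopifnot(inherits(dataset, "loc_dataset"))
  dataset$records |>
    dplyr::select("accession", "locations") |>
    tidyr::unnest_longer("locations", values_to = "location") |>
    dplyr::mutate(class = class_index(.data$location, dataset$scheme))
}
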