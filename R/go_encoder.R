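# Dense renumbering of the GO annotation vocabulary and the binary GO
# feature block.

go_number <- function(go_ids) as.integer(sub("^GO:", "", go_ids))

new_go_compress_map <- function(go_id, index, dim) {
  map <- tibble::tibble(go_id = go_id, index = as.integer(index))
  structure(map, class = c("go_compress_map", class(map)), go_dim = dim)
}

#' Build the compressed GO index from a dataset
#'
#' Every distinct GO id annotated to any protein in the dataset is assigned
#' a compressed index 1..D, in ascending order of the ids' 7-digit numbers
#' (the smallest GO number maps to index 1). The map is the frozen
#' vocabulary of the binary GO feature block: its dimension D is fixed at
#' training time and novel terms seen later are ignored.
#'
#' @param dataset A `loc_dataset`.
#' @return A `go_compress_map`: a tibble with columns `go_id` and `index`
#'   and attribute `dim = D`.
#' @export
build_compress_map <- function(dataset) {
  stopifnot(inherits(dataset, "loc_dataset"))
  ids <- unique(unlist(dataset$records$go_terms))
  if (length(ids) == 0L) stop("dataset has no GO terms", call. = FALSE)
  ids <- ids[order(go_number(ids))]
  new_go_compress_map(ids, seq_along(ids), length(ids))
}

#' Construct a compressed GO index explicitly
#'
#' Builds a `go_compress_map` from a given id-to-index assignment. This is
#' the audit-level constructor: it reproduces a published encoding (for
#' example, a map whose dimension exceeds the ids listed, with stated
#' compressed positions) without access to the full corpus that induced it.
#'
#' @param go_ids Character vector of GO ids (`GO:` + 7 digits).
#' @param index Integer vector of compressed indices, same length as
#'   `go_ids`; defaults to the ascending-GO-number ranks.
#' @param dim Total dimension D of the space; defaults to `max(index)`.
#' @return A `go_compress_map`.
#' @export
go_compress_map <- function(go_ids, index = NULL, dim = NULL) {
  bad <- go_ids[!grepl(go_id_regex, go_ids)]
  if (length(bad) > 0L) {
    stop("malformed GO id '", bad[1], "'", call. = FALSE)
  }
  if (anyDuplicated(go_ids)) stop("duplicate GO ids", call. = FALSE)
  if (is.null(index)) {
    index <- rank(go_number(go_ids))
  }
  index <- as.integer(index)
  if (length(index) != length(go_ids) || anyDuplicated(index) ||
      any(index < 1L)) {
    stop("`index` must be distinct positive integers, one per GO id",
         call. = FALSE)
  }
  if (is.null(dim)) dim <- max(index)
  if (dim < max(index)) stop("`dim` smaller than the largest index",
                             call. = FALSE)
  ord <- order(index)
  new_go_compress_map(go_ids[ord], index[ord], as.integer(dim))
}

#' @export
print.go_compress_map <- function(x, ...) {
  cat("<go_compress_map> ", nrow(x), " GO ids in a ", attr(x, "go_dim"),
      "-dimension binary block\n", sep = "")
  NextMethod()
}

#' Encode a protein's GO terms as a binary vector
#'
#' Component i is 1 iff one of the protein's GO terms has compressed index
#' i under the map; all other components are 0. Terms absent from the
#' (frozen) map are ignored, so a record annotated only with novel terms
#' encodes as the zero vector.
#'
#' @param go_terms Character vector of GO ids, or a single row of a
#'   `loc_dataset` records tibble.
#' @param map A `go_compress_map`.
#' @return A numeric 0/1 vector of length `D = attr(map, "go_dim")`, named
#'   `go_<NNNNNNN>` by compressed position (positions not covered by the
#'   map's ids are named `go_.<index>`).
#' @export
encode_go <- function(go_terms, map) {
  stopifnot(inherits(map, "go_compress_map"))
  if (is.data.frame(go_terms)) go_terms <- unlist(go_terms$go_terms)
  d <- attr(map, "go_dim")
  v <- numeric(d)
  names(v) <- go_block_names(map)
  hit <- map$index[match(go_terms, map$go_id, nomatch = 0L)]
  v[hit] <- 1
  v
}

# Column names of the GO block: the original 7-digit id where the map
# covers the position, a placeholder otherwise (explicit maps with
# dim > number of ids).
go_block_names <- function(map) {
  d <- attr(map, "go_dim")
  nm <- paste0("go_.", seq_len(d))
  nm[map$index] <- paste0("go_", sub("^GO:", "", map$go_id))
  nm
}

#' Write / read a compressed GO map as TSV
#'
#' The serialized form is a two-column TSV `GO:NNNNNNN<TAB>index` (one line
#' per id, ascending index) for audit and reuse; the dimension is recorded
#' in a `# dim=<D>` header comment.
#'
#' @param map A `go_compress_map`.
#' @param path Output (or input) path.
#' @return `path` invisibly; `read_compress_map()` returns the map.
#' @export
write_compress_map <- function(map, path) {
  stopifnot(inherits(map, "go_compress_map"))
  lines <- c(paste0("# dim=", attr(map, "go_dim")),
             paste(map$go_id, map$index, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_compress_map
#' @export
read_compress_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  dim_line <- grep("^# dim=", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#") & nchar(trimws(lines)) > 0L]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(fields, `[`, character(1), 1L)
  idx <- as.integer(vapply(fields, `[`, character(1), 2L))
  d <- if (length(dim_line) > 0L) {
    as.integer(sub("^# dim=", "", dim_line[1]))
  } else {
    NULL
  }
  go_compress_map(ids, idx, dim = d)
}
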