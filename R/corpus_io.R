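#' @importFrom rlang .data
NULL

PREDICATION_COLS <- c(
  "article_id", "subject_id", "subject_name", "subject_semtype",
  "predicate", "object_id", "object_name", "object_semtype"
)

MESH_ANNOTATION_COLS <- c("article_id", "descriptor_id", "descriptor_name", "is_major")

#' Read a predication table
#'
#' Reads a delimited table of subject-PREDICATE-object predications, one row
#' per extracted triple per article. Columns are bound by NAME, not position,
#' so permuted exports parse identically. Rows whose `article_id` does not
#' parse as a positive integer are dropped (and counted) rather than failing
#' the whole file: real predication dumps contain occasional malformed IDs.
#'
#' @param path Path to a delimited text file with a header row naming the
#'   eight predication columns (`article_id`, `subject_id`, `subject_name`,
#'   `subject_semtype`, `predicate`, `object_id`, `object_name`,
#'   `object_semtype`).
#' @param delim Field delimiter, tab by default.
#' @return A tibble of predications in file order, with attribute
#'   `"n_dropped"` giving the count of rows dropped for unparseable IDs.
#' @export
read_predications <- function(path, delim = "\t") {
  raw <- read_delim_table(path, delim)
  missing <- setdiff(PREDICATION_COLS, names(raw))
  if (length(missing) > 0) {
    stop("predication file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[PREDICATION_COLS]
  ids <- suppressWarnings(as.integer(raw$article_id))
  keep <- !is.na(ids) & ids > 0
  out <- raw[keep, , drop = FALSE]
  out$article_id <- ids[keep]
  out$predicate <- toupper(out$predicate)
  out <- tibble::as_tibble(out)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Read a MeSH annotation table
#'
#' @param path Path to a delimited file with columns `article_id`,
#'   `descriptor_id`, `descriptor_name`, `is_major`. The major-topic flag may
#'   be encoded `Y`/`N` or `1`/`0` (case-insensitive `TRUE`/`FALSE` also
#'   accepted).
#' @param delim Field delimiter, tab by default.
#' @return A tibble with `is_major` decoded to logical.
#' @export
read_mesh_annotations <- function(path, delim = "\t") {
  raw <- read_delim_table(path, delim)
  missing <- setdiff(MESH_ANNOTATION_COLS, names(raw))
  if (length(missing) > 0) {
    stop("MeSH annotation file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[MESH_ANNOTATION_COLS]
  tok <- toupper(trimws(raw$is_major))
  major <- ifelse(tok %in% c("Y", "1", "TRUE"), TRUE,
                  ifelse(tok %in% c("N", "0", "FALSE"), FALSE, NA))
  if (anyNA(major) && nrow(raw) > 0) {
    bad <- which(is.na(major))[1]
    stop("unknown is_major token '", raw$is_major[bad], "' at data row ", bad,
         " of ", path, call. = FALSE)
  }
  raw$is_major <- as.logical(major)
  raw$article_id <- as.integer(raw$article_id)
  tibble::as_tibble(raw)
}

#' Read a MeSH tree file
#'
#' @param path Two-column delimited file mapping `descriptor_id` to
#'   `tree_number` (dot-separated position codes such as `C04.557.470`). A
#'   descriptor may repeat, once per tree position; duplicate pairs are
#'   silently deduplicated.
#' @param delim Field delimiter, tab by default.
#' @return An object of class `mesh_tree`: a named list of character vectors
#'   of tree numbers per descriptor.
#' @export
read_mesh_tree <- function(path, delim = "\t") {
  raw <- read_delim_table(path, delim)
  missing <- setdiff(c("descriptor_id", "tree_number"), names(raw))
  if (length(missing) > 0) {
    stop("MeSH tree file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- unique(raw[c("descriptor_id", "tree_number")])
  if (any(!nzchar(raw$tree_number))) {
    stop("empty tree number in ", path, call. = FALSE)
  }
  tree <- split(raw$tree_number, raw$descriptor_id)
  structure(tree, class = "mesh_tree")
}

#' Depth of a descriptor in the MeSH hierarchy
#'
#' Depth is the minimum, over a descriptor's tree numbers, of one plus the
#' number of dots: a top-level code like `C04` has depth 1, `C04.557.470`
#' depth 3. Deeper descriptors are more specific topics.
#'
#' @param tree A `mesh_tree` from [read_mesh_tree()].
#' @param descriptor_id Character vector of descriptor UIs.
#' @return Integer vector of depths; `NA` for descriptors absent from the
#'   tree (unknown depth is not an error).
#' @export
mesh_depth <- function(tree, descriptor_id) {
  vapply(descriptor_id, function(d) {
    nums <- tree[[d]]
    if (is.null(nums)) return(NA_integer_)
    min(1L + vapply(strsplit(nums, ".", fixed = TRUE),
                    function(p) length(p) - 1L, integer(1)))
  }, integer(1), USE.NAMES = FALSE)
}

#' Read a PubMed ID list
#'
#' One integer per line; blank lines and lines starting with `#` are ignored.
#' Duplicates are removed, keeping first occurrence so file order is
#' preserved.
#'
#' @param path Path to a plain-text PMID list.
#' @return Integer vector of unique article IDs in file order.
#' @export
read_pmid_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  vals <- suppressWarnings(as.integer(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad_line <- which(keep)[which(is.na(vals))[1]]
    stop("non-integer PubMed ID at line ", bad_line, " of ", path,
         call. = FALSE)
  }
  unique(vals)
}

#' Write a predication or annotation table
#'
#' Tab-separated UTF-8 with header; the inverse of the readers, so any parsed
#' table round-trips field-by-field.
#'
#' @param x A tibble as returned by [read_predications()] or
#'   [read_mesh_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Write a MeSH tree
#' @param tree A `mesh_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh_tree <- function(tree, path) {
  df <- tibble::tibble(
    descriptor_id = rep(names(tree), lengths(tree)),
    tree_number = unlist(tree, use.names = FALSE)
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Write a PubMed ID list
#' @param ids Integer vector of article IDs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pmid_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

read_delim_table <- function(path, delim) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE, na = character()
  )
  as.data.frame(out, stringsAsFactors = FALSE)
}
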