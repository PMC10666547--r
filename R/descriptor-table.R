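#' Descriptor tables
#'
#' A `descriptor_table` holds a numeric chemicals-by-descriptors matrix
#' together with per-chemical metadata (the chemical records). It is the
#' common currency of the curation, modeling and applicability-domain
#' functions.
#'
#' @param values numeric matrix, rows = chemicals, columns = descriptors.
#'   Non-finite entries are treated as missing.
#' @param ids character vector of chemical identifiers (InChIKey preferred),
#'   one per row, unique and non-empty.
#' @param chemicals optional data.frame of chemical metadata with at least an
#'   `id` column; recognised columns are `name`, `smiles`,
#'   `monoisotopic_mass` (Da, > 0) and `lc50` (mg/L, > 0).
#' @param replicate_id optional integer tag for replicate descriptor
#'   calculations of the same chemicals.
#'
#' @return An object of class `descriptor_table`: a list with elements
#'   `values` (matrix with ids as rownames and descriptor names as colnames),
#'   `chemicals` (data.frame), `replicate_id`, and `n_missing` (count of
#'   missing cells).
#' @export
descriptor_table <- function(values, ids = rownames(values), chemicals = NULL,
                             replicate_id = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(ids)) stop("chemical ids are required")
  ids <- as.character(ids)
  if (length(ids) != nrow(values))
    stop("length of ids (", length(ids), ") does not match rows (",
         nrow(values), ")")
  if (any(!nzchar(ids)) || anyNA(ids)) stop("ids must be non-empty")
  if (anyDuplicated(ids)) stop("duplicate identifier: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("D", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values))) stop("descriptor names must be unique")
  rownames(values) <- ids
  values[!is.finite(values)] <- NA_real_

  if (is.null(chemicals)) {
    chemicals <- data.frame(id = ids, stringsAsFactors = FALSE)
  } else {
    chemicals <- as.data.frame(chemicals)
    if (!"id" %in% names(chemicals)) stop("chemicals metadata needs an 'id' column")
    chemicals <- chemicals[match(ids, as.character(chemicals$id)), , drop = FALSE]
    if (anyNA(chemicals$id)) stop("chemicals metadata does not cover all ids")
    rownames(chemicals) <- NULL
  }
  if (!is.null(chemicals$monoisotopic_mass)) {
    m <- chemicals$monoisotopic_mass
    if (any(!is.na(m) & m <= 0)) stop("monoisotopic_mass must be > 0")
  }
  if (!is.null(chemicals$lc50)) {
    l <- chemicals$lc50
    if (any(!is.na(l) & l <= 0)) stop("lc50 must be > 0")
  }

  structure(list(values = values, chemicals = chemicals,
                 replicate_id = replicate_id,
                 n_missing = sum(is.na(values))),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("descriptor_table: ", nrow(x$values), " chemicals x ",
      ncol(x$values), " descriptors", sep = "")
  if (!is.null(x$replicate_id)) cat(" (replicate ", x$replicate_id, ")", sep = "")
  cat("\n  missing cells: ", x$n_missing, "\n", sep = "")
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$values)

descriptor_names <- function(x) colnames(x$values)

chemical_ids <- function(x) rownames(x$values)

#' Restrict a descriptor table to a set of descriptors
#'
#' @param x a `descriptor_table`.
#' @param keep character vector of descriptor names to keep (order respected).
#' @return a `descriptor_table` with only those columns.
#' @export
subset_descriptors <- function(x, keep) {
  stopifnot(inherits(x, "descriptor_table"))
  missing <- setdiff(keep, descriptor_names(x))
  if (length(missing))
    stop("descriptors not present: ", paste(missing, collapse = ", "))
  descriptor_table(x$values[, keep, drop = FALSE], chemicals = x$chemicals,
                   replicate_id = x$replicate_id)
}

#' Read a descriptor table from a delimited file
#'
#' Reads a CSV or TSV export of a descriptor calculator (one row per
#' chemical, one column per descriptor, a header row). The delimiter is
#' chosen from the file extension (`.tsv`/`.txt` = tab, otherwise comma).
#' Non-numeric cells in descriptor columns become missing values and are
#' counted in the returned table.
#'
#' @param path path to the delimited file.
#' @param id_column name of the column holding the chemical identifier.
#' @param metadata optional data.frame of chemical metadata (see
#'   [descriptor_table()]).
#' @param replicate_id optional replicate tag.
#' @return a [descriptor_table()].
#' @export
load_descriptor_table <- function(path, id_column = "id", metadata = NULL,
                                  replicate_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", comment.char = "",
                           quote = "\"", fileEncoding = "UTF-8")
  if (!id_column %in% names(raw))
    stop("id column '", id_column, "' not found in ", path)
  ids <- raw[[id_column]]
  if (anyDuplicated(ids))
    stop("duplicate identifier: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  num <- raw[, setdiff(names(raw), id_column), drop = FALSE]
  values <- vapply(num, function(col) suppressWarnings(as.numeric(col)),
                   numeric(nrow(raw)))
  if (nrow(raw) == 1L) values <- matrix(values, nrow = 1L,
                                        dimnames = list(NULL, names(num)))
  rownames(values) <- ids
  descriptor_table(values, chemicals = metadata, replicate_id = replicate_id)
}

#' Write a descriptor table to CSV
#'
#' @param x a `descriptor_table`.
#' @param path output path.
#' @param id_column name for the identifier column.
#' @export
write_descriptor_table <- function(x, path, id_column = "id") {
  stopifnot(inherits(x, "descriptor_table"))
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                   setNames(list(chemical_ids(x)), id_column))
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
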