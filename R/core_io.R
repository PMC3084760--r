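#' Read protein sequences from a FASTA file
#'
#' The id is the header token up to the first whitespace; the full header
#' (without the leading `>`) is kept verbatim as the description. Residues
#' are normalized as in [protein_records()]: uppercased, `*` stripped,
#' non-canonical letters remapped to X with a warning.
#'
#' @param path path to a FASTA file.
#' @return a [protein_records()] data frame (zero rows for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) {
    return(protein_records(character(0), character(0)))
  }
  first <- nonempty[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: line ", first, " is not a '>' header: ",
         lines[first])
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  protein_records(id = ids, residues = as.character(set), description = headers)
}

#' Write protein records to a FASTA file
#'
#' Headers are the stored descriptions when present (they already begin with
#' the id), otherwise the bare id; sequence lines are wrapped at 60 columns.
#'
#' @param records a [protein_records()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$residues)
  hdr <- ifelse(nzchar(records$description) & !is.na(records$description),
                records$description, records$id)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta", width = 60)
  invisible(path)
}

#' Read a sequence-label table
#'
#' Tab-separated file with a header line and mandatory columns `id` and
#' `type`; an optional `taxonomy` column is carried through. Type tokens are
#' parsed case-insensitively onto {A1, A2, B, C, NOR}; unknown tokens and
#' conflicting duplicate ids are errors.
#'
#' @param path path to the TSV label file.
#' @return named character vector of enzyme types, names = sequence ids.
#'   The taxonomy column, when present, is attached as attribute `taxonomy`
#'   (named character vector).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  if (!all(c("id", "type") %in% names(tab))) {
    stop("label table must have columns 'id' and 'type' (tab-separated, with header)")
  }
  types <- tryCatch(parse_enzyme_type(tab$type), error = function(e) {
    bad <- !(toupper(trimws(tab$type)) %in% hco_types())
    stop("label table rows with unknown type: ",
         paste(sprintf("row %d (id=%s, type=%s)", which(bad), tab$id[bad],
                       tab$type[bad]), collapse = "; "), call. = FALSE)
  })
  labels <- stats::setNames(types, tab$id)
  if (anyDuplicated(tab$id)) {
    dup <- unique(tab$id[duplicated(tab$id)])
    for (d in dup) {
      if (length(unique(types[tab$id == d])) > 1) {
        stop("duplicate id with conflicting types in label table: ", d)
      }
    }
    keep <- !duplicated(tab$id)
    labels <- stats::setNames(types[keep], tab$id[keep])
    tab <- tab[keep, , drop = FALSE]
  }
  if ("taxonomy" %in% names(tab)) {
    attr(labels, "taxonomy") <- stats::setNames(as.character(tab$taxonomy), tab$id)
  }
  labels
}

#' Write a sequence-label table
#'
#' @param labels named character vector (id -> type).
#' @param path output TSV path.
#' @param taxonomy optional named character vector (id -> taxonomy string).
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, taxonomy = NULL) {
  tab <- data.frame(id = names(labels), type = unname(labels),
                    stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) tab$taxonomy <- unname(taxonomy[tab$id])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a labeled reference set
#'
#' Pairs records with their curated type labels (the "gold standard"). Only
#' records that have a label are included; the ids of unlabeled records are
#' reported in the `dropped` field. A label that points at a missing record
#' is an error.
#'
#' @param records a [protein_records()] data frame.
#' @param labels named character vector (id -> type in {A1, A2, B, C, NOR}).
#' @return a `reference_set`: list with `records` (labeled subset, original
#'   order), `labels` (named vector aligned to those records) and `dropped`
#'   (character vector of unlabeled record ids).
#' @export
build_reference_set <- function(records, labels) {
  types <- parse_enzyme_type(labels)
  names(types) <- names(labels)
  missing <- setdiff(names(types), records$id)
  if (length(missing) > 0) {
    stop("label(s) refer to missing record id(s): ",
         paste(missing, collapse = ", "))
  }
  keep <- records$id %in% names(types)
  out <- list(records = records[keep, , drop = FALSE],
              labels = types[records$id[keep]],
              dropped = records$id[!keep])
  class(out$records) <- c("protein_records", "data.frame")
  class(out) <- "reference_set"
  validate_reference_set(out)
  out
}

validate_reference_set <- function(x) {
  stopifnot(inherits(x, "reference_set"))
  if (!setequal(x$records$id, names(x$labels)) ||
      length(x$labels) != nrow(x$records)) {
    stop("reference set invariant violated: records and labels must be in bijection")
  }
  if (any(!(x$labels %in% hco_types()))) {
    stop("reference labels must lie in the closed type set")
  }
  invisible(x)
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set: ", nrow(x$records), " labeled sequence(s)\n", sep = "")
  print(table(x$labels))
  if (length(x$dropped)) cat("dropped (unlabeled): ", length(x$dropped), "\n", sep = "")
  invisible(x)
}
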