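#' @keywords internal
"_PACKAGE"

# 20 canonical amino acids; X is the ambiguity code kept after normalization
AA_CANONICAL <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALPHABET <- c(AA_CANONICAL, "X")
# non-canonical IUPAC letters collapsed to X on read
AA_REMAP_TO_X <- c("B", "Z", "J", "U", "O")

#' Enzyme type labels
#'
#' The closed label set used throughout: heme-copper oxygen reductase types
#' A1, A2, B and C, plus nitric oxide reductases (NOR). `UNCLASSIFIED` is a
#' classifier *output* only and is never a valid reference label.
#'
#' @return `hco_types()` returns the five reference labels;
#'   `hco_unclassified()` returns the sentinel output label.
#' @export
hco_types <- function() c("A1", "A2", "B", "C", "NOR")

#' @rdname hco_types
#' @export
hco_unclassified <- function() "UNCLASSIFIED"

#' Construct a set of protein records
#'
#' A `protein_records` object is a data frame with one row per sequence and
#' columns `id`, `description`, `residues`, `taxonomy`, `accession`.
#' Residues are normalized to uppercase, stop symbols (`*`) are stripped,
#' and non-canonical letters (B, Z, J, U, O) are remapped to X with a
#' warning. Ids must be nonempty and unique; residues must be nonempty.
#'
#' @param id character vector of unique sequence ids.
#' @param residues character vector of amino-acid strings.
#' @param description free-text header descriptions (default `""`).
#' @param taxonomy optional organism/taxonomy strings (opaque pass-through).
#' @param accession optional accession strings.
#' @return a `protein_records` data frame.
#' @export
protein_records <- function(id, residues, description = "", taxonomy = NA_character_,
                            accession = NA_character_) {
  id <- as.character(id)
  residues <- vapply(as.character(residues), normalize_residues, character(1),
                     USE.NAMES = FALSE)
  if (any(!nzchar(id)) || anyNA(id)) {
    stop("protein record ids must be nonempty")
  }
  if (anyDuplicated(id)) {
    stop("duplicate protein record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(residues))) {
    stop("protein records must have nonempty residues: ",
         paste(id[!nzchar(residues)], collapse = ", "))
  }
  out <- data.frame(id = id, description = rep_len(as.character(description), length(id)),
                    residues = residues,
                    taxonomy = rep_len(as.character(taxonomy), length(id)),
                    accession = rep_len(as.character(accession), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Normalize a residue string
#'
#' Uppercases, strips whitespace and `*` stop symbols, remaps non-canonical
#' letters (B, Z, J, U, O) to X, and rejects characters outside the
#' 20-letter alphabet plus X.
#'
#' @param x a single residue string.
#' @return the normalized string.
#' @export
normalize_residues <- function(x) {
  x <- toupper(gsub("[[:space:]*]", "", x))
  if (!nzchar(x)) return(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- ch %in% AA_REMAP_TO_X
  if (any(bad)) {
    warning("non-canonical residue letter(s) ",
            paste(unique(ch[bad]), collapse = ", "), " remapped to X",
            call. = FALSE)
    ch[bad] <- "X"
  }
  out <- setdiff(unique(ch), AA_ALPHABET)
  if (length(out) > 0) {
    stop("residue string contains letters outside the amino-acid alphabet: ",
         paste(out, collapse = ", "))
  }
  paste(ch, collapse = "")
}

#' @export
print.protein_records <- function(x, ...) {
  cat("protein_records: ", nrow(x), " sequence(s), lengths ",
      if (nrow(x)) paste0(min(nchar(x$residues)), "-", max(nchar(x$residues))) else "-",
      "\n", sep = "")
  invisible(x)
}

#' Parse enzyme-type tokens
#'
#' Case-insensitive parsing onto the closed label set; anything outside
#' {A1, A2, B, C, NOR} is an error.
#'
#' @param x character vector of type tokens.
#' @return character vector of canonical labels.
#' @export
parse_enzyme_type <- function(x) {
  up <- toupper(trimws(as.character(x)))
  bad <- !(up %in% hco_types())
  if (any(bad)) {
    stop("unknown enzyme type token(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (allowed: ", paste(hco_types(), collapse = ", "), ")")
  }
  up
}
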