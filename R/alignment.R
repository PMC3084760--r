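# Pairwise alignment, percent similarity and E-values.
#
# Local alignments use BLOSUM62 with affine gaps (a gap of length k costs
# open + k * extend); defaults follow the classic blastp parameterization
# (open 11, extend 1). E-values come from the plain Karlin-Altschul formula
# K * m * n * exp(-lambda * S) with fixed gapped-BLOSUM62 constants; no
# composition-based adjustment is applied.

#' Alignment scoring configuration
#'
#' @param matrix substitution matrix name; only "BLOSUM62" is shipped.
#' @param gap_open gap opening penalty (positive; default 11).
#' @param gap_extend gap extension penalty per residue (positive; default 1).
#' @param lambda Karlin-Altschul lambda for the gapped scheme (default 0.267).
#' @param K Karlin-Altschul K (default 0.041).
#' @param evalue_max reporting threshold for hits (default 10).
#' @return an `align_scoring` list.
#' @export
align_scoring <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          lambda = 0.267, K = 0.041, evalue_max = 10) {
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be nonnegative")
  if (!identical(matrix, "BLOSUM62")) stop("unsupported substitution matrix: ", matrix)
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, evalue_max = evalue_max),
            class = "align_scoring")
}

# cache the BLOSUM62 matrix from Biostrings
.subst_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.check_alphabet <- function(residues) {
  ch <- unique(strsplit(paste(residues, collapse = ""), "", fixed = TRUE)[[1]])
  bad <- setdiff(ch, AA_ALPHABET)
  if (length(bad) > 0) {
    stop("sequence contains letters outside the scoring alphabet: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# per-alignment statistics from gapped aligned strings
.alignment_stats <- function(pat, sub) {
  m <- .subst_matrix()
  n <- length(pat)
  pc <- strsplit(pat, "", fixed = TRUE)
  sc <- strsplit(sub, "", fixed = TRUE)
  span <- nchar(pat)
  positives <- integer(n)
  identities <- integer(n)
  for (i in seq_len(n)) {
    p <- pc[[i]]; s <- sc[[i]]
    nongap <- p != "-" & s != "-"
    if (any(nongap)) {
      sc_i <- m[cbind(p[nongap], s[nongap])]
      positives[i] <- sum(sc_i > 0)
      identities[i] <- sum(p[nongap] == s[nongap])
    }
  }
  data.frame(span = span, positives = positives, identities = identities)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` for a raw alignment score `S` between
#' a query of length `m` and a subject (or database) of length `n`.
#'
#' @param raw_score raw alignment score in substitution-matrix units.
#' @param m,n query and subject lengths (positive).
#' @param scoring an [align_scoring()] configuration supplying lambda and K.
#' @return the expected number of chance alignments scoring >= `raw_score`.
#' @export
karlin_evalue <- function(raw_score, m, n, scoring = align_scoring()) {
  if (any(m <= 0) || any(n <= 0)) stop("m and n must be positive")
  if (scoring$lambda <= 0 || scoring$K <= 0) stop("lambda and K must be positive")
  scoring$K * m * n * exp(-scoring$lambda * raw_score)
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman optimal local alignment under BLOSUM62 with affine gaps,
#' reporting the single best-scoring segment pair together with the counts
#' used by the percent-similarity score: `positives` (aligned residue pairs
#' with positive substitution score), `identities`, and `query_span` (all
#' alignment columns across the aligned query segment, gaps included — the
#' "alignment length" convention of BLAST reports).
#'
#' @param a,b residue strings (query, subject), or single-row
#'   [protein_records()].
#' @param scoring an [align_scoring()] configuration.
#' @param a_id,b_id ids used in the result (defaults taken from records).
#' @return a `pair_alignment` list: query_id, subject_id, raw_score,
#'   bit_score, evalue, positives, identities, query_span, and the 1-based
#'   aligned intervals on both sequences.
#' @export
local_align <- function(a, b, scoring = align_scoring(), a_id = "query",
                        b_id = "subject") {
  if (inherits(a, "protein_records")) { a_id <- a$id[1]; a <- a$residues[1] }
  if (inherits(b, "protein_records")) { b_id <- b$id[1]; b <- b$residues[1] }
  if (!nzchar(a) || !nzchar(b)) stop("cannot align empty sequences")
  .check_alphabet(c(a, b))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = .subst_matrix(),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  stats <- .alignment_stats(as.character(Biostrings::aligned(Biostrings::pattern(al))),
                            as.character(Biostrings::aligned(Biostrings::subject(al))))
  s <- Biostrings::score(al)
  structure(list(
    query_id = a_id, subject_id = b_id,
    raw_score = s,
    bit_score = (scoring$lambda * s - log(scoring$K)) / log(2),
    evalue = karlin_evalue(s, nchar(a), nchar(b), scoring),
    positives = stats$positives, identities = stats$identities,
    query_span = stats$span,
    query_start = Biostrings::start(Biostrings::pattern(al)),
    query_end = Biostrings::end(Biostrings::pattern(al)),
    subject_start = Biostrings::start(Biostrings::subject(al)),
    subject_end = Biostrings::end(Biostrings::subject(al))),
    class = "pair_alignment")
}

#' Percent similarity of a local alignment
#'
#' `100 * positives / query_span`: the number of positive-scoring aligned
#' residue pairs over the alignment length of the query segment.
#'
#' @param aln a `pair_alignment` from [local_align()].
#' @return percent similarity in \[0, 100\].
#' @export
similarity_percent <- function(aln) {
  if (aln$query_span <= 0) stop("undefined similarity: query_span is zero")
  100 * aln$positives / aln$query_span
}

# batch: align many query strings against one subject string; returns a
# data.frame of score/positives/identities/span per query
.align_batch <- function(queries, subject, scoring) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = .subst_matrix(),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  stats <- .alignment_stats(as.character(Biostrings::aligned(Biostrings::pattern(al))),
                            as.character(Biostrings::aligned(Biostrings::subject(al))))
  stats$score <- Biostrings::score(al)
  stats
}

#' Symmetrize a directed similarity matrix
#'
#' Directed percent-similarity values for the two orientations of a pair
#' are combined by their arithmetic mean; a missing direction (NA) is
#' treated as 0 with a warning. The diagonal is forced to 100.
#'
#' @param raw square numeric matrix of directed percent scores, with
#'   dimnames giving sequence ids.
#' @return a `similarity_matrix`: list with `ids` and symmetric `sim`.
#' @export
symmetrize <- function(raw) {
  stopifnot(is.matrix(raw), nrow(raw) == ncol(raw))
  if (anyNA(raw)) {
    warning("missing directed similarity value(s) treated as 0")
    raw[is.na(raw)] <- 0
  }
  sim <- (raw + t(raw)) / 2
  diag(sim) <- 100
  out <- list(ids = rownames(raw), sim = sim)
  class(out) <- "similarity_matrix"
  validate_similarity_matrix(out)
  out
}

validate_similarity_matrix <- function(x) {
  stopifnot(inherits(x, "similarity_matrix"))
  s <- x$sim
  if (any(s < 0 | s > 100)) stop("similarity values must lie in [0, 100]")
  if (any(abs(s - t(s)) > 1e-9)) stop("similarity matrix must be symmetric")
  if (any(abs(diag(s) - 100) > 1e-9)) stop("self-similarity must be 100")
  invisible(x)
}

#' All-versus-all percent-similarity matrix
#'
#' Aligns every pair of sequences locally and stores the symmetrized
#' percent-similarity score (`100 * positives / query_span`). With an exact
#' optimal aligner and a symmetric substitution matrix the two orientations
#' of a pair produce identical scores, so each unordered pair is aligned
#' once and the mean-symmetrization is the identity; pairs whose best local
#' score is not positive get similarity 0.
#'
#' @param records a [protein_records()] data frame with >= 2 rows.
#' @param scoring an [align_scoring()] configuration.
#' @return a `similarity_matrix`.
#' @export
all_vs_all <- function(records, scoring = align_scoring()) {
  n <- nrow(records)
  if (n < 2) stop("need at least 2 records")
  .check_alphabet(records$residues)
  raw <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (j in seq_len(n - 1)) {
    idx <- (j + 1):n
    st <- .align_batch(records$residues[idx], records$residues[j], scoring)
    val <- ifelse(st$score > 0 & st$span > 0, 100 * st$positives / st$span, 0)
    raw[idx, j] <- val
    raw[j, idx] <- val
  }
  diag(raw) <- 100
  symmetrize(raw)
}

#' Write a similarity matrix as a long-format TSV
#'
#' One row per unordered pair: `id1`, `id2`, `similarity`.
#'
#' @param simmatrix a `similarity_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(simmatrix, path) {
  ids <- simmatrix$ids
  pairs <- which(upper.tri(simmatrix$sim), arr.ind = TRUE)
  tab <- data.frame(id1 = ids[pairs[, 1]], id2 = ids[pairs[, 2]],
                    similarity = simmatrix$sim[pairs])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
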