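# Best-hit annotation-transfer classification and leave-one-out
# benchmarking. A query is searched against the labeled reference set;
# hits are ranked by E-value (raw score, then subject id break ties), only
# hits with E-value below the acceptance cutoff (default 0.01) can
# classify, and in top-k modes (k = 2, 3, 5) the label is transferred only
# when the top k hits agree — disagreement leaves the query unclassified.

CLASSIFY_MODES <- c(top1 = 1L, top2 = 2L, top3 = 3L, top5 = 5L)

#' Rank reference hits for a query
#'
#' Aligns the query locally against every reference sequence and returns
#' hits with E-value <= the scoring configuration's reporting threshold
#' (default 10), sorted by ascending E-value, ties broken by descending
#' raw score, then ascending subject id.
#'
#' @param query residue string or single-row [protein_records()].
#' @param refset a `reference_set` from [build_reference_set()].
#' @param scoring an [align_scoring()] configuration.
#' @return data frame: subject_id, type, score, evalue, similarity.
#' @export
rank_hits <- function(query, refset, scoring = align_scoring()) {
  if (inherits(query, "protein_records")) query <- query$residues[1]
  if (nrow(refset$records) == 0) stop("empty reference set")
  # one vectorized call: subjects aligned as patterns against the query —
  # the optimal local score, positives and span are orientation-symmetric
  stats <- .align_batch(refset$records$residues, query, scoring)
  hits <- data.frame(
    subject_id = refset$records$id,
    type = unname(refset$labels[refset$records$id]),
    score = stats$score,
    evalue = karlin_evalue(stats$score, nchar(query),
                           nchar(refset$records$residues), scoring),
    similarity = ifelse(stats$span > 0, 100 * stats$positives / stats$span, 0),
    stringsAsFactors = FALSE)
  hits <- hits[hits$evalue <= scoring$evalue_max, , drop = FALSE]
  hits[order(hits$evalue, -hits$score, hits$subject_id), , drop = FALSE]
}

# core decision rule shared by classify() and leave_one_out(): takes the
# ranked hit table and returns predicted type + status
.decide_from_hits <- function(hits, mode, evalue_cutoff) {
  k <- CLASSIFY_MODES[[mode]]
  pass <- hits[hits$evalue < evalue_cutoff, , drop = FALSE]
  if (nrow(pass) == 0) {
    return(list(predicted = hco_unclassified(), status = "no_hit"))
  }
  top <- pass[seq_len(min(k, nrow(pass))), , drop = FALSE]
  types <- unique(top$type)
  if (length(types) == 1) {
    list(predicted = types, status = "classified")
  } else {
    list(predicted = hco_unclassified(), status = "unclassified")
  }
}

#' Classify a query by best-hit annotation transfer
#'
#' Hits with E-value below `evalue_cutoff` are accepted; with no accepted
#' hit the query cannot be classified (status `no_hit`). In mode `top1`
#' the first hit's label is transferred; in modes `top2`/`top3`/`top5`
#' the label is transferred only if the first k accepted hits carry the
#' same label, otherwise the query is `unclassified`. When fewer than k
#' hits pass the cutoff, agreement is evaluated over those available.
#'
#' @param query residue string or single-row [protein_records()].
#' @param refset a `reference_set`.
#' @param mode one of "top1", "top2", "top3", "top5".
#' @param evalue_cutoff acceptance threshold (default 0.01).
#' @param scoring an [align_scoring()] configuration.
#' @return a `classification_result`: list with query_id, predicted, mode,
#'   status ("classified", "unclassified" or "no_hit") and the ranked
#'   `hits` data frame.
#' @export
classify <- function(query, refset, mode = "top1", evalue_cutoff = 0.01,
                     scoring = align_scoring()) {
  mode <- match.arg(mode, names(CLASSIFY_MODES))
  query_id <- if (inherits(query, "protein_records")) query$id[1] else "query"
  hits <- rank_hits(query, refset, scoring)
  dec <- .decide_from_hits(hits, mode, evalue_cutoff)
  structure(list(query_id = query_id, predicted = dec$predicted, mode = mode,
                 status = dec$status, hits = hits),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("classification_result [", x$mode, "]: ", x$query_id, " -> ",
      x$predicted, " (", x$status, ")\n", sep = "")
  invisible(x)
}

# all-vs-all score/evalue/similarity tables used by leave_one_out; one
# alignment per unordered pair (exact aligner is symmetric in score,
# positives and span), e-values recomputed per orientation from m and n
.pairwise_tables <- function(records, scoring) {
  n <- nrow(records)
  len <- nchar(records$residues)
  score <- matrix(-Inf, n, n, dimnames = list(records$id, records$id))
  simil <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (j in seq_len(n - 1)) {
    idx <- (j + 1):n
    st <- .align_batch(records$residues[idx], records$residues[j], scoring)
    score[idx, j] <- st$score
    score[j, idx] <- st$score
    val <- ifelse(st$span > 0, 100 * st$positives / st$span, 0)
    simil[idx, j] <- val
    simil[j, idx] <- val
  }
  evalue <- scoring$K * outer(len, len) * exp(-scoring$lambda * score)
  dimnames(evalue) <- dimnames(score)
  list(score = score, evalue = evalue, similarity = simil)
}

#' Leave-one-out benchmark of the best-hit classifier
#'
#' Each reference sequence in turn is removed from the reference set and
#' classified against the remainder. A correct prediction increments the
#' true-positive count of its type; a wrong classification increments the
#' false positives of the predicted type and the false negatives of the
#' true type; an unclassified or hit-less query counts as a false negative
#' of its true type.
#'
#' @param refset a `reference_set` with >= 2 records.
#' @param mode classification mode (default "top1").
#' @param evalue_cutoff acceptance threshold (default 0.01).
#' @param scoring an [align_scoring()] configuration.
#' @return a `confusion_tally`: list with `counts` (data frame type, tp,
#'   fp, fn), `n_unclassified`, and `predictions` (per-query data frame).
#' @export
leave_one_out <- function(refset, mode = "top1", evalue_cutoff = 0.01,
                          scoring = align_scoring()) {
  mode <- match.arg(mode, names(CLASSIFY_MODES))
  n <- nrow(refset$records)
  if (n < 2) stop("leave-one-out needs at least 2 reference sequences")
  labels <- refset$labels[refset$records$id]
  singles <- names(which(table(labels) == 1))
  if (length(singles) > 0) {
    warning("type(s) with a single member (no same-type neighbor in LOO): ",
            paste(singles, collapse = ", "))
  }
  tabs <- .pairwise_tables(refset$records, scoring)
  ids <- refset$records$id
  preds <- character(n); status <- character(n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    hits <- data.frame(subject_id = ids[keep],
                       type = unname(labels[keep]),
                       score = tabs$score[keep, i],
                       evalue = tabs$evalue[keep, i],
                       stringsAsFactors = FALSE)
    hits <- hits[hits$evalue <= scoring$evalue_max, , drop = FALSE]
    hits <- hits[order(hits$evalue, -hits$score, hits$subject_id), , drop = FALSE]
    dec <- .decide_from_hits(hits, mode, evalue_cutoff)
    preds[i] <- dec$predicted
    status[i] <- dec$status
  }
  confusion_tally(truth = unname(labels), predicted = preds, ids = ids,
                  status = status)
}

#' Build a confusion tally from truths and predictions
#'
#' @param truth character vector of true type labels.
#' @param predicted character vector of predicted labels (may contain
#'   UNCLASSIFIED).
#' @param ids optional query ids.
#' @param status optional per-query status strings.
#' @return a `confusion_tally`.
#' @export
confusion_tally <- function(truth, predicted, ids = NULL, status = NULL) {
  stopifnot(length(truth) == length(predicted))
  types <- hco_types()
  counts <- data.frame(type = types, tp = 0L, fp = 0L, fn = 0L,
                       stringsAsFactors = FALSE)
  rownames(counts) <- types
  n_unclassified <- 0L
  for (i in seq_along(truth)) {
    tr <- truth[i]; pr <- predicted[i]
    if (pr == tr) {
      counts[tr, "tp"] <- counts[tr, "tp"] + 1L
    } else if (pr %in% types) {
      counts[pr, "fp"] <- counts[pr, "fp"] + 1L
      counts[tr, "fn"] <- counts[tr, "fn"] + 1L
    } else {
      counts[tr, "fn"] <- counts[tr, "fn"] + 1L
      n_unclassified <- n_unclassified + 1L
    }
  }
  structure(list(counts = counts, n_unclassified = n_unclassified,
                 predictions = data.frame(
                   id = if (is.null(ids)) as.character(seq_along(truth)) else ids,
                   truth = truth, predicted = predicted,
                   status = if (is.null(status)) NA_character_ else status,
                   stringsAsFactors = FALSE)),
            class = "confusion_tally")
}

#' @export
print.confusion_tally <- function(x, ...) {
  print(x$counts, row.names = FALSE)
  cat("unclassified:", x$n_unclassified, "\n")
  invisible(x)
}

#' Per-type precision and recall
#'
#' Precision is Tp / (Tp + Fp): the fraction of sequences classified as a
#' type that truly belong to it. Recall is Tp / (Tp + Fn): the fraction of
#' a type's members that are recovered. An empty denominator yields NA
#' (never 0 or 1).
#'
#' @param tally a `confusion_tally`.
#' @param type one of the reference types.
#' @return a value in \[0, 1\], or NA.
#' @export
precision <- function(tally, type) {
  row <- tally$counts[tally$counts$type == type, ]
  if (nrow(row) == 0) stop("unknown type: ", type)
  den <- row$tp + row$fp
  if (den == 0) NA_real_ else row$tp / den
}

#' @rdname precision
#' @export
recall <- function(tally, type) {
  row <- tally$counts[tally$counts$type == type, ]
  if (nrow(row) == 0) stop("unknown type: ", type)
  den <- row$tp + row$fn
  if (den == 0) NA_real_ else row$tp / den
}

#' Global (micro-averaged) precision and recall
#'
#' Sums the per-type counts before taking ratios: precision =
#' sum(Tp) / (sum(Tp) + sum(Fp)), recall = sum(Tp) / (sum(Tp) + sum(Fn)).
#'
#' @param tally a `confusion_tally`.
#' @return named numeric vector `c(precision = , recall = )` (NA on empty
#'   denominators).
#' @export
global_precision_recall <- function(tally) {
  tp <- sum(tally$counts$tp); fp <- sum(tally$counts$fp); fn <- sum(tally$counts$fn)
  c(precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
}

#' Summarize a tally as a per-type statistics table
#'
#' @param tally a `confusion_tally`.
#' @return data frame: type, tp, fp, fn, precision, recall, with a final
#'   "global" row holding the micro-averaged values.
#' @export
loo_statistics <- function(tally) {
  per <- tally$counts
  per$precision <- vapply(per$type, function(t) precision(tally, t), numeric(1))
  per$recall <- vapply(per$type, function(t) recall(tally, t), numeric(1))
  glob <- global_precision_recall(tally)
  rbind(per,
        data.frame(type = "global", tp = sum(per$tp), fp = sum(per$fp),
                   fn = sum(per$fn), precision = glob[["precision"]],
                   recall = glob[["recall"]], stringsAsFactors = FALSE))
}
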