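# Gold-standard curation filters: minimum length, presence of the six
# conserved histidine ligands of Cu_B (HCO) / Fe (NOR) and of the low- and
# high-spin hemes, exact-duplicate removal, and the one-sequence-per-
# species-and-type redundancy rule. Filters compose in the fixed order
# length -> ligand -> deduplication.

.filter_report <- function(kept, discarded_id = character(0),
                           discarded_reason = character(0)) {
  out <- list(kept = kept,
              discarded = data.frame(id = discarded_id, reason = discarded_reason,
                                     stringsAsFactors = FALSE))
  class(out) <- "filter_report"
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report: ", length(x$kept), " kept, ", nrow(x$discarded),
      " discarded\n", sep = "")
  if (nrow(x$discarded)) print(table(x$discarded$reason))
  invisible(x)
}

#' Filter records by minimum sequence length
#'
#' Records shorter than `min_length` residues are discarded with reason
#' `too_short`; a record exactly at the boundary is kept.
#'
#' @param records a [protein_records()] data frame.
#' @param min_length minimum accepted length (default 400).
#' @return a `filter_report`: `kept` ids and a `discarded` data frame of
#'   (id, reason).
#' @export
filter_by_length <- function(records, min_length = 400) {
  stopifnot(min_length >= 1)
  short <- nchar(records$residues) < min_length
  .filter_report(kept = records$id[!short],
                 discarded_id = records$id[short],
                 discarded_reason = rep("too_short", sum(short)))
}

#' Check the six conserved metal-ligand histidines
#'
#' After a global alignment of the record onto the anchor, the record must
#' carry a histidine at each of the six anchor positions that ligate Cu_B
#' (HCO) or Fe (NOR) and the low- and high-spin hemes. A gap or a
#' non-histidine residue at any of the six mapped positions fails the
#' check.
#'
#' @param record residue string or single-row [protein_records()].
#' @param anchor an [anchor_profile()] (its `ligand_his` slot is used), or
#'   an anchor residue string combined with `anchor_his_positions`.
#' @param anchor_his_positions six 1-based histidine positions in anchor
#'   numbering (ignored when `anchor` is an `anchor_profile`).
#' @param scoring an [align_scoring()] configuration.
#' @return TRUE iff all six ligand histidines are present.
#' @export
check_metal_ligand_histidines <- function(record, anchor,
                                          anchor_his_positions = NULL,
                                          scoring = align_scoring()) {
  if (inherits(record, "protein_records")) record <- record$residues[1]
  if (!nzchar(record)) stop("record is empty")
  if (inherits(anchor, "anchor_profile")) {
    positions <- anchor$ligand_his
    anchor_res <- anchor$anchor$residues
  } else {
    if (inherits(anchor, "protein_records")) anchor <- anchor$residues[1]
    anchor_res <- normalize_residues(anchor)
    positions <- anchor_his_positions
    if (is.null(positions) || length(positions) != 6) {
      stop("exactly six anchor histidine positions are required")
    }
    ares <- strsplit(anchor_res, "", fixed = TRUE)[[1]]
    if (any(positions < 1 | positions > length(ares)) ||
        any(ares[positions] != "H")) {
      stop("declared ligand position is out of bounds or not histidine in the anchor")
    }
  }
  map <- build_position_map(record, anchor_res, scoring)
  res <- strsplit(record, "", fixed = TRUE)[[1]]
  all(vapply(positions, function(p) {
    qp <- map[p]
    !is.na(qp) && res[qp] == "H"
  }, logical(1)))
}

#' Filter records by the metal-ligand histidine check
#'
#' A record is kept if it passes [check_metal_ligand_histidines()] against
#' *any* of the configured anchors (typically one HCO anchor and one NOR
#' anchor); otherwise it is discarded with reason `missing_ligand`.
#'
#' @param records a [protein_records()] data frame.
#' @param anchors a list of [anchor_profile()] objects.
#' @param scoring an [align_scoring()] configuration.
#' @return a `filter_report`.
#' @export
filter_by_ligands <- function(records, anchors, scoring = align_scoring()) {
  if (inherits(anchors, "anchor_profile")) anchors <- list(anchors)
  ok <- vapply(seq_len(nrow(records)), function(i) {
    any(vapply(anchors, function(a) {
      check_metal_ligand_histidines(records$residues[i], a, scoring = scoring)
    }, logical(1)))
  }, logical(1))
  .filter_report(kept = records$id[ok],
                 discarded_id = records$id[!ok],
                 discarded_reason = rep("missing_ligand", sum(!ok)))
}

# species key: first two whitespace-separated tokens (binomial) of the
# taxonomy/organism string; NA when no taxonomy is available
.species_key <- function(taxonomy) {
  vapply(taxonomy, function(t) {
    if (is.na(t) || !nzchar(t)) return(NA_character_)
    tok <- strsplit(trimws(t), "[[:space:]]+")[[1]]
    paste(tok[seq_len(min(2, length(tok)))], collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Remove duplicate and strain-redundant records
#'
#' Exact duplicate residue strings are collapsed to a single record
#' (reason `duplicate`); among the remaining records that share both the
#' same species key (first two tokens of the taxonomy string) and the same
#' type label, only one is kept (reason `redundant_strain`). Ties are
#' broken deterministically: the lexicographically smallest id wins.
#' Records without taxonomy are never treated as strain-redundant.
#'
#' @param records a [protein_records()] data frame.
#' @param labels named character vector (id -> type) covering all records.
#' @return a `filter_report`.
#' @export
deduplicate <- function(records, labels) {
  if (!all(records$id %in% names(labels))) {
    stop("labels must cover all records: missing ",
         paste(setdiff(records$id, names(labels)), collapse = ", "))
  }
  ord <- order(records$id)
  rec <- records[ord, , drop = FALSE]
  disc_id <- character(0); disc_reason <- character(0)

  dup <- duplicated(rec$residues)
  disc_id <- c(disc_id, rec$id[dup])
  disc_reason <- c(disc_reason, rep("duplicate", sum(dup)))
  rec <- rec[!dup, , drop = FALSE]

  key <- .species_key(rec$taxonomy)
  group <- ifelse(is.na(key), NA_character_,
                  paste(key, unname(labels[rec$id]), sep = "\r"))
  red <- !is.na(group) & duplicated(group, incomparables = NA)
  disc_id <- c(disc_id, rec$id[red])
  disc_reason <- c(disc_reason, rep("redundant_strain", sum(red)))
  kept <- rec$id[!red]

  .filter_report(kept = records$id[records$id %in% kept],
                 discarded_id = disc_id, discarded_reason = disc_reason)
}

#' Run the full curation filter chain
#'
#' Applies, in order, the length filter, the metal-ligand histidine filter
#' and the duplicate/strain-redundancy filter, and merges the reports.
#' The union of kept and discarded ids always equals the input ids.
#'
#' @param records a [protein_records()] data frame.
#' @param labels named character vector (id -> type); required for the
#'   redundancy stage.
#' @param anchors list of [anchor_profile()] objects for the ligand check;
#'   `NULL` skips that stage.
#' @param min_length minimum accepted length (default 400).
#' @param scoring an [align_scoring()] configuration.
#' @param verbose log per-sequence discard reasons to stderr.
#' @return a list: `records` (kept subset) and `report` (`filter_report`).
#' @export
curate_records <- function(records, labels, anchors = NULL, min_length = 400,
                           scoring = align_scoring(), verbose = FALSE) {
  rep1 <- filter_by_length(records, min_length)
  cur <- records[records$id %in% rep1$kept, , drop = FALSE]
  disc <- rep1$discarded
  if (!is.null(anchors) && nrow(cur) > 0) {
    rep2 <- filter_by_ligands(cur, anchors, scoring)
    cur <- cur[cur$id %in% rep2$kept, , drop = FALSE]
    disc <- rbind(disc, rep2$discarded)
  }
  if (nrow(cur) > 0) {
    rep3 <- deduplicate(cur, labels)
    cur <- cur[cur$id %in% rep3$kept, , drop = FALSE]
    disc <- rbind(disc, rep3$discarded)
  }
  if (verbose && nrow(disc) > 0) {
    for (i in seq_len(nrow(disc))) {
      message("discarded ", disc$id[i], ": ", disc$reason[i])
    }
  }
  report <- .filter_report(cur$id, disc$id, disc$reason)
  class(cur) <- c("protein_records", "data.frame")
  list(records = cur, report = report)
}

#' Write a filter report as TSV
#'
#' @param report a `filter_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  tab <- rbind(data.frame(id = report$kept, status = "kept", reason = "",
                          stringsAsFactors = FALSE),
               data.frame(id = report$discarded$id, status = "discarded",
                          reason = report$discarded$reason,
                          stringsAsFactors = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
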