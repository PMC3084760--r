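# Synthetic sequence families with planted fingerprints.
#
# One packaged ~500-residue template per enzyme type carries that type's
# full residue fingerprint (channel residues, Tyr-I/Tyr-II, ligand
# histidines, NOR motifs) at known anchor positions; families are grown by
# copying a template and applying random point substitutions at a fixed
# per-site rate. Templates are synthetic sequences designed around the
# packaged anchor profile, not copies of database entries. Their
# background (non-fingerprint) positions avoid H, E and the aromatic
# residues so that motif and channel evidence can only arise from planted
# positions; mutations introduced by the generator are free to use the
# full alphabet.

# anchor coordinates shared by all templates (anchor numbering = template
# position; templates are 500 residues long, no indels between types)
TEMPLATE_LENGTH <- 500L
D_CHANNEL_POSITIONS <- c(Tyr35 = 35L, Asn113 = 113L, Asp124 = 124L,
                         Asn131 = 131L, Ser134 = 134L, Ser193 = 193L,
                         Asn199 = 199L)
POS_278 <- 278L
K_CHANNEL_POSITIONS <- c(Tyr280 = 280L, Ser291 = 291L, Thr351 = 351L,
                         Lys354 = 354L)
TYRII_REGION <- c(300L, 320L)
LIGAND_HIS_POSITIONS <- c(94L, 276L, 325L, 326L, 411L, 413L)
NOR_MOTIF1_WINDOW <- c(120L, 124L)
NOR_MOTIF2_WINDOW <- c(200L, 222L)

#' Packaged synthetic type templates
#'
#' Reads the five packaged templates (ids `A1_template` ... `NOR_template`),
#' each carrying its type's full fingerprint at the packaged anchor
#' positions.
#'
#' @return a [protein_records()] data frame of 5 rows.
#' @export
hco_templates <- function() {
  path <- system.file("extdata", "templates.fasta", package = "hcoclass",
                      mustWork = TRUE)
  read_fasta(path)
}

#' Default anchor profiles
#'
#' The packaged HCO profile (anchored on the A1 template, with D-channel,
#' K-channel, Tyr-II interval and ligand-histidine positions) and the NOR
#' ligand anchor (anchored on the NOR template).
#'
#' @return list with elements `hco` and `nor`, both [anchor_profile()]s.
#' @export
default_anchor_profiles <- function() {
  templates <- hco_templates()
  a1 <- templates[templates$id == "A1_template", , drop = FALSE]
  nor <- templates[templates$id == "NOR_template", , drop = FALSE]
  class(a1) <- class(nor) <- c("protein_records", "data.frame")
  list(
    hco = anchor_profile(a1, d_channel = D_CHANNEL_POSITIONS, pos278 = POS_278,
                         k_channel = K_CHANNEL_POSITIONS,
                         tyrII_region = TYRII_REGION,
                         ligand_his = LIGAND_HIS_POSITIONS),
    nor = anchor_profile(nor, ligand_his = LIGAND_HIS_POSITIONS))
}

#' Fingerprint positions protected from mutation
#'
#' The union of all planted fingerprint coordinates: D-channel roles,
#' position 278, K-channel roles, the Tyr-II helix-VII interval, the six
#' ligand histidines and the two NOR motif windows. The same protected set
#' is used for every type so that mutations can neither destroy a planted
#' fingerprint nor create a spurious one at a fingerprint site.
#'
#' @return sorted integer vector of template positions.
#' @export
protected_fingerprint_sites <- function() {
  sort(unique(c(D_CHANNEL_POSITIONS, POS_278, K_CHANNEL_POSITIONS,
                TYRII_REGION[1]:TYRII_REGION[2], LIGAND_HIS_POSITIONS,
                NOR_MOTIF1_WINDOW[1]:NOR_MOTIF1_WINDOW[2],
                NOR_MOTIF2_WINDOW[1]:NOR_MOTIF2_WINDOW[2])))
}

#' Generate one synthetic family
#'
#' Copies the type's template `n` times and substitutes each site
#' independently with probability `rate`, drawing the replacement
#' uniformly from the 19 alternative canonical residues. With
#' `protect_fingerprint = TRUE` (the default) the planted fingerprint
#' positions and motif windows are never mutated. Deterministic for a
#' fixed seed.
#'
#' @param type one of A1, A2, B, C, NOR.
#' @param n family size.
#' @param rate per-site substitution probability in \[0, 1).
#' @param seed integer seed.
#' @param protect_fingerprint keep fingerprint sites intact (default TRUE).
#' @param templates template records (default: packaged).
#' @param id_prefix prefix for generated ids (default the type).
#' @return a [protein_records()] data frame with `n` rows; each record's
#'   taxonomy is a distinct synthetic binomial so generated families are
#'   not strain-redundant.
#' @export
generate_family <- function(type, n, rate = 0.15, seed = 1,
                            protect_fingerprint = TRUE, templates = NULL,
                            id_prefix = NULL) {
  type <- parse_enzyme_type(type)
  stopifnot(n >= 1, rate >= 0, rate < 1)
  if (is.null(templates)) templates <- hco_templates()
  tid <- paste0(type, "_template")
  if (!tid %in% templates$id) stop("no template for type ", type)
  template <- strsplit(templates$residues[templates$id == tid], "", fixed = TRUE)[[1]]
  L <- length(template)
  mutable <- seq_len(L)
  if (protect_fingerprint) {
    mutable <- setdiff(mutable, protected_fingerprint_sites())
  }
  if (is.null(id_prefix)) id_prefix <- type
  set.seed(seed)
  seqs <- character(n)
  for (i in seq_len(n)) {
    res <- template
    hit <- mutable[stats::runif(length(mutable)) < rate]
    for (p in hit) {
      res[p] <- sample(setdiff(AA_CANONICAL, res[p]), 1)
    }
    seqs[i] <- paste(res, collapse = "")
  }
  protein_records(
    id = sprintf("%s_%03d", id_prefix, seq_len(n)),
    residues = seqs,
    description = sprintf("%s_%03d synthetic %s-type subunit I", id_prefix,
                          seq_len(n), type),
    taxonomy = sprintf("Synthetica %s%03d", tolower(type), seq_len(n)))
}

#' Generate a synthetic gold-standard reference set
#'
#' Union of five families (one per type) with their labels; a small-scale
#' stand-in for a curated, type-labeled reference collection.
#'
#' @param per_type_n sequences per type (>= 2).
#' @param rate per-site substitution rate (default 0.15).
#' @param seed integer seed; family i uses `seed + i`.
#' @param protect_fingerprint passed to [generate_family()].
#' @param out_dir optional directory; when given, writes
#'   `gold_standard.fasta` and `gold_standard_labels.tsv` there.
#' @return a `reference_set`.
#' @export
generate_gold_standard <- function(per_type_n = 30, rate = 0.15, seed = 1,
                                   protect_fingerprint = TRUE, out_dir = NULL) {
  stopifnot(per_type_n >= 2)
  templates <- hco_templates()
  fams <- lapply(seq_along(hco_types()), function(i) {
    generate_family(hco_types()[i], per_type_n, rate, seed = seed + i,
                    protect_fingerprint = protect_fingerprint,
                    templates = templates)
  })
  records <- do.call(rbind, fams)
  class(records) <- c("protein_records", "data.frame")
  labels <- stats::setNames(rep(hco_types(), each = per_type_n), records$id)
  refset <- build_reference_set(records, labels)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(records, file.path(out_dir, "gold_standard.fasta"))
    write_labels(labels, file.path(out_dir, "gold_standard_labels.tsv"),
                 taxonomy = stats::setNames(records$taxonomy, records$id))
  }
  refset
}
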