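# Residue-fingerprint typing.
#
# Types are called from the proton-channel residue fingerprints of the
# catalytic subunit: the D-channel residues (Asp124, Asn199, Asn113,
# Asn131, Tyr35, Ser134, Ser193 plus Glu278/Tyr278, P. denitrificans
# numbering), the A-type K-channel (Lys354, Thr351, Ser291, Tyr280 = Tyr-I),
# the B-type alternative K-channel (Tyr-I with Thr/Ser/Tyr at the K-channel
# role positions), the C-type alternative K-channel (Tyr-II in helix VII
# with Ser/Tyr at the Thr351/Ser291 role positions), and the two NOR
# sequence motifs H-X-(Arom)-X-E and H-H-X-(Arom)-(Arom)-X17-E. Anchor
# numbering is carried onto queries by a global pairwise alignment.

AROMATIC_RESIDUES <- c("F", "Y", "W")

FINGERPRINT_FEATURES <- c("d_channel", "d_channel_glu278", "d_channel_tyr_at_278",
                          "k_channel_A", "alt_k_channel_B", "alt_k_channel_C",
                          "tyrI", "tyrII", "nor_motif_1", "nor_motif_2")

# D-channel role -> expected residue (position 278 handled separately:
# Glu marks A1, Tyr marks A2)
D_CHANNEL_ROLES <- c(Tyr35 = "Y", Asn113 = "N", Asp124 = "D", Asn131 = "N",
                     Ser134 = "S", Ser193 = "S", Asn199 = "N")

# K-channel roles and the residues expected in the A-type channel and the
# B-type alternative channel (Thr, Ser, Tyr replace Lys354, Thr351, Ser291)
K_CHANNEL_ROLES_A <- c(Tyr280 = "Y", Ser291 = "S", Thr351 = "T", Lys354 = "K")
K_CHANNEL_ROLES_B <- c(Tyr280 = "Y", Ser291 = "Y", Thr351 = "S", Lys354 = "T")
# C-type alternative channel: Ser and Tyr at the Thr351/Ser291 positions,
# plus Tyr-II somewhere in the helix-VII interval of the anchor profile
K_CHANNEL_ROLES_C <- c(Ser291 = "Y", Thr351 = "S")

#' Construct an anchor profile
#'
#' An anchor profile ties a reference ("anchor") sequence to the 1-based
#' positions, in the anchor's own numbering, of the residue fingerprints:
#' the D-channel roles, the K-channel roles, position 278 (Glu in A1 / Tyr
#' in A2), the Tyr-I position, the helix-VII interval searched for Tyr-II,
#' and the six metal-ligand histidines. Every listed position must carry
#' the stated residue in the anchor itself.
#'
#' @param anchor a single-row [protein_records()] (or residue string).
#' @param d_channel named integer vector of anchor positions for the
#'   D-channel roles Tyr35, Asn113, Asp124, Asn131, Ser134, Ser193, Asn199.
#' @param pos278 anchor position of the Glu278/Tyr278 role.
#' @param k_channel named integer vector of anchor positions for the
#'   K-channel roles Tyr280, Ser291, Thr351, Lys354.
#' @param tyrII_region length-2 integer vector, the helix-VII interval
#'   (anchor numbering, inclusive) searched for Tyr-II.
#' @param ligand_his integer vector of exactly six histidine positions
#'   (Cu_B/Fe and heme ligands) used by the curation filter.
#' @param check_anchor validate that anchor residues match the stated
#'   roles (D/K channels checked only when `check_anchor = TRUE`; ligand
#'   positions are always required to be H).
#' @return an `anchor_profile` list.
#' @export
anchor_profile <- function(anchor, d_channel = NULL, pos278 = NULL,
                           k_channel = NULL, tyrII_region = NULL,
                           ligand_his, check_anchor = TRUE) {
  if (inherits(anchor, "protein_records")) {
    anchor <- list(id = anchor$id[1], residues = anchor$residues[1])
  } else {
    anchor <- list(id = "anchor", residues = normalize_residues(anchor))
  }
  res <- strsplit(anchor$residues, "", fixed = TRUE)[[1]]
  if (length(ligand_his) != 6) {
    stop("exactly six metal-ligand histidine positions are required")
  }
  if (any(ligand_his < 1 | ligand_his > length(res))) {
    stop("ligand histidine position outside anchor bounds")
  }
  if (any(res[ligand_his] != "H")) {
    stop("anchor residue at a declared ligand position is not histidine: ",
         paste(ligand_his[res[ligand_his] != "H"], collapse = ", "))
  }
  if (check_anchor && !is.null(d_channel)) {
    miss <- setdiff(names(D_CHANNEL_ROLES), names(d_channel))
    if (length(miss)) stop("d_channel positions missing roles: ", paste(miss, collapse = ", "))
    bad <- res[d_channel[names(D_CHANNEL_ROLES)]] != D_CHANNEL_ROLES
    if (any(bad)) stop("anchor D-channel residue mismatch at role(s): ",
                       paste(names(D_CHANNEL_ROLES)[bad], collapse = ", "))
  }
  if (check_anchor && !is.null(k_channel)) {
    miss <- setdiff(names(K_CHANNEL_ROLES_A), names(k_channel))
    if (length(miss)) stop("k_channel positions missing roles: ", paste(miss, collapse = ", "))
  }
  structure(list(anchor = anchor, d_channel = d_channel, pos278 = pos278,
                 k_channel = k_channel, tyrII_region = tyrII_region,
                 ligand_his = sort(as.integer(ligand_his))),
            class = "anchor_profile")
}

#' Map anchor positions onto a query by global alignment
#'
#' End-to-end (Needleman-Wunsch) alignment of the query against the anchor
#' under the same scoring scheme as the local aligner; every anchor
#' position is mapped to the aligned query position, or NA where the
#' anchor column faces a gap in the query.
#'
#' @param query residue string (or single-row [protein_records()]).
#' @param anchor residue string, single-row records, or `anchor_profile`.
#' @param scoring an [align_scoring()] configuration.
#' @return integer vector of length `nchar(anchor)`; element i is the
#'   1-based query position aligned to anchor position i, or NA.
#' @export
build_position_map <- function(query, anchor, scoring = align_scoring()) {
  if (inherits(query, "protein_records")) query <- query$residues[1]
  if (inherits(anchor, "anchor_profile")) anchor <- anchor$anchor$residues
  if (inherits(anchor, "protein_records")) anchor <- anchor$residues[1]
  if (!nzchar(query) || !nzchar(anchor)) stop("cannot align empty sequences")
  .check_alphabet(c(query, anchor))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(anchor),
    type = "global", substitutionMatrix = .subst_matrix(),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  qa <- strsplit(as.character(Biostrings::aligned(Biostrings::pattern(al))), "", fixed = TRUE)[[1]]
  aa <- strsplit(as.character(Biostrings::aligned(Biostrings::subject(al))), "", fixed = TRUE)[[1]]
  qpos <- cumsum(qa != "-")
  map <- ifelse(qa != "-", qpos, NA_integer_)[aa != "-"]
  as.integer(map)
}

.residue_at <- function(query_res, map, anchor_pos) {
  qp <- map[anchor_pos]
  if (is.na(qp)) NA_character_ else query_res[qp]
}

#' Detect D-channel fingerprint residues
#'
#' Checks the mapped positions of the seven core D-channel roles and
#' reports, in addition, whether the 278 role position carries Glu (the A1
#' signature) or Tyr (the A2 signature, where a tyrosine replaces the
#' glutamate). Gaps count as absent.
#'
#' @param query residue string or single-row [protein_records()].
#' @param profile an [anchor_profile()] with D-channel positions.
#' @param map position map from [build_position_map()] against
#'   `profile$anchor`.
#' @return named logical vector: `d_channel`, `d_channel_glu278`,
#'   `d_channel_tyr_at_278`.
#' @export
detect_d_channel <- function(query, profile, map) {
  if (inherits(query, "protein_records")) query <- query$residues[1]
  res <- strsplit(query, "", fixed = TRUE)[[1]]
  if (is.null(profile$d_channel)) {
    return(c(d_channel = FALSE, d_channel_glu278 = FALSE, d_channel_tyr_at_278 = FALSE))
  }
  got <- vapply(names(D_CHANNEL_ROLES), function(role) {
    r <- .residue_at(res, map, profile$d_channel[[role]])
    !is.na(r) && r == D_CHANNEL_ROLES[[role]]
  }, logical(1))
  at278 <- if (is.null(profile$pos278)) NA_character_ else .residue_at(res, map, profile$pos278)
  c(d_channel = all(got),
    d_channel_glu278 = !is.na(at278) && at278 == "E",
    d_channel_tyr_at_278 = !is.na(at278) && at278 == "Y")
}

#' Detect K-channel fingerprint variants
#'
#' Reports the A-type K-channel (Lys354, Thr351, Ser291, Tyr280 = Tyr-I),
#' the B-type alternative channel (Tyr-I retained; Thr, Ser and Tyr replace
#' the Lys354/Thr351/Ser291 residues), and the C-type alternative channel
#' (Tyr-II within the helix-VII interval, with Ser and Tyr at the
#' Thr351/Ser291 role positions). Gaps count as absent.
#'
#' @inheritParams detect_d_channel
#' @return named logical vector: `k_channel_A`, `alt_k_channel_B`,
#'   `alt_k_channel_C`, `tyrI`, `tyrII`.
#' @export
detect_k_channels <- function(query, profile, map) {
  if (inherits(query, "protein_records")) query <- query$residues[1]
  res <- strsplit(query, "", fixed = TRUE)[[1]]
  empty <- c(k_channel_A = FALSE, alt_k_channel_B = FALSE, alt_k_channel_C = FALSE,
             tyrI = FALSE, tyrII = FALSE)
  if (is.null(profile$k_channel)) return(empty)
  at <- function(role) .residue_at(res, map, profile$k_channel[[role]])
  matches <- function(roles) {
    all(vapply(names(roles), function(role) {
      r <- at(role)
      !is.na(r) && r == roles[[role]]
    }, logical(1)))
  }
  tyrI <- { r <- at("Tyr280"); !is.na(r) && r == "Y" }
  tyrII <- FALSE
  if (!is.null(profile$tyrII_region)) {
    span <- profile$tyrII_region[1]:profile$tyrII_region[2]
    qpos <- map[span]
    qpos <- qpos[!is.na(qpos)]
    tyrII <- length(qpos) > 0 && any(res[qpos] == "Y")
  }
  c(k_channel_A = matches(K_CHANNEL_ROLES_A),
    alt_k_channel_B = matches(K_CHANNEL_ROLES_B),
    alt_k_channel_C = tyrII && matches(K_CHANNEL_ROLES_C),
    tyrI = tyrI, tyrII = tyrII)
}

#' Match the two NOR sequence motifs
#'
#' Motif 1 is H-X-(Arom)-X-E; motif 2 is H-H-X-(Arom)-(Arom)-X17-E, where
#' (Arom) is an aromatic residue (F, Y or W), X is any residue and X17 is
#' exactly 17 arbitrary residues.
#'
#' @param residues a residue string.
#' @return logical vector `c(nor_motif_1, nor_motif_2)`.
#' @export
match_nor_motifs <- function(residues) {
  if (!nzchar(residues)) stop("cannot scan an empty residue string")
  arom <- paste0("[", paste(AROMATIC_RESIDUES, collapse = ""), "]")
  m1 <- grepl(paste0("H.", arom, ".E"), residues)
  m2 <- grepl(paste0("HH.", arom, arom, ".{17}E"), residues)
  c(nor_motif_1 = m1, nor_motif_2 = m2)
}

#' Decide the enzyme type from a fingerprint evidence vector
#'
#' Pure decision table over the fixed evidence vocabulary, applied in this
#' order: both NOR motifs -> NOR; D-channel with Glu278 -> A1; D-channel
#' with Tyr at 278 -> A2; no D-channel but the C-type alternative K-channel
#' (with Tyr-II) -> C; no D-channel but the B-type alternative K-channel
#' (with Tyr-I) -> B; anything else -> UNDETERMINED.
#'
#' @param evidence named logical vector over [FINGERPRINT_FEATURES].
#' @return one of "NOR", "A1", "A2", "C", "B", "UNDETERMINED".
#' @export
decide_type <- function(evidence) {
  ev <- function(k) isTRUE(unname(evidence[k]))
  if (ev("nor_motif_1") && ev("nor_motif_2")) return("NOR")
  if (ev("d_channel") && ev("d_channel_glu278")) return("A1")
  if (ev("d_channel") && ev("d_channel_tyr_at_278")) return("A2")
  if (!ev("d_channel") && ev("alt_k_channel_C")) return("C")
  if (!ev("d_channel") && ev("alt_k_channel_B")) return("B")
  "UNDETERMINED"
}

#' Assign an enzyme type from residue fingerprints
#'
#' Builds the evidence vector for a query — NOR motifs on the raw sequence,
#' channel residues through a global-alignment position map against the
#' HCO anchor profile — and applies the [decide_type()] decision table.
#'
#' @param query residue string or single-row [protein_records()].
#' @param profile an [anchor_profile()] for the HCO anchor (see
#'   [default_anchor_profiles()]).
#' @param scoring an [align_scoring()] configuration.
#' @return a `fingerprint_call`: list with `type` (A1/A2/B/C/NOR or
#'   "UNDETERMINED") and the named logical `evidence` vector.
#' @export
assign_type_by_fingerprint <- function(query, profile, scoring = align_scoring()) {
  if (inherits(query, "protein_records")) query <- query$residues[1]
  map <- build_position_map(query, profile, scoring)
  evidence <- c(detect_d_channel(query, profile, map),
                detect_k_channels(query, profile, map),
                match_nor_motifs(query))
  evidence <- evidence[FINGERPRINT_FEATURES]
  names(evidence) <- FINGERPRINT_FEATURES
  structure(list(type = decide_type(evidence), evidence = evidence),
            class = "fingerprint_call")
}

#' @export
print.fingerprint_call <- function(x, ...) {
  cat("fingerprint call:", x$type, "\n")
  cat("  evidence:", paste(names(x$evidence)[x$evidence], collapse = ", "), "\n")
  invisible(x)
}
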