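---
title: "Classifying heme-copper oxygen reductases and NORs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying heme-copper oxygen reductases and NORs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcoclass)
```

# The classification problem

Heme-copper oxygen reductases (HCOs) share a catalytic subunit I — at
least 12 transmembrane helices carrying a low-spin heme and a binuclear
center (high-spin heme plus Cu_B) — and divide into functional types A
(subdivided A1/A2), B and C according to the conserved residues of their
intra-protein proton channels. Nitric oxide reductases (NORs) are
homologs with Fe in place of Cu_B, no proton channel, and no cross-linked
tyrosine. `hcoclass` implements the two complementary typing procedures
used to build and exploit a curated, type-labeled reference set:
rule-based residue-fingerprint typing (used to label references) and
best-hit annotation transfer (used to classify arbitrary queries at
scale), together with the curation filters, the similarity network used
to validate the labeling, leave-one-out benchmarking, and
neighbor-joining trees.

# Curation filters

A candidate reference sequence is accepted when it

1. has at least `min_length = 400` residues (subunit I is a long
   polytopic membrane protein; shorter entries are fragments),
2. carries a histidine at all six anchor positions that ligate Cu_B/Fe
   and the two hemes, assessed after a global alignment onto an annotated
   anchor sequence; a record passes if it passes against *any* configured
   anchor (one HCO, one NOR) because the two enzyme classes have
   different reference numberings, and
3. survives redundancy removal: exact duplicate residue strings collapse
   to one, and among records sharing a species key (the first two tokens
   of the organism string, i.e. the binomial) *and* a type label only one
   is kept. The surviving record is the lexicographically smallest id —
   an arbitrary but deterministic tie-break.

The chain is fixed as length → ligand → deduplication, and each stage
partitions its input exactly into kept and discarded (with reasons), so
the composition conserves ids and is idempotent. Duplicate removal is by
exact residue string, not by accession: accessions are not guaranteed to
be present, and two accessions with identical sequences carry no extra
information for classification.

# Alignment and the similarity score

All pairwise comparisons use BLOSUM62 with affine gaps, gap open 11 and
extend 1 (a gap of length k costs `11 + k`); these are the classic
protein-search defaults. The per-pair percent similarity is

```
sim(x, y) = 100 * positives / query_span
```

where `positives` counts aligned residue pairs with a positive BLOSUM62
score and `query_span` counts all alignment columns across the aligned
query segment, gaps included (the "alignment length" of standard search
reports). Directed similarities are symmetrized by their arithmetic
mean. Because the internal aligner is an exact optimal aligner under a
symmetric substitution matrix, the two orientations of a pair give
identical score, positives and span — the mean-symmetrization is kept
for interface fidelity (heuristic engines do produce asymmetric scores)
but is the identity on the internal path, and `all_vs_all()` therefore
aligns each unordered pair once. The single best-scoring local alignment
is used per pair; summing secondary alignments would conflate domain
duplications with overall similarity.

E-values come from the plain Karlin–Altschul formula
`E = K·m·n·exp(−λS)` with the gapped-BLOSUM62 constants λ = 0.267,
K = 0.041 and no composition-based adjustment. Only the acceptance
threshold `E < 0.01` is decision-relevant, and ranking is monotone in
the raw score, so refinements of the E-value model cannot change any
classification — they only shift the absolute scale near the cutoff for
borderline (barely homologous) hits.

# Fingerprint typing

Anchor numbering (P. denitrificans convention) is carried onto a query
by an end-to-end global alignment against the packaged anchor; each
anchor position maps to a query position or to a gap. Evidence is then
read off:

- **D-channel**: Tyr35, Asn113, Asp124, Asn131, Ser134, Ser193, Asn199
  all present (exact residue identity at the mapped position; a gap
  counts as absent). Position 278 distinguishes Glu (A1) from Tyr (A2,
  where a tyrosine replaces the glutamate).
- **K-channel (A types)**: Lys354, Thr351, Ser291 and Tyr280 (Tyr-I).
- **Alternative K-channel (B)**: Tyr-I retained, with Thr, Ser and Tyr
  at the Lys354/Thr351/Ser291 role positions. The assignment order
  follows the listing order of the roles; it ships as editable profile
  data because no reference numbering for it is established.
- **Alternative K-channel (C)**: Tyr-II — any tyrosine within the
  helix-VII interval of the anchor profile (an interval because Tyr-II
  is located only to a helix, not to a column) — plus Ser and Tyr at
  the Thr351/Ser291 role positions.
- **NOR motifs**: `H-X-(Arom)-X-E` and `H-H-X-(Arom)-(Arom)-X17-E`,
  with (Arom) = {F, Y, W} and X17 exactly 17 arbitrary residues.
  Histidine is excluded from the aromatic class: the motifs spell their
  histidines explicitly, so reading H into (Arom) would blur the two.

The decision table, in priority order: both NOR motifs → NOR; D-channel
with Glu278 → A1; D-channel with Tyr278 → A2; no D-channel with the
C-type channel → C; no D-channel with the B-type channel → B; otherwise
UNDETERMINED with the full evidence vector returned. Requiring *both*
NOR motifs makes the NOR call robust: the short motif 1 can occur by
chance in unrelated sequence, motif 2 (two adjacent histidines, two
aromatics and an exactly spaced glutamate) essentially cannot. C is
tested before B because the C signature is the more specific one (it
requires Tyr-II); a sequence carrying both signatures is structurally
C-like. Channel matching is exact residue identity with no
conservative-substitution tolerance — sequences with degraded channels
are deliberately left UNDETERMINED and resolved by the best-hit
classifier, rather than by loosening the rules.

# Best-hit classification and benchmarking

A query is aligned against every reference; hits with E-value below the
reporting threshold (10) are ranked by ascending E-value, ties broken by
descending raw score and then ascending subject id (full determinism).
Hits with `E < 0.01` are accepted. `top1` transfers the best accepted
hit's label. `top2`/`top3`/`top5` transfer a label only when the first k
accepted hits agree; disagreement yields *unclassified* — once a
disagreement exists in the first k hits it persists for every larger k,
so larger k is monotonically more conservative. When fewer than k hits
pass the cutoff, agreement is evaluated over those available rather than
forcing unclassified, which would penalize small reference sets. With no
accepted hit at all the status is `no_hit` and the reported message is
"cannot be classified".

Leave-one-out cross-validation classifies each reference against the
remaining ones. Correct predictions increment the type's Tp; wrong
classifications increment Fp of the predicted and Fn of the true type;
unclassified queries increment Fn of the true type. Precision is
`Tp/(Tp+Fp)`, recall `Tp/(Tp+Fn)`, reported per type and globally. The
global statistic is micro-averaged (sum counts, then divide): with
heavily imbalanced type sizes this is the standard single-number
summary, and it makes global precision equal global recall whenever
every query is classified. An empty denominator yields NA, never 0 or 1,
so absent types cannot silently inflate a benchmark. The LOO driver
computes the all-vs-all alignment table once and re-ranks per held-out
query, rather than re-aligning n times.

# Network and trees

The similarity network has one node per sequence (annotated with its
label) and one weighted edge per unordered pair with positive similarity
at or above `min_edge` (default 0: all relationships retained). Cluster
structure is summarized by arithmetic-mean similarities within and
between types (within-type means over unordered distinct pairs; a
singleton type has an undefined within-mean, NA). The network is
exported (TSV edge list, GraphML with type attributes) but never laid
out here — layout is visualization, not inference.

Trees use classical Saitou–Nei neighbor joining on
`d = (100 − sim)/100`. No multiple-substitution correction is applied to
these similarity-derived distances: the tree serves the
clustering-consistency question, not branch-length estimation, and the
percent-similarity score is not a per-site substitution count to which
such corrections apply. NJ can return negative branch lengths on
non-additive input; they are clamped to zero with the deficit added to
the sibling edge, preserving the sibling–sibling path length. Bootstrap
support requires a user-supplied fixed multiple alignment (the package
deliberately has no multiple aligner): replicate r resamples alignment
columns with replacement after `set.seed(seed + r)`, builds an NJ tree
from pairwise p-distances (gap-containing columns skipped per pair;
pairs with no comparable columns get the maximal distance 1), and split
frequencies are recorded on the full-alignment tree. The default of 100
replicates is a desk-scale default; users wanting publication-grade
support values should raise it.

# The synthetic family generator

Real reference sets are built from public databases by homology search;
the packaged generator instead *plants* the fingerprints so that ground
truth is known exactly. Five ~500-residue templates (one per type)
descend from a single common ancestor background — the family is
homologous, and a shared scaffold is what keeps the global-alignment
position map in register for every type — diverged at 50% of
unconstrained sites, with conserved windows around every fingerprint
coordinate. Background positions avoid H, E, F, Y and W entirely, so
channel and motif evidence can only originate from planted sites; this
is the one deliberate unrealism of the templates (real membrane proteins
are rich in aromatics) and is what makes the zero-false-evidence
guarantee provable rather than probabilistic.

`generate_family()` copies a template and substitutes each site
independently with probability `rate`, drawing replacements uniformly
from the 19 alternative canonical residues (a simplest-neutral model: no
indels, no rate heterogeneity, no substitution bias).
`protect_fingerprint = TRUE` excludes the union of all fingerprint
coordinates of *all* types — including the helix-VII Tyr-II interval and
the NOR motif windows — from mutation, in every family. Protecting the
interval in non-C families matters: a mutation-introduced tyrosine in
the helix-VII window of a B-type sequence would satisfy the C signature
(B already carries the Ser/Tyr at the Thr351/Ser291 roles) and flip the
call. Mutations elsewhere are free to introduce any residue.

The default study conditions are 5 types × 30 sequences at rate 0.15
with protection — small enough to run on a laptop in ~2 minutes, large
enough that every type has a substantial family. Under these conditions
within-type mean similarity is ≈ 78% and cross-type means ≈ 48%: the
generated network reproduces the *qualitative* structure of real HCO/NOR
data (tight type clusters, looser between-cluster similarity), not its
quantitative values — real cross-type similarities are far lower because
real families diverged along entire evolutionary histories, not a single
50% scrambling step. Passing benchmarks on this synthetic set therefore
demonstrates correctness of the machinery (filters, alignment,
ranking, transfer rules, statistics), and says nothing about classifier
accuracy on sequences from families absent from a real reference set.

# Numerical and degenerate-input choices

- Residues are uppercased, `*` stop symbols stripped; the rare IUPAC
  letters B, Z, J, U, O map to X with a warning (X scores like an
  ambiguous residue under BLOSUM62) rather than rejecting usable
  records.
- Similarity with an empty alignment span is an error, not 0 — it can
  only arise from a zero-length alignment, which indicates a caller bug.
- `symmetrize()` treats a missing direction as 0 with a warning; the
  diagonal is forced to 100.
- NJ requires ≥ 3 taxa; the 3-taxon tree is the closed-form solution of
  the three-point equations.
- All stochastic components (generator, bootstrap) take explicit integer
  seeds and are reproducible bit-for-bit; the bootstrap seed protocol
  (`seed + r` per replicate) makes replicates independent of the order
  in which they are computed.

# Known limitations

- The fingerprint caller depends on the position map staying in
  register; queries with long insertions near fingerprint sites can map
  to gaps and fall back to UNDETERMINED (by design, never to a wrong
  type with silent confidence).
- The B/C alternative-channel role positions are shipped as editable
  profile data, not established truth; users with structural knowledge
  should adjust the packaged profile.
- E-values are single-pair Karlin–Altschul values, not database-size
  corrected; with very large reference sets the 0.01 cutoff is slightly
  more permissive than a database-corrected one.
- The internal aligner is exhaustive (no heuristic seeding); all-vs-all
  on thousands of sequences is quadratic and better delegated to an
  external search engine, re-importing its report.
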