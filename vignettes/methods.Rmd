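---
title: "Methods: how grasfam characterizes a GRAS gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how grasfam characterizes a GRAS gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`grasfam` implements the standard multi-stage workflow for genome-wide
characterization of a plant transcription-factor family — here the GRAS
family, whose members carry an ordered C-terminal domain of five motifs
(LHRI, VHIID, LHRII, PFYRE, SAW) and divide into subfamilies such as DELLA,
HAM, LISCL, PAT, SCR, SHR and SCL3. This vignette records the models,
parameter choices and numerical conventions behind each stage, and what the
bundled synthetic generator does and does not emulate.

## Locus tables and coordinates

All genomic coordinates are 1-based, fully closed intervals. This matches
both curated locus tables (comma-separated `start-end` spans) and GFF3, so
no half-open conversion happens at any boundary. Segments are stored in
ascending genomic order regardless of strand; exon indices count along the
genome, not along the transcript. Spliced length is the sum of segment
lengths, genomic span is `max(end) - min(start) + 1`, and the two coincide
exactly for single-exon genes. Span cells accept the hyphen-minus, en dash
and minus sign interchangeably, because curated tables copied through
word processors routinely mix them. Typographic emphasis that curated
tables sometimes use to carry annotation status is not machine-recoverable
and is dropped; an optional free-text `notes` column survives parsing.

Percentages in summaries are rounded half-even to two decimals (R's
`round`), e.g. 46/52 intronless reports as 88.46.

## Local alignment and expectation values

Cross-genome comparison uses exact affine-gap Smith–Waterman (in C++ via
Rcpp) rather than a heuristic seeded search. Exactness is a conservative
stand-in: it can only find alignments a heuristic search might miss, never
the reverse, and at gene-family scale (tens of proteins per genome, not
whole proteomes) the O(mn) cost is irrelevant. The scoring system is the
protein-search standard: BLOSUM62, gap open 11, gap extend 1, where a gap
of length L costs `gap_open + L * gap_extend`. Expectation values use the
Karlin–Altschul form `E = kappa * m * n * exp(-lambda * S)` with the gapped
constants lambda = 0.267 and kappa = 0.041 for this scoring system; m is
the query length and n the total residue count of the target set. All four
constants are arguments of `alignment_params()`.

Numerical conventions: identity is matches divided by aligned columns with
gap columns counted in the denominator; the traceback resolves ties
deterministically (diagonal, then gap-in-target, then gap-in-query); when
every attainable column score is negative, the optimal local alignment is
empty (score 0, empty span, identity undefined). The test suite checks the
scores against an exhaustive enumeration over every monotone set of aligned
residue pairs for all short words over a three-letter alphabet.

## Orthology

Hits are retained when `E < 1e-20` **and** identity `> 0.40`; both
inequalities are strict, read literally from the usual "lower than" /
"higher than" phrasing of such gates, and the tests pin the boundary
behavior (identity exactly 0.40 is rejected). Identity's denominator is the
alignment length; an alternative denominator (shorter sequence) would only
loosen the gate and can be emulated by lowering `min_identity`. The best
match is the retained hit with the highest raw score — the expectation
value depends on database size, so raw score is the more stable primary
criterion — with ties broken by lower E-value and then lexicographic target
ID so results never depend on input order. Gene A and its best match B are
one-to-one orthologs when A is also B's best match in the reverse
direction; queries with retained hits but no reciprocal best match are
homologs without ortholog; queries with no retained hit are absent.
Self-comparison within a genome is excluded.

## Progressive alignment and masking

The multiple aligner is a plain guide-tree progressive method: pairwise
local-alignment identities give distances, UPGMA (average linkage) gives
the merge order, and profiles are merged by affine-gap dynamic programming
over column-versus-column substitution scores (profile frequency vectors
with gap mass dropped), with end gaps free. There is no iterative
refinement. This is deliberate: downstream consumers are distance-based
phylogeny and within-subfamily motif discovery, which operate at low
divergence where progressive alignment is reliable; the package does not
claim alignment quality at deep divergence.

Columns with a non-gap fraction below 0.95 are then eliminated. The
comparison is strict ("less than"), so in a 20-row alignment a column with
exactly one gap — coverage exactly 0.95 — is kept. Only gaps count as
missing; ambiguous residues (X) count as coverage, a documented choice
where tools differ. Removing every column is an error signalling an
unusable alignment rather than silently returning an empty matrix.

## Distances, neighbor joining, bootstrap consensus

Distances are p-distances (mismatch fraction over mutually ungapped
columns) optionally corrected as `d = -ln(1 - p - 0.2 p^2)`, the standard
closed-form calibration to empirical amino-acid substitution models; the
correction is convex, so corrected distances never fall below p. Near
saturation (p above roughly 0.85) the logarithm's argument is floored at
1e-4, capping distances around 9.2 substitutions/site — large but finite so
neighbor joining remains defined between very distant subfamilies.

Trees come from Saitou–Nei neighbor joining. The package deliberately uses
NJ on corrected distances rather than a maximum-likelihood search: subfamily
assignment depends only on clade membership, which NJ recovers exactly from
additive distances (property-tested over random trees of up to six taxa)
and robustly at the divergences involved here, while remaining fast and
deterministic at desk scale. Negative branch lengths, which NJ can produce
on non-additive matrices, are clamped to zero in a single pass with the
deficit moved to the sibling edge (preserving leaf-to-leaf paths through
the parent), then floored at zero.

The bootstrap resamples alignment columns with replacement (seeded),
builds one NJ tree per replicate, and counts bipartitions in a canonical
form (the split side not containing the alphabetically first leaf).
Because NJ breaks exact distance ties by index, replicates are computed on
the label-sorted alignment so supports are invariant to input row order.
The consensus is an extended-majority dialect: splits with support at or
above the 30% floor (inclusive, tested at the boundary) are added greedily
in order of decreasing support — ties broken by split size and then by the
sorted label string — keeping each split only if compatible with those
already kept; everything else collapses to polytomies. Replicates whose
resampled columns leave some pair with no mutually ungapped position are
skipped with a warning and the support denominator adjusted.

Subfamily assignment anchors the consensus tree with reference proteins of
known subfamily: each unlabeled leaf takes the label of the smallest
retained clade containing it and at least one anchor, provided that
clade's anchors carry a single label; mixed or absent anchors leave the
leaf unassigned, and a fully collapsed star tree assigns nothing.

## Motif scanning and conserved windows

Patterns are residue strings where `X` and `+` are single-position
wildcards and `[LIVF]` is a per-position alternative set. `+` appears in
published consensus strings without a formal definition; it is read here as
a single-position wildcard, the most conservative interpretation. A
window's match score is the fraction of non-wildcard positions matched;
catalog scanning defaults to 0.7, and hits are made non-overlapping
greedily, best score first, leftmost on ties. The shipped catalog encodes
the five core GRAS-domain motifs plus DELLA, TVHYNP, LXXLL, `[LIVF]RITG`,
RVER and the XIV/XV/XVI units; literal units quoted in the primary
literature are verbatim, while core-unit consensus strings not printed
anywhere are synthetic placeholders (marked in the file) standing in for
curated subfamily alignments — users with curated alignments should edit
the catalog, which is a plain three-column text file.

De-novo discovery reports maximal runs of at least 10 consecutive columns
whose per-column identity is at least 0.50, both bounds inclusive.
Per-column identity is the modal-residue fraction with gaps counting
against the column — a deterministic replacement for manual
alignment-viewer inspection. Per-column (rather than window-average)
evaluation is the stricter reading and the default.

## Duplication classification

Tandem arrays are maximal chains of same-subfamily loci on one chromosome
with consecutive genomic spans at most 250 kb apart. No quantitative
definition of "tandem" is universal; 250 kb keeps genuinely arrayed
near-identical copies (tens of kb apart) in one array while excluding
same-chromosome subfamily members megabases away, and it is a flag, not a
constant. Segmental calls require two same-subfamily loci whose spans are
fully contained in the two intervals of a supplied paralogous-segment map
pair (the map is an input: ancestral-polyploidy segment coordinates are a
published resource, not something this package infers). Containment is
strict by default with an optional `tolerance_bp` for loci sitting just
beside a mapped segment.

## Expression

Replicates (typically 3–4 per condition) are averaged arithmetically in
log2 space. A gene gains a tissue's Plant Ontology term when its averaged
intensity in any condition of that tissue reaches log2 = 8; since raw 256
is exactly 2^8, the threshold is inclusive by default (a flag switches to
strict). Co-expression uses 1 − Pearson distance and average linkage, but
reported clusters must satisfy the bound pairwise — "distance lower than
0.2 between each other" is read as a complete-pair criterion, not merely a
tree height: the average-linkage tree is cut below the cutoff and any
cluster violating the pairwise bound is re-split by a complete-linkage cut,
whose merge heights are exactly maximal pairwise distances. Distances
within 1e-9 of the cutoff count as at the cutoff, so a pair at exactly 0.2
never co-clusters regardless of floating-point rounding. Constant profiles
(undefined correlation) are excluded with a warning; singletons are
reported as unclustered.

## The synthetic generator

`simulate_family()` emulates the statistical shape of the data the pipeline
consumes: 13 subfamilies of 4 members (the family's typical scale), protein
lengths 400–700, subfamily ancestors mutated from a shared root at half the
between-subfamily divergence (default 0.8 substitutions/site, deep but
below saturation), members mutated from their ancestor at half the
within-subfamily divergence (default 0.1), a mirrored second genome at
ortholog divergence 0.1 with a quarter of subfamilies dropped (emulating
lineage-specific loss), tandem arrays laid consecutively within the gap
rule, segmental pairs placed inside emitted map intervals, and an
expression atlas with 3–4 replicates per condition, tissue-specific genes
boosted well above the attribution threshold, and a 10-gene module sharing
a latent factor tuned to a target pairwise correlation of 0.9.

Sequence evolution is residue-frequency-weighted random replacement (each
site substitutes with probability `1 - exp(-d)`, replacement drawn from the
background excluding the current residue) along star-like subfamily trees,
with no indels. Motif instances are overwritten after mutation at fixed
per-subfamily offsets, so they are exactly conserved within a subfamily.
Two construction details keep the ground truth unambiguous: wildcard
positions of a planted instance are instantiated from residues outside the
pattern's own specified set, and each instance carries a three-residue
neutral guard flank, so a planted instance matches its pattern at exactly
one window and "exact boundary recovery" is well defined.

What the generator does **not** emulate — and hence what green tests do not
certify about real data: indel evolution and alignment-length variation
within subfamilies, rate heterogeneity and site-specific selection, codon
structure, genuinely nested within-subfamily phylogeny (a nested mode
exists for stress testing but the default is star-like, chosen so clade
recovery has an unambiguous truth), cross-platform probe effects, and the
mapping from probesets to genes. Results on real families additionally
depend on annotation quality, which no simulation captures.

## Problem sizes and runtime choices

Unit tests run reduced configurations (4 subfamilies × 3 members, proteins
of 320–380 residues, 50 expression conditions) chosen to preserve every
qualitative regime — multiple subfamilies, loss, arrays, a module — at
interactive speed; the end-to-end recovery checks and the acceptance script
run the full default configuration (52 genes, 100 bootstrap replicates).
The exhaustive alignment oracle covers all words of length up to five over
a three-letter alphabet; neighbor-joining recovery is property-checked over
200 random trees of up to six taxa. All randomness flows from explicit
seeds, and rerunning any pipeline stage with the same configuration and
seed is byte-identical.

## Known limitations

The progressive aligner has no refinement pass and should not be used as a
general-purpose aligner at deep divergence. The JTT-style distance
correction saturates and is capped; distances near the cap carry little
information, which is acceptable here only because subfamily assignment
needs clade membership, not accurate deep branch lengths. Orthology is
sequence-only (no synteny) and will report co-orthologs from recent
duplications as homolog-without-ortholog rather than resolving them.
Cross-platform expression integration is out of scope: the pipeline
operates on one normalized matrix at a time and expects probeset-to-gene
mapping to have happened upstream.
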