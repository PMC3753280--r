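---
title: "Modelling RNA junction topology with scaled tree graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling RNA junction topology with scaled tree graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(juncgraph)
```

## The problem and the representation

When three or more RNA helices meet at a junction, the fold of the whole
molecule depends on which helices stack coaxially and how the remaining
arms orient. `juncgraph` models each 3- or 4-way junction as a planar tree
graph: two vertices per helix (proximal = junction-facing end, distal =
far end) joined by a helix edge, plus one centroid vertex defined as the
arithmetic mean of the proximal vertices, joined to each of them by a
connector edge — 2n+1 vertices and 2n edges for an n-way junction. The
planarity assumption reflects the empirical tendency of junction helix
axes to be roughly coplanar; translated native graphs are *not* forced to
be planar, only model graphs are built that way.

## Pipeline

1. **Parsing.** Dot-bracket (four bracket families) or CT input; crossing
   pairs are removed by a dynamic program that keeps the
   maximum-cardinality nested subset (ties resolve toward the family whose
   first opening index is 5'-most — the choice is arbitrary but must be
   deterministic, and is validated against an exhaustive oracle in the
   tests). Helices require at least two consecutive stacked pairs;
   isolated single pairs dissolve into loops. Helices at a junction are
   labelled H1..Hn in 5'→3' encounter order with H1 the closing helix when
   one exists; this convention is what makes stack labels like "H1H2"
   well-defined.
2. **Topology prediction.** A two-stage random-forest classifier per
   degree: one forest predicts the coaxial-stack set, a second predicts
   the family with the (predicted) stack class appended to its features.
   The family taxonomy presupposes a stacking pattern, which is why the
   stages are ordered. A 3-way junction predicted unstacked gets family
   "none" and a radial model graph.
3. **Graph building.** Stacked pairs are laid antiparallel-collinear with
   a proximal-vertex gap `s0(L) = 2.75 L + 3.91` Å (L = intervening loop
   nucleotides, split symmetrically about the origin); helix edges have
   length `2.87 (b − 1)` Å; unstacked helices sit at their arrangement
   class's distance from the stack axis (parallel 20.48 Å, perpendicular
   19.95 Å, diagonal 21.17 Å) with the edge at 0°/90°/45° to the axis.
4. **Translation of solved structures.** Per terminal base pair: midpoint
   M of the two C1′ atoms, orthogonal projection P of M onto the
   purine-C8/pyrimidine-C6 line, vertex `O′ = M + 4 Å · unit(P − M)`.
   The proximal terminal pair is the one nearest the junction loop in
   sequence; pairs with missing atoms are skipped inward, and a helix with
   fewer than two usable pairs is a hard error naming the helix.
5. **Scoring.** RMSD over all 2n+1 label-matched vertices after
   least-squares proper-rotation superposition (SVD with determinant
   correction, so mirror images are never matched by a reflection);
   MaxAngle = the maximum angle over helix edges between corresponding
   edge vectors, evaluated in the same RMSD-optimal frame. Correspondence
   is always by vertex label, never nearest-neighbour.

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `s0_slope`, `s0_intercept` | 2.75, 3.91 | Å/nt, Å | coaxial gap regression |
| `base_rise` | 2.87 | Å/bp | helix edge length scale |
| `d_parallel`, `d_perpendicular`, `d_diagonal` | 20.48, 19.95, 21.17 | Å | unstacked-arm offset by class |
| `angle_*` | 0, 90, 45 | degrees | unstacked-arm direction by class |
| `ntree`, `mtry` | 500, √d | — | forest size / per-split feature draw |
| `side_sign` | +1 | — | which side of the stack axis unstacked arms occupy |

The distance values are knowledge-based averages from solved junctions and
are taken as published constants; an optional re-fit from user-supplied
native graphs is deliberately out of scope. Forest hyperparameters are
standard defaults — the learning problems involved are low-dimensional
(≈30–40 features) and were not tuned. `side_sign` exists because RMSD with
proper rotations only is *not* reflection-blind: the model's handedness
convention must match the translation module's, and the flag makes the
convention explicit.

## Committed design choices

Several geometric facts are under-determined by the published record and
are committed here as package conventions:

- **3-way family → arrangement**: A → perpendicular, B → diagonal,
  C → parallel. Only the parallel packing of family C is stated
  explicitly; A and B follow the schematic ordering.
- **4-way family table**: H {H1H2, H3H4} and cH {H1H4, H2H3} place their
  two stacks parallel, separated by `d_parallel`; cL {H1H4, H2H3} crosses
  them at 90°; cX {H1H2, H3H4} and X {H1H4, H2H3} cross at 45°;
  single-stack families π {H1H2}, cW {H2H3}, Ψ {H3H4}, cK {H1H4} place
  their two unstacked arms on opposite sides of the stack axis with
  committed arrangement classes (π: parallel/perpendicular, cW: both
  perpendicular, Ψ: both parallel, cK: both diagonal). The source material
  draws these families only schematically, without numeric angles; when
  native graphs are available, `derive_family_template()` offers a
  data-driven override (mean unit edge directions after mutual
  superposition, with degenerate averaged directions flagged).
- **Stack gaps in two-stack 4-way junctions** each use `s0` of their own
  intervening loop.
- **Arrangement distances are measured** from the unstacked helix's
  proximal vertex perpendicular to the stack-axis *line* — the same
  measurement the acceptance checks perform on built graphs.
- **Indices are 1-based** internally, matching R idiom and the CT format
  (a 0-based internal convention was considered and rejected as
  anti-idiomatic in R).

## The feature set

The published description names loop length and sequence content as the
classifier's inputs without enumerating a vector; the committed feature
set is: per-loop lengths; pairwise normalized length contrasts
`(Li − Lj)/(Li + Lj)`; per-loop A/C/G/U fractions and purine fraction
(all-zero for empty loops); closing-pair identity codes per helix; helix
base-pair counts; and total loop nucleotides. Dimensionality is fixed per
degree, and identical junctions always produce identical vectors.

## What the synthetic generator does and does not establish

`synthetic_junction_dataset()` emulates a curated junction corpus under a
stated world: coaxial stacks form across short loops (0–2 nt, weighted
toward 0) while unstacked arms are separated by 4–12 nt loops; roughly 10%
of 3-way junctions have no stack; the 3-way family follows the asymmetry
of the two loops flanking the unstacked helix with a ≥4 nt margin between
A and C; 4-way families sharing a stack set are distinguished by loop
composition (purine-rich vs pyrimidine-rich vs balanced). Labels are
deterministic functions of the generated features, so a faithful learner
can reach 100% leave-one-out accuracy on the stack class at zero noise,
and `label_noise = 0.1` bounds attainable accuracy near 90%.

A green classifier test therefore establishes that the pipeline *recovers
a recoverable signal* — determinism, feature plumbing, fold hygiene — not
that the real biological signal has the committed functional form. The
real-corpus accuracies reported in the literature (95/100 stacks, 94/100
families for 3-way; 92/100 and 87/100 for 4-way) require the curated PDB
junction dataset and are intentionally outside the offline test surface.
Similarly, `synthesize_junction()` produces idealized fixtures: every
base-pair vertex lies exactly on the helix axis, loop residues are bare
C1′ spacers, and no backbone continuity or sterics are modelled. Round
trips through these fixtures validate the geometry code to ~machine
precision but say nothing about conformational variability of real
junctions, where native RMSDs of 2–11 Å (3-way) are typical.

## Numerical choices and degenerate inputs

- Pseudoknot removal is exact (DP), with a deterministic 5'-most
  tie-break; its output cardinality is property-tested against exhaustive
  enumeration on small structures.
- Kabsch superposition flips the smallest singular direction when the raw
  optimum is a reflection; the result always has determinant +1 and is
  validated against a rotation-grid + Nelder-Mead oracle to 10⁻³ Å.
- `basepair_vertex` errors when C8/C6 coincide or M lies on the C8–C6
  line (undefined projection direction); translation skips such pairs
  inward along the helix.
- MaxAngle errors on zero-length edges rather than returning an arbitrary
  angle. Vote ties in the forest resolve to the earliest factor level;
  split ties to the first feature/threshold encountered — both
  deterministic under a fixed seed, which is threaded through R's RNG
  (`set.seed`) including inside the compiled tree builder.
- Geometric Watson-Crick detection (C1′–C1′ 10.4 ± 1.5 Å, purine-N1 to
  pyrimidine-N3 < 3.5 Å, canonical letters, ≥3 nt same-chain separation,
  best-scoring partner kept) is a fallback tuned to be exact on the
  generator's fixtures and reasonable on real A-form geometry; an external
  annotation table always overrides it, which is the recommended path for
  real structures.

## Known limitations

- Junctions of degree ≥5 are parsed but not classified or built; the
  published partitioning of higher-order junctions into 3/4-way
  sub-junctions is not implemented.
- Model graphs are strictly planar and use fixed arrangement angles; no
  refinement toward non-planar native geometry is attempted.
- The 4-way family geometry table is a convention (see above); cross-family
  comparisons of built 4-way graphs inherit it.
- GU wobble pairs are detected through the same N1–N3 window as WC pairs,
  which is approximate for real wobble geometry; supply an annotation
  table when exact pair classes matter.
- LOOCV retrains one forest pair per held-out record; with the 500-tree
  default and corpora of hundreds of junctions this is minutes of CPU (the
  test suite uses 150 trees for time-budget reasons, which is ample for
  the synthetic worlds).
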