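---
title: "Methods: conservation, crosslink networks and stoichiometry of the plastid-encoded RNA polymerase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PEP architecture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmap)
```

## The biological question

The chloroplast plastid-encoded RNA polymerase (PEP) is a prokaryotic-type
multi-subunit enzyme whose catalytic core (α, β, β′, β″, from rpoA/rpoB/
rpoC1/rpoC2) becomes, upon illumination of angiosperm seedlings, the hub of
a much larger ~900 kDa complex decorated with twelve nuclear-encoded
PEP-associated proteins (PAP1–PAP12) plus recurrent candidates (FLN2,
pTAC18). `pepmap` implements the desk-scale analyses by which such a complex
is characterized from sequence, structure and mass-spectrometry data:

1. **Conservation profiling** of core-subunit alignments, including clade
   subsets (e.g. plants with detected PAPs vs all taxa).
2. **Divergence mapping**: classifying alignment columns as homologous /
   nonhomologous / gap between a plant clade and bacterial references,
   flagging runs of strong functional-group change, and asking whether
   variable sites concentrate at the solvent-exposed surface.
3. **Crosslinking-MS (XL-MS) processing**: dipeptide tables into
   residue-level interaction graphs, cluster detection, and Cα–Cα distance
   restraints.
4. **iBAQ quantification**: label-free relative abundances and subunit
   stoichiometry with replicate normalization.

Every stage can be exercised on seeded synthetic data with known ground
truth, so the package is fully testable without external downloads.

## Conservation statistics

**Per-column identity** for a taxa subset is the frequency of the modal
non-gap residue, as a percentage of the subset size. Gaps stay in the
denominator (an 80%-gapped column is not "conserved" merely because the two
remaining residues agree) but can never be the mode; an all-gap column
scores 0. This is the statistic behind BOXSHADE-style shading, chosen over
mean pairwise identity because it is what a per-column identity track needs;
the two coincide for fully conserved columns and diverge gracefully
otherwise. **Homology** replaces the residue by its physicochemical
functional group before taking the mode, so homology ≥ identity at every
column by construction.

The **functional-group table** is the fixed six-class partition positive
{K,R,H}, negative {D,E}, polar {S,T,N,Q}, aromatic {F,W,Y}, aliphatic
{A,V,L,I,M,C}, special {G,P}. Published alignment figures of this kind
rarely print their grouping; fixing a standard partition makes "strong
modification of functional groups" operational and testable.

**Rolling profiles** use a centered moving mean of width 11 residues (odd,
enforced). At the ends the window shrinks instead of dropping columns, so
the profile has exactly one value per alignment column — a deliberate choice
that keeps profiles alignable to reference residue numbering and hence to
structures. The cost is mild end-of-sequence smoothing bias; the mean of a
constant profile is preserved exactly.

**Reference mapping**: the k-th non-gap column of a chosen reference taxon
maps to reference residue k; reference-gap columns are unmapped. All
structure-facing outputs (run tables, B-factor annotations) are in reference
coordinates.

```{r conservation-example}
msa <- new_msa(c(p1 = "KKKDAE", p2 = "KKKDAE", b1 = "KKKRGE", b2 = "KKKRGE"),
               c(p1 = "plant", p2 = "plant", b1 = "bact", b2 = "bact"))
round(sapply(1:6, function(j)
  c(identity = column_identity(msa, j), homology = column_homology(msa, j))), 1)
```

## Divergence classification and strong-change runs

Between two disjoint clades, a column is **gap** when either clade is more
than 50% gapped, **homologous** when the clades' modal residues share a
functional group, **nonhomologous** otherwise. Modal ties break
alphabetically for determinism (ties are rare in real alignments and any
fixed rule serves). A column shows **strong functional-group change** when
it is nonhomologous with differing modal groups; maximal runs of such
columns that are consecutive *in reference residue numbering* are reported
when at least 3 residues long. We follow reference numbering (rather than
alignment-column adjacency) because the flags ultimately color residues of
a structure, which exists only in reference coordinates.

Whether "variable" should include gap columns is genuinely open; the
surface-enrichment function therefore takes `variable_classes` and both
readings can be reported.

## Solvent accessibility and the surface claim

SASA is computed by the Shrake–Rupley construction with a deterministic
golden-spiral point sphere (default 960 points per atom, probe 1.4 Å,
Bondi-style van der Waals radii). Relative exposure divides per-residue SASA
by a tabulated per-residue-type maximum (Tien-style theoretical values);
residues at or above 0.25 relative SASA are called exposed — the
field-standard convention, stated explicitly because qualitative "surface"
claims need an operational cutoff. For non-standard residue types (toy
models), the residue's own isolated-sphere area is the fallback normalizer.

The claim "variable sites lie at the surface" becomes a 2×2 contingency
table (variable/conserved × exposed/buried) with the sample odds ratio and a
two-sided exact test. The exact test is an addition over a purely
qualitative statement: it makes the claim assertable and its strength
quantifiable. A zero margin flags the odds ratio as undefined rather than
inventing a continuity correction.

Numerical notes: the point construction is exact for an isolated sphere
(every test point accessible), agrees with a 4000-point reference within 3%
per residue on a 27-atom lattice except for near-buried residues with ~10 Å²
areas where relative error is ill-conditioned, and is monotone: adding an
atom never increases another atom's exposed area.

## XL-MS dipeptide processing

A dipeptide record carries the two partner proteins, the identification
score, both peptides with 1-based inclusive From/To spans, and each
crosslinked residue with its position relative to its peptide. The absolute
position is `from + relative − 1`; e.g. a peptide starting at 156 with Y at
relative position 2 crosslinks through Y157. Rows whose printed span length
disagrees with the peptide length (a typographic artifact the printed table
actually contains) are **kept and flagged**, never silently fixed — the From
coordinate and relative site suffice for the position arithmetic.

Filtering retains records with score ≥ 30 (the identification cutoff used
with MS-cleavable DSBU searches) whose link residues match DSBU chemistry
(Lys, Ser, Thr, Tyr or the protein N-terminus). Replicate sets merge by
union over the unordered (protein, absolute position) pair key, keeping the
maximum score and accumulating replicate ids; the operation is idempotent
and commutative.

**Graph construction** resolves protein labels against the bundled subunit
registry. Shared-peptide ambiguity groups ("PAP6/FLN1; FLN2"; "RPS2A;
RPS2B") become *single* nodes carrying the ambiguity, because a shared
peptide cannot distinguish near-identical paralogs — duplicating nodes would
invent interactions. Clusters are connected components, optionally after
restricting to registry members, ordered by size then name. Self links are
retained in records but excluded from cluster statistics by default.

**Distance assessment** measures Cα–Cα distances through a chain map and
calls a link compatible at ≤ 30 Å — the common modelling convention for a
~12.5 Å-spacer amine-reactive crosslinker once side chains and backbone
flexibility are allowed for (configurable; no cutoff is canonical). Links
whose residues cannot be located are "unmapped" and excluded from both
compatible and incompatible counts.

## iBAQ and stoichiometry

Raw iBAQ is summed MS1 intensity divided by the number of theoretically
observable tryptic peptides — fully cleaved Trypsin/P peptides (cleave after
K/R, including before P) of length 6–30. Missed cleavages matter for
identification, not for the iBAQ denominator, which follows the original
iBAQ convention. Within each replicate, iBAQ values are normalized by the
replicate total (summing to 1), then combined across replicates by summation
(a mean-based combiner is available); iBAQr divides by the α subunit's final
iBAQ, so iBAQr(α) = 1. Proteins absent from a replicate contribute 0 (no
imputation); proteins with no observable peptide are excluded with a
warning. Shared/razor peptide apportionment is assumed done upstream by the
quantification software.

Stoichiometry ratios are ratios of final iBAQ values with a bootstrap
percentile interval over replicates. With two α copies per β, the expected
α:β ratio is 2.

## The synthetic-data module

The generators are pure functions of (spec, seed) and emit ground truth
sufficient to score every downstream stage:

* **Alignments**: conserved blocks identical across taxa; variable patches
  where each clade draws its own consensus and taxa mutate from it at a
  stated rate (default 0.5); a clade-specific insertion gapped outside its
  clade. This emulates conserved catalytic blocks, variable surface patches
  and the long plant-specific β″ insertion — not a realistic evolutionary
  process (no substitution matrix, no phylogeny), which is out of scope.
* **Structures**: an ideal α-helix Cα trace (rise 1.5 Å, 100°/residue,
  radius 2.3 Å → 3.83 Å consecutive spacing) and a two-shell model whose
  inner cluster (1.2 Å radius) is verifiably buried under a dense 8 Å shell.
* **Intensities**: sequences built from 9-residue tryptic blocks so peptide
  counts are analytically known; intensity = copy number × count ×
  lognormal multiplicative noise (σ = 0.3 by default, the scale typical of
  MS1 label-free variation) × a per-replicate scale factor that
  normalization must cancel.
* **Crosslink tables**: planted intra-cluster links scored on [40, 130],
  decoys to non-member partners scored uniformly on [0, 60] so the score-30
  filter is exercised on both sides.

Passing tests on these data demonstrate the *computations* are right; they
do not demonstrate robustness to real-data pathologies (chimeric spectra,
shared peptides, alignment errors), which the generators deliberately do not
model.

## Problem sizes and determinism

The bundled analyses use a 14-taxon × 400-column synthetic alignment, 50–120
residue toy structures, 960-point SASA spheres, and 100-seed stoichiometry
recovery — sizes chosen so the whole suite re-runs in seconds while leaving
every statistic well away from small-sample artifacts. All randomness flows
through explicit seeds; two runs with the same configuration are
byte-identical (the pipeline report excludes timestamps for this reason).

## Known limitations

* The registry is a curated snapshot; subunit candidacy (FLN2, pTAC18) is an
  open biological question and the `candidate` role records that.
* Identity/homology statistics are modal, not pairwise; profiles from tools
  using mean pairwise identity will differ in variable regions.
* SASA on Cα-only models is a geometric proxy; absolute values are not
  comparable to all-atom calculations (relative comparisons within a model
  are).
* The exact test on the exposure table treats residues as independent,
  which spatially clustered variable patches violate; p-values are
  anti-conservative in that regime and should be read as effect summaries.
* Distance assessment assumes the chain map and numbering agree with the
  crosslink coordinates; no sequence-to-structure alignment is attempted.
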