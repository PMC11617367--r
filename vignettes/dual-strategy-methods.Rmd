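---
title: "Methods: dual-strategy plasma proteome comparison"
author: "dualprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-strategy plasma proteome comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualprot)
```

## Overview

`dualprot` compares two identification strategies over the same DDA plasma
cohort: a library search (peptides matched against a reference proteome)
and *de novo* sequencing (peptides read directly from spectra, assembled
into contigs). Neither the spectral search nor the neural *de novo*
sequencer is part of this package — their outputs are the inputs here, and
the synthetic-cohort generator emulates those outputs with ground truth.
The package's job is everything downstream: assembly, mapping, clustering,
evidence merging, group comparison, peptide physicochemistry and
phosphosite structural characterization.

## Contig assembly

Reads from one sample form a de Bruijn graph with **k = 8**: nodes are
7-mers, edges are 8-mers. Each read window contributes its *mean
per-residue confidence* to the edge weight and 1 to the edge count, so an
8-mer seen often and confidently dominates. Contigs are extracted greedily:
seed at the unused edge of highest weight (ties broken lexicographically by
k-mer), extend both ways along the heaviest unused edge, retire used edges,
and keep walks of ≥ 10 aa. Design notes:

* **Greedy heaviest-path with lexicographic ties** makes assembly a pure
  function of the read multiset — any read order yields the same contigs.
  The tests exercise this directly by permuting reads.
* **Edge reuse is forbidden**, so a repeated k-mer (a cycle) terminates the
  walk rather than looping. On low-complexity regions this truncates
  contigs; that is the accepted cost of determinism and termination.
* **Assembly is per sample**, because the downstream group comparison
  counts contig occurrences per sample; pooling reads across samples would
  destroy that resolution.
* A contig's `support_reads` is the number of distinct reads sharing at
  least one k-mer with it; `mean_confidence` is the mean over its edges of
  weight/count. These are reporting conventions, not tuning knobs.

## Mapping and identity gates

Contigs are aligned to every reference protein by exact Smith–Waterman
dynamic programming with affine gaps (match +2, mismatch −1, gap open −3,
gap extend −1, where a gap of length L costs open + (L−1)·extend). The
databases involved are small enough that heuristic seeding buys nothing,
and exactness makes the identity gates sharp. Two conventions matter:

* **Ile/Leu are treated as equivalent by default** in mapping, clustering
  and proteotypic counting: the isobaric pair is indistinguishable to
  *de novo* sequencing. The flag `il_equivalent` turns this off.
* Among co-optimal alignments, the one with the smallest target start and
  then the fewest gaps is returned, so mapping is deterministic.

A contig's best hit classifies it: identity = 100% → **canonical**;
75% ≤ identity < 100% → **noncanonical variant** (a putative sequence
variant or error); otherwise **unmatched**. An alignment must also cover
at least half the contig to count at all — a short perfect core inside an
otherwise alien sequence is not a protein identification.

Percent identity uses *alignment columns* as denominator for mapping, but
*the shorter sequence's length* for clustering. The clustering step must
unite sequences of different lengths — a tryptic peptide with the contig
that contains it, a peptide with its missed-cleavage extension — and an
alignment-column denominator would penalize exactly those nestings.

Clustering itself is single-pass greedy centroid assignment (sequences
sorted by length, longest first; each sequence joins the first centroid at
≥ 95% identity or founds a new cluster). On inputs whose similarity
structure is unambiguous this equals exhaustive single-linkage, which the
acceptance suite verifies against a brute-force all-pairs oracle on small
sets.

## Evidence merging and group comparison

Per protein, the package unions: exact library-peptide footprints
(`covered_library`), canonical contig alignment footprints
(`covered_denovo`), and the *matched columns only* of noncanonical
alignments (`covered_noncanonical`) — a mismatched column is evidence of a
variant, not of the reference residue. Reported coverage percentages are
rounded half-up (this reproduces every checked published coverage cell);
unrounded values stay available internally.

Sample counts (Sz = cases, Cnt = controls) count distinct samples with at
least one supporting identification of either strategy; the published
tables do not state whether strategy-concordance was required, and we
deliberately count any support. The cohort detection filter ("detected in
at least ten plasma samples") is read as **ten samples pooled across
groups** — the stricter per-group reading would exclude exactly the
case-specific rows the comparison is after (rows with Cnt as low as 0);
`per_group_filter = TRUE` restores it.

Abundance tiers follow the conventional plasma brackets: high > 1 μg/mL,
mid 10 ng/mL – 1 μg/mL (closed at both ends, so a protein at exactly
1 μg/mL is mid), low < 10 ng/mL; proteins without an annotated
concentration are `unknown`. Group-specific selection is
Sz ≥ 9 ∧ Cnt ≤ 5 ∧ PTPs ≥ 1; the thresholds were chosen to bracket the
extreme rows of the published group-specific table and are configuration,
not constants.

## Peptide physicochemistry

* **Tryptic flag**: C-terminal residue ∈ {K, R}.
* **Average mass**: standard average residue masses + one water (18.0153
  Da); average rather than monoisotopic masses because the published contig
  masses follow the average convention. Below 10 kDa the reported value is
  rounded to one decimal.
* **Aliphatic index** (Ikai): AI = X~Ala~ + 2.9·X~Val~ + 3.9·(X~Ile~ +
  X~Leu~), X in mole percent, reported half-up-rounded. Eight of the ten
  published contig rows reproduce exactly under this formula; two
  (`SLMVNLENVMVNLENPEGLPVK` printed as 123 where the formula gives 123.6
  → 124, and `RPHSMSALEVDEGSMDPK` printed as 43 where the formula gives
  37.8) do not reproduce under any standard parameterization we tried and
  are treated as discordant source values, excluded from exact checks.

## Phosphosite structural characterization

The source study reports, for each phosphosite, the ratio of the
identified peptide's solvent-accessible surface area in the intact versus
the phosphorylated protein (K_SASA), without stating how the
phosphorylated structures were built or SASA computed. The package
therefore fixes an explicit, reproducible protocol and documents it as a
methodological stand-in, not a claim of equivalence:

* **SASA** by Shrake–Rupley with a deterministic Fibonacci-spiral sampling
  of 960 points per atom, probe 1.4 Å, van der Waals radii C 1.70 / N 1.55
  / O 1.52 / S 1.80 / P 1.80 Å, hydrogens ignored (X-ray and predicted
  models generally lack them). Single isolated atoms reproduce the
  closed-form sphere area to < 0.1%; whole models agree with an
  independent latitude–longitude quadrature oracle to < 2%.
* **Phosphate placement**: P at 1.6 Å from the side-chain hydroxyl oxygen
  (OG/OG1/OH), extended along the bond from its parent carbon, plus three
  terminal oxygens at ideal tetrahedral geometry (P–O 1.5 Å, terminal O–O
  2.449 Å). No other atom moves and no minimization is performed; whether
  the original analysis relaxed structures is unknown.
* **K_SASA = intact / phospho**, phosphate atoms included in the phospho
  state. On every generated fixture with a solvent-exposed site the ratio
  is ≤ 1 — the published qualitative hallmark. The published *numeric*
  ratios are not reproduction targets: they depend on specific database
  structures and the unstated modeling protocol.
* **Secondary structure** at the site is a three-way φ/ψ-window label
  (helix: φ ∈ (−100°, −30°), ψ ∈ (−80°, −5°); strand: φ ∈ (−180°, −90°),
  ψ ∈ (90°, 180°); required for the site and both neighbors; `n/d` when
  backbone atoms for site ± 2 are missing). Full DSSP equivalence is a
  non-goal — the published table needs only this label.
* `build_peptide_structure()` constructs idealized fixtures (standard bond
  geometry, chosen φ/ψ, minimal side chains with the hydroxyl atoms needed
  for phospho-modeling); it exists so the structural code is tested on
  fully known geometry rather than downloaded models.

## The synthetic cohort generator

`sim_config()` encodes the study conditions: 48 case and 50 control
samples; protein lengths log-uniform over 50–3,000 aa; tier fractions
(high 0.23, mid 0.20, low 0.57) matching the observed proportions of the
annotated plasma proteome; per-tier detection probabilities 0.9 / 0.5 /
0.15 in the stochastic mode; sequences i.i.d. at Swiss-Prot background
frequencies. Planted structure with recorded truth:

* **Group-specific proteins** present in case samples and absent from
  controls;
* **Noncanonical-variant proteins**: their *de novo* evidence is a window
  carrying two interior single-residue substitutions (non-I/L, placed away
  from the window margins so local alignment cannot trim them off), and
  they emit no library peptides — they model sequences outside the
  library search's reach;
* tryptic library peptides (cleavage after K/R except before P, ≤ 2 missed
  cleavages, ≥ 6 aa) and *de novo* reads tiling a per-protein window
  (length 24, reads of 14, stride 2 — overlaps well above k−1) with
  Beta(8, 2) per-residue confidences, optional I/L-biased substitutions
  and adjacent transpositions — the canonical de novo failure modes.

**Noise-free mode** (the default) makes detection deterministic:
background proteins appear in every sample, planted group-specific
proteins in every case sample and no control, and error rates are zero.
This is the mode under which recovery must be *exact* — sensitivity and
specificity of group-specific selection are 1 by construction of the
conditions, not by a lucky draw, and that exactness is what the acceptance
suite asserts. The stochastic mode (per-tier detection or a uniform
`dropout`) is used for the robustness property (sensitivity ≥ 0.8 at 20%
dropout) and for the binomial sanity checks on detection counts.

What the generator does *not* emulate: spectra and their noise structure,
retention time, charge states, intensity-dependent detection, shared
peptides between homologous proteins, and real plasma's correlation
between abundance and protein family. Passing tests therefore demonstrate
the correctness of the downstream computations under the stated model, not
end-to-end performance on real mass-spectrometry data.

## Numerical conventions

* All internal coordinates are 0-based half-open; 1-based inclusive only
  at I/O boundaries (PTM positions, residue numbers).
* Reported percentages and indices round half away from zero
  (`round_half_up()`); base R's banker's rounding would change published
  cells.
* In the bracket PTM notation the three-letter code **replaces** the
  modified residue's letter (`A[SEP]QPQ…` = `ASQPQ…` with phospho-S2);
  this is the only reading consistent with phospho-codes sitting on their
  cognate residues, verified against the source protein sequences.
* Concentrations are stored in g/L and converted to μg/mL / ng/mL only for
  display.
* Problem sizes in the test suite (proteomes of 12–20 proteins of 60–600
  aa, full 48+50 cohorts for the recovery properties, 6+6 cohorts for
  pipeline mechanics) were chosen so the full suite completes in well
  under a minute while still populating all tiers and both planted
  structures.

## Known limitations

* The greedy assembler is a stand-in for the original ALPS assembler,
  whose internals are unpublished; behavior on repeats differs in an
  unknown direction.
* Greedy clustering can differ from single-linkage when similarity is
  intransitive near the threshold; the equivalence holds (and is only
  asserted) on unambiguous inputs.
* Phosphate geometry is idealized and unminimized; K_SASA values are
  reproducible within this protocol but not comparable in absolute terms
  to other protocols.
* The aliphatic-index and mass formulas are defined only for the 20
  canonical residues; inputs containing B/Z/X/U/O are rejected rather than
  approximated.
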