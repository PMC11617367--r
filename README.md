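# dualprot

Dual-strategy plasma proteome analysis: merging library-search peptide
identifications with *de novo* peptide contigs.

## The problem

Shotgun (DDA) plasma proteomics identifies peptides by matching tandem
spectra against a reference sequence database. That strategy is blind to
whatever the database does not contain: unannotated proteins, single
amino-acid variants, splice forms, and modified proteoforms. *De novo*
sequencing reads the peptide sequence directly from the spectrum, and its
short reads can be assembled into longer **contigs** and mapped back onto
the reference — recovering both canonical proteins the library search
missed and putative **noncanonical** sequences that match a protein only
partially. `dualprot` implements the comparison pipeline for a case/control
plasma cohort (48 schizophrenia-spectrum cases, 50 controls in the study
design it targets), from raw identification tables to per-protein evidence:

1. **Assembly** — *de novo* reads are assembled per sample with a
   confidence-weighted de Bruijn graph (*k* = 8): edges are k-mers weighted
   by the summed mean per-residue confidence of their supporting read
   windows; contigs are greedy heaviest paths, at least 10 aa long.
2. **Mapping** — each contig is aligned to the reference proteome by
   Smith–Waterman local alignment (match +2, mismatch −1, gap open −3,
   gap extend −1; Ile/Leu equivalent). Contigs with best identity ≥ 75%
   are kept; 100% identity is *canonical*, 75–100% is a
   *noncanonical variant*.
3. **Clustering** — peptides and contigs are clustered greedily at ≥ 95%
   identity, with identity defined over the shorter sequence
   (`100 · matches / min(len)`), so missed-cleavage extensions and nested
   contigs cluster together.
4. **Evidence merging** — per protein: residue coverage by each strategy,
   case/control detection counts (Sz / Cnt), plasma abundance tier
   (high > 1 μg/mL; mid 10 ng/mL – 1 μg/mL; low < 10 ng/mL), proteotypic
   peptide (PTP) count, and group-specific selection
   (Sz ≥ 9, Cnt ≤ 5, PTPs ≥ 1).
5. **Peptide physicochemistry** — tryptic status (C-terminal K/R), average
   molecular mass, and the aliphatic index
   `AI = X_Ala + 2.9·X_Val + 3.9·(X_Ile + X_Leu)` (mole percent; AI ≥ 70
   flags thermostability).
6. **Phosphosite structure** — Shrake–Rupley solvent-accessible surface
   area of the identified peptide in the intact protein versus a model with
   an explicit phosphate placed at the Ser/Thr/Tyr hydroxyl:
   `K_SASA = SASA_intact / SASA_phospho` (< 1 means phosphorylation
   increased exposure), plus a torsion-window secondary-structure label and
   the mean per-residue model confidence.

A synthetic-cohort generator (`simulate_cohort()`) emits reference
proteomes, library tables, *de novo* reads and ground truth in the same
file formats, so the whole pipeline is testable without any download.

## Worked example

```r
library(dualprot)

## peptide physicochemistry of a frequently detected contig
peptide_properties("GLYGGPSYGYGAPTSQR")
#>            sequence length_aa mw_kda aliphatic_index tryptic thermostable
#> 1 GLYGGPSYGYGAPTSQR        17    1.7              29    TRUE        FALSE

## a full synthetic cohort, end to end
sim <- simulate_cohort(sim_config(n_proteins = 20, len_range = c(60, 600),
                                  seed = 303))
dir <- tempfile(); write_simulation(sim, dir)
res <- run_pipeline(file.path(dir, "ref.fasta"), file.path(dir, "library.tsv"),
                    file.path(dir, "denovo_reads.tsv"), tempfile(),
                    abundance_tsv = file.path(dir, "abundance.tsv"),
                    samples_tsv = file.path(dir, "samples.tsv"))
res$overlap$proteins
#> library_only  denovo_only         both
#>            0            3           17
sort(res$group_specific)
#> [1] "SIM0001" "SIM0002" "SIM0003" "SIM0004" "SIM0005"
```

The overlap line reads: every protein was seen by *de novo* sequencing,
the 3 planted noncanonical-variant proteins were seen *only* by it, and the
5 planted case-specific proteins are recovered exactly by the
Sz ≥ 9 / Cnt ≤ 5 / PTPs ≥ 1 rule.

```r
## structural effect of phosphorylation at an exposed serine
model <- build_peptide_structure("AASAA", phi = -120, psi = 120)
k_sasa(model, 3, c(1, 5))
#> K_SASA at residue 3 (peptide 1-5): intact 589.8 A^2, phospho 641.2 A^2, ratio 0.92
```

A ratio below 1 reproduces the hallmark reported for circulating
phosphoproteoforms: the modeled phosphate adds exposed surface.

## Command line

A thin wrapper over the same functions ships in `inst/exec/dualprot`:

```sh
dualprot simulate seed=1 out=simdir
dualprot run db=simdir/ref.fasta library=simdir/library.tsv \
             reads=simdir/denovo_reads.tsv abundance=simdir/abundance.tsv \
             samples=simdir/samples.tsv out=report
```

Exit codes: 0 success, 2 input/format error, 3 configuration error,
4 internal invariant violation.
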