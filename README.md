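# orthostruct

Comparative analysis of orthologous proteins in **sequence** and in
**predicted structure**. Reproductive and germline proteins often diverge at
a startling pace — 10–30% of residues between species separated by a few
million years — yet their predicted structures can remain essentially
unchanged. orthostruct is for evolutionary and structural biologists who
have, for an ortholog family: a protein multiple sequence alignment
(optionally with reconstructed ancestral-node sequences), per-species
predicted models (PDB/mmCIF with plDDT in the B-factor column), PAE matrices
(JSON), and per-residue disorder Z-score tracks — and who want to know which
of the many sequence changes, if any, moved the structure.

## What it computes

* **Pairwise divergence** over alignment columns with an explicit,
  configurable gap rule (indel columns count as differences by default) and
  denominator (union length by default), reported raw and as rounded
  percentages.
* **Lineage-specific substitutions** against an ancestral row, scored with
  the **Miyata biochemical distance**
  `d(a,b) = sqrt((Δp/σp)² + (Δv/σv)²)` built from Grantham's polarity and
  volume columns, binned into the familiar integer classes 0–4 by
  `min(4, round(d))`.
* **Order/disorder masks** from plDDT (confident at ≥ 70) and disorder
  Z-scores (ordered at Z ≥ 3), combined per an explicit policy.
* **Alignment-guided rigid superposition** (Kabsch SVD fit with
  Matchmaker-style iterative pruning at 2 Å) and per-residue classification:
  deviation < 2 Å ⇒ *matched*, ≥ 2 Å ⇒ *different*, low confidence on either
  side ⇒ *unscored*; plus calling of columns *different in exactly one
  species*.
* **Hydrogen bonds** by a monotone geometric rule (donor–acceptor ≤ 3.3 + 0.4 Å,
  angle at donor ≥ 90° − 20°, intra-chain partners > 5 residues apart) and
  **interface contacts** (min heavy-atom distance ≤ 4 Å, PAE < 5 Å).
* **Category-stratified Fisher exact tests** (total / region / ordered /
  disordered) with explicit-family-size Bonferroni correction.
* A fully seeded **synthetic-data generator** that plants substitutions,
  displacements, disorder spans and interface contacts with a truth ledger,
  so the whole pipeline is testable offline.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on result types.

## Worked example

Generate a synthetic four-species family under the package's reference
conditions (400 residues, disordered spans diverging at 0.25/site vs 0.08 in
ordered spans, one planted 5-residue / 4 Å displacement in species `sp3`,
a planted interface with a 60-residue partner chain), then run the full
comparison:

```r
library(orthostruct)
library(dplyr)

bundle <- make_comparison_bundle(sim_config(seed = 101))
cmp <- run_comparison(bundle)
cmp
#> <ortho_comparison>
#>   species: sp1, sp2, sp3, sp4 (ancestor: root)
#>   substitutions: 246; indel columns: 6
#>   superposed pairs: 6; species-specific different columns: 5
#>   significant interaction category differences: 0

divergence_table(bundle$frame) |>
  filter(id_a == "root", id_b != "root") |>
  select(id_b, n_substitutions, n_indel_columns, percent)
#>   id_b  n_substitutions n_indel_columns percent
#> 1 sp1                61               4    16.2
#> 2 sp2                62               0    15.5
#> 3 sp3                54               0    13.5
#> 4 sp4                69               2    17.8

cmp$species_specific
#>   column n_focal_pairings n_other_pairings focal
#> 1    320                3                3 sp3
#> 2    321                3                3 sp3
#> ...
#> 5    324                3                3 sp3
```

Reading the output: each descendant differs from the ancestral root at
13–18% of compared columns (substitutions plus indel columns over the union
length) — the divergence regime of closely related orthologs. The
superposition stage classifies every confidently placed residue pair by the
2 Å rule and finds exactly columns 320–324 *different* in every pairing
involving `sp3` and *matched* among the others: the planted species-specific
displacement, recovered with no false columns. With nothing else planted,
all category-stratified exact tests (substitution counts, hydrogen bonds,
contacts; Bonferroni-corrected) are null — as they should be.

Real inputs follow the same shapes: `read_alignment()`, `read_structure()`,
`read_pae()`, `read_score_track()`, `read_regions()`, then the same
`run_comparison()`. A thin command-line front end is included at
`inst/cli/orthostruct.R` (subcommands `simulate`, `divergence`, `compare`).

## Documentation

The methods vignette (`vignettes/comparative-structure-evolution.Rmd`)
documents the model and every threshold: the gap/denominator rules, the
Miyata construction, the confidence gating, the superposition and pruning
algorithm, the interaction geometry, the exact-test constructions, and what
the synthetic generator does and does not emulate.
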