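---
title: "Methods: paired TCR repertoire statistics in pairrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired TCR repertoire statistics in pairrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairrep)
```

# Scope and data model

`pairrep` analyses paired single-cell TCR capture experiments. Its
inputs are (i) an AIRR Rearrangement table, one row per recovered chain
per cell (`cell_id`, `locus`, `v_call`, `j_call`, `junction_aa`, and
optionally `duplicate_count`, read as the UMI-collapsed molecule
count), and (ii) a cell-by-gene UMI count matrix from a targeted
expression panel. Upstream of these the package offers only a
simplified molecule-folding step; alignment, CDR3 calling from
nucleotide sequence, and platform-proprietary error correction are out
of scope, and molecule counts in the inputs are taken at face value.

CDR3 amino-acid strings are compared by exact string equality, stored
exactly as given. Printed repertoire tables conventionally omit the
invariant flanking residues of the IMGT junction, so the package never
adds or strips flanks; mixing conventions within one dataset will split
clonotypes, which is the caller's responsibility to avoid. The
amino-acid alphabet includes `*`, since stop-codon-containing junctions
do occur in real tables.

# Molecule folding and UMI error correction

Reads sharing cell label, UMI and gene are PCR copies of one molecule;
`fold_molecules()` counts distinct UMIs per (cell, gene).
`collapse_umis_hamming1()` corrects substitution errors beforehand with
a directional single-pass rule applied to a fixpoint: within a (cell,
gene) group, a UMI lying at Hamming distance 1 of a strictly more
abundant UMI is relabelled to it, candidates scanned most-abundant
first with lexicographic tie order. Two conventions matter:

* **Ties never merge.** Equal-abundance neighbours carry no evidence of
  direction, and merging them would make the result depend on scan
  order.
* **Iteration to a fixpoint.** A single pass can leave newly unequal
  neighbours (a survivor that absorbed reads may now strictly dominate
  a former tie); repeating the pass until nothing changes makes the
  operation idempotent, so applying the corrector to already-corrected
  data is a no-op.

Groups must carry equal-length UMIs (unequal lengths are an error, not
a silent skip). The corrector can only reduce molecule counts — this is
asserted property-style in the test suite.

# Segment catalog and functionality filtering

Germline V/J segments carry IMGT functionality classes (`functional`,
`pseudogene`, `ORF`). The catalog is a plain two-column file rather
than hard-coded data because functionality assignments are
release-dependent; the bundled `imgt_fixture.tsv` covers the full
TRAV/TRAJ/TRBV/TRBJ universe with 45/50/50/13 functional segments per
locus/type. Usage and pairing statistics exclude filtered classes from
both numerator and denominator.

Segment names are canonicalized to IMGT long form (`AV12-1` →
`TRAV12-1`; bare `V27` needs a locus argument; allele suffixes `*01`
are stripped — the package works at gene resolution). Normalization is
idempotent. Segments observed in data but missing from the catalog are
retained as functional with a warning: a panel drifting ahead of the
catalog should surface, not crash or silently drop molecules.

A separate, data-dependent *low-expression* filter (`min_count`)
controls the label set: the default (1) drops never-observed segments
from usage tables, while `min_count = 0` keeps the full filtered
catalog with explicit zeros — the shape under which the V–J pairing
matrix has exactly `possible_recombinants(n_V, n_J)` cells. This
filter is deliberately not a catalog property, because which segments
count as "low-expressed" depends on the sample.

# Usage, pairing and their weighting

The weight basis is a parameter (`molecules`, `reads`, `cells`) rather
than a fixed choice, because published repertoire figures are
variously read-weighted or molecule-weighted and the two differ under
amplification bias; the default is `molecules`, the quantity UMI
collapsing is designed to estimate. `cells` counts each distinct
(cell, segment) — or (cell, V, J) — pair once.

Usage filters on its own axis only; the pairing matrix requires both V
and J to be kept. Under functional-only data (the simulator's regime,
and any catalog-clean dataset) row and column sums of the pairing
matrix equal the V and J usage vectors; the suite asserts this to
1e−9 relative. When one axis of a record is filtered and the other is
not, the two denominators legitimately diverge.

# Shannon diversity and the choice of entity

H′ = −Σ pᵢ ln pᵢ, natural log, zero entries skipped, input normalized
to sum 1 — hence scale invariance (counts and proportions agree) and
the bound H′ ≤ ln S. Degenerate inputs (all-zero, negative, empty) are
errors rather than NA, because a silent 0 would be indistinguishable
from a genuinely monoclonal sample.

The *entity* whose frequencies enter H′ is configurable: per-locus
CDR3 amino-acid sequence (default), V–J pair, per-chain V/CDR3/J
triple, or the paired clonotype (cell-weighted). Published
whole-repertoire H′ values of ~10–11 from ~10⁴-cell captures exceed
ln(10⁴) ≈ 9.2, so they cannot be cell-level clonotype entropies and
must rest on a finer or larger observation set than cells; since the
entity behind such numbers is generally unstated, the package reports
H′ per entity and makes no claim to reproduce any particular published
absolute value. Subset comparisons (CD8⁺ vs FOXP3⁺ vs bulk) are
meaningful within a fixed entity, and that qualitative ordering is
what the tests pin down.

# Paired clonotype assembly

Per cell, the TRA and TRB chains with the largest molecule count are
selected; ties break on lexicographically smallest `junction_aa`, then
`v_call` — an arbitrary but deterministic rule, preferable to
order-of-file dependence. Cells lacking either locus are reported as
unpaired and excluded from frequency denominators (the alternative —
frequencies over all cells — can be recovered from `n_cells` and the
unpaired list). Ranked tables print frequencies to one decimal place;
internal values stay full precision.

# Subset gating

CD8⁺ and FOXP3⁺ subsets are cells with ≥ 1 raw UMI of the marker
(threshold configurable, monotone by construction). Raw counts are
used because the rule is a copy-number rule; normalization would move
cells across the threshold as library size varies. The panel symbol
for CD8 differs between panel releases, so `CD8` resolves to `CD8A`
via an alias table rather than being guessed from context. Outputs say
"FOXP3⁺ cells", not "Tregs": a single marker cannot separate
regulatory from activated conventional T cells.

# Fold-change ranking

Expression is normalized to counts-per-10k (each cell scaled to a
10⁴ library, matching targeted-panel depth; the scale is a parameter),
and genes are ranked by
log₂(mean_sample + c) − log₂(mean_ref + c) with pseudocount c = 1
over the like-gated subsets of sample and reference. Writing the
statistic as a difference of logarithms makes antisymmetry under
swapping sample and reference bitwise exact. No p-values are attached:
the deliverable is a ranked top-10/bottom-10 report, and attaching a
significance model to a cross-platform comparison would overstate what
the ranking supports. The pseudocount shrinks low-expression ratios
toward zero; as c → ∞ all values vanish, which the suite uses as a
sanity check.

# The synthetic generator

`sim_config()`/`simulate_repertoire()`/`simulate_expression()` emulate
one captured sample: 10⁴ cells by default (typical microwell capture
scale), a clone-frequency law (symmetric Dirichlet by default, 200
clones; geometric available), per-clone paired identities with V/J
drawn once from usage profiles skewed toward the segments dominant in
patient repertoires, CDR3 letters uniform over the amino-acid alphabet
at lengths 8–20 (spanning observed paired-clonotype tables), chain
molecule counts 1 + Poisson(2), and 10% per-chain dropout by default.
Clone identities are rejection-sampled to be distinct, so the
generating clone-frequency vector's entropy is exactly the true
clonotype entropy. Marker-positive cells receive zero-truncated
negative-binomial marker counts (mean 2, size 2) and are zero
elsewhere, so gating at ≥ 1 UMI recovers the truth labels exactly;
background panel genes are NB(mean 0.3, size 2) over a 100-gene panel
that includes the canonical CD8/Treg signature genes as named labels.
Planted effects scale gene means by 2^lfc in the case sample; the
default plants |log₂ FC| = 2 on five up- and four down-labelled genes.

Two structural choices deserve emphasis:

* **Nested subsets.** Each marker's positive cells are drawn from
  cells of the first `marker_clone_fraction` of clones (FOXP3 15%,
  CD8 60% by default). This is what makes subset diversity genuinely
  lower than bulk — the qualitative pattern marker-defined T-cell
  subsets show in practice — rather than a subsampling artefact.
* **Recovery is measured against the induced usage.** Because V/J are
  drawn once per clone, the cell-level segment distribution converges
  (as cells grow) to the clone-frequency-weighted distribution of the
  realized clone identities, not to the raw input profile; the
  difference is clone-sampling noise of order 0.15 total variation at
  200 clones and does not shrink with cells. Parameter-recovery
  checks therefore compare empirical usage to the induced usage
  recorded in the ground truth, which is the estimand the pipeline can
  consistently estimate.

All generator output is a pure function of the configuration,
including the seed; the expression stream uses a fixed offset from the
repertoire seed (and deliberately not of the case flag, so zero
planted effects give byte-identical case and control matrices).

What the generator does *not* emulate: biophysically realistic CDR3
composition (the pipeline only ever tests CDR3 identity), doublets and
ambient contamination, platform error correction beyond single-base
UMI substitutions, batch or chemistry effects between sample and
reference, and cross-talk between expression and chain recovery.
Passing tests therefore validate the statistics and their
book-keeping, not robustness to those real-data pathologies.

# Problem sizes and tolerances

The suite runs at sizes chosen to keep unit feedback fast while making
the statistical checks meaningful: entropy/usage recovery on a
50 000-cell, 200-clone, dropout-free sample (plug-in entropy bias
(S−1)/2n ≈ 0.002, so the 0.05 margin is generous); gating recovery at
5 000 cells against 3 binomial standard errors; fold-change rank
recovery at 2 000 cells per side; oracle equivalence of H′ on 1 000
random vectors (up to 10⁴ entries) at 1e−12. Exact identities
(marginal conservation, antisymmetry, determinism) are asserted at
1e−9 or bitwise. Fixed seeds are used throughout the suite;
`scripts/acceptance.R` takes its seed on the command line and its
recovery margins hold across seeds because they sit far above the
sampling noise at these sizes.

# Known limitations

* Chain-level diversity weights molecules, clonotype diversity weights
  cells; mixed-entity comparisons are not meaningful.
* The Hamming-1 merge is a stand-in convention for platform error
  correction, not a reimplementation of any proprietary algorithm;
  distribution-based (count-threshold) correction is not implemented.
* Fold-change rankings across platforms carry no batch correction, and
  none is claimed.
* The catalog fixture reflects one IMGT-style functionality snapshot;
  users tracking IMGT releases should supply their own file.
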