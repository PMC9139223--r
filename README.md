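# pairrep

Paired single-cell T-cell receptor (TCR) repertoire analysis in R.

Single-cell V(D)J capture (microwell platforms such as BD Rhapsody)
recovers, for each cell, the rearranged TCR alpha and beta chains — the
germline V and J segments plus the hypervariable CDR3 amino-acid loop —
together with a targeted cell-by-gene UMI count matrix. `pairrep`
implements the downstream repertoire analysis of such experiments for
immunologists studying clonal structure in peripheral blood T cells:

* **Molecule folding** — reads with identical cell label, UMI and gene
  are folded into one molecule; a directional Hamming-distance-1 merge
  corrects UMI substitution errors (a UMI one base away from a strictly
  more abundant UMI is absorbed by it).
* **Segment functionality filtering** — germline TRAV/TRAJ/TRBV/TRBJ
  segments carry IMGT functionality classes (functional, pseudogene,
  ORF); pseudogenes and ORFs are excluded from usage counting. The
  bundled catalog gives 41 × 50 = 2050 possible TRAV–TRAJ recombinants
  over the expressed functional set and 50 × 13 = 650 for TRB.
* **Usage and pairing** — percentage usage vectors per segment and the
  full V–J pairing matrix, weighted by molecules, reads or cells; row
  and column sums of the pairing matrix reproduce the usage vectors
  exactly.
* **Paired clonotype assembly** — per cell, the most abundant TRA and
  TRB chains define the clonotype 6-tuple
  (TRAV, CDR3α, TRAJ, TRBV, CDR3β, TRBJ); ranked top-10 tables report
  frequencies over all paired cells.
* **Shannon diversity** — H′ = −Σᵢ pᵢ ln pᵢ over the frequencies of a
  chosen repertoire entity (CDR3 sequence, V–J pair, per-chain
  V/CDR3/J, or paired clonotype), for the bulk sample and for
  marker-gated subsets.
* **Subset gating** — CD8⁺ and FOXP3⁺ subsets are cells with ≥ 1 raw
  UMI of the marker gene (threshold configurable).
* **Fold-change ranking** — genes ranked by
  log₂((mean_sample + 1) / (mean_ref + 1)) of counts-per-10k normalized
  expression between like-gated subsets of a sample and a reference,
  yielding top-10 up/down tables.
* **Synthetic data with ground truth** — a generator emulating a
  ~10⁴-cell paired capture (clone-frequency law, per-clone paired
  identities, nested marker subsets, planted fold changes) so every
  stage is testable against known parameters.

## Worked example

```r
library(pairrep)

cfg <- sim_config(n_cells = 5000, n_clones = 120, seed = 42)
sim <- simulate_repertoire(cfg)

asm <- assemble_clonotypes(sim$records)
asm
#> Paired clonotype assembly: 4048 paired cell(s), 115 clonotype(s),
#> 915 unpaired cell(s)

top_clonotypes(asm, 3)[, c("clone_id", "frequency_percent", "tra_v",
                           "cdr3_a", "tra_j", "trb_v", "trb_j")]
#>   clone_id frequency_percent      tra_v            cdr3_a  tra_j   trb_v   trb_j
#> 1        1          6.175889     TRAV17          NSMYKVHP TRAJ27 TRBV6-5 TRBJ2-4
#> 2        2          3.952569    TRAV9-2      IDCTDMFADQGS TRAJ12 TRBV6-5 TRBJ1-5
#> 3        3          3.705534 TRAV23/DV6 LIKDCGCSKFTNYEGCD TRAJ17  TRBV19 TRBJ2-1
```

With 10% chain dropout per locus, 4048 of 5000 cells yield a paired
clonotype; the most expanded clone occupies 6.2% of paired cells. TRAV
usage (molecule-weighted, pseudogenes/ORFs excluded) and diversity:

```r
u <- segment_usage(sim$records, "TRA", "V")
head(u[order(-u$percent), ], 3)
#>       label count  percent
#> 14  TRAV9-2  1832 13.48248
#> 23   TRAV17  1798 13.23226
#> 16 TRAV12-1  1468 10.80365

repertoire_diversity(sim$records, entity = "cdr3_aa", locus = "TRA")
#> [1] 4.255487

expr <- simulate_expression(cfg, sim$truth)
subset_diversity(sim$records, gate_cells(expr, "FOXP3"), "cdr3_aa", "TRA")
#> [1] 2.447314
```

The FOXP3⁺ subset (250 of 5000 cells, drawn from a restricted clone
pool) is markedly less diverse than the bulk repertoire (H′ 2.45 vs
4.26), the pattern expected when regulatory-like subsets are clonally
narrower. `run_report(sim$records, "out/", expression = expr)` writes
the full bundle — usage tables, pairing matrices, a diversity table
(bulk/CD8⁺/FOXP3⁺ × TRA/TRB), top-10 clonotype tables and a JSON
manifest — deterministically.

Real data enter through `read_rearrangements()` (AIRR Rearrangement
TSV) and `read_expression()` (MatrixMarket or dense TSV);
`fold_molecules()` and `collapse_umis_hamming1()` handle read-level
tables.

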