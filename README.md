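# lriso

Long-read single-cell RNA sequencing of tumors can resolve what short reads
cannot: which isoform of a gene each cell expresses, where its 3'UTR ends,
whether a transcript is a gene fusion, and which cells carry a known
mutation. The sequencing protocols that make this affordable concatenate
several full-length cDNA molecules into each HiFi read, so the raw data must
first be cut back into single tagged molecules before any of those questions
can be asked.

`lriso` implements the bespoke computational stages of such a study as a
tested, reusable R package, together with a fully seeded synthetic-data
generator that produces every input with known ground truth:

* **Deconcatenation** — approximate primer scanning (bounded edit distance,
  substitutions and indels), segmentation between successive primer pairs,
  extraction of the 16 nt cell barcode and 12 nt UMI, polyA detection and
  trimming, whitelist rescue at Hamming distance 1, and directional UMI
  deduplication.
* **Isoform catalog** — collapse of aligned molecules by junction chain,
  SQANTI-style structural classification (FSM / ISM / NIC / NNC), artifact
  filters (intrapriming, noncanonical novel junctions, RT template-switch
  repeats, minimum 3 UMIs), 5'/3' end validation against CAGE peaks and
  polyA sites (50 bp windows), and cell-type-specificity labels.
* **Alternative polyadenylation (APA)** — the two-polyA-site model on 3'UTR
  coverage. With `w[c][k]` the coverage of condition `c` at UTR position `k`
  (5'→3', length `L`):

  ```
  L* = max{ k : w[c][k] > 10 for some c }
  (C*, P*) = argmax over c, P of ( mean(w[c][P+1..P+50]) − mean(w[c][P−50..P−1]) )²
  W_d = mean(w[c][L*−50..L*−1]),  W_p = mean(w[c][P*−50..P*−1])
  F = W_d / (W_d + W_p)
  Fraction Change = F_C1 − F_C2      (positive = 3'UTR lengthening)
  ```

  with a two-sided Fisher's exact test on the rounded `W` table and
  Benjamini–Hochberg correction across genes.
* **Differential isoform usage** — Pearson χ² per gene on the isoform ×
  condition UMI table, per-isoform usage shares Π (percent) and ΔΠ, the
  "top two ΔΠ of common sign" effect size, the `p_adj ≤ 0.05 ∧ ΔΠ-sum > 20`
  calling rule, rank-product gene ranking, biotype-change accounting and
  noncoding-expression fractions.
* **Fusion detection** — reads split-aligned to two genes (different
  chromosomes or >100 kb apart, ≥200 aligned bases per locus), breakpoint
  clustering within ±10 bp, a ≥10 UMI support threshold, assignment of reads
  to small custom breakpoint references by local alignment with a margin
  rule, and per-reference group-specificity Fisher tests.
* **Mutation calling** — panel-guided per-cell counts of reference and
  alternative bases; a cell is mutated at one alternative read; variants
  mutated in any distal-biopsy cell are germline, the rest somatic.

## Worked example

Simulate a small cohort (8 genes, 120 cells, two conditions) with an
implanted APA contrast on gene `G003` (true distal usage 0.8 in tumor vs 0.3
in distal cells) and a 12-UMI gene fusion, then run the full pipeline:

```r
library(lriso)

cfg <- sim_config(seed = 1, n_genes = 8, cells_per_type = 60,
                  umis_per_cell_gene = 2,
                  apa_distal_fraction = data.frame(
                    gene_id = "G003", cell_type = c("tumor", "distal"),
                    fraction = c(0.8, 0.3)),
                  fusion_spec = list(gene_5p = 1, gene_3p = 2, n_umis = 12,
                                     cell_type = "tumor"))
ref <- simulate_reference(cfg)
sim <- simulate_molecules(cfg, ref)
rr  <- render_reads(sim, cfg)                      # 484 concatenated reads
dec <- deconcat_reads(rr$reads, unique(sim$cells$cell_barcode))
dd  <- dedup_umis(dec$molecules)                   # 1887 of 1893 molecules

aln <- emit_alignments(sim, ref)                   # aligner stand-in
aln <- aln[paste(aln$cell_barcode, aln$umi) %in% paste(dd$cell_barcode, dd$umi), ]
cells <- sim$cells[, c("cell_barcode", "cell_type")]
res <- run_catalog(aln, ref$exons, ref$genome, ref$cage, ref$polya, cells)
res$catalog
#> Isoform catalog: 18 isoforms, 1831 assigned molecules
#> FSM
#>  18

groups <- data.frame(cell_barcode = cells$cell_barcode,
                     condition = cells$cell_type)
apa <- run_apa(aln, ref$utr3, groups, "tumor", "distal")
head(apa$table[, c("gene_id", "L_star", "P_star", "F_c1", "F_c2",
                   "fraction_change", "p_adjusted", "direction")], 2)
#>   gene_id L_star P_star  F_c1  F_c2 fraction_change p_adjusted  direction
#> 1    G003    300    150 0.432 0.256           0.176    0.00185 lengthened
#> 2    G008    300    150 0.272 0.466          -0.194    0.00185  shortened

ev <- aggregate_events(find_fusion_reads(aln, ref$genes), cells)
ev
#>   gene_5p gene_3p breakpoint_5p breakpoint_3p n_umis n_cells celltype_counts
#> 1    G001    G002          2166          5148     12      12        tumor=12
```

Every isoform is recovered as a full splice match, the implanted APA
contrast on `G003` comes out as significant 3'UTR lengthening (estimated
`F = 0.43` vs `0.26`; under the two-site model the estimated `F` converges
to `f/(1+f)` of the true distal fraction `f`, i.e. 0.44 and 0.23 here), and
the fusion is found at its exact breakpoints with all 12 supporting UMIs in
tumor cells.

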