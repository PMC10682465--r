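---
title: "Models and methods of the lriso pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the lriso pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lriso` re-implements, as library code with tests, the analysis stages that a
long-read single-cell RNA-seq cancer study needs beyond the standard tool
chain: cutting concatenated HiFi reads back into tagged cDNA molecules,
building and filtering an isoform catalog, detecting alternative
polyadenylation (APA), testing differential isoform usage, calling gene
fusions from split alignments, and calling panel mutations per cell. This
vignette describes the models, the tunable parameters and their defaults,
the synthetic-data generator, and the numerical and design choices, in the
package's own words.

## The data model

A library molecule is one full-length cDNA carrying a 16 nt cell barcode and
a 12 nt UMI. To raise throughput, several molecules are ligated into one
sequencing read; each *segment* of such a read is

```
5' primer | barcode (16) | UMI (12) | polyT tract | reverse-complemented cDNA | 3' primer
```

and each segment independently lands in either strand orientation. The mean
number of segments per read is a library property; the generator and the
tests use 4. Downstream stages operate on *spliced alignment records*: one
record per deduplicated molecule with its exact genomic exon blocks
(0-based, half-open), the dialect the package reads and writes as TSV. The
generator emits these records directly from the simulated molecules, taking
the place of a spliced aligner so every downstream stage is testable without
one; with real data, any aligner that can be exported to the dialect (or the
corresponding BAM conversion) can feed the same functions.

## Deconcatenation (`find_primer_hits`, `split_segments`, `extract_tags`, `dedup_umis`)

Primers are located by bounded edit distance (substitutions and indels, unit
costs), default `max_edit = 3` on 22 nt primers, using a bit-parallel
semi-global scan in C++; overlapping candidate hits are resolved lowest edit
distance first, then leftmost. Edit-distance matching replaces the word-based
local alignment search an external aligner would provide — same intent, no
external tool, and exhaustively testable against a sliding-window oracle.

Candidate segments are the gaps between successive hits. Only gaps bounded
by a correctly oriented primer pair are parsed further: `forward(+) →
reverse(+)` (sense) or `reverse(−) → forward(−)` (antisense); everything
else is rejected as `wrong_pair` — this is what removes chimeric or
primer-dropout artifacts. After orientation normalization the barcode is the
first 16 nt, the UMI the next 12 nt. The polyA tail is detected in cDNA
sense orientation as a 3' terminal run of at least `polya_min_run = 20`
bases with at most 10% non-A, and trimmed; segments without it are rejected
(`no_polya`). Because a genomic A immediately upstream of the tail is
indistinguishable from the tail itself, trimming may remove a few genuine
terminal A's — tags and counts are unaffected. Barcodes must match the
whitelist exactly or have a unique Hamming-1 neighbour; ambiguous rescues
are rejected (`no_barcode_match`). Every candidate segment therefore ends up
accepted or rejected with exactly one primary reason.

UMI deduplication is directional within each cell: UMIs identical or within
Hamming distance 1 merge, lower-count into higher-count (ties resolved by
count order, then lexicographically), the representative keeps the longest
cDNA, and the read count of the merged cluster is reported.

## Isoform catalog (`collapse_molecules`, `classify_catalog`, filters)

Multi-exon molecules sharing an identical junction chain collapse into one
isoform; the TSS is the 5'-most observed start and the TES the modal end
(ties resolved 3'-most). Mono-exon molecules merge at ≥95% reciprocal
overlap. Junction-chain equality replaces the coverage/identity knobs of
alignment-based collapse tools; on exact alignments the two coincide, which
is the regime the generator produces. Collapse runs in a single cohort-level
pass — per-cell pre-collapse in the original setting was a runtime
workaround, not a semantic requirement.

Structural categories follow the SQANTI vocabulary: **FSM** (junction chain
equals a reference transcript), **ISM** (contiguous sub-chain), **NIC** (all
donors and acceptors known at the locus but new combination, including new
pairings of known sites), **NNC** (at least one unknown splice site, a
neojunction), and `other` for mono-exon or intergenic cases. Classification
is checked against a brute-force chain/sub-chain search in the tests.

Artifact filters, applied in a fixed precedence so each removal carries one
reason:

1. **intrapriming** — the 20 nt genomic window downstream of the TES (in
   transcript orientation) has A-fraction ≥ 0.6; windows truncated at contig
   ends are evaluated as-is;
2. **noncanonical** — a *novel* junction whose motif is outside
   {GT-AG, GC-AG, AT-AC}; reference-supported junctions are exempt, so FSM
   isoforms are never removed by this rule;
3. **rt_switch** — a novel junction with an exact direct repeat of ≥ 8 nt
   within 8 nt of both intron boundaries, the template-switch signature;
4. **min_umis** — fewer than 3 supporting UMIs.

The window, A-fraction and repeat-length defaults follow common practice for
this filter family. End validation then requires the TSS within 50 bp of a
CAGE interval and the TES within 50 bp of a polyA site; ISM/NIC/NNC isoforms
failing either are removed, FSM isoforms are always retained with the flag
recorded. The minimum-UMI filter runs before end validation; the order is a
package choice, fixed for deterministic reporting. Specificity labels apply
to FSM/NIC/NNC isoforms with ≥3 reads: `cell_specific` (exactly one cell),
`cell_type_specific` (≥3 cells, all of one type), else `shared`.

## Alternative polyadenylation (`run_apa`)

The analysis assumes the two-polyA-site model: reads of a gene end either at
a proximal site `P` or at the distal end of the annotated 3'UTR. Overlapping
3'UTR exons with different 5' starts are discarded gene-wide (they mimic
APA); same-start overlaps merge to their union; non-overlapping alternative
last exons stay separate regions. Coverage `w[c][k]` is computed per
condition over UTR positions `k = 1..L` in transcript orientation
(minus-strand regions are reversed at extraction).

* distal site: `L* = max{k : w[c][k] > 10 in any c}` (strict inequality:
  constant coverage 10 is untestable);
* proximal site: `(C*, P*)` maximizes the squared gap between the mean
  coverage of the 50 positions after and before `P`, over all conditions
  jointly and `P ∈ [51, L*−50]` so both windows fit; ties break to the
  smallest `P`, then the smallest condition index; a flat profile (objective
  identically zero) is flagged degenerate and excluded — it carries no site
  information;
* usage: `W_d` and `W_p` are the mean coverages of the 50 positions
  immediately upstream of `L*` and `P*`; `F = W_d / (W_d + W_p)`, undefined
  (excluded, `zero_coverage`) when both are zero.

Note that `W_p` counts reads using *either* site, so under the two-site
generative model with true distal fraction `f`, the estimand is
`F = f / (1 + f)`, not `f` itself. The definition is kept exactly as stated;
the mapping is monotone and invertible, and the recovery tests check it
explicitly. Between two named conditions, `Fraction Change = F_C1 − F_C2`
(positive = lengthening in `C1`); the p-value is a two-sided Fisher's exact
test on the 2×2 table of `W` values rounded to the nearest integer (halves
away from zero — `W` values are means of 50 integers, and Fisher needs
counts; the rounding is deterministic and unbiased). BH correction runs
across all tested genes, and direction calls use adjusted p < 0.05. Scaling
all coverage by a common factor leaves `F` unchanged but changes the Fisher
counts, hence the p-value — the test sees evidence, not just proportions.

## Differential isoform usage (`run_diff_usage`)

Genes are testable when they are not mitochondrial/ribosomal (name prefixes
`MT-`, `RPS`, `RPL`, `MRPS`, `MRPL`; configurable regex), have ≥2 isoforms,
and reach ≥25 UMIs in *each* condition ("did not reach sufficient depth" is
read as an inclusive ≥25 bound). Per gene, Pearson's χ² without continuity
correction on the isoform × condition table (the plain test; genes with
expected cells < 5 pass through but are flagged `low_expected`). Usage
shares Π are column percentages; ΔΠ = Π(C1) − Π(C2) per isoform in
percentage points, so the 20-point threshold applies directly. The effect
size is the larger of the summed two largest positive ΔΠ and the absolute
summed two most negative (a direction with a single moving isoform sums
alone). A gene is called when BH-adjusted p ≤ 0.05 (inclusive) *and* the
effect exceeds 20 points (strict). Called genes are ranked by
`sqrt(rank_ΔΠ × rank_p)` (descending effect rank × ascending p rank,
average ranks for ties, ties in the score broken by gene id).

Biotype change compares the biotypes (not the identities) of the top
expressed isoform per condition, ties resolved by the count in the other
condition then lexicographically; the transition label classifies
protein-coding vs non-coding. The noncoding fraction is reported for
protein-coding genes with ≥20 UMIs in a condition as noncoding UMIs over
total.

## Fusions (`find_fusion_reads`, `aggregate_events`, `assign_reads_to_references`)

Fusion candidates are reads split-aligned to two distinct genes, each locus
with ≥200 aligned bases, on different chromosomes or >100,000 bp apart (the
distance appears both as 100 kb in prose and 1 Mb in a quoted command line
in the source study; 100 kb is the default and the parameter is exposed).
Events group reads by gene pair and breakpoint pair with a ±10 bp clustering
tolerance (long-read end wobble; the study states no tolerance) and require
≥10 supporting UMIs; per-cell-type counts and distinct-cell counts are
reported, with the 5' gene taken from the read's locus order.

For validation against a small custom breakpoint reference, each read is
scored against every sequence by best local alignment (match +1, mismatch
−1, unit gaps, so one edit costs about two score units); a read is assigned
only when a single sequence wins by a margin of ≥2 edits and the best
alignment has ≥80% identity over its overlap, otherwise it is `ambiguous` or
`poor`. Group specificity per reference sequence is a two-sided Fisher test
of hits vs non-hits between the two groups. An optional deny-list for
recurrent artifact partners (e.g. mitochondrial rRNA) is deliberately not
built in: events are reported with their gene pair, and filtering is the
caller's decision.

## Mutations (`call_mutations`, `classify_variants`)

The panel is a user-supplied table of single-nucleotide variants (1-based
positions). Per cell and variant, reads with the alternative and reference
base are counted; a cell is *mutated* as soon as one alternative read is
seen (HiFi base quality; the minimum is exposed as a parameter). Absence of
coverage yields no call — it is not evidence of wild type. A variant mutated
in at least one cell from a distal (tumor-free) biopsy is **germline**;
otherwise, with at least one mutated tumor cell, **somatic**; with no
mutated cell, unclassified. Indels are out of scope.

## The synthetic-data generator

`sim_config()` fixes the study conditions; one top-level seed determines
every output, with fixed per-stage seed offsets so each stage is
reproducible on its own. The generator emulates:

* non-overlapping multi-exon genes (4–7 exons, 120–250 nt, introns
  300–800 nt) on two chromosomes, 1–3 isoforms per gene built by skipping
  internal exons, canonical GT-AG motifs planted at all annotated introns,
  and a 3'UTR (default 300 nt, >101 nt required so both APA windows fit) on
  the shared terminal exon;
* CAGE intervals at every TSS and polyA sites at every TES plus the
  proximal APA site halfway into the UTR;
* per-gene × cell-type isoform usage (symmetric Dirichlet, concentration 2,
  unless specified) and distal-usage fractions (uniform on [0.2, 0.9]
  unless specified) — the generative counterparts of Π and F;
* molecules per cell and gene (Poisson, default mean 1), 3' termination
  distal vs proximal by the gene × cell-type fraction, variants implanted at
  their allele fraction in carrier cell types, and fusion molecules joining
  the first two exons of one gene to the terminal exon of a gene on another
  chromosome;
* concatenated reads with truncated-Poisson segment counts (λ solved so the
  mean matches the configured 4; minimum 1), per-segment random strand
  orientation, a fixed 30 nt polyT tract (only presence matters
  downstream), substitution errors at the configured rate (default 0.002,
  HiFi-like; indels are not simulated), and an optional fraction of
  artifact segments lacking the tail or one primer.

What the generator does **not** emulate: realistic PacBio error profiles
(indels, quality-dependent errors), adapter chemistry, read-length
distributions, ambient RNA, doublets, expression magnitudes beyond Poisson
counts, or overlapping gene structures. Passing tests therefore demonstrate
the correctness of the *rules* — recovery of tags, categories, sites,
fractions and calls from data that satisfies the model assumptions — not
robustness to every failure mode of real libraries.

Artifact proportions in real data (the intrapriming / noncanonical /
RT-switch mix) are data-derived quantities; the generator's
`artifact_fraction` is a free parameter, not a calibrated claim.

## Numerical choices and problem sizes

Coordinates are 0-based half-open in memory; GTF is written 1-based
inclusive and BED 0-based half-open. Fisher tables round half away from
zero. The proximal-site search range is `[51, L*−50]`. All tie-breaks
(smallest P, smallest condition, lexicographic ids) are fixed and tested.
Rejection and removal reports carry exactly one reason each, in documented
precedence.

The verification suite runs at desk scale: the deconcatenation round trip
uses ~10,000 reads (≈41,000 segments), APA recovery 100 genes at per-base
coverage ≥100 per condition, differential-usage error control 200 null and
10 switched genes over 50 replicates at depth 100 per condition, and the
end-to-end run 20 genes × 200 cells. These sizes give the stochastic checks
comfortable margins (binomial standard errors well under the asserted
tolerances) while keeping the whole suite to a few minutes on one CPU.

## Known limitations

* The aligner is simulated: alignment records carry exact exon blocks, so
  alignment noise (soft-clipping, mis-spliced junctions) is untested.
* The two-site APA model reports at most one proximal site per UTR; genes
  with more than two sites fold into the dominant gap.
* χ² p-values are asymptotic; very sparse isoform tables are flagged rather
  than switched to an exact test.
* Fusion 5'/3' order relies on the locus order of the alignment records
  when strands leave it ambiguous.
* Biotypes of novel isoforms are not predicted (no ORF analysis); biotype
  accounting uses reference biotypes.
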