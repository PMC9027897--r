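---
title: "Discovering expressed Alu-containing lncRNA candidates in immune genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering expressed Alu-containing lncRNA candidates in immune genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aluscan)
```

## The screen and its assumptions

`aluscan` screens bulk RNA-seq cohorts for Alu elements embedded in genes
that behave like independent transcripts: they are expressed well above
background, differentially expressed between an inflammation group and
healthy controls, and associated with an empirical (CAGE) transcription
start site at their 5' side. The screen is deliberately simple and
annotation-driven; it assumes

* a single genome build shared by the repeat track, the gene annotation,
  the CAGE TSS track and the alignments;
* that per-insertion fragment counts are an adequate expression proxy —
  multi-mapping is not modelled (all primary alignments count), and reads
  are not re-assigned between overlapping features;
* that a two-sided t-test on normalized counts approximates the group
  comparison well enough at cohort-scale sample sizes (tens per group).
  The test is Welch's by default because the groups are unequal in size and
  count data are heteroscedastic; a pooled-variance variant is available
  via `pooled = TRUE`.

## Coordinate conventions

All intervals are `GRanges` (1-based, closed) internally. BED input/output
is 0-based half-open and converted exactly at the boundary; GTF and
genome-browser locus strings (`chr19:47321326-47321636`) are 1-based
inclusive and pass through unchanged. Keeping one internal convention —
the Bioconductor-native one — avoids the off-by-one drift that plagues
mixed BED/GTF pipelines.

## Parameters that matter

| parameter | default | unit | meaning |
|---|---|---|---|
| `min_gene_fraction` | 0.009 | fraction of gene span | minimum overlap for an insertion |
| `min_count` | 400 | raw fragments, ≥, in ≥1 sample | expression floor |
| `robust_count` | 1000 | raw fragments, strictly >, in ≥1 sample | robust-set floor |
| `fc_threshold` | 1.3 | ratio, ≥, either direction | fold-change filter |
| `alpha` | 0.001 | adjusted p, strictly < | significance |
| `tss_window` | 1000 | nt, strictly < | upstream TSS linkage |
| `strand_mode` | both | — | fragment counting strand handling |
| `tss_half_fraction` | 0.5 | fraction of element span | "5' part" for internal TSSs |
| `drop_window`, `drop_ratio` | 200 nt, 0.5 | — | coverage-drop signature at a TSS |

Boundary semantics are intentional and tested: the 400 floor is inclusive
("at least 400"), the 1000 floor is strict ("more than 1000"), significance
is strict (`p_adj < alpha`), and the TSS window is strict (`< 1000` nt; a
TSS exactly 1000 nt upstream is not linked).

The overlap fraction is measured on the **gene** span, reproducing the
behaviour of `bedtools intersect -a genes -b alu -f 0.009`: a ~300-bp
element cannot qualify inside a gene longer than ~33 kb. This is a property
of the published command that users should be aware of; the configuration
flag `fraction_of = "alu"` measures the fraction on the element instead.

## Design choices where the design was open

* **Reference transcript.** Candidate tables assign one position label per
  insertion, so features are derived from a single reference transcript per
  gene — the one with the largest summed exon length, ties broken by the
  lexicographically smallest id. Isoform-aware multi-labelling would not
  reproduce a one-label-per-row table.
* **"Excluding exons".** Insertions overlapping protein-coding exonic
  sequence (CDS) are excluded from candidates, but UTRs — which are exonic —
  are legitimate candidate positions; 3'UTR candidates are in fact the most
  common class. Position is decided by largest base-pair overlap with ties
  resolved by the precedence 3'UTR > 5'UTR > CDS > intron, which favours
  the biologically interpretable label when an element straddles a
  boundary.
* **Fragment unit.** Mates of a template are merged into one fragment
  spanning both alignments (strand from the first-in-pair mate), so a pair
  never counts twice. Mates on different chromosomes fall back to two
  single-end fragments.
* **Fold change.** `max(m_i/m_h, m_h/m_i)` on group means of normalized
  values with pseudocount 1, direction recorded separately — the screen
  keeps both up- and down-regulated candidates, and roughly half of the
  published candidate set moves in each direction.
* **TSS strand.** Embedded candidate transcripts run with their host gene,
  so TSS matching uses the host gene's strand; unstranded TSS records match
  either strand. "TSS in the 5' part" is formalized as the 5' half of the
  element span (`tss_half_fraction = 0.5`, configurable).
* **Clustering.** `hclust` with `ward.D2` on Euclidean distances (Ward's
  criterion on the original distance scale). Tie-breaking follows `hclust`'s
  deterministic behaviour given the input column order. Separation is
  scored as best-matching accuracy between the two root branches and the
  binary condition labels.
* **Coverage drop.** The qualitative genome-browser observation that read
  coverage drops at an internal TSS is quantified as the ratio of mean
  per-base coverage in a 200-nt window 5' of the TSS over the matching 3'
  window; ratios at or below 0.5 flag an independent-transcript signature.
  Both numbers are reported, never hard-coded into candidate status.

## What the synthetic data emulate — and what they do not

`simulate_annotation()` emits toy genomes in which the geometry is
noiseless: genes of 2–6 exons (spans ≤ ~22 kb, so every planted element
clears the gene-fraction threshold), elements planted wholly inside one
intron or 3'UTR with ≥1 kb clearance so TSS linkage cannot cross-talk, and
upstream TSS offsets drawn in 100–900 nt. Discovery on this geometry must
recover 100% of planted position labels, orientations and TSS offsets, and
the test suite asserts exactly that.

`simulate_counts()` draws negative-binomial counts (dispersion 0.1 — the
bulk RNA-seq overdispersion regime; Poisson would be unrealistically tight)
with log-uniform baseline means, planting a group fold change into a subset
of insertions. Default group sizes mirror a sepsis cohort (40 healthy, 12
infection, 18 sepsis, 18 septic shock); the statistical checks in the test
suite use 20 vs 20 with 1000 null insertions (type-I control within
binomial 99% bounds of 0.05, and essentially no BH calls at α = 0.001) and
a power setting of fold change 4 at baseline means 2000–4000, where the
full cascade must recover ≥90% of planted insertions and Ward clustering
must separate the groups exactly. These sizes keep the default test run in
minutes on one CPU.

What passing these simulations does **not** show about real data: no
mappability or multi-mapping structure (Alu elements are repeats — real
alignments have ambiguous placements the simulation does not generate), no
library-composition extremes, no isoform complexity (one transcript per
simulated gene), no correlated TSS noise (CAGE positions are exact), and no
batch effects. The simulations validate the pipeline's logic and its
statistical calibration, not the biology of any particular cohort.

A composition effect worth knowing about: with a large planted
differentially expressed fraction (50% in the power setting), median-of-
ratios size factors absorb some group signal and a few null rows can pass
the full cascade (observed false-discovery proportions of a few percent).
This mirrors the behaviour of median-of-ratios normalization on real data
when the equal-expression majority assumption is strained.

## Numerical and degenerate-input choices

* Size factors follow the plain median-of-ratios definition
  `sf_j = median_i(c_ij / g_i)` over rows with a positive geometric mean;
  a matrix with no all-positive row raises an error suggesting a
  pseudocount (the pipeline driver adds one before estimating factors).
* `bh_adjust` validates its input range and delegates to the standard
  step-up implementation; the test suite checks it against a brute-force
  enumeration of the step-up definition for all input lengths ≤ 6.
* A repeat with zero overlap to all derived features but inside the gene
  interval is labelled `Intron` (it lies outside the reference transcript's
  span); outside the gene interval it is an error.
* Zero downstream coverage makes the TSS coverage-drop ratio `Inf`
  ("no signal") rather than `NaN`.
* Empty symbol lists, headerless SAM files, malformed BED lines (including
  empty intervals with `start == end`) and unknown candidate-table tokens
  all fail fast with line-numbered messages where applicable.

## Known limitations

Alignment, CAGE peak calling, UMAP embedding, negative-binomial GLM testing
and multi-group comparisons across the four clinical conditions are out of
scope; the screen consumes alignments and tests only the pooled binary
contrast. Symbol matching is exact (case-insensitive) — alias resolution is
expected to have happened upstream of the symbol list. Reported p-values
for published cohorts depend on patient-level data and are not recomputable
from the packaged candidate table, whose role is summary-level.
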