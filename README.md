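# aluscan

Discovery of expressed Alu-containing lncRNA candidates in immune genes from
bulk RNA-seq.

## The problem

Alu elements are ~300-bp primate SINE retrotransposons with more than a
million genomic copies in three families (AluJ, AluS, AluY), concentrated in
introns and untranslated regions of genes. An Alu element embedded in a gene
body that (i) is differentially expressed between patients with severe
inflammation (infection, sepsis, septic shock) and healthy controls, and
(ii) carries its own CAGE-supported transcription start site just upstream
or in its 5' part, is a candidate for an independently transcribed
Alu-containing long non-coding RNA — a potential regulator of its host
immune gene and a possible RNA-therapeutic target. The best-known example of
this class sits in the 3'UTR of the complement C5a receptor 1 gene
(*C5AR1*/CD88), where an AluSx1 element with a TSS ~300 nt upstream behaves
as an independent ~1-kb transcript during inflammation.

`aluscan` is for transcriptomics researchers who want to run this screen on
their own cohorts (or on simulated data) without genome-scale downloads:
every stage consumes standard plain-text formats (BED, GTF, SAM, TSV) and
the package ships a synthetic-data generator with known ground truth.

## The method

1. **Catalog** — Alu elements are parsed from a RepeatMasker-derived track
   (BED or UCSC GTF export) by the strict name prefix `Alu` and classified
   into families by the following letter (J/S/Y).
2. **Intersection** — an element is an *insertion* in a gene when the
   overlap reaches `ceil(f × gene length)` with `f = 0.009` (the fraction is
   measured on the gene span, as in `bedtools intersect -a genes -b alu -f
   0.009`).
3. **Classification** — against one reference transcript per gene (largest
   exonic content), each insertion is labelled Intron / 5'UTR / 3'UTR /
   coding exon by largest base-pair overlap (ties resolved by the precedence
   3'UTR > 5'UTR > CDS > intron); coding-exon overlaps leave the candidate
   set. Orientation is Sense iff the element and host gene strands match.
4. **TSS linkage** — a CAGE TSS on the gene strand, strictly less than 1000
   nt 5' of the element, flags it `upstream` (with its distance); a TSS in
   the 5' half of the element flags `internal_5prime`.
5. **Quantification** — aligned fragments (SAM; mates merged to template
   spans) are counted per insertion (`-strand both` semantics by default),
   normalized by median-of-ratios size factors
   (`sf_j = median_i(c_ij / g_i)`, `g_i` the row geometric mean).
6. **Filter cascade and statistics** — keep insertions with ≥400 raw
   fragments in ≥1 sample; test healthy vs inflammation (all non-healthy
   conditions pooled) with a two-sided Welch t-test on normalized values;
   adjust by Benjamini–Hochberg; the robust candidate set requires >1000 raw
   fragments in ≥1 sample, fold change ≥1.3 (either direction, pseudocount
   1) and adjusted p < 0.001. Samples are clustered with Ward linkage on
   Euclidean distances.
7. **Reporting** — surviving insertions are assembled into a seven-column
   candidate table (gene, subfamily, locus, position, TSS, orientation,
   adjusted p) and summarized by position, family, orientation and TSS
   tallies.

## Worked example

```r
library(aluscan)

# simulate a small cohort with known ground truth
sim <- simulate_annotation(n_genes = 10, seed = 21)
cm  <- simulate_counts(sim, n_per_group = c(healthy = 12, sepsis = 12),
                       seed = 22, de_fraction = 0.5, fc = 4,
                       mean_range = c(2000, 4000))

res <- run_pipeline(sim$genes_gtf, sim$repeats_bed, repeat_format = "bed",
                    tss_bed = sim$tss_bed, symbols = sim$symbols,
                    sample_sheet = cm$samples, counts = cm$counts)
evaluate_recovery(res$candidates$locus, cm$truth)
#> $sensitivity
#> [1] 1
#> $fdp
#> [1] 0.09090909
```

All 10 planted differentially expressed insertions survive the full cascade
(sensitivity 1), with one extra call (fdp 0.09). The packaged candidate
table of 48 expressed Alu insertions in immune genes summarizes as:

```r
summarize_candidates(read_candidate_table(immune_candidates_path()))
#> Candidate summary: 48 insertion(s) in 26 gene(s)
#>   position: Intron=21 UTR3=27 UTR5=0
#>   family:   AluJ=8 AluS=35 AluY=5
#>   orientation: Sense=24 Inverted=24
#>   TSS-associated: 21 (intron 6, 3'UTR 15)
#>   max p: 4e-04
```

Note the 3'UTR bias (27/48), the AluS majority (35/48) and that most
TSS-associated elements sit in 3'UTRs — the signature of 3'UTR-derived
non-coding transcripts.

A thin command-line wrapper is installed as `exec/aluscan` with
`simulate`, `discover` and `summarize` subcommands.

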