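test_that("interval index hits on >=1 bp overlap with closed boundaries", {
  idx <- build_interval_index(gr("chr1", 1, 10))
  expect_equal(query_index(idx, "chr1", 6, 6), 1L)
  expect_length(query_index(idx, "chr1", 11, 20), 0L)  # adjacency, no overlap
  expect_length(query_index(idx, "chr2", 5, 6), 0L)
})

test_that("interval index agrees with a brute-force scan on random instances", {
  set.seed(31)
  n <- 200
  chrom <- sample(c("chr1", "chr2"), n, TRUE)
  s <- sample.int(5000, n, TRUE)
  e <- s + sample.int(400, n, TRUE)
  idx <- build_interval_index(gr(chrom, s, e))
  for (k in 1:50) {
    qc <- sample(c("chr1", "chr2"), 1)
    qs <- sample.int(5000, 1)
    qe <- qs + sample.int(400, 1)
    brute <- which(chrom == qc & s <= qe & e >= qs)
    expect_equal(query_index(idx, qc, qs, qe), brute)
  }
})

test_that("gene/Alu intersection applies the gene-fraction rule", {
  mk_gene <- function(id, chrom, s, e) {
    make_gene(id = id, txs = list(make_tx(paste0("T", id),
                                          exons = gr(chrom, s, e, "+"))))
  }
  genes <- list(G1 = mk_gene("G1", "chr1", 1, 1000),
                G2 = mk_gene("G2", "chr2", 1, 100000))
  catalog <- build_catalog(gr(c("chr1", "chr2"), c(501, 501), c(800, 800),
                              strand = "+", name = c("AluSx1", "AluSx1")))
  pairs <- intersect_genes_alus(genes, catalog, 0.009)
  # overlap 300 >= ceil(0.009 * 1000) = 9 -> reported
  expect_equal(pairs$gene_id, "G1")
  expect_equal(pairs$overlap_bp, 300L)
  # overlap 300 < ceil(0.009 * 100000) = 900 -> excluded (gene-fraction rule)
  expect_false("G2" %in% pairs$gene_id)
  # fraction measured on the Alu instead reports both
  pairs_alu <- intersect_genes_alus(genes, catalog, 0.009,
                                    fraction_of = "alu")
  expect_setequal(pairs_alu$gene_id, c("G1", "G2"))
})

test_that("an Alu overlapping two genes yields two pairs", {
  genes <- list(
    G1 = make_gene("G1", txs = list(make_tx("T1", exons = gr("chr1", 1, 600, "+")))),
    G2 = make_gene("G2", txs = list(make_tx("T2", exons = gr("chr1", 550, 1200, "+"))))
  )
  catalog <- build_catalog(gr("chr1", 500, 800, "+", name = "AluY"))
  pairs <- intersect_genes_alus(genes, catalog, 0.009)
  expect_equal(nrow(pairs), 2L)
})

test_that("intersection equals the all-pairs oracle on random instances", {
  set.seed(41)
  ng <- 200; na <- 200
  gs <- sample.int(50000, ng); ge <- gs + sample.int(20000, ng)
  as <- sample.int(50000, na); ae <- as + sample.int(350, na)
  gchrom <- sample(c("chr1", "chr2"), ng, TRUE)
  achrom <- sample(c("chr1", "chr2"), na, TRUE)
  genes <- lapply(seq_len(ng), function(i) {
    make_gene(sprintf("G%03d", i),
              txs = list(make_tx(sprintf("T%03d", i),
                                 exons = gr(gchrom[i], gs[i], ge[i], "+"))))
  })
  names(genes) <- sprintf("G%03d", seq_len(ng))
  catalog <- build_catalog(gr(achrom, as, ae, strand = "+",
                              name = rep("AluSx", na)))
  # catalog is re-sorted: recover its coordinates for the oracle
  adf <- data.frame(chrom = as.character(GenomicRanges::seqnames(catalog)),
                    start = GenomicRanges::start(catalog),
                    end = GenomicRanges::end(catalog))
  gdf <- data.frame(chrom = gchrom, start = gs, end = ge)
  pairs <- intersect_genes_alus(genes, catalog, 0.009)
  oracle <- brute_intersect(gdf, adf, 0.009)
  got <- sprintf("%s|%d|%d", pairs$gene_id, pairs$alu_idx, pairs$overlap_bp)
  want <- sprintf("G%03d|%d|%d", oracle[, 1], oracle[, 2], oracle[, 3])
  expect_setequal(got, want)
})

feature_fixture <- function(strand = "+") {
  # exons 101-400, 2001-2500, 4001-4600; CDS 201..2300, so the 3'UTR is
  # 2301-2500 plus the whole terminal exon; intron2 is 2501-4000
  tx <- make_tx(strand = strand,
                exons = gr("chr1", c(101, 2001, 4001), c(400, 2500, 4600),
                           strand),
                cds_span = gr("chr1", 201, 2300, strand))
  derive_features(tx, gene_interval = gr("chr1", 1, 6000, strand))
}

test_that("classify_position takes the majority feature with precedence ties", {
  fs <- feature_fixture("+")
  expect_equal(classify_position(gr("chr1", 500, 800, "+"), fs), "Intron")
  expect_equal(classify_position(gr("chr1", 4100, 4400, "+"), fs), "UTR3")
  # intron 180 bp vs utr3 120 bp -> Intron by majority
  expect_equal(classify_position(gr("chr1", 3821, 4120, "+"), fs), "Intron")
  # exact 150/150 tie intron/UTR3 -> UTR3 by precedence
  expect_equal(classify_position(gr("chr1", 3851, 4150, "+"), fs), "UTR3")
  fs2 <- derive_features(make_tx(exons = gr("chr1", c(101, 301), c(200, 400), "+"),
                                 cds_span = gr("chr1", 101, 300, "+")),
                         gene_interval = gr("chr1", 1, 500, "+"))
  # 50 bp intron vs 50 bp UTR3 -> UTR3 wins the tie
  expect_equal(classify_position(gr("chr1", 251, 350, "+"), fs2), "UTR3")
})

test_that("classify_position handles repeats outside the reference span", {
  fs <- feature_fixture("+")
  expect_equal(classify_position(gr("chr1", 5700, 5900, "+"), fs), "Intron")
  fs_nogene <- derive_features(make_tx(exons = gr("chr1", 101, 400, "+")))
  expect_error(classify_position(gr("chr1", 9000, 9300, "+"), fs_nogene),
               "no overlap")
})

test_that("orientation is Sense iff strands match", {
  expect_equal(call_orientation("+", "+"), "Sense")
  expect_equal(call_orientation("-", "+"), "Inverted")
  expect_equal(call_orientation("-", "-"), "Sense")
  expect_error(call_orientation("*", "+"), "stranded")
})

test_that("link_tss applies the strict upstream window and 5'-part rule", {
  alu <- gr("chr1", 10001, 10300, "+")
  # 300 nt upstream on the gene strand
  res <- link_tss(alu, "+", gr("chr1", 9701, 9701, "+"), window = 1000)
  expect_equal(res$flag, "upstream")
  expect_equal(res$distance, 300L)
  # exactly 1000 nt -> not linked (strict <1000)
  expect_equal(link_tss(alu, "+", gr("chr1", 9001, 9001, "+"))$flag, "none")
  expect_equal(link_tss(alu, "+", gr("chr1", 9002, 9002, "+"))$flag,
               "upstream")
  # TSS at 40% into the span -> internal_5prime; at 60% -> none
  expect_equal(link_tss(alu, "+", gr("chr1", 10121, 10121, "+"))$flag,
               "internal_5prime")
  expect_equal(link_tss(alu, "+", gr("chr1", 10181, 10181, "+"))$flag,
               "none")
  # strand matching: opposite-strand TSS ignored, unstranded accepted
  expect_equal(link_tss(alu, "+", gr("chr1", 9701, 9701, "-"))$flag, "none")
  expect_equal(link_tss(alu, "+", gr("chr1", 9701, 9701, "*"))$flag,
               "upstream")
  # upstream takes precedence and the smallest distance is reported
  both <- link_tss(alu, "+", gr("chr1", c(9701, 9901, 10121),
                                c(9701, 9901, 10121), "+"))
  expect_equal(both$flag, "upstream")
  expect_equal(both$distance, 100L)
})

test_that("link_tss is invariant under translation and strand mirroring", {
  set.seed(53)
  for (i in 1:20) {
    s <- sample.int(100000, 1) + 2000
    alu <- gr("chr1", s, s + 299, "+")
    tpos <- s + sample(-1500:400, 1)
    res <- link_tss(alu, "+", gr("chr1", tpos, tpos, "+"))
    # translation by a constant
    k <- sample.int(10000, 1)
    res_t <- link_tss(gr("chr1", s + k, s + 299 + k, "+"), "+",
                      gr("chr1", tpos + k, tpos + k, "+"))
    expect_equal(res_t, res)
    # mirror through a large coordinate M: minus-strand gene
    M <- 500000
    alu_m <- gr("chr1", M - (s + 299), M - s, "-")
    tss_m <- gr("chr1", M - tpos, M - tpos, "-")
    res_m <- link_tss(alu_m, "-", tss_m)
    expect_equal(res_m, res)
  }
})

test_that("discover_insertions is total over reported pairs", {
  sim <- simulate_annotation(8, seed = 99)
  genes <- build_gene_models(read_gtf(sim$genes_gtf, "ensembl"))
  catalog <- build_catalog(read_bed(sim$repeats_bed))
  tss <- read_bed(sim$tss_bed)
  ins <- discover_insertions(genes, catalog, tss)
  expect_equal(nrow(ins), nrow(sim$truth))
  expect_true(all(ins$position %in% c("Intron", "UTR5", "UTR3", "CDS_exon")))
  counts <- table(factor(ins$position,
                         c("Intron", "UTR5", "UTR3", "CDS_exon")))
  expect_equal(sum(counts), nrow(ins))
})
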