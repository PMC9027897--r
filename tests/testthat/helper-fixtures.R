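# Small in-code fixtures and independent oracles shared across test files.

gr <- function(chrom, start, end, strand = "*", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand,
                         ...)
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A two-gene Ensembl-style GTF: GENE_A (+, coding, 2 tx) and GENE_B (-, coding)
ensembl_gtf_lines <- function() {
  a <- "gene_id \"GA\"; transcript_id \"%s\"; gene_name \"GENE_A\";"
  b <- "gene_id \"GB\"; transcript_id \"TB1\"; gene_name \"GENE_B\";"
  c(
    sprintf("chr1\ttest\texon\t101\t400\t.\t+\t.\t%s", sprintf(a, "TA1")),
    sprintf("chr1\ttest\texon\t601\t900\t.\t+\t.\t%s", sprintf(a, "TA1")),
    sprintf("chr1\ttest\tCDS\t151\t350\t.\t+\t0\t%s", sprintf(a, "TA1")),
    sprintf("chr1\ttest\tCDS\t601\t700\t.\t+\t0\t%s", sprintf(a, "TA1")),
    sprintf("chr1\ttest\texon\t101\t500\t.\t+\t.\t%s", sprintf(a, "TA2")),
    sprintf("chr2\ttest\texon\t1001\t1400\t.\t-\t.\t%s", b),
    sprintf("chr2\ttest\tCDS\t1151\t1350\t.\t-\t0\t%s", b)
  )
}

# transcript-model constructor matching the gene_features contracts
make_tx <- function(id = "T1", gene_id = "G1", strand = "+",
                    exons, cds_span = NULL) {
  list(id = id, gene_id = gene_id, strand = strand, exons = exons,
       cds_span = cds_span)
}

make_gene <- function(id = "G1", symbol = id, strand = "+", txs) {
  all_ex <- do.call(c, unname(lapply(txs, `[[`, "exons")))
  interval <- range(all_ex, ignore.strand = TRUE)
  GenomicRanges::strand(interval) <- strand
  structure(list(id = id, symbol = symbol, interval = interval,
                 strand = strand,
                 transcripts = stats::setNames(txs, vapply(txs, `[[`, "", "id"))),
            class = "gene_model")
}

# brute-force fractional-overlap intersection oracle (all-pairs scan)
brute_intersect <- function(gene_df, alu_df, frac) {
  out <- list()
  for (i in seq_len(nrow(gene_df))) {
    for (j in seq_len(nrow(alu_df))) {
      if (gene_df$chrom[i] != alu_df$chrom[j]) next
      ov <- min(gene_df$end[i], alu_df$end[j]) -
        max(gene_df$start[i], alu_df$start[j]) + 1L
      glen <- gene_df$end[i] - gene_df$start[i] + 1L
      if (ov >= ceiling(frac * glen)) {
        out[[length(out) + 1L]] <- c(i, j, ov)
      }
    }
  }
  if (length(out) == 0L) {
    return(matrix(integer(0), ncol = 3L))
  }
  do.call(rbind, out)
}

# textbook step-up FDR oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# SAM text with a header over chr1/chr2 plus the supplied alignment lines
sam_file <- function(records) {
  write_tmp(c("@HD\tVN:1.6\tSO:unsorted",
              "@SQ\tSN:chr1\tLN:100000",
              "@SQ\tSN:chr2\tLN:100000",
              records), ext = ".sam")
}

sam_line <- function(qname, flag, chrom, pos, cigar, rnext = "*", pnext = 0) {
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t0\t*\t*",
          qname, flag, chrom, pos, cigar, rnext, pnext)
}
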