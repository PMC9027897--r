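#' Run the full candidate-discovery pipeline
#'
#' End-to-end driver: read annotation and repeat/TSS tracks, restrict to the
#' immune-gene list, discover and classify insertions, count fragments (or
#' take a pre-computed count matrix), normalize, apply the filter cascade
#' (minimum expression, then robust expression + fold change), test
#' differential expression between healthy and inflammation, and assemble
#' the candidate table with its summary.
#'
#' @param gene_gtf Path to Ensembl-dialect gene annotation (GTF).
#' @param repeat_path Path to the repeat track.
#' @param repeat_format `"bed"` or `"gtf"` (RepeatMasker dialect).
#' @param tss_bed Optional path to a BED of CAGE TSS positions.
#' @param symbols Optional path to an immune-gene symbol list; `NULL` keeps
#'   every gene.
#' @param sample_sheet Data.frame from [read_sample_sheet()] (needs a `path`
#'   column with SAM files unless `counts` is supplied).
#' @param counts Optional pre-computed count matrix (rows = insertion ids as
#'   locus strings, columns = samples in the sample sheet).
#' @param config A [pipeline_config()].
#' @return A list with `insertions`, `counts`, `size_factors`, `normalized`,
#'   `de` (over the minimum-expression survivors), `robust_ids`,
#'   `candidates`, `summary` and `cluster` (an `hclust` over samples, `NULL`
#'   when fewer than 2 samples).
#' @export
run_pipeline <- function(gene_gtf, repeat_path,
                         repeat_format = c("bed", "gtf"),
                         tss_bed = NULL, symbols = NULL,
                         sample_sheet, counts = NULL,
                         config = pipeline_config()) {
  repeat_format <- match.arg(repeat_format)

  ann <- read_gtf(gene_gtf, dialect = "ensembl")
  genes <- build_gene_models(ann)
  if (!is.null(symbols)) {
    genes <- restrict_to_symbols(genes, read_gene_symbols(symbols))
  }
  track <- if (repeat_format == "bed") read_bed(repeat_path) else {
    read_gtf(repeat_path, dialect = "repeatmasker")
  }
  catalog <- build_catalog(track)
  tss <- if (!is.null(tss_bed)) read_bed(tss_bed) else GenomicRanges::GRanges()

  insertions <- discover_insertions(genes, catalog, tss, config)
  candidates_geom <- insertions[insertions$position != "CDS_exon", , drop = FALSE]

  ins_gr <- GenomicRanges::GRanges(
    candidates_geom$chrom,
    IRanges::IRanges(candidates_geom$start, candidates_geom$end),
    strand = candidates_geom$alu_strand
  )
  names(ins_gr) <- candidates_geom$insertion_id

  if (is.null(counts)) {
    if (is.null(sample_sheet$path)) {
      stop("sample sheet needs a 'path' column when no count matrix is given")
    }
    counts <- build_count_matrix(
      stats::setNames(sample_sheet$path, sample_sheet$sample),
      ins_gr, strand_mode = config$strand_mode)
  } else {
    counts <- as.matrix(counts)[intersect(rownames(counts),
                                          candidates_geom$insertion_id),
                                sample_sheet$sample, drop = FALSE]
  }

  groups <- derive_binary_group(sample_sheet$condition)
  keep_min <- filter_min_expression(counts, min_count = config$min_count,
                                    min_samples = 1)
  expressed <- counts[keep_min, , drop = FALSE]

  sf <- size_factors(counts + 1L)  # pseudocount guards all-zero reference rows
  norm_all <- normalize_counts(counts, sf)
  norm <- norm_all[keep_min, , drop = FALSE]

  de <- run_de(norm, groups, pooled = config$pooled)
  keep_robust <- filter_robust(expressed, de$fold_change,
                               robust_count = config$robust_count,
                               fc_threshold = config$fc_threshold)
  sig <- call_significant(de, alpha = config$alpha)
  surviving <- intersect(names(keep_robust)[keep_robust], sig$insertion_id)

  cand_ins <- candidates_geom[candidates_geom$insertion_id %in% surviving, ,
                              drop = FALSE]
  candidates <- build_candidate_table(cand_ins, de)
  cl <- if (ncol(norm) >= 2L && nrow(norm) >= 1L) hierarchical_cluster(norm) else NULL

  list(insertions = insertions,
       counts = counts,
       size_factors = sf,
       normalized = norm_all,
       de = de,
       robust_ids = names(keep_robust)[keep_robust],
       candidates = candidates,
       summary = summarize_candidates(candidates),
       cluster = cl)
}
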