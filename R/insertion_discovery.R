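#' Pipeline configuration
#'
#' Collects every tunable threshold of the discovery and filtering pipeline.
#' Defaults reproduce the published analysis settings: a repeat must cover at
#' least 0.9% of its host gene's span to count as an insertion, candidate
#' expression filters at 400 (inclusive) and 1000 (strict) raw fragments,
#' fold-change threshold 1.3 (inclusive, either direction), adjusted-p
#' significance strictly below 0.001, and a 1000-nt (strict) upstream window
#' for CAGE TSS linkage with unstranded counting.
#'
#' @param min_gene_fraction Minimum overlap as a fraction of the gene span.
#' @param min_count Raw-fragment floor for the expression filter (inclusive).
#' @param robust_count Raw-fragment floor for the robust set (strict `>`).
#' @param fc_threshold Fold-change threshold (inclusive, either direction).
#' @param alpha Adjusted-p significance level (strict `<`).
#' @param tss_window Upstream TSS window in nucleotides (strict `<`).
#' @param strand_mode Fragment counting mode: `both`, `sense` or `antisense`.
#' @param fraction_of Apply `min_gene_fraction` to the `gene` span (default,
#'   mirroring `bedtools intersect -f` on the gene file) or to the `alu` span.
#' @param tss_half_fraction Fraction of the repeat span (from its 5' end in
#'   transcription direction) counted as the "5' part" for internal TSSs.
#' @param drop_window Window (nt) on each side of a TSS for the coverage-drop
#'   ratio.
#' @param drop_ratio Coverage ratio at or below which the drop flags an
#'   independent-transcript signature.
#' @param pooled Use a pooled-variance t-test instead of Welch.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_gene_fraction = 0.009,
                            min_count = 400,
                            robust_count = 1000,
                            fc_threshold = 1.3,
                            alpha = 0.001,
                            tss_window = 1000,
                            strand_mode = c("both", "sense", "antisense"),
                            fraction_of = c("gene", "alu"),
                            tss_half_fraction = 0.5,
                            drop_window = 200,
                            drop_ratio = 0.5,
                            pooled = FALSE) {
  strand_mode <- match.arg(strand_mode)
  fraction_of <- match.arg(fraction_of)
  stopifnot(min_gene_fraction > 0, min_gene_fraction <= 1,
            min_count > 0, robust_count > 0, fc_threshold > 0,
            alpha > 0, tss_window > 0,
            tss_half_fraction > 0, tss_half_fraction <= 1,
            drop_window > 0, drop_ratio > 0)
  structure(list(min_gene_fraction = min_gene_fraction,
                 min_count = min_count,
                 robust_count = robust_count,
                 fc_threshold = fc_threshold,
                 alpha = alpha,
                 tss_window = tss_window,
                 strand_mode = strand_mode,
                 fraction_of = fraction_of,
                 tss_half_fraction = tss_half_fraction,
                 drop_window = drop_window,
                 drop_ratio = drop_ratio,
                 pooled = pooled),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys keep their defaults. The effective
#' configuration is echoed via a message.
#'
#' @param path Path to a YAML file whose keys match [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  cfg <- do.call(pipeline_config, vals)
  message("pipeline config: ",
          paste(sprintf("%s=%s", names(cfg), unlist(cfg)), collapse = " "))
  cfg
}

#' Build a queryable interval index
#'
#' Wraps a nested containment list over the stored intervals; a query
#' returns every stored interval overlapping the query span by at least one
#' base.
#'
#' @param gr A `GRanges` of intervals to index.
#' @return An object of class `interval_index`.
#' @export
build_interval_index <- function(gr) {
  structure(list(gr = gr, nclist = GenomicRanges::GNCList(gr)),
            class = "interval_index")
}

#' Query an interval index
#'
#' @param index An `interval_index` from [build_interval_index()].
#' @param chrom Chromosome name.
#' @param start,end 1-based closed query coordinates.
#' @return Integer indices (into the stored `GRanges`) of all overlapping
#'   intervals.
#' @export
query_index <- function(index, chrom, start, end) {
  if (!chrom %in% GenomeInfoDb::seqlevels(index$gr)) return(integer(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, index$nclist, ignore.strand = TRUE)
  sort(S4Vectors::subjectHits(hits))
}

#' Intersect gene bodies with the Alu catalog
#'
#' Reports a (gene, repeat) pair whenever the overlap reaches
#' `ceiling(min_gene_fraction * gene length)` base pairs — the fractional
#' overlap is measured against the gene span, mirroring
#' `bedtools intersect -a genes -b alu -f`, which excludes short repeats in
#' very long genes. Set `fraction_of = "alu"` in the configuration to measure
#' the fraction against the repeat instead.
#'
#' @param genes List of gene models.
#' @param catalog Alu catalog `GRanges` from [build_catalog()].
#' @param min_gene_fraction Overlap fraction threshold (default 0.009).
#' @param fraction_of `"gene"` (default) or `"alu"`.
#' @return A data.frame with one row per reported pair: `gene_id`,
#'   `gene_symbol`, `alu_idx` (index into `catalog`), `subfamily`, `family`,
#'   `chrom`, `start`, `end`, `alu_strand`, `overlap_bp`.
#' @export
intersect_genes_alus <- function(genes, catalog, min_gene_fraction = 0.009,
                                 fraction_of = c("gene", "alu")) {
  fraction_of <- match.arg(fraction_of)
  if (length(genes) == 0L || length(catalog) == 0L) {
    return(data.frame(gene_id = character(0), gene_symbol = character(0),
                      alu_idx = integer(0), subfamily = character(0),
                      family = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      alu_strand = character(0), overlap_bp = integer(0)))
  }
  gene_gr <- GenomicRanges::GRanges(
    vapply(genes, function(g) as.character(GenomicRanges::seqnames(g$interval)), ""),
    IRanges::IRanges(
      vapply(genes, function(g) GenomicRanges::start(g$interval), 0L),
      vapply(genes, function(g) GenomicRanges::end(g$interval), 0L)
    )
  )
  hits <- GenomicRanges::findOverlaps(gene_gr, catalog, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- pmin(GenomicRanges::end(gene_gr)[q], GenomicRanges::end(catalog)[s]) -
    pmax(GenomicRanges::start(gene_gr)[q], GenomicRanges::start(catalog)[s]) + 1L
  ref_len <- if (fraction_of == "gene") {
    GenomicRanges::width(gene_gr)[q]
  } else {
    GenomicRanges::width(catalog)[s]
  }
  keep <- ov >= ceiling(min_gene_fraction * ref_len)
  q <- q[keep]; s <- s[keep]; ov <- ov[keep]
  data.frame(
    gene_id = vapply(genes, `[[`, "", "id")[q],
    gene_symbol = vapply(genes, `[[`, "", "symbol")[q],
    alu_idx = s,
    subfamily = as.character(catalog$subfamily)[s],
    family = as.character(catalog$family)[s],
    chrom = as.character(GenomicRanges::seqnames(catalog))[s],
    start = GenomicRanges::start(catalog)[s],
    end = GenomicRanges::end(catalog)[s],
    alu_strand = as.character(GenomicRanges::strand(catalog))[s],
    overlap_bp = as.integer(ov),
    stringsAsFactors = FALSE
  )
}

#' Classify an insertion's position within its host gene
#'
#' The label is the feature class (intron, 5'UTR, 3'UTR, coding exon) with
#' the largest base-pair overlap with the repeat; ties are broken by the
#' precedence UTR3 > UTR5 > CDS_exon > Intron. A repeat outside the reference
#' transcript's span but inside the gene interval is labelled `Intron`;
#' a repeat outside the gene interval is an error.
#'
#' @param repeat_gr A `GRanges` of length 1 (the repeat).
#' @param features A `feature_set` from [gene_feature_set()].
#' @return One of `"Intron"`, `"UTR5"`, `"UTR3"`, `"CDS_exon"`.
#' @export
classify_position <- function(repeat_gr, features) {
  stopifnot(length(repeat_gr) == 1L)
  ov_bp <- function(gr) {
    if (length(gr) == 0L) return(0L)
    sum(GenomicRanges::width(GenomicRanges::intersect(
      GenomicRanges::granges(repeat_gr), gr, ignore.strand = TRUE)))
  }
  # precedence order: first maximum wins
  ov <- c(UTR3 = ov_bp(features$utr3),
          UTR5 = ov_bp(features$utr5),
          CDS_exon = ov_bp(features$cds_exons),
          Intron = ov_bp(features$introns))
  if (all(ov == 0L)) {
    gi <- features$gene_interval
    inside <- !is.null(gi) && length(GenomicRanges::findOverlaps(
      GenomicRanges::granges(repeat_gr), GenomicRanges::granges(gi),
      ignore.strand = TRUE)) > 0L
    if (inside) return("Intron")
    stop("repeat ", locus_string(repeat_gr),
         " has no overlap with gene features or gene interval")
  }
  names(ov)[which.max(ov)]
}

#' Call the orientation of a repeat relative to its host gene
#'
#' @param repeat_strand Repeat strand, `"+"` or `"-"`.
#' @param gene_strand Gene strand, `"+"` or `"-"`.
#' @return `"Sense"` if the strands match, `"Inverted"` otherwise.
#' @export
call_orientation <- function(repeat_strand, gene_strand) {
  if (!all(c(repeat_strand, gene_strand) %in% c("+", "-"))) {
    stop("orientation requires stranded repeat and gene (+/-)")
  }
  ifelse(repeat_strand == gene_strand, "Sense", "Inverted")
}

#' Link a CAGE TSS to a repeat
#'
#' A TSS on the host gene's strand (or unstranded) qualifies as `upstream`
#' when it lies strictly within `window` nucleotides 5' of the repeat's
#' transcription-direction start (distance of at least 1, strictly less than
#' `window`), and as `internal_5prime` when it falls in the 5' part of the
#' repeat span (first `half_fraction` of the element in transcription
#' direction). `upstream` takes precedence; the reported distance is the
#' smallest qualifying one.
#'
#' @param repeat_gr `GRanges` of length 1.
#' @param gene_strand Host gene strand (`"+"` or `"-"`); transcription
#'   direction of the embedded element.
#' @param tss `GRanges` of TSS positions (width-1; strand `"*"` matches
#'   either).
#' @param window Upstream window in nucleotides (strict `<`; default 1000).
#' @param half_fraction 5'-part fraction of the repeat span (default 0.5).
#' @return A list with `flag` (`"none"`, `"upstream"` or `"internal_5prime"`)
#'   and `distance` (nt from TSS to the repeat 5' end, `NA` unless upstream).
#' @export
link_tss <- function(repeat_gr, gene_strand, tss, window = 1000,
                     half_fraction = 0.5) {
  stopifnot(length(repeat_gr) == 1L, gene_strand %in% c("+", "-"))
  chrom <- as.character(GenomicRanges::seqnames(repeat_gr))
  tss <- tss[as.character(GenomicRanges::seqnames(tss)) == chrom]
  ts <- as.character(GenomicRanges::strand(tss))
  tss <- tss[ts == gene_strand | ts == "*"]
  if (length(tss) == 0L) return(list(flag = "none", distance = NA_integer_))
  pos <- GenomicRanges::start(tss)
  rs <- GenomicRanges::start(repeat_gr)
  re <- GenomicRanges::end(repeat_gr)
  w <- GenomicRanges::width(repeat_gr)
  if (gene_strand == "+") {
    alu5 <- rs
    dist <- alu5 - pos
    offset <- pos - rs
  } else {
    alu5 <- re
    dist <- pos - alu5
    offset <- re - pos
  }
  up <- dist >= 1 & dist < window
  if (any(up)) {
    return(list(flag = "upstream", distance = as.integer(min(dist[up]))))
  }
  internal <- offset >= 0 & offset < w & offset < half_fraction * w
  if (any(internal)) {
    return(list(flag = "internal_5prime", distance = NA_integer_))
  }
  list(flag = "none", distance = NA_integer_)
}

#' Discover and classify Alu insertions in a gene set
#'
#' Runs the intersection, position classification, orientation call and TSS
#' linkage for every reported (gene, repeat) pair. All pairs are returned,
#' including coding-exon overlaps; downstream candidate assembly excludes
#' `CDS_exon` rows.
#'
#' @param genes List of gene models (e.g. after [restrict_to_symbols()]).
#' @param catalog Alu catalog `GRanges`.
#' @param tss `GRanges` of CAGE TSS positions (may be empty).
#' @param config A [pipeline_config()].
#' @return A data.frame of insertions: `insertion_id` (locus string),
#'   `gene_id`, `gene_symbol`, `chrom`, `start`, `end`, `alu_strand`,
#'   `gene_strand`, `subfamily`, `family`, `position`, `orientation`,
#'   `tss_flag`, `tss_distance`, `overlap_bp`.
#' @export
discover_insertions <- function(genes, catalog, tss = GenomicRanges::GRanges(),
                                config = pipeline_config()) {
  pairs <- intersect_genes_alus(genes, catalog,
                                min_gene_fraction = config$min_gene_fraction,
                                fraction_of = config$fraction_of)
  n <- nrow(pairs)
  position <- character(n)
  orientation <- character(n)
  tss_flag <- character(n)
  tss_distance <- rep(NA_integer_, n)
  gene_strand <- character(n)
  fs_cache <- list()
  for (i in seq_len(n)) {
    gid <- pairs$gene_id[i]
    if (is.null(fs_cache[[gid]])) fs_cache[[gid]] <- gene_feature_set(genes[[gid]])
    fs <- fs_cache[[gid]]
    rep_gr <- GenomicRanges::GRanges(
      pairs$chrom[i], IRanges::IRanges(pairs$start[i], pairs$end[i]),
      strand = pairs$alu_strand[i])
    gene_strand[i] <- genes[[gid]]$strand
    position[i] <- classify_position(rep_gr, fs)
    orientation[i] <- call_orientation(pairs$alu_strand[i], gene_strand[i])
    lt <- link_tss(rep_gr, gene_strand[i], tss,
                   window = config$tss_window,
                   half_fraction = config$tss_half_fraction)
    tss_flag[i] <- lt$flag
    tss_distance[i] <- lt$distance
  }
  out <- data.frame(
    insertion_id = sprintf("%s:%d-%d", pairs$chrom, pairs$start, pairs$end),
    pairs[, c("gene_id", "gene_symbol", "chrom", "start", "end",
              "alu_strand")],
    gene_strand = gene_strand,
    pairs[, c("subfamily", "family")],
    position = position,
    orientation = orientation,
    tss_flag = tss_flag,
    tss_distance = tss_distance,
    overlap_bp = pairs$overlap_bp,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write an insertion table as TSV
#'
#' @param insertions Data.frame from [discover_insertions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_insertions <- function(insertions, path) {
  utils::write.table(insertions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
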