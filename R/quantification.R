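#' Count aligned fragments over insertion intervals
#'
#' A fragment increments every insertion interval its span overlaps by at
#' least one base, so a fragment spanning two adjacent insertions counts once
#' for each. `strand_mode = "both"` ignores strand; `"sense"` requires the
#' fragment strand to match the insertion strand, `"antisense"` to oppose it.
#'
#' @param fragments `GRanges` of fragments from [read_alignments()].
#' @param insertions `GRanges` of insertion intervals (stranded for the
#'   sense/antisense modes).
#' @param strand_mode One of `"both"`, `"sense"`, `"antisense"`.
#' @return Integer vector of counts, one per insertion (named after
#'   `names(insertions)` when set).
#' @export
count_fragments <- function(fragments, insertions,
                            strand_mode = c("both", "sense", "antisense")) {
  strand_mode <- match.arg(strand_mode)
  frags <- switch(strand_mode,
                  both = fragments,
                  sense = fragments,
                  antisense = GenomicRanges::invertStrand(fragments))
  counts <- GenomicRanges::countOverlaps(insertions, frags,
                                         ignore.strand = strand_mode == "both")
  stats::setNames(as.integer(counts), names(insertions))
}

#' Build a count matrix from per-sample alignments
#'
#' @param sam_paths Named character vector of SAM file paths (names become
#'   column ids).
#' @param insertions `GRanges` of insertion intervals; `names(insertions)`
#'   (or locus strings) become row ids.
#' @param strand_mode Counting mode, see [count_fragments()].
#' @return Integer matrix (insertions x samples).
#' @export
build_count_matrix <- function(sam_paths, insertions,
                               strand_mode = c("both", "sense", "antisense")) {
  strand_mode <- match.arg(strand_mode)
  if (is.null(names(sam_paths)) || any(!nzchar(names(sam_paths)))) {
    stop("sam_paths must be a named vector of sample id -> path")
  }
  ids <- if (!is.null(names(insertions))) names(insertions) else locus_string(insertions)
  if (anyDuplicated(ids)) stop("duplicate insertion ids")
  mat <- vapply(sam_paths, function(p) {
    count_fragments(read_alignments(p), insertions, strand_mode)
  }, integer(length(insertions)))
  mat <- matrix(mat, nrow = length(insertions),
                dimnames = list(ids, names(sam_paths)))
  storage.mode(mat) <- "integer"
  mat
}

#' Median-of-ratios size factors
#'
#' For each row with a positive geometric mean `g_i`, the per-sample factor
#' is `median_i(c_ij / g_i)`. Rows containing a zero are excluded from the
#' reference set, as in the standard median-of-ratios estimator.
#'
#' @param mat Count matrix (rows = insertions, columns = samples).
#' @return Positive numeric vector of per-sample factors.
#' @export
size_factors <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("counts must be non-negative")
  log_gm <- rowMeans(log(mat))
  use <- is.finite(log_gm)
  if (!any(use)) {
    stop("no row with a positive geometric mean; consider adding a pseudocount")
  }
  ref <- exp(log_gm[use])
  sf <- apply(mat[use, , drop = FALSE], 2L, function(col) {
    stats::median(col / ref)
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("degenerate size factor; consider adding a pseudocount")
  }
  sf
}

#' Normalize a count matrix by per-sample factors
#'
#' @param mat Count matrix.
#' @param factors Positive per-sample factors (e.g. from [size_factors()]).
#' @return Numeric matrix `mat[, j] / factors[j]`.
#' @export
normalize_counts <- function(mat, factors = size_factors(mat)) {
  stopifnot(length(factors) == ncol(mat), all(factors > 0))
  sweep(as.matrix(mat), 2L, factors, "/")
}

#' Minimum-expression filter
#'
#' Keeps rows with at least `min_samples` entries greater than or equal to
#' `min_count` ("a coverage of at least 400 in one or more participants" at
#' the defaults — the 400 boundary is inclusive).
#'
#' @param mat Raw count matrix.
#' @param min_count Inclusive count floor (default 400).
#' @param min_samples Number of samples that must reach the floor (default 1).
#' @return Named logical vector over rows.
#' @export
filter_min_expression <- function(mat, min_count = 400, min_samples = 1) {
  keep <- rowSums(as.matrix(mat) >= min_count) >= min_samples
  if (!any(keep)) warning("minimum-expression filter removed every row")
  keep
}

#' Per-row fold changes between the binary groups
#'
#' Fold change is direction-free: `max(m_i/m_h, m_h/m_i)` on group means of
#' normalized values with a pseudocount, with the direction recorded
#' separately (`up_in`).
#'
#' @param norm_mat Normalized matrix.
#' @param groups Factor/character vector over columns with values `healthy` /
#'   `inflammation` (see [derive_binary_group()]).
#' @param pseudocount Added to group means before forming the ratio
#'   (default 1).
#' @return Data.frame with `fold_change` (>= 1) and `up_in`.
#' @export
fold_changes <- function(norm_mat, groups, pseudocount = 1) {
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(norm_mat),
            all(groups %in% c("healthy", "inflammation")))
  mh <- rowMeans(norm_mat[, groups == "healthy", drop = FALSE]) + pseudocount
  mi <- rowMeans(norm_mat[, groups == "inflammation", drop = FALSE]) + pseudocount
  data.frame(
    fold_change = pmax(mi / mh, mh / mi),
    up_in = ifelse(mi >= mh, "inflammation", "healthy"),
    row.names = rownames(norm_mat),
    stringsAsFactors = FALSE
  )
}

#' Robust-candidate filter
#'
#' Keeps rows with a raw count strictly above `robust_count` in at least one
#' sample ("more than 1000 raw reads") and a fold change at or above
#' `fc_threshold` (1.3 at the default, either direction).
#'
#' @param mat Raw count matrix.
#' @param fc Numeric vector of per-row fold changes (aligned with rows).
#' @param robust_count Strict raw-count floor (default 1000).
#' @param fc_threshold Inclusive fold-change threshold (default 1.3).
#' @return Named logical vector over rows.
#' @export
filter_robust <- function(mat, fc, robust_count = 1000, fc_threshold = 1.3) {
  stopifnot(length(fc) == nrow(mat))
  maxc <- apply(as.matrix(mat), 1L, max)
  keep <- maxc > robust_count & fc >= fc_threshold
  stats::setNames(keep, rownames(mat))
}

#' Read-coverage drop across a putative TSS
#'
#' Quantifies the drop in read alignment at a TSS inside a gene body: the
#' mean per-base fragment coverage in the window immediately 5' of the TSS
#' (transcription direction) divided by the mean coverage immediately 3' of
#' it. A ratio at or below the configured threshold (default 0.5) is the
#' signature of a transcript initiating at the TSS independently of the host
#' mRNA. With zero downstream coverage the ratio is `Inf` ("no signal").
#'
#' @param fragments `GRanges` of aligned fragments.
#' @param tss_pos 1-based TSS position.
#' @param chrom Chromosome of the TSS.
#' @param gene_strand Transcription direction (`"+"` or `"-"`).
#' @param window Window size in nt on each side (default 200).
#' @return The upstream/downstream mean coverage ratio.
#' @export
tss_coverage_drop <- function(fragments, tss_pos, chrom, gene_strand,
                              window = 200) {
  stopifnot(window > 0, gene_strand %in% c("+", "-"))
  frags <- fragments[as.character(GenomicRanges::seqnames(fragments)) == chrom]
  mean_cov <- function(lo, hi) {
    lo <- max(lo, 1L)
    if (hi < lo || length(frags) == 0L) return(0)
    win <- GenomicRanges::GRanges(chrom, IRanges::IRanges(lo, hi))
    hits <- GenomicRanges::findOverlaps(win, frags, ignore.strand = TRUE)
    if (length(hits) == 0L) return(0)
    f <- frags[S4Vectors::subjectHits(hits)]
    covered <- pmin(GenomicRanges::end(f), hi) -
      pmax(GenomicRanges::start(f), lo) + 1L
    sum(covered) / (hi - lo + 1L)
  }
  if (gene_strand == "+") {
    up <- mean_cov(tss_pos - window, tss_pos - 1L)
    down <- mean_cov(tss_pos, tss_pos + window - 1L)
  } else {
    up <- mean_cov(tss_pos + 1L, tss_pos + window)
    down <- mean_cov(tss_pos - window + 1L, tss_pos)
  }
  if (down == 0) return(Inf)
  up / down
}

#' Write / read a count matrix as TSV
#'
#' @param mat Count matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(insertion_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  storage.mode(mat) <- "integer"
  mat
}
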