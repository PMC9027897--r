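#' Two-sided two-sample t-test p-value
#'
#' Welch's unequal-variance test by default (appropriate for unequal group
#' sizes and heteroscedastic normalized counts); `pooled = TRUE` switches to
#' the classical pooled-variance test.
#'
#' @param values Numeric vector of per-sample values.
#' @param groups Binary labels over `values` (factor or character, exactly
#'   two levels).
#' @param pooled Use pooled variance instead of Welch (default `FALSE`).
#' @return Two-sided p-value.
#' @export
welch_ttest <- function(values, groups, pooled = FALSE) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("groups must have exactly two levels")
  x <- values[groups == lv[1L]]
  y <- values[groups == lv[2L]]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 samples")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("zero variance in both groups")
  }
  stats::t.test(x, y, var.equal = pooled)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * n / j`, capped at 1
#' and mapped back to input order.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential expression over the binary grouping
#'
#' Runs the per-row two-sided t-test on normalized values between the
#' healthy and inflammation groups, computes direction-free fold changes and
#' applies the Benjamini-Hochberg correction.
#'
#' @param norm_mat Normalized matrix (rows = insertions).
#' @param groups `healthy` / `inflammation` labels over columns.
#' @param pooled Pooled-variance t-test instead of Welch.
#' @param pseudocount Pseudocount for the fold change (default 1).
#' @return Data.frame with `insertion_id`, `fold_change`, `up_in`, `p`,
#'   `p_adj`.
#' @export
run_de <- function(norm_mat, groups, pooled = FALSE, pseudocount = 1) {
  groups <- as.character(groups)
  fc <- fold_changes(norm_mat, groups, pseudocount = pseudocount)
  p <- apply(norm_mat, 1L, function(v) welch_ttest(v, groups, pooled = pooled))
  data.frame(
    insertion_id = rownames(norm_mat),
    fold_change = fc$fold_change,
    up_in = fc$up_in,
    p = p,
    p_adj = bh_adjust(p),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Select significant differential-expression results
#'
#' Significance is strict: `p_adj < alpha` (an adjusted p exactly equal to
#' alpha is excluded).
#'
#' @param results Data.frame with a `p_adj` column (see [run_de()]).
#' @param alpha Significance level (default 0.001).
#' @return The significant subset of `results`.
#' @export
call_significant <- function(results, alpha = 0.001) {
  stopifnot("p_adj" %in% names(results))
  results[results$p_adj < alpha, , drop = FALSE]
}

#' Hierarchical clustering of samples (Ward on Euclidean)
#'
#' Agglomerative clustering of the sample columns with Euclidean distances
#' and Ward's linkage (`hclust` method `ward.D2`, Ward's criterion on the
#' original distance scale). Deterministic given the input column order.
#'
#' @param norm_mat Normalized matrix (columns = samples).
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(norm_mat) {
  if (ncol(norm_mat) < 2L) stop("clustering requires at least 2 samples")
  stats::hclust(stats::dist(t(norm_mat), method = "euclidean"),
                method = "ward.D2")
}

#' Condition separation at the root of a dendrogram
#'
#' Cuts the dendrogram into its two root branches and scores the
#' best-matching accuracy between branch membership and the binary condition
#' labels. 1.0 means the two conditions form separate branches exactly; the
#' best-match maximum over the two label assignments bounds the score below
#' at 0.5 for balanced labels.
#'
#' @param hc An `hclust` object over samples.
#' @param labels Binary condition labels in the order of the clustered
#'   samples.
#' @return Fraction in \[0, 1\].
#' @export
separation_score <- function(hc, labels) {
  k2 <- stats::cutree(hc, k = 2L)
  labels <- as.character(labels)
  stopifnot(length(labels) == length(k2))
  lv <- unique(labels)
  if (length(lv) != 2L) stop("labels must have exactly two levels")
  acc <- mean((k2 == 1L) == (labels == lv[1L]))
  max(acc, 1 - acc)
}

#' Export a dendrogram as Newick
#'
#' @param hc An `hclust` object (leaf labels become tip names).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write differential-expression results as TSV
#'
#' @param results Data.frame from [run_de()].
#' @param path Output path.
#' @param alpha Significance level used for the `significant` flag.
#' @return `path`, invisibly.
#' @export
write_de_results <- function(results, path, alpha = 0.001) {
  results$significant <- results$p_adj < alpha
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
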