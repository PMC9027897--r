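#' Assemble the candidate table
#'
#' One record per insertion surviving the robust filter and the significance
#' call, joining the classification columns with the differential-expression
#' result. Rows are sorted by (chromosome lexicographic, start) — the order
#' the published candidate tables use; set `karyotype_sort = TRUE` for the
#' natural chr1..chr22,chrX order instead.
#'
#' @param insertions Insertion data.frame (see [discover_insertions()]);
#'   `CDS_exon` rows are excluded from candidates.
#' @param de Differential-expression results (see [run_de()]), restricted to
#'   the surviving insertions. Every insertion must have a DE row.
#' @param karyotype_sort Use natural chromosome order (default `FALSE`).
#' @return A candidate data.frame with columns `gene_symbol`, `subfamily`,
#'   `locus`, `position`, `tss`, `orientation`, `p_value`.
#' @export
build_candidate_table <- function(insertions, de, karyotype_sort = FALSE) {
  insertions <- insertions[insertions$position != "CDS_exon", , drop = FALSE]
  idx <- match(insertions$insertion_id, de$insertion_id)
  if (anyNA(idx)) {
    stop("insertion(s) without a differential-expression result: ",
         paste(utils::head(insertions$insertion_id[is.na(idx)], 3L),
               collapse = ", "))
  }
  tss <- c(none = "no", upstream = "yes",
           internal_5prime = "yes_5prime")[insertions$tss_flag]
  out <- data.frame(
    gene_symbol = insertions$gene_symbol,
    subfamily = insertions$subfamily,
    locus = insertions$insertion_id,
    position = insertions$position,
    tss = unname(tss),
    orientation = insertions$orientation,
    p_value = de$p_adj[idx],
    stringsAsFactors = FALSE
  )
  chrom <- insertions$chrom
  key <- if (karyotype_sort) {
    num <- suppressWarnings(as.integer(sub("^chr", "", chrom)))
    order(is.na(num), num, sub("^chr", "", chrom), insertions$start)
  } else {
    order(chrom, insertions$start)
  }
  out <- out[key, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# token maps between internal labels and the display dialect used in
# published candidate tables
.position_tokens <- c(
  "Intron" = "Intron", "intron" = "Intron",
  "3'UTR" = "UTR3", "3′UTR" = "UTR3", "3’UTR" = "UTR3",
  "UTR3" = "UTR3",
  "5'UTR" = "UTR5", "5′UTR" = "UTR5", "5’UTR" = "UTR5",
  "UTR5" = "UTR5"
)
.position_display <- c(Intron = "Intron", UTR3 = "3'UTR", UTR5 = "5'UTR")
.tss_tokens <- c(
  "no" = "no", "yes" = "yes",
  "yes ^1" = "yes_5prime", "yes^1" = "yes_5prime", "yes 1" = "yes_5prime",
  "yes ¹" = "yes_5prime", "yes¹" = "yes_5prime",
  "yes_5prime" = "yes_5prime"
)

#' Read a candidate table from TSV
#'
#' Accepts both the internal snake_case header and the display header of
#' published tables ("Gene Name", "Alu Subfamily", "Genomic Location",
#' "Position in Gene", "TSS", "Alu Orientation", "p-Value"). Position and
#' TSS tokens are normalised (`3'UTR` with any apostrophe/prime variant;
#' footnote-marked `yes ^1` maps to `yes_5prime`); scientific-notation
#' p-values are accepted. Unknown tokens raise a parse error naming the
#' line.
#'
#' @param path Path to the TSV file (7 columns, header required).
#' @return Candidate data.frame (see [build_candidate_table()]).
#' @export
read_candidate_table <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("candidate table has no header: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields[[1L]]) != 7L) {
    stop("candidate table header must have 7 columns")
  }
  rows <- fields[-1L]
  bad <- which(lengths(rows) != 7L)
  if (length(bad) > 0L) {
    stop("candidate table parse error at line ", bad[1L] + 1L,
         ": expected 7 fields")
  }
  get <- function(i) vapply(rows, `[[`, "", i)
  pos_raw <- trimws(get(4L))
  pos <- .position_tokens[pos_raw]
  if (anyNA(pos)) {
    stop("candidate table parse error at line ",
         which(is.na(pos))[1L] + 1L, ": unknown position token '",
         pos_raw[which(is.na(pos))[1L]], "'")
  }
  tss_raw <- trimws(get(5L))
  tss <- .tss_tokens[tss_raw]
  if (anyNA(tss)) {
    stop("candidate table parse error at line ",
         which(is.na(tss))[1L] + 1L, ": unknown TSS token '",
         tss_raw[which(is.na(tss))[1L]], "'")
  }
  ori <- trimws(get(6L))
  if (!all(ori %in% c("Sense", "Inverted"))) {
    stop("candidate table parse error at line ",
         which(!(ori %in% c("Sense", "Inverted")))[1L] + 1L,
         ": unknown orientation token")
  }
  p <- suppressWarnings(as.numeric(get(7L)))
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("candidate table parse error: p-values must be numeric in (0, 1]")
  }
  # validate loci parse
  loci <- get(3L)
  for (i in seq_along(loci)) parse_locus(loci[i])
  data.frame(
    gene_symbol = get(1L),
    subfamily = get(2L),
    locus = loci,
    position = unname(pos),
    tss = unname(tss),
    orientation = ori,
    p_value = p,
    stringsAsFactors = FALSE
  )
}

#' Write a candidate table as TSV
#'
#' Positions are written in the display dialect (`3'UTR`, `5'UTR`, `Intron`);
#' [read_candidate_table()] round-trips the file exactly.
#'
#' @param records Candidate data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(records, path) {
  lines <- c(
    paste(c("gene_symbol", "subfamily", "locus", "position", "tss",
            "orientation", "p_value"), collapse = "\t"),
    sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%.15g",
            records$gene_symbol, records$subfamily, records$locus,
            .position_display[records$position], records$tss,
            records$orientation, records$p_value)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Summarize a candidate table
#'
#' Tallies rows, distinct genes, positions, Alu families, orientations and
#' TSS associations, plus the largest p-value.
#'
#' @param records Candidate data.frame (see [read_candidate_table()]).
#' @return A list of class `candidate_summary` with `n_rows`, `n_genes`,
#'   `by_position`, `by_family`, `by_orientation`, `n_tss`, `n_tss_intron`,
#'   `n_tss_utr3`, `max_p`.
#' @export
summarize_candidates <- function(records) {
  pos_levels <- c("Intron", "UTR3", "UTR5")
  by_position <- vapply(pos_levels, function(p) sum(records$position == p), 0L)
  fams <- if (nrow(records)) alu_family(records$subfamily) else character(0)
  fam_levels <- c("AluJ", "AluS", "AluY")
  by_family <- vapply(fam_levels, function(f) sum(fams == f), 0L)
  ori_levels <- c("Sense", "Inverted")
  by_orientation <- vapply(ori_levels, function(o) sum(records$orientation == o), 0L)
  tss_pos <- records$tss != "no"
  structure(list(
    n_rows = nrow(records),
    n_genes = length(unique(records$gene_symbol)),
    by_position = by_position,
    by_family = by_family,
    by_orientation = by_orientation,
    n_tss = sum(tss_pos),
    n_tss_intron = sum(tss_pos & records$position == "Intron"),
    n_tss_utr3 = sum(tss_pos & records$position == "UTR3"),
    max_p = if (nrow(records)) max(records$p_value) else NA_real_
  ), class = "candidate_summary")
}

#' @export
print.candidate_summary <- function(x, ...) {
  cat("Candidate summary:", x$n_rows, "insertion(s) in", x$n_genes,
      "gene(s)\n")
  cat("  position:", paste(names(x$by_position), x$by_position,
                           sep = "=", collapse = " "), "\n")
  cat("  family:  ", paste(names(x$by_family), x$by_family,
                           sep = "=", collapse = " "), "\n")
  cat("  orientation:", paste(names(x$by_orientation), x$by_orientation,
                              sep = "=", collapse = " "), "\n")
  cat("  TSS-associated:", x$n_tss,
      sprintf("(intron %d, 3'UTR %d)", x$n_tss_intron, x$n_tss_utr3), "\n")
  cat("  max p:", format(x$max_p), "\n")
  invisible(x)
}

#' Serialize a candidate summary as JSON
#'
#' @param summary A `candidate_summary`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
summary_to_json <- function(summary, path = NULL) {
  x <- unclass(summary)
  x$by_position <- as.list(x$by_position)
  x$by_family <- as.list(x$by_family)
  x$by_orientation <- as.list(x$by_orientation)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Path to the packaged immune-gene candidate table
#'
#' A curated 48-row table of expressed Alu insertions in 26 immune genes
#' identified from blood transcriptomes of patients with sepsis and healthy
#' controls, shipped as a plain-text fixture.
#'
#' @return File path to the TSV fixture.
#' @export
immune_candidates_path <- function() {
  system.file("extdata", "immune_alu_candidates.tsv", package = "aluscan",
              mustWork = TRUE)
}
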