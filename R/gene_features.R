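#' Build gene models from Ensembl-dialect annotation records
#'
#' Groups `exon` (and, when present, `CDS`) records by `transcript_id` and
#' `gene_id` into per-gene models. The gene symbol is taken from the
#' `gene_name` attribute when present, otherwise it falls back to the gene id.
#'
#' @param records A `GRanges` from [read_gtf()] (`ensembl` dialect) carrying
#'   `type`, `gene_id`, `transcript_id` and optionally `gene_name` columns.
#' @param symbol_key Attribute used for the gene symbol (default
#'   `"gene_name"`).
#' @return A named list of gene models. Each model is a list with elements
#'   `id`, `symbol`, `interval` (`GRanges`), `strand` and `transcripts`; each
#'   transcript has `id`, `gene_id`, `strand`, `exons` (sorted `GRanges`) and
#'   `cds_span` (`GRanges` or `NULL`).
#' @export
build_gene_models <- function(records, symbol_key = "gene_name") {
  type <- as.character(records$type)
  exons <- records[type == "exon"]
  cds <- records[type == "CDS"]
  declared_tx <- records[type == "transcript"]
  if (length(exons) == 0L) stop("annotation contains no exon records")
  if (is.null(exons$transcript_id) || anyNA(exons$transcript_id)) {
    stop("exon records must carry a transcript_id attribute")
  }
  missing_tx <- setdiff(as.character(declared_tx$transcript_id),
                        as.character(exons$transcript_id))
  if (length(missing_tx) > 0L) {
    stop("transcript(s) with zero exons: ", paste(missing_tx, collapse = ", "))
  }

  ex_tx <- as.character(exons$transcript_id)
  cds_tx <- if (length(cds)) as.character(cds$transcript_id) else character(0)
  tx_ids <- unique(ex_tx)

  transcripts <- lapply(tx_ids, function(tid) {
    ex <- exons[ex_tx == tid]
    ex <- ex[order(GenomicRanges::start(ex))]
    ex_gr <- GenomicRanges::granges(ex)
    if (length(GenomicRanges::reduce(ex_gr, ignore.strand = TRUE)) != length(ex_gr)) {
      stop("transcript ", tid, " has overlapping exons")
    }
    span <- NULL
    cd <- cds[cds_tx == tid]
    if (length(cd) > 0L) {
      span <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(cd)[1L],
        IRanges::IRanges(min(GenomicRanges::start(cd)),
                         max(GenomicRanges::end(cd))),
        strand = GenomicRanges::strand(cd)[1L]
      )
    }
    list(id = tid,
         gene_id = as.character(ex$gene_id[1L]),
         strand = as.character(GenomicRanges::strand(ex))[1L],
         exons = ex_gr,
         cds_span = span)
  })
  names(transcripts) <- tx_ids

  gene_of_tx <- vapply(transcripts, `[[`, "", "gene_id")
  gene_ids <- unique(gene_of_tx)
  symbols <- stats::setNames(as.character(exons$gene_id), NULL)
  sym_lookup <- if (!is.null(S4Vectors::mcols(exons)[[symbol_key]])) {
    stats::setNames(as.character(S4Vectors::mcols(exons)[[symbol_key]]),
                    as.character(exons$gene_id))
  } else NULL

  models <- lapply(gene_ids, function(gid) {
    txs <- transcripts[gene_of_tx == gid]
    all_ex <- do.call(c, unname(lapply(txs, `[[`, "exons")))
    interval <- range(GenomicRanges::granges(all_ex), ignore.strand = TRUE)
    strand <- txs[[1L]]$strand
    GenomicRanges::strand(interval) <- strand
    symbol <- gid
    if (!is.null(sym_lookup) && gid %in% names(sym_lookup) &&
        !is.na(sym_lookup[[gid]]) && nzchar(sym_lookup[[gid]])) {
      symbol <- sym_lookup[[gid]]
    }
    structure(list(id = gid, symbol = symbol, interval = interval,
                   strand = strand, transcripts = txs),
              class = "gene_model")
  })
  names(models) <- gene_ids
  models
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model>", x$id, "(", x$symbol, ")",
      locus_string(x$interval), x$strand,
      "-", length(x$transcripts), "transcript(s)\n")
  invisible(x)
}

#' Select the reference transcript of a gene
#'
#' One transcript per gene anchors the intron/UTR feature derivation so that
#' each insertion receives a single position label. The transcript with the
#' largest summed exon length wins; ties go to the lexicographically smallest
#' transcript id.
#'
#' @param gene A gene model from [build_gene_models()].
#' @return A transcript model (list).
#' @export
select_reference_transcript <- function(gene) {
  stopifnot(length(gene$transcripts) >= 1L)
  exlen <- vapply(gene$transcripts,
                  function(tx) sum(GenomicRanges::width(tx$exons)), 0)
  ids <- vapply(gene$transcripts, `[[`, "", "id")
  ord <- order(-exlen, ids)
  gene$transcripts[[ord[1L]]]
}

#' Derive intron and UTR features from a transcript
#'
#' Introns are the gaps between consecutive exons. When a CDS span is
#' present, the exonic sequence 5' of it (in transcription direction) is the
#' 5'UTR, the exonic sequence 3' of it the 3'UTR, and the exon/CDS-span
#' intersection the coding exons. For transcripts without a CDS all exonic
#' sequence is kept in the coding-exon slot, flagged `noncoding`
#' ("exonic_noncoding" surrogate).
#'
#' @param tx A transcript model.
#' @param gene_interval Optional `GRanges` with the full gene span (used by
#'   [classify_position()] for repeats outside the reference transcript).
#' @return A `feature_set` list with `GRanges` elements `introns`, `utr5`,
#'   `utr3`, `cds_exons`, plus `gene_id`, `tx_id`, `strand`, `span`,
#'   `gene_interval` and the `noncoding` flag.
#' @export
derive_features <- function(tx, gene_interval = NULL) {
  ex <- tx$exons
  stopifnot(!is.unsorted(GenomicRanges::start(ex)))
  span <- range(ex, ignore.strand = TRUE)
  introns <- GenomicRanges::setdiff(span, GenomicRanges::granges(ex),
                                    ignore.strand = TRUE)
  empty <- GenomicRanges::GRanges()
  minus <- identical(tx$strand, "-")
  if (is.null(tx$cds_span)) {
    fs <- list(introns = introns, utr5 = empty, utr3 = empty,
               cds_exons = GenomicRanges::granges(ex), noncoding = TRUE)
  } else {
    cs <- GenomicRanges::start(tx$cds_span)
    ce <- GenomicRanges::end(tx$cds_span)
    chrom <- as.character(GenomicRanges::seqnames(ex))[1L]
    left <- if (cs > GenomicRanges::start(span)) {
      GenomicRanges::intersect(
        GenomicRanges::granges(ex),
        GenomicRanges::GRanges(chrom, IRanges::IRanges(GenomicRanges::start(span), cs - 1L)),
        ignore.strand = TRUE)
    } else empty
    right <- if (ce < GenomicRanges::end(span)) {
      GenomicRanges::intersect(
        GenomicRanges::granges(ex),
        GenomicRanges::GRanges(chrom, IRanges::IRanges(ce + 1L, GenomicRanges::end(span))),
        ignore.strand = TRUE)
    } else empty
    cds_ex <- GenomicRanges::intersect(
      GenomicRanges::granges(ex),
      GenomicRanges::GRanges(chrom, IRanges::IRanges(cs, ce)),
      ignore.strand = TRUE)
    fs <- list(introns = introns,
               utr5 = if (minus) right else left,
               utr3 = if (minus) left else right,
               cds_exons = cds_ex,
               noncoding = FALSE)
  }
  structure(c(fs, list(gene_id = tx$gene_id, tx_id = tx$id,
                       strand = tx$strand, span = span,
                       gene_interval = gene_interval)),
            class = "feature_set")
}

#' Derive features for a gene via its reference transcript
#'
#' @param gene A gene model.
#' @return A `feature_set` (see [derive_features()]).
#' @export
gene_feature_set <- function(gene) {
  tx <- select_reference_transcript(gene)
  derive_features(tx, gene_interval = gene$interval)
}

#' Read an immune-gene symbol list
#'
#' Plain text, one symbol per line; `#` starts a comment. Symbols are
#' upper-cased on load and de-duplicated.
#'
#' @param path Path to the list file.
#' @return Character vector of symbols.
#' @export
read_gene_symbols <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  unique(toupper(lines[nzchar(lines)]))
}

#' Restrict gene models to a symbol set
#'
#' Matching is exact but case-insensitive. The number of list symbols not
#' found in the annotation is reported via a message; an empty result raises
#' a warning.
#'
#' @param genes List of gene models.
#' @param symbols Character vector of gene symbols (e.g. from
#'   [read_gene_symbols()]).
#' @return The matching subset of `genes`.
#' @export
restrict_to_symbols <- function(genes, symbols) {
  if (length(symbols) == 0L) stop("empty gene symbol set")
  symbols <- unique(toupper(symbols))
  gene_syms <- toupper(vapply(genes, `[[`, "", "symbol"))
  keep <- gene_syms %in% symbols
  unmatched <- sum(!(symbols %in% gene_syms))
  if (unmatched > 0L) {
    message(unmatched, " symbol(s) from the list not present in the annotation")
  }
  if (!any(keep)) {
    warning("no gene in the annotation matches the symbol list")
  }
  genes[keep]
}
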