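#' Read a BED3-BED6 file into a GRanges
#'
#' Reads tab-separated BED records. BED coordinates are 0-based half-open on
#' disk; the returned `GRanges` uses the package-wide 1-based closed
#' convention, so a BED line `chr1 0 10` becomes `chr1:1-10` (width 10).
#' A missing or "." strand field is mapped to `"*"` (unstranded).
#'
#' @param path Path to a BED file. Lines starting with `#`, `track` or
#'   `browser` are skipped.
#' @return A `GRanges` with metadata columns `name` and `score` (`NA` where
#'   the field is absent or ".").
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr19\t47321325\t47321636\tAluSx1\t0\t+", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  skip <- grepl("^(#|track\\b|browser\\b)", lines) | !nzchar(trimws(lines))
  idx <- which(!skip)
  if (length(idx) == 0L) {
    return(GenomicRanges::GRanges(name = character(0), score = numeric(0)))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED parse error at line ", idx[which(nf < 3L)[1L]],
         ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad)) {
    stop("BED parse error at line ", idx[which(bad)[1L]],
         ": non-integer coordinates")
  }
  bad <- start0 < 0L | start0 >= end0
  if (any(bad)) {
    stop("BED parse error at line ", idx[which(bad)[1L]],
         ": requires 0 <= start < end")
  }
  if (any(!nzchar(chrom))) {
    stop("BED parse error at line ", idx[which(!nzchar(chrom))[1L]],
         ": empty chromosome name")
  }
  opt <- function(i) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_,
           "")
  }
  nm <- opt(4L)
  nm[nm == "."] <- NA_character_
  sc <- suppressWarnings(as.numeric(opt(5L)))
  st <- opt(6L)
  st[is.na(st) | !(st %in% c("+", "-"))] <- "*"
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = st,
    name = nm,
    score = sc
  )
}

#' Write a GRanges as BED6
#'
#' The inverse of [read_bed()]: internal 1-based closed coordinates are
#' written as 0-based half-open BED fields. The `name` and `score` metadata
#' columns are used when present ("." / 0 otherwise).
#'
#' @param gr A `GRanges`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  nm <- if (!is.null(gr$name)) as.character(gr$name) else rep(NA_character_, length(gr))
  nm[is.na(nm)] <- "."
  sc <- if (!is.null(gr$score)) as.numeric(gr$score) else rep(NA_real_, length(gr))
  sc[is.na(sc)] <- 0
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                     as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr) - 1L,
                     GenomicRanges::end(gr),
                     nm, sc, st),
             path)
  invisible(path)
}

#' Read a GTF file (Ensembl or RepeatMasker dialect)
#'
#' GTF coordinates are 1-based inclusive and are kept as such in the returned
#' `GRanges`. The `repeatmasker` dialect (UCSC table-browser GTF export of the
#' RepeatMasker track) exposes the repeat name as a `name` column, taken from
#' whichever of `gene_id` / `transcript_id` first matches an Alu-style name,
#' falling back to `gene_id`. The `ensembl` dialect requires a `gene_id`
#' attribute on every record.
#'
#' @param path Path to a GTF file.
#' @param dialect One of `"ensembl"` or `"repeatmasker"`.
#' @return A `GRanges` with the GTF `type`, `source` and attribute columns.
#' @export
read_gtf <- function(path, dialect = c("ensembl", "repeatmasker")) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = "gtf")
  if (dialect == "ensembl") {
    if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
      stop("ensembl-dialect GTF records must carry a gene_id attribute")
    }
  } else {
    gid <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else rep(NA_character_, length(gr))
    tid <- if (!is.null(gr$transcript_id)) as.character(gr$transcript_id) else rep(NA_character_, length(gr))
    nm <- ifelse(!is.na(gid) & startsWith(gid, "Alu"), gid,
                 ifelse(!is.na(tid) & startsWith(tid, "Alu"), tid, gid))
    gr$name <- nm
  }
  gr
}

#' Write a GRanges as GTF
#'
#' Coordinates are written 1-based inclusive; reading the file back with
#' [read_gtf()] restores them exactly.
#'
#' @param gr A `GRanges` (attribute columns such as `gene_id` are exported).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gr, path) {
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Parse a locus string such as "chr19:47321326-47321636"
#'
#' Locus strings are 1-based inclusive, the convention used in genome-browser
#' displays and in the candidate table. Thousands separators (",") are
#' tolerated.
#'
#' @param text A single string of the form `chrom:start-end`.
#' @return A `GRanges` of length 1.
#' @examples
#' parse_locus("chr19:47321326-47321636")  # width 311
#' @export
parse_locus <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regexec("^([^:[:space:]]+):([0-9,]+)-([0-9,]+)$", text)
  parts <- regmatches(text, m)[[1L]]
  if (length(parts) != 4L) {
    stop("malformed locus string: ", text)
  }
  s <- as.numeric(gsub(",", "", parts[3L], fixed = TRUE))
  e <- as.numeric(gsub(",", "", parts[4L], fixed = TRUE))
  if (s < 1 || s > e) {
    stop("locus start must satisfy 1 <= start <= end: ", text)
  }
  GenomicRanges::GRanges(parts[2L], IRanges::IRanges(s, e))
}

#' Format a GRanges as 1-based locus strings
#'
#' @param gr A `GRanges`.
#' @return Character vector `chrom:start-end`.
#' @export
locus_string <- function(gr) {
  sprintf("%s:%d-%d",
          as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr),
          GenomicRanges::end(gr))
}

#' Read aligned fragments from a SAM file
#'
#' Loads primary aligned records (secondary 0x100, supplementary 0x800 and
#' unmapped reads are excluded) and collapses the two mates of a properly
#' co-located pair into one fragment whose span covers both mate alignments.
#' The fragment strand is taken from the first-in-pair mate. Mates aligned to
#' different chromosomes fall back to two single-end fragments (a message is
#' emitted).
#'
#' @param path Path to a SAM text file with a header.
#' @return A `GRanges` of fragments with metadata columns `read_id` and
#'   `is_paired`.
#' @export
read_alignments <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !startsWith(first, "@")) {
    stop("SAM file has no header: ", path)
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flag, what = c("qname", "flag"))
  )
  if (length(ga) == 0L) {
    return(GenomicRanges::GRanges(read_id = character(0), is_paired = logical(0)))
  }
  df <- data.frame(
    qname = S4Vectors::mcols(ga)$qname,
    flag = S4Vectors::mcols(ga)$flag,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga),
    end = GenomicAlignments::end(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    stringsAsFactors = FALSE
  )
  df$paired <- bitwAnd(df$flag, 1L) > 0L
  df$first_in_pair <- bitwAnd(df$flag, 64L) > 0L

  single <- df[!df$paired, , drop = FALSE]
  frags <- list()
  if (nrow(single) > 0L) {
    frags[[length(frags) + 1L]] <- data.frame(
      chrom = single$chrom, start = single$start, end = single$end,
      strand = single$strand, read_id = single$qname, is_paired = FALSE,
      stringsAsFactors = FALSE
    )
  }
  paired <- df[df$paired, , drop = FALSE]
  if (nrow(paired) > 0L) {
    n_split <- 0L
    for (grp in split(paired, paired$qname)) {
      same_chrom <- length(unique(grp$chrom)) == 1L
      if (nrow(grp) == 2L && same_chrom) {
        first_mate <- grp[grp$first_in_pair, , drop = FALSE]
        st <- if (nrow(first_mate) == 1L) first_mate$strand else grp$strand[1L]
        frags[[length(frags) + 1L]] <- data.frame(
          chrom = grp$chrom[1L], start = min(grp$start), end = max(grp$end),
          strand = st, read_id = grp$qname[1L], is_paired = TRUE,
          stringsAsFactors = FALSE
        )
      } else {
        # cross-chromosome (or orphaned) mates: keep each as single-end
        n_split <- n_split + 1L
        frags[[length(frags) + 1L]] <- data.frame(
          chrom = grp$chrom, start = grp$start, end = grp$end,
          strand = grp$strand, read_id = grp$qname, is_paired = FALSE,
          stringsAsFactors = FALSE
        )
      }
    }
    if (n_split > 0L) {
      message(n_split, " template(s) with mates on different chromosomes ",
              "kept as single-end fragments")
    }
  }
  out <- do.call(rbind, frags)
  GenomicRanges::GRanges(
    seqnames = out$chrom,
    ranges = IRanges::IRanges(out$start, out$end),
    strand = out$strand,
    read_id = out$read_id,
    is_paired = out$is_paired
  )
}

#' Read a sample sheet
#'
#' Tab-separated `sample<TAB>condition` with an optional third `path` column
#' pointing at each sample's SAM alignments. A header line is detected (first
#' line starting with `sample`). A binary `group` column is derived: samples
#' whose condition is `healthy` (case-insensitive) form one group, everything
#' else (infection, sepsis, septic shock, ...) is pooled as `inflammation`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `sample`, `condition`, `group` and
#'   optionally `path`.
#' @export
read_sample_sheet <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty sample sheet: ", path)
  if (grepl("^sample\\b", lines[1L], ignore.case = TRUE)) lines <- lines[-1L]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("sample sheet lines must have at least sample<TAB>condition")
  }
  out <- data.frame(
    sample = vapply(fields, `[[`, "", 1L),
    condition = vapply(fields, `[[`, "", 2L),
    stringsAsFactors = FALSE
  )
  if (all(lengths(fields) >= 3L)) {
    out$path <- vapply(fields, `[[`, "", 3L)
  }
  if (anyDuplicated(out$sample)) stop("duplicate sample ids in sample sheet")
  out$group <- derive_binary_group(out$condition)
  out
}

#' Derive the binary healthy-vs-inflammation grouping
#'
#' @param condition Character vector of condition labels.
#' @return Factor with levels `healthy`, `inflammation`.
#' @export
derive_binary_group <- function(condition) {
  factor(ifelse(tolower(condition) == "healthy", "healthy", "inflammation"),
         levels = c("healthy", "inflammation"))
}
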