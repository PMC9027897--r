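# All simulation randomness flows from one seed through with_seed(), which
# restores the caller's RNG state on exit.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

.sim_subfamilies <- c("AluJb", "AluJo", "AluSx", "AluSx1", "AluSz", "AluSc",
                      "AluSp", "AluSg", "AluY", "AluYb8")

#' Simulate gene annotation with planted Alu insertions
#'
#' Emits a toy genome annotation in the same dialects the pipeline consumes:
#' an Ensembl-style GTF of protein-coding genes (2-6 exons, CDS, UTRs), a
#' BED6 repeat track of Alu elements planted into introns and 3'UTRs with
#' drawn subfamilies and strands, a BED6 CAGE-style TSS track where a
#' configurable fraction of planted elements receives an upstream TSS at a
#' drawn offset, a symbol list covering every gene, and a ground-truth table.
#' The geometry is noiseless: each planted element lies wholly inside one
#' feature, elements are spaced so TSS linkage cannot cross-talk, and every
#' gene is short enough that a ~300-bp element always clears the default
#' gene-fraction overlap threshold. Output files are byte-identical for a
#' given seed.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param tss_fraction Fraction of planted elements given an upstream TSS
#'   (default 0.5).
#' @param tss_window Upstream window the offsets are drawn inside, strict
#'   upper bound (default 1000; offsets are drawn in 100..900).
#' @return A list with paths `genes_gtf`, `repeats_bed`, `tss_bed`,
#'   `symbols`, the `truth` data.frame (one row per planted element:
#'   `insertion_id`, `gene_id`, `symbol`, `chrom`, `gene_strand`, `start`,
#'   `end`, `subfamily`, `alu_strand`, `position`, `orientation`,
#'   `tss_offset`), and `chrom_lengths`.
#' @export
simulate_annotation <- function(n_genes, seed, dir = tempfile("simanno"),
                                tss_fraction = 0.5, tss_window = 1000) {
  stopifnot(n_genes >= 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    gtf <- character(0)
    bed <- character(0)
    tssb <- character(0)
    truth <- list()
    chroms <- paste0("chr", c("1", "2", "3", "4"))
    cursor <- stats::setNames(rep(10000L, length(chroms)), chroms)

    for (i in seq_len(n_genes)) {
      chrom <- chroms[1L + (i - 1L) %% length(chroms)]
      gene_strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(2:6, 1L)
      # exon widths in genomic order; the 3'-terminal exon (transcription
      # direction) is long enough to host a UTR3 Alu with a 1 kb 5' flank
      widths <- sample(200:400, n_ex, replace = TRUE)
      long_ex <- sample(1700:2000, 1L)
      if (gene_strand == "+") widths[n_ex] <- long_ex else widths[1L] <- long_ex
      introns_w <- if (n_ex > 1L) sample(2400:3600, n_ex - 1L, replace = TRUE) else integer(0)

      gstart <- cursor[[chrom]]
      ex_start <- integer(n_ex)
      ex_end <- integer(n_ex)
      pos <- gstart
      for (k in seq_len(n_ex)) {
        ex_start[k] <- pos
        ex_end[k] <- pos + widths[k] - 1L
        pos <- ex_end[k] + if (k < n_ex) introns_w[k] else 0L
      }
      gend <- ex_end[n_ex]
      cursor[[chrom]] <- gend + 10000L

      utr5_len <- sample(50:150, 1L)
      utr3_len <- sample(1450:1600, 1L)
      if (gene_strand == "+") {
        cds_start <- ex_start[1L] + utr5_len
        cds_end <- ex_end[n_ex] - utr3_len
      } else {
        cds_start <- ex_start[1L] + utr3_len
        cds_end <- ex_end[n_ex] - utr5_len
      }

      gid <- sprintf("G%06d", i)
      tid <- sprintf("T%06d", i)
      sym <- sprintf("GENE%04d", i)
      attr_g <- sprintf("gene_id \"%s\"; gene_name \"%s\";", gid, sym)
      attr_t <- sprintf("gene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
                        gid, tid, sym)
      gtf <- c(gtf,
               sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       chrom, gstart, gend, gene_strand, attr_g),
               sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       chrom, gstart, gend, gene_strand, attr_t))
      for (k in seq_len(n_ex)) {
        gtf <- c(gtf, sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
                              chrom, ex_start[k], ex_end[k], gene_strand,
                              attr_t, k))
        cs <- max(ex_start[k], cds_start)
        ce <- min(ex_end[k], cds_end)
        if (cs <= ce) {
          gtf <- c(gtf, sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                chrom, cs, ce, gene_strand, attr_t))
        }
      }

      # choose host features: each intron w.p. 0.5, the 3'UTR w.p. 0.5,
      # forcing the 3'UTR when nothing was chosen
      in_intron <- if (n_ex > 1L) stats::runif(n_ex - 1L) < 0.5 else logical(0)
      in_utr3 <- stats::runif(1L) < 0.5
      if (!any(in_intron) && !in_utr3) in_utr3 <- TRUE

      plant <- function(lo, hi, position) {
        # plant one Alu with >= 1000 nt clearance inside [lo, hi]
        w <- sample(280:320, 1L)
        a_start <- lo + 1020L + sample(0:max(0L, hi - lo - w - 2060L), 1L)
        a_end <- a_start + w - 1L
        subfam <- sample(.sim_subfamilies, 1L)
        a_strand <- sample(c("+", "-"), 1L)
        has_tss <- stats::runif(1L) < tss_fraction
        offset <- NA_integer_
        tpos <- NA_integer_
        if (has_tss) {
          offset <- sample(100:900, 1L)
          tpos <- if (gene_strand == "+") a_start - offset else a_end + offset
        }
        list(start = a_start, end = a_end, subfamily = subfam,
             strand = a_strand, position = position, tss_offset = offset,
             tss_pos = tpos)
      }

      planted <- list()
      for (k in which(in_intron)) {
        planted[[length(planted) + 1L]] <-
          plant(ex_end[k] + 1L, ex_start[k + 1L] - 1L, "Intron")
      }
      if (in_utr3) {
        if (gene_strand == "+") {
          planted[[length(planted) + 1L]] <-
            plant(cds_end + 1L, ex_end[n_ex], "UTR3")
        } else {
          planted[[length(planted) + 1L]] <-
            plant(ex_start[1L], cds_start - 1L, "UTR3")
        }
      }

      for (p in planted) {
        bed <- c(bed, sprintf("%s\t%d\t%d\t%s\t0\t%s",
                              chrom, p$start - 1L, p$end, p$subfamily,
                              p$strand))
        if (!is.na(p$tss_offset)) {
          tssb <- c(tssb, sprintf("%s\t%d\t%d\ttss\t0\t%s",
                                  chrom, p$tss_pos - 1L, p$tss_pos,
                                  gene_strand))
        }
        truth[[length(truth) + 1L]] <- data.frame(
          insertion_id = sprintf("%s:%d-%d", chrom, p$start, p$end),
          gene_id = gid, symbol = sym, chrom = chrom,
          gene_strand = gene_strand, start = p$start, end = p$end,
          subfamily = p$subfamily, alu_strand = p$strand,
          position = p$position,
          orientation = ifelse(p$strand == gene_strand, "Sense", "Inverted"),
          tss_offset = p$tss_offset,
          stringsAsFactors = FALSE
        )
      }
    }

    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    genes_gtf <- file.path(dir, "genes.gtf")
    repeats_bed <- file.path(dir, "repeats.bed")
    tss_bed <- file.path(dir, "tss.bed")
    symbols <- file.path(dir, "symbols.txt")
    writeLines(gtf, genes_gtf)
    writeLines(bed, repeats_bed)
    writeLines(tssb, tss_bed)
    writeLines(unique(truth$symbol), symbols)
    list(genes_gtf = genes_gtf, repeats_bed = repeats_bed, tss_bed = tss_bed,
         symbols = symbols, truth = truth,
         chrom_lengths = cursor + 100000L, seed = seed)
  })
}

#' Simulate a count matrix with planted group effects
#'
#' Draws negative-binomial fragment counts for every planted insertion over
#' two sample groups (healthy vs inflammation), giving a configurable subset
#' of insertions a planted fold change between the groups. Optionally emits
#' per-sample SAM files whose per-insertion fragment tallies equal the drawn
#' counts exactly.
#'
#' @param sim Output of [simulate_annotation()] (supplies the truth geometry
#'   and chromosome lengths).
#' @param n_per_group Named integer vector condition -> sample count;
#'   conditions other than `healthy` pool into the inflammation group.
#'   Defaults mirror a sepsis cohort: 40 healthy, 12 infection, 18 sepsis,
#'   18 septic shock.
#' @param seed Integer seed.
#' @param de_fraction Fraction of insertions given a planted effect
#'   (default 0.2).
#' @param fc Planted fold change for affected insertions (default 4);
#'   direction (up/down in inflammation) is drawn per insertion.
#' @param dispersion Negative-binomial dispersion (default 0.1).
#' @param mean_range Range the per-insertion baseline means are drawn from,
#'   log-uniformly (default 500..3000).
#' @param sam_dir When non-`NULL`, write one SAM file per sample here.
#' @return A list with `counts` (insertions x samples), `samples` (sample
#'   sheet data.frame with `sample`, `condition`, `group` and `path` when SAM
#'   files were written) and `truth` (the geometry truth augmented with
#'   `base_mean`, `dispersion`, `is_de`, `lfc`).
#' @export
simulate_counts <- function(sim,
                            n_per_group = c(healthy = 40, infection = 12,
                                            sepsis = 18, septic_shock = 18),
                            seed = 1,
                            de_fraction = 0.2,
                            fc = 4,
                            dispersion = 0.1,
                            mean_range = c(500, 3000),
                            sam_dir = NULL) {
  stopifnot(all(n_per_group >= 2), "healthy" %in% names(n_per_group),
            fc >= 1, dispersion > 0)
  truth <- sim$truth
  n_ins <- nrow(truth)
  with_seed(seed, {
    conditions <- rep(names(n_per_group), times = n_per_group)
    samples <- data.frame(
      sample = sprintf("%s%02d", gsub("_", "", conditions),
                       unlist(lapply(n_per_group, seq_len))),
      condition = conditions,
      stringsAsFactors = FALSE
    )
    samples$group <- derive_binary_group(samples$condition)

    base_mean <- exp(stats::runif(n_ins, log(mean_range[1L]),
                                  log(mean_range[2L])))
    is_de <- stats::runif(n_ins) < de_fraction
    direction <- sample(c(1, -1), n_ins, replace = TRUE)
    lfc <- ifelse(is_de, direction * log2(fc), 0)

    mu <- outer(base_mean, rep(1, nrow(samples)))
    infl <- samples$group == "inflammation"
    mu[, infl] <- mu[, infl] * 2^lfc

    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
      nrow = n_ins,
      dimnames = list(truth$insertion_id, samples$sample)
    )

    truth$base_mean <- base_mean
    truth$dispersion <- dispersion
    truth$is_de <- is_de
    truth$lfc <- lfc

    if (!is.null(sam_dir)) {
      dir.create(sam_dir, showWarnings = FALSE, recursive = TRUE)
      samples$path <- vapply(seq_len(nrow(samples)), function(j) {
        p <- file.path(sam_dir, paste0(samples$sample[j], ".sam"))
        write_sim_sam(p, truth, counts[, j], sim$chrom_lengths)
        p
      }, "")
    }
    list(counts = counts, samples = samples, truth = truth, seed = seed)
  })
}

# Emit a SAM file with exactly `counts[i]` single-end fragments placed fully
# inside insertion i (insertions are pairwise disjoint by construction, so
# per-interval fragment tallies reproduce the counts).
write_sim_sam <- function(path, truth, counts, chrom_lengths) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     as.integer(chrom_lengths)), con)
  for (i in seq_len(nrow(truth))) {
    n <- counts[i]
    if (n == 0L) next
    w <- truth$end[i] - truth$start[i] + 1L
    rl <- min(100L, w)
    # deterministic tiling inside the insertion
    offs <- (seq_len(n) - 1L) %% (w - rl + 1L)
    writeLines(sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                       sprintf("frag_%d_%d", i, seq_len(n)),
                       truth$chrom[i], truth$start[i] + offs, rl), con)
  }
  invisible(path)
}

#' Sensitivity and false-discovery proportion of a call set
#'
#' @param called Character vector of called insertion ids.
#' @param truth Truth data.frame with `insertion_id` and `is_de` columns
#'   (from [simulate_counts()]).
#' @return A list with `sensitivity` (recovered / planted) and `fdp`
#'   (false calls / all calls; 0 when there are no calls).
#' @export
evaluate_recovery <- function(called, truth) {
  planted <- truth$insertion_id[truth$is_de]
  sens <- if (length(planted) == 0L) NA_real_ else {
    length(intersect(called, planted)) / length(planted)
  }
  fdp <- if (length(called) == 0L) 0 else {
    length(setdiff(called, planted)) / length(called)
  }
  list(sensitivity = sens, fdp = fdp)
}
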