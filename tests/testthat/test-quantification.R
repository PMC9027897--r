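test_that("fragments count toward every insertion they touch", {
  ins <- gr("chr1", c(1001, 1301), c(1300, 1600), c("+", "+"))
  names(ins) <- c("a", "b")
  frags <- gr("chr1", c(1100, 1150, 1200, 1250), c(1199, 1249, 1299, 1399),
              c("+", "-", "+", "+"))
  counts <- count_fragments(frags, ins, "both")
  expect_equal(counts, c(a = 4L, b = 1L))  # the spanning fragment hits both
  # strand-aware modes
  expect_equal(count_fragments(frags, ins, "sense"), c(a = 3L, b = 1L))
  expect_equal(count_fragments(frags, ins, "antisense"), c(a = 1L, b = 0L))
})

test_that("column totals conserve fragments over disjoint insertions", {
  set.seed(61)
  starts <- seq(1000, by = 1000, length.out = 10)
  ins <- gr("chr1", starts, starts + 400, "+")
  names(ins) <- paste0("i", 1:10)
  fs <- sample.int(11000, 200)
  frags <- gr("chr1", fs, fs + 80, "+")
  n_overlapping <- sum(GenomicRanges::countOverlaps(frags, ins,
                                                    ignore.strand = TRUE) > 0)
  expect_equal(sum(count_fragments(frags, ins, "both")), n_overlapping)
})

test_that("size factors reproduce the median-of-ratios hand oracle", {
  m <- matrix(c(10, 100, 4, 20, 200, 8), ncol = 2,
              dimnames = list(c("r1", "r2", "r3"), c("s1", "s2")))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  # identical columns
  expect_equal(unname(size_factors(cbind(a = c(5, 9), b = c(5, 9)))), c(1, 1))
  # scale equivariance: B = 2A on every row
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "pseudocount")
})

test_that("size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(67)
  # odd row count: the plain median of ratios coincides with the
  # median-of-log-ratios form the reference estimator uses
  m <- matrix(rnbinom(594, mu = 200, size = 5) + 1L, ncol = 6)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("scaling a column scales its factor relative to the others", {
  set.seed(71)
  m <- matrix(rpois(300, 100) + 1, ncol = 3)
  sf <- size_factors(m)
  m2 <- m
  m2[, 2] <- m2[, 2] * 3
  sf2 <- size_factors(m2)
  # the reference geometric means rescale too, so only ratios are invariant
  expect_equal(sf2[2] / sf2[1], 3 * sf[2] / sf[1], tolerance = 1e-12)
  expect_equal(sf2[3] / sf2[1], sf[3] / sf[1], tolerance = 1e-12)
})

test_that("normalization divides by the per-sample factor", {
  m <- matrix(1:6, ncol = 2, dimnames = list(letters[1:3], c("x", "y")))
  expect_equal(normalize_counts(m, c(1, 1)), m + 0)
  nm <- normalize_counts(m, c(1, 2))
  expect_equal(nm[, "y"], (m + 0)[, "y"] / 2)
  # row sums conserved under column-sum/mean-column-sum factors
  cs <- colSums(m)
  f <- cs / mean(cs)
  expect_equal(sum(normalize_counts(m, f)), sum(cs / f))
})

test_that("minimum-expression filter is inclusive at the floor", {
  m <- rbind(low = c(399, 120), edge = c(400, 0), high = c(2000, 5))
  keep <- filter_min_expression(m, min_count = 400, min_samples = 1)
  expect_equal(unname(keep), c(FALSE, TRUE, TRUE))
  expect_warning(filter_min_expression(m, min_count = 1e6), "every row")
})

test_that("robust filter is strict on counts, inclusive on fold change", {
  m <- rbind(a = c(1000, 900), b = c(1500, 10), c = c(1500, 20), d = c(4000, 1))
  fc <- c(2.0, 1.25, 1.3, 1.31)
  keep <- filter_robust(m, fc, robust_count = 1000, fc_threshold = 1.3)
  expect_equal(unname(keep), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("the filter cascade is monotone in its thresholds", {
  set.seed(73)
  m <- matrix(rnbinom(400, mu = 700, size = 10), ncol = 8)
  rownames(m) <- paste0("r", seq_len(nrow(m)))
  fc <- runif(nrow(m), 1, 3)
  base <- filter_min_expression(m, 400) & filter_robust(m, fc, 1000, 1.3)
  for (mc in c(500, 800)) {
    for (rc in c(1200, 2000)) {
      for (ft in c(1.5, 2.5)) {
        tight <- filter_min_expression(m, mc) & filter_robust(m, fc, rc, ft)
        expect_true(all(!tight | base))  # tight subset of base
      }
    }
  }
})

test_that("fold changes are direction-free with recorded direction", {
  nm <- rbind(up = c(10, 10, 40, 40), down = c(40, 40, 10, 10))
  groups <- c("healthy", "healthy", "inflammation", "inflammation")
  fc <- fold_changes(nm, groups, pseudocount = 1)
  expect_equal(fc$fold_change, c(41 / 11, 41 / 11))
  expect_equal(fc$up_in, c("inflammation", "healthy"))
})

test_that("TSS coverage drop quantifies the upstream/downstream ratio", {
  # uniform coverage across the TSS -> 1.0
  frags <- gr("chr1", seq(801, 1200, by = 10), seq(900, 1299, by = 10), "+")
  expect_equal(tss_coverage_drop(frags, 1100, "chr1", "+", window = 100), 1.0)
  # 5 fragments wholly upstream vs 50 wholly downstream, equal length -> 0.1
  up <- gr("chr1", rep(901, 5), rep(1000, 5), "+")
  down <- gr("chr1", rep(1001, 50), rep(1100, 50), "+")
  expect_equal(tss_coverage_drop(c(up, down), 1001, "chr1", "+", window = 100),
               0.1)
  # zero upstream -> 0; zero downstream -> Inf sentinel
  expect_equal(tss_coverage_drop(down, 1001, "chr1", "+", window = 100), 0)
  expect_equal(tss_coverage_drop(up, 1001, "chr1", "+", window = 100), Inf)
  # minus-strand gene mirrors the windows
  up_m <- gr("chr1", rep(1001, 5), rep(1100, 5), "-")
  down_m <- gr("chr1", rep(901, 50), rep(1000, 50), "-")
  expect_equal(tss_coverage_drop(c(up_m, down_m), 1000, "chr1", "-",
                                 window = 100), 0.1)
})

test_that("count matrices round-trip through TSV", {
  m <- matrix(1:6, ncol = 2,
              dimnames = list(c("chr1:1-10", "chr1:20-30", "chr2:5-15"),
                              c("s1", "s2")))
  path <- tempfile(fileext = ".tsv")
  write_count_matrix(m, path)
  expect_equal(read_count_matrix(path), m)
})

test_that("counting from SAM matches the simulated matrix", {
  sim <- simulate_annotation(3, seed = 5)
  cm <- simulate_counts(sim, n_per_group = c(healthy = 2, sepsis = 2),
                        seed = 6, mean_range = c(5, 20),
                        sam_dir = tempfile("sams"))
  ins <- gr(cm$truth$chrom, cm$truth$start, cm$truth$end,
            cm$truth$alu_strand)
  names(ins) <- cm$truth$insertion_id
  mat <- build_count_matrix(stats::setNames(cm$samples$path,
                                            cm$samples$sample),
                            ins, strand_mode = "both")
  expect_equal(mat, cm$counts)
})
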