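make_counts <- function(values, ids) {
  ns <- length(values) / length(ids)
  matrix(as.integer(values), nrow = length(ids),
         dimnames = list(ids, paste0("S", seq_len(ns))))
}

test_that("coverage is reads divided by contig length", {
  counts <- make_counts(c(1000, 0), c("c1", "c2"))
  cov <- compute_coverage(counts, c(c1 = 2000, c2 = 500))
  expect_equal(unclass(cov)[, 1], c(c1 = 0.5, c2 = 0))
  expect_false(attr(cov, "transformed"))
})

test_that("coverage equals an elementwise quotient oracle on a random table", {
  set.seed(42)
  counts <- matrix(rpois(300, 50), 50, 6,
                   dimnames = list(sprintf("c%02d", 1:50), paste0("S", 1:6)))
  lens <- setNames(sample(2000:20000, 50), rownames(counts))
  cov <- compute_coverage(counts, lens)
  oracle <- counts
  storage.mode(oracle) <- "double"
  for (i in 1:50) for (j in 1:6) oracle[i, j] <- counts[i, j] / lens[i]
  expect_equal(unclass(cov), oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("coverage input errors name the offending contig", {
  counts <- make_counts(c(10, 20), c("c1", "c2"))
  expect_error(compute_coverage(counts, c(c1 = 100)), "c2")
  counts2 <- make_counts(c(10, -5), c("c1", "cBad"))
  expect_error(compute_coverage(counts2, c(c1 = 100, cBad = 100)), "cBad")
  counts3 <- make_counts(c(10, 5), c("c1", "cZero"))
  expect_error(compute_coverage(counts3, c(c1 = 100, cZero = 0)), "cZero")
})

test_that("transform scales once and only once", {
  cov <- compute_coverage(make_counts(1000, "c1"), c(c1 = 2000))
  t5 <- transform_coverage(cov, 5)
  expect_equal(unclass(t5)[1, 1], 2.5)
  expect_equal(attr(t5, "scale_factor"), 5)
  t1 <- transform_coverage(cov, 1)
  expect_equal(unclass(t1), unclass(cov), ignore_attr = TRUE)
  expect_error(transform_coverage(t5), "already transformed")
  expect_error(transform_coverage(cov, 0), "positive")
  expect_error(transform_coverage(cov, -2), "positive")
})

test_that("transforming coverage commutes with scaling the counts", {
  set.seed(1)
  counts <- matrix(rpois(60, 40), 10, 6,
                   dimnames = list(paste0("c", 1:10), paste0("S", 1:6)))
  lens <- setNames(rep(5000, 10), rownames(counts))
  a <- transform_coverage(compute_coverage(counts, lens), 5)
  b <- compute_coverage(counts * 5L, lens)
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("length filtering is inclusive and order preserving", {
  df <- data.frame(contig_id = c("a", "b", "c"),
                   length = c(7499, 7500, 7501))
  kept <- filter_contigs(df, 7500)
  expect_identical(kept$contig_id, c("b", "c"))
  expect_identical(filter_contigs(df, 0), df)

  set.seed(3)
  lens <- setNames(sample(500:30000, 1000), sprintf("c%04d", 1:1000))
  kept2 <- filter_contigs(lens, 2000)
  expect_identical(length(kept2), sum(lens >= 2000))  # independent recount
  expect_identical(names(kept2), names(lens)[lens >= 2000])
})

test_that("filter-then-coverage equals coverage-then-row-filter", {
  set.seed(9)
  counts <- matrix(rpois(40, 30), 10, 4,
                   dimnames = list(paste0("c", 1:10), paste0("S", 1:4)))
  lens <- setNames(sample(c(3000, 9000), 10, replace = TRUE),
                   rownames(counts))
  keep <- names(filter_contigs(lens, 7500))
  a <- compute_coverage(counts[keep, , drop = FALSE], lens)
  b <- compute_coverage(counts, lens)
  expect_equal(unclass(a), unclass(b)[keep, , drop = FALSE], ignore_attr = TRUE)
})

test_that("recruitment fraction handles full, partial and empty recruitment", {
  counts <- make_counts(c(60, 40, 0, 0), c("c1", "c2"))
  expect_equal(recruitment_fraction(counts, c("c1", "c2")),
               c(S1 = 100, S2 = NA))
  half <- make_counts(c(50, 50), c("c1", "c2"))
  expect_equal(recruitment_fraction(half, "c1"), c(S1 = 50))
  expect_error(recruitment_fraction(half, c("c1", "c2"), total_reads = 10),
               "smaller")
  # hand-summed oracle on a random fixture
  set.seed(5)
  m <- matrix(rpois(30, 20), 10, 3,
              dimnames = list(paste0("c", 1:10), paste0("S", 1:3)))
  sub <- paste0("c", 1:4)
  expect_equal(recruitment_fraction(m, sub),
               100 * colSums(m[sub, ]) / colSums(m))
})

test_that("coverage TSV round-trips with its transform state", {
  cov <- transform_coverage(
    compute_coverage(make_counts(c(100, 300, 40, 80), c("c1", "c2")),
                     c(c1 = 1000, c2 = 4000)), 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coverage_tsv(cov, path)
  back <- read_coverage_tsv(path)
  expect_equal(unclass(back), unclass(cov), tolerance = 1e-9)
  expect_true(attr(back, "transformed"))
  expect_equal(attr(back, "scale_factor"), 5)
})

test_that("SAM ingestion counts primary mapped alignments only", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:c1\tLN:1000",
    "@SQ\tSN:c2\tLN:800",
    paste("r1", 0, "c1", 1, 60, "50M", "*", 0, 0,
          paste(rep("A", 50), collapse = ""), "*", sep = "\t"),
    paste("r2", 16, "c1", 100, 60, "50M", "*", 0, 0,
          paste(rep("C", 50), collapse = ""), "*", sep = "\t"),
    paste("r3", 0, "c2", 5, 60, "50M", "*", 0, 0,
          paste(rep("G", 50), collapse = ""), "*", sep = "\t"),
    paste("r4", 256, "c1", 1, 60, "50M", "*", 0, 0, "*", "*", sep = "\t"),
    paste("r5", 4, "*", 0, 0, "*", "*", 0, 0,
          paste(rep("T", 50), collapse = ""), "*", sep = "\t")), sam)
  counts <- count_reads_sam(sam)
  expect_equal(counts, c(c1 = 2L, c2 = 1L))
})
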