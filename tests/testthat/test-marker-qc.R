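mk_rows <- function(marker_id, contig_id, identity = 1.0) {
  data.frame(genome_id = "G", marker_id = marker_id, contig_id = contig_id,
             start = 0L, end = 900L, identity = identity,
             stringsAsFactors = FALSE)
}

test_that("marker tallies match hand counts", {
  uni <- marker_universe(4)
  tab <- mk_rows(c("M001", "M001", "M002", "M003"),
                 c("c1", "c2", "c1", "c9"))
  expect_equal(tally_markers(character(0), tab, uni),
               c(M001 = 0L, M002 = 0L, M003 = 0L, M004 = 0L))
  expect_equal(tally_markers(c("c1", "c2"), tab, uni),
               c(M001 = 2L, M002 = 1L, M003 = 0L, M004 = 0L))
  expect_equal(tally_markers(c("c1", "c2", "c9"), tab, uni),
               c(M001 = 2L, M002 = 1L, M003 = 1L, M004 = 0L))
})

test_that("completeness and contamination follow the copy-count definitions", {
  M <- 104
  all_once <- setNames(rep(1L, M), marker_universe(M))
  expect_equal(completeness(all_once), 100)
  expect_equal(contamination(all_once), 0)

  none <- setNames(rep(0L, M), marker_universe(M))
  expect_equal(completeness(none), 0)

  half <- setNames(c(rep(1L, 52), rep(0L, 52)), marker_universe(M))
  expect_equal(completeness(half), 50)

  doubled <- setNames(rep(2L, M), marker_universe(M))
  expect_equal(contamination(doubled), 100)
  expect_equal(completeness(doubled), 100)
})

test_that("strain heterogeneity counts near-identical duplicate pairs", {
  expect_equal(strain_heterogeneity(mk_rows("M001", "c1")), 0)

  dup_same <- mk_rows(c("M001", "M001", "M002", "M002"),
                      c("c1", "c2", "c1", "c2"), identity = 1.0)
  expect_equal(strain_heterogeneity(dup_same), 100)

  # 4 duplicate pairs, 3 with pairwise identity above the 0.9 threshold
  rows <- mk_rows(rep(c("M001", "M002", "M003", "M004"), each = 2),
                  rep(c("c1", "c2"), 4),
                  identity = c(1.0, 0.95,   # pairwise 0.95 -> strain
                               0.9, 0.88,   # pairwise 0.98 -> strain
                               1.0, 0.92,   # pairwise 0.92 -> strain
                               1.0, 0.60))  # pairwise 0.60 -> distinct
  expect_equal(strain_heterogeneity(rows), 75)
})

test_that("cumulative redundancy discounts contamination by strain heterogeneity", {
  expect_equal(cumulative_redundancy(20, 50), 10)
  expect_equal(cumulative_redundancy(85, 100), 0)
  expect_equal(cumulative_redundancy(37.5, 0), 37.5)
  # stays within [0, contamination] across the whole strain range
  for (sh in seq(0, 100, by = 12.5)) {
    cr <- cumulative_redundancy(60, sh)
    expect_gte(cr, 0)
    expect_lte(cr, 60)
  }
})

test_that("triage respects the inclusive 50%/10% boundaries", {
  expect_equal(triage_bin(50.0, 10.0), "draft")
  expect_equal(triage_bin(49.9, 0), "low_completion")
  expect_equal(triage_bin(80, 25), "high_contamination")
  expect_equal(triage_bin(100, 0), "draft")
  expect_equal(triage_bin(50, 10.01), "high_contamination")
})

test_that("genome count estimate tracks merged complete genomes", {
  expect_equal(estimate_genome_count(0), 1L)
  expect_equal(estimate_genome_count(100), 2L)
  expect_equal(estimate_genome_count(310), 4L)
  expect_equal(estimate_genome_count(5), 1L)
})

test_that("adding duplicates never decreases contamination nor changes completeness", {
  uni <- marker_universe(10)
  base <- mk_rows(uni, sprintf("c%d", 1:10))
  counts0 <- tally_markers(sprintf("c%d", 1:10), base, uni)
  for (i in 1:5) {
    extra <- rbind(base, mk_rows(sample(uni, i), rep("c1", i)))
    counts1 <- tally_markers(sprintf("c%d", 1:10), extra, uni)
    expect_gte(contamination(counts1), contamination(counts0))
    expect_equal(completeness(counts1), completeness(counts0))
  }
})

test_that("merging bins dominates both parents in completeness and contamination", {
  uni <- marker_universe(8)
  tab <- rbind(mk_rows(uni[1:6], rep("a1", 6)),
               mk_rows(uni[4:8], rep("b1", 5)))
  ca <- tally_markers("a1", tab, uni)
  cb <- tally_markers("b1", tab, uni)
  cm <- tally_markers(c("a1", "b1"), tab, uni)
  expect_gte(completeness(cm), max(completeness(ca), completeness(cb)))
  expect_gte(contamination(cm), contamination(ca))
  expect_gte(contamination(cm), contamination(cb))
})

test_that("two merged complete genomes score contamination 100", {
  uni <- marker_universe(20)
  tab <- rbind(mk_rows(uni, rep("g1c1", 20), identity = 0.95),
               mk_rows(uni, rep("g2c1", 20), identity = 0.55))
  counts <- tally_markers(c("g1c1", "g2c1"), tab, uni)
  expect_equal(contamination(counts), 100)
  qc <- bin_qc(list(m = c("g1c1", "g2c1")), tab, uni)
  expect_equal(qc$strain_heterogeneity, 0)   # pairwise identity 0.6 < 0.9
  expect_equal(qc$cumulative_redundancy, 100)
  expect_equal(qc$category, "high_contamination")
  expect_equal(qc$est_genomes, 2L)
})

test_that("clean single-genome bins report a perfect draft", {
  uni <- marker_universe(104)
  tab <- mk_rows(uni, sprintf("c%03d", rep(1:13, each = 8)))
  qc <- bin_qc(list(g = sprintf("c%03d", 1:13)), tab, uni)
  expect_equal(qc$completeness, 100)
  expect_equal(qc$contamination, 0)
  expect_equal(qc$strain_heterogeneity, 0)
  expect_equal(qc$cumulative_redundancy, 0)
  expect_equal(qc$category, "draft")
})

test_that("HMMER tabular hits convert to a marker table", {
  path <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c(
    "#                                        --- full sequence ----",
    "# target name  accession  query name  accession  E-value  score",
    "contig_1  -  M001  -  1e-30  100.0",
    "contig_2  -  M002  -  1e-20  80.0"), path)
  tab <- read_hmmer_tblout(path)
  expect_equal(tab$contig_id, c("contig_1", "contig_2"))
  expect_equal(tab$marker_id, c("M001", "M002"))
  expect_equal(tab$identity, c(1, 1))
})
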