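test_that("fragment_genome honours boundaries and the constant law", {
  law_const <- list(type = "constant", length = 2500, min_length = 2000)
  expect_identical(fragment_genome(10000, law_const), rep(2500L, 4))

  law_ln <- list(type = "lognormal", meanlog = log(9000), sdlog = 0.5,
                 min_length = 7500)
  expect_identical(fragment_genome(7500, law_ln, seed = 1), 7500L)
  expect_error(fragment_genome(1000, law_ln, genome_id = "G99"), "G99")

  expect_identical(fragment_genome(2e6, law_ln, seed = 7),
                   fragment_genome(2e6, law_ln, seed = 7))
})

test_that("fragment lengths follow the truncated log-normal law", {
  law <- list(type = "lognormal", meanlog = 9.2, sdlog = 0.8,
              min_length = 2000)
  lens <- fragment_genome(2e6, law, seed = 7)
  expect_true(all(lens >= 2000))
  expect_lte(sum(lens), 2e6)
  # independent Monte-Carlo oracle of the same truncated law
  oracle_mean <- magladder:::with_seed(99, {
    p0 <- plnorm(2000, 9.2, 0.8)
    mean(round(qlnorm(runif(1e5, p0, 1), 9.2, 0.8)))
  })
  expect_lt(abs(mean(lens) - oracle_mean) / oracle_mean, 0.10)
})

test_that("read counts match the stated moment structure", {
  expect_identical(sample_read_counts(0, 10000, seed = 1), 0L)

  # dispersion 0 degenerates to Poisson: mean 500 over 1e4 replicates
  x <- sample_read_counts(rep(0.05, 1e4), 10000, dispersion = 0, seed = 3)
  se <- sqrt(500 / 1e4)
  expect_lt(abs(mean(x) - 500), 3 * se)

  # NB with dispersion 2: variance/mean ratio 1 + dispersion = 3
  y <- sample_read_counts(rep(0.05, 1e4), 10000, dispersion = 2, seed = 4)
  expect_lt(abs(var(y) / mean(y) - 3) / 3, 0.15)
})

test_that("simulated community is cross-consistent with its truth tables", {
  cfg <- community_config(n_genomes = 3, n_samples = 4,
                          genome_length_range = c(3e5, 4e5),
                          sequences = FALSE, seed = 5)
  com <- simulate_community(cfg)

  # every contig maps to exactly one genome
  expect_setequal(names(com$truth$contig_to_genome), com$contigs$contig_id)
  expect_false(anyDuplicated(com$contigs$contig_id) > 0)

  # observed per-genome reads/bp close to the truth coverage matrix
  for (g in rownames(com$truth$genome_coverage)) {
    ids <- com$contigs$contig_id[com$contigs$genome_id == g]
    obs <- colSums(com$counts[ids, ]) / sum(com$lengths[ids])
    rel <- abs(obs - com$truth$genome_coverage[g, ]) /
      com$truth$genome_coverage[g, ]
    expect_lt(max(rel), 0.10)
  }

  # marker conservation and coordinates within the host contig
  expect_equal(unname(table(com$markers$genome_id)),
               rep(cfg$marker_set_size, 3), ignore_attr = TRUE)
  expect_true(all(com$markers$start >= 0))
  expect_true(all(com$markers$end <= com$lengths[com$markers$contig_id]))
})

test_that("single-genome single-sample community is degenerate but valid", {
  com <- simulate_community(community_config(
    n_genomes = 1, n_samples = 1, genome_length_range = c(1e5, 1e5),
    sequences = FALSE, seed = 2))
  expect_true(all(com$contigs$genome_id == "G01"))
  expect_true(all(com$counts >= 0))
})

test_that("community generation is deterministic, including sequences", {
  cfg <- community_config(n_genomes = 2, n_samples = 2,
                          genome_length_range = c(5e4, 6e4),
                          sequences = TRUE, seed = 11)
  a <- simulate_community(cfg)
  b <- simulate_community(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$markers, b$markers)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
})

test_that("duplicated markers with copy identity 1 give 100/100 QC", {
  com <- simulate_community(community_config(
    n_genomes = 1, n_samples = 2, genome_length_range = c(2e5, 2e5),
    marker_copy_number = 2, marker_copy_identity = 1.0,
    sequences = FALSE, seed = 3))
  qc <- bin_qc(list(bin1 = com$contigs$contig_id), com$markers)
  expect_equal(qc$contamination, 100)
  expect_equal(qc$strain_heterogeneity, 100)
  expect_equal(qc$cumulative_redundancy, 0)
})

test_that("infeasible marker placement is rejected", {
  cfg <- community_config(n_genomes = 1, n_samples = 1,
                          genome_length_range = c(8000, 9000),
                          marker_length = 20000, sequences = FALSE, seed = 1)
  expect_error(simulate_community(cfg), "markers exceed genome length")
})

test_that("community files are byte-identical across rewrites", {
  com <- simulate_community(community_config(
    n_genomes = 2, n_samples = 3, genome_length_range = c(5e4, 6e4),
    sequences = TRUE, seed = 8))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_community(com, d1)
  write_community(com, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # round trip of the counts table
  tab <- read_counts_tsv(file.path(d1, "counts.tsv"))
  expect_equal(tab$counts, com$counts)
  expect_equal(tab$lengths, com$lengths)
  mk <- read_marker_tsv(file.path(d1, "markers.tsv"))
  expect_equal(mk, com$markers)
})

test_that("unassigned_fraction adds markerless noise contigs", {
  com <- simulate_community(community_config(
    n_genomes = 2, n_samples = 3, genome_length_range = c(2e5, 3e5),
    unassigned_fraction = 0.2, sequences = FALSE, seed = 6))
  noise <- grepl("^noise", com$contigs$genome_id)
  frac <- mean(noise)
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.3)
  expect_false(any(com$markers$contig_id %in% com$contigs$contig_id[noise]))
})
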