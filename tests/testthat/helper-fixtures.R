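# Shared fixtures and independent oracles.

# Exhaustive-search oracle: maximum net similarity over all non-empty
# exemplar subsets of a similarity matrix (diagonal = preferences).
# Feasible for n <= 12.
ap_oracle_net_similarity <- function(S) {
  n <- nrow(S)
  stopifnot(n <= 12)
  best <- -Inf
  bits <- 2^(0:(n - 1))
  for (mask in seq_len(2^n - 1)) {
    ex <- which(bitwAnd(mask, bits) > 0)
    net <- sum(diag(S)[ex])
    non <- setdiff(seq_len(n), ex)
    if (length(non) > 0)
      net <- net + sum(apply(S[non, ex, drop = FALSE], 1, max))
    if (net > best) best <- net
  }
  best
}

# Gaussian blobs around given centers (rows), n_per points each.
make_blobs <- function(centers, n_per, spread, seed = 1) {
  magladder:::with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(b) {
      matrix(rnorm(n_per * ncol(centers), sd = spread), n_per) +
        matrix(centers[b, ], n_per, ncol(centers), byrow = TRUE)
    }))
    rownames(pts) <- sprintf("p%02d", seq_len(nrow(pts)))
    pts
  })
}

# The shipped small (n <= 12) clustering fixtures: feature matrix,
# preference, and the true blob partition where meaningful.
shipped_small_fixtures <- function() {
  three_blobs <- make_blobs(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 10)),
                            n_per = 4, spread = 0.05, seed = 11)
  two_blobs <- make_blobs(rbind(c(0, 0), c(30, 30)), n_per = 4,
                          spread = 0.1, seed = 12)
  one_cloud <- make_blobs(rbind(c(1, 1, 1)), n_per = 10, spread = 0.05,
                          seed = 13)
  dup <- matrix(c(0, 0, 5, 5, 9, 0), ncol = 2,
                byrow = TRUE)[rep(1:3, each = 3), ]
  rownames(dup) <- sprintf("d%d", 1:9)
  list(
    three_blobs_p3 = list(features = three_blobs, preference = -3,
                          truth = rep(1:3, each = 4)),
    three_blobs_p100 = list(features = three_blobs, preference = -100,
                            truth = NULL),
    three_blobs_p1000 = list(features = three_blobs, preference = -1000,
                             truth = NULL),
    two_blobs_p100 = list(features = two_blobs, preference = -100,
                          truth = rep(1:2, each = 4)),
    one_cloud_p3 = list(features = one_cloud, preference = -3,
                        truth = rep(1, 10)),
    duplicates_p3 = list(features = dup, preference = -3,
                         truth = rep(1:3, each = 3)))
}

# Pure-R dictionary 4-mer counter (independent of Biostrings).
oracle_tetramers <- function(seq) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  chars <- strsplit(seq, "")[[1]]
  counts <- new.env()
  n <- length(chars)
  for (i in seq_len(max(0, n - 3))) {
    w <- paste(chars[i:(i + 3)], collapse = "")
    if (grepl("[^ACGT]", w)) next
    key <- min(w, rc(w))
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  vals <- unlist(as.list(counts))
  vals / sum(vals)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-constructed multi-genome fixture with full control over coverage
# rows and marker identities; mimics the community layout without
# sequences. Each genome gets n_contigs of contig_len bp and one copy of
# every marker, cycled over its contigs at start 0.
make_fixture_community <- function(genome_cov, n_contigs, contig_len = 10000,
                                   identities = NULL, dispersion = 0.5,
                                   marker_n = 104, marker_len = 900,
                                   seed = 1) {
  G <- nrow(genome_cov)
  S <- ncol(genome_cov)
  genome_ids <- sprintf("G%02d", seq_len(G))
  rownames(genome_cov) <- genome_ids
  colnames(genome_cov) <- sprintf("S%02d", seq_len(S))
  if (is.null(identities)) identities <- seq(0.95, by = -0.3 / G, length.out = G)
  if (length(n_contigs) == 1) n_contigs <- rep(n_contigs, G)
  contig_id <- unlist(lapply(seq_len(G), function(g)
    sprintf("%s_c%03d", genome_ids[g], seq_len(n_contigs[g]))))
  genome_of <- rep(genome_ids, n_contigs)
  lengths <- stats::setNames(rep(contig_len, length(contig_id)), contig_id)
  counts <- magladder:::with_seed(seed, {
    m <- matrix(0L, length(contig_id), S,
                dimnames = list(contig_id, colnames(genome_cov)))
    for (s in seq_len(S)) {
      m[, s] <- sample_read_counts(genome_cov[genome_of, s], lengths,
                                   dispersion = dispersion)
    }
    m
  })
  markers <- do.call(rbind, lapply(seq_len(G), function(g) {
    host <- sprintf("%s_c%03d", genome_ids[g],
                    ((seq_len(marker_n) - 1) %% n_contigs[g]) + 1)
    data.frame(genome_id = genome_ids[g],
               marker_id = sprintf("M%03d", seq_len(marker_n)),
               contig_id = host, start = 0L, end = marker_len,
               identity = identities[g], stringsAsFactors = FALSE)
  }))
  list(counts = counts, lengths = lengths, markers = markers,
       truth = list(contig_to_genome = stats::setNames(genome_of, contig_id),
                    genome_coverage = genome_cov))
}

# Memoised heavyweight fixtures shared across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# The fixed-seed recovery community: 20 genomes, 6 samples, log-normal
# abundances (sigma_log 1.0), NB dispersion 0.5, >= 200 contigs per genome.
recovery_community <- function() {
  cached("recovery_com", simulate_community(community_config(seed = 1)))
}

recovery_fit <- function() {
  cached("recovery_fit", mag_pipeline(recovery_community()))
}
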