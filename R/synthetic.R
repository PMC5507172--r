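#' Configuration for a synthetic multi-sample metagenome community
#'
#' Bundles every knob of the community generator. The defaults describe the
#' regime the binning pipeline targets: a low-coverage multi-sample survey in
#' which genomes differ in mean abundance by orders of magnitude (log-normal
#' across genomes) and each genome keeps a characteristic coverage profile
#' across samples.
#'
#' @param n_genomes Number of genomes with recoverable truth.
#' @param n_samples Number of samples (columns of the count table).
#' @param genome_length_range Two-element vector, uniform range of genome
#'   lengths in bp.
#' @param marker_set_size Number of distinct universal single-copy markers
#'   placed on every genome.
#' @param marker_length Length of each placed marker, bp.
#' @param contig_length_law Contig length distribution: a list with
#'   `type = "lognormal"` (`meanlog`, `sdlog` in log-bp, truncated at
#'   `min_length`) or `type = "constant"` (`length`), plus `min_length` (bp).
#' @param abundance_law Per-genome per-sample mean coverage (reads/bp) model:
#'   list with `mean_coverage` (median coverage of a typical genome),
#'   `sigma_log` (between-genome log-sd), `sample_sigma` (within-genome
#'   between-sample log-sd) and `rho` (between-sample correlation of the
#'   within-genome noise).
#' @param read_length Nominal read length in bp (recorded for provenance;
#'   counts are parameterized directly in reads).
#' @param dispersion Overdispersion of the read-count model: counts are
#'   negative binomial with variance = mean * (1 + dispersion); 0 gives
#'   Poisson counts.
#' @param unassigned_fraction Fraction of contigs drawn from "noise" genomes
#'   (independent coverage profiles, no markers) that no bin should recover.
#' @param marker_copy_number Copies of each marker placed per genome (1 =
#'   clean single-copy; >1 builds contamination fixtures).
#' @param marker_copy_identity Identity of extra copies to the primary copy,
#'   in `[0, 1]`; only used when `marker_copy_number > 1`.
#' @param divergence_range Uniform range of each genome's divergence from the
#'   universal marker reference; marker rows carry identity
#'   `1 - divergence`.
#' @param composition_bias Strength in `[0, 1)` of a per-genome Dirichlet
#'   perturbation of the nucleotide transition table; 0 gives i.i.d. uniform
#'   sequence.
#' @param sequences Logical; generate nucleotide sequences for the contigs.
#' @param seed Integer seed; the whole community is a deterministic function
#'   of the configuration including this seed.
#' @return An object of class `community_config` (a validated list).
#' @seealso [simulate_community()]
#' @export
community_config <- function(n_genomes = 20,
                             n_samples = 6,
                             genome_length_range = c(2.4e6, 3.0e6),
                             marker_set_size = 104,
                             marker_length = 900,
                             contig_length_law = list(type = "lognormal",
                                                      meanlog = log(8500),
                                                      sdlog = 0.45,
                                                      min_length = 7500),
                             abundance_law = list(mean_coverage = 0.3,
                                                  sigma_log = 1.0,
                                                  sample_sigma = 0.6,
                                                  rho = 0.3),
                             read_length = 100,
                             dispersion = 0.5,
                             unassigned_fraction = 0,
                             marker_copy_number = 1,
                             marker_copy_identity = 1.0,
                             divergence_range = c(0, 0.5),
                             composition_bias = 0,
                             sequences = TRUE,
                             seed = 1) {
  cfg <- list(n_genomes = as.integer(n_genomes),
              n_samples = as.integer(n_samples),
              genome_length_range = as.numeric(genome_length_range),
              marker_set_size = as.integer(marker_set_size),
              marker_length = as.integer(marker_length),
              contig_length_law = contig_length_law,
              abundance_law = abundance_law,
              read_length = as.integer(read_length),
              dispersion = as.numeric(dispersion),
              unassigned_fraction = as.numeric(unassigned_fraction),
              marker_copy_number = as.integer(marker_copy_number),
              marker_copy_identity = as.numeric(marker_copy_identity),
              divergence_range = as.numeric(divergence_range),
              composition_bias = as.numeric(composition_bias),
              sequences = isTRUE(sequences),
              seed = as.integer(seed))
  validate_community_config(cfg)
  structure(cfg, class = "community_config")
}

validate_community_config <- function(cfg) {
  stopifnot(cfg$n_genomes >= 1, cfg$n_samples >= 1,
            length(cfg$genome_length_range) == 2,
            all(cfg$genome_length_range > 0),
            cfg$genome_length_range[1] <= cfg$genome_length_range[2],
            cfg$marker_set_size >= 1, cfg$marker_length > 0,
            cfg$read_length > 0, cfg$dispersion >= 0,
            cfg$unassigned_fraction >= 0, cfg$unassigned_fraction < 1,
            cfg$marker_copy_number >= 1,
            cfg$marker_copy_identity >= 0, cfg$marker_copy_identity <= 1,
            cfg$composition_bias >= 0, cfg$composition_bias < 1)
  law <- cfg$contig_length_law
  if (is.null(law$min_length) || law$min_length <= 0)
    stop("contig_length_law$min_length must be a positive length in bp")
  if (!law$type %in% c("lognormal", "constant"))
    stop("contig_length_law$type must be 'lognormal' or 'constant'")
  if (law$type == "constant" && law$length < law$min_length)
    stop("constant contig length below min_length")
  invisible(cfg)
}

#' @export
print.community_config <- function(x, ...) {
  cat("Synthetic community configuration\n")
  cat(sprintf("  genomes: %d (%.2g-%.2g Mbp), samples: %d, seed: %d\n",
              x$n_genomes, x$genome_length_range[1] / 1e6,
              x$genome_length_range[2] / 1e6, x$n_samples, x$seed))
  cat(sprintf("  markers: %d x %d bp, copy number %d\n",
              x$marker_set_size, x$marker_length, x$marker_copy_number))
  cat(sprintf("  coverage: median %.3g reads/bp, sigma_log %.2f, dispersion %.2f\n",
              x$abundance_law$mean_coverage, x$abundance_law$sigma_log,
              x$dispersion))
  invisible(x)
}

# Draw one value from the configured contig-length law, truncated below at
# min_length (inverse-CDF sampling keeps the truncation exact).
draw_contig_length <- function(n, law) {
  if (law$type == "constant") return(rep(law$length, n))
  p0 <- plnorm(law$min_length, law$meanlog, law$sdlog)
  round(qlnorm(runif(n, p0, 1), law$meanlog, law$sdlog))
}

#' Fragment a genome into contig lengths
#'
#' Splits a genome of known length into contigs whose lengths follow the
#' configured law truncated below at `min_length`. Lengths are drawn until the
#' unallocated remainder falls below `min_length`; a draw longer than the
#' remainder is capped at the remainder (which is itself at least
#' `min_length`), and any final sub-minimum remainder is discarded, so the
#' lengths sum to at most the genome length.
#'
#' @param genome_length Genome length, bp (must be at least
#'   `law$min_length`).
#' @param law Contig length law, see [community_config()].
#' @param seed Optional integer; when given the draw is performed under a
#'   private RNG stream and is reproducible.
#' @param genome_id Label used in error messages.
#' @return Integer vector of contig lengths (bp), each `>= law$min_length`,
#'   summing to at most `genome_length`.
#' @export
fragment_genome <- function(genome_length, law, seed = NULL,
                            genome_id = "genome") {
  if (genome_length < law$min_length)
    stop(sprintf("%s is shorter (%d bp) than the minimum contig length (%d bp)",
                 genome_id, as.integer(genome_length),
                 as.integer(law$min_length)))
  run <- function() {
    lens <- integer(0)
    remaining <- as.numeric(genome_length)
    while (remaining >= law$min_length) {
      len <- draw_contig_length(1L, law)
      if (len > remaining) len <- remaining
      lens <- c(lens, as.integer(len))
      remaining <- remaining - len
    }
    lens
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Draw read counts for contigs under an overdispersed count model
#'
#' Counts are negative binomial with mean `true_coverage * contig_length`
#' and variance `mean * (1 + dispersion)`; `dispersion = 0` degenerates to
#' Poisson. A zero mean yields a zero count with probability 1.
#'
#' @param true_coverage Mean coverage in reads/bp (recycled).
#' @param contig_length Contig length in bp (recycled).
#' @param read_length Nominal read length (recorded only; the model is
#'   parameterized in read counts).
#' @param dispersion Overdispersion, `>= 0`.
#' @param seed Optional integer for a private reproducible RNG stream.
#' @return Integer vector of read counts.
#' @export
sample_read_counts <- function(true_coverage, contig_length,
                               read_length = 100, dispersion = 0,
                               seed = NULL) {
  stopifnot(all(true_coverage >= 0), all(contig_length >= 0), dispersion >= 0)
  mu <- true_coverage * contig_length
  run <- function() {
    out <- numeric(length(mu))
    pos <- mu > 0
    if (any(pos)) {
      out[pos] <- if (dispersion == 0) {
        rpois(sum(pos), mu[pos])
      } else {
        rnbinom(sum(pos), mu = mu[pos], size = mu[pos] / dispersion)
      }
    }
    out
  }
  counts <- if (is.null(seed)) run() else with_seed(seed, run())
  as.integer(round(counts))
}

# One row of a Dirichlet draw (via gamma variates).
rdirichlet_row <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Generate one nucleotide sequence. With a transition table (4x4, rows sum to
# 1) a first-order Markov chain is used; otherwise i.i.d. uniform bases.
random_sequence <- function(len, trans = NULL) {
  bases <- c("A", "C", "G", "T")
  if (is.null(trans)) {
    return(paste(sample(bases, len, replace = TRUE), collapse = ""))
  }
  cum <- t(apply(trans, 1, cumsum))
  idx <- integer(len)
  idx[1] <- sample.int(4L, 1L)
  u <- runif(len)
  for (i in seq_len(len - 1L)) {
    idx[i + 1L] <- findInterval(u[i + 1L], cum[idx[i], ]) + 1L
  }
  paste(bases[idx], collapse = "")
}

#' Simulate a multi-sample synthetic metagenome community
#'
#' Generates genomes, fragments them into contigs, assigns each genome a
#' per-sample mean coverage (reads/bp) profile, draws per-contig per-sample
#' read counts from the overdispersed count model, and places the universal
#' single-copy marker set on every genome with known coordinates (0-based,
#' half-open). The returned truth tables are the oracle for downstream
#' binning and QC tests. The whole object is a deterministic function of the
#' configuration.
#'
#' @param config A [community_config()].
#' @return An object of class `mag_community`: a list with
#'   \describe{
#'     \item{contigs}{data.frame `contig_id`, `length`, `genome_id`.}
#'     \item{counts}{integer matrix contigs x samples (rownames = contig
#'       ids).}
#'     \item{lengths}{named integer vector of contig lengths.}
#'     \item{sequences}{`Biostrings::DNAStringSet` or `NULL`.}
#'     \item{markers}{data.frame `genome_id`, `marker_id`, `contig_id`,
#'       `start`, `end`, `identity`.}
#'     \item{truth}{list `contig_to_genome` (named character),
#'       `genome_coverage` (genomes x samples), `marker_placements`
#'       (same as `markers`), `divergence` (named per-genome).}
#'     \item{config}{the configuration.}
#'   }
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  with_seed(config$seed, simulate_community_impl(config))
}

simulate_community_impl <- function(cfg) {
  G <- cfg$n_genomes
  S <- cfg$n_samples
  law <- cfg$contig_length_law
  ab <- cfg$abundance_law
  genome_ids <- sprintf("G%02d", seq_len(G))
  sample_ids <- sprintf("S%02d", seq_len(S))

  genome_lengths <- round(runif(G, cfg$genome_length_range[1],
                                cfg$genome_length_range[2]))

  # per-genome per-sample true mean coverage (reads/bp)
  base <- rnorm(G, log(ab$mean_coverage), ab$sigma_log)
  shared <- rnorm(G)
  eps <- ab$sample_sigma *
    (sqrt(ab$rho) * matrix(shared, G, S) +
       sqrt(1 - ab$rho) * matrix(rnorm(G * S), G, S))
  genome_coverage <- exp(matrix(base, G, S) + eps)
  dimnames(genome_coverage) <- list(genome_ids, sample_ids)

  # fragment each genome
  contig_id <- character(0)
  contig_len <- integer(0)
  contig_genome <- character(0)
  for (g in seq_len(G)) {
    lens <- fragment_genome(genome_lengths[g], law, genome_id = genome_ids[g])
    ids <- sprintf("%s_c%03d", genome_ids[g], seq_along(lens))
    contig_id <- c(contig_id, ids)
    contig_len <- c(contig_len, lens)
    contig_genome <- c(contig_genome, rep(genome_ids[g], length(lens)))
  }

  # noise contigs: independent coverage profiles, no markers
  noise_coverage <- NULL
  if (cfg$unassigned_fraction > 0) {
    n_true <- length(contig_id)
    n_noise <- max(1L, round(cfg$unassigned_fraction /
                               (1 - cfg$unassigned_fraction) * n_true))
    noise_len <- draw_contig_length(n_noise, law)
    noise_ids <- sprintf("noise_%04d_c001", seq_len(n_noise))
    noise_genomes <- sprintf("noise_%04d", seq_len(n_noise))
    noise_coverage <- exp(matrix(rnorm(n_noise * S, log(ab$mean_coverage),
                                       ab$sigma_log), n_noise, S))
    dimnames(noise_coverage) <- list(noise_genomes, sample_ids)
    contig_id <- c(contig_id, noise_ids)
    contig_len <- c(contig_len, as.integer(noise_len))
    contig_genome <- c(contig_genome, noise_genomes)
  }

  n <- length(contig_id)
  lengths <- setNames(as.integer(contig_len), contig_id)

  # per-contig per-sample counts from the host genome's coverage row
  cov_rows <- rbind(genome_coverage, noise_coverage)[contig_genome, ,
                                                     drop = FALSE]
  counts <- matrix(0L, n, S, dimnames = list(contig_id, sample_ids))
  for (s in seq_len(S)) {
    counts[, s] <- sample_read_counts(cov_rows[, s], contig_len,
                                      read_length = cfg$read_length,
                                      dispersion = cfg$dispersion)
  }

  # marker placement: marker_set_size distinct markers per genome,
  # marker_copy_number copies each, coordinates 0-based half-open
  marker_ids <- sprintf("M%03d", seq_len(cfg$marker_set_size))
  divergence <- setNames(runif(G, cfg$divergence_range[1],
                               cfg$divergence_range[2]), genome_ids)
  mk <- vector("list", G)
  for (g in seq_len(G)) {
    gmask <- contig_genome == genome_ids[g] & contig_len >= cfg$marker_length
    host_ids <- contig_id[gmask]
    host_len <- contig_len[gmask]
    if (length(host_ids) == 0)
      stop(sprintf("markers exceed genome length: no contig of %s can hold a %d bp marker",
                   genome_ids[g], cfg$marker_length))
    ncopies <- cfg$marker_copy_number
    nrows <- cfg$marker_set_size * ncopies
    pick <- sample.int(length(host_ids), nrows, replace = TRUE,
                       prob = host_len)
    start <- floor(runif(nrows) * (host_len[pick] - cfg$marker_length + 1))
    id_primary <- round(1 - divergence[g], 4)
    identity <- rep(c(id_primary,
                      rep(max(0, id_primary - (1 - cfg$marker_copy_identity)),
                          ncopies - 1L)),
                    times = cfg$marker_set_size)
    mk[[g]] <- data.frame(genome_id = genome_ids[g],
                          marker_id = rep(marker_ids, each = ncopies),
                          contig_id = host_ids[pick],
                          start = as.integer(start),
                          end = as.integer(start + cfg$marker_length),
                          identity = identity,
                          stringsAsFactors = FALSE)
  }
  markers <- do.call(rbind, mk)
  rownames(markers) <- NULL

  sequences <- NULL
  if (cfg$sequences) {
    trans <- NULL
    seqs <- character(n)
    all_genomes <- unique(contig_genome)
    for (gn in all_genomes) {
      idx <- which(contig_genome == gn)
      if (cfg$composition_bias > 0) {
        alpha <- rep(4 * (1 / cfg$composition_bias - 1), 4)
        trans <- t(vapply(1:4, function(i) rdirichlet_row(alpha),
                          numeric(4)))
      }
      for (i in idx) seqs[i] <- random_sequence(contig_len[i], trans)
    }
    sequences <- Biostrings::DNAStringSet(setNames(seqs, contig_id))
  }

  structure(list(
    contigs = data.frame(contig_id = contig_id, length = lengths,
                         genome_id = contig_genome,
                         stringsAsFactors = FALSE, row.names = NULL),
    counts = counts,
    lengths = lengths,
    sequences = sequences,
    markers = markers,
    truth = list(contig_to_genome = setNames(contig_genome, contig_id),
                 genome_coverage = genome_coverage,
                 noise_coverage = noise_coverage,
                 marker_placements = markers,
                 divergence = divergence),
    config = cfg), class = "mag_community")
}

#' @export
print.mag_community <- function(x, ...) {
  cat(sprintf("Synthetic community: %d genomes, %d contigs, %d samples (seed %d)\n",
              x$config$n_genomes, nrow(x$contigs), x$config$n_samples,
              x$config$seed))
  cat(sprintf("  contig lengths %d-%d bp (median %d); %d marker rows\n",
              min(x$lengths), max(x$lengths), as.integer(median(x$lengths)),
              nrow(x$markers)))
  invisible(x)
}

provenance_header <- function(what, seed) {
  sprintf("# magladder %s seed=%d", what, as.integer(seed))
}

#' Write a synthetic community to plain-text files
#'
#' Writes `contigs.fasta` (when sequences are present), `counts.tsv`
#' (contig_id, length, one integer column per sample), `truth.tsv`
#' (contig_id, genome_id), `markers.tsv` and `genome_coverage.tsv`. Each TSV
#' carries a `#` provenance line echoing the seed. Reruns with the same
#' community object are byte-identical.
#'
#' @param community A [simulate_community()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "mag_community"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- community$config$seed
  files <- character(0)

  write_tsv_with_header <- function(df, path, what) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(provenance_header(what, seed), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }

  counts_df <- data.frame(contig_id = rownames(community$counts),
                          length = as.integer(community$lengths),
                          community$counts, check.names = FALSE,
                          stringsAsFactors = FALSE)
  files <- c(files, write_tsv_with_header(counts_df,
                                          file.path(dir, "counts.tsv"),
                                          "counts"))
  truth_df <- data.frame(contig_id = names(community$truth$contig_to_genome),
                         genome_id = unname(community$truth$contig_to_genome),
                         stringsAsFactors = FALSE)
  files <- c(files, write_tsv_with_header(truth_df,
                                          file.path(dir, "truth.tsv"),
                                          "truth"))
  files <- c(files, write_tsv_with_header(community$markers,
                                          file.path(dir, "markers.tsv"),
                                          "markers"))
  cov_df <- data.frame(genome_id = rownames(community$truth$genome_coverage),
                       community$truth$genome_coverage, check.names = FALSE,
                       stringsAsFactors = FALSE)
  files <- c(files, write_tsv_with_header(cov_df,
                                          file.path(dir, "genome_coverage.tsv"),
                                          "genome_coverage"))
  if (!is.null(community$sequences)) {
    fa <- file.path(dir, "contigs.fasta")
    Biostrings::writeXStringSet(community$sequences, fa)
    files <- c(files, fa)
  }
  invisible(files)
}

#' Read a counts table written by [write_community()]
#'
#' @param path Path to a counts TSV (columns: contig_id, length, then one
#'   integer column per sample; `#` lines are ignored).
#' @return List with `counts` (integer matrix, rownames = contig ids) and
#'   `lengths` (named integer vector).
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  stopifnot(all(c("contig_id", "length") %in% names(df)))
  counts <- as.matrix(df[, setdiff(names(df), c("contig_id", "length")),
                         drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$contig_id
  list(counts = counts,
       lengths = setNames(as.integer(df$length), df$contig_id))
}

#' Read a marker table (synthetic dialect)
#'
#' @param path Path to a marker TSV with columns `genome_id` (optional),
#'   `marker_id`, `contig_id`, `start`, `end`, `identity` (optional,
#'   defaults to 1).
#' @return data.frame of marker rows.
#' @export
read_marker_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("marker_id", "contig_id") %in% names(df)))
  if (is.null(df$identity)) df$identity <- 1.0
  df
}
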