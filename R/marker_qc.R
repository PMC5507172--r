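#' Default universal single-copy marker universe
#'
#' @param size Number of markers (default 104).
#' @return Character vector of marker ids.
#' @export
marker_universe <- function(size = 104) sprintf("M%03d", seq_len(size))

#' Per-marker copy counts within a bin
#'
#' @param bin_contigs Contig ids belonging to the bin.
#' @param markers Marker table (rows `contig_id`, `marker_id`, `identity`).
#' @param universe Expected single-copy marker ids.
#' @return Named integer vector of copy counts, one per marker in the
#'   universe (zero for absent markers).
#' @export
tally_markers <- function(bin_contigs, markers,
                          universe = marker_universe()) {
  rows <- markers[markers$contig_id %in% bin_contigs, , drop = FALSE]
  counts <- table(factor(rows$marker_id, levels = universe))
  setNames(as.integer(counts), universe)
}

#' Completeness from marker copy counts
#'
#' Percentage of expected single-copy markers present at least once.
#'
#' @param counts Named copy counts from [tally_markers()].
#' @param M Marker universe size (defaults to `length(counts)`).
#' @return Percent in `[0, 100]`.
#' @export
completeness <- function(counts, M = length(counts)) {
  100 * sum(counts >= 1) / M
}

#' Contamination from marker copy counts
#'
#' Percentage of redundant marker copies: `100 * sum(max(0, count - 1)) / M`.
#' Can exceed 100 when bins hold several genomes.
#'
#' @inheritParams completeness
#' @return Percent, `>= 0`.
#' @export
contamination <- function(counts, M = length(counts)) {
  100 * sum(pmax(0L, counts - 1L)) / M
}

# Pairwise identity between two marker copies whose rows store identity to
# the marker reference: copies diverged d1 and d2 at shared sites agree at
# 1 - |d1 - d2| of positions (upper-bound model, documented in the vignette).
pairwise_copy_identity <- function(id_i, id_j) 1 - abs(id_i - id_j)

#' Strain heterogeneity of duplicated markers
#'
#' Fraction (percent) of duplicate marker-copy pairs whose pairwise identity
#' is at or above the threshold, indicating near-identical strains rather
#' than distinct contaminating genomes. Zero when no marker is duplicated.
#'
#' @param markers Marker rows of one bin (needs `marker_id`, `identity`).
#' @param identity_threshold Pairs at or above this identity count as
#'   strain-level duplicates (default 0.9).
#' @return Percent in `[0, 100]`.
#' @export
strain_heterogeneity <- function(markers, identity_threshold = 0.9) {
  if (nrow(markers) == 0) return(0)
  pairs_total <- 0L
  pairs_strain <- 0L
  for (ids in split(markers$identity, markers$marker_id)) {
    k <- length(ids)
    if (k < 2) next
    cmb <- utils::combn(k, 2)
    pw <- pairwise_copy_identity(ids[cmb[1, ]], ids[cmb[2, ]])
    pairs_total <- pairs_total + ncol(cmb)
    pairs_strain <- pairs_strain + sum(pw >= identity_threshold)
  }
  if (pairs_total == 0) return(0)
  100 * pairs_strain / pairs_total
}

#' Cumulative redundancy
#'
#' Contamination discounted by strain heterogeneity:
#' `contamination - contamination * strain_het / 100`. Fully
#' strain-heterogeneous duplication (100%) reduces it to zero.
#'
#' @param contamination Percent contamination.
#' @param strain_het Percent strain heterogeneity.
#' @return Percent in `[0, contamination]`.
#' @export
cumulative_redundancy <- function(contamination, strain_het) {
  contamination - contamination * strain_het / 100
}

#' Triage a bin into draft / high-contamination / low-completion
#'
#' Categories: `draft` (completeness >= `complete_min` and cumulative
#' redundancy <= `redundancy_max`), `high_contamination` (complete but
#' redundant), `low_completion` (completeness below `complete_min`). Both
#' boundaries are inclusive for the draft category.
#'
#' @param completeness Percent completeness.
#' @param cumulative_redundancy Percent cumulative redundancy.
#' @param complete_min Draft completeness threshold (default 50).
#' @param redundancy_max Draft cumulative-redundancy ceiling (default 10).
#' @return One of `"draft"`, `"high_contamination"`, `"low_completion"`.
#' @export
triage_bin <- function(completeness, cumulative_redundancy,
                       complete_min = 50, redundancy_max = 10) {
  ifelse(completeness < complete_min, "low_completion",
         ifelse(cumulative_redundancy <= redundancy_max,
                "draft", "high_contamination"))
}

#' Estimate the number of genomes in a bin
#'
#' `k` merged complete genomes score about `(k - 1) * 100%` contamination
#' under the copy-count definition, so the estimate is
#' `max(1, 1 + round(contamination / 100))`.
#'
#' @param contamination Percent contamination.
#' @return Integer genome-count estimate, at least 1.
#' @export
estimate_genome_count <- function(contamination) {
  pmax(1L, 1L + as.integer(round(contamination / 100)))
}

#' Quality-control report for a set of bins
#'
#' Computes completeness, contamination, strain heterogeneity, cumulative
#' redundancy, triage category and estimated genome count for every bin.
#'
#' @param bins A `bin_set` (see [bin_contigs()]) or a named list of
#'   contig-id vectors.
#' @param markers Marker table (`contig_id`, `marker_id`, `identity`).
#' @param universe Expected marker ids.
#' @param identity_threshold See [strain_heterogeneity()].
#' @param complete_min,redundancy_max See [triage_bin()].
#' @return data.frame of class `qc_report`, one row per bin: `bin_id`,
#'   `n_contigs`, `completeness`, `contamination`, `strain_heterogeneity`,
#'   `cumulative_redundancy`, `category`, `est_genomes`.
#' @export
bin_qc <- function(bins, markers, universe = marker_universe(),
                   identity_threshold = 0.9, complete_min = 50,
                   redundancy_max = 10) {
  if (inherits(bins, "bin_set")) bins <- bin_members(bins)
  stopifnot(is.list(bins))
  rows <- lapply(names(bins), function(bid) {
    contigs <- bins[[bid]]
    counts <- tally_markers(contigs, markers, universe)
    comp <- completeness(counts)
    cont <- contamination(counts)
    mrows <- markers[markers$contig_id %in% contigs, , drop = FALSE]
    sh <- strain_heterogeneity(mrows, identity_threshold)
    cr <- cumulative_redundancy(cont, sh)
    data.frame(bin_id = bid, n_contigs = length(contigs),
               completeness = comp, contamination = cont,
               strain_heterogeneity = sh, cumulative_redundancy = cr,
               category = triage_bin(comp, cr, complete_min, redundancy_max),
               est_genomes = estimate_genome_count(cont),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(bin_id = character(0), n_contigs = integer(0),
               completeness = numeric(0), contamination = numeric(0),
               strain_heterogeneity = numeric(0),
               cumulative_redundancy = numeric(0), category = character(0),
               est_genomes = integer(0), stringsAsFactors = FALSE)
  class(out) <- c("qc_report", class(out))
  out
}

#' Convert HMMER tabular output to a marker table
#'
#' Reads a `--tblout` style space-delimited file and keeps the target
#' (contig) and query (marker) names; identity is not reported by HMMER and
#' defaults to 1.
#'
#' @param path Path to a HMMER `--tblout` file.
#' @return data.frame with `contig_id`, `marker_id`, `identity`.
#' @export
read_hmmer_tblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(contig_id = character(0), marker_id = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  data.frame(contig_id = vapply(fields, `[`, "", 1),
             marker_id = vapply(fields, `[`, "", 3),
             identity = 1.0, stringsAsFactors = FALSE)
}
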