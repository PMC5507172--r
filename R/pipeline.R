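#' Configuration of the multi-round binning ladder
#'
#' @param initial [ap_params()] for the first binning round on transformed
#'   coverage (and for the raw-coverage re-binning of leftover contigs).
#' @param refine_damping,refine_max_iter,refine_conv_iter Message-passing
#'   budget of every refinement round.
#' @param preference_schedule Named numeric vector mapping the estimated
#'   number of genomes in a high-contamination bin to the re-binning
#'   preference; estimates at or below 2 use the `"2"` entry, estimates at or
#'   above 4 the `"4"` entry.
#' @param second_refine_preference Preference of the final refinement round
#'   of the transformed-coverage phase.
#' @param leftover_second_preference Preference of the final refinement round
#'   of the raw-coverage phase.
#' @param min_bin_contigs Minimum contigs for a low-completion bin to be
#'   kept at finalization; smaller non-draft bins dissolve into the unbinned
#'   set.
#' @param binned_min_length Minimum contig length (bp) admitted to binning.
#' @param data_rich_min_length Minimum contig length (bp) of the read
#'   recruitment universe used for relative abundance.
#' @param scale_factor Coverage transform factor (see
#'   [transform_coverage()]).
#' @param use_composition_in_refine Add canonical tetranucleotide features in
#'   the final refinement rounds when sequences are available.
#' @param complete_min,redundancy_max Triage thresholds, see [triage_bin()].
#' @param label_prefix Prefix of the final genome labels (drafts get
#'   `<prefix>1, <prefix>2, ...`, low-completion bins `<prefix>lc1, ...`).
#' @param seed Base seed for all tie-breaking streams of the ladder.
#' @return Validated list of class `ladder_config`.
#' @export
ladder_config <- function(initial = ap_params(preference = -3, damping = 0.9,
                                              max_iter = 4000,
                                              conv_iter = 400),
                          refine_damping = 0.9,
                          refine_max_iter = 2000,
                          refine_conv_iter = 200,
                          preference_schedule = c("2" = -1000, "3" = -500,
                                                  "4" = -100),
                          second_refine_preference = -100,
                          leftover_second_preference = -10,
                          min_bin_contigs = 5,
                          binned_min_length = 7500,
                          data_rich_min_length = 2000,
                          scale_factor = 5,
                          use_composition_in_refine = TRUE,
                          complete_min = 50,
                          redundancy_max = 10,
                          label_prefix = "MAG",
                          seed = 1) {
  cfg <- list(initial = initial, refine_damping = refine_damping,
              refine_max_iter = as.integer(refine_max_iter),
              refine_conv_iter = as.integer(refine_conv_iter),
              preference_schedule = preference_schedule,
              second_refine_preference = second_refine_preference,
              leftover_second_preference = leftover_second_preference,
              min_bin_contigs = as.integer(min_bin_contigs),
              binned_min_length = binned_min_length,
              data_rich_min_length = data_rich_min_length,
              scale_factor = scale_factor,
              use_composition_in_refine = isTRUE(use_composition_in_refine),
              complete_min = complete_min, redundancy_max = redundancy_max,
              label_prefix = label_prefix, seed = as.integer(seed))
  stopifnot(inherits(initial, "ap_params"),
            all(cfg$preference_schedule < 0),
            cfg$second_refine_preference < 0,
            cfg$leftover_second_preference < 0,
            cfg$refine_max_iter > 0, cfg$refine_conv_iter > 0,
            cfg$refine_conv_iter <= cfg$refine_max_iter,
            cfg$min_bin_contigs >= 1)
  structure(cfg, class = "ladder_config")
}

schedule_preference <- function(est_genomes, schedule) {
  ifelse(est_genomes <= 2, schedule[["2"]],
         ifelse(est_genomes == 3, schedule[["3"]], schedule[["4"]]))
}

refine_params <- function(cfg, preference, seed) {
  ap_params(preference = preference, damping = cfg$refine_damping,
            max_iter = cfg$refine_max_iter, conv_iter = cfg$refine_conv_iter,
            seed = seed)
}

# Subset a coverage matrix by contig ids, keeping class and attributes.
cov_subset <- function(m, ids) {
  coverage_matrix(unclass(m)[ids, , drop = FALSE],
                  transformed = attr(m, "transformed"),
                  scale_factor = attr(m, "scale_factor"))
}

qc_for_members <- function(members, markers, universe, cfg) {
  bin_qc(members, markers, universe,
         complete_min = cfg$complete_min, redundancy_max = cfg$redundancy_max)
}

# Working state: named list of member vectors plus an aligned qc_report.
split_by_category <- function(members, qc) {
  lapply(c(draft = "draft", high = "high_contamination",
           low = "low_completion"),
         function(cat) members[qc$bin_id[qc$category == cat]])
}

#' Initial binning round on transformed coverage
#'
#' Clusters the (pre-filtered, length-admitted) contigs on transformed
#' coverage profiles and triages every resulting bin.
#'
#' @param coverage Transformed `coverage_matrix` of the contigs to bin.
#' @param markers Marker table.
#' @param universe Expected marker ids.
#' @param cfg A [ladder_config()].
#' @param round_label Provenance tag.
#' @return List with `bins` (a `bin_set`), `members` (named list of contig
#'   ids) and `qc` (a `qc_report`).
#' @export
run_initial_binning <- function(coverage, markers,
                                universe = marker_universe(),
                                cfg = ladder_config(),
                                round_label = "initial") {
  if (nrow(coverage) == 0) stop("no contigs to bin")
  params <- cfg$initial
  params$seed <- derive_seed(cfg$seed, round_label)
  bins <- bin_contigs(coverage, params = params, round_label = round_label)
  members <- bin_members(bins)
  names(members) <- sprintf("%s_b%03d", round_label,
                            seq_along(members))
  qc <- qc_for_members(members, markers, universe, cfg)
  list(bins = bins, members = members, qc = qc)
}

#' Re-bin high-contamination bins
#'
#' Each high-contamination bin is independently re-clustered on its own
#' contigs' features. The preference comes from the schedule keyed by the
#' bin's estimated genome count unless `preference` is given (the final
#' refinement round uses a fixed preference and, optionally, composition
#' features). Bins with fewer than 2 contigs, or whose re-clustering yields
#' no exemplar, pass through unchanged with a log note.
#'
#' @param high Named list of contig-id vectors (the high-contamination
#'   bins).
#' @param qc `qc_report` rows for those bins (for `est_genomes`).
#' @param coverage `coverage_matrix` covering at least those contigs.
#' @param markers,universe,cfg See [run_initial_binning()].
#' @param round_label Provenance tag (also seeds the jitter stream).
#' @param preference Fixed preference overriding the schedule, or `NULL`.
#' @param sequences Optional `DNAStringSet`; when present and
#'   `cfg$use_composition_in_refine` is set, tetranucleotide features are
#'   appended to the coverage features.
#' @return List with `members`, `qc` (all refined sub-bins, re-triaged) and
#'   `notes` (character log lines).
#' @export
refine_high_contamination <- function(high, qc, coverage, markers,
                                      universe = marker_universe(),
                                      cfg = ladder_config(),
                                      round_label = "refine",
                                      preference = NULL,
                                      sequences = NULL) {
  out_members <- list()
  notes <- character(0)
  use_comp <- cfg$use_composition_in_refine && !is.null(sequences) &&
    !is.null(preference)
  for (i in seq_along(high)) {
    bid <- names(high)[i]
    contigs <- high[[i]]
    if (length(contigs) < 2) {
      out_members[[sprintf("%s_%s_pass", round_label, bid)]] <- contigs
      notes <- c(notes, sprintf("%s: bin %s has <2 contigs, passed through",
                                round_label, bid))
      next
    }
    pref <- preference %||%
      schedule_preference(qc$est_genomes[qc$bin_id == bid],
                          cfg$preference_schedule)
    feats <- cov_subset(coverage, contigs)
    if (use_comp) feats <- composition_features(feats, sequences)
    params <- refine_params(cfg, pref,
                            derive_seed(cfg$seed, paste0(round_label, i)))
    sub <- bin_contigs(feats, params = params,
                       round_label = sprintf("%s_%s", round_label, bid))
    sub_members <- bin_members(sub)
    if (length(sub_members) == 0) {
      out_members[[sprintf("%s_%s_pass", round_label, bid)]] <- contigs
      notes <- c(notes, sprintf("%s: bin %s yielded no exemplar, passed through",
                                round_label, bid))
      next
    }
    names(sub_members) <- sprintf("%s_%s_s%02d", round_label, bid,
                                  seq_along(sub_members))
    out_members <- c(out_members, sub_members)
  }
  list(members = out_members,
       qc = qc_for_members(out_members, markers, universe, cfg),
       notes = notes)
}

# One full refinement ladder on an already-binned state: schedule-preference
# round, then a fixed-preference final round; residual high-contamination
# bins are demoted to low-completion (flagged). Returns drafts/lows plus log.
run_refine_ladder <- function(state, coverage, markers, universe, cfg,
                              phase, final_preference, sequences,
                              round_log) {
  cats <- split_by_category(state$members, state$qc)
  drafts <- cats$draft
  lows <- cats$low
  high <- cats$high
  high_qc <- state$qc[state$qc$category == "high_contamination", , drop = FALSE]
  notes <- character(0)

  round_log <- log_round(round_log, phase, "triage", length(state$members),
                         NA, length(drafts), length(high), length(lows))

  if (length(high) > 0) {
    r1 <- refine_high_contamination(high, high_qc, coverage, markers,
                                    universe, cfg,
                                    round_label = paste0(phase, "_refine1"))
    notes <- c(notes, r1$notes)
    cats1 <- split_by_category(r1$members, r1$qc)
    drafts <- c(drafts, cats1$draft)
    lows <- c(lows, cats1$low)
    high <- cats1$high
    high_qc <- r1$qc[r1$qc$category == "high_contamination", , drop = FALSE]
    round_log <- log_round(round_log, phase, "refine_schedule",
                           length(r1$members), NA, length(cats1$draft),
                           length(high), length(cats1$low))
  }
  if (length(high) > 0) {
    r2 <- refine_high_contamination(high, high_qc, coverage, markers,
                                    universe, cfg,
                                    round_label = paste0(phase, "_refine2"),
                                    preference = final_preference,
                                    sequences = sequences)
    notes <- c(notes, r2$notes)
    cats2 <- split_by_category(r2$members, r2$qc)
    drafts <- c(drafts, cats2$draft)
    lows <- c(lows, cats2$low)
    # paper's terminal categories are draft or low completion: demote
    residual <- cats2$high
    if (length(residual) > 0) {
      notes <- c(notes, sprintf("%s: %d residual high-contamination bins demoted to low completion",
                                phase, length(residual)))
      lows <- c(lows, residual)
    }
    round_log <- log_round(round_log, phase, "refine_final",
                           length(r2$members), final_preference,
                           length(cats2$draft), 0L,
                           length(cats2$low) + length(residual))
  }
  list(drafts = drafts, lows = lows, notes = notes, round_log = round_log)
}

#' Re-bin contigs left out of draft genomes, on raw coverage
#'
#' Clusters the leftover contigs on raw (untransformed) coverage with the
#' initial message-passing budget, then runs the two refinement rounds (the
#' schedule-preference round and a final round at the leftover preference).
#'
#' @param leftover Contig ids not assigned to any draft genome.
#' @param raw_coverage Raw `coverage_matrix` covering those contigs.
#' @param markers,universe,cfg See [run_initial_binning()].
#' @param sequences Optional sequences for composition-assisted refinement.
#' @return As [run_refine_ladder] internals: list with `drafts`, `lows`,
#'   `notes`, `round_log` entries.
#' @export
rebin_unassigned <- function(leftover, raw_coverage, markers,
                             universe = marker_universe(),
                             cfg = ladder_config(), sequences = NULL) {
  if (length(leftover) == 0) {
    return(list(drafts = list(), lows = list(), unbinned = character(0),
                notes = character(0), round_log = empty_round_log()))
  }
  cov <- cov_subset(raw_coverage, leftover)
  init <- run_initial_binning(cov, markers, universe, cfg,
                              round_label = "raw")
  unbinned <- names(init$bins$assignment)[is.na(init$bins$assignment)]
  ladder <- run_refine_ladder(init, cov, markers, universe, cfg,
                              phase = "raw",
                              final_preference = cfg$leftover_second_preference,
                              sequences = sequences,
                              round_log = empty_round_log())
  list(drafts = ladder$drafts, lows = ladder$lows, unbinned = unbinned,
       notes = ladder$notes, round_log = ladder$round_log)
}

empty_round_log <- function() {
  data.frame(phase = character(0), stage = character(0),
             n_bins = integer(0), preference = numeric(0),
             n_draft = integer(0), n_high = integer(0), n_low = integer(0),
             stringsAsFactors = FALSE)
}

log_round <- function(log, phase, stage, n_bins, preference, n_draft,
                      n_high, n_low) {
  rbind(log, data.frame(phase = phase, stage = stage,
                        n_bins = as.integer(n_bins),
                        preference = as.numeric(preference),
                        n_draft = as.integer(n_draft),
                        n_high = as.integer(n_high),
                        n_low = as.integer(n_low),
                        stringsAsFactors = FALSE))
}

#' Finalize bins into the terminal draft / low-completion / unbinned sets
#'
#' Drafts are labelled sequentially with the configured prefix. Non-draft
#' bins with at least `min_bin_contigs` contigs become low-completion bins
#' (`<prefix>lc<n>`); smaller ones dissolve into the unbinned set. The three
#' sets partition the input universe.
#'
#' @param drafts Named list of draft-bin contig vectors.
#' @param lows Named list of non-draft bin contig vectors.
#' @param unbinned Contig ids in no bin.
#' @param universe_contigs All contigs that entered binning.
#' @param markers,universe,cfg See [run_initial_binning()].
#' @return List with relabelled `draft_bins`, `draft_qc`,
#'   `low_completion_bins`, `low_completion_qc`, `unbinned`.
#' @export
finalize_bins <- function(drafts, lows, unbinned, universe_contigs,
                          markers, universe = marker_universe(),
                          cfg = ladder_config()) {
  keep <- vapply(lows, length, 1L) >= cfg$min_bin_contigs
  dissolved <- unlist(lows[!keep], use.names = FALSE)
  lows <- lows[keep]
  unbinned <- c(unbinned, dissolved)

  if (length(drafts) > 0)
    names(drafts) <- sprintf("%s%d", cfg$label_prefix, seq_along(drafts))
  if (length(lows) > 0)
    names(lows) <- sprintf("%slc%d", cfg$label_prefix, seq_along(lows))

  assigned <- c(unlist(drafts, use.names = FALSE),
                unlist(lows, use.names = FALSE), unbinned)
  if (anyDuplicated(assigned))
    stop("internal error: contig assigned to more than one terminal set")
  stray <- setdiff(assigned, universe_contigs)
  lost <- setdiff(universe_contigs, assigned)
  if (length(stray) > 0 || length(lost) > 0)
    stop("internal error: terminal sets do not partition the binning universe")

  list(draft_bins = drafts,
       draft_qc = qc_for_members(drafts, markers, universe, cfg),
       low_completion_bins = lows,
       low_completion_qc = qc_for_members(lows, markers, universe, cfg),
       unbinned = unbinned)
}

#' Run the full MAG binning and refinement ladder
#'
#' The end-to-end procedure: (1) admit contigs at or above the binning
#' length cutoff and bin them on transformed coverage profiles; (2) triage
#' every bin on the single-copy marker set and re-bin high-contamination
#' bins through the preference schedule, then a final fixed-preference
#' refinement (residual contaminated bins are demoted to low completion);
#' (3) re-bin every contig not captured in a draft genome on raw coverage and
#' run the same refinement ladder with the leftover final preference;
#' (4) finalize drafts and low-completion bins (at least
#' `cfg$min_bin_contigs` contigs) and label them.
#'
#' @param counts Count matrix (contigs x samples, rownames = contig ids), a
#'   [read_counts_tsv()] list, or a `mag_community`.
#' @param lengths Named contig lengths (bp); taken from `counts` when it is a
#'   list or community.
#' @param markers Marker table; taken from a `mag_community` input.
#' @param sequences Optional `DNAStringSet` for composition-assisted
#'   refinement; taken from a `mag_community` input.
#' @param universe Expected marker ids.
#' @param cfg A [ladder_config()].
#' @return Object of class `mag_pipeline`: list with `draft_bins`,
#'   `draft_qc`, `low_completion_bins`, `low_completion_qc`, `unbinned`,
#'   `binned_contigs` (the admitted universe), `round_log`, `notes`,
#'   `counts`, `lengths`, `cfg`.
#' @examples
#' \donttest{
#' com <- simulate_community(community_config(n_genomes = 3, n_samples = 4,
#'   genome_length_range = c(2e5, 3e5), sequences = FALSE, seed = 42))
#' fit <- mag_pipeline(com)
#' summary(fit)
#' }
#' @export
mag_pipeline <- function(counts, lengths = NULL, markers = NULL,
                         sequences = NULL, universe = marker_universe(),
                         cfg = ladder_config()) {
  if (inherits(counts, "mag_community")) {
    com <- counts
    counts <- com$counts
    lengths <- com$lengths
    markers <- markers %||% com$markers
    sequences <- sequences %||% com$sequences
    universe <- marker_universe(com$config$marker_set_size)
  }
  if (is.list(counts) && !is.null(counts$counts)) {
    lengths <- counts$lengths
    counts <- counts$counts
  }
  stopifnot(is.matrix(counts), !is.null(markers))

  binned <- names(lengths)[lengths >= cfg$binned_min_length]
  binned <- intersect(rownames(counts), binned)
  if (length(binned) == 0)
    stop("no contigs at or above the binning length cutoff")

  raw_all <- compute_coverage(counts, lengths)
  raw <- cov_subset(raw_all, binned)
  trans <- transform_coverage(raw, cfg$scale_factor)

  init <- run_initial_binning(trans, markers, universe, cfg,
                              round_label = "t")
  unbinned_t <- names(init$bins$assignment)[is.na(init$bins$assignment)]
  ladder_t <- run_refine_ladder(init, trans, markers, universe, cfg,
                                phase = "transformed",
                                final_preference = cfg$second_refine_preference,
                                sequences = sequences,
                                round_log = empty_round_log())
  drafts <- ladder_t$drafts

  leftover <- setdiff(binned, unlist(drafts, use.names = FALSE))
  raw_phase <- rebin_unassigned(leftover, raw, markers, universe, cfg,
                                sequences = sequences)
  drafts <- c(drafts, raw_phase$drafts)

  fin <- finalize_bins(drafts, raw_phase$lows, raw_phase$unbinned,
                       binned, markers, universe, cfg)

  structure(c(fin,
              list(binned_contigs = binned,
                   round_log = rbind(ladder_t$round_log,
                                     raw_phase$round_log),
                   notes = c(ladder_t$notes, raw_phase$notes),
                   counts = counts, lengths = lengths, cfg = cfg)),
            class = "mag_pipeline")
}

#' @export
print.mag_pipeline <- function(x, ...) {
  cat("MAG binning ladder\n")
  cat(sprintf("  %d contigs admitted (>= %g bp)\n",
              length(x$binned_contigs), x$cfg$binned_min_length))
  cat(sprintf("  %d draft genomes, %d low-completion bins, %d unbinned contigs\n",
              length(x$draft_bins), length(x$low_completion_bins),
              length(x$unbinned)))
  if (length(x$draft_bins) > 0)
    cat(sprintf("  draft completeness %.1f-%.1f%% (mean %.1f%%)\n",
                min(x$draft_qc$completeness), max(x$draft_qc$completeness),
                mean(x$draft_qc$completeness)))
  invisible(x)
}

#' @export
summary.mag_pipeline <- function(object, ...) {
  out <- list(n_draft = length(object$draft_bins),
              n_low_completion = length(object$low_completion_bins),
              n_unbinned = length(object$unbinned),
              n_contigs = length(object$binned_contigs),
              draft_qc = object$draft_qc,
              round_log = object$round_log)
  class(out) <- "summary.mag_pipeline"
  out
}

#' @export
print.summary.mag_pipeline <- function(x, ...) {
  cat(sprintf("%d draft genomes, %d low-completion bins, %d unbinned of %d contigs\n",
              x$n_draft, x$n_low_completion, x$n_unbinned, x$n_contigs))
  if (x$n_draft > 0) {
    cat("Draft genome QC:\n")
    print(x$draft_qc[, c("bin_id", "n_contigs", "completeness",
                         "contamination", "strain_heterogeneity",
                         "cumulative_redundancy")], row.names = FALSE)
  }
  cat("Round log:\n")
  print(x$round_log, row.names = FALSE)
  invisible(x)
}

#' Completeness-contamination overview of a pipeline result
#'
#' Scatter of per-bin completeness against cumulative redundancy with the
#' draft triage thresholds marked.
#'
#' @param x A `mag_pipeline` result.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.mag_pipeline <- function(x, ...) {
  qc <- rbind(x$draft_qc, x$low_completion_qc)
  plot(qc$completeness, qc$cumulative_redundancy,
       xlab = "Completeness (%)", ylab = "Cumulative redundancy (%)",
       pch = ifelse(qc$category == "draft", 19, 1),
       xlim = c(0, 100), ...)
  abline(v = x$cfg$complete_min, lty = 2)
  abline(h = x$cfg$redundancy_max, lty = 2)
  legend("topleft", pch = c(19, 1), bty = "n",
         legend = c("draft", "other"))
  invisible(x)
}

#' Export final bins to TSV (and per-bin FASTA)
#'
#' Writes the contig-to-bin assignment table (`contig_id`, `bin_id`,
#' `category`, `exemplar_flag` placeholder column kept for compatibility)
#' plus the round log and, when sequences are given, one FASTA per draft
#' genome.
#'
#' @param result A `mag_pipeline` result.
#' @param dir Output directory.
#' @param sequences Optional `DNAStringSet` of contig sequences.
#' @return Invisibly, the assignment file path.
#' @export
write_bins <- function(result, dir, sequences = NULL) {
  stopifnot(inherits(result, "mag_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- rbind(
    assignment_rows(result$draft_bins, "draft"),
    assignment_rows(result$low_completion_bins, "low_completion"),
    if (length(result$unbinned) > 0)
      data.frame(contig_id = result$unbinned, bin_id = NA_character_,
                 category = "unbinned", stringsAsFactors = FALSE))
  path <- file.path(dir, "bins.tsv")
  con <- file(path, open = "wb")
  writeLines(provenance_header("bins", result$cfg$seed), con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  log_path <- file.path(dir, "round_log.tsv")
  write.table(result$round_log, log_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(sequences)) {
    for (bid in names(result$draft_bins)) {
      Biostrings::writeXStringSet(sequences[result$draft_bins[[bid]]],
                                  file.path(dir, paste0(bid, ".fasta")))
    }
  }
  invisible(path)
}

assignment_rows <- function(bins, category) {
  if (length(bins) == 0)
    return(data.frame(contig_id = character(0), bin_id = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  data.frame(contig_id = unlist(bins, use.names = FALSE),
             bin_id = rep(names(bins), lengths(bins)),
             category = category, stringsAsFactors = FALSE)
}
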