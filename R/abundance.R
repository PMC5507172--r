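#' Length-normalized relative abundance of draft genomes
#'
#' For each draft genome and sample:
#' `(reads/bp of the genome / sum of reads/bp over all genomes) *
#'  (reads recruited to genome contigs / reads recruited to all data-rich
#'  contigs) * 100`,
#' where the data-rich universe is every contig at or above
#' `data_rich_min_length` (2 kb by default). A genome's reads/bp is its total
#' recruited reads divided by its total length (length-weighted; set
#' `per_contig_mean = TRUE` for the unweighted mean of per-contig reads/bp).
#'
#' @param bins Named list of draft-genome contig-id vectors, or a
#'   `mag_pipeline` result (its `draft_bins` are used).
#' @param counts Count matrix over the data-rich universe (contigs x
#'   samples); defaults to the counts stored in a `mag_pipeline` input.
#' @param lengths Named contig lengths (bp).
#' @param data_rich_min_length Length cutoff (bp) of the recruitment
#'   universe.
#' @param per_contig_mean Use the unweighted mean of per-contig reads/bp as
#'   the genome's reads/bp.
#' @return Object of class `abundance_table`: genomes x samples matrix of
#'   percent values with attribute `sample_totals` (percent of each sample's
#'   data-rich reads recruited to draft genomes). A sample with zero
#'   data-rich reads yields `NA` values.
#' @export
relative_abundance <- function(bins, counts = NULL, lengths = NULL,
                               data_rich_min_length = 2000,
                               per_contig_mean = FALSE) {
  if (inherits(bins, "mag_pipeline")) {
    counts <- counts %||% bins$counts
    lengths <- lengths %||% bins$lengths
    data_rich_min_length <- bins$cfg$data_rich_min_length
    bins <- bins$draft_bins
  }
  stopifnot(is.matrix(counts), !is.null(lengths))
  rich <- rownames(counts)[lengths[rownames(counts)] >= data_rich_min_length]
  counts <- counts[rich, , drop = FALSE]
  missing <- setdiff(unlist(bins, use.names = FALSE), rich)
  if (length(missing) > 0)
    stop("genome contigs absent from the data-rich count table: ",
         paste(head(missing, 5), collapse = ", "))

  G <- length(bins)
  S <- ncol(counts)
  genome_reads <- matrix(0, G, S,
                         dimnames = list(names(bins), colnames(counts)))
  rpb <- genome_reads
  for (g in seq_len(G)) {
    sub <- counts[bins[[g]], , drop = FALSE]
    genome_reads[g, ] <- colSums(sub)
    rpb[g, ] <- if (per_contig_mean) {
      colMeans(sub / as.numeric(lengths[bins[[g]]]))
    } else {
      colSums(sub) / sum(lengths[bins[[g]]])
    }
  }
  total_rich <- colSums(counts)
  rpb_total <- colSums(rpb)
  values <- matrix(NA_real_, G, S,
                   dimnames = dimnames(genome_reads))
  totals <- setNames(rep(NA_real_, S), colnames(counts))
  ok <- total_rich > 0
  for (s in which(ok)) {
    frac_rpb <- if (rpb_total[s] > 0) rpb[, s] / rpb_total[s] else
      rep(0, G)
    recruit <- sum(genome_reads[, s]) / total_rich[s]
    values[, s] <- frac_rpb * recruit * 100
    totals[s] <- 100 * recruit
  }
  structure(values, sample_totals = totals,
            class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Relative abundance: %d genomes x %d samples (%%)\n",
              nrow(x), ncol(x)))
  print(round(unclass(x), 4))
  cat("Per-sample draft totals (%):\n")
  print(round(attr(x, "sample_totals"), 4))
  invisible(x)
}

#' Per-sample abundance totals and top-n totals
#'
#' @param table An `abundance_table`.
#' @param n Number of most abundant genomes to sum (default 10). Ties at
#'   rank `n` are broken by genome label for determinism.
#' @return data.frame with one row per sample: `sample_id`, `total`
#'   (percent of data-rich reads in draft genomes) and `top_n_total`.
#' @export
summarize_abundance <- function(table, n = 10) {
  stopifnot(inherits(table, "abundance_table"))
  vals <- unclass(table)
  top <- vapply(seq_len(ncol(vals)), function(s) {
    v <- vals[, s]
    if (all(is.na(v))) return(NA_real_)
    ord <- order(-v, rownames(vals))
    sum(v[ord][seq_len(min(n, length(v)))])
  }, numeric(1))
  data.frame(sample_id = colnames(vals),
             total = unname(attr(table, "sample_totals")),
             top_n_total = top, stringsAsFactors = FALSE)
}

#' Evaluate a binning result against synthetic truth
#'
#' Scores each draft genome bin against the known contig-to-genome map:
#' per-genome truth completeness (fraction of the genome's bp captured in
#' its majority bin), truth contamination of that bin (fraction of bin bp
#' from other genomes), the adjusted Rand index between the final bin
#' partition and the genome partition over all binned contigs, and category
#' counts. A genome counts as recovered when its majority bin is a draft
#' with truth completeness at or above `complete_min` and truth
#' contamination at or below `contam_max`.
#'
#' @param result A `mag_pipeline` result (or a named list of bins).
#' @param truth A `SyntheticTruth` list (from [simulate_community()]'s
#'   `truth` element, or a `mag_community`).
#' @param lengths Named contig lengths; taken from the result if absent.
#' @param complete_min,contam_max Recovery thresholds as fractions (defaults
#'   0.8 and 0.1).
#' @return Object of class `bin_evaluation`: list with `per_genome`
#'   data.frame (`genome_id`, `majority_bin`, `bin_category`,
#'   `truth_completeness`, `truth_contamination`, `recovered`), `ari`,
#'   `recovery_rate`, `n_draft`, `n_low_completion`, `n_unbinned`.
#' @export
evaluate_bins <- function(result, truth, lengths = NULL,
                          complete_min = 0.8, contam_max = 0.1) {
  if (inherits(truth, "mag_community")) truth <- truth$truth
  if (inherits(result, "mag_pipeline")) {
    lengths <- lengths %||% result$lengths
    bins <- c(result$draft_bins, result$low_completion_bins)
    categories <- c(rep("draft", length(result$draft_bins)),
                    rep("low_completion", length(result$low_completion_bins)))
    names(categories) <- names(bins)
    n_unbinned <- length(result$unbinned)
  } else {
    bins <- result
    categories <- setNames(rep("draft", length(bins)), names(bins))
    n_unbinned <- NA_integer_
  }
  stopifnot(!is.null(lengths))
  c2g <- truth$contig_to_genome

  contig_bin <- setNames(rep(names(bins), lengths(bins)),
                         unlist(bins, use.names = FALSE))
  binned_ids <- names(contig_bin)
  ari <- if (length(binned_ids) > 1) {
    mclust::adjustedRandIndex(contig_bin, c2g[binned_ids])
  } else NA_real_

  genomes <- rownames(truth$genome_coverage) %||% unique(c2g)
  per <- lapply(genomes, function(g) {
    gc <- names(c2g)[c2g == g]
    g_bp <- sum(lengths[gc])
    in_bins <- contig_bin[intersect(gc, binned_ids)]
    if (length(in_bins) == 0 || g_bp == 0) {
      return(data.frame(genome_id = g, majority_bin = NA_character_,
                        bin_category = NA_character_,
                        truth_completeness = 0, truth_contamination = NA_real_,
                        recovered = FALSE, stringsAsFactors = FALSE))
    }
    bp_by_bin <- tapply(lengths[names(in_bins)], in_bins, sum)
    maj <- names(bp_by_bin)[which.max(bp_by_bin)]
    comp <- unname(bp_by_bin[maj]) / g_bp
    bin_contigs <- bins[[maj]]
    bin_bp <- sum(lengths[bin_contigs])
    contam <- 1 - sum(lengths[intersect(bin_contigs, gc)]) / bin_bp
    cat_maj <- unname(categories[maj])
    data.frame(genome_id = g, majority_bin = maj, bin_category = cat_maj,
               truth_completeness = comp, truth_contamination = contam,
               recovered = cat_maj == "draft" && comp >= complete_min &&
                 contam <= contam_max,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(per_genome = per, ari = ari,
                 recovery_rate = mean(per$recovered),
                 n_draft = sum(categories == "draft"),
                 n_low_completion = sum(categories == "low_completion"),
                 n_unbinned = n_unbinned),
            class = "bin_evaluation")
}

#' @export
print.bin_evaluation <- function(x, ...) {
  cat(sprintf("Bin evaluation: %.0f%% of genomes recovered, ARI %.3f\n",
              100 * x$recovery_rate, x$ari))
  cat(sprintf("  %d draft bins, %d low-completion bins, %s unbinned contigs\n",
              x$n_draft, x$n_low_completion,
              ifelse(is.na(x$n_unbinned), "?", x$n_unbinned)))
  cat(sprintf("  truth completeness mean %.1f%%, truth contamination mean %.1f%%\n",
              100 * mean(x$per_genome$truth_completeness),
              100 * mean(x$per_genome$truth_contamination, na.rm = TRUE)))
  invisible(x)
}
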