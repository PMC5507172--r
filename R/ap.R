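#' Affinity-propagation parameters
#'
#' @param preference Shared preference (diagonal similarity); more negative
#'   values yield fewer exemplars. Default -3.
#' @param damping Message damping in `[0.5, 1)`. Default 0.9.
#' @param max_iter Maximum iterations. Default 4000.
#' @param conv_iter Consecutive iterations with an unchanged exemplar set
#'   required to declare convergence. Default 400.
#' @param seed Seed for the tie-breaking jitter stream.
#' @return Validated list of class `ap_params`.
#' @export
ap_params <- function(preference = -3, damping = 0.9, max_iter = 4000,
                      conv_iter = 400, seed = 1) {
  p <- list(preference = as.numeric(preference), damping = as.numeric(damping),
            max_iter = as.integer(max_iter), conv_iter = as.integer(conv_iter),
            seed = as.integer(seed))
  stopifnot(p$damping >= 0.5, p$damping < 1, p$conv_iter >= 1,
            p$conv_iter <= p$max_iter)
  structure(p, class = "ap_params")
}

#' Similarity matrix for affinity propagation
#'
#' Off-diagonal similarity is the negative squared Euclidean distance between
#' feature vectors; the diagonal is set to the preference.
#'
#' @param features Numeric matrix, one row per item (contig).
#' @param preference Diagonal similarity (scalar, or one value per item).
#' @return Dense n x n similarity matrix.
#' @export
build_similarity <- function(features, preference) {
  features <- as.matrix(features)
  if (nrow(features) < 1) stop("need at least one feature row")
  if (!all(is.finite(features))) stop("features must be finite")
  S <- -as.matrix(dist(features))^2
  diag(S) <- preference
  dimnames(S) <- list(rownames(features), rownames(features))
  S
}

# Net similarity of an exemplar set E on similarity matrix S (diagonal holds
# the preferences): sum of each non-exemplar's best similarity to an
# exemplar plus the exemplars' preferences.
net_similarity <- function(S, exemplars) {
  if (length(exemplars) == 0) return(-Inf)
  non <- setdiff(seq_len(nrow(S)), exemplars)
  total <- sum(diag(S)[exemplars])
  if (length(non) > 0)
    total <- total + sum(apply(S[non, exemplars, drop = FALSE], 1, max))
  total
}

#' Cluster items by affinity propagation
#'
#' Fits exemplar-based clusters by damped message passing on the negative
#' squared Euclidean distance similarity. Exemplars are the items whose
#' self-responsibility plus self-availability is positive at termination;
#' every other item is assigned to its most similar exemplar. Exact
#' similarity ties are broken by a seeded jitter of at most 1e-12 relative to
#' the similarity range (disable with `jitter = FALSE`); argmax ties resolve
#' to the lowest index.
#'
#' @param features Numeric matrix of feature vectors (rows = items), or a
#'   `coverage_matrix`.
#' @param preference Diagonal similarity; more negative gives fewer bins.
#' @param damping,max_iter,conv_iter,seed See [ap_params()].
#' @param params Optional [ap_params()] overriding the individual arguments.
#' @param jitter Add the seeded tie-breaking perturbation (default TRUE).
#' @return Object of class `ap_fit`: list with `assignment` (named integer
#'   cluster ids, `NA` when no exemplar emerged), `exemplars` (item indices),
#'   `exemplar_ids`, `k`, `converged`, `iterations`, `net_similarity`,
#'   `params`.
#' @examples
#' x <- rbind(matrix(rnorm(10, 0), 5), matrix(rnorm(10, 8), 5))
#' fit <- ap_cluster(x, preference = -3)
#' fit$k
#' @export
ap_cluster <- function(features, preference = -3, damping = 0.9,
                       max_iter = 4000, conv_iter = 400, seed = 1,
                       params = NULL, jitter = TRUE) {
  if (is.null(params))
    params <- ap_params(preference, damping, max_iter, conv_iter, seed)
  features <- as.matrix(features)
  n <- nrow(features)
  if (n == 0) stop("no items to cluster")
  ids <- rownames(features) %||% as.character(seq_len(n))

  S <- build_similarity(features, params$preference)
  if (n == 1) {
    return(structure(list(assignment = setNames(1L, ids),
                          exemplars = 1L, exemplar_ids = ids, k = 1L,
                          converged = TRUE, iterations = 0L,
                          net_similarity = params$preference,
                          params = params), class = "ap_fit"))
  }
  Sj <- S
  if (jitter) {
    rng <- range(S[is.finite(S)])
    eps <- 1e-12 * max(1, rng[2] - rng[1])
    Sj <- S + with_seed(params$seed,
                        matrix(runif(n * n, 0, eps), n, n))
  }
  core <- ap_core(Sj, params$damping, params$max_iter, params$conv_iter)
  ex <- as.integer(core$exemplars)
  # Guard against the degenerate all-exemplar fixed point message passing
  # can reach when items are near-identical relative to |preference|: if
  # the best single-exemplar solution attains strictly higher net
  # similarity than the returned set, it is the better clustering.
  if (length(ex) > 1) {
    net1 <- colSums(S)  # net similarity of each singleton exemplar set
    if (max(net1) > net_similarity(S, ex)) ex <- which.max(net1)
  }
  if (length(ex) == 0) {
    return(structure(list(assignment = setNames(rep(NA_integer_, n), ids),
                          exemplars = integer(0), exemplar_ids = character(0),
                          k = 0L, converged = FALSE,
                          iterations = core$iterations,
                          net_similarity = -Inf, params = params),
                     class = "ap_fit"))
  }
  # assign each item to its most similar exemplar (lowest index on ties),
  # exemplars to themselves; similarities from the clean matrix
  sub <- S[, ex, drop = FALSE]
  best <- max.col(sub, ties.method = "first")
  best[ex] <- seq_along(ex)
  assignment <- setNames(as.integer(best), ids)
  structure(list(assignment = assignment, exemplars = ex,
                 exemplar_ids = ids[ex], k = length(ex),
                 converged = isTRUE(core$converged),
                 iterations = core$iterations,
                 net_similarity = net_similarity(S, ex),
                 params = params), class = "ap_fit")
}

#' @export
print.ap_fit <- function(x, ...) {
  cat(sprintf("Affinity propagation fit: %d clusters over %d items\n",
              x$k, length(x$assignment)))
  cat(sprintf("  preference %g, %d iterations, %s (net similarity %.4g)\n",
              x$params$preference, x$iterations,
              if (x$converged) "converged" else "not converged",
              x$net_similarity))
  invisible(x)
}

#' @export
summary.ap_fit <- function(object, ...) {
  sizes <- if (object$k > 0) as.integer(table(object$assignment)) else integer(0)
  out <- list(k = object$k, sizes = sizes, converged = object$converged,
              iterations = object$iterations,
              net_similarity = object$net_similarity,
              preference = object$params$preference)
  class(out) <- "summary.ap_fit"
  out
}

#' @export
print.summary.ap_fit <- function(x, ...) {
  cat(sprintf("%d clusters (sizes: %s), preference %g, %d iterations, %s\n",
              x$k, paste(sort(x$sizes, decreasing = TRUE), collapse = " "),
              x$preference, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Bin contigs on feature vectors
#'
#' Thin wrapper around [ap_cluster()] that returns a bin set: the partition
#' of contigs into bins with one exemplar contig per bin and a provenance
#' label for the binning round.
#'
#' @param features Contig feature matrix (e.g. a `coverage_matrix`).
#' @param params An [ap_params()].
#' @param round_label Provenance tag recorded on the bin set.
#' @param jitter See [ap_cluster()].
#' @return Object of class `bin_set`: list with `assignment` (named integer,
#'   `NA` = unbinned), `exemplars` (named: bin id -> exemplar contig id),
#'   `round_label`, `converged`, `iterations`.
#' @export
bin_contigs <- function(features, params = ap_params(),
                        round_label = "initial", jitter = TRUE) {
  fit <- ap_cluster(features, params = params, jitter = jitter)
  bin_set(fit$assignment,
          exemplars = setNames(fit$exemplar_ids,
                               seq_along(fit$exemplar_ids)),
          round_label = round_label, converged = fit$converged,
          iterations = fit$iterations)
}

bin_set <- function(assignment, exemplars, round_label, converged,
                    iterations = NA_integer_) {
  structure(list(assignment = assignment, exemplars = exemplars,
                 round_label = round_label, converged = converged,
                 iterations = iterations), class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  nb <- length(unique(x$assignment[!is.na(x$assignment)]))
  cat(sprintf("Bin set '%s': %d bins over %d contigs (%d unbinned), %s\n",
              x$round_label, nb, length(x$assignment),
              sum(is.na(x$assignment)),
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

# Split a bin_set into a list of contig-id vectors keyed by bin id.
bin_members <- function(bins) {
  a <- bins$assignment
  ok <- !is.na(a)
  split(names(a)[ok], a[ok])
}

#' Canonical tetranucleotide frequency profile
#'
#' Counts all 4-mers in a sequence (windows containing non-ACGT letters are
#' skipped), pools each 4-mer with its reverse complement into 136 canonical
#' 4-mers, and normalizes to sum to 1.
#'
#' @param sequence A character string, `Biostrings::DNAString`, or
#'   `DNAStringSet` (one profile per sequence).
#' @return Named numeric vector of 136 canonical 4-mer frequencies, or a
#'   matrix (sequences x 136) for a `DNAStringSet`. A sequence with fewer
#'   than 4 valid windows yields a zero vector with a warning.
#' @export
tetranucleotide_profile <- function(sequence) {
  if (is.character(sequence) && length(sequence) > 1)
    sequence <- Biostrings::DNAStringSet(sequence)
  if (inherits(sequence, "DNAStringSet")) {
    counts <- Biostrings::oligonucleotideFrequency(sequence, width = 4)
    return(t(apply(counts, 1, pool_canonical_4mers)))
  }
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  counts <- Biostrings::oligonucleotideFrequency(sequence, width = 4)
  pool_canonical_4mers(counts)
}

canonical_4mer_map <- local({
  map <- NULL
  function() {
    if (is.null(map)) {
      kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4)
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(kmers)))
      map <<- setNames(pmin(kmers, rc), kmers)
    }
    map
  }
})

pool_canonical_4mers <- function(counts) {
  map <- canonical_4mer_map()
  pooled <- tapply(counts[names(map)], map, sum)
  pooled <- pooled[sort(unique(map))]
  total <- sum(pooled)
  if (total < 4) {
    warning("fewer than 4 valid 4-mer windows; returning a zero profile")
    return(setNames(rep(0, length(pooled)), names(pooled)))
  }
  pooled / total
}

# Coverage + z-scaled composition feature block, equal block weighting:
# tetramer columns are z-scored across the given contigs and the block is
# scaled by sqrt(d_cov / d_comp) so both blocks contribute comparable
# expected squared distance.
composition_features <- function(coverage, sequences) {
  ids <- rownames(coverage)
  comp <- tetranucleotide_profile(sequences[ids])
  comp <- scale(comp)
  comp[!is.finite(comp)] <- 0
  w <- sqrt(ncol(coverage) / ncol(comp))
  cbind(unclass(coverage), comp * w)
}
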