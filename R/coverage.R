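#' Per-contig per-sample coverage from read counts
#'
#' Coverage is the number of reads recruited to a contig divided by the
#' contig length (reads/bp), computed per sample.
#'
#' @param counts Integer matrix contigs x samples with contig ids as
#'   rownames (or a list as returned by [read_counts_tsv()]).
#' @param lengths Named vector of contig lengths (bp); must cover every
#'   contig in `counts` with a positive length. Ignored when `counts` is a
#'   [read_counts_tsv()] list.
#' @return A `coverage_matrix`: the reads/bp matrix with attributes
#'   `transformed` (FALSE) and `scale_factor` (NA until transformed).
#' @export
compute_coverage <- function(counts, lengths = NULL) {
  if (is.list(counts) && !is.null(counts$counts)) {
    lengths <- counts$lengths
    counts <- counts$counts
  }
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  ids <- rownames(counts)
  missing <- setdiff(ids, names(lengths))
  if (length(missing) > 0)
    stop("missing contig length for: ", paste(head(missing, 5), collapse = ", "))
  len <- lengths[ids]
  if (any(len <= 0))
    stop("non-positive length for contig: ",
         paste(head(ids[len <= 0], 5), collapse = ", "))
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative read count for contig: ",
         paste(head(unique(ids[neg[, 1]]), 5), collapse = ", "))
  values <- sweep(counts, 1, as.numeric(len), "/")
  coverage_matrix(values, transformed = FALSE)
}

coverage_matrix <- function(values, transformed = FALSE, scale_factor = NA_real_) {
  stopifnot(is.matrix(values), all(is.finite(values)), all(values >= 0))
  structure(values, transformed = transformed, scale_factor = scale_factor,
            class = c("coverage_matrix", class(values)))
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("Coverage matrix: %d contigs x %d samples (%s%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "transformed"))) "transformed" else "raw reads/bp",
              if (isTRUE(attr(x, "transformed")))
                sprintf(", x%g", attr(x, "scale_factor")) else ""))
  invisible(x)
}

#' Scale a raw coverage matrix
#'
#' Multiplies every reads/bp value by a constant factor (default 5), used to
#' spread low-coverage profiles apart before clustering. A matrix can only be
#' transformed once.
#'
#' @param m A raw `coverage_matrix`.
#' @param factor Positive scale factor.
#' @return The transformed `coverage_matrix`.
#' @export
transform_coverage <- function(m, factor = 5) {
  stopifnot(inherits(m, "coverage_matrix"))
  if (isTRUE(attr(m, "transformed")))
    stop("coverage matrix is already transformed")
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("factor must be a single positive number")
  coverage_matrix(unclass(m) * factor, transformed = TRUE,
                  scale_factor = factor)
}

#' Filter contigs by minimum length
#'
#' Keeps contigs with `length >= min_length` (inclusive), preserving input
#' order.
#'
#' @param contigs Either a data.frame with columns `contig_id` and `length`,
#'   or a named vector of lengths.
#' @param min_length Minimum length in bp.
#' @return The filtered object, same type as the input.
#' @export
filter_contigs <- function(contigs, min_length) {
  stopifnot(is.numeric(min_length), length(min_length) == 1)
  if (is.data.frame(contigs)) {
    stopifnot(all(c("contig_id", "length") %in% names(contigs)))
    return(contigs[contigs$length >= min_length, , drop = FALSE])
  }
  contigs[contigs >= min_length]
}

#' Fraction of reads recruited to a contig subset, per sample
#'
#' @param counts Count matrix (contigs x samples, rownames = contig ids).
#' @param subset Contig ids (or a contig data.frame with a `contig_id`
#'   column) defining the subset.
#' @param total_reads Per-sample totals to normalize by; defaults to the
#'   column sums of `counts`. Must be at least the subset column sums.
#' @return Named numeric vector, percent of reads per sample; `NA` for a
#'   sample with zero total reads.
#' @export
recruitment_fraction <- function(counts, subset,
                                 total_reads = colSums(counts)) {
  if (is.data.frame(subset)) subset <- subset$contig_id
  subset <- intersect(rownames(counts), subset)
  sub_sum <- colSums(counts[subset, , drop = FALSE])
  if (any(total_reads + 1e-9 < sub_sum))
    stop("total_reads smaller than reads recruited to the subset")
  out <- ifelse(total_reads > 0, 100 * sub_sum / total_reads, NA_real_)
  setNames(out, colnames(counts))
}

#' Write a coverage matrix to TSV
#'
#' @param m A `coverage_matrix`.
#' @param path Output path; a `#` provenance line records whether values are
#'   raw or transformed.
#' @return Invisibly, `path`.
#' @export
write_coverage_tsv <- function(m, path) {
  stopifnot(inherits(m, "coverage_matrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# magladder coverage %s scale_factor=%s",
                     if (isTRUE(attr(m, "transformed"))) "transformed" else "raw",
                     format(attr(m, "scale_factor"))), con)
  df <- data.frame(contig_id = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a coverage TSV written by [write_coverage_tsv()]
#'
#' @param path Input path.
#' @return A `coverage_matrix` (transform state recovered from the
#'   provenance line).
#' @export
read_coverage_tsv <- function(path) {
  first <- readLines(path, n = 1)
  transformed <- grepl("transformed", first, fixed = TRUE)
  sf <- sub(".*scale_factor=", "", first)
  sf <- suppressWarnings(as.numeric(sf))
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  coverage_matrix(m, transformed = transformed, scale_factor = sf)
}

#' Count primary alignments per contig from a SAM/BAM file
#'
#' Optional ingester for workflows that start from read mappings rather than
#' a count table: counts primary (non-secondary, non-supplementary) mapped
#' alignments per reference sequence, with no MAPQ filter and no duplicate
#' removal.
#'
#' @param file Path to a SAM or BAM file (SAM is converted in memory;
#'   requires the Rsamtools package).
#' @return Named integer vector, one count per reference contig (zero for
#'   contigs with no alignments).
#' @export
count_reads_sam <- function(file) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("count_reads_sam requires the Rsamtools package")
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    file <- bam
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = "rname")
  res <- Rsamtools::scanBam(file, param = param)[[1]]$rname
  refs <- levels(res)
  counts <- table(factor(res, levels = refs))
  setNames(as.integer(counts), refs)
}
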