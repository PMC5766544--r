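# Repeat depletion: remove read pairs dominated by high-copy repeats via
# per-read median canonical k-mer coverage, plus pairs containing N.

#' Depletion configuration
#'
#' A pair is removed when either mate's median k-mer coverage is
#' `<= low_cutoff` (likely error/contaminant) or `> high_cutoff` (likely
#' high-copy repeat), or -- with `drop_ambiguous` -- when either mate
#' contains an `N`.  Defaults follow the published operating point:
#' 31-mers, retain median coverage in (1, 40].
#'
#' @param k k-mer size (odd, 3..31; the exact in-memory counter packs a
#'   k-mer into 64 bits).
#' @param low_cutoff remove if median coverage `<=` this.
#' @param high_cutoff remove if median coverage `>` this.
#' @param drop_ambiguous drop pairs with an `N` in either mate.
#' @return list of class `depletion_config`.
#' @export
depletion_config <- function(k = 31, low_cutoff = 1, high_cutoff = 40,
                             drop_ambiguous = TRUE) {
  stopifnot(k >= 3, k <= 31, k %% 2 == 1,
            low_cutoff >= 0, low_cutoff < high_cutoff)
  structure(list(k = as.integer(k), low_cutoff = as.integer(low_cutoff),
                 high_cutoff = as.integer(high_cutoff),
                 drop_ambiguous = isTRUE(drop_ambiguous)),
            class = "depletion_config")
}

#' Build a canonical k-mer count table over a read set
#'
#' Counts every k-length window of every mate (both strands collapse onto
#' the canonical form); windows containing `N` are skipped.  Exact hash
#' counting, not a probabilistic sketch: desk-scale inputs fit in memory.
#'
#' @param pairs a [read_pairs] data frame, or a character vector of reads.
#' @param k k-mer size.
#' @return object of class `kmer_table` with fields `k`, `n_kmers`.
#' @export
build_kmer_table <- function(pairs, k = 31) {
  seqs <- if (is.data.frame(pairs)) c(pairs$seq1, pairs$seq2) else pairs
  stopifnot(k >= 1, k <= 32)
  ptr <- cpp_kmer_table_build(seqs, as.integer(k))
  n <- cpp_kmer_table_size(ptr)
  if (n == 0 && length(seqs) > 0)
    warning("k exceeds every read length: empty k-mer table")
  structure(list(k = as.integer(k), ptr = ptr, n_kmers = n),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("<kmer_table> k=%d, %d distinct canonical k-mers\n",
              x$k, as.integer(x$n_kmers)))
  invisible(x)
}

#' Look up counts of explicit k-mers (canonicalized); mainly for tests.
#' @param table a `kmer_table`.
#' @param kmers character vector of k-mers.
#' @return integer counts; `NA` for k-mers containing `N`.
#' @export
kmer_count <- function(table, kmers) {
  stopifnot(inherits(table, "kmer_table"))
  cpp_kmer_table_query(table$ptr, kmers)
}

#' Median k-mer coverage of reads
#'
#' For each read, the lower median of the multiset of counts of all its
#' k-length windows; windows containing `N` contribute count 0 so ambiguous
#' bases depress coverage.  Reads shorter than k are "uncounted" (`NA`);
#' the filter treats them as coverage 0.
#'
#' @param reads character vector of reads.
#' @param table a `kmer_table`.
#' @return integer vector, `NA` for reads shorter than k.
#' @export
median_kmer_coverage <- function(reads, table) {
  stopifnot(inherits(table, "kmer_table"))
  cpp_median_kmer_coverage(reads, table$ptr)
}

#' Filter read pairs by median k-mer coverage
#'
#' @param pairs a [read_pairs] data frame.
#' @param table `kmer_table` built over the same read universe (or a
#'   superset).
#' @param config a [depletion_config].
#' @return list with `pairs` (retained, same columns) and `report`
#'   (one-row data frame: n_input, n_retained, removed_low, removed_high,
#'   removed_ambiguous).
#' @export
filter_read_pairs <- function(pairs, table, config = depletion_config()) {
  stopifnot(inherits(table, "kmer_table"), inherits(config, "depletion_config"))
  m1 <- median_kmer_coverage(pairs$seq1, table)
  m2 <- median_kmer_coverage(pairs$seq2, table)
  m1[is.na(m1)] <- 0L   # uncounted (shorter than k) counts as coverage 0
  m2[is.na(m2)] <- 0L
  low  <- m1 <= config$low_cutoff | m2 <= config$low_cutoff
  high <- m1 > config$high_cutoff | m2 > config$high_cutoff
  amb  <- config$drop_ambiguous &
    (grepl("N", pairs$seq1, fixed = TRUE) | grepl("N", pairs$seq2, fixed = TRUE))
  reason <- rep(NA_character_, nrow(pairs))
  reason[amb]  <- "ambiguous"
  reason[high] <- "high"
  reason[low]  <- "low"   # low takes precedence in the report
  keep <- is.na(reason)
  report <- data.frame(
    n_input = nrow(pairs),
    n_retained = sum(keep),
    removed_low = sum(reason == "low", na.rm = TRUE),
    removed_high = sum(reason == "high", na.rm = TRUE),
    removed_ambiguous = sum(reason == "ambiguous", na.rm = TRUE))
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(pairs)
  list(pairs = out, report = report)
}
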