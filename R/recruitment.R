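# Read indexing and maximal-exact-match recruitment.
#
# The read set (not the reference) is indexed: fixed-length seeds of every
# mate go into one sorted array, and matches are recovered by exact
# extension.  Recruitment is by maximal exact matches (MEMs) of length >=
# a threshold, an approximation of super-maximal exact match (SMEM)
# search that cannot change recruit/no-recruit membership.

#' Build a seed index over a read-pair set
#'
#' Every `seed_len`-window of every mate (forward strand, N-free) is
#' indexed.  Queries sample seeds at a stride derived from the minimum
#' match length, which guarantees complete recall: every maximal exact
#' match of length >= `min_match_len` between a query and any mate (either
#' strand) is discoverable.  Correctness does not depend on `seed_len`.
#'
#' @param pairs a [read_pairs] data frame (may be empty).
#' @param seed_len seed length (4..32); must not exceed the smallest
#'   `min_match_len` later queried.
#' @return object of class `read_index`.
#' @export
build_read_index <- function(pairs, seed_len = 20) {
  seqs <- c(pairs$seq1, pairs$seq2)
  ptr <- cpp_build_seed_index(seqs, as.integer(seed_len))
  structure(list(pairs = as.data.frame(pairs)[, c("pair_id", "seq1", "seq2")],
                 seed_len = as.integer(seed_len), ptr = ptr),
            class = "read_index")
}

#' @export
print.read_index <- function(x, ...) {
  cat(sprintf("<read_index> %d pairs, seed_len=%d\n", nrow(x$pairs), x$seed_len))
  invisible(x)
}

#' Persist a read index to a directory
#'
#' The reads and parameters are written as plain text; [load_read_index]
#' rebuilds the lookup structure, which is deterministic, so a reloaded
#' index returns byte-identical search results.
#'
#' @param index a `read_index`.
#' @param dir output directory (created if needed).
#' @export
save_read_index <- function(index, dir) {
  stopifnot(inherits(index, "read_index"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(index$pairs, file.path(dir, "reads.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed_len = index$seed_len),
                       file.path(dir, "index.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_read_index
#' @export
load_read_index <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "index.json"))
  tab <- utils::read.table(file.path(dir, "reads.tsv"), sep = "\t",
                           header = TRUE, colClasses = "character")
  build_read_index(read_pairs(tab$pair_id, tab$seq1, tab$seq2),
                   seed_len = meta$seed_len)
}

.index_mate <- function(index, seq_idx) {
  n <- nrow(index$pairs)
  ifelse(seq_idx > n, 2L, 1L)
}

.index_pair_row <- function(index, seq_idx) {
  n <- nrow(index$pairs)
  ifelse(seq_idx > n, seq_idx - n, seq_idx)
}

#' Find maximal exact matches between a query and indexed reads
#'
#' Returns exactly the maximal exact matches (extendable in neither
#' direction) of length >= `min_match_len`, on both strands, in
#' deterministic order (pair id, then query offset).  A `-` strand hit
#' means the reverse complement of the query interval equals the read
#' interval.
#'
#' @param query a single DNA sequence (character scalar).
#' @param index a `read_index`.
#' @param min_match_len minimum match length; must be >= the index seed
#'   length (config error otherwise).
#' @return data.frame: pair_id, mate, read_start, read_end, query_start,
#'   query_end, strand, length.  Intervals are 0-based half-open.
#' @export
find_exact_matches <- function(query, index, min_match_len) {
  stopifnot(inherits(index, "read_index"), length(query) == 1)
  if (min_match_len < index$seed_len)
    stop(sprintf("min_match_len (%d) below index seed_len (%d)",
                 min_match_len, index$seed_len), call. = FALSE)
  m <- cpp_find_mems(index$ptr, query, as.integer(min_match_len))
  row <- .index_pair_row(index, m$seq)
  out <- data.frame(pair_id = index$pairs$pair_id[row],
                    mate = .index_mate(index, m$seq),
                    read_start = m$subject_start,
                    read_end = m$subject_start + m$length,
                    query_start = m$query_start,
                    query_end = m$query_start + m$length,
                    strand = m$strand, length = m$length,
                    stringsAsFactors = FALSE)
  out[order(out$pair_id, out$query_start, out$read_start, out$mate), ,
      drop = FALSE]
}

#' Recruit read pairs matching any of a set of queries
#'
#' A pair is recruited iff at least one mate shares a maximal exact match
#' of length >= `min_match_len` with at least one query; both mates always
#' travel together.
#'
#' @param queries character vector of query sequences.
#' @param index a `read_index`.
#' @param min_match_len minimum exact-match length.
#' @return sorted character vector of recruited pair ids.
#' @export
recruit_pairs <- function(queries, index, min_match_len) {
  stopifnot(inherits(index, "read_index"))
  if (min_match_len < index$seed_len)
    stop(sprintf("min_match_len (%d) below index seed_len (%d)",
                 min_match_len, index$seed_len), call. = FALSE)
  hits <- character(0)
  for (q in queries) {
    if (nchar(q) < min_match_len) next
    m <- cpp_find_mems(index$ptr, q, as.integer(min_match_len))
    if (length(m$seq))
      hits <- c(hits, index$pairs$pair_id[.index_pair_row(index, m$seq)])
  }
  sort(unique(hits))
}

#' Subset a read-pair table by pair id
#' @param pairs a [read_pairs] data frame.
#' @param ids pair ids to keep.
#' @return the matching rows, in `pairs` order.
#' @export
pairs_subset <- function(pairs, ids) {
  out <- pairs[pairs$pair_id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(pairs)
  out
}
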