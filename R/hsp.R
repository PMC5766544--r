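# Local alignment blocks (HSPs) by ungapped seed-and-extend, and batch
# read-vs-contig alignment.  These stand in for BLASTn/BWA in the
# published pipeline; the sequences compared here diverge by scattered
# substitutions, so an ungapped x-drop extension is adequate and exactly
# reproducible.

#' Find local alignment blocks (HSPs) between two sequences
#'
#' Exact shared words seed an ungapped x-drop extension along the
#' diagonal.  Indels are not modelled.  On the `-` strand, the reverse
#' complement of the query interval aligns to the subject interval.
#'
#' @param query,subject DNA sequences (character scalars; subject may
#'   contain N runs, which never match).
#' @param word_len exact seed word length.
#' @param min_len minimum HSP length to report.
#' @param min_ident minimum HSP identity (fraction, 0..1).
#' @param xdrop score drop-off halting extension (match +1, mismatch -2).
#' @param both_strands search the reverse complement of the query too.
#' @return data.frame: q_start, q_end, s_start, s_end, length, matches,
#'   ident, score, strand; best score first.  0-based half-open intervals.
#' @export
find_hsps <- function(query, subject, word_len = 11, min_len = 40,
                      min_ident = 0.9, xdrop = 20, both_strands = TRUE) {
  stopifnot(length(query) == 1, length(subject) == 1)
  cpp_find_hsps(query, subject, as.integer(word_len), as.integer(min_len),
                min_ident, as.integer(xdrop), isTRUE(both_strands))
}

# Best ungapped alignment of each read against each contig.  Returns one
# row per (read, contig) with identity and read-coverage fractions;
# callers threshold.  min_anchor is the minimum exact run that nominates
# a candidate diagonal.
align_reads_to_contigs <- function(reads, contigs, min_anchor = 31,
                                   seed_len = 20) {
  if (length(contigs) == 0 || length(reads) == 0)
    return(data.frame(read = integer(0), contig = character(0),
                      c_start = integer(0), c_end = integer(0),
                      ident = numeric(0), cover = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE))
  seed_len <- min(seed_len, min_anchor)
  idx <- cpp_build_seed_index(contigs, as.integer(seed_len))
  a <- cpp_align_reads(idx, reads, as.integer(min_anchor))
  data.frame(read = a$read,
             contig = names(contigs)[a$seq],
             c_start = a$c_start, c_end = a$c_end,
             ident = ifelse(a$overlap > 0, a$matches / a$overlap, 0),
             cover = a$overlap / nchar(reads)[a$read],
             strand = a$strand, stringsAsFactors = FALSE)
}
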