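# Sequence primitives and FASTA/FASTQ readers/writers.
#
# Sequences are plain named character vectors over {A,C,G,T,N}; read pairs
# are data frames with columns pair_id, seq1, seq2 (class "read_pairs").
# Biostrings does the actual file parsing (including transparent gzip).

.DNA_RE <- "^[ACGTN]+$"

validate_dna <- function(seqs, what = "sequence") {
  if (length(seqs) == 0) return(invisible(seqs))
  bad <- !grepl(.DNA_RE, seqs)
  if (any(bad)) {
    stop(sprintf("%s %s contains characters outside {A,C,G,T,N} (or is empty)",
                 what, paste(utils::head(which(bad), 3), collapse = ",")),
         call. = FALSE)
  }
  invisible(seqs)
}

#' Reverse complement
#'
#' Watson-Crick complement, reversed.  `N` maps to `N`.  Input must be
#' uppercase over the alphabet \{A,C,G,T,N\}; anything else is an error.
#'
#' @param seq character vector of DNA sequences (names preserved).
#' @return character vector of the same length.
#' @export
reverse_complement <- function(seq) {
  validate_dna(seq)
  cpp_revcomp(seq)
}

#' Canonical k-mer
#'
#' The lexicographically smaller of a k-mer and its reverse complement, so
#' that one count table serves both strands.  A k-mer containing `N` cannot
#' be canonicalized and is returned as `NA` (callers skip it).
#'
#' @param kmer character vector of equal-length k-mers.
#' @return character vector; `NA` where the k-mer contains `N`.
#' @export
canonical_kmer <- function(kmer) {
  if (length(kmer) && length(unique(nchar(kmer))) != 1)
    stop("k-mers must share one length", call. = FALSE)
  cpp_canonical_kmers(kmer)
}

#' Read a (possibly gzipped) FASTA file
#'
#' Lowercase bases are uppercased on read; soft-masking is irrelevant here.
#' Record ids are the first whitespace-delimited word of each header and
#' must be unique within the file.
#'
#' @param path path to a FASTA file, plain or gzip.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                error = function(e) stop("malformed FASTA '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in ", path, call. = FALSE)
  validate_dna(seqs, "FASTA record")
  seqs
}

#' Write sequences to FASTA
#'
#' @param path output path.
#' @param seqs named character vector.
#' @param width line wrap width.
#' @export
write_fasta <- function(path, seqs, width = 70) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named", call. = FALSE)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Construct a read-pair table
#'
#' @param pair_id character ids, unique and stable across filtering stages.
#' @param seq1,seq2 mate sequences.
#' @return data.frame of class `read_pairs`.
#' @export
read_pairs <- function(pair_id, seq1, seq2) {
  if (length(pair_id) != length(seq1) || length(seq1) != length(seq2))
    stop("pair_id, seq1 and seq2 must have equal length", call. = FALSE)
  if (anyDuplicated(pair_id)) stop("pair ids must be unique", call. = FALSE)
  validate_dna(seq1, "mate1")
  validate_dna(seq2, "mate2")
  out <- data.frame(pair_id = as.character(pair_id),
                    seq1 = toupper(seq1), seq2 = toupper(seq2),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Read paired FASTQ files (or one interleaved file)
#'
#' Qualities are parsed and discarded: no stage of the method uses base
#' quality.  With two files, records are paired by position and the files
#' must have equal record counts.  With one file, odd records are mate 1
#' and even records mate 2.  Gzip input is handled transparently.
#'
#' @param path1 FASTQ file of first mates, or an interleaved file.
#' @param path2 FASTQ file of second mates, or `NULL` for interleaved.
#' @return a [read_pairs] data frame.
#' @export
read_fastq_pairs <- function(path1, path2 = NULL) {
  rd <- function(p) {
    if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
    x <- tryCatch(Biostrings::readDNAStringSet(p, format = "fastq"),
                  error = function(e) stop("malformed FASTQ '", p, "': ",
                                           conditionMessage(e), call. = FALSE))
    seqs <- toupper(as.character(x))
    names(seqs) <- sub("\\s.*$", "", sub("/[12]$", "", names(x)))
    seqs
  }
  if (is.null(path2)) {
    x <- rd(path1)
    if (length(x) %% 2 != 0)
      stop("interleaved FASTQ has an odd number of records", call. = FALSE)
    m1 <- x[seq(1, length(x), by = 2)]
    m2 <- x[seq(2, length(x), by = 2)]
  } else {
    m1 <- rd(path1)
    m2 <- rd(path2)
    if (length(m1) != length(m2))
      stop(sprintf("mate files disagree: %d vs %d records", length(m1),
                   length(m2)), call. = FALSE)
  }
  ids <- names(m1)
  if (is.null(ids) || anyDuplicated(ids)) ids <- sprintf("pair%07d", seq_along(m1))
  read_pairs(ids, unname(m1), unname(m2))
}

#' Write read pairs as two FASTQ files
#'
#' Constant placeholder qualities are emitted ("I"); the method never
#' consumes them.
#'
#' @param pairs a [read_pairs] data frame.
#' @param path1,path2 output paths for mate 1 and mate 2.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  wr <- function(ids, seqs, path, mate) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", ids, "/", mate, "\n", seqs, "\n+\n",
                      vapply(nchar(seqs), function(n) strrep("I", n), "")), con)
  }
  wr(pairs$pair_id, pairs$seq1, path1, 1)
  wr(pairs$pair_id, pairs$seq2, path2, 2)
  invisible(c(path1, path2))
}
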