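# Shared fixture builders.  Everything is generated in code; no binary or
# stored data.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# error-free tiling reads over a sequence (forward strand)
tiling_reads <- function(seq, read_len = 80, step = 7) {
  n <- nchar(seq)
  starts <- seq(1, max(1, n - read_len + 1), by = step)
  if (starts[length(starts)] != n - read_len + 1 && n >= read_len)
    starts <- c(starts, n - read_len + 1)
  substring(seq, starts, pmin(n, starts + read_len - 1))
}

# perfect convergent read pairs drawn deterministically along a sequence
tiling_pairs <- function(seq, read_len = 100, insert = 300, step = 25,
                         prefix = "p") {
  n <- nchar(seq)
  starts <- seq(1, n - insert + 1, by = step)
  m1 <- substring(seq, starts, starts + read_len - 1)
  m2 <- as.character(reverse_complement(
    substring(seq, starts + insert - read_len, starts + insert - 1)))
  read_pairs(sprintf("%s%04d", prefix, seq_along(starts)), m1, m2)
}

# brute-force oracle: occurrences of a word over a read set (both strands
# via canonical identification), counting overlapping occurrences
oracle_word_count <- function(w, reads) {
  count_one <- function(w, r) {
    n <- nchar(r); k <- nchar(w)
    if (n < k) return(0L)
    s <- substring(r, 1:(n - k + 1), k:n)
    sum(s == w)
  }
  rc <- as.character(reverse_complement(w))
  tot <- sum(vapply(reads, count_one, 0L, w = w))
  if (rc != w) tot <- tot + sum(vapply(reads, count_one, 0L, w = rc))
  tot
}

# brute-force oracle for per-read median k-mer coverage (lower median,
# N windows contribute 0)
oracle_median_cov <- function(read, reads, k) {
  n <- nchar(read)
  if (n < k) return(NA_integer_)
  cnts <- vapply(1:(n - k + 1), function(i) {
    w <- substr(read, i, i + k - 1)
    if (grepl("N", w, fixed = TRUE)) return(0L)
    as.integer(oracle_word_count(w, reads))
  }, 0L)
  sort(cnts)[(length(cnts) - 1) %/% 2 + 1]
}

# brute-force oracle for maximal exact matches between a query and one
# read: per-diagonal runs of equality
oracle_mems <- function(query, read, min_len) {
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else as.character(reverse_complement(query))
    qv <- strsplit(q, "")[[1]]
    rv <- strsplit(read, "")[[1]]
    nq <- length(qv); nr <- length(rv)
    for (d in (-(nq - 1)):(nr - 1)) {
      i0 <- max(1, 1 - d); i1 <- min(nq, nr - d)
      if (i1 < i0) next
      eq <- qv[i0:i1] == rv[(i0:i1) + d] & qv[i0:i1] != "N"
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in seq_along(r$values)) {
        if (!r$values[k] || r$lengths[k] < min_len) next
        qs1 <- i0 + starts[k] - 1       # 1-based on strand-oriented query
        len <- r$lengths[k]
        oqs <- if (strand == "+") qs1 - 1 else nq - (qs1 - 1) - len
        rs <- qs1 + d - 1               # 0-based read start
        out[[length(out) + 1L]] <- data.frame(read_start = rs,
                                              query_start = oqs,
                                              length = len, strand = strand,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(read_start = integer(0),
                                      query_start = integer(0),
                                      length = integer(0),
                                      strand = character(0)))
  u <- unique(do.call(rbind, out))
  u[order(u$read_start, u$query_start, u$strand), , drop = FALSE]
}

mem_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(sprintf("%d:%d:%d:%s", df$read_start, df$query_start, df$length,
               df$strand))
}
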