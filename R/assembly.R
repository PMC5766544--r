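# Local assembly: de Bruijn unitigs over recruited reads, then
# overlap-layout-consensus merging of contig sets, plus a greedy
# read-based elongation step for contig ends.

#' Overlap/merge parameter profiles
#'
#' The `permissive` profile mirrors an overlap-permissive assembler
#' configuration (minimum overlap 30, identity 75%, overhang up to 80% of
#' the overlap length) used when combining contig sets during the walk;
#' the `strict` profile (overlap 40, identity 90%) is used for read-based
#' elongation, standing in for assembler defaults.
#'
#' @param profile `"permissive"` or `"strict"`.
#' @param min_overlap_len minimum accepted end-overlap length (>= 10).
#' @param min_overlap_identity minimum overlap identity, percent.
#' @param max_overhang_fraction tolerated unaligned overhang adjacent to
#'   an accepted overlap, as a percent of the overlap length.
#' @param max_internal_gap cap on gap runs inside an accepted overlap
#'   (the aligner here is ungapped, so this is a guard, not a tuning).
#' @return list of class `overlap_params`.
#' @export
overlap_params <- function(profile = c("permissive", "strict"),
                           min_overlap_len = NULL,
                           min_overlap_identity = NULL,
                           max_overhang_fraction = NULL,
                           max_internal_gap = NULL) {
  profile <- match.arg(profile)
  def <- if (profile == "permissive")
    list(min_overlap_len = 30, min_overlap_identity = 75,
         max_overhang_fraction = 80, max_internal_gap = 200)
  else
    list(min_overlap_len = 40, min_overlap_identity = 90,
         max_overhang_fraction = 20, max_internal_gap = 20)
  for (f in names(def)) {
    v <- get(f)
    if (!is.null(v)) def[[f]] <- v
  }
  stopifnot(def$min_overlap_identity > 0, def$min_overlap_identity <= 100,
            def$min_overlap_len >= 10)
  structure(c(def, list(profile = profile)), class = "overlap_params")
}

#' De Bruijn unitigs of a read set
#'
#' Counts canonical k-mers, drops those below `min_count` (absorbing
#' scattered sequencing errors), optionally clips dead-end tips shorter
#' than 2k, and reports the maximal non-branching paths of the resulting
#' graph.  Output is strand-canonical and lexicographically sorted, hence
#' fully deterministic.
#'
#' @param reads character vector of reads (both strands welcome).
#' @param k odd k-mer size (the walk default is 63).
#' @param min_count coverage floor below which k-mers are dropped; use 1
#'   for error-free input.
#' @param clip_tips clip short dead-end unitigs.
#' @return named character vector of contigs (`u0001`, ...).
#' @export
dbg_unitigs <- function(reads, k = 63, min_count = 2, clip_tips = TRUE) {
  stopifnot(k %% 2 == 1, k >= 3)
  reads <- reads[nchar(reads) >= k]
  if (length(reads) == 0) return(stats::setNames(character(0), character(0)))
  u <- cpp_dbg_unitigs(reads, as.integer(k), as.integer(min_count),
                       isTRUE(clip_tips))
  stats::setNames(u, sprintf("u%04d", seq_along(u)))
}

# Best merge of contigs a and b (considering b's reverse complement).
# Arrangements: containment (one contig absorbed) or dovetail (end
# overlap; overhang beyond the overlap tolerated up to the configured
# fraction of the overlap length, then clipped).  The consensus of two
# disagreeing columns is a tie broken toward the longer contig, so the
# overlap region is taken verbatim from the longer contig.
# Returns NULL or list(seq, score, type).
best_pair_merge <- function(a, b, params) {
  la <- nchar(a); lb <- nchar(b)
  best <- NULL
  hs <- cpp_find_hsps(b, a, 11L, as.integer(params$min_overlap_len),
                      params$min_overlap_identity / 100, 20L, TRUE)
  if (nrow(hs)) {
    bo_rc <- NULL
    for (r in seq_len(min(nrow(hs), 5L))) {
      if (hs$strand[r] == "+") {
        bo <- b
        q1 <- hs$q_start[r]; q2 <- hs$q_end[r]
      } else {
        if (is.null(bo_rc)) bo_rc <- as.character(cpp_revcomp(b))
        bo <- bo_rc
        # q interval on b maps to [lb - q_end, lb - q_start) on revcomp(b)
        q1 <- lb - hs$q_end[r]; q2 <- lb - hs$q_start[r]
      }
      s1 <- hs$s_start[r]; s2 <- hs$s_end[r]
      ovl <- hs$length[r]; ident <- hs$ident[r]
      tol <- floor(params$max_overhang_fraction / 100 * ovl)
      score <- ovl * ident
      seg <- if (la >= lb) substr(a, s1 + 1, s2) else substr(bo, q1 + 1, q2)
      # unaligned amounts on each side of the overlap; which of them are
      # overhangs (clipped) depends on the arrangement
      left_a <- s1; right_a <- la - s2
      left_b <- q1; right_b <- lb - q2
      cands <- list()
      if (left_b + right_b <= tol)                 # b contained in a
        cands$contain_b <- a
      if (left_a + right_a <= tol)                 # a contained in b
        cands$contain_a <- bo
      if (right_a + left_b <= tol && right_b > right_a)  # a left, b right
        cands$dovetail_ab <- paste0(substr(a, 1, s1), seg,
                                    substr(bo, q2 + 1, lb))
      if (left_a + right_b <= tol && left_b > left_a)    # b left, a right
        cands$dovetail_ba <- paste0(substr(bo, 1, q1), seg,
                                    substr(a, s2 + 1, la))
      if (length(cands) == 0) next
      # prefer the arrangement losing the least sequence
      pick <- names(cands)[order(-nchar(unlist(cands)),
                                 match(names(cands),
                                       c("contain_b", "contain_a",
                                         "dovetail_ab", "dovetail_ba")))][1]
      cand <- list(seq = cands[[pick]], score = score, type = pick)
      if (is.null(best) || cand$score > best$score)
        best <- cand
    }
  }
  best
}

#' Merge contigs by overlap-layout-consensus
#'
#' Greedily merges the contig pair with the best end-to-end overlap
#' (length >= `min_overlap_len`, identity >= `min_overlap_identity`;
#' overhang beyond the overlap tolerated up to `max_overhang_fraction`
#' percent of the overlap length, then clipped) until no merge applies.
#' Contained contigs are absorbed.  Merge order is by descending overlap
#' score (identity x length), ties broken by contig id, so layout is
#' deterministic.  A contig is never merged with its own reverse
#' complement into a palindromic artifact.
#'
#' @param contigs named character vector.
#' @param params an [overlap_params] profile.
#' @return named character vector; merged contigs keep the id of their
#'   longer constituent.
#' @export
overlap_layout_merge <- function(contigs, params = overlap_params()) {
  stopifnot(inherits(params, "overlap_params"))
  if (length(contigs) < 2) return(contigs)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contigs must have unique names", call. = FALSE)
  work <- contigs
  cache <- new.env(parent = emptyenv())
  pair_key <- function(x, y) paste(sort(c(x, y)), collapse = "\r")
  repeat {
    ids <- sort(names(work))
    if (length(ids) < 2) break
    best <- NULL
    for (i in seq_len(length(ids) - 1)) {
      for (j in (i + 1):length(ids)) {
        k <- pair_key(ids[i], ids[j])
        m <- if (exists(k, envir = cache, inherits = FALSE))
          get(k, envir = cache)
        else {
          v <- best_pair_merge(work[[ids[i]]], work[[ids[j]]], params)
          assign(k, if (is.null(v)) list(NULL) else v, envir = cache)
          if (is.null(v)) list(NULL) else v
        }
        if (is.null(m$seq)) next
        if (is.null(best) || m$score > best$score)
          best <- c(m, list(id_i = ids[i], id_j = ids[j]))
      }
    }
    if (is.null(best)) break
    keep <- if (nchar(work[[best$id_i]]) >= nchar(work[[best$id_j]]))
      best$id_i else best$id_j
    # invalidate cached pairs touching either constituent
    for (other in setdiff(ids, c(best$id_i, best$id_j))) {
      for (gone in c(best$id_i, best$id_j)) {
        k <- pair_key(other, gone)
        if (exists(k, envir = cache, inherits = FALSE)) rm(list = k, envir = cache)
      }
    }
    work <- work[setdiff(names(work), c(best$id_i, best$id_j))]
    work[[keep]] <- best$seq
  }
  work[order(names(work))]
}

#' Elongate a contig with recruited reads
#'
#' Greedy strict-overlap extension: a read whose exact match reaches a
#' contig end and overhangs it (overlap >= the strict profile's minimum,
#' exact by construction) extends that end by its overhang; repeat until
#' no read extends.  The input contig is always contained in the result;
#' length never decreases.
#'
#' @param contig character scalar.
#' @param reads character vector of recruited reads (ignored when
#'   `reads_index` is supplied).
#' @param params an [overlap_params], normally the strict profile.
#' @param reads_index optional prebuilt seed index over `reads` (an
#'   external pointer from `cpp_build_seed_index`), reused across calls.
#' @param max_rounds cap on extension rounds per end.
#' @param window length of the end window queried each round.
#' @return the elongated contig (character scalar).
#' @export
elongate_with_reads <- function(contig, reads,
                                params = overlap_params("strict"),
                                reads_index = NULL, max_rounds = 20,
                                window = 200) {
  if (is.null(reads_index)) {
    if (length(reads) == 0) return(contig)
    reads_index <- cpp_build_seed_index(reads, as.integer(min(20, params$min_overlap_len)))
  }
  extend_right <- function(s) {
    for (round in seq_len(max_rounds)) {
      wl <- min(window, nchar(s))
      win <- substr(s, nchar(s) - wl + 1, nchar(s))
      m <- cpp_find_mems(reads_index, win, as.integer(params$min_overlap_len))
      reach <- which(m$query_start + m$length == wl)
      if (length(reach) == 0) return(s)
      seq_i <- m$seq[reach]
      sstart <- m$subject_start[reach]
      slen <- m$length[reach]
      strand <- m$strand[reach]
      # overhang of each hit read beyond the contig end
      rl <- nchar_index_seq(reads_index, seq_i)
      ext_len <- ifelse(strand == "+", rl - (sstart + slen), sstart)
      if (max(ext_len) <= 0) return(s)
      pick <- order(-ext_len, seq_i, strand)[1]
      rseq <- index_seq(reads_index, seq_i[pick])
      ext <- if (strand[pick] == "+")
        substr(rseq, sstart[pick] + slen[pick] + 1, rl[pick])
      else
        cpp_revcomp(substr(rseq, 1, sstart[pick]))
      s <- paste0(s, ext)
    }
    s
  }
  s <- extend_right(contig)
  s <- cpp_revcomp(extend_right(cpp_revcomp(s)))
  s
}

# helpers to read sequences back out of a seed index pointer
index_seq <- function(ptr, i) cpp_index_seqs(ptr, as.integer(i))
nchar_index_seq <- function(ptr, i) nchar(cpp_index_seqs(ptr, as.integer(i)))
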