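# Post-walk cleanup per transcript: chimera detection/splitting by
# perfect-pair coverage, orientation against the transcript, similarity
# grouping with consensus, exon-order layout, overlap joining, and
# fixed-length N-gap scaffolding.

#' Scaffold container
#'
#' An ordered, oriented sequence of contigs separated by explicit gap
#' records (fixed runs of N).  Parts begin and end with a contig; the
#' rendered FASTA sequence is the concatenation of contig bases and
#' N runs.
#'
#' @param scaffold_id id (normally the source transcript id).
#' @param contigs named character vector, already ordered left to right.
#' @param gaps integer vector of gap lengths between consecutive contigs
#'   (length `length(contigs) - 1`); 0 means the contigs were joined and
#'   should be fused by the caller, so normally all entries equal the
#'   configured spacer (default 500).
#' @return object of class `scaffold`.
#' @export
scaffold <- function(scaffold_id, contigs, gaps = rep(500L, max(0L, length(contigs) - 1L))) {
  stopifnot(length(contigs) >= 1, length(gaps) == length(contigs) - 1)
  parts <- list()
  for (i in seq_along(contigs)) {
    parts[[length(parts) + 1L]] <- list(type = "contig", id = names(contigs)[i],
                                        seq = unname(contigs[[i]]))
    if (i < length(contigs))
      parts[[length(parts) + 1L]] <- list(type = "gap", length = as.integer(gaps[i]),
                                          reason = "no_overlap")
  }
  structure(list(scaffold_id = scaffold_id, parts = parts), class = "scaffold")
}

#' @export
print.scaffold <- function(x, ...) {
  k <- vapply(x$parts, function(p) p$type, "")
  cat(sprintf("<scaffold> %s: %d contig(s), %d gap(s), %d bp rendered\n",
              x$scaffold_id, sum(k == "contig"), sum(k == "gap"),
              nchar(scaffold_sequence(x))))
  invisible(x)
}

#' Rendered scaffold sequence (contigs and N runs)
#' @param x a `scaffold`.
#' @return character scalar.
#' @export
scaffold_sequence <- function(x) {
  stopifnot(inherits(x, "scaffold"))
  paste(vapply(x$parts, function(p)
    if (p$type == "contig") p$seq else strrep("N", p$length), ""), collapse = "")
}

#' Contigs of a scaffold
#' @param x a `scaffold`.
#' @return named character vector.
#' @export
scaffold_contigs <- function(x) {
  stopifnot(inherits(x, "scaffold"))
  ct <- Filter(function(p) p$type == "contig", x$parts)
  stats::setNames(vapply(ct, function(p) p$seq, ""),
                  vapply(ct, function(p) p$id, ""))
}

#' Part coordinates on the rendered sequence
#' @param x a `scaffold`.
#' @return data.frame: part, type, id, start, end (0-based half-open).
#' @export
scaffold_part_coords <- function(x) {
  stopifnot(inherits(x, "scaffold"))
  lens <- vapply(x$parts, function(p)
    if (p$type == "contig") nchar(p$seq) else p$length, 0)
  ends <- cumsum(lens)
  data.frame(part = seq_along(x$parts),
             type = vapply(x$parts, function(p) p$type, ""),
             id = vapply(x$parts, function(p)
               if (p$type == "contig") p$id else NA_character_, ""),
             start = c(0, utils::head(ends, -1)), end = ends,
             stringsAsFactors = FALSE)
}

#' Parse a rendered scaffold back into parts
#'
#' Contigs are the maximal runs between N runs of length >=
#' `min_gap_run`; shorter N runs stay inside contigs.  Round-trips the
#' part structure of scaffolds built with the default 500-N spacer.
#'
#' @param seq rendered sequence.
#' @param scaffold_id id for the result.
#' @param min_gap_run minimum N run treated as a gap.
#' @return a `scaffold`.
#' @export
parse_scaffold <- function(seq, scaffold_id = "scaffold", min_gap_run = 100) {
  m <- gregexpr(sprintf("N{%d,}", min_gap_run), seq)[[1]]
  if (m[1] == -1) {
    ct <- stats::setNames(seq, paste0(scaffold_id, "_c001"))
    return(scaffold(scaffold_id, ct, integer(0)))
  }
  gs <- as.integer(m)
  gl <- attr(m, "match.length")
  starts <- c(1L, gs + gl)
  ends <- c(gs - 1L, nchar(seq))
  ctg <- substring(seq, starts, ends)
  keep <- nchar(ctg) > 0
  if (!all(keep))
    stop("rendered scaffold begins or ends with a gap", call. = FALSE)
  names(ctg) <- sprintf("%s_c%03d", scaffold_id, seq_along(ctg))
  scaffold(scaffold_id, ctg, gl)
}

#' Detect likely-chimeric contigs
#'
#' A contig is flagged when it carries two or more transcript alignment
#' blocks covering overlapping transcript intervals (overlap >=
#' `min_overlap` bases) at distinct, non-overlapping contig intervals --
#' i.e. the same exonic sequence appears twice in one contig.
#'
#' @param transcript character scalar.
#' @param contigs named character vector.
#' @param cfg a [walker_config] (HSP floors).
#' @param min_overlap minimum transcript-interval overlap between two
#'   blocks to count as "the same exon sequence".
#' @return character vector of flagged contig ids.
#' @export
detect_chimeric_contigs <- function(transcript, contigs, cfg = walker_config(),
                                    min_overlap = 20) {
  flagged <- character(0)
  for (id in names(contigs)) {
    h <- find_hsps(transcript, contigs[[id]], min_len = cfg$hsp_min_len,
                   min_ident = cfg$hsp_min_ident)
    if (nrow(h) < 2) next
    for (i in seq_len(nrow(h) - 1)) {
      for (j in (i + 1):nrow(h)) {
        t_ovl <- min(h$q_end[i], h$q_end[j]) - max(h$q_start[i], h$q_start[j])
        c_ovl <- min(h$s_end[i], h$s_end[j]) - max(h$s_start[i], h$s_start[j])
        if (t_ovl >= min_overlap && c_ovl < min_overlap) {
          flagged <- c(flagged, id)
          break
        }
      }
      if (id %in% flagged) break
    }
  }
  flagged
}

#' Perfect proper-pair coverage profile of a contig
#'
#' A pair contributes iff both mates occur in the contig full-length with
#' zero mismatches, in convergent orientation, with an implied insert in
#' `insert_range`.  Contributing pairs add 1 over the union of their mate
#' intervals (`coverage`) and mark strictly interior positions of that
#' union as `spanned`.
#'
#' @param contig character scalar.
#' @param pairs recruited [read_pairs].
#' @param insert_range numeric length-2; default `[0.5, 2] x` the median
#'   candidate insert.
#' @return list of class `pair_coverage`: integer `coverage`, logical
#'   `spanned`, both of contig length; `n_pairs_used`.
#' @export
perfect_pair_coverage <- function(contig, pairs, insert_range = NULL) {
  L <- nchar(contig)
  cov <- integer(L)
  spanned <- logical(L)
  n <- nrow(pairs)
  if (n > 0) {
    occ <- cpp_exact_occurrences(contig, c(pairs$seq1, pairs$seq2))
    placements <- NULL
    if (nrow(occ) > 0) {
      occ$pair <- ifelse(occ$query > n, occ$query - n, occ$query)
      occ$mate <- ifelse(occ$query > n, 2L, 1L)
      occ$len <- ifelse(occ$mate == 1L, nchar(pairs$seq1)[occ$pair],
                        nchar(pairs$seq2)[occ$pair])
      # candidate convergent placements: '+' mate left of '-' mate end
      cand <- list()
      for (p in unique(occ$pair)) {
        o1 <- occ[occ$pair == p & occ$mate == 1L, , drop = FALSE]
        o2 <- occ[occ$pair == p & occ$mate == 2L, , drop = FALSE]
        if (nrow(o1) == 0 || nrow(o2) == 0) next
        for (i in seq_len(nrow(o1))) {
          for (j in seq_len(nrow(o2))) {
            a <- o1[i, ]; b <- o2[j, ]
            fw <- if (a$strand == "+" && b$strand == "-") a
                  else if (b$strand == "+" && a$strand == "-") b
                  else next
            rv <- if (identical(fw, a)) b else a
            ins <- (rv$pos + rv$len) - fw$pos
            if (ins < max(fw$len, rv$len)) next
            cand[[length(cand) + 1L]] <- data.frame(
              pair = p, start = fw$pos, end = rv$pos + rv$len, insert = ins)
          }
        }
      }
      if (length(cand)) placements <- do.call(rbind, cand)
    }
    if (!is.null(placements) && nrow(placements)) {
      if (is.null(insert_range)) {
        med <- stats::median(placements$insert)
        insert_range <- c(0.5 * med, 2 * med)
      }
      ok <- placements$insert >= insert_range[1] &
        placements$insert <= insert_range[2]
      placements <- placements[ok, , drop = FALSE]
      # one placement per pair: the smallest valid insert
      placements <- placements[order(placements$pair, placements$insert), ,
                               drop = FALSE]
      placements <- placements[!duplicated(placements$pair), , drop = FALSE]
      for (r in seq_len(nrow(placements))) {
        s <- placements$start[r]; e <- placements$end[r]
        cov[(s + 1):e] <- cov[(s + 1):e] + 1L
        if (e - s > 2) spanned[(s + 2):(e - 1)] <- TRUE
      }
    }
  }
  structure(list(coverage = cov, spanned = spanned,
                 n_pairs_used = if (exists("placements") && !is.null(placements))
                   nrow(placements) else 0L),
            class = "pair_coverage")
}

#' Split a chimeric contig at unsupported internal regions
#'
#' Internal maximal regions with coverage 0, and internal positions never
#' spanned by any contributing pair, are excised; runs touching either
#' contig end are never removed.  Flanking sub-contigs are returned in
#' original order.
#'
#' @param contig character scalar (typically one flagged by
#'   [detect_chimeric_contigs]).
#' @param profile a `pair_coverage` for this contig.
#' @param min_piece drop resulting pieces shorter than this.
#' @return named character vector of sub-contigs (`_s1`, `_s2`, ... when
#'   split; the input contig unchanged otherwise).
#' @export
split_contig <- function(contig, profile, min_piece = 1) {
  stopifnot(inherits(profile, "pair_coverage"))
  L <- nchar(contig)
  bad <- profile$coverage == 0 | !profile$spanned
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- rep(TRUE, L)
  for (i in seq_along(r$values)) {
    if (r$values[i] && starts[i] > 1 && ends[i] < L)
      keep[starts[i]:ends[i]] <- FALSE
  }
  if (all(keep)) return(stats::setNames(contig, "c1"))
  kr <- rle(keep)
  ke <- cumsum(kr$lengths)
  ks <- ke - kr$lengths + 1
  pieces <- substring(contig, ks[kr$values], ke[kr$values])
  pieces <- pieces[nchar(pieces) >= min_piece]
  stats::setNames(pieces, paste0("s", seq_along(pieces)))
}

#' Orient contigs according to the transcript
#'
#' Each contig whose best-scoring transcript alignment lies on the `-`
#' strand is reverse complemented.  Contigs with no alignment are left
#' untouched and flagged; contigs with mixed-strand alignments are
#' oriented by the best-scoring one and flagged.
#'
#' @param transcript character scalar.
#' @param contigs named character vector.
#' @param cfg a [walker_config].
#' @return list: `contigs` (oriented), `flagged` (ids).
#' @export
orient_contigs <- function(transcript, contigs, cfg = walker_config()) {
  flagged <- character(0)
  out <- contigs
  for (id in names(contigs)) {
    h <- find_hsps(transcript, contigs[[id]], min_len = cfg$hsp_min_len,
                   min_ident = cfg$hsp_min_ident)
    if (nrow(h) == 0) {
      flagged <- c(flagged, id)
      next
    }
    if (length(unique(h$strand)) > 1) flagged <- c(flagged, id)
    if (h$strand[1] == "-") out[[id]] <- cpp_revcomp(contigs[[id]])
  }
  list(contigs = out, flagged = flagged)
}

#' Collapse near-identical contigs to a consensus
#'
#' Contigs sharing an alignment of >= `min_sim_len` bases at >=
#' `min_sim_ident` percent identity (same strand; contigs are expected to
#' be oriented already) are grouped by transitive closure.  Each group is
#' replaced by a column-majority consensus anchored on its longest
#' member (ties to the anchor); singletons pass through.
#'
#' @param contigs named character vector (oriented).
#' @param min_sim_len minimum similarity-region length.
#' @param min_sim_ident minimum similarity identity, percent.
#' @return named character vector (group consensi keep the anchor's id).
#' @export
group_and_consensus <- function(contigs, min_sim_len = 200, min_sim_ident = 95) {
  n <- length(contigs)
  if (n < 2) return(contigs)
  ids <- names(contigs)
  parent <- stats::setNames(seq_len(n), ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  sim <- vector("list", 0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      h <- find_hsps(contigs[[j]], contigs[[i]], min_len = min_sim_len,
                     min_ident = min_sim_ident / 100, both_strands = FALSE)
      if (nrow(h)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  out <- character(0)
  for (r in sort(unique(roots))) {
    members <- contigs[roots == r]
    if (length(members) == 1) {
      out[names(members)] <- members
      next
    }
    anchor_id <- names(members)[order(-nchar(members), names(members))][1]
    out[anchor_id] <- .column_consensus(members, anchor_id)
  }
  out[order(names(out))]
}

# Column-majority consensus of near-identical contigs: each member is
# projected onto the anchor's coordinates along its best ungapped
# alignment diagonal; ties go to the anchor (then to longer members).
.column_consensus <- function(members, anchor_id) {
  anchor <- members[[anchor_id]]
  proj <- list()
  ord <- names(members)[order(-nchar(members), names(members))]
  for (id in ord) {
    if (id == anchor_id) { proj[[id]] <- list(off = 0L, seq = anchor); next }
    h <- find_hsps(members[[id]], anchor, min_len = 40, min_ident = 0.8,
                   both_strands = FALSE)
    if (nrow(h) == 0) next
    proj[[id]] <- list(off = h$s_start[1] - h$q_start[1], seq = members[[id]])
  }
  lo <- min(vapply(proj, function(p) p$off, 0L))
  hi <- max(vapply(proj, function(p) p$off + nchar(p$seq), 0L))
  width <- hi - lo
  counts <- matrix(0L, nrow = 4, ncol = width)
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  first <- integer(width)  # base of the first (= preferred) writer
  for (id in names(proj)) {
    p <- proj[[id]]
    v <- code[strsplit(p$seq, "")[[1]]]
    pos <- (p$off - lo) + seq_along(v)
    okv <- !is.na(v)
    idx <- cbind(v[okv], pos[okv])
    counts[idx] <- counts[idx] + 1L
    newpos <- pos[okv][first[pos[okv]] == 0L]
    first[newpos] <- v[okv][first[pos[okv]] == 0L]
  }
  best <- max.col(t(counts), ties.method = "first")
  tallies <- counts[cbind(best, seq_len(width))]
  # ties: prefer the anchor/longest member's base (the first writer)
  for (i in seq_len(width)) {
    if (first[i] > 0L && counts[first[i], i] == tallies[i]) best[i] <- first[i]
  }
  paste(c("A", "C", "G", "T")[best], collapse = "")
}

#' Order contigs by transcript position and join into one scaffold
#'
#' Contigs are sorted by the transcript coordinate of their best
#' alignment block; adjacent contigs with a detectable end overlap
#' (>= `join_min_overlap` bases at >= `join_min_ident` percent) are fused
#' using the overlap consensus, otherwise a fixed N gap separates them.
#'
#' @param transcript character scalar.
#' @param contigs named character vector, oriented.
#' @param gap_len gap spacer length (default 500 N).
#' @param join_min_overlap,join_min_ident overlap acceptance floors.
#' @param cfg a [walker_config].
#' @return a `scaffold` (id = name of `transcript` if present).
#' @export
order_and_join <- function(transcript, contigs, gap_len = 500,
                           join_min_overlap = 30, join_min_ident = 90,
                           cfg = walker_config()) {
  sid <- if (!is.null(names(transcript))) names(transcript)[1] else "scaffold"
  transcript <- unname(transcript)
  keys <- data.frame(id = names(contigs), q = NA_integer_,
                     len = nchar(contigs), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(keys))) {
    h <- find_hsps(transcript, contigs[[keys$id[i]]], min_len = cfg$hsp_min_len,
                   min_ident = cfg$hsp_min_ident)
    if (nrow(h)) keys$q[i] <- h$q_start[1]
  }
  keys <- keys[!is.na(keys$q), , drop = FALSE]
  if (nrow(keys) == 0) stop("no contig aligns to the transcript", call. = FALSE)
  if (anyDuplicated(keys$q))
    warning("contigs tie on transcript position; breaking by length then id")
  keys <- keys[order(keys$q, -keys$len, keys$id), , drop = FALSE]
  .join_ordered(contigs[keys$id], sid, gap_len, join_min_overlap,
                join_min_ident)
}

# Fuse-or-gap walk over contigs already in layout order: adjacent contigs
# with an acceptable end overlap are fused on the overlap consensus,
# otherwise separated by a fixed N gap.
.join_ordered <- function(ordered, scaffold_id, gap_len = 500,
                          join_min_overlap = 30, join_min_ident = 90,
                          max_overhang_fraction = 80) {
  cur_seq <- ordered[[1]]
  cur_id <- names(ordered)[1]
  out_ct <- character(0)
  out_gap <- integer(0)
  if (length(ordered) > 1) {
    for (i in 2:length(ordered)) {
      nxt <- ordered[[i]]
      h <- find_hsps(nxt, cur_seq, min_len = join_min_overlap,
                     min_ident = join_min_ident / 100, both_strands = FALSE)
      fused <- FALSE
      if (nrow(h)) {
        q1 <- h$q_start[1]; q2 <- h$q_end[1]
        s1 <- h$s_start[1]; s2 <- h$s_end[1]
        la <- nchar(cur_seq); lb <- nchar(nxt)
        tol <- floor(max_overhang_fraction / 100 * h$length[1])
        if (q1 + (la - s2) <= tol && (lb - q2) > (la - s2)) {
          seg <- if (la >= lb) substr(cur_seq, s1 + 1, s2) else substr(nxt, q1 + 1, q2)
          cur_seq <- paste0(substr(cur_seq, 1, s1), seg, substr(nxt, q2 + 1, lb))
          fused <- TRUE
        } else if (q1 <= tol && (lb - q2) <= tol) {
          fused <- TRUE  # next contig contained in current
        }
      }
      if (!fused) {
        out_ct[cur_id] <- cur_seq
        out_gap <- c(out_gap, as.integer(gap_len))
        cur_seq <- nxt
        cur_id <- names(ordered)[i]
      }
    }
  }
  out_ct[cur_id] <- cur_seq
  scaffold(scaffold_id, out_ct, out_gap)
}

#' Finish one walk into a scaffold
#'
#' The per-transcript cleanup sequence: flag and split chimeric contigs
#' (perfect-pair coverage), orient against the transcript, collapse
#' near-identical alternative assemblies to consensus, order by exon
#' position and join with overlap consensus or fixed N gaps.
#'
#' @param state a `walk_state` with contigs.
#' @param pairs the full depleted [read_pairs] table (the state's
#'   recruited subset is used).
#' @param cfg a [walker_config].
#' @param gap_len N-gap spacer length.
#' @param insert_range proper-pair insert range for chimera coverage;
#'   default derives from the data (see [perfect_pair_coverage]).
#' @return a `scaffold`, or `NULL` when the state has no contigs.
#' @export
finish_walk <- function(state, pairs, cfg = walker_config(), gap_len = 500,
                        insert_range = NULL) {
  stopifnot(inherits(state, "walk_state"))
  if (length(state$contigs) == 0) return(NULL)
  contigs <- state$contigs
  rec <- pairs_subset(pairs, state$recruited)
  flagged <- detect_chimeric_contigs(state$transcript, contigs, cfg)
  for (id in flagged) {
    prof <- perfect_pair_coverage(contigs[[id]], rec, insert_range)
    pieces <- split_contig(contigs[[id]], prof)
    contigs <- contigs[setdiff(names(contigs), id)]
    if (length(pieces) == 1 && names(pieces)[1] == "c1") {
      contigs[id] <- pieces
    } else if (length(pieces)) {
      contigs[paste0(id, "_", names(pieces))] <- pieces
    }
  }
  ori <- orient_contigs(state$transcript, contigs, cfg)
  contigs <- ori$contigs
  contigs <- group_and_consensus(contigs)
  # contigs that lost their transcript alignment (e.g. split remnants of
  # pure intergenic sequence) cannot be placed
  placeable <- vapply(names(contigs), function(id) {
    nrow(find_hsps(state$transcript, contigs[[id]], min_len = cfg$hsp_min_len,
                   min_ident = cfg$hsp_min_ident)) > 0
  }, TRUE)
  # keep unplaceable contigs only if pair-linked to a placeable one
  if (any(!placeable) && any(placeable)) {
    lnk <- paired_link_contigs(contigs[placeable], contigs[!placeable], rec, cfg)
    drop <- setdiff(names(contigs)[!placeable], lnk$retained)
    contigs <- contigs[setdiff(names(contigs), drop)]
  } else if (!any(placeable)) {
    return(NULL)
  }
  # unplaceable-but-linked contigs cannot be ordered by exon position;
  # they are appended after the last placed contig
  placed <- names(contigs)[vapply(names(contigs), function(id) {
    nrow(find_hsps(state$transcript, contigs[[id]], min_len = cfg$hsp_min_len,
                   min_ident = cfg$hsp_min_ident)) > 0
  }, TRUE)]
  sc <- order_and_join(stats::setNames(state$transcript, state$transcript_id),
                       contigs[placed], gap_len = gap_len, cfg = cfg)
  extra <- setdiff(names(contigs), placed)
  if (length(extra)) {
    ct <- c(scaffold_contigs(sc), contigs[extra])
    sc <- scaffold(sc$scaffold_id, ct, rep(as.integer(gap_len), length(ct) - 1))
  }
  sc
}
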