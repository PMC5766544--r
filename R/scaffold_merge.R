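# Scaffold post-processing: map transcripts back to scaffolds by chained
# alignment blocks, drop contigs no transcript maps to, and collapse
# scaffolds derived from splice variants / fragments of one gene.
#
# Splice-aware alignment is replaced by coordinate-monotone HSP chaining:
# scaffolds were built around these very transcripts, so near-exact
# blocks exist and base-pair-precise intron boundaries are not claimed.

#' Map a transcript onto a scaffold as chained exon blocks
#'
#' HSPs between transcript and rendered scaffold are computed, the strand
#' with the larger total match count is kept, and a highest-weight chain
#' with increasing transcript and scaffold coordinates is selected;
#' transcript-side overlaps between adjacent chained blocks are trimmed.
#'
#' @param transcript character scalar.
#' @param scaffold a `scaffold` or a rendered sequence.
#' @param cfg a [walker_config] (HSP floors).
#' @return list of class `exon_mapping`: `blocks` (data.frame t_start,
#'   t_end, s_start, s_end, ident), `strand`, `coverage` (fraction of the
#'   transcript inside blocks).  Empty blocks when nothing aligns.
#' @export
map_transcript_to_scaffold <- function(transcript, scaffold,
                                       cfg = walker_config()) {
  seq <- if (inherits(scaffold, "scaffold")) scaffold_sequence(scaffold) else scaffold
  empty <- structure(list(blocks = data.frame(t_start = integer(0),
                                              t_end = integer(0),
                                              s_start = integer(0),
                                              s_end = integer(0),
                                              ident = numeric(0)),
                          strand = "+", coverage = 0), class = "exon_mapping")
  if (nchar(seq) == 0) return(empty)
  hs <- find_hsps(transcript, seq, min_len = cfg$hsp_min_len,
                  min_ident = cfg$hsp_min_ident)
  if (nrow(hs) == 0) return(empty)
  tot <- tapply(hs$matches, hs$strand, sum)
  st <- names(tot)[which.max(tot)]
  hs <- hs[hs$strand == st, , drop = FALSE]
  hs <- hs[order(hs$q_start, hs$s_start), , drop = FALSE]
  n <- nrow(hs)
  slack <- 10L
  # weighted chain DP: increasing transcript AND scaffold coordinates
  f <- hs$matches
  pred <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      compat_q <- hs$q_start[i] >= hs$q_end[j] - slack &&
        hs$q_end[i] > hs$q_end[j]
      compat_s <- if (st == "+")
        hs$s_start[i] >= hs$s_end[j] - slack && hs$s_end[i] > hs$s_end[j]
      else
        hs$s_end[i] <= hs$s_start[j] + slack && hs$s_start[i] < hs$s_start[j]
      if (compat_q && compat_s && f[j] + hs$matches[i] > f[i]) {
        f[i] <- f[j] + hs$matches[i]
        pred[i] <- j
      }
    }
  }
  i <- which.max(f)
  chain <- integer(0)
  while (i > 0) { chain <- c(i, chain); i <- pred[i] }
  b <- hs[chain, , drop = FALSE]
  # trim transcript-side overlaps between adjacent blocks
  if (nrow(b) > 1) {
    for (i in 2:nrow(b)) {
      d <- b$q_end[i - 1] - b$q_start[i]
      if (d > 0) {
        b$q_start[i] <- b$q_start[i] + d
        if (st == "+") b$s_start[i] <- b$s_start[i] + d
        else b$s_end[i] <- b$s_end[i] - d
      }
    }
  }
  blocks <- data.frame(t_start = b$q_start, t_end = b$q_end,
                       s_start = b$s_start, s_end = b$s_end,
                       ident = b$ident)
  structure(list(blocks = blocks, strand = st,
                 coverage = sum(blocks$t_end - blocks$t_start) /
                   nchar(transcript)),
            class = "exon_mapping")
}

#' @export
print.exon_mapping <- function(x, ...) {
  cat(sprintf("<exon_mapping> %d block(s), strand %s, %.1f%% of transcript\n",
              nrow(x$blocks), x$strand, 100 * x$coverage))
  invisible(x)
}

#' Remove contigs no transcript block maps to
#'
#' Contigs (gap-delimited scaffold parts) intersecting no mapping block
#' are removed; neighbouring gaps collapse to one.  When every contig is
#' unmapped the result is an empty scaffold carrying attribute
#' `flagged_empty`.
#'
#' @param scaffold a `scaffold`.
#' @param mapping the scaffold's own-transcript `exon_mapping` (or a list
#'   of mappings whose blocks are pooled).
#' @return a `scaffold`.
#' @export
strip_unmapped_contigs <- function(scaffold, mapping) {
  stopifnot(inherits(scaffold, "scaffold"))
  if (inherits(mapping, "exon_mapping")) mapping <- list(mapping)
  blocks <- do.call(rbind, lapply(mapping, function(m) m$blocks))
  pc <- scaffold_part_coords(scaffold)
  ct <- pc[pc$type == "contig", , drop = FALSE]
  keep <- vapply(seq_len(nrow(ct)), function(i) {
    any(blocks$s_start < ct$end[i] & blocks$s_end > ct$start[i])
  }, TRUE)
  if (!any(keep)) {
    out <- structure(list(scaffold_id = scaffold$scaffold_id, parts = list()),
                     class = "scaffold")
    attr(out, "flagged_empty") <- TRUE
    return(out)
  }
  ctg <- scaffold_contigs(scaffold)[keep]
  gap_len <- {
    gl <- pc$end[pc$type == "gap"] - pc$start[pc$type == "gap"]
    if (length(gl)) as.integer(gl[1]) else 500L
  }
  scaffold(scaffold$scaffold_id, ctg,
           rep(gap_len, max(0L, length(ctg) - 1L)))
}

#' Group scaffolds that describe the same locus
#'
#' Scaffolds are processed longest first.  A candidate scaffold joins the
#' current group iff every one of its own exon blocks lies inside a
#' scaffold-to-scaffold HSP of at least `min_ident_all` percent identity
#' and at least one block lies inside an HSP of `min_ident_one` percent.
#' Groups are disjoint; input order does not affect the result.
#'
#' @param scaffolds named list of `scaffold` objects (names are their
#'   transcript ids).
#' @param transcripts named character vector covering those ids.
#' @param min_ident_all,min_ident_one identity floors, percent (the
#'   published rule: 95 everywhere, 99 at least once).
#' @param cfg a [walker_config].
#' @param slack coordinate slack (bases) when testing block containment.
#' @return list of character vectors of scaffold ids (each a group).
#' @export
find_redundant_groups <- function(scaffolds, transcripts,
                                  min_ident_all = 95, min_ident_one = 99,
                                  cfg = walker_config(), slack = 20) {
  ids <- names(scaffolds)
  stopifnot(!is.null(ids), all(ids %in% names(transcripts)))
  seqs <- lapply(scaffolds, scaffold_sequence)
  ord <- ids[order(-vapply(seqs, nchar, 0), ids)]
  own_blocks <- lapply(ids, function(id)
    map_transcript_to_scaffold(transcripts[[id]], seqs[[id]], cfg)$blocks)
  names(own_blocks) <- ids
  assigned <- character(0)
  groups <- list()
  for (s in ord) {
    if (s %in% assigned) next
    grp <- s
    assigned <- c(assigned, s)
    for (cid in setdiff(ord, assigned)) {
      bl <- own_blocks[[cid]]
      if (nrow(bl) == 0) next
      hs <- find_hsps(seqs[[cid]], seqs[[s]], min_len = cfg$hsp_min_len,
                      min_ident = min_ident_all / 100 - 0.02)
      if (nrow(hs) == 0) next
      in_hsp <- function(b, min_id) {
        any(hs$ident * 100 >= min_id &
              hs$q_start <= bl$s_start[b] + slack &
              hs$q_end >= bl$s_end[b] - slack)
      }
      all95 <- all(vapply(seq_len(nrow(bl)), in_hsp, TRUE,
                          min_id = min_ident_all))
      one99 <- any(vapply(seq_len(nrow(bl)), in_hsp, TRUE,
                          min_id = min_ident_one))
      if (all95 && one99) {
        grp <- c(grp, cid)
        assigned <- c(assigned, cid)
      }
    }
    groups[[length(groups) + 1L]] <- grp
  }
  groups
}

#' Merge a group of same-locus scaffolds into one
#'
#' Pools the groups' contigs, merges them by overlap-layout-consensus,
#' collapses remaining near-identical contigs to consensus, orders the
#' final contigs by the member transcripts' mappings (the longest
#' transcript's order wins conflicts) and joins them.
#'
#' @param scaffolds named list of the group's `scaffold`s.
#' @param transcripts named character vector covering the group.
#' @param cfg a [walker_config].
#' @param gap_len N-gap spacer.
#' @return a single `scaffold` (id = longest member transcript's id).
#' @export
merge_group <- function(scaffolds, transcripts, cfg = walker_config(),
                        gap_len = 500) {
  ids <- names(scaffolds)
  if (length(ids) == 1) return(scaffolds[[1]])
  txs <- transcripts[ids]
  txs <- txs[order(-nchar(txs), names(txs))]
  pool <- character(0)
  for (id in ids) {
    ct <- scaffold_contigs(scaffolds[[id]])
    names(ct) <- paste0(id, ".", names(ct))
    pool <- c(pool, ct)
  }
  merged <- overlap_layout_merge(pool, overlap_params("permissive"))
  merged <- group_and_consensus(merged)
  # layout key: first transcript (longest first) with an alignment, then
  # its coordinate
  key_rank <- rep(NA_integer_, length(merged))
  key_pos <- rep(NA_integer_, length(merged))
  for (ci in seq_along(merged)) {
    for (ti in seq_along(txs)) {
      h <- find_hsps(txs[[ti]], merged[[ci]], min_len = cfg$hsp_min_len,
                     min_ident = cfg$hsp_min_ident)
      if (nrow(h)) {
        key_rank[ci] <- ti
        key_pos[ci] <- h$q_start[1]
        break
      }
    }
  }
  placeable <- !is.na(key_rank)
  if (!any(placeable))
    stop("no contig in the merged group aligns to any member transcript",
         call. = FALSE)
  ord <- order(key_rank[placeable], key_pos[placeable],
               -nchar(merged[placeable]), names(merged)[placeable])
  ordered <- merged[placeable][ord]
  .join_ordered(ordered, names(txs)[1], gap_len = gap_len)
}
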