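# Post-hoc reports: intron bridging, flank walk lengths, contig-end stop
# classification, and assembly size statistics.

#' N50 of a length set
#' @param lengths numeric vector of sequence lengths.
#' @return the N50 (0 for an empty set).
#' @export
n50 <- function(lengths) {
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  if (length(lengths) == 0 || sum(lengths) == 0) return(0)
  lengths[which(cumsum(lengths) >= sum(lengths) / 2)[1]]
}

#' Intron report for one gene model
#'
#' Introns are the scaffold intervals between consecutive transcript
#' blocks.  An intron is bridged iff no gap record lies between its
#' flanking blocks (both exons on one contig); its length counts real
#' bases only (gap Ns are excluded, and such cases are already flagged
#' unreliable when >= 2 gap records fall inside).
#'
#' @param scaffold a `scaffold`.
#' @param mapping an `exon_mapping` of the gene's transcript.
#' @param gene_id id for the report.
#' @return data.frame: gene_id, intron_index, length, bridged, reliable.
#'   Empty for single-block mappings.
#' @export
intron_report <- function(scaffold, mapping, gene_id = scaffold$scaffold_id) {
  stopifnot(inherits(scaffold, "scaffold"), inherits(mapping, "exon_mapping"))
  b <- mapping$blocks
  if (mapping$strand == "-") b <- b[order(b$s_start), , drop = FALSE]
  if (nrow(b) < 2)
    return(data.frame(gene_id = character(0), intron_index = integer(0),
                      length = integer(0), bridged = logical(0),
                      reliable = logical(0)))
  pc <- scaffold_part_coords(scaffold)
  gaps <- pc[pc$type == "gap", , drop = FALSE]
  out <- lapply(seq_len(nrow(b) - 1), function(i) {
    lo <- b$s_end[i]
    hi <- b$s_start[i + 1]
    if (hi < lo) { tmp <- lo; lo <- hi; hi <- tmp }
    inside <- gaps$start >= lo & gaps$end <= hi
    gap_bases <- sum(gaps$end[inside] - gaps$start[inside])
    data.frame(gene_id = gene_id, intron_index = i,
               length = (hi - lo) - gap_bases,
               bridged = !any(inside),
               reliable = sum(inside) < 2)
  })
  do.call(rbind, out)
}

#' Flank lengths walked beyond the outermost exons
#'
#' Real bases (N gaps excluded) from the scaffold start to the first
#' transcript block, and from the last block to the scaffold end.
#'
#' @param scaffold a `scaffold`.
#' @param mapping an `exon_mapping` with at least one block.
#' @return named numeric: upstream, downstream.
#' @export
flank_report <- function(scaffold, mapping) {
  stopifnot(inherits(scaffold, "scaffold"), inherits(mapping, "exon_mapping"),
            nrow(mapping$blocks) > 0)
  pc <- scaffold_part_coords(scaffold)
  gaps <- pc[pc$type == "gap", , drop = FALSE]
  total <- max(pc$end)
  lo <- min(mapping$blocks$s_start)
  hi <- max(mapping$blocks$s_end)
  gap_in <- function(a, b) {
    if (b <= a) return(0)
    sum(pmax(0, pmin(gaps$end, b) - pmax(gaps$start, a)))
  }
  c(upstream = lo - gap_in(0, lo),
    downstream = (total - hi) - gap_in(hi, total))
}

#' Classify why each contig end stopped extending
#'
#' For every contig end of every finished walk, the median read coverage
#' over the terminal 60 bases is computed from `pairs` aligned to the
#' contigs.  Ends that still changed in the walk's final iteration are
#' `extending`; stopped ends with median coverage above the mode of the
#' extending ends' medians (integer-binned) are `repeat`, the rest
#' `low_coverage`.
#'
#' @param states list of `walk_state`s.
#' @param pairs [read_pairs] used as the coverage source.  Using the
#'   pre-depletion read set makes high-copy repeats visible even when
#'   depletion removed them from the walk.
#' @param cfg a [walker_config].
#' @param fallback_threshold used when no end is still extending
#'   (mode undefined); a warning is raised.
#' @param window terminal window length (60 bases).
#' @return data.frame: transcript, contig, end, median_cov, status.
#' @export
end_status_report <- function(states, pairs, cfg = walker_config(),
                              fallback_threshold = NULL, window = 60) {
  rows <- list()
  reads <- c(pairs$seq1, pairs$seq2)
  for (st in states) {
    if (!inherits(st, "walk_state") || length(st$contigs) == 0) next
    aln <- align_reads_to_contigs(reads, st$contigs)
    # count clipped alignments too (a depth track would): a repeat read
    # overlapping a contig's terminal repeat stub contributes over its
    # aligned part even though most of the read hangs off the end
    aln <- aln[aln$ident >= 0.95 & (aln$c_end - aln$c_start) >= 50, ,
               drop = FALSE]
    # which ends changed in the final iteration?
    nh <- length(st$end_history)
    final_tails <- st$end_history[[nh]]
    prev_tails <- if (nh >= 2) st$end_history[[nh - 1]]$tail else character(0)
    prev_all <- unique(c(prev_tails, as.character(cpp_revcomp(prev_tails))))
    for (r in seq_len(nrow(final_tails))) {
      id <- final_tails$contig[r]
      side <- final_tails$end[r]
      L <- nchar(st$contigs[[id]])
      iv <- if (side == "L") c(0, min(window, L)) else c(max(0, L - window), L)
      a <- aln[aln$contig == id, , drop = FALSE]
      cov <- integer(iv[2] - iv[1])
      if (nrow(a)) {
        for (k in seq_len(nrow(a))) {
          lo <- max(a$c_start[k], iv[1])
          hi <- min(a$c_end[k], iv[2])
          if (hi > lo) {
            ix <- (lo - iv[1] + 1):(hi - iv[1])
            cov[ix] <- cov[ix] + 1L
          }
        }
      }
      med <- as.numeric(stats::median(cov))
      changed <- st$status == "extending" &&
        !(final_tails$tail[r] %in% prev_all)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript = st$transcript_id, contig = id, end = side,
        median_cov = med,
        status = if (changed) "extending" else "stopped",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  ext <- out$median_cov[out$status == "extending"]
  if (length(ext)) {
    bins <- floor(ext)  # integer-binned medians, bin width 1x
    mode_cov <- as.numeric(names(which.max(table(bins))))
  } else {
    if (is.null(fallback_threshold))
      fallback_threshold <- 2 * stats::median(out$median_cov)
    warning("no extending ends: falling back to configured threshold")
    mode_cov <- fallback_threshold
  }
  stopped <- out$status == "stopped"
  out$status[stopped] <- ifelse(out$median_cov[stopped] > mode_cov,
                                "repeat", "low_coverage")
  attr(out, "extending_mode") <- if (length(ext)) mode_cov else NA_real_
  out
}

#' Assembly size summary excluding gap Ns
#'
#' Contig and scaffold counts, lengths and N50 with the artificial
#' N spacers excluded from all length accounting.
#'
#' @param scaffolds list of `scaffold`s.
#' @return one-row data.frame.
#' @export
assembly_summary <- function(scaffolds) {
  scaffolds <- Filter(function(s) inherits(s, "scaffold") &&
                        length(s$parts) > 0, scaffolds)
  ctg_lens <- unlist(lapply(scaffolds, function(s) nchar(scaffold_contigs(s))))
  scf_lens <- vapply(scaffolds, function(s) sum(nchar(scaffold_contigs(s))), 0)
  data.frame(n_scaffolds = length(scaffolds),
             n_contigs = length(ctg_lens),
             contig_n50 = n50(ctg_lens),
             scaffold_n50 = n50(scf_lens),
             total_bases = sum(as.numeric(ctg_lens)))
}
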