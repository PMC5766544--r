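# The iteration engine: seed a walk from a transcript, then repeatedly
# recruit reads from contig end windows, assemble, merge, classify, and
# apply the continue/stop/drop rules.

#' Walker configuration
#'
#' Defaults follow the published operating point: initial recruitment at
#' 40 bp exact matches against the whole transcript, extension rounds at
#' 60 bp exact matches against the terminal 600 bp of each contig end,
#' local assembly at k = 63, up to 30 iterations, and a drop rule firing
#' when a transcript's contig count reaches 500 or triples within one
#' iteration (runaway repeat recruitment).
#'
#' @param min_match_initial minimum exact-match length when seeding.
#' @param min_match_extend minimum exact-match length when extending.
#' @param end_window bases taken from each contig end as extension query.
#' @param assembly_k de Bruijn k-mer size.
#' @param max_iterations extension iterations after seeding.
#' @param max_contigs drop the transcript when its contig count reaches
#'   this value.
#' @param contig_growth_drop_factor drop when the contig count grows by
#'   more than this factor within one iteration.
#' @param min_pair_links proper pairs required to retain a non-exon
#'   neighbour contig ("sufficient paired-end read mappings").
#' @param culling_limit an exon alignment is discarded when enveloped by
#'   this many higher-scoring alignments from other contigs.
#' @param hsp_min_len,hsp_min_ident floors for transcript-to-contig
#'   alignment blocks used in exon classification.
#' @param dbg_min_count k-mer coverage floor for local assembly.
#' @param link_min_ident,link_min_cover identity and read-coverage floors
#'   for a mate to count as mapped to a contig when counting pair links.
#' @return list of class `walker_config`.
#' @export
walker_config <- function(min_match_initial = 40, min_match_extend = 60,
                          end_window = 600, assembly_k = 63,
                          max_iterations = 30, max_contigs = 500,
                          contig_growth_drop_factor = 3.0,
                          min_pair_links = 3, culling_limit = 2,
                          hsp_min_len = 40, hsp_min_ident = 0.9,
                          dbg_min_count = 2, link_min_ident = 0.95,
                          link_min_cover = 0.9) {
  cfg <- list(min_match_initial = min_match_initial,
              min_match_extend = min_match_extend,
              end_window = end_window, assembly_k = assembly_k,
              max_iterations = max_iterations, max_contigs = max_contigs,
              contig_growth_drop_factor = contig_growth_drop_factor,
              min_pair_links = min_pair_links, culling_limit = culling_limit,
              hsp_min_len = hsp_min_len, hsp_min_ident = hsp_min_ident,
              dbg_min_count = dbg_min_count, link_min_ident = link_min_ident,
              link_min_cover = link_min_cover)
  stopifnot(all(vapply(cfg, function(x) is.numeric(x) && x >= 0, TRUE)),
            cfg$min_match_initial > 0, cfg$min_match_extend > 0,
            cfg$end_window > 0, cfg$assembly_k > 0)
  structure(cfg, class = "walker_config")
}

.contig_stats <- function(contigs, iteration) {
  data.frame(iteration = iteration,
             max_contig_len = if (length(contigs)) max(nchar(contigs)) else 0L,
             sum_contig_len = if (length(contigs)) sum(nchar(contigs)) else 0L,
             n_contigs = length(contigs))
}

.contig_ends <- function(contigs) {
  if (length(contigs) == 0)
    return(data.frame(contig = character(0), end = character(0),
                      tail = character(0), stringsAsFactors = FALSE))
  n <- nchar(contigs)
  data.frame(contig = rep(names(contigs), 2),
             end = rep(c("L", "R"), each = length(contigs)),
             tail = c(substr(contigs, 1, pmin(60, n)),
                      substr(contigs, pmax(1, n - 59), n)),
             stringsAsFactors = FALSE)
}

.walk_state <- function(transcript_id, transcript, status, reason = NA_character_) {
  structure(list(transcript_id = transcript_id, transcript = transcript,
                 iteration = 0L, contigs = stats::setNames(character(0), character(0)),
                 recruited = character(0),
                 stats = .contig_stats(character(0), 0L)[0, ],
                 status = status, reason = reason, end_history = list()),
            class = "walk_state")
}

#' @export
print.walk_state <- function(x, ...) {
  cat(sprintf("<walk_state> %s: %s after %d iteration(s); %d contigs, %d pairs recruited\n",
              x$transcript_id, x$status, x$iteration, length(x$contigs),
              length(x$recruited)))
  invisible(x)
}

#' Classify contigs as exon-containing
#'
#' Aligns the transcript to every contig (ungapped HSPs, identity >=
#' `hsp_min_ident`, length >= `hsp_min_len`), then applies the culling
#' rule: an HSP is discarded when its transcript interval is enveloped by
#' at least `culling_limit` higher-scoring HSPs from other contigs.  A
#' contig is exon-containing iff it retains at least one HSP.
#'
#' @param transcript character scalar.
#' @param contigs named character vector.
#' @param cfg a [walker_config].
#' @return list: `exon_contigs` and `other_contigs` (names), `hsps`
#'   (data.frame with a `kept` flag).
#' @export
classify_exon_contigs <- function(transcript, contigs, cfg = walker_config()) {
  hs_list <- lapply(names(contigs), function(id) {
    h <- find_hsps(transcript, contigs[[id]], min_len = cfg$hsp_min_len,
                   min_ident = cfg$hsp_min_ident)
    if (nrow(h)) h$contig <- id
    h
  })
  hs <- do.call(rbind, hs_list[vapply(hs_list, nrow, 0L) > 0])
  if (is.null(hs) || nrow(hs) == 0) {
    return(list(exon_contigs = character(0), other_contigs = names(contigs),
                hsps = data.frame()))
  }
  hs <- hs[order(-hs$score, hs$contig, hs$q_start), , drop = FALSE]
  n <- nrow(hs)
  kept <- logical(n)
  # a few bases of slack absorb x-drop extension jitter at block edges
  slack <- 5L
  for (i in seq_len(n)) {
    env <- hs$score > hs$score[i] & hs$contig != hs$contig[i] &
      hs$q_start <= hs$q_start[i] + slack & hs$q_end >= hs$q_end[i] - slack
    kept[i] <- sum(env) < cfg$culling_limit
  }
  hs$kept <- kept
  exon <- sort(unique(hs$contig[kept]))
  list(exon_contigs = exon,
       other_contigs = setdiff(names(contigs), exon),
       hsps = hs)
}

#' Retain non-exon contigs linked to exon contigs by read pairs
#'
#' A non-exon contig is retained iff at least `min_pair_links` pairs have
#' one mate aligning to it (identity >= `link_min_ident` over >=
#' `link_min_cover` of the mate) and the other mate aligning to an
#' exon-containing contig.
#'
#' @param exon_contigs,other_contigs named character vectors of sequences.
#' @param pairs recruited [read_pairs] for this transcript.
#' @param cfg a [walker_config].
#' @return list: `retained` (names of linked non-exon contigs), `links`
#'   (named integer link counts for all non-exon contigs).
#' @export
paired_link_contigs <- function(exon_contigs, other_contigs, pairs,
                                cfg = walker_config()) {
  links <- stats::setNames(integer(length(other_contigs)), names(other_contigs))
  if (length(other_contigs) == 0 || length(exon_contigs) == 0 ||
      nrow(pairs) == 0)
    return(list(retained = character(0), links = links))
  contigs <- c(exon_contigs, other_contigs)
  n <- nrow(pairs)
  aln <- align_reads_to_contigs(c(pairs$seq1, pairs$seq2), contigs)
  good <- aln[aln$ident >= cfg$link_min_ident &
                aln$cover >= cfg$link_min_cover, , drop = FALSE]
  if (nrow(good) == 0) return(list(retained = character(0), links = links))
  good$pair <- ifelse(good$read > n, good$read - n, good$read)
  good$mate <- ifelse(good$read > n, 2L, 1L)
  is_exon <- good$contig %in% names(exon_contigs)
  ex1 <- unique(good$pair[good$mate == 1L & is_exon])
  ex2 <- unique(good$pair[good$mate == 2L & is_exon])
  for (id in names(other_contigs)) {
    on1 <- unique(good$pair[good$mate == 1L & good$contig == id])
    on2 <- unique(good$pair[good$mate == 2L & good$contig == id])
    links[id] <- length(union(intersect(on1, ex2), intersect(on2, ex1)))
  }
  list(retained = names(links)[links >= cfg$min_pair_links], links = links)
}

# shared by seed and extend: assemble new reads, elongate, merge with
# carried-over contigs, classify and retain.
.assemble_round <- function(state, index, cfg, new_reads, label) {
  all_pairs <- pairs_subset(index$pairs, state$recruited)
  new_unitigs <- if (length(new_reads))
    dbg_unitigs(new_reads, cfg$assembly_k, cfg$dbg_min_count)
  else stats::setNames(character(0), character(0))
  candidates <- state$contigs
  # elongation works at contig ends, and only the newly recruited reads
  # (drawn from the end windows) can reach past them, so the elongation
  # index is built over the new reads alone
  if (length(new_reads) && (length(candidates) || length(new_unitigs))) {
    ridx <- cpp_build_seed_index(new_reads, 20L)
    strict <- overlap_params("strict")
    elong <- function(v) vapply(v, elongate_with_reads, "", reads = NULL,
                                params = strict, reads_index = ridx)
    if (length(candidates)) candidates[] <- elong(candidates)
    if (length(new_unitigs)) new_unitigs[] <- elong(new_unitigs)
  }
  if (length(new_unitigs))
    names(new_unitigs) <- sprintf("%s_new%04d", label, seq_along(new_unitigs))
  candidates <- c(candidates, new_unitigs)
  # drop candidates that are exact substrings of another candidate: the
  # merge would absorb them as containments anyway, at quadratic cost
  if (length(candidates) > 1) {
    ord <- order(-nchar(candidates), names(candidates))
    keep <- rep(TRUE, length(candidates))
    rc <- as.character(cpp_revcomp(candidates))
    for (i in seq_along(ord)[-1]) {
      ci <- ord[i]
      for (j in seq_len(i - 1)) {
        cj <- ord[j]
        if (!keep[cj]) next
        if (grepl(candidates[[ci]], candidates[[cj]], fixed = TRUE) ||
            grepl(rc[[ci]], candidates[[cj]], fixed = TRUE)) {
          keep[ci] <- FALSE
          break
        }
      }
    }
    candidates <- candidates[keep]
  }
  if (length(candidates) >= cfg$max_contigs) {
    # runaway recruitment: skip the quadratic merge, report counts and
    # let the drop rule fire
    return(list(contigs = candidates, dropped_early = TRUE))
  }
  merged <- overlap_layout_merge(candidates, overlap_params("permissive"))
  names(merged) <- sprintf("%s_c%03d", label, seq_along(merged))
  cls <- classify_exon_contigs(state$transcript, merged, cfg)
  lnk <- paired_link_contigs(merged[cls$exon_contigs],
                             merged[cls$other_contigs], all_pairs, cfg)
  keep <- c(cls$exon_contigs, lnk$retained)
  list(contigs = merged[sort(keep)], hsps = cls$hsps, links = lnk$links,
       dropped_early = FALSE)
}

#' Seed a walk from a transcript
#'
#' Recruits pairs sharing a >= `min_match_initial` exact match with the
#' transcript, assembles them, merges, classifies exon-containing contigs
#' and retains pair-linked neighbours.  Fails to seed when the transcript
#' is shorter than the match threshold or recruits nothing.
#'
#' @param transcript character scalar (optionally named; the name becomes
#'   the transcript id).
#' @param index a `read_index` built from depleted reads.
#' @param cfg a [walker_config].
#' @param transcript_id id used in contig names and reports.
#' @return a `walk_state`.
#' @export
seed_iteration <- function(transcript, index, cfg = walker_config(),
                           transcript_id = NULL) {
  if (is.null(transcript_id))
    transcript_id <- if (!is.null(names(transcript))) names(transcript) else "tx"
  transcript <- unname(transcript)
  if (nchar(transcript) < cfg$min_match_initial) {
    st <- .walk_state(transcript_id, transcript, "failed_to_seed",
                      "transcript shorter than min_match_initial")
    return(st)
  }
  ids <- recruit_pairs(transcript, index, cfg$min_match_initial)
  if (length(ids) == 0)
    return(.walk_state(transcript_id, transcript, "failed_to_seed",
                       "no reads recruited"))
  state <- .walk_state(transcript_id, transcript, "extending")
  state$recruited <- ids
  prs <- pairs_subset(index$pairs, ids)
  res <- .assemble_round(state, index, cfg, c(prs$seq1, prs$seq2),
                         sprintf("%s_i00", transcript_id))
  if (res$dropped_early) {
    state$status <- "dropped"
    state$reason <- "contig count reached max_contigs at seeding"
    state$stats <- .contig_stats(res$contigs, 0L)
    return(state)
  }
  if (length(res$contigs) == 0) {
    state$status <- "failed_to_seed"
    state$reason <- "no exon-containing contig assembled"
    return(state)
  }
  state$contigs <- res$contigs
  state$stats <- .contig_stats(res$contigs, 0L)
  state$end_history <- list(.contig_ends(res$contigs))
  state
}

#' Continue/stop/drop decision between iterations
#'
#' Dropped when the contig count reaches `max_contigs` or grows by more
#' than `contig_growth_drop_factor` within the iteration; otherwise the
#' walk continues iff the maximum contig length or the summed contig
#' length increased, and finishes when neither did.
#'
#' @param prev_stats,curr_stats one-row stats frames
#'   (max_contig_len, sum_contig_len, n_contigs); `prev_stats = NULL`
#'   (first iteration) always continues.
#' @param cfg a [walker_config].
#' @return one of `"continue"`, `"finished"`, `"dropped"`.
#' @export
assess_progress <- function(prev_stats, curr_stats, cfg = walker_config()) {
  if (curr_stats$n_contigs >= cfg$max_contigs) return("dropped")
  if (is.null(prev_stats)) return("continue")
  if (curr_stats$n_contigs > cfg$contig_growth_drop_factor * prev_stats$n_contigs)
    return("dropped")
  if (curr_stats$max_contig_len > prev_stats$max_contig_len ||
      curr_stats$sum_contig_len > prev_stats$sum_contig_len)
    return("continue")
  "finished"
}

#' Run one extension iteration
#'
#' The terminal `end_window` bases of each contig end (the whole contig
#' when shorter) are queried against the read index at
#' `min_match_extend`; newly recruited pairs are assembled and merged
#' with the previous contigs, classification and pair-linking are
#' reapplied, and the progress rules decide the next status.
#'
#' @param state a `walk_state` with status `"extending"`.
#' @param index the `read_index`.
#' @param cfg a [walker_config].
#' @return the updated `walk_state`.
#' @export
extend_iteration <- function(state, index, cfg = walker_config()) {
  stopifnot(inherits(state, "walk_state"), state$status == "extending")
  n <- nchar(state$contigs)
  queries <- unique(c(substr(state$contigs, 1, pmin(cfg$end_window, n)),
                      substr(state$contigs, pmax(1, n - cfg$end_window + 1), n)))
  ids_new <- setdiff(recruit_pairs(queries, index, cfg$min_match_extend),
                     state$recruited)
  state$recruited <- sort(union(state$recruited, ids_new))
  new_pairs <- pairs_subset(index$pairs, ids_new)
  iter <- state$iteration + 1L
  res <- .assemble_round(state, index, cfg,
                         c(new_pairs$seq1, new_pairs$seq2),
                         sprintf("%s_i%02d", state$transcript_id, iter))
  prev <- state$stats[nrow(state$stats), , drop = FALSE]
  curr <- .contig_stats(res$contigs, iter)
  state$iteration <- iter
  state$stats <- rbind(state$stats, curr)
  if (res$dropped_early) {
    state$status <- "dropped"
    state$reason <- "contig count reached max_contigs"
    return(state)
  }
  state$contigs <- res$contigs
  state$end_history <- c(state$end_history, list(.contig_ends(res$contigs)))
  decision <- assess_progress(prev, curr, cfg)
  state$status <- switch(decision, continue = "extending",
                         finished = "finished", dropped = "dropped")
  if (decision == "dropped") state$reason <- "contig count cap or growth factor"
  state
}

#' Run a full walk for one transcript
#'
#' Seeds, then extends until the walk finishes, is dropped, or
#' `max_iterations` extension rounds have run (a walk still extending at
#' the cap keeps status `"extending"`).
#'
#' @inheritParams seed_iteration
#' @return a `walk_state`.
#' @export
run_walk <- function(transcript, index, cfg = walker_config(),
                     transcript_id = NULL) {
  state <- seed_iteration(transcript, index, cfg, transcript_id)
  while (state$status == "extending" && state$iteration < cfg$max_iterations)
    state <- extend_iteration(state, index, cfg)
  state
}

#' Run walks for a transcript collection
#'
#' Per-transcript isolation: one transcript's failure is recorded as a
#' state with status `"error"` and never aborts the batch.
#'
#' @param transcripts named character vector.
#' @param index the `read_index`.
#' @param cfg a [walker_config].
#' @param verbose print one line per transcript.
#' @return named list of `walk_state`s, in input order.
#' @export
run_all_walks <- function(transcripts, index, cfg = walker_config(),
                          verbose = FALSE) {
  stopifnot(!is.null(names(transcripts)))
  out <- lapply(names(transcripts), function(id) {
    st <- tryCatch(run_walk(transcripts[[id]], index, cfg, transcript_id = id),
                   error = function(e) {
                     s <- .walk_state(id, transcripts[[id]], "error",
                                      conditionMessage(e))
                     s
                   })
    if (verbose)
      message(sprintf("%s: %s (%d iterations, %d contigs)", id, st$status,
                      st$iteration, length(st$contigs)))
    st
  })
  stats::setNames(out, names(transcripts))
}
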