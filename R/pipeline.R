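# End-to-end orchestration: deplete -> index -> walk -> finish -> strip
# -> redundancy merge -> reports, with per-stage artifacts and one seed.

#' Pipeline configuration
#'
#' Aggregates every stage's parameters.  All randomness flows from the
#' single `seed` (the method itself is deterministic; the seed matters
#' only when the caller also simulates input).
#'
#' @param seed integer seed recorded with the run.
#' @param depletion a [depletion_config].
#' @param walker a [walker_config].
#' @param seed_len read-index seed length.
#' @param gap_len N-gap spacer length.
#' @param merge_ident_all,merge_ident_one redundancy-merge identity
#'   floors, percent (95/99 rule).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, depletion = depletion_config(),
                            walker = walker_config(), seed_len = 20,
                            gap_len = 500, merge_ident_all = 95,
                            merge_ident_one = 99) {
  stopifnot(inherits(depletion, "depletion_config"),
            inherits(walker, "walker_config"))
  structure(list(seed = as.integer(seed), depletion = depletion,
                 walker = walker, seed_len = seed_len, gap_len = gap_len,
                 merge_ident_all = merge_ident_all,
                 merge_ident_one = merge_ident_one),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages: k-mer counting and repeat depletion; read indexing; one walk
#' per transcript; per-transcript finishing into scaffolds; removal of
#' contigs the transcript does not map to; redundancy grouping/merging;
#' summary metrics (lengths exclude the artificial N gaps).  Rerunning
#' with the same inputs and config reproduces identical outputs.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param pairs a [read_pairs] table of genomic read pairs.
#' @param config a [pipeline_config].
#' @param out_dir optional directory for stage artifacts (scaffold FASTA,
#'   GFF3 exon annotations, summary TSV, JSON-lines walk logs).
#' @param verbose print stage progress.
#' @return list: `scaffolds` (named list, one per retained locus),
#'   `states`, `mappings`, `groups`, `depletion_report`, `summary`,
#'   `config`.
#' @export
run_pipeline <- function(transcripts, pairs, config = pipeline_config(),
                         out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"), !is.null(names(transcripts)))
  set.seed(config$seed)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("[deplete] counting %d-mers over %d pairs", config$depletion$k,
      nrow(pairs))
  tab <- build_kmer_table(pairs, config$depletion$k)
  dep <- filter_read_pairs(pairs, tab, config$depletion)
  say("[deplete] retained %d/%d pairs", dep$report$n_retained,
      dep$report$n_input)

  say("[index] building seed index (seed_len=%d)", config$seed_len)
  index <- build_read_index(dep$pairs, config$seed_len)

  say("[walk] %d transcripts", length(transcripts))
  states <- run_all_walks(transcripts, index, config$walker,
                          verbose = verbose)

  say("[finish] scaffolding")
  scaffolds <- list()
  for (id in names(states)) {
    st <- states[[id]]
    if (length(st$contigs) == 0) next
    sc <- tryCatch(finish_walk(st, dep$pairs, config$walker,
                               gap_len = config$gap_len),
                   error = function(e) {
                     warning(sprintf("finishing %s failed: %s", id,
                                     conditionMessage(e)))
                     NULL
                   })
    if (!is.null(sc)) scaffolds[[id]] <- sc
  }

  say("[strip] removing unmapped contigs")
  mappings <- list()
  for (id in names(scaffolds)) {
    mp <- map_transcript_to_scaffold(transcripts[[id]], scaffolds[[id]],
                                     config$walker)
    sc <- strip_unmapped_contigs(scaffolds[[id]], mp)
    if (isTRUE(attr(sc, "flagged_empty"))) {
      scaffolds[[id]] <- NULL
      next
    }
    scaffolds[[id]] <- sc
    mappings[[id]] <- map_transcript_to_scaffold(transcripts[[id]], sc,
                                                 config$walker)
  }

  say("[merge] redundancy groups over %d scaffolds", length(scaffolds))
  groups <- if (length(scaffolds) >= 2) {
    find_redundant_groups(scaffolds, transcripts,
                          config$merge_ident_all, config$merge_ident_one,
                          config$walker)
  } else {
    lapply(names(scaffolds), identity)
  }
  merged <- list()
  for (grp in groups) {
    sc <- if (length(grp) == 1) scaffolds[[grp]]
    else merge_group(scaffolds[grp], transcripts, config$walker,
                     config$gap_len)
    merged[[sc$scaffold_id]] <- sc
  }
  final_maps <- lapply(names(merged), function(id)
    map_transcript_to_scaffold(transcripts[[id]], merged[[id]],
                               config$walker))
  names(final_maps) <- names(merged)

  n_status <- table(factor(vapply(states, function(s) s$status, ""),
                           levels = c("extending", "finished", "dropped",
                                      "failed_to_seed", "error")))
  summary <- cbind(data.frame(transcripts_in = length(transcripts),
                              seeded = sum(vapply(states, function(s)
                                s$status != "failed_to_seed", TRUE))),
                   as.data.frame(t(as.matrix(n_status))),
                   assembly_summary(merged),
                   data.frame(runtime_s = as.numeric(difftime(Sys.time(), t0,
                                                              units = "secs"))))

  out <- list(scaffolds = merged, states = states, mappings = final_maps,
              groups = groups, depletion_report = dep$report,
              summary = summary, config = config)
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir)
  out
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (length(res$scaffolds)) {
    seqs <- vapply(res$scaffolds, scaffold_sequence, "")
    write_fasta(file.path(out_dir, "scaffolds.fasta"), seqs)
    con <- file(file.path(out_dir, "exons.gff3"), "w")
    writeLines("##gff-version 3", con)
    for (id in names(res$mappings)) {
      b <- res$mappings[[id]]$blocks
      if (nrow(b) == 0) next
      writeLines(sprintf("%s\tgenewalker\texon_match\t%d\t%d\t.\t%s\t.\tID=%s.block%d",
                         id, pmin(b$s_start, b$s_end) + 1,
                         pmax(b$s_start, b$s_end), res$mappings[[id]]$strand,
                         id, seq_len(nrow(b))), con)
    }
    close(con)
  }
  utils::write.table(res$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_con <- file(file.path(out_dir, "walk_log.jsonl"), "w")
  for (id in names(res$states)) {
    st <- res$states[[id]]
    writeLines(jsonlite::toJSON(list(transcript = id, status = st$status,
                                     iterations = st$iteration,
                                     stats = st$stats),
                                auto_unbox = TRUE, digits = NA), log_con)
  }
  close(log_con)
  invisible(out_dir)
}
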