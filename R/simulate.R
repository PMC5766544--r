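# Synthetic genomes, gene models, repeat families, transcripts and
# paired reads with full ground truth.  The defaults emulate the input
# regime the method targets: ~20x uniform coverage of 2x100 bp pairs with
# a small insert, genes with multi-kilobase introns, and an interspersed
# high-copy repeat family.

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_subs <- function(seq, n_subs) {
  if (n_subs <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(v), min(n_subs, length(v)))
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

#' Simulation configuration
#'
#' @param seed RNG seed; everything downstream is reproducible from it.
#' @param genome_len total genome length (bases).
#' @param n_genes number of genes.
#' @param exons_per_gene inclusive range.
#' @param exon_len inclusive range (bases).
#' @param intron_len inclusive range (bases).
#' @param repeat_families list of `list(unit_len =, copies =,
#'   divergence =)` (divergence in percent per copy).
#' @param intronic_repeat `NULL`, or `list(gene =, intron =, family =)`
#'   to insert one extra diverged copy of that family into the middle of
#'   a specific intron (for repeat-stop experiments).
#' @param read_len read length.
#' @param insert_mean,insert_sd fragment length distribution.
#' @param coverage target mean per-base coverage.
#' @param error_rate substitution rate per sequenced base (no indels).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, genome_len = 1e6, n_genes = 10,
                       exons_per_gene = c(3, 8), exon_len = c(120, 400),
                       intron_len = c(200, 3000),
                       repeat_families = list(list(unit_len = 2000,
                                                   copies = 100,
                                                   divergence = 2)),
                       intronic_repeat = NULL,
                       read_len = 100, insert_mean = 300, insert_sd = 30,
                       coverage = 20, error_rate = 0.001) {
  stopifnot(genome_len > 0, n_genes >= 0, coverage > 0, read_len > 0,
            error_rate >= 0, error_rate < 1)
  for (f in repeat_families)
    stopifnot(f$unit_len > 0, f$copies >= 0,
              f$divergence >= 0, f$divergence <= 50)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a genome with genes and repeat families
#'
#' Background sequence is i.i.d. uniform; genes (drawn exon/intron
#' structures, random strand) are placed non-overlapping, separated by
#' intergenic segments; repeat copies (consensus per family, per-copy
#' substitution divergence) are interspersed in the intergenic segments.
#' Fully reproducible from the seed.
#'
#' @param cfg a [sim_config].
#' @return list of class `synthetic_truth`: `genome` (character scalar),
#'   `genes` (exon records: gene_id, strand, exon_index, start, end),
#'   `repeats` (family, copy, start, end, in_intron), `cfg`.
#'   Intervals are 0-based half-open on the forward strand.
#' @export
simulate_genome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ri <- function(rng, n = 1) {
    if (rng[1] == rng[2]) rep(rng[1], n)
    else sample(rng[1]:rng[2], n, replace = TRUE)
  }
  fam_seqs <- lapply(cfg$repeat_families, function(f) .rand_dna(f$unit_len))
  # draw gene structures
  genes <- list()
  for (g in seq_len(cfg$n_genes)) {
    n_ex <- ri(cfg$exons_per_gene)
    exl <- ri(cfg$exon_len, n_ex)
    inl <- if (n_ex > 1) ri(cfg$intron_len, n_ex - 1) else integer(0)
    genes[[g]] <- list(gene_id = sprintf("g%03d", g),
                       strand = sample(c("+", "-"), 1),
                       exon_len = exl, intron_len = inl,
                       intron_repeat = rep(NA_integer_, max(0, n_ex - 1)))
  }
  if (!is.null(cfg$intronic_repeat)) {
    tgt <- cfg$intronic_repeat
    stopifnot(tgt$gene <= cfg$n_genes,
              tgt$intron <= length(genes[[tgt$gene]]$intron_len))
    genes[[tgt$gene]]$intron_repeat[tgt$intron] <- tgt$family
  }
  gene_total <- vapply(genes, function(g) {
    sum(g$exon_len) + sum(g$intron_len) +
      sum(vapply(which(!is.na(g$intron_repeat)), function(i)
        cfg$repeat_families[[g$intron_repeat[i]]]$unit_len, 0))
  }, 0)
  rep_total <- sum(vapply(seq_along(cfg$repeat_families), function(i)
    cfg$repeat_families[[i]]$unit_len * cfg$repeat_families[[i]]$copies, 0))
  bg_total <- cfg$genome_len - sum(gene_total) - rep_total
  n_slots <- cfg$n_genes + 1
  if (bg_total < n_slots * 100)
    stop(sprintf("infeasible packing: features need %d of %d bases",
                 sum(gene_total) + rep_total, cfg$genome_len), call. = FALSE)
  # split background across intergenic slots (at least 100 bases each)
  w <- as.vector(stats::rmultinom(1, bg_total - n_slots * 100, rep(1, n_slots)))
  slot_bg <- w + 100
  # assign intergenic repeat copies to slots
  placements <- list()
  for (fi in seq_along(cfg$repeat_families)) {
    f <- cfg$repeat_families[[fi]]
    if (f$copies > 0)
      placements[[fi]] <- data.frame(family = fi,
                                     copy = seq_len(f$copies),
                                     slot = sample.int(n_slots, f$copies,
                                                       replace = TRUE))
  }
  placements <- if (length(placements)) {
    do.call(rbind, placements)
  } else {
    data.frame(family = integer(0), copy = integer(0), slot = integer(0))
  }
  # build the genome left to right
  pieces <- character(0)
  pos <- 0L
  exon_rows <- list()
  repeat_rows <- list()
  emit <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  emit_slot <- function(si) {
    here <- placements[placements$slot == si, , drop = FALSE]
    n_here <- nrow(here)
    chunk <- as.vector(stats::rmultinom(1, slot_bg[si], rep(1, n_here + 1)))
    for (r in seq_len(n_here)) {
      emit(.rand_dna(chunk[r]))
      f <- cfg$repeat_families[[here$family[r]]]
      copy_seq <- .mutate_subs(fam_seqs[[here$family[r]]],
                               stats::rbinom(1, f$unit_len, f$divergence / 100))
      repeat_rows[[length(repeat_rows) + 1L]] <<- data.frame(
        family = here$family[r], copy = here$copy[r],
        start = pos, end = pos + nchar(copy_seq), in_intron = FALSE)
      emit(copy_seq)
    }
    emit(.rand_dna(chunk[n_here + 1]))
  }
  for (g in seq_len(cfg$n_genes)) {
    emit_slot(g)
    ge <- genes[[g]]
    for (e in seq_along(ge$exon_len)) {
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        gene_id = ge$gene_id, strand = ge$strand, exon_index = e,
        start = pos, end = pos + ge$exon_len[e])
      emit(.rand_dna(ge$exon_len[e]))
      if (e < length(ge$exon_len)) {
        il <- ge$intron_len[e]
        fi <- ge$intron_repeat[e]
        if (!is.na(fi)) {
          half <- il %/% 2
          emit(.rand_dna(half))
          f <- cfg$repeat_families[[fi]]
          copy_seq <- .mutate_subs(fam_seqs[[fi]],
                                   stats::rbinom(1, f$unit_len, f$divergence / 100))
          repeat_rows[[length(repeat_rows) + 1L]] <- data.frame(
            family = fi, copy = NA_integer_,
            start = pos, end = pos + nchar(copy_seq), in_intron = TRUE)
          emit(copy_seq)
          emit(.rand_dna(il - half))
        } else {
          emit(.rand_dna(il))
        }
      }
    }
  }
  emit_slot(n_slots)
  genome <- paste(pieces, collapse = "")
  structure(list(genome = genome,
                 genes = if (length(exon_rows)) do.call(rbind, exon_rows)
                 else data.frame(gene_id = character(0), strand = character(0),
                                 exon_index = integer(0), start = integer(0),
                                 end = integer(0)),
                 repeats = if (length(repeat_rows)) do.call(rbind, repeat_rows)
                 else data.frame(family = integer(0), copy = integer(0),
                                 start = integer(0), end = integer(0),
                                 in_intron = logical(0)),
                 repeat_consensus = fam_seqs,
                 cfg = cfg),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d bp genome, %d genes, %d repeat copies\n",
              nchar(x$genome), length(unique(x$genes$gene_id)),
              nrow(x$repeats)))
  invisible(x)
}

#' Spliced transcripts of the simulated genes
#'
#' Concatenated exon sequences per gene, reverse complemented for minus
#' strand genes.  With `variants = TRUE`, every gene with at least four
#' exons additionally emits a splice variant skipping one internal exon
#' (id suffix `_v2`), which drives redundancy-merge tests.
#'
#' @param truth a `synthetic_truth`.
#' @param variants also emit exon-skipping variants.
#' @return named character vector of transcripts.
#' @export
extract_transcripts <- function(truth, variants = FALSE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  out <- character(0)
  for (gid in unique(truth$genes$gene_id)) {
    ex <- truth$genes[truth$genes$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$exon_index), , drop = FALSE]
    splice <- function(idx) {
      s <- paste(substring(truth$genome, ex$start[idx] + 1, ex$end[idx]),
                 collapse = "")
      if (ex$strand[1] == "-") as.character(cpp_revcomp(s)) else s
    }
    out[gid] <- splice(seq_len(nrow(ex)))
    if (variants && nrow(ex) >= 4) {
      skip <- ceiling(nrow(ex) / 2)
      out[paste0(gid, "_v2")] <- splice(setdiff(seq_len(nrow(ex)), skip))
    }
  }
  out
}

#' Simulate paired-end reads from the genome
#'
#' Fragments are drawn uniformly over the genome at the target coverage
#' (pair count = round(coverage x genome_len / (2 x read_len))), each
#' sequenced from both ends in convergent orientation with i.i.d.
#' substitution errors; fragment strand is random.  Provenance records
#' the true origin interval and strand of every pair.
#'
#' @param truth a `synthetic_truth`.
#' @param cfg a [sim_config]; defaults to the truth's own.
#' @return list: `pairs` (a [read_pairs]), `provenance` (pair_id, start,
#'   end, strand).
#' @export
simulate_reads <- function(truth, cfg = truth$cfg) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(cfg$seed + 1L)
  glen <- nchar(truth$genome)
  rl <- cfg$read_len
  n <- round(cfg$coverage * glen / (2 * rl))
  ins <- pmax(rl, round(stats::rnorm(n, cfg$insert_mean, cfg$insert_sd)))
  ins <- pmin(ins, glen)
  start <- floor(stats::runif(n, 0, glen - ins + 1))
  fw <- substring(truth$genome, start + 1, start + rl)
  rv <- as.character(cpp_revcomp(substring(truth$genome, start + ins - rl + 1,
                                           start + ins)))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  m1 <- ifelse(strand == "+", fw, rv)
  m2 <- ifelse(strand == "+", rv, fw)
  if (cfg$error_rate > 0) {
    m1 <- .add_read_errors(m1, cfg$error_rate)
    m2 <- .add_read_errors(m2, cfg$error_rate)
  }
  ids <- sprintf("p%07d", seq_len(n))
  list(pairs = read_pairs(ids, m1, m2),
       provenance = data.frame(pair_id = ids, start = start,
                               end = start + ins, strand = strand,
                               stringsAsFactors = FALSE))
}

.add_read_errors <- function(seqs, rate) {
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_err > 0)
  for (i in hit) seqs[i] <- .mutate_subs(seqs[i], n_err[i])
  seqs
}

#' Write simulated gene annotations as GFF3
#'
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @export
write_truth_gff3 <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- truth$genes
  if (nrow(g)) {
    writeLines(sprintf("genome\tgenewalker_sim\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                       g$start + 1, g$end, g$strand, g$gene_id, g$exon_index,
                       g$gene_id), con)
  }
  invisible(path)
}
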