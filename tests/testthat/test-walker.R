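# a small shared world: one 3-exon gene in 30 kb, error-free 20x pairs
walker_world <- local({
  cfg <- sim_config(seed = 501, genome_len = 30000, n_genes = 1,
                    exons_per_gene = c(3, 3), exon_len = c(150, 250),
                    intron_len = c(300, 700), repeat_families = list(),
                    coverage = 20, error_rate = 0)
  truth <- simulate_genome(cfg)
  tx <- extract_transcripts(truth)
  rd <- simulate_reads(truth, cfg)
  idx <- build_read_index(rd$pairs, 20)
  list(truth = truth, tx = tx, pairs = rd$pairs, idx = idx)
})

test_that("seed_iteration recovers every exon of a synthetic gene", {
  w <- walker_world
  st <- seed_iteration(w$tx[1], w$idx, walker_config(), "g001")
  expect_s3_class(st, "walk_state")
  expect_equal(st$status, "extending")
  ex <- w$truth$genes
  for (i in seq_len(nrow(ex))) {
    es <- substr(w$truth$genome, ex$start[i] + 1, ex$end[i])
    found <- any(grepl(es, st$contigs, fixed = TRUE) |
                   grepl(as.character(reverse_complement(es)), st$contigs,
                         fixed = TRUE))
    expect_true(found, label = sprintf("exon %d recovered", i))
  }
  expect_equal(nrow(st$stats), 1)
})

test_that("seeding failure modes are explicit", {
  w <- walker_world
  # transcript of length 39 with min 40
  st <- seed_iteration(substr(w$tx[1], 1, 39), w$idx, walker_config(), "short")
  expect_equal(st$status, "failed_to_seed")
  expect_match(st$reason, "min_match")
  # transcript absent from the genome
  set.seed(502)
  st2 <- seed_iteration(random_dna(500), w$idx, walker_config(), "absent")
  expect_equal(st2$status, "failed_to_seed")
  expect_match(st2$reason, "no reads")
})

test_that("extension recruits only from the terminal end windows", {
  set.seed(503)
  g <- random_dna(4000)
  contig <- substr(g, 1001, 3000)  # 2000 bp
  # pair A matches within the right end window; pair B matches the middle
  inA <- substr(g, 2601, 2700)
  inB <- substr(g, 1801, 1900)
  pairs <- read_pairs(c("A", "B"), c(inA, inB),
                      c(random_dna(100), random_dna(100)))
  idx <- build_read_index(pairs, 20)
  st <- structure(list(transcript_id = "t", transcript = substr(g, 1201, 1400),
                       iteration = 0L,
                       contigs = stats::setNames(contig, "c1"),
                       recruited = character(0),
                       stats = data.frame(iteration = 0L,
                                          max_contig_len = 2000L,
                                          sum_contig_len = 2000L,
                                          n_contigs = 1L),
                       status = "extending", reason = NA_character_,
                       end_history = list()), class = "walk_state")
  st2 <- extend_iteration(st, idx, walker_config())
  expect_true("A" %in% st2$recruited)
  expect_false("B" %in% st2$recruited)
  # a contig shorter than the window clamps, no error
  st$contigs <- stats::setNames(substr(g, 1001, 1300), "c1")
  st$stats$max_contig_len <- 300L
  st$stats$sum_contig_len <- 300L
  expect_s3_class(extend_iteration(st, idx, walker_config()), "walk_state")
})

test_that("assess_progress implements continue/finish/drop rules", {
  cfg <- walker_config()
  row <- function(mx, sm, n) data.frame(max_contig_len = mx,
                                        sum_contig_len = sm, n_contigs = n)
  expect_equal(assess_progress(row(1000, 5000, 10), row(1000, 5100, 10), cfg),
               "continue")
  expect_equal(assess_progress(row(1000, 5000, 10), row(1100, 5000, 10), cfg),
               "continue")
  expect_equal(assess_progress(row(1000, 5000, 10), row(1000, 5000, 10), cfg),
               "finished")
  expect_equal(assess_progress(row(1000, 5000, 150), row(1000, 5000, 460), cfg),
               "dropped")    # tripled within one iteration
  expect_equal(assess_progress(row(1000, 5000, 400), row(1200, 6000, 500), cfg),
               "dropped")    # reached the 500 cap
  expect_equal(assess_progress(NULL, row(10, 10, 1), cfg), "continue")
})

test_that("culling limit keeps at most 2 contigs per exon interval", {
  set.seed(504)
  exon <- random_dna(200)
  tx <- paste0(random_dna(100), exon, random_dna(100))
  mut1 <- exon
  substr(mut1, 50, 50) <- "A"
  substr(mut1, 51, 51) <- "C"
  mut2 <- exon
  for (p in c(20, 60, 100, 140)) substr(mut2, p, p) <-
      setdiff(c("A", "C", "G", "T"), substr(mut2, p, p))[1]
  contigs <- stats::setNames(c(paste0(random_dna(50), exon, random_dna(50)),
                               paste0(random_dna(50), mut1, random_dna(50)),
                               paste0(random_dna(50), mut2, random_dna(50))),
                             c("exact", "near", "far"))
  cls <- classify_exon_contigs(tx, contigs, walker_config())
  expect_true("exact" %in% cls$exon_contigs)
  expect_lte(length(cls$exon_contigs), 2)
  expect_true("far" %in% cls$other_contigs)
  # pure intergenic contig is never exon-containing
  cls2 <- classify_exon_contigs(tx, stats::setNames(random_dna(300), "junk"),
                                walker_config())
  expect_equal(cls2$exon_contigs, character(0))
})

test_that("paired-end linking thresholds neighbour retention", {
  set.seed(505)
  g <- random_dna(3000)
  exon_ct <- stats::setNames(substr(g, 1, 1000), "ex")
  nbr_ct <- stats::setNames(substr(g, 1501, 2500), "nb")
  mk_bridge <- function(i) {
    s <- 830 + i * 7
    read_pairs(sprintf("br%d", i),
               substr(g, s, s + 99),
               as.character(reverse_complement(substr(g, 1501 + i * 5,
                                                      1600 + i * 5))))
  }
  bridges <- do.call(rbind, lapply(1:5, mk_bridge))
  class(bridges) <- c("read_pairs", "data.frame")
  cfg <- walker_config(min_pair_links = 3)
  r5 <- paired_link_contigs(exon_ct, nbr_ct, bridges, cfg)
  expect_equal(r5$retained, "nb")
  expect_equal(unname(r5$links["nb"]), 5L)
  r2 <- paired_link_contigs(exon_ct, nbr_ct, bridges[1:2, ], cfg)
  expect_equal(length(r2$retained), 0)
  r0 <- paired_link_contigs(exon_ct, nbr_ct, bridges[0, ], cfg)
  expect_equal(length(r0$retained), 0)
})

test_that("run_walk is deterministic and honours max_iterations = 0", {
  w <- walker_world
  cfg <- walker_config(max_iterations = 2)
  s1 <- run_walk(w$tx[1], w$idx, cfg, "g001")
  s2 <- run_walk(w$tx[1], w$idx, cfg, "g001")
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$stats, s2$stats)
  s0 <- run_walk(w$tx[1], w$idx, walker_config(max_iterations = 0), "g001")
  expect_equal(s0$iteration, 0L)
  expect_equal(nrow(s0$stats), 1)
})

test_that("walked length grows with iterations; recruited set is monotone", {
  w <- walker_world
  cfg <- walker_config(max_iterations = 3)
  st <- seed_iteration(w$tx[1], w$idx, cfg, "g001")
  lens <- st$stats$max_contig_len
  rec <- length(st$recruited)
  while (st$status == "extending" && st$iteration < cfg$max_iterations) {
    st <- extend_iteration(st, w$idx, cfg)
    lens <- c(lens, st$stats$max_contig_len[nrow(st$stats)])
    expect_gte(length(st$recruited), rec)
    rec <- length(st$recruited)
  }
  expect_true(all(diff(lens) >= 0))
  expect_gt(lens[length(lens)], lens[1])
  expect_equal(nrow(st$stats), st$iteration + 1)
})

test_that("run_all_walks isolates per-transcript failures", {
  w <- walker_world
  txs <- c(w$tx, bad = "ACGT")  # too short to seed
  res <- run_all_walks(txs, w$idx, walker_config(max_iterations = 1))
  expect_length(res, 2)
  expect_equal(res$bad$status, "failed_to_seed")
  expect_equal(res$g001$status, "extending")
})
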