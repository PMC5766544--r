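# constructed gene world shared by the mapping tests
sm_world <- local({
  set.seed(71)
  ex <- replicate(3, random_dna(200))
  it <- replicate(2, random_dna(400))
  genomic <- paste0(ex[1], it[1], ex[2], it[2], ex[3])
  tx <- paste0(ex[1], ex[2], ex[3])
  list(ex = ex, it = it, genomic = genomic, tx = tx)
})

test_that("map_transcript_to_scaffold covers a gene-derived scaffold", {
  w <- sm_world
  sc <- scaffold("g", stats::setNames(w$genomic, "c1"))
  mp <- map_transcript_to_scaffold(w$tx, sc)
  expect_s3_class(mp, "exon_mapping")
  expect_gte(mp$coverage, 0.95)
  expect_equal(nrow(mp$blocks), 3)
  expect_true(all(diff(mp$blocks$t_start) > 0))
  expect_true(all(diff(mp$blocks$s_start) > 0))
  # unrelated transcript: empty mapping
  set.seed(72)
  expect_equal(nrow(map_transcript_to_scaffold(random_dna(500), sc)$blocks), 0)
})

test_that("an exon split across a gap yields blocks flanking the gap", {
  w <- sm_world
  # exon 2 split in half across two contigs
  c1 <- stats::setNames(paste0(w$ex[1], w$it[1], substr(w$ex[2], 1, 100)), "c1")
  c2 <- stats::setNames(paste0(substr(w$ex[2], 101, 200), w$it[2], w$ex[3]), "c2")
  sc <- scaffold("g", c(c1, c2))
  mp <- map_transcript_to_scaffold(w$tx, sc)
  expect_gte(nrow(mp$blocks), 4)
  pc <- scaffold_part_coords(sc)
  gap <- pc[pc$type == "gap", ]
  # some adjacent block pair straddles the gap
  straddle <- any(mp$blocks$s_end <= gap$start + 10 &
                    c(mp$blocks$s_start[-1], Inf) >= gap$end - 10)
  expect_true(straddle)
})

test_that("strip_unmapped_contigs removes gap-delimited unmapped contigs", {
  w <- sm_world
  set.seed(73)
  junk <- stats::setNames(random_dna(700), "junk")
  c1 <- stats::setNames(paste0(w$ex[1], w$it[1], w$ex[2]), "c1")
  c3 <- stats::setNames(w$ex[3], "c3")
  sc <- scaffold("g", c(c1, junk, c3))
  mp <- map_transcript_to_scaffold(w$tx, sc)
  st <- strip_unmapped_contigs(sc, mp)
  expect_equal(names(scaffold_contigs(st)), c("c1", "c3"))
  pc <- scaffold_part_coords(st)
  expect_equal(sum(pc$type == "gap"), 1)
  # fully mapped scaffold unchanged
  sc2 <- scaffold("g", c(c1, c3))
  st2 <- strip_unmapped_contigs(sc2, map_transcript_to_scaffold(w$tx, sc2))
  expect_equal(scaffold_sequence(st2), scaffold_sequence(sc2))
  # single unmapped contig: flagged empty
  sc3 <- scaffold("g", junk)
  st3 <- strip_unmapped_contigs(sc3, map_transcript_to_scaffold(w$tx, sc3))
  expect_true(isTRUE(attr(st3, "flagged_empty")))
})

test_that("find_redundant_groups applies the 95/99 rule", {
  set.seed(74)
  locus <- random_dna(3000)
  exA <- substr(locus, 201, 500)
  exB <- substr(locus, 1201, 1500)
  exC <- substr(locus, 2301, 2600)
  tx_full <- paste0(exA, exB, exC)
  tx_skip <- paste0(exA, exC)
  scaffolds <- list(full = scaffold("full", stats::setNames(locus, "c1")),
                    skip = scaffold("skip",
                                    stats::setNames(substr(locus, 150, 2700), "c1")))
  txs <- c(full = tx_full, skip = tx_skip)
  grp <- find_redundant_groups(scaffolds, txs)
  expect_length(grp, 1)
  expect_setequal(grp[[1]], c("full", "skip"))
  # ~96% identity everywhere, no 99% region -> kept apart
  noisy <- locus
  for (p in seq(10, 3000, by = 25))
    substr(noisy, p, p) <- setdiff(c("A", "C", "G", "T"), substr(noisy, p, p))[1]
  scaffolds2 <- list(full = scaffolds$full,
                     noisy = scaffold("noisy", stats::setNames(noisy, "c1")))
  txs2 <- c(full = tx_full, noisy = tx_full)
  grp2 <- find_redundant_groups(scaffolds2, txs2)
  expect_length(grp2, 2)
  # unrelated loci -> singletons; order-stable under permutation
  set.seed(75)
  other <- random_dna(2500)
  scaffolds3 <- list(full = scaffolds$full,
                     other = scaffold("other", stats::setNames(other, "c1")))
  txs3 <- c(full = tx_full, other = substr(other, 501, 1400))
  expect_length(find_redundant_groups(scaffolds3, txs3), 2)
  g_fwd <- find_redundant_groups(scaffolds, txs)
  g_rev <- find_redundant_groups(rev(scaffolds), txs)
  expect_equal(lapply(g_fwd, sort), lapply(g_rev, sort))
})

test_that("merge_group collapses variant scaffolds without losing exons", {
  set.seed(76)
  locus <- random_dna(4000)
  exs <- lapply(c(201, 1201, 2201, 3201), function(s) substr(locus, s, s + 299))
  tx_full <- paste0(exs[[1]], exs[[2]], exs[[3]], exs[[4]])
  tx_skip <- paste0(exs[[1]], exs[[3]], exs[[4]])
  scA <- scaffold("full", stats::setNames(substr(locus, 1, 2800), "c1"))
  scB <- scaffold("skip", stats::setNames(substr(locus, 1901, 4000), "c1"))
  txs <- c(full = tx_full, skip = tx_skip)
  pre_full <- map_transcript_to_scaffold(tx_full, scA)$coverage
  pre_skip <- map_transcript_to_scaffold(tx_skip, scB)$coverage
  merged <- merge_group(list(full = scA, skip = scB), txs)
  expect_s3_class(merged, "scaffold")
  post_full <- map_transcript_to_scaffold(tx_full, merged)$coverage
  post_skip <- map_transcript_to_scaffold(tx_skip, merged)$coverage
  expect_gte(post_full, pre_full - 1e-9)
  expect_gte(post_skip, pre_skip - 1e-9)
  # group of one is the identity
  expect_identical(merge_group(list(full = scA), txs), scA)
  # three overlapping fragments collapse into a single contig scaffold
  f1 <- scaffold("f1", stats::setNames(substr(locus, 1, 1600), "c1"))
  f2 <- scaffold("f2", stats::setNames(substr(locus, 1301, 2900), "c1"))
  f3 <- scaffold("f3", stats::setNames(substr(locus, 2601, 4000), "c1"))
  txs3 <- c(f1 = substr(locus, 201, 500), f2 = substr(locus, 1401, 1700),
            f3 = substr(locus, 2801, 3100))
  m3 <- merge_group(list(f1 = f1, f2 = f2, f3 = f3), txs3)
  expect_length(scaffold_contigs(m3), 1)
  expect_equal(unname(scaffold_contigs(m3)[[1]]), locus)
})
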