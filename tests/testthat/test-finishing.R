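test_that("scaffold render/parse round trip and length accounting", {
  set.seed(61)
  ct <- stats::setNames(c(random_dna(800), random_dna(450), random_dna(1200)),
                        c("a", "b", "c"))
  sc <- scaffold("s1", ct)
  seq <- scaffold_sequence(sc)
  expect_equal(nchar(seq), sum(nchar(ct)) + 2 * 500)
  back <- parse_scaffold(seq, "s1")
  expect_equal(unname(scaffold_contigs(back)), unname(ct))
  expect_equal(vapply(Filter(function(p) p$type == "gap", back$parts),
                      function(p) p$length, 0L), c(500L, 500L))
  # single contig: no gaps
  one <- scaffold("s2", ct[1])
  expect_equal(scaffold_sequence(one), unname(ct[1]))
  expect_equal(nrow(subset(scaffold_part_coords(one), type == "gap")), 0)
})

test_that("chimeric contigs are flagged; normal multi-exon contigs are not", {
  set.seed(62)
  ex1 <- random_dna(200); ex2 <- random_dna(200)
  tx <- paste0(ex1, ex2)
  chimera <- stats::setNames(paste0(ex2, random_dna(300), ex2), "chim")
  normal <- stats::setNames(paste0(random_dna(80), ex1, random_dna(400),
                                   ex2, random_dna(80)), "norm")
  single <- stats::setNames(paste0(random_dna(50), ex1, random_dna(50)), "single")
  flg <- detect_chimeric_contigs(tx, c(chimera, normal, single))
  expect_equal(flg, "chim")
})

test_that("perfect_pair_coverage: junction has zero/unspanned support", {
  set.seed(63)
  locusA <- random_dna(900)
  locusB <- random_dna(900)
  chimera <- paste0(locusA, locusB)
  pairs <- rbind(tiling_pairs(locusA, insert = 280, step = 17, prefix = "a"),
                 tiling_pairs(locusB, insert = 280, step = 17, prefix = "b"))
  class(pairs) <- c("read_pairs", "data.frame")
  prof <- perfect_pair_coverage(chimera, pairs)
  expect_length(prof$coverage, 1800)
  # junction neighbourhood unsupported
  expect_true(any(prof$coverage[870:930] == 0 | !prof$spanned[870:930]))
  # interiors well supported
  expect_true(all(prof$coverage[300:600] > 0))
  expect_true(all(prof$spanned[300:600]))
  # a single mismatched mate contributes nothing
  p1 <- pairs[10, ]
  substr(p1$seq1, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                     substr(p1$seq1, 50, 50))[1]
  prof1 <- perfect_pair_coverage(chimera, p1)
  expect_true(all(prof1$coverage == 0))
  # a clean contig rebuilt from its own pairs has no internal zero
  profA <- perfect_pair_coverage(locusA, tiling_pairs(locusA, insert = 280,
                                                      step = 9))
  expect_true(all(profA$coverage[150:750] > 0))
})

test_that("split_contig excises internal unsupported runs, spares ends", {
  contig <- strrep("A", 1000)
  prof <- structure(list(coverage = rep(5L, 1000), spanned = rep(TRUE, 1000)),
                    class = "pair_coverage")
  # internal zero-coverage run at [400,450)
  prof$coverage[401:450] <- 0L
  pieces <- split_contig(contig, prof)
  expect_length(pieces, 2)
  expect_equal(nchar(pieces), c(s1 = 400L, s2 = 550L))
  # zero coverage only in the last 30 bases: unchanged
  prof2 <- structure(list(coverage = rep(5L, 1000), spanned = rep(TRUE, 1000)),
                     class = "pair_coverage")
  prof2$coverage[971:1000] <- 0L
  expect_equal(unname(split_contig(contig, prof2)), contig)
  # uniform support: unchanged
  prof3 <- structure(list(coverage = rep(3L, 1000), spanned = rep(TRUE, 1000)),
                     class = "pair_coverage")
  expect_equal(unname(split_contig(contig, prof3)), contig)
  # unspanned-but-covered internal position is also excised
  prof4 <- structure(list(coverage = rep(3L, 1000), spanned = rep(TRUE, 1000)),
                     class = "pair_coverage")
  prof4$spanned[500] <- FALSE
  expect_length(split_contig(contig, prof4), 2)
})

test_that("orient_contigs flips minus-strand contigs", {
  set.seed(64)
  tx <- random_dna(400)
  plus <- stats::setNames(paste0(random_dna(60), tx, random_dna(60)), "p")
  minus <- stats::setNames(as.character(reverse_complement(plus)), "m")
  none <- stats::setNames(random_dna(300), "n")
  res <- orient_contigs(tx, c(plus, minus, none))
  expect_equal(unname(res$contigs["m"]), unname(plus))
  expect_equal(unname(res$contigs["p"]), unname(plus))
  expect_equal(res$flagged, "n")
})

test_that("group_and_consensus collapses alternative assemblies by majority", {
  set.seed(65)
  locus <- random_dna(600)
  alt <- locus
  substr(alt, 300, 300) <- setdiff(c("A", "C", "G", "T"),
                                   substr(alt, 300, 300))[1]
  g <- group_and_consensus(stats::setNames(c(locus, alt), c("a", "b")))
  expect_length(g, 1)
  expect_equal(unname(g[[1]]), locus)  # tie broken toward the longest/anchor
  # three copies, two agreeing: majority wins even against the anchor
  longer <- paste0(locus, random_dna(5))
  alt2 <- substr(longer, 1, 600)
  substr(alt2, 300, 300) <- "A"
  substr(longer, 300, 300) <- "C"
  votes <- stats::setNames(c(longer,
                             paste0(substr(alt2, 1, 600)),
                             paste0(substr(alt2, 1, 600))),
                           c("anchor", "v1", "v2"))
  if (substr(locus, 300, 300) != "A") {
    gc <- group_and_consensus(votes)
    expect_length(gc, 1)
    expect_equal(substr(gc[[1]], 300, 300), "A")
  }
  # dissimilar contigs pass through untouched
  un <- stats::setNames(c(random_dna(400), random_dna(400)), c("x", "y"))
  expect_equal(group_and_consensus(un), un[order(names(un))])
})

test_that("order_and_join fuses true overlaps and gaps the rest", {
  set.seed(66)
  g <- random_dna(2000)
  tx <- paste0(substr(g, 101, 260), substr(g, 901, 1060), substr(g, 1701, 1860))
  # contigs around exon 1 and exon 2 overlapping by 50 bases
  c1 <- stats::setNames(substr(g, 1, 500), "c1")
  c2 <- stats::setNames(substr(g, 451, 1200), "c2")
  sc <- order_and_join(stats::setNames(tx, "gene"), c(c1, c2))
  expect_length(scaffold_contigs(sc), 1)
  expect_equal(unname(scaffold_contigs(sc)[[1]]), substr(g, 1, 1200))
  # disjoint contigs get a 500-N gap
  c3 <- stats::setNames(substr(g, 1601, 2000), "c3")
  sc2 <- order_and_join(stats::setNames(tx, "gene"), c(c1, c3))
  pc <- scaffold_part_coords(sc2)
  expect_equal(pc$type, c("contig", "gap", "contig"))
  expect_equal(pc$end[2] - pc$start[2], 500)
  expect_equal(sc2$scaffold_id, "gene")
  # single contig passes through
  sc3 <- order_and_join(stats::setNames(tx, "gene"), c1)
  expect_equal(scaffold_sequence(sc3), unname(c1))
})
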