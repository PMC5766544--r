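test_that("n50 matches a brute-force oracle on random length sets", {
  oracle_n50 <- function(v) {
    v <- sort(v, decreasing = TRUE)
    tot <- sum(v)
    run <- 0
    for (x in v) { run <- run + x; if (run >= tot / 2) return(x) }
    0
  }
  set.seed(81)
  for (i in 1:50) {
    v <- sample(1:5000, sample(1:40, 1), replace = TRUE)
    expect_equal(n50(v), oracle_n50(v))
  }
  expect_equal(n50(numeric(0)), 0)
  expect_equal(n50(7), 7)
})

test_that("intron_report: bridged, unbridged and single-exon cases", {
  set.seed(82)
  ex1 <- random_dna(150); ex2 <- random_dna(150); ex3 <- random_dna(150)
  intr <- random_dna(800)
  tx <- paste0(ex1, ex2, ex3)
  # exons 1+2 on one contig (800 bases apart), exon 3 on another
  c1 <- stats::setNames(paste0(ex1, intr, ex2), "c1")
  c3 <- stats::setNames(paste0(ex3, random_dna(100)), "c3")
  sc <- scaffold("g", c(c1, c3))
  mp <- map_transcript_to_scaffold(tx, sc)
  ir <- intron_report(sc, mp, "g")
  expect_equal(nrow(ir), 2)
  expect_true(ir$bridged[1])
  expect_equal(ir$length[1], 800)
  expect_false(ir$bridged[2])
  expect_true(all(ir$reliable))
  expect_equal(ir$length[2], 0)   # nothing but the gap between the blocks
  # two gap records inside one intron -> unreliable
  cjunk <- stats::setNames(random_dna(400), "cj")
  # force placement of the junk contig between c1 and c3 manually
  sc2 <- scaffold("g", c(c1, cjunk, c3))
  mp2 <- map_transcript_to_scaffold(tx, sc2)
  ir2 <- intron_report(sc2, mp2, "g")
  expect_false(ir2$reliable[2])
  expect_equal(ir2$length[2], 400)  # the stray contig's real bases count
  # single-exon transcript: no introns
  sc3 <- scaffold("g1", c1)
  mp3 <- map_transcript_to_scaffold(ex1, sc3)
  expect_equal(nrow(intron_report(sc3, mp3, "g1")), 0)
})

test_that("flank_report excludes N gaps from the count", {
  set.seed(83)
  ex <- random_dna(200)
  tx <- ex
  # block starts at position 0: upstream 0
  scA <- scaffold("g", stats::setNames(paste0(ex, random_dna(100)), "c1"))
  fA <- flank_report(scA, map_transcript_to_scaffold(tx, scA))
  expect_equal(unname(fA["upstream"]), 0)
  expect_equal(unname(fA["downstream"]), 100)
  # 1200 real bases then the exon
  scB <- scaffold("g", stats::setNames(paste0(random_dna(1200), ex), "c1"))
  fB <- flank_report(scB, map_transcript_to_scaffold(tx, scB))
  expect_equal(unname(fB["upstream"]), 1200)
  # trailing gap + 300 real bases downstream: gap excluded
  scC <- scaffold("g", c(stats::setNames(paste0(random_dna(50), ex), "c1"),
                         stats::setNames(random_dna(300), "c2")))
  # map only against exon-bearing contig; block sits before the gap
  fC <- flank_report(scC, map_transcript_to_scaffold(tx, scC))
  expect_equal(unname(fC["downstream"]), 300)
})

test_that("end_status_report separates repeat from low-coverage stops", {
  set.seed(84)
  # two walks: one still extending (normal coverage), one stopped with a
  # high-coverage end, one stopped quiet end
  mk_state <- function(id, contig, status, changed) {
    tails <- data.frame(contig = names(contig), end = c("L", "R"),
                        tail = c(substr(contig, 1, 60),
                                 substr(contig, nchar(contig) - 59,
                                        nchar(contig))),
                        stringsAsFactors = FALSE)
    prev <- tails
    if (!changed) prev$tail <- tails$tail      # identical: unchanged
    else prev$tail <- c(substr(contig, 2, 61), # shifted: "changed"
                        substr(contig, nchar(contig) - 60,
                               nchar(contig) - 1))
    structure(list(transcript_id = id, transcript = "", iteration = 2L,
                   contigs = contig, recruited = character(0),
                   stats = data.frame(), status = status,
                   reason = NA_character_,
                   end_history = list(prev, tails)), class = "walk_state")
  }
  uniq <- random_dna(3000)
  rep_unit <- random_dna(400)
  stopped_ct <- stats::setNames(paste0(substr(uniq, 1, 1000), rep_unit), "s1")
  extend_ct <- stats::setNames(substr(uniq, 1201, 2400), "e1")
  # reads: 6x over unique sequence, 60x over the repeat unit
  prs <- rbind(tiling_pairs(uniq, insert = 300, step = 60, prefix = "u"),
               tiling_pairs(strrep(rep_unit, 12), insert = 300, step = 6,
                            prefix = "r"))
  class(prs) <- c("read_pairs", "data.frame")
  states <- list(mk_state("t_ext", extend_ct, "extending", changed = TRUE),
                 mk_state("t_rep", stopped_ct, "finished", changed = FALSE))
  rep_report <- end_status_report(states, prs)
  expect_equal(sort(unique(rep_report$status[rep_report$transcript == "t_ext"])),
               "extending")
  r_end <- rep_report[rep_report$transcript == "t_rep" & rep_report$end == "R", ]
  l_end <- rep_report[rep_report$transcript == "t_rep" & rep_report$end == "L", ]
  expect_equal(r_end$status, "repeat")        # terminal 60 bp in the repeat
  expect_equal(l_end$status, "low_coverage")  # quiet unique end
  # no extending ends: fallback threshold with warning
  expect_warning(
    fb <- end_status_report(states[2], prs, fallback_threshold = 30),
    "falling back")
  expect_equal(fb$status[fb$end == "R"], "repeat")
})

test_that("assembly_summary excludes artificial gap Ns", {
  set.seed(85)
  ct <- stats::setNames(c(random_dna(1000), random_dna(3000)), c("a", "b"))
  sc <- scaffold("s", ct)
  s <- assembly_summary(list(sc))
  expect_equal(s$total_bases, 4000)          # not 4500
  expect_equal(s$scaffold_n50, 4000)
  expect_equal(s$contig_n50, 3000)
  expect_equal(s$n_contigs, 2)
})
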