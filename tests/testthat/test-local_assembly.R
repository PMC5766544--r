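test_that("dbg_unitigs reconstructs a repeat-free sequence from tiling reads", {
  set.seed(41)
  g <- random_dna(500)
  u <- dbg_unitigs(tiling_reads(g), k = 63, min_count = 1)
  expect_length(u, 1)
  expect_true(u[[1]] == g || u[[1]] == as.character(reverse_complement(g)))
})

test_that("dbg_unitigs breaks at a repeated 63-mer", {
  set.seed(42)
  rep63 <- random_dna(63)
  g <- paste0(random_dna(200), rep63, random_dna(200), rep63, random_dna(200))
  u <- dbg_unitigs(tiling_reads(g, read_len = 90, step = 3), k = 63,
                   min_count = 1)
  expect_gte(length(u), 2)
  for (s in u) {
    expect_true(grepl(s, g, fixed = TRUE) ||
                  grepl(as.character(reverse_complement(s)), g, fixed = TRUE))
  }
})

test_that("dbg_unitigs degenerate inputs", {
  expect_length(dbg_unitigs(character(0)), 0)
  expect_length(dbg_unitigs("ACGT", k = 63), 0)  # no read >= k
  expect_error(dbg_unitigs("ACGT", k = 4))       # k must be odd
})

test_that("coverage floor absorbs singleton error k-mers", {
  set.seed(43)
  g <- random_dna(400)
  reads <- tiling_reads(g, read_len = 80, step = 4)
  bad <- reads[10]
  substr(bad, 40, 40) <- setdiff(c("A", "C", "G", "T"), substr(bad, 40, 40))[1]
  u <- dbg_unitigs(c(reads, bad), k = 31, min_count = 2)
  expect_length(u, 1)
  # the error k-mers are gone; terminal k-mers seen once are also dropped,
  # so the unitig is a near-full-length exact substring of the truth
  expect_true(grepl(u[[1]], g, fixed = TRUE) ||
                grepl(as.character(reverse_complement(u[[1]])), g, fixed = TRUE))
  expect_gte(nchar(u[[1]]), nchar(g) - 16)
})

test_that("overlap_layout_merge: exact 30-base overlap boundary", {
  set.seed(44)
  core <- random_dna(30)
  a <- stats::setNames(paste0(random_dna(170), core), "a")
  b <- stats::setNames(paste0(core, random_dna(170)), "b")
  m <- overlap_layout_merge(c(a, b), overlap_params("permissive"))
  expect_length(m, 1)
  expect_equal(nchar(m[[1]]), 370)
  expect_equal(unname(m[[1]]), paste0(substr(a, 1, 170), core, substr(b, 31, 200)))
  # 29 identical bases -> no merge
  a29 <- stats::setNames(paste0(random_dna(170), substr(core, 1, 29)), "a")
  b29 <- stats::setNames(paste0(substr(core, 1, 29), random_dna(170)), "b")
  m29 <- overlap_layout_merge(c(a29, b29), overlap_params("permissive"))
  expect_length(m29, 2)
})

test_that("overlap below the identity floor is rejected", {
  set.seed(45)
  core <- random_dna(40)
  # mutate 12/40 positions -> 70% identity
  mut <- core
  pos <- seq(2, 35, by = 3)
  for (p in pos) substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"),
                                              substr(mut, p, p))[1]
  a <- stats::setNames(paste0(random_dna(160), core), "a")
  b <- stats::setNames(paste0(mut, random_dna(160)), "b")
  m <- overlap_layout_merge(c(a, b), overlap_params("permissive"))
  expect_length(m, 2)
})

test_that("overlap_layout_merge is idempotent and respects a base budget", {
  set.seed(46)
  for (trial in 1:5) {
    g <- random_dna(900)
    starts <- sort(sample(1:500, 4))
    ctg <- stats::setNames(substring(g, starts, starts + 399),
                           paste0("c", 1:4))
    m1 <- overlap_layout_merge(ctg, overlap_params("permissive"))
    m2 <- overlap_layout_merge(m1, overlap_params("permissive"))
    expect_identical(unname(sort(m1)), unname(sort(m2)))
    expect_lte(sum(nchar(m1)), sum(nchar(ctg)))
  }
})

test_that("a contig is not merged with itself into a palindrome", {
  set.seed(47)
  a <- stats::setNames(random_dna(300), "a")
  m <- overlap_layout_merge(a, overlap_params("permissive"))
  expect_identical(m, a)
  # a and its exact reverse complement collapse to one (containment), not
  # a doubled palindrome
  b <- stats::setNames(as.character(reverse_complement(a)), "b")
  m2 <- overlap_layout_merge(c(a, b), overlap_params("permissive"))
  expect_length(m2, 1)
  expect_equal(nchar(m2[[1]]), 300)
})

test_that("elongate_with_reads extends ends and leaves interiors alone", {
  set.seed(48)
  g <- random_dna(600)
  contig <- substr(g, 101, 420)
  # reads extending 80 bp beyond the right end with perfect overlaps
  reads <- substring(g, seq(340, 420, by = 10), seq(340, 420, by = 10) + 99)
  out <- elongate_with_reads(contig, reads)
  expect_gt(nchar(out), nchar(contig))
  expect_lte(nchar(out), nchar(contig) + 99)
  expect_true(grepl(contig, out, fixed = TRUE))
  expect_true(grepl(out, g, fixed = TRUE))  # extension follows the truth
  # reads only re-covering the interior: unchanged
  interior <- substring(g, seq(150, 250, by = 20), seq(150, 250, by = 20) + 79)
  expect_equal(elongate_with_reads(contig, interior), contig)
  # no read overlaps an end: unchanged
  expect_equal(elongate_with_reads(contig, random_dna(100)), contig)
})

test_that("exact-reconstruction property holds on random sequences", {
  set.seed(49)
  ok <- 0
  n_trials <- 20
  for (trial in seq_len(n_trials)) {
    g <- random_dna(sample(300:1500, 1))
    reads <- tiling_reads(g, read_len = 100, step = 5)  # ~20x
    u <- dbg_unitigs(reads, k = 63, min_count = 1)
    m <- overlap_layout_merge(u, overlap_params("permissive"))
    if (length(m) == 1 &&
        (m[[1]] == g || m[[1]] == as.character(reverse_complement(g))))
      ok <- ok + 1
  }
  expect_gte(ok, ceiling(0.95 * n_trials))
})
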