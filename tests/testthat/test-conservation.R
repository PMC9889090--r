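test_that("self-alignment is full-length with score match * length", {
  p <- alignment_params()
  for (n in c(4, 12, 30)) {
    set.seed(n)
    x <- random_dna(n)
    aln <- local_align(x, x, p)
    expect_equal(aln$score, 5 * n)
    expect_equal(length(aln$a_pos), n)
    expect_equal(aln$a_pos, aln$b_pos)
    expect_false(anyNA(aln$a_pos))
  }
})

test_that("dissimilar sequences yield an empty zero-score alignment", {
  aln <- local_align("AAAA", "CCCC")
  expect_equal(aln$score, 0)
  expect_length(aln$a_pos, 0L)
  expect_equal(aln$a_start, 0L)
})

test_that("empty or invalid sequences are rejected", {
  expect_error(local_align("", "ACGT"), "non-empty")
  expect_error(local_align("ACGT", "ACXT"), "position 3")
})

test_that("DP score equals the brute-force enumeration oracle", {
  p <- alignment_params()
  set.seed(55)
  for (k in 1:60) {
    a <- random_dna(sample(1:10, 1))
    b <- random_dna(sample(1:10, 1))
    expect_equal(local_align(a, b, p)$score, enumerate_local_score(a, b, p),
                 info = paste(a, b))
  }
})

test_that("DP score agrees with an independent aligner implementation", {
  # cross-check against Biostrings on longer pairs; gap conventions mapped:
  # cost(L) = open + (L-1) * ext  <=>  gapOpening = open - ext per gap plus
  # gapExtension = ext per residue
  p <- alignment_params()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = TRUE)
  set.seed(77)
  for (k in 1:20) {
    a <- random_dna(sample(20:60, 1))
    b <- random_dna(sample(20:60, 1))
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 9.5,
                                         gapExtension = 0.5)
    expect_equal(local_align(a, b, p)$score, Biostrings::score(ref))
  }
})

test_that("swapping inputs preserves the score for arbitrary pairs", {
  set.seed(88)
  for (k in 1:15) {
    a <- random_dna(sample(5:30, 1)); b <- random_dna(sample(5:30, 1))
    expect_equal(local_align(a, b)$score, local_align(b, a)$score)
  }
})

test_that("swapping inputs swaps stretch coordinates when the optimum is unique", {
  # a long shared core at different offsets pins down a unique optimum,
  # so the stretch table must mirror exactly under argument swap
  set.seed(89)
  core <- random_dna(24)
  a <- paste0(random_dna(7), core, random_dna(4))
  b <- paste0(random_dna(12), core)
  st_f <- conserved_stretches(local_align(a, b), min_len = 20)
  st_r <- conserved_stretches(local_align(b, a), min_len = 20)
  expect_equal(st_f$a_start, st_r$b_start)
  expect_equal(st_f$a_end, st_r$b_end)
  expect_equal(st_f$b_start, st_r$a_start)
  expect_equal(st_f$identity, st_r$identity)
})

test_that("conserved stretches respect the gapless >= 20 bp rule", {
  set.seed(99)
  core25 <- random_dna(25)
  aln <- local_align(core25, core25)
  st <- conserved_stretches(aln, min_len = 20)
  expect_equal(nrow(st), 1L)
  expect_equal(st$length, 25L)
  expect_equal(st$identity, 1.0)
  expect_equal(st$a_start, 0L)
  expect_equal(st$a_end, 25L)

  # 19 aligned bases sit below the threshold
  core19 <- random_dna(19)
  st19 <- conserved_stretches(local_align(core19, core19), min_len = 20)
  expect_equal(nrow(st19), 0L)

  # a deletion after 22 columns splits the run; the 17-column rest drops
  left <- random_dna(22); right <- random_dna(17)
  ins <- setdiff(c("A", "C", "G", "T"),
                 c(substr(left, 22, 22), substr(right, 1, 1)))[1]
  a <- paste0(left, ins, right)
  b <- paste0(left, right)
  aln2 <- local_align(a, b)
  expect_equal(length(aln2$a_pos), 40L) # 39 aligned pairs + 1 gap column
  st2 <- conserved_stretches(aln2, min_len = 20)
  expect_equal(nrow(st2), 1L)
  expect_equal(st2$length, 22L)
})

test_that("gap-free columns are conserved across run splitting", {
  set.seed(111)
  for (k in 1:10) {
    a <- random_dna(40); b <- random_dna(40)
    aln <- local_align(a, b)
    if (!length(aln$a_pos)) next
    gapless <- sum(!is.na(aln$a_pos) & !is.na(aln$b_pos))
    runs <- conserved_stretches(aln, min_len = 1)
    expect_equal(sum(runs$length), gapless)
  }
})

test_that("substitutions stay inside a stretch and lower its identity", {
  set.seed(123)
  x <- random_dna(30)
  y <- x
  substr(y, 15, 15) <- chartr("ACGT", "GTAC", substr(x, 15, 15))
  st <- conserved_stretches(local_align(x, y), min_len = 20)
  expect_equal(nrow(st), 1L)
  expect_equal(st$length, 30L)
  expect_equal(st$identity, 29 / 30)
})

test_that("conservation summary reports coverage fractions", {
  st <- data.frame(a_start = 0, a_end = 25, b_start = 0, b_end = 25,
                   length = 25, identity = 1)
  s <- conservation_summary(st, a_len = 100, b_len = 200)
  expect_equal(s$coverage_a, 0.25)
  expect_equal(s$coverage_b, 0.125)
  s0 <- conservation_summary(st[0, ], 100, 100)
  expect_equal(s0$coverage_a, 0)
  st2 <- data.frame(a_start = c(0, 100), a_end = c(20, 130),
                    b_start = c(0, 100), b_end = c(20, 130),
                    length = c(20, 30), identity = c(1, 1))
  expect_equal(conservation_summary(st2, 1000, 1000)$coverage_a, 0.05)
})

test_that("the whole-locus convenience wrapper composes the steps", {
  set.seed(131)
  shared <- random_dna(35)
  a <- paste0(random_dna(15), shared, random_dna(10))
  b <- paste0(random_dna(8), shared, random_dna(20))
  res <- conservation_analysis(a, b)
  expect_gte(res$summary$n_stretches, 1L)
  expect_gte(max(res$stretches$length), 35L)
  expect_equal(res$summary$coverage_a,
               sum(res$stretches$length) / nchar(a))
})
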