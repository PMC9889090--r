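make_tiny_genome <- function(n = 4000, seed = 5) {
  set.seed(seed)
  setNames(random_dna(n), "chrT")
}

test_that("primer trimming honours error rate and length floor", {
  primer <- "ACGTACGTACGTACGTACGT" # 20 nt -> floor(20 * 0.05) = 1 error
  insert <- strrep("TGCA", 8)      # 32 nt
  spec <- trim_spec(primer)

  r <- trim_reads(data.frame(id = "a", seq = paste0(primer, insert)), spec)
  expect_equal(r$seq, insert)

  # one mismatch in the primer is tolerated at rate 0.05
  p1 <- paste0("T", substring(primer, 2))
  r1 <- trim_reads(data.frame(id = "a", seq = paste0(p1, insert)), spec)
  expect_equal(r1$seq, insert)

  # two mismatches exceed the allowance
  p2 <- paste0("TT", substring(primer, 3))
  r2 <- trim_reads(data.frame(id = "a", seq = paste0(p2, insert)), spec)
  expect_equal(nrow(r2), 0L)

  # reads without a primer are removed when discard_untrimmed
  r3 <- trim_reads(data.frame(id = "a", seq = strrep("G", 60)), spec)
  expect_equal(nrow(r3), 0L)
  keep <- trim_spec(primer, discard_untrimmed = FALSE)
  r4 <- trim_reads(data.frame(id = "a", seq = strrep("G", 60)), keep)
  expect_equal(nrow(r4), 1L)

  # too short after trimming -> dropped
  r5 <- trim_reads(data.frame(id = "a", seq = paste0(primer, "ACGTACGT")),
                   spec)
  expect_equal(nrow(r5), 0L)
  tal <- attr(r5, "tally")
  expect_equal(unname(tal["input"] - tal["kept"]), 1)
})

test_that("iterative mapping trims 5 nt at a time until mapped or < 25 bp", {
  g <- make_tiny_genome()
  gs <- g[[1]]

  # 27-nt genomic prefix + 5 junk nt: unmapped at 32, mapped at 27
  core <- substr(gs, 101, 127)
  nxt <- substr(gs, 128, 128)
  junk <- paste(rep(setdiff(c("A", "C", "G", "T"), nxt)[1], 5), collapse = "")
  mp <- iterative_map(data.frame(id = "r", seq = paste0(core, junk)),
                      genome = g)
  expect_true(mp$mapped)
  expect_equal(mp$final_length, 27L)
  expect_equal(mp$n_trims, 1L)
  expect_equal(mp$pos, 100L)
  expect_equal(mp$strand, "+")

  # exact 30-nt read maps with no trimming
  mp2 <- iterative_map(data.frame(id = "r", seq = substr(gs, 501, 530)),
                       genome = g)
  expect_true(mp2$mapped)
  expect_equal(mp2$n_trims, 0L)

  # a read absent at every trim length terminates unmapped below 25
  set.seed(9)
  repeat { # draw a 30-mer whose every 5-step prefix is absent
    cand <- random_dna(30)
    absent <- all(vapply(c(30, 25), function(L)
      !grepl(substr(cand, 1, L), gs, fixed = TRUE) &&
        !grepl(substr(cand, 1, L), as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(gs))),
          fixed = TRUE), logical(1)))
    if (absent) break
  }
  mp3 <- iterative_map(data.frame(id = "r", seq = cand), genome = g)
  expect_false(mp3$mapped)
  expect_equal(mp3$final_length, 20L)
  expect_equal(mp3$n_trims, 2L)
})

test_that("mapping invariants: length floor and 5-nt trim arithmetic", {
  g <- make_tiny_genome()
  set.seed(21)
  reads <- data.frame(
    id = sprintf("r%02d", 1:40),
    seq = vapply(1:40, function(i) {
      start <- sample(nchar(g[[1]]) - 60, 1)
      core <- substr(g[[1]], start, start + sample(25:40, 1))
      if (runif(1) < 0.5) paste0(core, random_dna(sample(c(5, 10), 1)))
      else core
    }, character(1)))
  mp <- iterative_map(reads, genome = g)
  expect_true(all(mp$final_length[mp$mapped] >= 25))
  expect_true(all((nchar(reads$seq) - mp$final_length) %% 5 == 0))
  expect_true(all((nchar(reads$seq) - mp$final_length) / 5 == mp$n_trims))
})

test_that("the exact aligner reports multi-mapping and reverse strand", {
  g <- c(chrT = paste0("AAAAC", strrep("G", 30), "TTTTTCAT",
                       strrep("G", 30), "AAAA"))
  al <- exact_aligner(g)
  # a repeated 30-mer is ambiguous -> unmapped
  r <- al(strrep("G", 30))
  expect_false(r$mapped)
  # unique sequence maps on the minus strand at the correct leftmost pos
  sub <- substr(g[[1]], 6, 43)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  r2 <- al(rc)
  expect_true(r2$mapped)
  expect_equal(r2$strand, "-")
  expect_equal(r2$pos, 5L)
})

test_that("fragment assignment uses the 5'-most coordinate, half-open", {
  g <- c(chrA = "TTTCATGAAACATGGG")
  fm <- build_fragment_map(g, nlaiii, dpnii, min_len = 1)
  fm$fragments$valid <- TRUE # force all valid for the geometry check
  mk <- function(pos, strand, len = 4L)
    data.frame(read_id = "r", mapped = TRUE, chrom = "chrA", pos = pos,
               strand = strand, final_length = len, n_trims = 0L)
  expect_equal(which(assign_to_fragments(mk(5L, "+"), fm)$counts == 1L), 2L)
  # half-open boundary: pos 3 belongs to fragment [3,10)
  expect_equal(which(assign_to_fragments(mk(3L, "+"), fm)$counts == 1L), 2L)
  # minus strand: 5'-most coordinate is pos + len - 1
  expect_equal(which(assign_to_fragments(mk(1L, "-", 4L), fm)$counts == 1L),
               2L)
  # coordinate outside the map -> genome mismatch error
  expect_error(assign_to_fragments(mk(99L, "+"), fm), "mismatch")
})

test_that("reads in invalid fragments are dropped and tallies conserve reads", {
  g <- c(chrA = "TTTCATGAAACATGAAGATCGG") # fragment 2 has GATC, others blind
  fm <- build_fragment_map(g, nlaiii, dpnii, min_len = 1)
  expect_equal(fm$fragments$valid, c(FALSE, FALSE, TRUE))
  mp <- data.frame(read_id = c("a", "b", "c"),
                   mapped = c(TRUE, TRUE, FALSE),
                   chrom = c("chrA", "chrA", NA),
                   pos = c(4L, 15L, NA),
                   strand = c("+", "+", NA),
                   final_length = c(4L, 4L, 20L), n_trims = 0L)
  asg <- assign_to_fragments(mp, fm, exclude_invalid = TRUE)
  expect_equal(sum(asg$counts), 1L)
  tal <- asg$tally
  expect_equal(unname(tal["counted"] + tal["dropped_invalid"] +
                        tal["unmapped"]), 3)
  # keeping invalid fragments counts the blind-fragment read too
  asg2 <- assign_to_fragments(mp, fm, exclude_invalid = FALSE)
  expect_equal(sum(asg2$counts), 2L)
})

test_that("RPM normalization scales to one million and is conservative", {
  expect_equal(rpm_normalize(c(1, 3, 6)), c(1e5, 3e5, 6e5))
  expect_equal(rpm_normalize(c(0, 0, 0)), c(0, 0, 0))
  set.seed(3)
  for (k in 1:20) {
    x <- rpois(sample(3:50, 1), lambda = 4)
    if (sum(x) == 0) next
    expect_equal(sum(rpm_normalize(x)), 1e6, tolerance = 1e-9)
  }
})

test_that("closest-five smoothing: centered window, truncated at ends", {
  expect_equal(smooth_profile(c(0, 0, 10, 0, 0, 0, 0))[3], 2.0)
  expect_equal(smooth_profile(c(0, 0, 10, 0, 0, 0, 0)),
               c(10/3, 10/4, 2, 2, 2, 0, 0))
  # constants are a fixed point
  expect_equal(smooth_profile(rep(7, 5)), rep(7, 5))
  # truncated edge window of 3
  expect_equal(smooth_profile(c(10, 0, 0, 0, 0))[1], 10/3)
  # fragments on another chromosome never enter a window
  two <- smooth_profile(c(10, 0, 0, 0, 0, 0), chrom = c("a", "a", "a",
                                                        "b", "b", "b"))
  expect_equal(two, c(10/3, 10/3, 10/3, 0, 0, 0))
  expect_error(smooth_profile(numeric(0)), "empty")
})

test_that("smoothing is linear and permutation-insensitive on constants", {
  set.seed(13)
  x <- runif(20); y <- runif(20)
  expect_equal(smooth_profile(2 * x + 3 * y),
               2 * smooth_profile(x) + 3 * smooth_profile(y))
})

test_that("distance-based smoothing matches the index window on uniform tiling", {
  set.seed(31)
  x <- runif(12)
  mids <- seq(50, by = 100, length.out = 12) # equal spacing
  expect_equal(smooth_profile(x, method = "distance", midpoints = mids)[3:10],
               smooth_profile(x)[3:10])
})

test_that("run_fourc composes the stages and reports tallies", {
  cfg <- sim_config(seed = 17, genome_length = 20000, n_reads = 400,
                    contamination = 0.25)
  g <- make_genome(cfg)
  fm <- build_fragment_map(g, cfg$primary, cfg$secondary, min_len = 40)
  sim <- simulate_fourc_reads(cfg, g, fm)
  prof <- run_fourc(sim$reads, g, fm, trimspec = trim_spec(cfg$primer),
                    viewpoint = sprintf("chrS:%d-%d",
                                        fm$fragments$start[sim$viewpoint_row] + 1,
                                        fm$fragments$end[sim$viewpoint_row]))
  expect_s3_class(prof, "FourCProfile")
  expect_equal(sum(prof$rpm), 1e6, tolerance = 1e-6)
  expect_equal(length(prof$smoothed), nrow(fm$fragments))
  tal <- prof$tally
  expect_equal(unname(tal["counted"] + tal["dropped_invalid"] +
                        tal["unmapped"]), unname(tal["after_trim"]))

  # single-source library: all RPM on one fragment before smoothing
  one <- sim$truth$fragment_row[1]
  f <- fm$fragments
  reads1 <- data.frame(id = sprintf("s%03d", 1:50),
                       seq = substring(g[[1]], f$start[one] + 1,
                                       f$start[one] + 30))
  prof1 <- run_fourc(reads1, g, fm, trimspec = NULL)
  expect_equal(prof1$rpm[one], 1e6)
  expect_equal(sum(prof1$rpm != 0), 1L)

  # zero surviving reads -> empty profile with a warning
  expect_warning(
    prof0 <- run_fourc(data.frame(id = "x", seq = strrep("G", 60)), g, fm,
                       trimspec = trim_spec(cfg$primer)),
    "no reads")
  expect_equal(sum(prof0$counts), 0L)
})

test_that("bedGraph track export writes one line per fragment", {
  g <- c(chrA = "TTTCATGAAGATCACATGAAGATCGG")
  fm <- build_fragment_map(g, nlaiii, dpnii, min_len = 1)
  prof <- structure(list(fragments = fm$fragments,
                         counts = c(1L, 2L, 3L),
                         rpm = rpm_normalize(c(1, 2, 3)),
                         smoothed = smooth_profile(rpm_normalize(c(1, 2, 3))),
                         tally = c(input = 6)),
                    class = "FourCProfile")
  dir <- tempfile()
  paths <- write_fourc_tracks(prof, dir)
  expect_length(paths, 3L)
  counts_lines <- readLines(paths[1])
  body <- grep("^chrA\t", counts_lines, value = TRUE)
  expect_length(body, 3L)
  expect_equal(strsplit(body[1], "\t")[[1]][2], "0") # 0-based half-open
})
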