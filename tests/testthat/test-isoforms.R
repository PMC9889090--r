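trex_window <- "chr8:55115873-55141447"

test_that("junctions derive from block gaps with 1-based flank coordinates", {
  # blocks [100,200) and [500,600) half-open = 101-200, 501-600 inclusive
  b <- data.frame(start = c(101L, 501L), end = c(200L, 600L))
  jx <- lnckit:::junctions_from_blocks(b)
  expect_equal(jx$left, 200L)
  expect_equal(jx$right, 501L)
  # canonicalization: order of arguments never matters
  expect_equal(junction(55140806, 55125601),
               list(left = 55125601L, right = 55140806L))
})

test_that("extraction filters by window, merges small gaps, flags unspliced", {
  tbl <- tiny_spliced_tbl()
  # append one read outside the window and one with a sub-intron gap
  tbl <- rbind(tbl, data.frame(
    read_id = c("far", "del"), chrom = c("chr8", "chr8"), strand = "+",
    blocks = c("1000-1400", "55120000-55120100,55120110-55120300")))
  sr <- extract_spliced_reads(tbl, trex_window, min_intron = 20)
  expect_false("far" %in% sr$reads$read_id)
  # 9-nt gap merged into one block -> unspliced
  expect_true("del" %in% sr$reads$read_id)
  expect_false(sr$reads$spliced[sr$reads$read_id == "del"])
  expect_equal(unname(sr$tally["spliced"]), 3L)
  expect_equal(unname(sr$tally["unspliced"]), 2L)
  # junction coordinates for r1
  j1 <- sr$junctions[sr$junctions$read_id == "r1", ]
  expect_equal(c(j1$left, j1$right), c(55125601L, 55140806L))
})

test_that("malformed block strings are skipped with a warning and tallied", {
  tbl <- tiny_spliced_tbl()
  tbl$blocks[2] <- "oops"
  expect_warning(sr <- extract_spliced_reads(tbl, trex_window), "skipping")
  expect_equal(unname(sr$tally["rejected"]), 1L)
  expect_false("r2" %in% sr$reads$read_id)
})

test_that("reads classify to the packaged isoform definitions or sloppy", {
  defs <- trex17_isoform_defs()
  sr <- extract_spliced_reads(tiny_spliced_tbl(), trex_window)
  cl <- classify_reads(sr, defs)
  expect_equal(cl$category[cl$read_id == "r1"], "Ex1+2")
  expect_equal(cl$category[cl$read_id == "r2"], "Ex1+3")
  expect_equal(cl$category[cl$read_id == "r3"], "sloppy")
})

test_that("classification with no split reads is an error", {
  tbl <- tiny_spliced_tbl()[4, , drop = FALSE] # only the unspliced read
  sr <- extract_spliced_reads(tbl, trex_window)
  expect_error(classify_reads(sr, trex17_isoform_defs()), "no split reads")
})

test_that("tolerance widens matches monotonically", {
  cfg <- sim_config(seed = 23,
                    isoform_composition = c("Ex1+2" = 20L, "Ex1+3" = 10L,
                                            sloppy = 30L))
  sim <- simulate_spliced_reads(cfg, jitter = 3L)
  sr <- extract_spliced_reads(sim, trex_window)
  matched <- function(tol) {
    cl <- classify_reads(sr, trex17_isoform_defs(tolerance = tol))
    sum(cl$category != "sloppy")
  }
  m <- vapply(c(0L, 2L, 5L, 8L), matched, integer(1))
  expect_true(all(diff(m) >= 0))
  expect_equal(m[3], 30L) # jitter 3 is always inside tolerance 5
})

test_that("quantification reproduces the published worked example", {
  q <- quantify_isoforms(c("Ex1+2" = 16L, "Ex1+3" = 11L, sloppy = 89L))
  expect_equal(q$total_split_reads, 116L)
  expect_equal(q$defined_pct, 23.3)
  expect_equal(q$sloppy_pct, 76.7)
  expect_equal(unname(q$fractions["Ex1+2"]), 13.8)

  q2 <- quantify_isoforms(c(A = 1L, sloppy = 0L))
  expect_equal(unname(q2$fractions["A"]), 100.0)

  q3 <- quantify_isoforms(c(A = 1L, B = 1L, sloppy = 2L))
  expect_equal(unname(q3$fractions[c("A", "B")]), c(25.0, 25.0))
  expect_equal(q3$defined_pct, 50.0)

  expect_error(quantify_isoforms(c(A = 0L, sloppy = 0L)), "zero split")
})

test_that("percentages sum to 100 within rounding for random compositions", {
  set.seed(71)
  for (k in 1:25) {
    counts <- setNames(rpois(4, 20) + c(1, 0, 0, 0),
                       c("w", "x", "y", "sloppy"))
    q <- quantify_isoforms(counts)
    expect_lt(abs(sum(q$fractions) - 100), 0.2 + 1e-9)
    # pre-rounding, defined + sloppy is exactly 100
    expect_equal(sum(q$counts[c("w", "x", "y")]) / q$total_split_reads * 100 +
                   q$counts[["sloppy"]] / q$total_split_reads * 100, 100)
  }
})

test_that("simulated spliced reads round-trip through SAM and the classifier", {
  cfg <- sim_config(seed = 31)
  sim <- simulate_spliced_reads(cfg)
  # TSV route
  sr <- extract_spliced_reads(sim, trex_window)
  q <- quantify_isoforms(classify_reads(sr, trex17_isoform_defs()),
                         trex17_isoform_defs())
  expect_equal(unname(q$counts), unname(cfg$isoform_composition))
  # SAM/BAM route gives identical junctions
  sam <- tempfile(fileext = ".sam")
  write_spliced_sam(sim, sam)
  back <- read_spliced_bam(sam)
  sr2 <- extract_spliced_reads(back, trex_window)
  expect_equal(nrow(sr2$junctions), nrow(sr$junctions))
  q2 <- quantify_isoforms(classify_reads(sr2, trex17_isoform_defs()),
                          trex17_isoform_defs())
  expect_equal(q2$counts, q$counts)
})

test_that("isoform models export as parseable BED12", {
  path <- tempfile(fileext = ".bed")
  write_isoform_bed(trex17_isoform_defs(), trex_window, path)
  lines <- readLines(path)
  expect_length(lines, 2L)
  f <- strsplit(lines[1], "\t")[[1]]
  expect_equal(f[4], "Ex1+2")
  expect_equal(as.integer(f[10]), 2L)
  sizes <- as.integer(strsplit(f[11], ",")[[1]])
  starts <- as.integer(strsplit(f[12], ",")[[1]])
  # block arithmetic is consistent with the record span
  expect_equal(as.integer(f[2]) + starts[2] + sizes[2], as.integer(f[3]))
})
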