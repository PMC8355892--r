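test_that("direction calling uses strict thresholds on both sides", {
  p <- scna_params()
  expect_equal(call_direction(0.50, p), "AMP")
  expect_equal(call_direction(0.32, p), "NEUTRAL")
  expect_equal(call_direction(-0.43, p), "DEL")
  expect_equal(call_direction(-0.42, p), "NEUTRAL")
  expect_equal(call_direction(c(0.321, -0.421, 0), p),
               c("AMP", "DEL", "NEUTRAL"))
})

test_that("events partition into indel / SCNA / aneuploidy", {
  b <- toy_build()
  # 5 kb amplified segment -> indel
  expect_equal(classify_event(genomic_interval("chrA", 100000, 105000), b), "INDEL")
  # exactly 10 kb is not an indel
  expect_equal(classify_event(genomic_interval("chrA", 100000, 110000), b), "SCNA")
  # 80% of chrA p (1 Mb, non-acrocentric) -> aneuploidy
  expect_equal(classify_event(genomic_interval("chrA", 0, 800000), b), "ANEUPLOIDY")
  # 100% of the acrocentric chrC p arm (150 kb, > 10 kb, < 75% of q) -> SCNA
  expect_equal(classify_event(genomic_interval("chrC", 0, 150000), b), "SCNA")
})

test_that("decision boundaries sit exactly at the configured constants", {
  b <- make_toy_genome(n_chroms = 1, chrom_length = 2.2e8, p_frac = 0.45,
                       gap_frac = 0.05)
  p <- scna_params()
  # log2 grid: largest value NOT amplified is 0.32; smallest NOT deleted -0.42
  grid <- (0:1000) / 1000
  dir_amp <- call_direction(grid, p)
  expect_equal(max(grid[dir_amp == "NEUTRAL"]), 0.32)
  dir_del <- call_direction(-grid, p)
  expect_equal(min(-grid[dir_del == "NEUTRAL"]), -0.42)
  # length grid at 100-bp steps: smallest non-indel length is 10,000 bp
  arm <- b$arms[b$arms$arm == "q", ]
  lens <- seq(100, 50000, by = 100)
  cls <- vapply(lens, function(L) {
    classify_event(genomic_interval("chr1", arm$start + 1e6,
                                    arm$start + 1e6 + L), b)
  }, character(1))
  expect_equal(min(lens[cls != "INDEL"]), 10000)
  # arm-fraction grid at 0.1% steps: largest SCNA coverage is exactly 75%
  armlen <- arm$end - arm$start
  pcts <- seq(50, 100, by = 0.1)
  cls <- vapply(pcts, function(pc) {
    classify_event(genomic_interval("chr1", arm$start,
                                    arm$start + round(pc / 100 * armlen)), b)
  }, character(1))
  expect_equal(max(pcts[cls == "SCNA"]), 75)
})

test_that("classification matches the raster oracle on random events", {
  b <- toy_build()
  raster <- build_arm_raster(b)
  set.seed(42)
  n <- 400
  ci <- sample(nrow(b$chromosomes), n, replace = TRUE)
  chrom <- b$chromosomes$chrom[ci]
  L <- b$chromosomes$length[ci]
  start <- floor(runif(n, 0, L - 1))
  end <- pmin(L, start + pmax(1, floor(rlnorm(n, log(5e4), 2))))
  for (i in seq_len(n)) {
    expect_equal(
      classify_event(genomic_interval(chrom[i], start[i], end[i]), b),
      oracle_classify(raster, b, chrom[i], start[i], end[i]),
      info = sprintf("%s:%d-%d", chrom[i], start[i], end[i]))
  }
})

test_that("growing an event never demotes its class", {
  b <- toy_build()
  # fixed start on chrA q, sweep the end through the arm
  start <- 1300000
  ranks <- c(INDEL = 1, SCNA = 2, ANEUPLOIDY = 3)
  ends <- start + sort(unique(c(seq(500, 1.1e6, length.out = 60), 9999, 10000)))
  cls <- vapply(ends, function(e) {
    classify_event(genomic_interval("chrA", start, e), b)
  }, character(1))
  expect_true(all(diff(ranks[cls]) >= 0))
})

test_that("classify_sample drops neutrals, keeps order, and counts planted events", {
  b <- toy_build()
  segs <- rbind(
    seg_df("S1", "chrA", c(0, 20000, 40000), c(10000, 30000, 50000),
           c(0, 0.1, -0.2)),
    seg_df("S1", "chrB", c(0, 100000, 300000), c(60000, 200000, 400000), 0.8),
    seg_df("S1", "chrC", c(300000, 400000), c(305000, 402000), -0.9))
  alts <- classify_sample(segs, b)
  # 3 AMP SCNAs on chrB, 2 DEL indels on chrC, neutrals gone
  expect_equal(sum(alts$direction == "AMP" & alts$class == "SCNA"), 3)
  expect_equal(sum(alts$direction == "DEL" & alts$class == "INDEL"), 2)
  expect_equal(nrow(alts), 5)
  # deterministic ordering: chromosome order then start
  expect_equal(alts$chrom, c(rep("chrB", 3), rep("chrC", 2)))
  expect_true(all(diff(alts$start[alts$chrom == "chrB"]) > 0))
  # mixed samples are rejected
  segs2 <- seg_df(c("S1", "S2"), "chrA", c(0, 0), c(1000, 1000), 1)
  expect_error(classify_sample(segs2, b), "multiple samples")
})

test_that("an all-neutral sample yields an empty alteration set", {
  b <- toy_build()
  segs <- seg_df("S1", "chrA", c(0, 50000), c(40000, 90000), c(0.1, -0.3))
  expect_equal(nrow(classify_sample(segs, b)), 0)
})

test_that("a centromere-spanning aneuploidy is counted once, not per arm", {
  b <- toy_build()
  # covers 90% of chrA p and 85% of chrA q
  segs <- seg_df("S1", "chrA", 100000, 1200000 + 0.85 * 1280000, 1.2)
  alts <- classify_sample(segs, b)
  expect_equal(nrow(alts), 1)
  expect_equal(alts$class, "ANEUPLOIDY")
})

test_that("the called-event partition identity holds on a random cohort", {
  b <- toy_build()
  set.seed(42)
  n <- 300
  ci <- sample(nrow(b$chromosomes), n, replace = TRUE)
  segs <- data.frame(
    sample = sample(sprintf("S%02d", 1:10), n, replace = TRUE),
    chrom = b$chromosomes$chrom[ci], stringsAsFactors = FALSE)
  L <- b$chromosomes$length[ci]
  segs$start <- floor(runif(n, 0, L - 10))
  segs$end <- pmin(L, segs$start + pmax(1, floor(rlnorm(n, log(2e4), 2))))
  segs$log2_ratio <- round(runif(n, -1.5, 1.5), 3)
  # avoid within-sample overlap complications: classification is per-segment
  alts <- classify_cohort(segs, b)
  called <- sum(call_direction(segs$log2_ratio) != "NEUTRAL")
  expect_equal(nrow(alts), called)
  expect_equal(sum(alts$class == "INDEL") + sum(alts$class == "SCNA") +
                 sum(alts$class == "ANEUPLOIDY"), nrow(alts))
  expect_true(all(alts$length == alts$end - alts$start))
})

test_that("segments outside the analysis set are dropped with a note", {
  chroms <- data.frame(chrom = c("chr1", "chrY"), length = c(1e6, 1e6))
  arms <- data.frame(chrom = c("chr1", "chr1", "chrY", "chrY"),
                     arm = c("p", "q", "p", "q"),
                     start = c(0, 5e5, 0, 5e5), end = c(4.5e5, 1e6, 4.5e5, 1e6),
                     acrocentric_short = FALSE)
  b <- genome_build(chroms, arms)
  segs <- seg_df("S1", c("chr1", "chrY"), c(0, 0), c(2e4, 2e4), 1)
  expect_message(alts <- classify_cohort(segs, b), "outside the analysis set")
  expect_equal(alts$chrom, "chr1")
})

test_that("opt-in merging joins adjacent same-direction segments", {
  b <- toy_build()
  segs <- seg_df("S1", "chrA", c(100000, 161000), c(160000, 220000), c(0.8, 1.0))
  off <- classify_cohort(segs, b)
  expect_equal(nrow(off), 2)
  on <- classify_cohort(segs, b, merge_gap = 5000)
  expect_equal(nrow(on), 1)
  expect_equal(on$start, 100000)
  expect_equal(on$end, 220000)
  # weighted mean ratio: (0.8*60000 + 1.0*59000) / 119000
  expect_equal(on$log2_ratio, (0.8 * 60000 + 1.0 * 59000) / 119000)
})
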