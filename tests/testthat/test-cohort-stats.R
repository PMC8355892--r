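test_that("sample_burden computes counts, percents and mean lengths", {
  b <- make_toy_genome(n_chroms = 2, chrom_length = 5e8)  # 1 Gb analysis set
  # empty sample
  empty <- sample_burden(alt_df(character(), character(), numeric(),
                                numeric(), character(), character()),
                         b, sample_id = "S0")
  expect_equal(empty$pct_genome_amp, 0)
  expect_equal(empty$n_amp + empty$n_del, 0)
  expect_true(is.na(empty$mean_scna_len_amp))
  # one 10-Mb AMP SCNA on the 1-Gb genome -> 1.0% amplified
  one <- sample_burden(alt_df("S1", "chr1", 1e6, 11e6, "AMP", "SCNA"), b)
  expect_equal(one$pct_genome_amp, 1.0)
  expect_equal(one$mean_scna_len_amp, 1e7)
  expect_equal(one$n_amp_scna, 1)
})

test_that("overlapping events contribute their union to percent genome altered", {
  b <- make_toy_genome(n_chroms = 2, chrom_length = 5e8)
  alts <- alt_df("S1", "chr1", c(1e6, 6e6), c(11e6, 16e6), "AMP", "SCNA")
  bu <- sample_burden(alts, b)
  # union is 15 Mb of 1 Gb, not the 20 Mb sum
  expect_equal(bu$pct_genome_amp, 1.5)
  # against the marking oracle
  expect_equal(bu$pct_genome_amp,
               100 * oracle_union_bp(alts$start, alts$end, 5e8) / 1e9)
})

test_that("percent genome altered stays within bounds on random cohorts", {
  b <- toy_build()
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    ci <- sample(nrow(b$chromosomes), n, replace = TRUE)
    L <- b$chromosomes$length[ci]
    start <- floor(runif(n, 0, L - 10))
    alts <- alt_df("S1", b$chromosomes$chrom[ci], start,
                   pmin(L, start + sample(1e3:1e6, n, replace = TRUE)),
                   sample(c("AMP", "DEL"), n, replace = TRUE), "SCNA")
    bu <- sample_burden(alts, b)
    expect_lte(bu$pct_genome_amp, 100)
    expect_lte(bu$pct_genome_del, 100)
    expect_gte(bu$pct_genome_amp, 0)
  }
})

test_that("cohort tables aggregate per-sample values and pool event lengths", {
  b <- make_toy_genome(n_chroms = 2, chrom_length = 5e8)
  alts <- rbind(
    alt_df("S1", "chr1", c(1e6, 20e6), c(2e6, 24e6), "AMP", "SCNA"),
    alt_df("S2", "chr1", c(1e6, 20e6, 40e6, 60e6), c(3e6, 22e6, 41e6, 66e6),
           "AMP", "SCNA"))
  ann <- data.frame(sample = c("S1", "S2"), tumor_type = "TT")
  burdens <- cohort_burden(alts, b, ann)
  tab <- cohort_tables(burdens, alts)
  # two samples with 2 and 4 AMP SCNAs -> mean 3
  r <- tab[tab$tumor_type == "TT" & tab$metric == "n_scna" & tab$direction == "AMP", ]
  expect_equal(r$mean, 3)
  expect_equal(r$n, 2)
  # single-sample type: mean equals the sample value
  bu1 <- burdens[burdens$sample == "S1", , drop = FALSE]
  t1 <- cohort_tables(bu1)
  expect_equal(t1$mean[t1$metric == "n_scna" & t1$direction == "AMP" &
                         t1$tumor_type == "TT"], 2)
  # pooled event-level mean/sd equals a flat recomputation over all events
  ev <- tab[tab$tumor_type == "ALL" & tab$metric == "scna_len_event" &
              tab$direction == "AMP", ]
  expect_equal(ev$mean, mean(alts$length))
  expect_equal(ev$sd, sd(alts$length))
  expect_equal(ev$n, nrow(alts))
})

test_that("class mix recovers planted proportions and reports empty types as missing", {
  alts <- rbind(alt_df("S1", "chr1", (0:9) * 1e6, (0:9) * 1e6 + 2e4, "AMP",
                       rep(c("SCNA", "INDEL", "ANEUPLOIDY"), c(5, 3, 2))))
  ann <- data.frame(sample = c("S1", "S2"), tumor_type = c("TA", "TB"))
  cm <- class_mix(alts, ann)
  expect_equal(cm$pct_scna[cm$tumor_type == "TA"], 50)
  expect_equal(cm$pct_indel[cm$tumor_type == "TA"], 30)
  expect_equal(cm$pct_aneuploidy[cm$tumor_type == "TA"], 20)
  expect_equal(sum(cm[cm$tumor_type == "TA", c("pct_indel", "pct_scna",
                                               "pct_aneuploidy")]), 100)
  # TB has no events: missing, not zero
  expect_true(is.na(cm$pct_scna[cm$tumor_type == "TB"]))
  # a type with only SCNAs
  cm2 <- class_mix(alt_df("S2", "chr1", 0, 2e4, "DEL", "SCNA"),
                   data.frame(sample = "S2", tumor_type = "TB"))
  expect_equal(cm2$pct_scna, 100)
  expect_equal(cm2$pct_indel, 0)
})

test_that("chromosome distributions normalize by length in both modes", {
  b <- genome_build(
    data.frame(chrom = c("chr1", "chr2"), length = c(1e8, 5e7)),
    arms = data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
                      arm = c("p", "q", "p", "q"),
                      start = c(0, 5e7, 0, 2.5e7), end = c(4.5e7, 1e8, 2.2e7, 5e7),
                      acrocentric_short = FALSE))
  # equal SCNA counts on a 100-Mb and a 50-Mb chromosome
  alts <- alt_df("S1", c("chr1", "chr1", "chr2", "chr2"),
                 c(0, 2e6, 0, 2e6), c(1e6, 3e6, 1e6, 3e6), "AMP", "SCNA")
  d <- chrom_distribution(alts, b, mode = "divide")
  expect_equal(d$raw_prop, c(0.5, 0.5))
  expect_equal(sum(d$raw_prop), 1)
  expect_equal(d$value, c(0.005, 0.010))
  lit <- chrom_distribution(alts, b, mode = "literal")
  expect_equal(lit$value, c(50, 25))
  # all SCNAs on one chromosome
  d1 <- chrom_distribution(alts[alts$chrom == "chr1", ], b)
  expect_equal(d1$raw_prop, c(1, 0))
  # no SCNAs at all -> missing values
  d0 <- chrom_distribution(alts[0, ], b)
  expect_true(all(is.na(d0$value)))
})

test_that("raw chromosome proportions sum to one whenever SCNAs exist", {
  b <- toy_build()
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(1:40, 1)
    ci <- sample(nrow(b$chromosomes), n, replace = TRUE)
    L <- b$chromosomes$length[ci]
    start <- floor(runif(n, 0, L - 2e4))
    alts <- alt_df("S1", b$chromosomes$chrom[ci], start, start + 15000,
                   "AMP", "SCNA")
    d <- chrom_distribution(alts, b)
    expect_equal(sum(d$raw_prop), 1)
  }
})

test_that("the exact Wilcoxon path reproduces small-sample enumeration", {
  # {1,2} vs {3,4}: 6 equally likely rank assignments, most extreme both ways
  expect_equal(wilcoxon_two_sided(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(wilcoxon_two_sided(c(3, 4), c(1, 2)), 1 / 3)
  # identical tied sets -> approximation path, symmetric null
  expect_equal(wilcoxon_two_sided(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(wilcoxon_two_sided(numeric(0), 1:3), "non-empty")
  # agrees with the stats reference on a tied example
  x <- c(1, 2, 2, 5, 7); y <- c(2, 3, 3, 6, 9)
  expect_equal(wilcoxon_two_sided(x, y),
               suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                   correct = TRUE)$p.value))
})

test_that("Spearman correlation handles monotone, reversed and tied inputs", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_cor(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)
  # tie case against hand-assigned mid-ranks
  xt <- c(1, 2, 2, 3); yt <- c(10, 30, 20, 40)
  hand <- stats::cor(c(1, 2.5, 2.5, 4), c(1, 3, 2, 4))
  expect_equal(spearman_cor(xt, yt)$rho, hand)
  expect_warning(res <- spearman_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(res$rho))
})

test_that("significance stars follow the figure-caption cutoffs", {
  expect_equal(p_stars(0.20), "ns")
  expect_equal(p_stars(0.0005), "***")
  expect_equal(p_stars(0.00009), "****")
  expect_equal(p_stars(c(0.04, 0.009, 0.05, 0.01)), c("*", "**", "ns", "*"))
  expect_equal(p_stars(1), "ns")
  expect_equal(p_stars(0), "****")
})

test_that("group comparisons report a row per type and metric with stars", {
  set.seed(42)
  b <- make_toy_genome(n_chroms = 2, chrom_length = 5e8)
  mk <- function(s, namp, ndel, bump) {
    starts <- seq(0, by = 4e6, length.out = namp + ndel)
    lens <- rep(c(1e6, 2e6), c(namp, ndel)) + bump
    alt_df(s, "chr1", starts, starts + lens,
           rep(c("AMP", "DEL"), c(namp, ndel)), "SCNA")
  }
  alts <- do.call(rbind, lapply(1:12, function(i) {
    mk(sprintf("S%02d", i), 8 + (i %% 3), 2, i * 1e4)
  }))
  ann <- data.frame(sample = sprintf("S%02d", 1:12), tumor_type = "TT")
  burdens <- cohort_burden(alts, b, ann)
  comp <- compare_groups(burdens)
  expect_setequal(unique(comp$tumor_type), c("TT", "ALL"))
  expect_setequal(unique(comp$metric), c("n_events", "pct_genome", "mean_scna_len"))
  expect_true(all(comp$stars %in% c("ns", "*", "**", "***", "****")))
  # many more amplifications than deletions in every sample -> significant
  expect_lt(comp$p_value[comp$tumor_type == "TT" & comp$metric == "n_events"],
            0.05)
})

test_that("scna_length_stats pools event lengths by group", {
  alts <- rbind(alt_df("S1", "chrA", c(0, 2e6), c(1e6, 3.5e6), "AMP", "SCNA"),
                alt_df("S1", "chrA", 5e6, 5.005e6, "AMP", "INDEL"))
  st <- scna_length_stats(alts)
  expect_equal(st$n, 2)  # indel excluded
  expect_equal(st$mean_bp, mean(c(1e6, 1.5e6)))
})
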