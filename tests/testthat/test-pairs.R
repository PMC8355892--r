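mk_calls <- function(sample, gene, direction) {
  if (length(gene) == 0) {
    return(data.frame(sample = character(), gene = character(),
                      direction = character(), overlap_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  data.frame(sample = sample, gene = gene, direction = direction,
             overlap_fraction = 1, stringsAsFactors = FALSE)
}

test_that("pair_events enumerates co-altered pairs of one sample", {
  # two amplified genes -> one AMP-AMP pair
  ev <- pair_events(mk_calls("S1", c("B", "A"), "AMP"))
  expect_equal(ev$gene_a, "A")
  expect_equal(ev$gene_b, "B")
  expect_equal(ev$event_type, "AMP-AMP")
  # AMP on A, DEL on B -> AMP-DEL with A recorded as amplified
  ev <- pair_events(mk_calls("S1", c("A", "B"), c("AMP", "DEL")))
  expect_equal(ev$event_type, "AMP-DEL")
  expect_equal(ev$amp_gene, "A")
  # three amplified genes -> all 3 unordered pairs
  ev <- pair_events(mk_calls("S1", c("A", "B", "C"), "AMP"))
  expect_equal(nrow(ev), 3)
  expect_equal(ev[c("gene_a", "gene_b", "event_type")],
               oracle_pair_events(mk_calls("S1", c("A", "B", "C"), "AMP")),
               ignore_attr = TRUE)
  # no self-pairs when a gene carries both calls
  ev <- pair_events(mk_calls("S1", c("A", "A", "B"), c("AMP", "DEL", "AMP")))
  expect_false(any(ev$gene_a == ev$gene_b))
  expect_true(all(c("AMP-AMP", "AMP-DEL") %in% ev$event_type))
})

test_that("pair_events matches the double-loop oracle on random call sets", {
  set.seed(42)
  genes <- LETTERS[1:6]
  for (rep in 1:30) {
    n <- sample(0:8, 1)
    calls <- unique(mk_calls("S1", sample(genes, n, replace = TRUE),
                             sample(c("AMP", "DEL"), n, replace = TRUE)))
    got <- pair_events(calls)[c("gene_a", "gene_b", "event_type")]
    want <- oracle_pair_events(calls)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("pair frequencies count samples, not events", {
  ann <- data.frame(sample = sprintf("S%02d", 1:10), tumor_type = "TA")
  calls <- rbind(mk_calls("S01", c("A", "B"), "AMP"),
                 mk_calls("S02", c("A", "B"), "AMP"),
                 mk_calls("S03", c("A"), "AMP"))
  pf <- pair_frequency(calls, ann)
  expect_equal(nrow(pf), 1)
  expect_equal(pf$n, 2)
  expect_equal(pf$frequency, 0.2)
  # single tumor type: pan-cohort equals per-type
  pt <- pair_frequency(calls, ann, scope = "tumor_type")
  expect_equal(pt$frequency, pf$frequency)
  expect_equal(pt$n, pf$n)
})

test_that("pair results are invariant under input row order and gene label swap", {
  ann <- data.frame(sample = sprintf("S%02d", 1:5), tumor_type = "TA")
  calls <- rbind(mk_calls("S01", c("A", "B", "C"), "AMP"),
                 mk_calls("S02", c("C", "A"), "AMP"))
  pf1 <- pair_frequency(calls, ann)
  pf2 <- pair_frequency(calls[sample(nrow(calls)), ], ann)
  expect_equal(pf1, pf2)
})

test_that("co-occurrence frequency is bounded by the marginal call frequencies", {
  set.seed(42)
  ann <- data.frame(sample = sprintf("S%02d", 1:20), tumor_type = "TA")
  calls <- do.call(rbind, lapply(ann$sample, function(s) {
    g <- sample(LETTERS[1:5], sample(0:4, 1))
    if (length(g) == 0) return(NULL)
    mk_calls(s, g, sample(c("AMP", "DEL"), length(g), replace = TRUE))
  }))
  pf <- pair_frequency(calls, ann)
  marg <- function(g, d) {
    length(unique(calls$sample[calls$gene == g & calls$direction == d])) / 20
  }
  aa <- pf[pf$event_type == "AMP-AMP", ]
  for (i in seq_len(nrow(aa))) {
    expect_lte(aa$frequency[i],
               min(marg(aa$gene_a[i], "AMP"), marg(aa$gene_b[i], "AMP")))
  }
})

test_that("filtering keeps the inclusive threshold and can mask intra-chromosomal pairs", {
  pairs <- data.frame(
    scope = "ALL", gene_a = c("A", "C", "E"), gene_b = c("B", "D", "F"),
    event_type = "AMP-AMP", n = c(5, 4, 1), frequency = c(0.05, 0.04, 0.01),
    same_chromosome = c(FALSE, TRUE, FALSE), stringsAsFactors = FALSE)
  f <- filter_pairs(pairs, min_frequency = 0.05)
  expect_equal(f$gene_a, "A")  # exactly at threshold kept
  f2 <- filter_pairs(pairs, min_frequency = 0.04, inter_chromosomal_only = TRUE)
  expect_equal(f2$gene_a, "A")  # C-D dropped as intra-chromosomal
  expect_equal(nrow(filter_pairs(pairs[0, ], 0.05)), 0)
  # AMP-DEL rows masked by the default event-type filter
  pairs$event_type <- c("AMP-AMP", "AMP-DEL", "DEL-DEL")
  f3 <- filter_pairs(pairs, min_frequency = 0)
  expect_setequal(f3$event_type, c("AMP-AMP", "DEL-DEL"))
})

test_that("chromosome and arm flags derive from gene coordinates", {
  b <- toy_build()
  genes <- data.frame(symbol = c("A", "B", "C"),
                      chrom = c("chrA", "chrA", "chrB"),
                      start = c(100000, 1300000, 100000),
                      end = c(200000, 1400000, 200000),
                      stringsAsFactors = FALSE)
  ann <- data.frame(sample = "S1", tumor_type = "TA")
  calls <- mk_calls("S1", c("A", "B", "C"), "AMP")
  pf <- pair_frequency(calls, ann, genes = genes, build = b)
  ab <- pf[pf$gene_a == "A" & pf$gene_b == "B", ]
  expect_true(ab$same_chromosome)
  expect_false(ab$same_arm)  # A on chrA p, B on chrA q
  ac <- pf[pf$gene_a == "A" & pf$gene_b == "C", ]
  expect_false(ac$same_chromosome)
})

test_that("participation counts gene appearances in the ranked top k", {
  pairs <- data.frame(
    scope = "ALL",
    gene_a = c("HUB", "HUB", "HUB", "X"), gene_b = c("A", "B", "C", "Y"),
    event_type = "AMP-AMP", n = c(9, 8, 7, 6),
    frequency = c(0.9, 0.8, 0.7, 0.6), stringsAsFactors = FALSE)
  part <- participation(pairs, k = 3)
  expect_equal(part$n_pairs[part$gene == "HUB"], 3)  # in every top pair
  expect_equal(part$n_pairs[part$gene == "X"], 0)    # below the cut
  expect_equal(unique(part$k), 3)
  # sum of counts = 2k for distinct-gene pairs
  expect_equal(sum(part$n_pairs), 2 * 3)
  # fewer pairs than k: all used, actual k recorded
  p2 <- participation(pairs[1:2, ], k = 100)
  expect_equal(unique(p2$k), 2)
  expect_error(participation(transform(pairs, event_type = c("AMP-AMP", "DEL-DEL",
                                                             "AMP-AMP", "AMP-AMP"))),
               "single event type")
})

test_that("tie-breaking at the rank-k cut is lexicographic and stable", {
  pairs <- data.frame(
    scope = "ALL", gene_a = c("B", "A", "C"), gene_b = c("Z", "Z", "Z"),
    event_type = "DEL-DEL", n = 5, frequency = 0.5, stringsAsFactors = FALSE)
  part1 <- participation(pairs, k = 2)
  part2 <- participation(pairs[c(3, 1, 2), ], k = 2)
  expect_equal(part1, part2)
  # A-Z and B-Z make the cut, C-Z does not
  expect_equal(part1$n_pairs[part1$gene == "A"], 1)
  expect_equal(part1$n_pairs[part1$gene == "C"], 0)
})
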