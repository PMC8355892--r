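# In-code fixtures: a small three-chromosome genome (chrC acrocentric) and
# segment/alteration constructors. All coordinates zero-based half-open.

toy_build <- function() {
  chroms <- data.frame(chrom = c("chrA", "chrB", "chrC"),
                       length = c(2480000, 2000000, 1500000),
                       stringsAsFactors = FALSE)
  arms <- data.frame(
    chrom = c("chrA", "chrA", "chrB", "chrB", "chrC", "chrC"),
    arm = c("p", "q", "p", "q", "p", "q"),
    start = c(0, 1200000, 0, 1050000, 0, 200000),
    end = c(1000000, 2480000, 1000000, 2000000, 150000, 1500000),
    acrocentric_short = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  genome_build(chroms, arms)
}

seg_df <- function(sample, chrom, start, end, ratio) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             num_probes = NA_real_, log2_ratio = ratio,
             stringsAsFactors = FALSE)
}

alt_df <- function(sample, chrom, start, end, direction, class,
                   ratio = ifelse(direction == "AMP", 1, -1)) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             length = end - start, log2_ratio = ratio, direction = direction,
             class = class, stringsAsFactors = FALSE)
}

write_seg_text <- function(lines, path = tempfile(fileext = ".seg")) {
  writeLines(c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
               lines), path)
  path
}
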