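# Brute-force base-pair oracles, independent of the package's interval
# arithmetic: they enumerate or mark individual genome positions.

oracle_overlap_bp <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0)
  length(intersect(seq.int(s1, e1 - 1), seq.int(s2, e2 - 1)))
}

# per-chromosome integer raster: position i+1 holds the row index of the arm
# covering [i, i+1), 0 where no arm
build_arm_raster <- function(build) {
  rs <- lapply(seq_len(nrow(build$chromosomes)), function(ci) {
    cc <- build$chromosomes$chrom[ci]
    v <- integer(build$chromosomes$length[ci])
    rows <- which(build$arms$chrom == cc)
    for (r in rows) {
      v[(build$arms$start[r] + 1):build$arms$end[r]] <- r
    }
    v
  })
  names(rs) <- build$chromosomes$chrom
  rs
}

# fraction of each arm of the segment's chromosome covered, by counting marks
oracle_arm_fractions <- function(raster, build, chrom, start, end) {
  v <- raster[[chrom]][(start + 1):end]
  rows <- which(build$arms$chrom == chrom)
  vapply(rows, function(r) {
    sum(v == r) / (build$arms$end[r] - build$arms$start[r])
  }, numeric(1))
}

# event class by base-pair counting over eligible (non-acrocentric) arms
oracle_classify <- function(raster, build, chrom, start, end,
                            params = scna_params()) {
  if (end - start < params$indel_max_bp) return("INDEL")
  rows <- which(build$arms$chrom == chrom & !build$arms$acrocentric_short)
  v <- raster[[chrom]][(start + 1):end]
  for (r in rows) {
    if (sum(v == r) / (build$arms$end[r] - build$arms$start[r]) >
        params$arm_frac) {
      return("ANEUPLOIDY")
    }
  }
  "SCNA"
}

# union length by marking positions on one chromosome
oracle_union_bp <- function(starts, ends, chrom_len) {
  v <- logical(chrom_len)
  for (i in seq_along(starts)) v[(starts[i] + 1):ends[i]] <- TRUE
  sum(v)
}

# base pairs of [g_start, g_end) covered by any of the events
oracle_covered_bp <- function(g_start, g_end, ev_starts, ev_ends) {
  pos <- logical(g_end - g_start)
  for (i in seq_along(ev_starts)) {
    lo <- max(ev_starts[i], g_start)
    hi <- min(ev_ends[i], g_end)
    if (lo < hi) pos[(lo - g_start + 1):(hi - g_start)] <- TRUE
  }
  sum(pos)
}

# all co-alteration pair events of one sample by explicit double loop
oracle_pair_events <- function(calls) {
  g <- unique(calls$gene)
  out <- list()
  for (i in seq_along(g)) {
    for (j in seq_along(g)) {
      if (i >= j) next
      a <- sort(c(g[i], g[j]))[1]
      b <- sort(c(g[i], g[j]))[2]
      da <- calls$direction[calls$gene == a]
      db <- calls$direction[calls$gene == b]
      if ("AMP" %in% da && "AMP" %in% db) {
        out[[length(out) + 1]] <- c(a, b, "AMP-AMP")
      }
      if ("DEL" %in% da && "DEL" %in% db) {
        out[[length(out) + 1]] <- c(a, b, "DEL-DEL")
      }
      if (("AMP" %in% da && "DEL" %in% db) || ("DEL" %in% da && "AMP" %in% db)) {
        out[[length(out) + 1]] <- c(a, b, "AMP-DEL")
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      event_type = character(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  df <- data.frame(gene_a = m[, 1], gene_b = m[, 2], event_type = m[, 3],
                   stringsAsFactors = FALSE)
  df[order(df$event_type, df$gene_a, df$gene_b), ]
}
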