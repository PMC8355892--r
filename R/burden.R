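# Per-sample and per-tumor-type burden summaries: event counts by direction
# and class, percent genome altered (interval-union arithmetic), SCNA length
# statistics, class mix, and per-chromosome SCNA distributions.

.DIRS <- c("AMP", "DEL")
.CLASSES <- c("INDEL", "SCNA", "ANEUPLOIDY")

#' Burden summary for one sample
#'
#' Tallies event counts per direction and class, the percentage of the
#' analysis-set genome covered by the union of amplified (resp. deleted)
#' events, and the mean SCNA-class event length per direction (`NA` when the
#' sample has no SCNA of that direction).
#'
#' @param alts Alterations of one sample (possibly zero rows).
#' @param build `genome_build`; the percent denominators are the summed
#'   lengths of its analysis-set chromosomes.
#' @param sample_id Sample label (required when `alts` is empty).
#' @param tumor_type Cohort label carried through to the output.
#' @return One-row data frame.
#' @export
sample_burden <- function(alts, build, sample_id = NULL,
                          tumor_type = NA_character_) {
  if (nrow(alts) > 0) {
    sid <- unique(alts$sample)
    if (length(sid) > 1) stop("sample_burden() received multiple samples")
    if (is.null(sample_id)) sample_id <- sid
  } else if (is.null(sample_id)) {
    stop("sample_id required for an empty alteration set")
  }
  genome_len <- sum(build$chromosomes$length[
    build$chromosomes$chrom %in% build$analysis_set])
  counts <- table(factor(alts$direction, .DIRS), factor(alts$class, .CLASSES))
  pct <- vapply(.DIRS, function(d) {
    ev <- alts[alts$direction == d, , drop = FALSE]
    covered <- sum(vapply(split(ev, ev$chrom),
                          function(p) bp_union(p$start, p$end), numeric(1)))
    100 * covered / genome_len
  }, numeric(1))
  mean_len <- vapply(.DIRS, function(d) {
    len <- alts$length[alts$direction == d & alts$class == "SCNA"]
    if (length(len) == 0) NA_real_ else mean(len)
  }, numeric(1))
  data.frame(
    sample = sample_id, tumor_type = tumor_type,
    n_amp_indel = counts["AMP", "INDEL"], n_amp_scna = counts["AMP", "SCNA"],
    n_amp_aneuploidy = counts["AMP", "ANEUPLOIDY"],
    n_del_indel = counts["DEL", "INDEL"], n_del_scna = counts["DEL", "SCNA"],
    n_del_aneuploidy = counts["DEL", "ANEUPLOIDY"],
    n_amp = sum(counts["AMP", ]), n_del = sum(counts["DEL", ]),
    pct_genome_amp = pct[["AMP"]], pct_genome_del = pct[["DEL"]],
    mean_scna_len_amp = mean_len[["AMP"]], mean_scna_len_del = mean_len[["DEL"]],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Burden table for a whole cohort
#'
#' One [sample_burden()] row per sample. Samples listed in the annotations but
#' absent from the alteration table get an all-zero row; samples with events
#' but no annotation are assigned tumor type `"UNKNOWN"` with a warning.
#'
#' @param alts Cohort alteration data frame from [classify_cohort()].
#' @param build `genome_build`.
#' @param annotations Data frame from [read_sample_annotations()] (optional).
#' @param samples Optional explicit sample universe.
#' @return Data frame with one row per sample.
#' @export
cohort_burden <- function(alts, build, annotations = NULL, samples = NULL) {
  if (is.null(samples)) {
    samples <- sort(unique(c(alts$sample, annotations$sample)))
  }
  types <- lookup_type(samples, annotations)
  pieces <- split(alts, factor(alts$sample, levels = samples))
  out <- mapply(function(a, s, tt) sample_burden(a, build, s, tt),
                pieces, samples, types, SIMPLIFY = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.summ <- function(v) {
  v <- v[!is.na(v)]
  c(n = length(v), mean = if (length(v)) mean(v) else NA_real_,
    sd = if (length(v) > 1) stats::sd(v) else NA_real_)
}

#' Per-tumor-type summary tables
#'
#' For every tumor type (plus a pooled `"ALL"` row) and every burden metric -
#' total event count, SCNA-class count, percent genome altered, and mean SCNA
#' length - the sample count, mean and standard deviation, split by
#' amplification vs deletion. When the cohort alteration table is supplied,
#' an additional event-level metric `scna_len_event` is computed directly over
#' individual SCNA events (a flat recomputation, not a mean of per-sample
#' means).
#'
#' @param burdens Data frame from [cohort_burden()].
#' @param alts Optional alteration data frame for event-level length rows.
#' @return Long-format data frame: `tumor_type`, `metric`, `direction`, `n`,
#'   `mean`, `sd`.
#' @export
cohort_tables <- function(burdens, alts = NULL) {
  metric_cols <- list(
    n_events = c(AMP = "n_amp", DEL = "n_del"),
    n_scna = c(AMP = "n_amp_scna", DEL = "n_del_scna"),
    pct_genome = c(AMP = "pct_genome_amp", DEL = "pct_genome_del"),
    mean_scna_len = c(AMP = "mean_scna_len_amp", DEL = "mean_scna_len_del")
  )
  groups <- c(sort(unique(burdens$tumor_type)), "ALL")
  rows <- list()
  for (g in groups) {
    b <- if (g == "ALL") burdens else burdens[burdens$tumor_type == g, , drop = FALSE]
    for (m in names(metric_cols)) {
      for (d in .DIRS) {
        s <- .summ(b[[metric_cols[[m]][[d]]]])
        rows[[length(rows) + 1L]] <- data.frame(
          tumor_type = g, metric = m, direction = d,
          n = unname(s["n"]), mean = unname(s["mean"]), sd = unname(s["sd"]),
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(alts)) {
      a <- alts[alts$class == "SCNA", , drop = FALSE]
      if (g != "ALL") {
        keep <- a$sample %in% burdens$sample[burdens$tumor_type == g]
        a <- a[keep, , drop = FALSE]
      }
      for (d in .DIRS) {
        s <- .summ(a$length[a$direction == d])
        rows[[length(rows) + 1L]] <- data.frame(
          tumor_type = g, metric = "scna_len_event", direction = d,
          n = unname(s["n"]), mean = unname(s["mean"]), sd = unname(s["sd"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Class mix per tumor type
#'
#' Percentage of indels, SCNAs and aneuploidies among all called events of
#' each tumor type. A type with no called events reports `NA` (missing), not
#' zero.
#'
#' @param alts Cohort alteration data frame.
#' @param annotations Sample annotations (defines the set of tumor types).
#' @return Data frame: `tumor_type`, `n_events`, `pct_indel`, `pct_scna`,
#'   `pct_aneuploidy`.
#' @export
class_mix <- function(alts, annotations = NULL) {
  tt <- lookup_type(alts$sample, annotations)
  types <- sort(unique(c(tt, annotations$tumor_type)))
  rows <- lapply(types, function(g) {
    cls <- alts$class[tt == g]
    n <- length(cls)
    pct <- if (n == 0) rep(NA_real_, 3) else
      100 * as.vector(table(factor(cls, .CLASSES))) / n
    data.frame(tumor_type = g, n_events = n,
               pct_indel = pct[1], pct_scna = pct[2], pct_aneuploidy = pct[3],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Per-chromosome SCNA distribution
#'
#' Only SCNA-class events are counted. The raw proportion for chromosome c is
#' `n_c / N` over the analysis set. Two normalizations by chromosome length
#' `L_c` (in Mb) are offered: `"divide"` (default) reports `(n_c / N) / L_c`,
#' a per-Mb density; `"literal"` reports `(n_c / N) * L_c`. With no SCNAs all
#' values are missing.
#'
#' @param alts Alterations of one cohort slice (e.g. one tumor type).
#' @param build `genome_build`.
#' @param mode `"divide"` or `"literal"`.
#' @return Data frame: `chrom`, `n_scna`, `raw_prop`, `value`.
#' @export
chrom_distribution <- function(alts, build, mode = c("divide", "literal")) {
  mode <- match.arg(mode)
  chroms <- build$analysis_set
  scna <- alts[alts$class == "SCNA", , drop = FALSE]
  n_c <- as.vector(table(factor(scna$chrom, levels = chroms)))
  N <- sum(n_c)
  L_mb <- build$chromosomes$length[match(chroms, build$chromosomes$chrom)] / 1e6
  if (N == 0) {
    raw <- rep(NA_real_, length(chroms))
    val <- raw
  } else {
    raw <- n_c / N
    val <- if (mode == "divide") raw / L_mb else raw * L_mb
  }
  data.frame(chrom = chroms, n_scna = n_c, raw_prop = raw, value = val,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @describeIn chrom_distribution One [chrom_distribution()] per tumor type,
#'   stacked with a `tumor_type` column.
#' @param annotations Sample annotations.
#' @export
chrom_distribution_by_type <- function(alts, build, annotations,
                                       mode = c("divide", "literal")) {
  mode <- match.arg(mode)
  tt <- lookup_type(alts$sample, annotations)
  types <- sort(unique(c(tt, annotations$tumor_type)))
  rows <- lapply(types, function(g) {
    d <- chrom_distribution(alts[tt == g, , drop = FALSE], build, mode)
    cbind(tumor_type = g, d, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' SCNA length statistics
#'
#' Event-level mean and standard deviation of SCNA-class event lengths, pooled
#' or grouped by tumor type or chromosome. In chromosome mode, `normalize =
#' TRUE` additionally reports the mean divided by the chromosome length in Mb.
#'
#' @param alts Cohort alteration data frame.
#' @param by `"cohort"`, `"tumor_type"` or `"chromosome"`.
#' @param annotations Needed for `by = "tumor_type"`.
#' @param build Needed for `by = "chromosome"`.
#' @param normalize Divide chromosome-mode means by chromosome length (Mb).
#' @return Data frame with `group`, `n`, `mean_bp`, `sd_bp` (and
#'   `mean_per_mb` when normalizing).
#' @export
scna_length_stats <- function(alts, by = c("cohort", "tumor_type", "chromosome"),
                              annotations = NULL, build = NULL,
                              normalize = FALSE) {
  by <- match.arg(by)
  scna <- alts[alts$class == "SCNA", , drop = FALSE]
  grp <- switch(by,
    cohort = rep("ALL", nrow(scna)),
    tumor_type = lookup_type(scna$sample, annotations),
    chromosome = scna$chrom)
  levels <- switch(by,
    cohort = "ALL",
    tumor_type = sort(unique(c(grp, annotations$tumor_type))),
    chromosome = build$analysis_set)
  rows <- lapply(levels, function(g) {
    s <- .summ(scna$length[grp == g])
    data.frame(group = g, n = unname(s["n"]), mean_bp = unname(s["mean"]),
               sd_bp = unname(s["sd"]), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (by == "chromosome" && normalize) {
    L_mb <- build$chromosomes$length[match(res$group, build$chromosomes$chrom)] / 1e6
    res$mean_per_mb <- res$mean_bp / L_mb
  }
  rownames(res) <- NULL
  res
}
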