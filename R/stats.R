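# Group comparisons: two-sided Wilcoxon rank-sum tests, Spearman correlation,
# and the significance-star convention used in the burden figures.

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Unpaired two-sided rank-sum test. The exact null enumeration is used when
#' both groups have at most 25 observations and there are no ties; otherwise
#' the normal approximation with tie and continuity corrections.
#'
#' @param x,y Non-empty numeric vectors.
#' @param paired Use the signed-rank (paired) variant instead.
#' @return The two-sided p-value.
#' @export
wilcoxon_two_sided <- function(x, y, paired = FALSE) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 25 && length(y) <= 25 && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", paired = paired,
                       exact = exact, correct = TRUE)$p.value
  )
}

#' Spearman rank correlation
#'
#' The product-moment correlation of mid-ranks, with the p-value from the
#' t approximation. A constant input vector has no defined rank correlation
#' and reports missing values.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @return List with elements `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("spearman_cor() needs at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Significance stars for a p-value
#'
#' `*` iff p < 0.05, `**` iff p < 0.01, `***` iff p < 0.001, `****` iff
#' p < 0.0001, `ns` otherwise; boundary values take the weaker label.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Character vector of labels.
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    stopifnot(pi >= 0, pi <= 1)
    if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Amplification-vs-deletion comparisons per tumor type
#'
#' For every tumor type (and pooled `"ALL"`), compares the per-sample
#' amplification and deletion values of each burden metric (total event count,
#' percent genome altered, mean SCNA length) with a two-sided Wilcoxon test.
#' No multiple-testing correction is applied by default; Benjamini-Hochberg
#' is available via `adjust`.
#'
#' @param burdens Data frame from [cohort_burden()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame: `tumor_type`, `metric`, `p_value`, `stars`.
#' @export
compare_groups <- function(burdens, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  metrics <- list(n_events = c("n_amp", "n_del"),
                  pct_genome = c("pct_genome_amp", "pct_genome_del"),
                  mean_scna_len = c("mean_scna_len_amp", "mean_scna_len_del"))
  groups <- c(sort(unique(burdens$tumor_type)), "ALL")
  rows <- list()
  for (g in groups) {
    b <- if (g == "ALL") burdens else burdens[burdens$tumor_type == g, , drop = FALSE]
    for (m in names(metrics)) {
      x <- b[[metrics[[m]][1]]]; x <- x[!is.na(x)]
      y <- b[[metrics[[m]][2]]]; y <- y[!is.na(y)]
      p <- if (length(x) && length(y)) wilcoxon_two_sided(x, y) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        tumor_type = g, metric = m, p_value = p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (adjust == "BH") res$p_value <- stats::p.adjust(res$p_value, "BH")
  res$stars <- p_stars(res$p_value)
  rownames(res) <- NULL
  res
}

#' Correlation between amplification and deletion burden
#'
#' Two distinct Spearman correlations of per-sample amplification vs deletion
#' event counts, labeled by scope: `within_type` correlates across the samples
#' of each tumor type; `across_types` correlates the per-type mean counts
#' across tumor types.
#'
#' @param burdens Data frame from [cohort_burden()].
#' @return Data frame: `scope`, `tumor_type`, `n`, `rho`, `p_value`.
#' @export
amp_del_correlation <- function(burdens) {
  rows <- list()
  for (g in sort(unique(burdens$tumor_type))) {
    b <- burdens[burdens$tumor_type == g, , drop = FALSE]
    if (nrow(b) >= 3) {
      sc <- suppressWarnings(spearman_cor(b$n_amp, b$n_del))
      rows[[length(rows) + 1L]] <- data.frame(
        scope = "within_type", tumor_type = g, n = nrow(b),
        rho = sc$rho, p_value = sc$p_value, stringsAsFactors = FALSE)
    }
  }
  means <- stats::aggregate(cbind(n_amp, n_del) ~ tumor_type, burdens, mean)
  if (nrow(means) >= 3) {
    sc <- suppressWarnings(spearman_cor(means$n_amp, means$n_del))
    rows[[length(rows) + 1L]] <- data.frame(
      scope = "across_types", tumor_type = "ALL", n = nrow(means),
      rho = sc$rho, p_value = sc$p_value, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
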