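# Gene-pair co-alteration analysis: which census gene pairs are co-amplified
# (AMP-AMP), co-deleted (DEL-DEL) or discordantly altered (AMP-DEL) in the
# same tumor, at what cohort frequency, and which genes dominate the most
# frequent inter-chromosomal pairs.

.pair_types <- c("AMP-AMP", "DEL-DEL", "AMP-DEL")

#' Co-alteration pair events of one sample
#'
#' Every unordered pair of distinct genes called in the sample contributes
#' AMP-AMP when both are amplified, DEL-DEL when both deleted, and AMP-DEL
#' when the directions differ (the amplified member is recorded). A gene
#' carrying both calls participates in all matching event types. Self-pairs
#' are excluded.
#'
#' @param calls One sample's gene calls (deduplicated per gene/direction).
#' @return Data frame: `gene_a`, `gene_b` (`gene_a < gene_b`), `event_type`,
#'   `amp_gene` (`NA` except for AMP-DEL).
#' @export
pair_events <- function(calls) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      event_type = character(), amp_gene = character(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0) return(empty)
  if (length(unique(calls$sample)) > 1) {
    stop("pair_events() expects the calls of a single sample")
  }
  amp <- sort(unique(calls$gene[calls$direction == "AMP"]))
  del <- sort(unique(calls$gene[calls$direction == "DEL"]))
  rows <- list(empty)
  same_dir <- function(g, type) {
    if (length(g) < 2) return(NULL)
    cmb <- utils::combn(g, 2)
    data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ], event_type = type,
               amp_gene = NA_character_, stringsAsFactors = FALSE)
  }
  rows$aa <- same_dir(amp, "AMP-AMP")
  rows$dd <- same_dir(del, "DEL-DEL")
  if (length(amp) && length(del)) {
    gr <- expand.grid(a = amp, d = del, stringsAsFactors = FALSE)
    gr <- gr[gr$a != gr$d, , drop = FALSE]
    if (nrow(gr)) {
      rows$ad <- data.frame(gene_a = pmin(gr$a, gr$d),
                            gene_b = pmax(gr$a, gr$d),
                            event_type = "AMP-DEL", amp_gene = gr$a,
                            stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res <- unique(res)
  # a gene called in both directions yields the same AMP-DEL pair in both
  # orientations; keep one row per (pair, event_type), preferring the
  # orientation where gene_a is the amplified member
  pref <- ifelse(is.na(res$amp_gene) | res$amp_gene == res$gene_a, 0L, 1L)
  res <- res[order(res$event_type, res$gene_a, res$gene_b, pref), ,
             drop = FALSE]
  res <- res[!duplicated(res[c("gene_a", "gene_b", "event_type")]), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# arm label containing the larger part of each gene (NA when no arm overlaps)
.gene_arm <- function(genes, build) {
  vapply(seq_len(nrow(genes)), function(i) {
    arms <- build$arms[build$arms$chrom == genes$chrom[i], , drop = FALSE]
    if (nrow(arms) == 0) return(NA_character_)
    ov <- pmax(0, pmin(genes$end[i], arms$end) - pmax(genes$start[i], arms$start))
    if (max(ov) == 0) NA_character_ else arms$arm[which.max(ov)]
  }, character(1))
}

#' Cohort co-alteration pair frequencies
#'
#' Counts samples (not events: each sample contributes at most once per pair
#' and event type) and divides by the number of samples in scope. With
#' `scope = "tumor_type"` one frequency per type is reported instead of the
#' pan-cohort fraction. When the gene census (and a build with arms) is
#' given, `same_chromosome`/`same_arm` flags are attached.
#'
#' @param calls Cohort gene calls from [call_genes_cohort()].
#' @param annotations Sample annotations (the sample universe).
#' @param scope `"cohort"` (default) or `"tumor_type"`.
#' @param genes Optional gene census for chromosome/arm flags.
#' @param build Optional `genome_build` (needed for `same_arm`).
#' @return Data frame: `scope`, `gene_a`, `gene_b`, `event_type`, `n`,
#'   `frequency`, plus `same_chromosome`/`same_arm` when derivable; ordered by
#'   event type, descending frequency, then pair.
#' @export
pair_frequency <- function(calls, annotations, scope = c("cohort", "tumor_type"),
                           genes = NULL, build = NULL) {
  scope <- match.arg(scope)
  per_sample <- lapply(split(calls, calls$sample), pair_events)
  ev <- do.call(rbind, c(per_sample, list(pair_events(calls[0, ]))))
  samp <- rep(names(per_sample), vapply(per_sample, nrow, integer(1)))
  if (scope == "cohort") {
    grp <- rep("ALL", length(samp))
    denom <- c(ALL = nrow(annotations))
  } else {
    grp <- annotations$tumor_type[match(samp, annotations$sample)]
    denom <- table(annotations$tumor_type)
    ok <- !is.na(grp)
    ev <- ev[ok, , drop = FALSE]
    grp <- grp[ok]
  }
  key <- paste(grp, ev$gene_a, ev$gene_b, ev$event_type, sep = "\r")
  agg <- unique(data.frame(scope = grp, gene_a = ev$gene_a, gene_b = ev$gene_b,
                           event_type = ev$event_type, key = key,
                           stringsAsFactors = FALSE))
  n <- as.vector(table(factor(key, levels = agg$key)))
  res <- agg[, c("scope", "gene_a", "gene_b", "event_type")]
  res$n <- n
  res$frequency <- n / as.numeric(denom[res$scope])
  if (!is.null(genes)) {
    ca <- genes$chrom[match(res$gene_a, genes$symbol)]
    cb <- genes$chrom[match(res$gene_b, genes$symbol)]
    res$same_chromosome <- ca == cb
    if (!is.null(build) && nrow(build$arms) > 0) {
      arm <- .gene_arm(genes, build)
      aa <- arm[match(res$gene_a, genes$symbol)]
      ab <- arm[match(res$gene_b, genes$symbol)]
      res$same_arm <- res$same_chromosome & !is.na(aa) & !is.na(ab) & aa == ab
    }
  }
  res <- res[order(res$scope, match(res$event_type, .pair_types),
                   -res$frequency, res$gene_a, res$gene_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter pair frequencies
#'
#' Keeps pairs at or above a frequency threshold (inclusive), optionally
#' restricted to inter-chromosomal pairs and to a subset of event types
#' (default: co-amplifications and co-deletions only, as in the co-occurrence
#' matrix display; AMP-DEL pairs are computed upstream but masked here).
#'
#' @param pairs Data frame from [pair_frequency()].
#' @param min_frequency Inclusive threshold (default 0.05).
#' @param inter_chromosomal_only Drop same-chromosome pairs.
#' @param event_types Event types to keep.
#' @return Filtered data frame.
#' @export
filter_pairs <- function(pairs, min_frequency = 0.05,
                         inter_chromosomal_only = FALSE,
                         event_types = c("AMP-AMP", "DEL-DEL")) {
  stopifnot(min_frequency >= 0, min_frequency <= 1)
  keep <- pairs$frequency >= min_frequency & pairs$event_type %in% event_types
  if (inter_chromosomal_only) {
    if (is.null(pairs$same_chromosome)) {
      stop("pairs lack the same_chromosome flag; pass genes to pair_frequency()")
    }
    keep <- keep & !pairs$same_chromosome
  }
  res <- pairs[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gene participation in the top-k most frequent pairs
#'
#' Ranks the supplied pairs (one event type at a time) by descending
#' frequency, ties broken lexicographically by (`gene_a`, `gene_b`), takes the
#' top `k`, and counts how many of those pairs each gene participates in.
#' With fewer than `k` pairs available, all are used and the actual `k` is
#' recorded.
#'
#' @param pairs Data frame from [pair_frequency()] / [filter_pairs()],
#'   restricted to one event type.
#' @param k Size of the top list (default 100).
#' @return Data frame: `gene`, `k`, `n_pairs`, sorted by descending `n_pairs`
#'   then gene; genes appearing in the input but not the top `k` report 0.
#' @export
participation <- function(pairs, k = 100) {
  if (length(unique(pairs$event_type)) > 1) {
    stop("participation() expects pairs of a single event type")
  }
  pairs <- pairs[order(-pairs$frequency, pairs$gene_a, pairs$gene_b), ,
                 drop = FALSE]
  k_actual <- min(k, nrow(pairs))
  top <- pairs[seq_len(k_actual), , drop = FALSE]
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  cnt <- table(factor(c(top$gene_a, top$gene_b), levels = genes))
  res <- data.frame(gene = genes, k = k_actual, n_pairs = as.vector(cnt),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$n_pairs, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}
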