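# Gene-level alteration calling: a census gene is called amplified or deleted
# in a sample when at least half of its body (by default) is covered by that
# sample's SCNA-class events of the matching direction.

#' Call amplified/deleted genes for one sample
#'
#' For every gene and direction, the fraction of the gene body covered by the
#' union of that direction's events of the included classes is computed; a
#' call is emitted when the fraction reaches `gene_overlap_frac` (inclusive).
#' A gene may carry both an AMP and a DEL call in the same sample. With
#' `union = FALSE`, the fraction is instead the maximum overlap with any
#' single event.
#'
#' @param alts Alterations of one sample.
#' @param genes Gene census data frame (`symbol`, `chrom`, `start`, `end`).
#' @param params An `scna_params` object.
#' @param include_classes Event classes eligible to cover genes; default
#'   `"SCNA"` only (indels and aneuploidies excluded).
#' @param union Union-of-events overlap (default) vs best single event.
#' @return Data frame: `sample`, `gene`, `direction`, `overlap_fraction`.
#' @export
call_genes <- function(alts, genes, params = scna_params(),
                       include_classes = "SCNA", union = TRUE) {
  if (nrow(alts) > 0 && length(unique(alts$sample)) > 1) {
    stop("call_genes() received multiple samples; use call_genes_cohort()")
  }
  sid <- if (nrow(alts)) alts$sample[1] else NA_character_
  empty <- data.frame(sample = character(), gene = character(),
                      direction = character(), overlap_fraction = numeric(),
                      stringsAsFactors = FALSE)
  ev <- alts[alts$class %in% include_classes, , drop = FALSE]
  if (nrow(ev) == 0 || nrow(genes) == 0) return(empty)
  g <- events_granges(genes)
  glen <- genes$end - genes$start
  rows <- list()
  for (d in .DIRS) {
    e <- ev[ev$direction == d, , drop = FALSE]
    if (nrow(e) == 0) next
    er <- events_granges(e)
    if (union) er <- GenomicRanges::reduce(er)
    hits <- GenomicRanges::findOverlaps(g, er)
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits)
    ovw <- GenomicRanges::width(GenomicRanges::pintersect(
      g[qh], er[S4Vectors::subjectHits(hits)]))
    frac <- if (union) {
      tapply(ovw, factor(qh, levels = seq_len(nrow(genes))), sum)
    } else {
      tapply(ovw, factor(qh, levels = seq_len(nrow(genes))), max)
    }
    frac <- as.numeric(frac) / glen
    frac[is.na(frac)] <- 0
    called <- which(frac >= params$gene_overlap_frac)
    if (length(called)) {
      rows[[d]] <- data.frame(sample = sid, gene = genes$symbol[called],
                              direction = d,
                              overlap_fraction = frac[called],
                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  res <- do.call(rbind, rows)
  res <- res[order(res$gene, res$direction), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gene calls for a whole cohort
#'
#' @param alts Cohort alteration data frame.
#' @inheritParams call_genes
#' @return Data frame of gene calls across all samples.
#' @export
call_genes_cohort <- function(alts, genes, params = scna_params(),
                              include_classes = "SCNA", union = TRUE) {
  pieces <- split(alts, alts$sample)
  out <- lapply(pieces, call_genes, genes = genes, params = params,
                include_classes = include_classes, union = union)
  res <- do.call(rbind, out)
  if (is.null(res)) res <- call_genes(alts[0, ], genes[0, ], params)
  rownames(res) <- NULL
  res
}

#' Gene alteration frequencies
#'
#' Fraction of samples of each tumor type (and of the whole cohort, labeled
#' `"ALL"`) carrying a call for each gene and direction. All census genes are
#' reported, including never-called ones at frequency 0. Rows are ordered by
#' direction, then descending pan-cohort frequency, then symbol.
#'
#' @param calls Gene calls from [call_genes_cohort()].
#' @param annotations Sample annotations (defines the sample universe and
#'   tumor types).
#' @param genes Gene census data frame.
#' @return Data frame: `gene`, `direction`, `tumor_type`, `n_called`,
#'   `n_samples`, `frequency`.
#' @export
gene_frequency <- function(calls, annotations, genes) {
  types <- sort(unique(annotations$tumor_type))
  groups <- c("ALL", types)
  n_samples <- c(ALL = nrow(annotations),
                 table(factor(annotations$tumor_type, types)))
  tt <- annotations$tumor_type[match(calls$sample, annotations$sample)]
  rows <- list()
  for (d in .DIRS) {
    cd <- calls[calls$direction == d, , drop = FALSE]
    ttd <- tt[calls$direction == d]
    for (g in groups) {
      keep <- if (g == "ALL") rep(TRUE, nrow(cd)) else !is.na(ttd) & ttd == g
      cnt <- table(factor(cd$gene[keep], levels = genes$symbol))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = genes$symbol, direction = d, tumor_type = g,
        n_called = as.vector(cnt), n_samples = unname(n_samples[g]),
        frequency = as.vector(cnt) / unname(n_samples[g]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  pan <- res[res$tumor_type == "ALL", ]
  key <- paste(res$gene, res$direction)
  pan_freq <- pan$frequency[match(key, paste(pan$gene, pan$direction))]
  res <- res[order(res$direction, -pan_freq, res$gene, res$tumor_type), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Top-k most frequently altered genes
#'
#' Ranks genes of one direction by pan-cohort frequency (ties broken
#' alphabetically by symbol) and returns the top `k`.
#'
#' @param freq Data frame from [gene_frequency()].
#' @param k Number of genes (default 25).
#' @param direction `"AMP"` or `"DEL"`.
#' @return Data frame: `rank`, `gene`, `direction`, `frequency`.
#' @export
top_genes <- function(freq, k = 25, direction = c("AMP", "DEL")) {
  direction <- match.arg(direction)
  stopifnot(k >= 1)
  pan <- freq[freq$tumor_type == "ALL" & freq$direction == direction, ,
              drop = FALSE]
  pan <- pan[order(-pan$frequency, pan$gene), , drop = FALSE]
  if (k > nrow(pan)) {
    warning("requested top ", k, " but only ", nrow(pan), " genes available")
    k <- nrow(pan)
  }
  res <- data.frame(rank = seq_len(k), gene = pan$gene[seq_len(k)],
                    direction = direction,
                    frequency = pan$frequency[seq_len(k)],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
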