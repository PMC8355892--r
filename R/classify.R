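# Core event calling: direction from the log2 copy ratio, then a mutually
# exclusive class for every called event - indel, SCNA, or arm-level
# aneuploidy.

#' Classification parameters
#'
#' The five thresholds driving event calling. Defaults: segments with log2
#' ratio strictly above 0.32 are amplified and strictly below -0.42 deleted;
#' called events shorter than 10 kb are indels; events covering strictly more
#' than 75% of an eligible chromosome arm (acrocentric short arms excluded)
#' are aneuploidies; everything else is an SCNA. Genes are called altered at a
#' reciprocal overlap of at least 50% (inclusive).
#'
#' @param amp_log2 Amplification threshold on the log2 ratio (exclusive).
#' @param del_log2 Deletion threshold (exclusive, negative).
#' @param indel_max_bp Indel size bound in bp (exclusive upper bound).
#' @param arm_frac Arm-fraction bound for aneuploidy (exclusive lower bound).
#' @param gene_overlap_frac Gene-overlap bound for gene calls (inclusive).
#' @return An object of class `scna_params`.
#' @export
scna_params <- function(amp_log2 = 0.32, del_log2 = -0.42,
                        indel_max_bp = 10000, arm_frac = 0.75,
                        gene_overlap_frac = 0.5) {
  stopifnot(del_log2 < 0, amp_log2 > 0,
            arm_frac > 0, arm_frac <= 1,
            gene_overlap_frac > 0, gene_overlap_frac <= 1,
            indel_max_bp > 0)
  structure(list(amp_log2 = amp_log2, del_log2 = del_log2,
                 indel_max_bp = indel_max_bp, arm_frac = arm_frac,
                 gene_overlap_frac = gene_overlap_frac),
            class = "scna_params")
}

#' @export
print.scna_params <- function(x, ...) {
  cat("<scna_params>\n")
  cat(sprintf("  AMP:        log2 ratio > %g\n", x$amp_log2))
  cat(sprintf("  DEL:        log2 ratio < %g\n", x$del_log2))
  cat(sprintf("  INDEL:      length < %g bp\n", x$indel_max_bp))
  cat(sprintf("  ANEUPLOIDY: arm fraction > %g (acrocentric p arms excluded)\n",
              x$arm_frac))
  cat(sprintf("  gene call:  overlap >= %g of gene length\n", x$gene_overlap_frac))
  invisible(x)
}

#' Call alteration direction from the log2 ratio
#'
#' Strict thresholds: `AMP` iff ratio > `amp_log2`, `DEL` iff ratio <
#' `del_log2`, otherwise `NEUTRAL` (including equality at either threshold).
#'
#' @param log2_ratio Numeric vector of segment means.
#' @param params An `scna_params` object.
#' @return Character vector in `{"AMP","DEL","NEUTRAL"}`.
#' @export
call_direction <- function(log2_ratio, params = scna_params()) {
  stopifnot(all(is.finite(log2_ratio)))
  ifelse(log2_ratio > params$amp_log2, "AMP",
         ifelse(log2_ratio < params$del_log2, "DEL", "NEUTRAL"))
}

# max fraction of any aneuploidy-eligible arm covered by each event;
# 0 when the chromosome has no eligible arm
.max_eligible_arm_frac <- function(df, build) {
  arms <- build$arms
  armless <- setdiff(unique(df$chrom), arms$chrom)
  if (length(armless)) {
    stop("no arms loaded for ", armless[1], "; call load_arms() first")
  }
  arms <- arms[!arms$acrocentric_short, , drop = FALSE]
  frac <- numeric(nrow(df))
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    on <- df$chrom == a$chrom
    if (!any(on)) next
    ov <- pmax(0, pmin(df$end[on], a$end) - pmax(df$start[on], a$start))
    frac[on] <- pmax(frac[on], ov / (a$end - a$start))
  }
  frac
}

#' Classify one called event
#'
#' An event is an `INDEL` iff its length is strictly below the indel bound;
#' otherwise an `ANEUPLOIDY` iff it covers strictly more than `arm_frac` of
#' some eligible arm (the maximum fraction over the chromosome's arms,
#' acrocentric short arms excluded); otherwise an `SCNA`. A centromere-
#' spanning or whole-chromosome event is thus a single event, never one per
#' arm.
#'
#' @param seg One-row data frame with `chrom`, `start`, `end`.
#' @param build `genome_build` with arms loaded.
#' @param params An `scna_params` object.
#' @return One of `"INDEL"`, `"SCNA"`, `"ANEUPLOIDY"`.
#' @export
classify_event <- function(seg, build, params = scna_params()) {
  stopifnot(nrow(seg) == 1)
  len <- seg$end - seg$start
  if (len < params$indel_max_bp) return("INDEL")
  if (.max_eligible_arm_frac(seg, build) > params$arm_frac) return("ANEUPLOIDY")
  "SCNA"
}

#' Classify all segments of a cohort
#'
#' Calls direction on every segment, drops neutral segments and segments on
#' chromosomes outside the build's analysis set (count reported via
#' `message()`), optionally merges adjacent same-direction segments, and
#' assigns each remaining event exactly one class.
#'
#' @param segments Data frame from [read_seg()] (columns `sample`, `chrom`,
#'   `start`, `end`, `log2_ratio`).
#' @param build `genome_build` with arms loaded.
#' @param params An `scna_params` object.
#' @param merge_gap If non-`NULL`, adjacent same-sample same-direction
#'   segments separated by at most this many bp are merged (length-weighted
#'   mean ratio) before classification. Default off.
#' @return Data frame of alterations: `sample`, `chrom`, `start`, `end`,
#'   `length`, `log2_ratio`, `direction`, `class`, ordered by sample, then
#'   chromosome order, then start.
#' @export
classify_cohort <- function(segments, build, params = scna_params(),
                            merge_gap = NULL) {
  stopifnot(inherits(build, "genome_build"),
            all(c("sample", "chrom", "start", "end", "log2_ratio") %in%
                  names(segments)))
  df <- segments[, c("sample", "chrom", "start", "end", "log2_ratio")]
  outside <- !(df$chrom %in% build$analysis_set)
  if (any(outside)) {
    message("dropping ", sum(outside),
            " segment(s) on chromosomes outside the analysis set")
    df <- df[!outside, , drop = FALSE]
  }
  df$direction <- call_direction(df$log2_ratio, params)
  df <- df[df$direction != "NEUTRAL", , drop = FALSE]
  if (nrow(df) == 0) {
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(), length = numeric(),
                      log2_ratio = numeric(), direction = character(),
                      class = character(), stringsAsFactors = FALSE))
  }
  if (!is.null(merge_gap)) df <- .merge_called(df, merge_gap)
  df$length <- df$end - df$start
  df$class <- .classify_called(df, build, params)
  df <- df[order(df$sample, chrom_rank(df$chrom, build), df$start), ,
           drop = FALSE]
  rownames(df) <- NULL
  df[, c("sample", "chrom", "start", "end", "length", "log2_ratio",
         "direction", "class")]
}

.classify_called <- function(df, build, params) {
  cls <- rep("SCNA", nrow(df))
  len <- df$end - df$start
  cls[len < params$indel_max_bp] <- "INDEL"
  big <- cls == "SCNA"
  if (any(big)) {
    frac <- .max_eligible_arm_frac(df[big, , drop = FALSE], build)
    cls[big][frac > params$arm_frac] <- "ANEUPLOIDY"
  }
  # indels may sit on arm-less chromosomes in principle, but the classifier
  # requires arm geometry for every chromosome it touches
  .max_eligible_arm_frac(df[len < params$indel_max_bp, , drop = FALSE], build)
  cls
}

.merge_called <- function(df, gap) {
  key <- paste(df$sample, df$chrom, df$direction, sep = "\r")
  pieces <- split(df, key)
  out <- lapply(pieces, function(p) {
    p <- p[order(p$start), , drop = FALSE]
    run <- cumsum(c(TRUE, p$start[-1] > p$end[-nrow(p)] + gap))
    merged <- lapply(split(p, run), function(r) {
      w <- r$end - r$start
      data.frame(sample = r$sample[1], chrom = r$chrom[1],
                 start = min(r$start), end = max(r$end),
                 log2_ratio = sum(r$log2_ratio * w) / sum(w),
                 direction = r$direction[1], stringsAsFactors = FALSE)
    })
    do.call(rbind, merged)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify the segments of a single sample
#'
#' Same as [classify_cohort()] but insists all segments share one sample id.
#'
#' @inheritParams classify_cohort
#' @return Alteration data frame (see [classify_cohort()]).
#' @export
classify_sample <- function(segments, build, params = scna_params(),
                            merge_gap = NULL) {
  if (length(unique(segments$sample)) > 1) {
    stop("classify_sample() received segments from multiple samples")
  }
  classify_cohort(segments, build, params, merge_gap)
}

#' Write / read classified events
#'
#' Classified-event tables keep the package's zero-based half-open
#' coordinates on disk (they are internal pipeline artifacts, not SEG files).
#'
#' @param alts Alteration data frame from [classify_cohort()].
#' @param path File path.
#' @return `read_alterations()` returns the alteration data frame.
#' @export
write_alterations <- function(alts, path) {
  write_table(alts, path, keys = c("sample", "chrom", "start", "end", "direction"))
  invisible(path)
}

#' @rdname write_alterations
#' @export
read_alterations <- function(path) {
  df <- read_result_table(path)
  need <- c("sample", "chrom", "start", "end", "length", "log2_ratio",
            "direction", "class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("classified-events table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$sample <- as.character(df$sample)
  df$chrom <- as.character(df$chrom)
  df
}
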