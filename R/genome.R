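# Genome coordinate frame: chromosome lengths, p/q arm intervals, acrocentric
# short-arm flags, and the interval arithmetic used by event classification.

#' Default acrocentric chromosomes (human)
#'
#' The five human acrocentric chromosomes whose p arms carry essentially no
#' unique sequence; their short arms are excluded from the arm-level aneuploidy
#' definition.
#' @export
ACROCENTRIC_DEFAULT <- c("chr13", "chr14", "chr15", "chr21", "chr22")

#' Construct a genome build
#'
#' A genome build holds the ordered chromosome table, optional p/q arm
#' intervals and the analysis set: the chromosomes that enter percent-genome
#' denominators and per-chromosome summaries. Coordinates are zero-based
#' half-open.
#'
#' @param chromosomes Data frame with columns `chrom`, `length` (bp).
#' @param arms Optional data frame with columns `chrom`, `arm` ("p"/"q"),
#'   `start`, `end` (zero-based half-open) and `acrocentric_short` (logical).
#' @param analysis_set Character vector of chromosome names used in
#'   denominators; default all chromosomes except chrY.
#' @return An object of class `genome_build`.
#' @export
genome_build <- function(chromosomes, arms = NULL, analysis_set = NULL) {
  stopifnot(is.data.frame(chromosomes), all(c("chrom", "length") %in% names(chromosomes)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$chrom)) {
    dup <- chromosomes$chrom[duplicated(chromosomes$chrom)][1]
    stop("duplicate chromosome name: ", dup)
  }
  bad <- which(!is.finite(chromosomes$length) | chromosomes$length <= 0)
  if (length(bad)) stop("non-positive chromosome length at row ", bad[1])
  if (is.null(arms)) {
    arms <- data.frame(chrom = character(), arm = character(),
                       start = numeric(), end = numeric(),
                       acrocentric_short = logical(), stringsAsFactors = FALSE)
  }
  if (is.null(analysis_set)) analysis_set <- setdiff(chromosomes$chrom, "chrY")
  build <- structure(list(chromosomes = chromosomes[, c("chrom", "length")],
                          arms = arms, analysis_set = analysis_set),
                     class = "genome_build")
  validate_genome_build(build)
  build
}

validate_genome_build <- function(build) {
  ch <- build$chromosomes
  arms <- build$arms
  if (!all(build$analysis_set %in% ch$chrom)) {
    stop("analysis_set names unknown chromosome: ",
         setdiff(build$analysis_set, ch$chrom)[1])
  }
  if (nrow(arms) > 0) {
    if (!all(arms$chrom %in% ch$chrom)) {
      stop("arm table references unknown chromosome: ",
           setdiff(arms$chrom, ch$chrom)[1])
    }
    if (!all(arms$arm %in% c("p", "q"))) stop("arm labels must be 'p' or 'q'")
    if (any(arms$acrocentric_short & arms$arm != "p")) {
      stop("acrocentric_short may be flagged only on p arms")
    }
    len <- ch$length[match(arms$chrom, ch$chrom)]
    if (any(arms$start < 0 | arms$start >= arms$end)) stop("arm with start >= end or start < 0")
    over <- which(arms$end > len)
    if (length(over)) {
      stop("arm ", arms$chrom[over[1]], arms$arm[over[1]],
           " extends beyond chromosome length (", arms$end[over[1]], " > ",
           len[over[1]], ")")
    }
    for (cc in unique(arms$chrom)) {
      a <- arms[arms$chrom == cc, ]
      if (nrow(a) > 2) stop("more than two arms for ", cc)
      if (nrow(a) == 2 && max(a$start) < min(a$end)) {
        stop("overlapping arms on ", cc)
      }
    }
  }
  invisible(build)
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build> ", nrow(x$chromosomes), " chromosomes, total ",
      format(sum(x$chromosomes$length), big.mark = ","), " bp\n", sep = "")
  cat("  arms loaded: ", nrow(x$arms), "  (acrocentric short arms: ",
      sum(x$arms$acrocentric_short), ")\n", sep = "")
  cat("  analysis set: ", length(x$analysis_set), " chromosomes\n", sep = "")
  invisible(x)
}

#' Read a chrom.sizes file
#'
#' Two tab-separated columns (chromosome name, length in bp), no header.
#' Arms are left empty; attach them with [load_arms()].
#'
#' @param path Path to a chrom.sizes file.
#' @param analysis_set Optional analysis set override (default: everything but
#'   chrY).
#' @return A `genome_build` with empty arm table.
#' @export
load_chrom_sizes <- function(path, analysis_set = NULL) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"))
  if (nrow(raw) < 1) stop("empty chrom.sizes file: ", path)
  raw$chrom <- normalize_chrom(raw$chrom)
  lens <- suppressWarnings(as.numeric(raw$length))
  bad <- which(!is.finite(lens) | lens <= 0 | lens != floor(lens))
  if (length(bad)) stop("non-positive or unparseable length at row ", bad[1],
                        " of ", path)
  raw$length <- lens
  genome_build(raw, analysis_set = analysis_set)
}

#' Attach chromosome-arm intervals to a genome build
#'
#' Accepts either an explicit arm table (tab-separated with a header containing
#' `chrom`, `arm`, `start`, `end` and optionally `acrocentric`; coordinates
#' 1-based inclusive on disk) or a UCSC cytoBand file (no header, five columns,
#' zero-based half-open) from which p/q extents are derived as the span of the
#' `p*` / `q*` bands.
#'
#' @param path Arm table or cytoBand file.
#' @param build A `genome_build` from [load_chrom_sizes()].
#' @param acrocentric Chromosomes whose p arms are flagged acrocentric when the
#'   file itself carries no flag. Default [ACROCENTRIC_DEFAULT].
#' @return The build with arms populated.
#' @export
load_arms <- function(path, build, acrocentric = ACROCENTRIC_DEFAULT) {
  stopifnot(inherits(build, "genome_build"))
  first <- readLines(path, n = 1L)
  fields <- tolower(strsplit(first, "\t", fixed = TRUE)[[1]])
  if ("arm" %in% fields) {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    stopifnot(all(c("chrom", "arm", "start", "end") %in% names(tab)))
    arms <- data.frame(chrom = normalize_chrom(tab$chrom),
                       arm = as.character(tab$arm),
                       start = as.numeric(tab$start) - 1,  # 1-based incl -> half-open
                       end = as.numeric(tab$end),
                       stringsAsFactors = FALSE)
    if ("acrocentric" %in% names(tab)) {
      arms$acrocentric_short <- as.logical(tab$acrocentric) & arms$arm == "p"
    } else {
      arms$acrocentric_short <- arms$arm == "p" & arms$chrom %in% acrocentric
    }
  } else {
    # cytoBand dialect: chrom, start, end, band, stain (0-based half-open)
    cb <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "band", "stain"))
    cb$chrom <- normalize_chrom(cb$chrom)
    cb$arm <- substr(cb$band, 1, 1)
    cb <- cb[cb$arm %in% c("p", "q"), ]
    agg_s <- stats::aggregate(start ~ chrom + arm, cb, min)
    agg_e <- stats::aggregate(end ~ chrom + arm, cb, max)
    arms <- merge(agg_s, agg_e, by = c("chrom", "arm"))
    arms$acrocentric_short <- arms$arm == "p" & arms$chrom %in% acrocentric
  }
  arms <- arms[order(chrom_rank(arms$chrom, build), arms$arm), ]
  rownames(arms) <- NULL
  build$arms <- arms[, c("chrom", "arm", "start", "end", "acrocentric_short")]
  validate_genome_build(build)
  armless <- setdiff(build$analysis_set, arms$chrom)
  if (length(armless)) {
    warning("analysis-set chromosomes without arms: ",
            paste(armless, collapse = ", "))
  }
  build
}

#' Write a genome build to chrom.sizes + arm-table files
#'
#' The inverse of [load_chrom_sizes()] + [load_arms()]: reloading the files
#' reproduces identical coordinates.
#'
#' @param build A `genome_build`.
#' @param chrom_sizes,arms Output paths (arm file skipped when `arms = NULL` or
#'   the build has no arms).
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(build, chrom_sizes, arms = NULL) {
  con <- file(chrom_sizes, open = "wb")
  utils::write.table(build$chromosomes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  close(con)
  written <- chrom_sizes
  if (!is.null(arms) && nrow(build$arms) > 0) {
    a <- build$arms
    disk <- data.frame(chrom = a$chrom, arm = a$arm,
                       start = a$start + 1,  # half-open -> 1-based inclusive
                       end = a$end,
                       acrocentric = a$acrocentric_short)
    con <- file(arms, open = "wb")
    utils::write.table(disk, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n")
    close(con)
    written <- c(written, arms)
  }
  invisible(written)
}

#' Construct a genomic interval
#'
#' @param chrom Chromosome label.
#' @param start,end Zero-based half-open coordinates, `start < end`.
#' @return A one-row data frame with columns `chrom`, `start`, `end`.
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(start < 0) || any(start >= end)) {
    stop("invalid interval: require 0 <= start < end")
  }
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), stringsAsFactors = FALSE)
}

#' Base pairs shared by two genomic intervals
#'
#' Vectorized; returns `max(0, min(ends) - max(starts))` when the chromosomes
#' match and 0 otherwise. Symmetric in its arguments.
#'
#' @param a,b Data frames (recycled to a common length) with columns `chrom`,
#'   `start`, `end`.
#' @return Numeric vector of overlapping base pairs.
#' @export
overlap_bp <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  idx <- function(df) df[rep_len(seq_len(nrow(df)), n), , drop = FALSE]
  a <- idx(a); b <- idx(b)
  ifelse(a$chrom == b$chrom,
         pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start)),
         0)
}

#' Fraction of each chromosome arm covered by a segment
#'
#' For every arm of the segment's chromosome, the fraction of that arm's length
#' covered by the segment (in `[0, 1]`). This is the quantity thresholded by
#' the arm-level aneuploidy rule.
#'
#' @param seg One-row data frame with `chrom`, `start`, `end`.
#' @param build A `genome_build` with arms loaded.
#' @return The arm rows for the segment's chromosome with an extra `fraction`
#'   column.
#' @export
arm_fractions <- function(seg, build) {
  stopifnot(inherits(build, "genome_build"), nrow(seg) == 1)
  arms <- build$arms[build$arms$chrom == seg$chrom, , drop = FALSE]
  if (nrow(arms) == 0) {
    stop("no arms loaded for ", seg$chrom, "; call load_arms() first")
  }
  ov <- pmax(0, pmin(seg$end, arms$end) - pmax(seg$start, arms$start))
  arms$fraction <- ov / (arms$end - arms$start)
  rownames(arms) <- NULL
  arms
}
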