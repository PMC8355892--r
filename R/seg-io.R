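# Readers/writers for the tabular formats the pipeline touches: SEG segment
# tables, BED/TSV gene lists, and sample -> tumor-type annotations.

.seg_synonyms <- list(
  sample = c("sample", "sampleid", "id", "samplename", "samplebarcode"),
  chrom = c("chromosome", "chrom", "chr"),
  start = c("start", "locstart", "chromstart", "startposition"),
  end = c("end", "locend", "chromend", "stop", "endposition"),
  num_probes = c("numprobes", "nummark", "nprobes", "probes", "markers"),
  log2_ratio = c("segmentmean", "segmean", "log2ratio", "log2", "mean", "seg")
)

.match_col <- function(headers, keys) {
  norm <- gsub("[._ -]", "", tolower(headers))
  hit <- which(norm %in% keys)
  if (length(hit)) hit[1] else NA_integer_
}

#' Read a SEG file of segmented copy-number calls
#'
#' The SEG dialect is tab-separated with a header row naming at least sample,
#' chromosome, start, end and segment-mean columns (common synonyms are
#' recognized; a probe-count column is optional and carried through unused).
#' On-disk coordinates are 1-based inclusive and are converted to the package's
#' zero-based half-open convention on read. The segment mean is taken directly
#' as the log2 copy ratio, with no re-centering.
#'
#' @param path SEG file path.
#' @param build Optional `genome_build`: when given, rows are validated against
#'   it and rows on unknown chromosomes are handled per `unknown_chrom`.
#' @param overlap_action What to do when two segments of one sample overlap:
#'   `"error"` (default), `"merge"` (length-weighted mean ratio over the
#'   overlapping run) or `"keep"`.
#' @param unknown_chrom `"skip"` (drop with a warning, default) or `"error"`.
#' @return Data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `num_probes`, `log2_ratio`, in file order (unless merging reorders within
#'   a sample).
#' @export
read_seg <- function(path, build = NULL,
                     overlap_action = c("error", "merge", "keep"),
                     unknown_chrom = c("skip", "error")) {
  overlap_action <- match.arg(overlap_action)
  unknown_chrom <- match.arg(unknown_chrom)
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  cols <- vapply(.seg_synonyms, function(k) .match_col(names(raw), k), integer(1))
  need <- c("sample", "chrom", "start", "end", "log2_ratio")
  miss <- need[is.na(cols[need])]
  if (length(miss)) stop("SEG header missing column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(
    sample = as.character(raw[[cols["sample"]]]),
    chrom = normalize_chrom(raw[[cols["chrom"]]]),
    start = suppressWarnings(as.numeric(raw[[cols["start"]]])) - 1,
    end = suppressWarnings(as.numeric(raw[[cols["end"]]])),
    num_probes = if (is.na(cols["num_probes"])) NA_real_ else
      suppressWarnings(as.numeric(raw[[cols["num_probes"]]])),
    log2_ratio = suppressWarnings(as.numeric(raw[[cols["log2_ratio"]]])),
    stringsAsFactors = FALSE
  )
  if (nrow(df) == 0) return(df)
  bad <- which(!is.finite(df$log2_ratio))
  if (length(bad)) stop("unparseable or non-finite segment mean at row ", bad[1])
  bad <- which(!is.finite(df$start) | !is.finite(df$end) | df$start >= df$end | df$start < 0)
  if (length(bad)) stop("invalid coordinates (start >= end after conversion) at row ", bad[1])
  if (!is.null(build)) {
    known <- df$chrom %in% build$chromosomes$chrom
    if (any(!known)) {
      if (unknown_chrom == "error") {
        stop("unknown chromosome in SEG file: ", unique(df$chrom[!known])[1])
      }
      warning("dropping ", sum(!known), " segment(s) on unknown chromosomes: ",
              paste(unique(df$chrom[!known]), collapse = ", "))
      df <- df[known, , drop = FALSE]
    }
    len <- build$chromosomes$length[chrom_rank(df$chrom, build)]
    bad <- which(df$end > len)
    if (length(bad)) stop("segment beyond chromosome end at row ", bad[1])
  }
  df <- .handle_overlaps(df, overlap_action)
  rownames(df) <- NULL
  df
}

.handle_overlaps <- function(df, action) {
  if (action == "keep" || nrow(df) < 2) return(df)
  key <- paste(df$sample, df$chrom, sep = "\r")
  pieces <- split(df, key)
  out <- lapply(pieces, function(p) {
    p <- p[order(p$start), , drop = FALSE]
    if (!any(p$start[-1] < p$end[-nrow(p)])) return(p)
    if (action == "error") {
      stop("overlapping segments for sample ", p$sample[1], " on ", p$chrom[1])
    }
    # merge: collapse each overlapping run, length-weighted mean ratio
    run <- cumsum(c(TRUE, p$start[-1] >= cummax(p$end)[-nrow(p)]))
    merged <- lapply(split(p, run), function(r) {
      w <- r$end - r$start
      data.frame(sample = r$sample[1], chrom = r$chrom[1],
                 start = min(r$start), end = max(r$end),
                 num_probes = sum(r$num_probes),
                 log2_ratio = sum(r$log2_ratio * w) / sum(w),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, merged)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(paste(res$sample, res$chrom, sep = "\r"), key), res$start), ,
      drop = FALSE]
}

#' Write segments as a SEG file
#'
#' Converts internal half-open coordinates back to the 1-based inclusive
#' on-disk dialect. `read_seg()` of the result reproduces the input
#' (sample, interval, ratio) triples.
#'
#' @param segments Data frame as returned by [read_seg()].
#' @param path Output path.
#' @export
write_seg <- function(segments, path) {
  disk <- data.frame(Sample = segments$sample,
                     Chromosome = segments$chrom,
                     Start = segments$start + 1,
                     End = segments$end,
                     Num_Probes = segments$num_probes,
                     Segment_Mean = segments$log2_ratio)
  con <- file(path, open = "wb")
  on.exit(close(con))
  disk$Segment_Mean <- formatC(disk$Segment_Mean, digits = 6, format = "g")
  utils::write.table(disk, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a cancer gene census
#'
#' Either BED4 (no header, zero-based half-open: chrom, start, end, symbol) or
#' a TSV with header columns `symbol`/`gene`, `chrom`, `start`, `end`
#' (1-based inclusive). Both dialects yield identical internal intervals.
#'
#' @param path Gene file.
#' @param build Optional `genome_build` for coordinate validation.
#' @param format `"auto"` (default; header sniffing), `"bed"` or `"tsv"`.
#' @return Data frame with columns `symbol`, `chrom`, `start`, `end`.
#' @export
read_gene_census <- function(path, build = NULL,
                             format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    fields <- tolower(strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]])
    format <- if (any(c("symbol", "gene", "chrom", "chromosome") %in% fields)) "tsv" else "bed"
  }
  if (format == "bed") {
    raw <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end", "symbol"))
    genes <- data.frame(symbol = as.character(raw$symbol),
                        chrom = normalize_chrom(raw$chrom),
                        start = as.numeric(raw$start),
                        end = as.numeric(raw$end), stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    names(raw) <- tolower(names(raw))
    sym <- if ("symbol" %in% names(raw)) "symbol" else "gene"
    chr <- if ("chrom" %in% names(raw)) "chrom" else "chromosome"
    genes <- data.frame(symbol = as.character(raw[[sym]]),
                        chrom = normalize_chrom(raw[[chr]]),
                        start = as.numeric(raw$start) - 1,
                        end = as.numeric(raw$end), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(genes$symbol)) {
    stop("duplicate gene symbol: ", genes$symbol[duplicated(genes$symbol)][1])
  }
  if (any(genes$start >= genes$end)) {
    stop("zero- or negative-length gene: ",
         genes$symbol[which(genes$start >= genes$end)[1]])
  }
  if (!is.null(build)) {
    if (!all(genes$chrom %in% build$chromosomes$chrom)) {
      stop("gene on unknown chromosome: ",
           genes$symbol[which(!genes$chrom %in% build$chromosomes$chrom)[1]])
    }
    len <- build$chromosomes$length[chrom_rank(genes$chrom, build)]
    if (any(genes$end > len)) {
      stop("gene beyond chromosome end: ", genes$symbol[which(genes$end > len)[1]])
    }
  }
  rownames(genes) <- NULL
  genes
}

#' Write a gene census as BED4
#' @param genes Data frame with `symbol`, `chrom`, `start`, `end` (half-open).
#' @param path Output path.
#' @export
write_gene_census <- function(genes, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(genes[, c("chrom", "start", "end", "symbol")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read sample -> tumor-type annotations
#'
#' Two-column TSV with header (sample, tumor_type). A sample listed twice with
#' conflicting types is an error; exact duplicate rows are collapsed.
#'
#' @param path Annotation file.
#' @return Data frame with columns `sample`, `tumor_type`.
#' @export
read_sample_annotations <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("annotation file needs two columns (sample, tumor_type)")
  ann <- data.frame(sample = as.character(raw[[1]]),
                    tumor_type = as.character(raw[[2]]),
                    stringsAsFactors = FALSE)
  ann <- unique(ann)
  if (anyDuplicated(ann$sample)) {
    stop("conflicting tumor types for sample ",
         ann$sample[duplicated(ann$sample)][1])
  }
  rownames(ann) <- NULL
  ann
}

# tumor_type lookup with UNKNOWN fill for unannotated samples
lookup_type <- function(samples, annotations) {
  if (is.null(annotations)) return(rep("UNKNOWN", length(samples)))
  tt <- annotations$tumor_type[match(samples, annotations$sample)]
  if (anyNA(tt)) {
    warning(sum(is.na(tt)), " sample(s) missing annotation; assigned UNKNOWN")
    tt[is.na(tt)] <- "UNKNOWN"
  }
  tt
}
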