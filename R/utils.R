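# Internal helpers shared across modules. All genomic coordinates inside the
# package are zero-based half-open; conversions happen only at file boundaries.

# "1"/"x" -> "chr1"/"chrX" for standard chromosome names; other labels (toy
# genomes) pass through untouched.
normalize_chrom <- function(x) {
  x <- as.character(x)
  core <- sub("^chr", "", x, ignore.case = TRUE)
  std <- grepl("^([0-9]{1,2}|x|y|m|mt)$", core, ignore.case = TRUE)
  x[std] <- paste0("chr", toupper(core[std]))
  x
}

chrom_rank <- function(chrom, build) {
  match(chrom, build$chromosomes$chrom)
}

# total base pairs covered by the union of half-open intervals on one chromosome
bp_union <- function(start, end) {
  if (length(start) == 0L) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1, end = end))
  sum(as.numeric(IRanges::width(ir)))
}

# base pairs of the query interval covered by the union of subject intervals
# (all on one chromosome)
bp_covered <- function(q_start, q_end, s_start, s_end) {
  if (length(s_start) == 0L) return(0)
  red <- IRanges::reduce(IRanges::IRanges(start = s_start + 1, end = s_end))
  q <- IRanges::IRanges(start = q_start + 1, end = q_end)
  sum(as.numeric(IRanges::width(IRanges::intersect(red, q))))
}

events_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Write a deterministic tab-separated result table
#'
#' Writes a data frame as TSV with a header row, rows sorted by the given key
#' columns and numeric (double) columns serialized at 6 significant digits, so
#' that identical inputs always produce byte-identical files regardless of the
#' in-memory row order.
#'
#' @param df A data frame.
#' @param path Output file path.
#' @param keys Character vector of column names to sort by (in order). Default
#'   all columns left to right.
#' @return Invisibly, the (sorted, formatted) data frame that was written.
#' @export
write_table <- function(df, path, keys = names(df)) {
  stopifnot(is.data.frame(df))
  keys <- intersect(keys, names(df))
  if (nrow(df) > 0 && length(keys) > 0) {
    df <- df[do.call(order, df[keys]), , drop = FALSE]
  }
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- ifelse(is.na(v), "NA", formatC(v, digits = 6, format = "g"))
      out[[j]] <- s
    }
  }
  con <- file(path, open = "wb")  # binary: fixed "\n" line endings everywhere
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(df)
}

read_result_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
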