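# Multi-stage pipeline driver: simulate -> classify -> burden -> genes ->
# pairs, exchanging plain TSV artifacts with documented schemas so every stage
# is independently runnable and diffable. Logging goes to stderr; results only
# to files.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every recognized key; a user
#' config (YAML file or list) is merged over it. Paths are `NULL` until set.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    out_dir = "scnatlas_out",
    seed = 1,
    segments = NULL, genome = NULL, arms = NULL, genes = NULL,
    annotations = NULL,
    params = list(amp_log2 = 0.32, del_log2 = -0.42, indel_max_bp = 10000,
                  arm_frac = 0.75, gene_overlap_frac = 0.5),
    modes = list(chrom_norm = "divide", gene_overlap_union = TRUE,
                 include_classes = "SCNA", pair_min_frequency = 0.05,
                 top_genes_k = 25, top_pairs_k = 100,
                 inter_chromosomal_only = TRUE),
    simulate = list(enabled = FALSE)
  )
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a pipeline configuration
#'
#' @param config A YAML file path, a list of overrides, or `NULL` for the
#'   defaults.
#' @return Full configuration list.
#' @export
load_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  .merge_config(base, config)
}

.log <- function(...) message("[scnatlas] ", ...)

.config_params <- function(config) do.call(scna_params, config$params)

.load_inputs <- function(config) {
  for (key in c("segments", "genome", "arms")) {
    if (is.null(config[[key]])) stop("config is missing required path: ", key)
    if (!file.exists(config[[key]])) {
      stop("input file for '", key, "' not found: ", config[[key]])
    }
  }
  build <- load_chrom_sizes(config$genome)
  build <- load_arms(config$arms, build)
  list(build = build)
}

#' Run pipeline stages
#'
#' Executes the requested stages in order against the configured inputs,
#' writing deterministic TSV artifacts into `out_dir` plus a manifest
#' (`manifest.tsv`: file, md5, rows) and a config echo
#' (`config_used.yaml`). Identical configuration and inputs produce
#' byte-identical outputs. Each stage consumes the previous stage's TSVs, so
#' stages can also be run one at a time on intermediate files.
#'
#' @param config Config list or YAML path (see [default_config()]).
#' @param stages Character vector among `"simulate"`, `"classify"`,
#'   `"burden"`, `"genes"`, `"pairs"`, or `"all"`.
#' @return Invisibly, the manifest data frame.
#' @export
run_pipeline <- function(config = NULL, stages = "all") {
  config <- load_config(config)
  if (identical(stages, "all")) {
    stages <- c(if (isTRUE(config$simulate$enabled)) "simulate",
                "classify", "burden", "genes", "pairs")
  }
  known <- c("simulate", "classify", "burden", "genes", "pairs")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  # fail fast on missing inputs before any stage writes
  if (any(c("genes", "pairs") %in% stages) && !"simulate" %in% stages) {
    if (is.null(config$genes) || !file.exists(config$genes)) {
      stop("gene census file required for the genes/pairs stages: ",
           config$genes %||% "<unset>")
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (st in stages) {
    t0 <- Sys.time()
    .log("stage ", st, " ...")
    config <- switch(st,
                     simulate = .stage_simulate(config),
                     classify = .stage_classify(config),
                     burden = .stage_burden(config),
                     genes = .stage_genes(config),
                     pairs = .stage_pairs(config))
    .log("stage ", st, " done in ",
         sprintf("%.2fs", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  .write_manifest(config)
}

.stage_simulate <- function(config) {
  sim_dir <- file.path(config$out_dir, "sim")
  sim_args <- config$simulate
  sim_args$enabled <- NULL
  sim_args$seed <- sim_args$seed %||% config$seed
  # YAML represents named vectors as maps and tables as lists of rows
  for (k in c("tumor_types", "amp_mu", "del_mu", "class_mix")) {
    if (is.list(sim_args[[k]])) sim_args[[k]] <- unlist(sim_args[[k]])
  }
  for (k in c("planted_genes", "planted_pairs")) {
    if (is.list(sim_args[[k]]) && !is.data.frame(sim_args[[k]])) {
      sim_args[[k]] <- do.call(rbind, lapply(sim_args[[k]], as.data.frame))
    }
  }
  spec <- do.call(cohort_spec, sim_args)
  cohort <- generate_cohort(spec, params = .config_params(config),
                            dir = sim_dir)
  .log("simulated ", nrow(cohort$annotations), " samples / ",
       nrow(cohort$segments), " segments")
  config$segments <- file.path(sim_dir, "segments.seg")
  config$genome <- file.path(sim_dir, "chrom.sizes")
  config$arms <- file.path(sim_dir, "arms.tsv")
  config$genes <- file.path(sim_dir, "genes.bed")
  config$annotations <- file.path(sim_dir, "annotations.tsv")
  config
}

.stage_classify <- function(config) {
  inp <- .load_inputs(config)
  segs <- read_seg(config$segments, build = inp$build)
  alts <- classify_cohort(segs, inp$build, .config_params(config))
  write_alterations(alts, file.path(config$out_dir, "classified_events.tsv"))
  .log(nrow(alts), " called events from ", nrow(segs), " segments")
  config
}

.read_stage_alts <- function(config) {
  path <- file.path(config$out_dir, "classified_events.tsv")
  if (!file.exists(path)) {
    stop("classified_events.tsv not found in out_dir; run the classify stage first")
  }
  read_alterations(path)
}

.stage_burden <- function(config) {
  inp <- .load_inputs(config)
  alts <- .read_stage_alts(config)
  ann <- if (!is.null(config$annotations)) {
    read_sample_annotations(config$annotations)
  } else NULL
  burdens <- cohort_burden(alts, inp$build, ann)
  out <- config$out_dir
  write_table(burdens, file.path(out, "burden_per_sample.tsv"), keys = "sample")
  write_table(cohort_tables(burdens, alts),
              file.path(out, "burden_per_type.tsv"),
              keys = c("tumor_type", "metric", "direction"))
  write_table(class_mix(alts, ann), file.path(out, "class_mix.tsv"),
              keys = "tumor_type")
  write_table(chrom_distribution_by_type(alts, inp$build,
                                         ann %||% data.frame(sample = unique(alts$sample),
                                                             tumor_type = "UNKNOWN"),
                                         mode = config$modes$chrom_norm),
              file.path(out, "chrom_distribution.tsv"),
              keys = c("tumor_type", "chrom"))
  write_table(compare_groups(burdens), file.path(out, "comparisons.tsv"),
              keys = c("tumor_type", "metric"))
  corr <- amp_del_correlation(burdens)
  if (!is.null(corr)) {
    write_table(corr, file.path(out, "correlations.tsv"),
                keys = c("scope", "tumor_type"))
  }
  write_table(scna_length_stats(alts, by = "chromosome", build = inp$build,
                                normalize = TRUE),
              file.path(out, "scna_length_by_chrom.tsv"), keys = "group")
  config
}

.stage_genes <- function(config) {
  inp <- .load_inputs(config)
  alts <- .read_stage_alts(config)
  genes <- read_gene_census(config$genes, build = inp$build)
  ann <- read_sample_annotations(config$annotations)
  params <- .config_params(config)
  calls <- call_genes_cohort(alts, genes, params,
                             include_classes = config$modes$include_classes,
                             union = isTRUE(config$modes$gene_overlap_union))
  freq <- gene_frequency(calls, ann, genes)
  out <- config$out_dir
  write_table(calls, file.path(out, "gene_calls.tsv"),
              keys = c("sample", "gene", "direction"))
  write_table(freq, file.path(out, "gene_frequency.tsv"),
              keys = c("direction", "gene", "tumor_type"))
  k <- config$modes$top_genes_k
  tops <- rbind(top_genes(freq, k = min(k, nrow(genes)), direction = "AMP"),
                top_genes(freq, k = min(k, nrow(genes)), direction = "DEL"))
  write_table(tops, file.path(out, "top_genes.tsv"),
              keys = c("direction", "rank"))
  .log(nrow(calls), " gene calls across ", nrow(ann), " samples")
  config
}

.stage_pairs <- function(config) {
  inp <- .load_inputs(config)
  genes <- read_gene_census(config$genes, build = inp$build)
  ann <- read_sample_annotations(config$annotations)
  calls_path <- file.path(config$out_dir, "gene_calls.tsv")
  if (!file.exists(calls_path)) {
    stop("gene_calls.tsv not found in out_dir; run the genes stage first")
  }
  calls <- read_result_table(calls_path)
  pairs <- pair_frequency(calls, ann, scope = "cohort", genes = genes,
                          build = inp$build)
  pairs_type <- pair_frequency(calls, ann, scope = "tumor_type",
                               genes = genes, build = inp$build)
  out <- config$out_dir
  write_table(pairs, file.path(out, "pair_frequency.tsv"),
              keys = c("event_type", "gene_a", "gene_b"))
  write_table(pairs_type, file.path(out, "pair_frequency_by_type.tsv"),
              keys = c("scope", "event_type", "gene_a", "gene_b"))
  filt <- filter_pairs(pairs,
                       min_frequency = config$modes$pair_min_frequency,
                       inter_chromosomal_only =
                         isTRUE(config$modes$inter_chromosomal_only))
  write_table(filt, file.path(out, "filtered_pairs.tsv"),
              keys = c("event_type", "gene_a", "gene_b"))
  part <- do.call(rbind, lapply(c("AMP-AMP", "DEL-DEL"), function(tp) {
    p <- pairs[pairs$event_type == tp, , drop = FALSE]
    p <- p[!p$same_chromosome, , drop = FALSE]
    if (nrow(p) == 0) return(NULL)
    cbind(event_type = tp, participation(p, k = config$modes$top_pairs_k),
          stringsAsFactors = FALSE)
  }))
  if (!is.null(part)) {
    write_table(part, file.path(out, "participation.tsv"),
                keys = c("event_type", "gene"))
  }
  .log(nrow(pairs), " pan-cohort pair frequencies")
  config
}

.write_manifest <- function(config) {
  out <- config$out_dir
  files <- sort(setdiff(list.files(out, pattern = "\\.(tsv|seg|bed|sizes)$",
                                   recursive = TRUE), "manifest.tsv"))
  rows <- lapply(files, function(f) {
    p <- file.path(out, f)
    n <- length(readLines(p, warn = FALSE))
    data.frame(file = f, md5 = unname(tools::md5sum(p)), lines = n,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write_table(manifest, file.path(out, "manifest.tsv"), keys = "file")
  cfg <- config
  yaml_txt <- yaml::as.yaml(cfg)
  con <- file(file.path(out, "config_used.yaml"), open = "wb")
  writeLines(yaml_txt, con, sep = "")
  close(con)
  invisible(manifest)
}
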