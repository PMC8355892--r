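# Seeded synthetic cohorts with planted ground truth. Every generated event
# keeps a guard margin from all decision boundaries (log2 thresholds, indel
# size, arm fraction, gene overlap), so the classification of the emitted SEG
# rows is unambiguous and the truth tables are exact by construction:
#  - background SCNA/indel events never touch census-gene territory, so the
#    gene-call truth is exactly the planted incidence;
#  - all segments within a sample are non-overlapping, so genome-fraction
#    truth is a plain sum of event lengths;
#  - pair truth is derived combinatorially from the planted gene incidence.

#' Build a toy genome with files
#'
#' Equal-length chromosomes with p/q arms separated by a centromeric gap.
#' Chromosomes listed in `acrocentric_p` get a short flagged p arm (10% of the
#' chromosome), emulating the human acrocentrics.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param p_frac,gap_frac Fractions of the chromosome taken by the p arm and
#'   the centromeric gap (q arm gets the rest).
#' @param acrocentric_p Chromosome indices whose p arm is flagged acrocentric.
#' @param dir If non-`NULL`, `chrom.sizes` and `arms.tsv` are written there.
#' @return A `genome_build`.
#' @export
make_toy_genome <- function(n_chroms = 8, chrom_length = 5e7, p_frac = 0.45,
                            gap_frac = 0.05, acrocentric_p = integer(0),
                            dir = NULL) {
  stopifnot(n_chroms >= 1, chrom_length > 0, p_frac > 0, gap_frac >= 0,
            p_frac + gap_frac < 1)
  chroms <- paste0("chr", seq_len(n_chroms))
  arms <- do.call(rbind, lapply(seq_len(n_chroms), function(i) {
    acro <- i %in% acrocentric_p
    pf <- if (acro) 0.10 else p_frac
    gf <- if (acro) 0.02 else gap_frac
    p_end <- floor(pf * chrom_length)
    q_start <- floor((pf + gf) * chrom_length)
    if (p_end <= 0 || q_start >= chrom_length) {
      stop("arm layout inconsistent with chromosome length")
    }
    data.frame(chrom = chroms[i], arm = c("p", "q"),
               start = c(0, q_start), end = c(p_end, chrom_length),
               acrocentric_short = c(acro, FALSE), stringsAsFactors = FALSE)
  }))
  build <- genome_build(
    data.frame(chrom = chroms, length = chrom_length, stringsAsFactors = FALSE),
    arms = arms)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_genome(build, file.path(dir, "chrom.sizes"), file.path(dir, "arms.tsv"))
  }
  build
}

.toy_symbols <- c("MYC", "ERBB2", "CDKN2A", "EGFR", "CSMD3", "FAM135B",
                  "ARHGEF10", "PCM1", "PTEN", "TP53", "NDRG1", "LRP1B",
                  "PTPRT", "PTK6", "RB1", "KRAS", "CCND1", "MDM2", "FGFR1",
                  "SMAD4")

#' Toy cancer-gene census
#'
#' Places fixed-length genes at deterministic positions on the q arms of the
#' first chromosomes of a build, well separated so gene-level overlap calls
#' never interact.
#'
#' @param build A `genome_build` with arms.
#' @param n_genes Number of genes (default 12).
#' @param gene_length Gene length in bp.
#' @return Gene census data frame (`symbol`, `chrom`, `start`, `end`).
#' @export
toy_gene_census <- function(build, n_genes = 12, gene_length = 1e5) {
  q <- build$arms[build$arms$arm == "q", , drop = FALSE]
  q <- q[order(chrom_rank(q$chrom, build)), , drop = FALSE]
  per_arm <- ceiling(n_genes / nrow(q))
  fr <- seq(0.2, 0.8, length.out = per_arm)
  slots <- do.call(rbind, lapply(seq_len(nrow(q)), function(i) {
    data.frame(chrom = q$chrom[i],
               start = floor(q$start[i] + fr * (q$end[i] - q$start[i])),
               stringsAsFactors = FALSE)
  }))
  slots <- slots[order(rep(seq_along(fr), times = nrow(q))), , drop = FALSE][seq_len(n_genes), ]
  syms <- c(.toy_symbols, sprintf("GENE%03d", seq_len(max(0, n_genes - length(.toy_symbols)))))
  genes <- data.frame(symbol = syms[seq_len(n_genes)], chrom = slots$chrom,
                      start = slots$start, end = slots$start + gene_length,
                      stringsAsFactors = FALSE)
  genes[order(chrom_rank(genes$chrom, build), genes$start), ]
}

#' Specification of a synthetic cohort
#'
#' Defines the study conditions of a simulated cohort: tumor types and sample
#' sizes, per-type negative-binomial event-count rates, the target class mix,
#' the SCNA length distribution (log-normal, truncated to the legal SCNA
#' range per arm), guard margins, planted gene events and planted co-altered
#' pairs, and the amplification/deletion coupling switch.
#'
#' @param seed Integer seed; all randomness in [generate_cohort()] flows from
#'   it.
#' @param tumor_types Named integer vector: samples per tumor type.
#' @param amp_mu,del_mu Named per-type (or scalar) negative-binomial means of
#'   amplification / deletion event counts per sample.
#' @param amp_size,del_size Negative-binomial dispersion (size) parameters.
#' @param class_mix Named proportions for INDEL/SCNA/ANEUPLOIDY; must sum
#'   to 1.
#' @param scna_len_meanlog,scna_len_sdlog Log-normal parameters of SCNA
#'   lengths (bp).
#' @param indel_len_range Uniform range of indel lengths (bp), strictly inside
#'   the indel bound.
#' @param ratio_margin Guard margin (log2 units) between generated ratios and
#'   the calling thresholds.
#' @param len_margin Guard margin (bp) from the size and arm-fraction
#'   boundaries.
#' @param neutral_per_chrom Neutral filler segments per chromosome and sample.
#' @param neutral_len_range Length range of neutral fillers (bp).
#' @param planted_genes Data frame (`gene`, `direction`, `tumor_type`,
#'   `frequency`); `tumor_type = "ALL"` plants at that frequency in every
#'   type.
#' @param planted_pairs Data frame (`gene_a`, `gene_b`, `event_type`,
#'   `frequency`); frequencies are fractions of the whole cohort. For
#'   `AMP-DEL`, `gene_a` is the amplified member.
#' @param coupling Couple per-sample AMP and DEL counts through a shared
#'   gamma intensity (positive correlation); `FALSE` draws them
#'   independently.
#' @param coupling_shape Gamma shape (= rate; mean 1) of the shared intensity.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(seed = 1,
                        tumor_types = c(OV = 50, BRCA = 50, SARC = 50,
                                        KIRC = 50, THCA = 50),
                        amp_mu = c(OV = 18, BRCA = 12, SARC = 16, KIRC = 6,
                                   THCA = 4),
                        del_mu = c(OV = 12, BRCA = 9, SARC = 13, KIRC = 4,
                                   THCA = 3),
                        amp_size = 4, del_size = 4,
                        class_mix = c(INDEL = 0.30, SCNA = 0.60,
                                      ANEUPLOIDY = 0.10),
                        scna_len_meanlog = log(1.2e6), scna_len_sdlog = 1.4,
                        indel_len_range = c(300, 9500),
                        ratio_margin = 0.02, len_margin = 100,
                        neutral_per_chrom = 2,
                        neutral_len_range = c(5e4, 5e5),
                        planted_genes = NULL, planted_pairs = NULL,
                        coupling = TRUE, coupling_shape = 2) {
  stopifnot(length(tumor_types) >= 1, all(tumor_types >= 1),
            !is.null(names(tumor_types)))
  expand <- function(v, was_missing, fallback) {
    if (was_missing && !all(names(tumor_types) %in% names(v))) v <- fallback
    if (length(v) == 1 && is.null(names(v))) {
      stats::setNames(rep(v, length(tumor_types)), names(tumor_types))
    } else {
      stopifnot(all(names(tumor_types) %in% names(v)))
      v[names(tumor_types)]
    }
  }
  stopifnot(abs(sum(class_mix) - 1) < 1e-9, all(class_mix >= 0),
            all(c("INDEL", "SCNA", "ANEUPLOIDY") %in% names(class_mix)),
            ratio_margin > 0, len_margin > 0)
  for (pf in list(planted_genes, planted_pairs)) {
    if (!is.null(pf)) stopifnot(all(pf$frequency >= 0 & pf$frequency <= 1))
  }
  structure(list(seed = seed, tumor_types = tumor_types,
                 amp_mu = expand(amp_mu, missing(amp_mu), 12),
                 del_mu = expand(del_mu, missing(del_mu), 8),
                 amp_size = amp_size, del_size = del_size,
                 class_mix = class_mix[c("INDEL", "SCNA", "ANEUPLOIDY")],
                 scna_len_meanlog = scna_len_meanlog,
                 scna_len_sdlog = scna_len_sdlog,
                 indel_len_range = indel_len_range,
                 ratio_margin = ratio_margin, len_margin = len_margin,
                 neutral_per_chrom = neutral_per_chrom,
                 neutral_len_range = neutral_len_range,
                 planted_genes = planted_genes, planted_pairs = planted_pairs,
                 coupling = coupling, coupling_shape = coupling_shape),
            class = "cohort_spec")
}

# --- interval placement ------------------------------------------------------

# gaps of [lo, hi) not covered by blocked intervals
.free_gaps <- function(lo, hi, blocked) {
  if (is.null(blocked) || nrow(blocked) == 0) {
    return(data.frame(start = lo, end = hi))
  }
  b <- blocked[blocked$end > lo & blocked$start < hi, , drop = FALSE]
  if (nrow(b) == 0) return(data.frame(start = lo, end = hi))
  b$start <- pmax(b$start, lo); b$end <- pmin(b$end, hi)
  b <- b[order(b$start), , drop = FALSE]
  cm <- cummax(b$end)
  starts <- c(lo, cm)
  ends <- c(b$start, hi)
  keep <- starts < ends
  data.frame(start = starts[keep], end = ends[keep])
}

# uniformly choose a start position for an interval of length len inside the
# gaps; NA when it does not fit anywhere
.place_in_gaps <- function(gaps, len) {
  slack <- gaps$end - gaps$start - len
  ok <- which(slack >= 0)
  if (length(ok) == 0) return(NA_real_)
  w <- slack[ok] + 1
  i <- ok[sample.int(length(ok), 1, prob = w)]
  gaps$start[i] + floor(stats::runif(1, 0, slack[i] + 1))
}

.rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

#' Generate a synthetic cohort with planted truth
#'
#' Produces SEG-format segments, sample annotations, a gene census and truth
#' tables for a cohort drawn from a [cohort_spec()]. All randomness flows from
#' `spec$seed`; the same spec and build always yield identical output. An
#' infeasible spec (a planted event that cannot be placed) is an error before
#' any file is written - never a silent truncation. Neutral filler segments
#' are best-effort and skipped when a chromosome has no room left.
#'
#' @param spec A `cohort_spec`.
#' @param build A `genome_build` with arms; default [make_toy_genome()] with
#'   one acrocentric chromosome.
#' @param genes Gene census; default [toy_gene_census()] on the build.
#' @param params `scna_params` whose boundaries the guard margins refer to.
#' @param dir If non-`NULL`, all inputs and truth tables are written there
#'   (`segments.seg`, `annotations.tsv`, `genes.bed`, `chrom.sizes`,
#'   `arms.tsv`, `truth_events.tsv`, `truth_sample.tsv`,
#'   `truth_gene_calls.tsv`, `truth_pairs.tsv`).
#' @return An object of class `scna_cohort`: list with `segments`,
#'   `annotations`, `genes`, `build`, `truth` (events, sample_summary,
#'   gene_calls, pair_frequency, class_mix) and `spec`.
#' @export
generate_cohort <- function(spec, build = NULL, genes = NULL,
                            params = scna_params(), dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(build)) build <- make_toy_genome(acrocentric_p = 8)
  if (is.null(genes)) genes <- toy_gene_census(build)
  set.seed(spec$seed)
  types <- names(spec$tumor_types)
  samples <- unlist(lapply(types, function(g) {
    sprintf("%s_%03d", g, seq_len(spec$tumor_types[[g]]))
  }), use.names = FALSE)
  annotations <- data.frame(
    sample = samples,
    tumor_type = rep(types, spec$tumor_types[types]),
    stringsAsFactors = FALSE)
  n_total <- length(samples)

  arms <- build$arms[build$arms$chrom %in% build$analysis_set, , drop = FALSE]
  arms$len <- arms$end - arms$start
  eligible <- arms[!arms$acrocentric_short, , drop = FALSE]

  # ---- planted gene incidence -----------------------------------------------
  incidence <- data.frame(sample = character(), gene = character(),
                          direction = character(), stringsAsFactors = FALSE)
  add_incidence <- function(ss, gene, direction) {
    rbind(incidence, data.frame(sample = ss, gene = gene,
                                direction = direction, stringsAsFactors = FALSE))
  }
  pg <- spec$planted_genes
  if (!is.null(pg)) {
    for (i in seq_len(nrow(pg))) {
      if (!pg$gene[i] %in% genes$symbol) {
        stop("planted gene not in census: ", pg$gene[i])
      }
      targets <- if (pg$tumor_type[i] == "ALL") types else pg$tumor_type[i]
      for (g in targets) {
        ss <- annotations$sample[annotations$tumor_type == g]
        k <- round(pg$frequency[i] * length(ss))
        if (k > 0) incidence <- add_incidence(sort(sample(ss, k)),
                                              pg$gene[i], pg$direction[i])
      }
    }
  }
  pp <- spec$planted_pairs
  if (!is.null(pp)) {
    for (i in seq_len(nrow(pp))) {
      dirs <- switch(pp$event_type[i],
                     "AMP-AMP" = c("AMP", "AMP"), "DEL-DEL" = c("DEL", "DEL"),
                     "AMP-DEL" = c("AMP", "DEL"),
                     stop("unknown event_type: ", pp$event_type[i]))
      gg <- c(pp$gene_a[i], pp$gene_b[i])
      if (!all(gg %in% genes$symbol)) stop("planted pair gene not in census")
      k <- round(pp$frequency[i] * n_total)
      if (k > 0) {
        ss <- sort(sample(samples, k))
        incidence <- add_incidence(ss, gg[1], dirs[1])
        incidence <- add_incidence(ss, gg[2], dirs[2])
      }
    }
  }
  incidence <- unique(incidence)
  conf <- duplicated(incidence[, c("sample", "gene")])
  if (any(conf)) {
    stop("infeasible planted spec: gene ",
         incidence$gene[conf][1], " planted in both directions in sample ",
         incidence$sample[conf][1])
  }

  # ---- per-sample event placement -------------------------------------------
  m <- spec$len_margin
  rm_ <- spec$ratio_margin
  amp_band <- c(params$amp_log2 + rm_, params$amp_log2 + rm_ + 1)
  del_band <- c(params$del_log2 - rm_ - 1, params$del_log2 - rm_)
  neu_band <- c(params$del_log2 + rm_, params$amp_log2 - rm_)
  draw_ratio <- function(direction, n = 1) {
    b <- switch(direction, AMP = amp_band, DEL = del_band, NEUTRAL = neu_band)
    round(stats::runif(n, b[1], b[2]), 4)
  }
  gene_arm_row <- vapply(seq_len(nrow(genes)), function(i) {
    hit <- which(arms$chrom == genes$chrom[i] & arms$start <= genes$start[i] &
                   arms$end >= genes$end[i])
    if (length(hit) == 0) stop("planted census gene ", genes$symbol[i],
                               " does not lie inside a single arm")
    hit[1]
  }, integer(1))

  all_rows <- vector("list", n_total)
  truth_rows <- vector("list", n_total)
  for (si in seq_len(n_total)) {
    sid <- samples[si]
    ttype <- annotations$tumor_type[si]
    occupied <- list()  # per chrom data.frame(start, end)
    occ <- function(chrom) occupied[[chrom]] %||% data.frame(start = numeric(),
                                                             end = numeric())
    block <- function(chrom, start, end) {
      occupied[[chrom]] <<- rbind(occ(chrom),
                                  data.frame(start = start, end = end))
    }
    ev <- list()
    push <- function(chrom, start, end, direction, class, ratio) {
      ev[[length(ev) + 1L]] <<- data.frame(
        sample = sid, chrom = chrom, start = start, end = end,
        log2_ratio = ratio, direction = direction, class = class,
        stringsAsFactors = FALSE)
      block(chrom, start, end)
    }

    # 1. planted gene events (SCNA class, full gene coverage)
    inc <- incidence[incidence$sample == sid, , drop = FALSE]
    if (nrow(inc) > 0) {
      inc <- inc[order(inc$gene), , drop = FALSE]
      for (i in seq_len(nrow(inc))) {
        gi <- match(inc$gene[i], genes$symbol)
        a <- arms[gene_arm_row[gi], ]
        fl <- floor(stats::runif(2, 2000, 20000))
        start <- max(a$start, genes$start[gi] - fl[1])
        end <- min(a$end, genes$end[gi] + fl[2])
        len <- end - start
        if (len < params$indel_max_bp + m ||
            len > params$arm_frac * a$len - m) {
          stop("infeasible planted spec: gene event for ", inc$gene[i],
               " cannot respect the SCNA class margins")
        }
        if (nrow(.free_gaps(start, end, occ(a$chrom))) != 1 ||
            .free_gaps(start, end, occ(a$chrom))$start != start) {
          stop("infeasible planted spec: overlapping planted events in ", sid)
        }
        push(a$chrom, start, end, inc$direction[i], "SCNA",
             draw_ratio(inc$direction[i]))
      }
    }

    # 2. background counts (negative binomial, optional shared intensity)
    f <- if (spec$coupling) stats::rgamma(1, spec$coupling_shape,
                                          rate = spec$coupling_shape) else 1
    n_amp <- stats::rnbinom(1, mu = spec$amp_mu[[ttype]] * f,
                            size = spec$amp_size)
    n_del <- stats::rnbinom(1, mu = spec$del_mu[[ttype]] * f,
                            size = spec$del_size)
    dirs <- c(rep("AMP", n_amp), rep("DEL", n_del))
    if (length(dirs) > 0) {
      cls <- sample(names(spec$class_mix), length(dirs), replace = TRUE,
                    prob = spec$class_mix)
      ord <- order(match(cls, c("ANEUPLOIDY", "SCNA", "INDEL")))
      dirs <- dirs[ord]; cls <- cls[ord]
      gene_zones <- split(genes[, c("start", "end")], genes$chrom)
      for (i in seq_along(dirs)) {
        placed <- FALSE
        if (cls[i] == "ANEUPLOIDY") {
          for (ai in sample(nrow(eligible))) {
            a <- eligible[ai, ]
            len <- floor(stats::runif(1, params$arm_frac * a$len + m, a$len))
            start <- .place_in_gaps(.free_gaps(a$start, a$end, occ(a$chrom)),
                                    len)
            if (!is.na(start)) {
              push(a$chrom, start, start + len, dirs[i], "ANEUPLOIDY",
                   draw_ratio(dirs[i]))
              placed <- TRUE
              break
            }
          }
          # at most one arm-level event fits per arm: demand beyond the free
          # arm supply is realized as a large sub-arm SCNA instead (the truth
          # table records realized classes)
          if (!placed) cls[i] <- "SCNA"
        }
        if (!placed) {
          for (ai in sample(nrow(arms))) {
            if (placed) break
            a <- arms[ai, ]
            blocked <- rbind(occ(a$chrom),
                             gene_zones[[a$chrom]] %||%
                               data.frame(start = numeric(), end = numeric()))
            gaps <- .free_gaps(a$start, a$end, blocked)
            max_gap <- max(c(0, gaps$end - gaps$start))
            # condition the length draw on the space actually available, so
            # crowded genomes receive smaller events instead of failing
            len <- if (cls[i] == "INDEL") {
              if (max_gap <= spec$indel_len_range[1]) next
              floor(stats::runif(1, spec$indel_len_range[1],
                                 min(spec$indel_len_range[2], max_gap)))
            } else {
              lo <- params$indel_max_bp + m
              hi <- min(params$arm_frac * a$len - m, max_gap)
              if (hi <= lo) next
              floor(.rlnorm_trunc(1, spec$scna_len_meanlog,
                                  spec$scna_len_sdlog, lo, hi))
            }
            start <- .place_in_gaps(gaps, len)
            if (!is.na(start)) {
              push(a$chrom, start, start + len, dirs[i], cls[i],
                   draw_ratio(dirs[i]))
              placed <- TRUE
              break
            }
          }
        }
        if (!placed) {
          stop("event placement failed for sample ", sid, " (class ", cls[i],
               "); the cohort spec is infeasible on this genome")
        }
      }
    }

    # 3. neutral fillers (best effort)
    for (cc in unique(arms$chrom)) {
      ch_arms <- arms[arms$chrom == cc, , drop = FALSE]
      for (j in seq_len(spec$neutral_per_chrom)) {
        a <- ch_arms[sample.int(nrow(ch_arms), 1), ]
        len <- floor(stats::runif(1, spec$neutral_len_range[1],
                                  spec$neutral_len_range[2]))
        start <- .place_in_gaps(.free_gaps(a$start, a$end, occ(a$chrom)), len)
        if (!is.na(start)) {
          push(a$chrom, start, start + len, "NEUTRAL", "NEUTRAL",
               draw_ratio("NEUTRAL"))
        }
      }
    }

    sd_ev <- do.call(rbind, ev)
    if (!is.null(sd_ev)) {
      sd_ev <- sd_ev[order(chrom_rank(sd_ev$chrom, build), sd_ev$start), ,
                     drop = FALSE]
      all_rows[[si]] <- sd_ev
      truth_rows[[si]] <- sd_ev[sd_ev$direction != "NEUTRAL", , drop = FALSE]
    }
  }

  seg_all <- do.call(rbind, all_rows)
  rownames(seg_all) <- NULL
  segments <- data.frame(sample = seg_all$sample, chrom = seg_all$chrom,
                         start = seg_all$start, end = seg_all$end,
                         num_probes = pmax(2, round((seg_all$end - seg_all$start) / 5000)),
                         log2_ratio = seg_all$log2_ratio,
                         stringsAsFactors = FALSE)
  truth_events <- do.call(rbind, truth_rows)
  if (is.null(truth_events)) {
    truth_events <- seg_all[0, ]
  }
  truth_events$length <- truth_events$end - truth_events$start
  rownames(truth_events) <- NULL

  truth <- list(
    events = truth_events[, c("sample", "chrom", "start", "end", "length",
                              "log2_ratio", "direction", "class")],
    sample_summary = .truth_sample_summary(truth_events, annotations, build),
    gene_calls = incidence,
    pair_frequency = .truth_pairs(incidence, n_total),
    class_mix = .truth_class_mix(truth_events, annotations)
  )
  cohort <- structure(list(segments = segments, annotations = annotations,
                           genes = genes, build = build, truth = truth,
                           spec = spec),
                      class = "scna_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

# sums are exact unions because within-sample segments never overlap
.truth_sample_summary <- function(ev, annotations, build) {
  genome_len <- sum(build$chromosomes$length[
    build$chromosomes$chrom %in% build$analysis_set])
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    s <- annotations$sample[i]
    e <- ev[ev$sample == s, , drop = FALSE]
    cnt <- table(factor(e$direction, .DIRS), factor(e$class, .CLASSES))
    scna_amp <- e$length[e$direction == "AMP" & e$class == "SCNA"]
    scna_del <- e$length[e$direction == "DEL" & e$class == "SCNA"]
    data.frame(
      sample = s, tumor_type = annotations$tumor_type[i],
      n_amp_indel = cnt["AMP", "INDEL"], n_amp_scna = cnt["AMP", "SCNA"],
      n_amp_aneuploidy = cnt["AMP", "ANEUPLOIDY"],
      n_del_indel = cnt["DEL", "INDEL"], n_del_scna = cnt["DEL", "SCNA"],
      n_del_aneuploidy = cnt["DEL", "ANEUPLOIDY"],
      n_amp = sum(cnt["AMP", ]), n_del = sum(cnt["DEL", ]),
      pct_genome_amp = 100 * sum(e$length[e$direction == "AMP"]) / genome_len,
      pct_genome_del = 100 * sum(e$length[e$direction == "DEL"]) / genome_len,
      mean_scna_len_amp = if (length(scna_amp)) mean(scna_amp) else NA_real_,
      mean_scna_len_del = if (length(scna_del)) mean(scna_del) else NA_real_,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

.truth_class_mix <- function(ev, annotations) {
  tt <- annotations$tumor_type[match(ev$sample, annotations$sample)]
  rows <- lapply(sort(unique(annotations$tumor_type)), function(g) {
    cls <- ev$class[tt == g]
    n <- length(cls)
    pct <- if (n == 0) rep(NA_real_, 3) else
      100 * as.vector(table(factor(cls, .CLASSES))) / n
    data.frame(tumor_type = g, n_events = n, pct_indel = pct[1],
               pct_scna = pct[2], pct_aneuploidy = pct[3],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# combinatorial pair truth from the planted gene incidence
.truth_pairs <- function(incidence, n_total) {
  rows <- list()
  for (s in unique(incidence$sample)) {
    inc <- incidence[incidence$sample == s, , drop = FALSE]
    amp <- sort(inc$gene[inc$direction == "AMP"])
    del <- sort(inc$gene[inc$direction == "DEL"])
    pair_up <- function(g, type) {
      if (length(g) < 2) return(NULL)
      cmb <- utils::combn(g, 2)
      data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ], event_type = type,
                 stringsAsFactors = FALSE)
    }
    ad <- NULL
    if (length(amp) && length(del)) {
      gr <- expand.grid(a = amp, d = del, stringsAsFactors = FALSE)
      ad <- data.frame(gene_a = pmin(gr$a, gr$d), gene_b = pmax(gr$a, gr$d),
                       event_type = "AMP-DEL", stringsAsFactors = FALSE)
    }
    rows[[s]] <- rbind(pair_up(amp, "AMP-AMP"), pair_up(del, "DEL-DEL"), ad)
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev) || nrow(ev) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      event_type = character(), n = integer(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(ev$gene_a, ev$gene_b, ev$event_type, sep = "\r")
  agg <- unique(data.frame(gene_a = ev$gene_a, gene_b = ev$gene_b,
                           event_type = ev$event_type, key = key,
                           stringsAsFactors = FALSE))
  n <- as.vector(table(factor(key, levels = agg$key)))
  res <- agg[, c("gene_a", "gene_b", "event_type")]
  res$n <- n
  res$frequency <- n / n_total
  res <- res[order(res$event_type, -res$frequency, res$gene_a, res$gene_b), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a synthetic cohort to disk
#'
#' Emits exactly the formats the readers consume plus the truth tables.
#'
#' @param cohort An `scna_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    segments = file.path(dir, "segments.seg"),
    annotations = file.path(dir, "annotations.tsv"),
    genes = file.path(dir, "genes.bed"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    arms = file.path(dir, "arms.tsv"))
  write_seg(cohort$segments, paths["segments"])
  write_table(cohort$annotations, paths["annotations"], keys = "sample")
  write_gene_census(cohort$genes, paths["genes"])
  write_genome(cohort$build, paths["chrom_sizes"], paths["arms"])
  tr <- cohort$truth
  tpaths <- c(file.path(dir, "truth_events.tsv"),
              file.path(dir, "truth_sample.tsv"),
              file.path(dir, "truth_gene_calls.tsv"),
              file.path(dir, "truth_pairs.tsv"),
              file.path(dir, "truth_class_mix.tsv"))
  write_table(tr$events, tpaths[1], keys = c("sample", "chrom", "start"))
  write_table(tr$sample_summary, tpaths[2], keys = "sample")
  write_table(tr$gene_calls, tpaths[3], keys = c("sample", "gene"))
  write_table(tr$pair_frequency, tpaths[4],
              keys = c("event_type", "gene_a", "gene_b"))
  write_table(tr$class_mix, tpaths[5], keys = "tumor_type")
  invisible(c(paths, tpaths))
}

#' @export
print.scna_cohort <- function(x, ...) {
  cat("<scna_cohort> ", length(unique(x$annotations$sample)), " samples, ",
      length(unique(x$annotations$tumor_type)), " tumor types, ",
      nrow(x$segments), " segments (", nrow(x$truth$events),
      " true events)\n", sep = "")
  invisible(x)
}
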