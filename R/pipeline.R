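# Config-driven orchestration of the full analysis: nucleosome maps,
# dynamics, promoter NDRs, promoter HM states, enhancers, enhancer NDRs and
# the synergy table, with a machine-readable JSON run report.
#
# Stages are cached on a content hash of their parameters and input files:
# rerunning with unchanged inputs skips the stage. Log lines go to the
# console only, so output files are byte-identical across reruns.

REPORT_SCHEMA_VERSION <- "1.0"

#' Run the full chromatin-remodeling pipeline
#'
#' @param config either a list (see Details) or a path to a YAML file. A
#'   synthetic run needs `config$synthetic` (arguments to
#'   [synthetic_config()]); a real-data run needs `config$inputs` with paths
#'   `mnase_a`, `mnase_b`, `chip_<mark>_a/b`, `annotation`, `enhancers`
#'   (optional), `expression`, `chrom_sizes`. Stage parameters live under
#'   `config$params` (sigma, exclusion_bp, min_reads, tss_k, fc_min, fdr,
#'   ndr_k, seed, ...).
#' @param outdir output directory.
#' @param force rerun all stages even if cached.
#' @return an object of class `remodel_run`: the report list, invisibly
#'   augmented with output paths.
#' @export
run_pipeline <- function(config, outdir, force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- pipeline_params(config$params)
  report <- list(schema_version = REPORT_SCHEMA_VERSION,
                 package_version = as.character(
                   utils::packageVersion("remodelscan")),
                 params = p)

  # ---- stage: inputs ----------------------------------------------------
  indir <- file.path(outdir, "inputs")
  if (!is.null(config$synthetic)) {
    sc <- do.call(synthetic_config, config$synthetic)
    stage_run(outdir, "simulate", list(cfg = unclass(sc)), character(0),
              force, function() {
      sim <- simulate_chromatin(sc)
      write_simulation(sim, indir)
    })
    inputs <- synthetic_input_paths(indir, sc$states)
    states <- sc$states
    report$seed <- sc$seed
  } else if (!is.null(config$inputs)) {
    inputs <- config$inputs
    states <- config$states %||% c("A", "B")
    missing_in <- names(inputs)[!file.exists(unlist(inputs))]
    if (length(missing_in)) {
      stop("missing input file(s): ", paste(missing_in, collapse = ", "))
    }
  } else {
    stop("config must provide either $synthetic or $inputs")
  }
  for (req in c("mnase_a", "mnase_b", "annotation", "chrom_sizes")) {
    if (is.null(inputs[[req]])) stop("config is missing input: ", req)
  }

  genes <- read_annotation(inputs$annotation)
  cs <- read.table(inputs$chrom_sizes, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  chrom_sizes <- setNames(as.integer(cs$size), cs$chrom)

  tags_a <- read_tags(inputs$mnase_a)
  tags_b <- read_tags(inputs$mnase_b)
  dyads_a <- reads_to_dyads(tags_a, chrom_sizes)
  dyads_b <- reads_to_dyads(tags_b, chrom_sizes)

  # ---- stage: nucleosome maps ------------------------------------------
  calls_file <- function(st) file.path(outdir, sprintf("calls_%s.tsv", st))
  stage_run(outdir, "nucmap",
            list(sigma = p$sigma, excl = p$exclusion_bp, mr = p$min_reads),
            c(inputs$mnase_a, inputs$mnase_b), force, function() {
    ca <- call_nucleosomes(dyads_a, p$sigma, p$exclusion_bp, p$min_reads,
                           total_reads = nrow(tags_a),
                           chrom_sizes = chrom_sizes)
    cb <- call_nucleosomes(dyads_b, p$sigma, p$exclusion_bp, p$min_reads,
                           total_reads = nrow(tags_b),
                           chrom_sizes = chrom_sizes)
    write_tsv(as.data.frame(ca), calls_file(states[1]))
    write_tsv(as.data.frame(cb), calls_file(states[2]))
  })
  calls_a <- read.table(calls_file(states[1]), header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  calls_b <- read.table(calls_file(states[2]), header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  report$n_calls <- setNames(c(nrow(calls_a), nrow(calls_b)), states)

  # ---- stage: dynamics --------------------------------------------------
  matches <- match_nucleosomes(calls_a, calls_b)
  write_tsv(as.data.frame(matches), file.path(outdir, "matches.tsv"))
  ms <- summary(matches)
  report$dynamics <- list(counts = as.list(ms$counts),
                          fractions_union = as.list(ms$fractions_union),
                          n_union = ms$n_union, n_a = ms$n_a, n_b = ms$n_b)

  # ---- stage: TSS clustering -------------------------------------------
  if (nrow(genes) >= p$tss_k) {
    ma <- tss_matrix(dyads_a, genes, chrom_sizes, "occupancy",
                     bin_bp = p$tss_bin_bp, total_reads = nrow(tags_a))
    mb <- tss_matrix(dyads_b, genes, chrom_sizes, "occupancy",
                     bin_bp = p$tss_bin_bp, total_reads = nrow(tags_b))
    cl <- tss_difference_clusters(ma, mb, k = p$tss_k, seed = p$seed)
    write_tsv(data.frame(gene_id = names(cl$labels), cluster = cl$labels),
              file.path(outdir, "tss_clusters.tsv"))
    report$tss_clusters <- list(k = p$tss_k, degenerate = cl$degenerate,
                                sizes = as.list(table(cl$labels)))
  }

  # ---- stage: promoter NDR ---------------------------------------------
  ndr_a <- promoter_ndr_occupancy(dyads_a, genes, chrom_sizes, nrow(tags_a))
  ndr_b <- promoter_ndr_occupancy(dyads_b, genes, chrom_sizes, nrow(tags_b))
  ndr_tab <- data.frame(gene_id = ndr_a$gene_id,
                        occupancy_a = ndr_a$occupancy,
                        occupancy_b = ndr_b$occupancy)
  names(ndr_tab)[2:3] <- paste0("occupancy_", states)
  write_tsv(ndr_tab, file.path(outdir, "promoter_ndr.tsv"))
  if (!is.null(inputs$expression)) {
    expr <- read_expression(inputs$expression)
    fa <- paste0("fpkm_", states[1]); fb <- paste0("fpkm_", states[2])
    if (all(c(fa, fb) %in% names(expr)) && nrow(expr) >= 3) {
      assoc_a <- ndr_expression_association(
        data.frame(gene_id = ndr_a$gene_id, occupancy = ndr_a$occupancy),
        data.frame(gene_id = expr$gene_id, fpkm = expr[[fa]]))
      assoc_b <- ndr_expression_association(
        data.frame(gene_id = ndr_b$gene_id, occupancy = ndr_b$occupancy),
        data.frame(gene_id = expr$gene_id, fpkm = expr[[fb]]))
      report$ndr_expression <- setNames(
        list(list(rho = assoc_a$rho, p = assoc_a$p_value),
             list(rho = assoc_b$rho, p = assoc_b$p_value)), states)
    }
  }

  # ---- stage: promoter HM states ---------------------------------------
  marks <- p$marks[vapply(p$marks, function(m)
    !is.null(inputs[[sprintf("chip_%s_a", m)]]), logical(1))]
  if (length(marks) && nrow(genes)) {
    lv_a <- lv_b <- matrix(0, nrow(genes), length(marks),
                           dimnames = list(genes$gene_id, marks))
    for (m in marks) {
      ta <- read_tags(inputs[[sprintf("chip_%s_a", m)]])
      tb <- read_tags(inputs[[sprintf("chip_%s_b", m)]])
      lv_a[, m] <- promoter_mark_levels(ta, genes, nrow(ta))
      lv_b[, m] <- promoter_mark_levels(tb, genes, nrow(tb))
    }
    thresholds <- lapply(marks, function(m)
      mark_threshold(c(lv_a[, m], lv_b[, m]), m, seed = p$seed))
    names(thresholds) <- marks
    st_a <- assign_promoter_states(lv_a, thresholds)
    st_b <- assign_promoter_states(lv_b, thresholds)
    trans <- state_transitions(st_a$state, st_b$state)
    fc <- cluster_mark_fold_changes(lv_a, lv_b, fc_min = p$fc_min,
                                    k = p$hm_k, seed = p$seed)
    hm_tab <- data.frame(gene_id = genes$gene_id, state_a = st_a$state,
                         state_b = st_b$state,
                         bivalent_a = st_a$bivalent, bivalent_b = st_b$bivalent)
    write_tsv(hm_tab, file.path(outdir, "promoter_hm_states.tsv"))
    write_tsv(as.data.frame(trans), file.path(outdir, "hm_transitions.tsv"))
    report$hm <- list(
      thresholds = lapply(thresholds, function(t)
        list(method = t$method, value = t$value)),
      n_bivalent = setNames(list(sum(st_a$bivalent), sum(st_b$bivalent)),
                            states),
      fc_clusters = if (!fc$empty) as.list(table(fc$labels)) else list(),
      n_fc_genes = sum(fc$selected))
    gain_modes <- lapply(intersect(c("H3K4me3", "H3K9ac"), marks),
                         function(m) {
      table(classify_gain_mode(lv_a[, m], lv_b[, m], thresholds[[m]],
                               fc_min = p$fc_min))
    })
    names(gain_modes) <- intersect(c("H3K4me3", "H3K9ac"), marks)
    report$gain_modes <- lapply(gain_modes, as.list)
  }

  # ---- stage: enhancers -------------------------------------------------
  if (all(c("H3K4me1", "H3K27ac", "H3K4me3") %in% marks)) {
    k4me1_a <- read_tags(inputs$chip_H3K4me1_a)
    k4me1_b <- read_tags(inputs$chip_H3K4me1_b)
    k27ac_a <- read_tags(inputs$chip_H3K27ac_a)
    k27ac_b <- read_tags(inputs$chip_H3K27ac_b)
    k4me3 <- list(read_tags(inputs$chip_H3K4me3_a),
                  read_tags(inputs$chip_H3K4me3_b))
    names(k4me3) <- states
    pk_a <- call_mark_peaks(k4me1_a, chrom_sizes, p$peak_window_bp,
                            p$peak_step_bp, p$fdr)
    pk_b <- call_mark_peaks(k4me1_b, chrom_sizes, p$peak_window_bp,
                            p$peak_step_bp, p$fdr)
    merged <- merge_peak_sets(pk_a, pk_b)
    report$enhancers <- list(n_peaks = setNames(
      list(nrow(pk_a), nrow(pk_b)), states), n_merged = nrow(merged))
    if (nrow(merged) >= 100L) {
      filt <- filter_peaks_to_enhancers(merged, k4me3, seed = p$seed)
      enh <- filt$enhancers
      report$enhancers$k4me3_threshold <- filt$threshold
      report$enhancers$n_enhancers <- nrow(enh)
      if (nrow(enh) >= 10L) {
        bg1 <- background_threshold(k4me1_b, chrom_sizes, nrow(enh),
                                    seed = p$seed, total = nrow(k4me1_b))
        bg2 <- background_threshold(k27ac_b, chrom_sizes, nrow(enh),
                                    seed = p$seed + 1L,
                                    total = nrow(k27ac_b))
        t_k4 <- bg1$threshold; t_k27 <- bg2$threshold
        enh_iv <- peak_signal_intervals(enh)
        k4l <- cbind(interval_rpkm(k4me1_a, enh_iv, nrow(k4me1_a)),
                     interval_rpkm(k4me1_b, enh_iv, nrow(k4me1_b)))
        k27l <- cbind(interval_rpkm(k27ac_a, enh_iv, nrow(k27ac_a)),
                      interval_rpkm(k27ac_b, enh_iv, nrow(k27ac_b)))
        colnames(k4l) <- colnames(k27l) <- states
        cls <- classify_enhancer_states(k4l, k27l, t_k4, t_k27)
        ng <- assign_nearest_gene(enh, genes)
        enh_out <- cbind(enh, state_a = cls$states[, 1L],
                         state_b = cls$states[, 2L], ng)
        write_tsv(enh_out, file.path(outdir, "enhancers.tsv"))
        report$enhancers$thresholds <- list(k4me1 = t_k4, k27ac = t_k27)
        report$enhancers$states <- list(
          a = as.list(table(cls$states[, 1L])),
          b = as.list(table(cls$states[, 2L])))

        # enhancer NDRs in state-B-active enhancers
        active_b <- enh[cls$states[, 2L] == "active", , drop = FALSE]
        if (nrow(active_b)) {
          active_b$enhancer_id <- sprintf("enh%d",
                                          which(cls$states[, 2L] == "active"))
          ndrs <- scan_enhancer_ndrs(active_b, calls_b)
          write_tsv(ndrs, file.path(outdir, "enhancer_ndrs.tsv"))
          report$enhancer_ndrs <- list(
            n = nrow(ndrs),
            frac_150_250 = ndr_length_summary(ndrs)$frac_150_250)
          if (nrow(ndrs) >= 1L) {
            modes <- cluster_ndr_modes(ndrs, dyads_a, dyads_b, chrom_sizes,
                                       k = p$ndr_k, seed = p$seed)
            ndrs$mode <- modes$modes
            write_tsv(ndrs, file.path(outdir, "enhancer_ndrs.tsv"))
            report$enhancer_ndrs$modes <- as.list(table(modes$modes))
          }
        }

        # synergy
        if (!is.null(inputs$expression)) {
          expr <- read_expression(inputs$expression)
          fa <- paste0("fpkm_", states[1]); fb <- paste0("fpkm_", states[2])
          if (all(c(fa, fb) %in% names(expr))) {
            enh_fc <- log2((k27l[, 2L] + 1) / (k27l[, 1L] + 1))
            ei <- match(ng$gene_id, expr$gene_id)
            syn_in <- data.frame(
              gene_id = ng$gene_id,
              log2fc_expr = log2((expr[[fb]][ei] + 1) / (expr[[fa]][ei] + 1)),
              log2fc_enh_k27ac = enh_fc, stringsAsFactors = FALSE)
            syn_in <- syn_in[!is.na(syn_in$gene_id), , drop = FALSE]
            syn_in <- syn_in[!duplicated(syn_in$gene_id), , drop = FALSE]
            syn <- promoter_enhancer_synergy(syn_in, fc_min = p$synergy_fc_min)
            write_tsv(syn$table, file.path(outdir, "synergy.tsv"))
            report$synergy <- list(n = nrow(syn$table),
                                   n_up = length(syn$up),
                                   n_down = length(syn$down))
          }
        }
      }
    }
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(c(report, list(outdir = outdir)), class = "remodel_run")
}

#' @export
print.remodel_run <- function(x, ...) {
  cat("remodelscan run ->", x$outdir, "\n")
  cat("  nucleosome calls:", paste(names(x$n_calls), unlist(x$n_calls),
                                   sep = "=", collapse = ", "), "\n")
  if (!is.null(x$dynamics)) {
    f <- x$dynamics$fractions_union
    cat(sprintf("  dynamics: fixed %.1f%% shift %.1f%% loss %.1f%% gain %.1f%%\n",
                100 * f$fixed, 100 * f$shift, 100 * f$loss, 100 * f$gain))
  }
  if (!is.null(x$enhancers$n_enhancers)) {
    cat("  enhancers:", x$enhancers$n_enhancers, "\n")
  }
  invisible(x)
}

pipeline_params <- function(params) {
  defaults <- list(sigma = 20, exclusion_bp = 147L, min_reads = 3L,
                   tss_bin_bp = 5L, tss_k = 5L, fc_min = 2, hm_k = 4L,
                   fdr = 0.001, peak_window_bp = 1000L, peak_step_bp = 100L,
                   ndr_k = 3L, synergy_fc_min = 1.5, seed = 1L,
                   marks = HM_MARKS)
  for (nm in names(params)) defaults[[nm]] <- params[[nm]]
  defaults
}

synthetic_input_paths <- function(indir, states) {
  inputs <- list(
    mnase_a = file.path(indir, sprintf("mnase_%s.bed", states[1])),
    mnase_b = file.path(indir, sprintf("mnase_%s.bed", states[2])),
    annotation = file.path(indir, "genes.tsv"),
    enhancers = file.path(indir, "enhancers.tsv"),
    expression = file.path(indir, "expression.tsv"),
    chrom_sizes = file.path(indir, "chrom_sizes.tsv"))
  for (m in HM_MARKS) {
    inputs[[sprintf("chip_%s_a", m)]] <-
      file.path(indir, sprintf("chip_%s_%s.bed", m, states[1]))
    inputs[[sprintf("chip_%s_b", m)]] <-
      file.path(indir, sprintf("chip_%s_%s.bed", m, states[2]))
  }
  inputs
}

# Run `fun` unless the stage's content hash (parameters + input file md5s)
# matches the cached hash from a previous run.
stage_run <- function(outdir, stage, params, input_files, force, fun) {
  hash_file <- file.path(outdir, sprintf(".%s.hash", stage))
  ins <- input_files[file.exists(input_files)]
  h <- paste(c(deparse(params), unname(tools::md5sum(ins))), collapse = "|")
  h <- paste(stage, nchar(h), sum(utf8ToInt(h) * seq_along(utf8ToInt(h))))
  if (!force && file.exists(hash_file) &&
      identical(readLines(hash_file, warn = FALSE), h)) {
    message("[remodelscan] stage '", stage, "' is up to date; skipping")
    return(invisible(FALSE))
  }
  message("[remodelscan] running stage '", stage, "'")
  t0 <- proc.time()[["elapsed"]]
  fun()
  message(sprintf("[remodelscan] stage '%s' done in %.1f s", stage,
                  proc.time()[["elapsed"]] - t0))
  writeLines(h, hash_file)
  invisible(TRUE)
}

#' Expression fold-change pass-through flag
#'
#' Differential-expression calling is upstream of this pipeline; expression
#' tables may carry a significance flag column which is passed through
#' unchanged by [read_expression()].
#' @name expression-passthrough
NULL
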