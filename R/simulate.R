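# Synthetic chromatin generator with planted, recorded ground truth.
#
# The generator emits aligned tag coordinates directly (the pipeline starts
# at uniquely mapped reads), for two cell states ("NSC" -> "neuron" by
# default):
#   * a genome-wide nucleosome array (blocks of nucleosomes at the
#     configured repeat length, separated by short boundary linkers) whose
#     blocks carry fixed / shift / loss / gain dynamics labels; shift blocks
#     move coherently by one uniform draw from the shift range, as chromatin
#     remodeling acts on runs of nucleosomes;
#   * canonical promoter architecture per gene: phased -1/+1 arrays around a
#     nucleosome-depleted region (NDR) at [-200, +50], with a configurable
#     gene subset whose NDR is occupied in state A and evicted in state B;
#   * enhancers with local nucleosome arrays; a subset hosts a planted NDR
#     formed by eviction or a coherent 5'/3' shift of the central
#     nucleosome in state B;
#   * bimodal promoter histone-mark levels, enhancer active/poised/off
#     states, and expression coupled to planted promoter-NDR occupancy.
#
# Every random draw comes from a named RNG stream derived from the master
# seed, so adding a mark or state never perturbs the other outputs.

#' Build a synthetic-genome configuration
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes total genes (split across chromosomes).
#' @param n_enhancers total enhancers.
#' @param spacing_mean nucleosome repeat length within arrays (bp).
#' @param fuzziness_bp standard deviation of read dyads around a planted
#'   dyad.
#' @param coverage expected reads per planted nucleosome.
#' @param dynamics_fractions named proportions over fixed/shift/loss/gain
#'   (sum to 1).
#' @param shift_range inclusive bp interval for planted shift magnitudes
#'   (within [1, 127]).
#' @param ndr_mode_fractions named proportions over eviction/shift5/shift3.
#' @param mark_bimodal_params per-mark list(low_mean, low_sd, high_mean,
#'   high_sd, weight); `weight` is the marked fraction.
#' @param expression_coupling slope linking planted promoter-NDR occupancy
#'   to log2 FPKM (>= 0).
#' @param expression_baseline baseline log2(FPKM + 1).
#' @param expression_noise_sd Gaussian noise on log2(FPKM + 1).
#' @param ndr_occupied_frac fraction of genes whose promoter NDR is occupied
#'   in state A and free in state B.
#' @param ndr_enhancer_frac fraction of enhancers hosting a planted NDR.
#' @param mark_flip_prob per-mark probability that a promoter's marked
#'   status flips between states.
#' @param reads_per_rpkm expected ChIP reads per kb per RPKM unit of
#'   planted level.
#' @param chip_background_per_kb uniform ChIP background reads per kb.
#' @param mnase_background_per_kb uniform MNase background reads per kb.
#' @param block_size nucleosomes per dynamics block.
#' @param linker_bp extra linker between adjacent blocks (bp,
#'   center-to-center gap = linker_bp).
#' @param enh_spacing nucleosome repeat inside enhancer arrays.
#' @param enh_shift_bp coherent shift magnitude forming enhancer NDRs.
#' @param enhancer_width enhancer element width (bp).
#' @param synergy_effect log2 expression offset applied to
#'   enhancer-synergy genes.
#' @param states names of the two cell states (A then B).
#' @param seed master integer seed.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_chroms = 2L, chrom_length = 5e5,
                             n_genes = 150L, n_enhancers = 60L,
                             spacing_mean = 180L, fuzziness_bp = 20,
                             coverage = 20,
                             dynamics_fractions = c(fixed = 0.10,
                                                    shift = 0.80,
                                                    loss = 0.05,
                                                    gain = 0.05),
                             shift_range = c(1L, 120L),
                             ndr_mode_fractions = c(eviction = 1 / 3,
                                                    shift5 = 1 / 3,
                                                    shift3 = 1 / 3),
                             mark_bimodal_params = default_mark_params(),
                             expression_coupling = 1,
                             expression_baseline = 5,
                             expression_noise_sd = 0.3,
                             ndr_occupied_frac = 0.5,
                             ndr_enhancer_frac = 0.5,
                             mark_flip_prob = 0.15,
                             reads_per_rpkm = 2,
                             chip_background_per_kb = 1,
                             mnase_background_per_kb = 0,
                             block_size = 10L, linker_bp = 350L,
                             enh_spacing = 280L, enh_shift_bp = 120L,
                             enhancer_width = 1000L,
                             synergy_effect = 2.5,
                             states = c("NSC", "neuron"), seed = 1L) {
  cfg <- as.list(environment())
  validate_fractions(dynamics_fractions, "dynamics_fractions")
  validate_fractions(ndr_mode_fractions, "ndr_mode_fractions")
  if (!identical(sort(names(dynamics_fractions)),
                 sort(c("fixed", "shift", "loss", "gain")))) {
    stop("dynamics_fractions must be named fixed/shift/loss/gain")
  }
  if (coverage <= 0) stop("coverage must be positive")
  if (shift_range[1] < 1 || shift_range[2] > 127 ||
      shift_range[1] > shift_range[2]) {
    stop("shift_range must lie within [1, 127]")
  }
  if (ndr_occupied_frac < 0 || ndr_occupied_frac > 1) {
    stop("ndr_occupied_frac must lie in [0, 1]")
  }
  if (length(states) != 2L) stop("exactly two cell states required")
  structure(cfg, class = "synthetic_config")
}

#' Default bimodal promoter-mark level parameters
#'
#' H3K4me1/H3K4me3/H3K9ac/H3K27ac are well-separated two-mode mixtures;
#' H3K27me3 modes are close enough that its promoter level density is
#' effectively unimodal, which exercises the K-means threshold fallback.
#' Enhancer-level parameters (`enh_*`) set the H3K4me1 "on" and H3K27ac
#' "active" signal against the off/background level.
#' @export
default_mark_params <- function() {
  list(
    H3K4me1 = list(low_mean = 1.2, low_sd = 0.6, high_mean = 12, high_sd = 2.5,
                   weight = 0.45),
    H3K4me3 = list(low_mean = 2, low_sd = 1, high_mean = 24, high_sd = 5,
                   weight = 0.50),
    H3K9ac = list(low_mean = 2, low_sd = 1, high_mean = 22, high_sd = 4,
                  weight = 0.50),
    H3K27ac = list(low_mean = 1.2, low_sd = 0.6, high_mean = 10, high_sd = 2,
                   weight = 0.40),
    H3K27me3 = list(low_mean = 3, low_sd = 1.5, high_mean = 8, high_sd = 2,
                    weight = 0.35),
    enh_k4me1_on = list(mean = 40, sd = 4),
    enh_k27ac_on = list(mean = 40, sd = 4),
    enh_low = list(mean = 0.2, sd = 0.1)
  )
}

#' Build the synthetic annotation: genes, enhancers, chromosome sizes
#'
#' Elements (genes and enhancers) are shuffled into evenly spaced slots per
#' chromosome with a small positional jitter, which guarantees
#' non-overlapping +/- 1 kb promoters and keeps every enhancer >= 2 kb from
#' every TSS. Strands are drawn at random; gene bodies (TSS to TES) span
#' 1-2 kb.
#'
#' @param config a `synthetic_config`.
#' @return list: `genes` (gene_id, chrom, strand, tss, tes), `enhancers`
#'   (enhancer_id, chrom, start, end), `chrom_sizes` (named vector).
#' @export
build_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  chrom_sizes <- setNames(rep(as.integer(config$chrom_length),
                              config$n_chroms), chroms)
  total <- config$n_genes + config$n_enhancers
  genes <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tss = integer(), tes = integer(),
                      stringsAsFactors = FALSE)
  enhancers <- data.frame(enhancer_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          stringsAsFactors = FALSE)
  if (total > 0L) {
    margin <- 5000L
    per_chrom <- diff(round(seq(0, total, length.out = config$n_chroms + 1L)))
    res <- with_stream(config$seed, "annotation", expr = {
      types <- sample(c(rep("gene", config$n_genes),
                        rep("enhancer", config$n_enhancers)))
      rows <- list()
      idx <- 0L
      for (ci in seq_along(chroms)) {
        n_slot <- per_chrom[ci]
        if (n_slot == 0L) next
        slot_w <- (config$chrom_length - 2 * margin) / n_slot
        if (slot_w < 4600) {
          stop("chromosome too short to host the requested elements ",
               "(slot width ", round(slot_w), " bp < 4600 bp)")
        }
        centers <- round(margin + (seq_len(n_slot) - 0.5) * slot_w +
                           runif(n_slot, -200, 200))
        for (j in seq_len(n_slot)) {
          idx <- idx + 1L
          rows[[idx]] <- list(type = types[idx], chrom = chroms[ci],
                              center = centers[j],
                              strand = if (runif(1) < 0.5) "+" else "-",
                              body = round(runif(1, 1000, 2000)))
        }
      }
      rows
    })
    gi <- 0L; ei <- 0L
    for (r in res) {
      if (r$type == "gene") {
        gi <- gi + 1L
        tes <- if (r$strand == "+") r$center + r$body else r$center - r$body
        genes <- rbind(genes, data.frame(
          gene_id = sprintf("g%04d", gi), chrom = r$chrom, strand = r$strand,
          tss = as.integer(r$center), tes = as.integer(tes),
          stringsAsFactors = FALSE))
      } else {
        ei <- ei + 1L
        half <- config$enhancer_width %/% 2L
        enhancers <- rbind(enhancers, data.frame(
          enhancer_id = sprintf("e%03d", ei), chrom = r$chrom,
          start = as.integer(r$center - half),
          end = as.integer(r$center - half + config$enhancer_width),
          stringsAsFactors = FALSE))
      }
    }
  }
  genes <- genes[order(genes$chrom, genes$tss), , drop = FALSE]
  rownames(genes) <- NULL
  enhancers <- enhancers[order(enhancers$chrom, enhancers$start), , drop = FALSE]
  rownames(enhancers) <- NULL
  list(genes = genes, enhancers = enhancers, chrom_sizes = chrom_sizes)
}

#' Plant the full ground truth
#'
#' Places the genome-wide nucleosome array with block-level dynamics labels
#' (exact label quotas over blocks, shuffled under the seed; shift blocks
#' draw one signed magnitude uniformly from `shift_range`), the canonical
#' promoter architecture (phased flanks around an NDR at [-200, +50], with
#' the configured subset NDR-occupied in state A only), enhancer-local
#' arrays with planted NDR modes, promoter mark states, enhancer chromatin
#' states, and the enhancer-synergy gene set.
#'
#' @param annotation output of [build_annotation()].
#' @param config the `synthetic_config`.
#' @return a `synthetic_truth` list; see Details.
#' @export
plant_nucleosome_truth <- function(annotation, config) {
  genes <- annotation$genes
  enhancers <- annotation$enhancers
  chrom_sizes <- annotation$chrom_sizes
  spacing <- config$spacing_mean

  # --- reserved zones: promoters and enhancer neighborhoods -------------
  reserved <- list()
  for (i in seq_len(nrow(genes))) {
    reserved[[length(reserved) + 1L]] <- c(genes$chrom[i],
                                           genes$tss[i] - 1100L,
                                           genes$tss[i] + 1100L)
  }
  for (i in seq_len(nrow(enhancers))) {
    reserved[[length(reserved) + 1L]] <- c(enhancers$chrom[i],
                                           enhancers$start[i] - 300L,
                                           enhancers$end[i] + 300L)
  }
  in_reserved <- function(ch, pos) {
    for (r in reserved) {
      if (r[1] == ch && pos >= as.numeric(r[2]) && pos < as.numeric(r[3])) {
        return(TRUE)
      }
    }
    FALSE
  }

  nuc <- list()
  add_nuc <- function(chrom, dyad_a, dyad_b, label, context, weight = 1) {
    nuc[[length(nuc) + 1L]] <<- data.frame(
      chrom = chrom, dyad_a = dyad_a, dyad_b = dyad_b, label = label,
      context = context, weight = weight, stringsAsFactors = FALSE)
  }

  # --- genome-wide block array ------------------------------------------
  with_stream(config$seed, "nucleosome-truth", expr = {
    for (ch in names(chrom_sizes)) {
      len <- as.numeric(chrom_sizes[[ch]])
      # block layout: block_size dyads at `spacing`, then a linker
      block_span <- (config$block_size - 1L) * spacing + config$linker_bp
      pos <- 90
      blocks <- list()
      while (pos + (config$block_size - 1L) * spacing < len - 90) {
        dy <- pos + (seq_len(config$block_size) - 1L) * spacing
        dy <- dy[!vapply(dy, function(p) in_reserved(ch, p), logical(1))]
        if (length(dy)) blocks[[length(blocks) + 1L]] <- dy
        pos <- pos + block_span
      }
      nb <- length(blocks)
      if (nb == 0L) next
      quota <- floor(nb * config$dynamics_fractions)
      quota["shift"] <- quota["shift"] + (nb - sum(quota))
      labels <- sample(rep(names(quota), quota))
      for (bi in seq_len(nb)) {
        dy <- as.integer(round(blocks[[bi]]))
        lab <- labels[bi]
        if (lab == "fixed") {
          add_nuc(ch, dy, dy, "fixed", "array")
        } else if (lab == "loss") {
          add_nuc(ch, dy, NA_integer_, "loss", "array")
        } else if (lab == "gain") {
          add_nuc(ch, NA_integer_, dy, "gain", "array")
        } else {
          mag <- sample(seq.int(config$shift_range[1], config$shift_range[2]),
                        1L)
          u <- if (runif(1) < 0.5) -mag else mag
          add_nuc(ch, dy, dy + u, "shift", "array")
        }
      }
    }

    # --- canonical promoter architecture --------------------------------
    ndr_occupied <- if (nrow(genes)) {
      setNames(runif(nrow(genes)) < config$ndr_occupied_frac, genes$gene_id)
    } else logical(0)
    ndr_occ_level <- if (nrow(genes)) {
      setNames(ifelse(ndr_occupied, runif(nrow(genes), 1, 2), 0),
               genes$gene_id)
    } else numeric(0)
    for (i in seq_len(nrow(genes))) {
      sgn <- if (genes$strand[i] == "+") 1L else -1L
      up <- -seq.int(270L, 990L, by = spacing)
      down <- seq.int(75L, 990L, by = spacing)
      rel <- c(up, down)
      dy <- as.integer(genes$tss[i] + sgn * rel)
      add_nuc(genes$chrom[i], dy, dy, "fixed", "promoter")
      if (ndr_occupied[[genes$gene_id[i]]]) {
        nd <- as.integer(genes$tss[i] + sgn * (-75L))
        add_nuc(genes$chrom[i], nd, NA_integer_, "loss", "promoter_ndr",
                weight = ndr_occ_level[[genes$gene_id[i]]])
      }
    }

    # --- enhancer arrays and planted NDR modes --------------------------
    n_enh <- nrow(enhancers)
    ndr_host <- if (n_enh) runif(n_enh) < config$ndr_enhancer_frac else logical(0)
    modes <- rep(NA_character_, n_enh)
    if (any(ndr_host)) {
      modes[ndr_host] <- sample(names(config$ndr_mode_fractions),
                                sum(ndr_host), replace = TRUE,
                                prob = config$ndr_mode_fractions)
    }
    enh_ndrs <- list()
    for (i in seq_len(n_enh)) {
      d0 <- as.integer((enhancers$start[i] + enhancers$end[i]) %/% 2L)
      offs <- seq.int(-2L, 2L) * config$enh_spacing
      for (o in offs) {
        dy <- d0 + as.integer(o)
        if (o == 0L && !is.na(modes[i])) {
          s <- config$enh_shift_bp
          if (modes[i] == "eviction") {
            add_nuc(enhancers$chrom[i], dy, NA_integer_, "loss", "enhancer")
            ndr <- c(d0 - config$enh_spacing + 74L, d0 + config$enh_spacing - 73L)
          } else if (modes[i] == "shift5") {
            add_nuc(enhancers$chrom[i], dy, dy - s, "shift", "enhancer")
            ndr <- c(d0 - s + 74L, d0 + config$enh_spacing - 73L)
          } else {
            add_nuc(enhancers$chrom[i], dy, dy + s, "shift", "enhancer")
            ndr <- c(d0 - config$enh_spacing + 74L, d0 + s - 73L)
          }
          enh_ndrs[[length(enh_ndrs) + 1L]] <- data.frame(
            enhancer_id = enhancers$enhancer_id[i], chrom = enhancers$chrom[i],
            start = ndr[1], end = ndr[2], mode = modes[i],
            stringsAsFactors = FALSE)
        } else {
          add_nuc(enhancers$chrom[i], dy, dy, "fixed", "enhancer")
        }
      }
    }
    enh_ndrs <- if (length(enh_ndrs)) do.call(rbind, enh_ndrs) else
      data.frame(enhancer_id = character(), chrom = character(),
                 start = integer(), end = integer(), mode = character(),
                 stringsAsFactors = FALSE)

    # --- promoter mark truth --------------------------------------------
    marks <- HM_MARKS
    pm <- NULL
    if (nrow(genes)) {
      pm <- expand.grid(gene_id = genes$gene_id, mark = marks,
                        stringsAsFactors = FALSE)
      w <- vapply(pm$mark, function(m)
        config$mark_bimodal_params[[m]]$weight, numeric(1))
      pm$marked_a <- runif(nrow(pm)) < w
      flip <- runif(nrow(pm)) < config$mark_flip_prob
      pm$marked_b <- xor(pm$marked_a, flip)
    } else {
      pm <- data.frame(gene_id = character(), mark = character(),
                       marked_a = logical(), marked_b = logical(),
                       stringsAsFactors = FALSE)
    }

    # --- enhancer state truth -------------------------------------------
    est <- data.frame(enhancer_id = enhancers$enhancer_id,
                      state_a = character(n_enh), state_b = character(n_enh),
                      ndr_host = ndr_host, ndr_mode = modes,
                      stringsAsFactors = FALSE)
    if (n_enh) {
      est$state_a <- sample(c("active", "poised", "off"), n_enh,
                            replace = TRUE, prob = c(0.5, 0.3, 0.2))
      stay <- runif(n_enh) < 0.7
      est$state_b <- ifelse(stay, est$state_a,
                            sample(c("active", "poised", "off"), n_enh,
                                   replace = TRUE))
      # NDR hosts are active in neurons; ~75% were already active in NSCs
      est$state_b[ndr_host] <- "active"
      est$state_a[ndr_host] <- ifelse(runif(sum(ndr_host)) < 0.75, "active",
                                      sample(c("poised", "off"),
                                             sum(ndr_host), replace = TRUE))
    }

    # --- synergy gene set ------------------------------------------------
    synergy <- data.frame(gene_id = character(), enhancer_id = character(),
                          sign = integer(), stringsAsFactors = FALSE)
    if (n_enh && nrow(genes)) {
      nearest <- assign_nearest_gene(enhancers, genes)
      k27_a <- est$state_a == "active"
      k27_b <- est$state_b == "active"
      chg <- which(k27_a != k27_b & !is.na(nearest$gene_id))
      if (length(chg)) {
        synergy <- data.frame(gene_id = nearest$gene_id[chg],
                              enhancer_id = enhancers$enhancer_id[chg],
                              sign = ifelse(k27_b[chg], 1L, -1L),
                              stringsAsFactors = FALSE)
        synergy <- synergy[!duplicated(synergy$gene_id), , drop = FALSE]
      }
    }

    nucleosomes <- do.call(rbind, nuc)
    if (is.null(nucleosomes)) {
      nucleosomes <- data.frame(chrom = character(), dyad_a = integer(),
                                dyad_b = integer(), label = character(),
                                context = character(), weight = numeric(),
                                stringsAsFactors = FALSE)
    }
    nucleosomes <- nucleosomes[order(nucleosomes$chrom,
                                     ifelse(is.na(nucleosomes$dyad_a),
                                            nucleosomes$dyad_b,
                                            nucleosomes$dyad_a)), ,
                               drop = FALSE]
    rownames(nucleosomes) <- NULL
    structure(list(nucleosomes = nucleosomes,
                   ndr_occupancy = ndr_occ_level,
                   promoter_marks = pm,
                   enhancer_states = est,
                   enhancer_ndrs = enh_ndrs,
                   synergy = synergy,
                   fuzziness_bp = config$fuzziness_bp),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  n <- x$nucleosomes
  cat("Synthetic truth:", nrow(n), "planted nucleosomes\n")
  if (nrow(n)) print(table(n$label, n$context))
  cat(" ", nrow(x$enhancer_ndrs), "planted enhancer NDRs;",
      nrow(x$synergy), "synergy genes\n")
  invisible(x)
}

#' Sample MNase tags from the planted nucleosome map
#'
#' Per planted nucleosome present in the requested state: Poisson(coverage x
#' weight) reads, dyads Normal(planted dyad, fuzziness) rounded, strand
#' uniform, 5' position back-computed as dyad - 73 (+) or dyad + 73 (-).
#' Reads whose 147-bp extension would leave the chromosome are dropped.
#'
#' @param truth a `synthetic_truth`.
#' @param config the `synthetic_config`.
#' @param cell_state 1 or 2 (state A or B), or a state name.
#' @param chrom_sizes named chromosome lengths.
#' @return a `tag_set` data.frame.
#' @export
sample_mnase_reads <- function(truth, config, cell_state, chrom_sizes) {
  si <- state_index(config, cell_state)
  nucs <- truth$nucleosomes
  dy <- if (si == 1L) nucs$dyad_a else nucs$dyad_b
  present <- !is.na(dy)
  with_stream(config$seed, "mnase", si, expr = {
    n_reads <- rpois(sum(present), config$coverage * nucs$weight[present])
    dyad0 <- rep(dy[present], n_reads)
    chrom <- rep(nucs$chrom[present], n_reads)
    rdy <- as.integer(round(rnorm(length(dyad0), dyad0,
                                  config$fuzziness_bp)))
    strand <- ifelse(runif(length(rdy)) < 0.5, "+", "-")
    # background tags, uniform over the genome
    if (config$mnase_background_per_kb > 0) {
      for (ch in names(chrom_sizes)) {
        nb <- rpois(1L, config$mnase_background_per_kb *
                      chrom_sizes[[ch]] / 1000)
        if (nb > 0L) {
          bd <- as.integer(sample.int(as.integer(chrom_sizes[[ch]]), nb,
                                      replace = TRUE) - 1L)
          rdy <- c(rdy, bd)
          chrom <- c(chrom, rep(ch, nb))
          strand <- c(strand, ifelse(runif(nb) < 0.5, "+", "-"))
        }
      }
    }
    len <- unname(chrom_sizes[chrom])
    ok <- rdy >= 73L & rdy <= len - 74L
    pos5 <- ifelse(strand[ok] == "+", rdy[ok] - 73L, rdy[ok] + 73L)
    as_tag_set(data.frame(chrom = chrom[ok], pos5 = as.integer(pos5),
                          strand = strand[ok], stringsAsFactors = FALSE))
  })
}

#' Sample ChIP tags for one histone mark and cell state
#'
#' Each promoter draws a true level from the mark's two-component mixture
#' according to its planted marked status; enhancers draw H3K4me1/H3K27ac
#' levels from their planted chromatin state ("on"/"active" = high mode),
#' and a low level for other marks. Reads are placed uniformly within the
#' element, count Poisson(level x width_kb x reads_per_rpkm), plus a uniform
#' genome-wide background.
#'
#' @inheritParams sample_mnase_reads
#' @param annotation output of [build_annotation()].
#' @param mark one of the five histone marks.
#' @return a `tag_set` with attribute `planted_levels` (list of promoter and
#'   enhancer level vectors).
#' @export
sample_hm_reads <- function(annotation, truth, config, mark, cell_state) {
  stopifnot(mark %in% HM_MARKS)
  si <- state_index(config, cell_state)
  genes <- annotation$genes
  enhancers <- annotation$enhancers
  chrom_sizes <- annotation$chrom_sizes
  mp <- config$mark_bimodal_params
  with_stream(config$seed, "chip", mark, si, expr = {
    chrom <- character(0); pos <- integer(0)
    prom_levels <- numeric(0); enh_levels <- numeric(0)
    if (nrow(genes)) {
      pm <- truth$promoter_marks
      pm <- pm[pm$mark == mark, , drop = FALSE]
      marked <- if (si == 1L) pm$marked_a else pm$marked_b
      marked <- marked[match(genes$gene_id, pm$gene_id)]
      p <- mp[[mark]]
      lvl <- ifelse(marked,
                    rnorm(nrow(genes), p$high_mean, p$high_sd),
                    rnorm(nrow(genes), p$low_mean, p$low_sd))
      lvl <- pmax(lvl, 0)
      prom_levels <- setNames(lvl, genes$gene_id)
      cnt <- rpois(nrow(genes), lvl * 2 * config$reads_per_rpkm)
      for (i in which(cnt > 0L)) {
        pp <- as.integer(genes$tss[i] - 1000L +
                           sample.int(2000L, cnt[i], replace = TRUE) - 1L)
        chrom <- c(chrom, rep(genes$chrom[i], cnt[i]))
        pos <- c(pos, pp)
      }
    }
    if (nrow(enhancers)) {
      est <- truth$enhancer_states
      st <- if (si == 1L) est$state_a else est$state_b
      lvl <- if (mark == "H3K4me1") {
        ifelse(st %in% c("active", "poised"),
               rnorm(nrow(enhancers), mp$enh_k4me1_on$mean,
                     mp$enh_k4me1_on$sd),
               rnorm(nrow(enhancers), mp$enh_low$mean, mp$enh_low$sd))
      } else if (mark == "H3K27ac") {
        ifelse(st == "active",
               rnorm(nrow(enhancers), mp$enh_k27ac_on$mean,
                     mp$enh_k27ac_on$sd),
               rnorm(nrow(enhancers), mp$enh_low$mean, mp$enh_low$sd))
      } else {
        rnorm(nrow(enhancers), mp$enh_low$mean, mp$enh_low$sd)
      }
      lvl <- pmax(lvl, 0)
      enh_levels <- setNames(lvl, enhancers$enhancer_id)
      w <- enhancers$end - enhancers$start
      cnt <- rpois(nrow(enhancers), lvl * w / 1000 * config$reads_per_rpkm)
      for (i in which(cnt > 0L)) {
        pp <- as.integer(enhancers$start[i] +
                           sample.int(w[i], cnt[i], replace = TRUE) - 1L)
        chrom <- c(chrom, rep(enhancers$chrom[i], cnt[i]))
        pos <- c(pos, pp)
      }
    }
    for (ch in names(chrom_sizes)) {
      nb <- rpois(1L, config$chip_background_per_kb *
                    chrom_sizes[[ch]] / 1000)
      if (nb > 0L) {
        chrom <- c(chrom, rep(ch, nb))
        pos <- c(pos, as.integer(sample.int(as.integer(chrom_sizes[[ch]]),
                                            nb, replace = TRUE) - 1L))
      }
    }
    strand <- ifelse(runif(length(pos)) < 0.5, "+", "-")
    # drop tags whose notional 50-bp read would leave the chromosome
    len <- unname(chrom_sizes[chrom])
    ok <- ifelse(strand == "+", pos <= len - 50L, pos >= 49L)
    out <- as_tag_set(data.frame(chrom = chrom[ok], pos5 = pos[ok],
                                 strand = strand[ok],
                                 stringsAsFactors = FALSE))
    attr(out, "planted_levels") <- list(promoter = prom_levels,
                                        enhancer = enh_levels)
    out
  })
}

#' Sample the expression table
#'
#' log2(FPKM + 1) = baseline - coupling x (planted NDR occupancy of the
#' state) + Gaussian noise; enhancer-synergy genes additionally receive a
#' state-B offset whose sign matches their enhancer's planted H3K27ac
#' change.
#'
#' @inheritParams sample_mnase_reads
#' @param annotation output of [build_annotation()].
#' @return data.frame gene_id, fpkm_a, fpkm_b (named after the states).
#' @export
sample_expression <- function(annotation, truth, config) {
  genes <- annotation$genes
  if (config$expression_coupling < 0) stop("expression_coupling must be >= 0")
  with_stream(config$seed, "expression", expr = {
    occ_a <- truth$ndr_occupancy[genes$gene_id]
    occ_b <- rep(0, nrow(genes))  # planted NDR nucleosomes are evicted in B
    la <- config$expression_baseline -
      config$expression_coupling * occ_a +
      rnorm(nrow(genes), 0, config$expression_noise_sd)
    lb <- config$expression_baseline -
      config$expression_coupling * occ_b +
      rnorm(nrow(genes), 0, config$expression_noise_sd)
    syn <- truth$synergy
    if (nrow(syn)) {
      j <- match(syn$gene_id, genes$gene_id)
      lb[j] <- la[j] + syn$sign * config$synergy_effect +
        rnorm(length(j), 0, config$expression_noise_sd / 2)
    }
    out <- data.frame(gene_id = genes$gene_id,
                      fpkm_a = pmax(2^la - 1, 0),
                      fpkm_b = pmax(2^lb - 1, 0),
                      stringsAsFactors = FALSE)
    names(out)[2:3] <- paste0("fpkm_", config$states)
    out
  })
}

state_index <- function(config, cell_state) {
  if (is.character(cell_state)) {
    si <- match(cell_state, config$states)
    if (is.na(si)) stop("unknown cell state: ", cell_state)
    si
  } else {
    si <- as.integer(cell_state)
    if (!si %in% c(1L, 2L)) stop("cell_state must be 1, 2 or a state name")
    si
  }
}

#' Generate a complete synthetic data set
#'
#' Runs annotation, truth planting, MNase and ChIP sampling for both states
#' and all five marks, and the expression table.
#'
#' @param config a `synthetic_config`.
#' @param marks marks to sample ChIP tags for.
#' @return list of class `synthetic_dataset`: config, annotation, truth,
#'   mnase (list per state), chip (list mark -> state), expression.
#' @export
simulate_chromatin <- function(config = synthetic_config(),
                               marks = HM_MARKS) {
  ann <- build_annotation(config)
  truth <- plant_nucleosome_truth(ann, config)
  mnase <- lapply(1:2, function(si)
    sample_mnase_reads(truth, config, si, ann$chrom_sizes))
  names(mnase) <- config$states
  chip <- lapply(marks, function(m) {
    out <- lapply(1:2, function(si) sample_hm_reads(ann, truth, config, m, si))
    names(out) <- config$states
    out
  })
  names(chip) <- marks
  expression <- sample_expression(ann, truth, config)
  structure(list(config = config, annotation = ann, truth = truth,
                 mnase = mnase, chip = chip, expression = expression),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic chromatin data set\n")
  cat("  genome:", x$config$n_chroms, "x", x$config$chrom_length, "bp;",
      nrow(x$annotation$genes), "genes,", nrow(x$annotation$enhancers),
      "enhancers\n")
  cat("  planted nucleosomes:", nrow(x$truth$nucleosomes), "\n")
  cat("  MNase tags:", paste(sprintf("%s=%d", names(x$mnase),
                                     vapply(x$mnase, nrow, integer(1))),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic data set to disk
#'
#' Tags as BED6, annotation/truth/expression as TSV, the configuration as
#' YAML.
#'
#' @param sim a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  states <- sim$config$states
  for (st in states) {
    write_tags(sim$mnase[[st]], file.path(dir, sprintf("mnase_%s.bed", st)))
    for (m in names(sim$chip)) {
      write_tags(sim$chip[[m]][[st]],
                 file.path(dir, sprintf("chip_%s_%s.bed", m, st)),
                 read_length = 50L)
    }
  }
  write_tsv(sim$annotation$genes, file.path(dir, "genes.tsv"))
  write_tsv(sim$annotation$enhancers, file.path(dir, "enhancers.tsv"))
  write_tsv(data.frame(chrom = names(sim$annotation$chrom_sizes),
                       size = as.integer(sim$annotation$chrom_sizes)),
            file.path(dir, "chrom_sizes.tsv"))
  write_tsv(sim$truth$nucleosomes, file.path(dir, "truth_nucleosomes.tsv"))
  write_tsv(sim$truth$promoter_marks, file.path(dir, "truth_promoter_marks.tsv"))
  write_tsv(sim$truth$enhancer_states, file.path(dir, "truth_enhancer_states.tsv"))
  write_tsv(sim$truth$enhancer_ndrs, file.path(dir, "truth_enhancer_ndrs.tsv"))
  write_tsv(sim$expression, file.path(dir, "expression.tsv"))
  cfg <- sim$config
  cfg$mark_bimodal_params <- NULL  # nested lists go verbose in YAML; re-add
  yaml::write_yaml(c(unclass(cfg),
                     list(mark_bimodal_params = sim$config$mark_bimodal_params)),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
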