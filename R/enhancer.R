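# Enhancer identification and chromatin-state classification.
#
# H3K4me1-enriched regions are found with a Poisson sliding-window scan under
# Benjamini-Hochberg FDR control (a transparent re-implementation of the
# HOMER-style caller: the window size and FDR are the published parameters,
# the internals are exposed here). Promoter-like peaks are removed with a
# two-Gaussian mixture threshold on H3K4me3 signal; active/poised/off states
# are called against thresholds derived from random background regions.

#' Sliding-window Poisson peak calling with BH FDR
#'
#' Windows of `window_bp` advance by `step_bp`; each window's tag count is
#' tested against Poisson(genome-wide tag rate x window width), p-values are
#' Benjamini-Hochberg adjusted over all windows, and significant windows are
#' merged. Merged peaks closer than `merge_bp` are merged again (adjacent
#' peaks must be separated by at least that much). The peak score is its tag
#' count per kb per million mapped.
#'
#' @param tags tag data.frame (chrom, pos5, strand).
#' @param chrom_sizes named chromosome lengths (bp).
#' @param window_bp sliding window width.
#' @param step_bp window step.
#' @param fdr false-discovery-rate cutoff (0.001 = 0.1%).
#' @param merge_bp minimum separation between distinct peaks.
#' @param total total mapped tags (defaults to `nrow(tags)`).
#' @return data.frame chrom, start, end, score, count.
#' @export
call_mark_peaks <- function(tags, chrom_sizes, window_bp = 1000L,
                            step_bp = 100L, fdr = 0.001, merge_bp = 1000L,
                            total = nrow(tags)) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      score = numeric(), count = integer(),
                      stringsAsFactors = FALSE)
  if (total == 0L) return(empty)
  genome_len <- sum(as.numeric(chrom_sizes))
  lambda <- total / genome_len * window_bp
  win <- list(); cnt <- list()
  for (ch in names(chrom_sizes)) {
    len <- as.integer(chrom_sizes[[ch]])
    starts <- seq.int(0L, max(0L, len - 1L), by = step_bp)
    ends <- pmin(starts + window_bp, len)
    p <- sort(tags$pos5[tags$chrom == ch])
    k <- if (length(p)) {
      findInterval(ends - 0.5, p) - findInterval(starts - 0.5, p)
    } else integer(length(starts))
    win[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            stringsAsFactors = FALSE)
    cnt[[ch]] <- k
  }
  windows <- do.call(rbind, win)
  counts <- unlist(cnt, use.names = FALSE)
  pval <- ppois(counts - 1L, lambda, lower.tail = FALSE)
  padj <- p.adjust(pval, method = "BH")
  sig <- padj <= fdr
  if (!any(sig)) return(empty)
  gr <- GenomicRanges::GRanges(windows$chrom[sig],
    IRanges::IRanges(windows$start[sig] + 1L, windows$end[sig]))
  peaks <- GenomicRanges::reduce(gr, min.gapwidth = merge_bp)
  pk <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   start = GenomicRanges::start(peaks) - 1L,
                   end = GenomicRanges::end(peaks),
                   stringsAsFactors = FALSE)
  pk$count <- count_in_intervals(tags$chrom, tags$pos5, pk)
  # summit window: the highest-count significant window inside the peak
  # (ties: leftmost) -- the fixed-width peak a HOMER-style caller reports;
  # scores and element-level signals use it, so that the merged extent
  # (element +/- one window of overhang) does not dilute them
  sw <- windows[sig, , drop = FALSE]
  sc <- counts[sig]
  grp <- GenomicRanges::findOverlaps(gr, peaks, select = "first")
  pk$summit_start <- NA_integer_; pk$summit_end <- NA_integer_
  for (g in seq_len(nrow(pk))) {
    idx <- which(grp == g)
    best <- idx[order(-sc[idx], sw$start[idx])][1L]
    pk$summit_start[g] <- sw$start[best]
    pk$summit_end[g] <- sw$end[best]
  }
  summit_counts <- count_in_intervals(tags$chrom, tags$pos5,
    data.frame(chrom = pk$chrom, start = pk$summit_start,
               end = pk$summit_end))
  pk$score <- summit_counts * 1e9 /
    ((pk$summit_end - pk$summit_start) * total)
  rownames(pk) <- NULL
  pk[, c("chrom", "start", "end", "summit_start", "summit_end", "score",
         "count")]
}

# interval set used for element-level signal: the summit window if present
peak_signal_intervals <- function(peaks) {
  if (all(c("summit_start", "summit_end") %in% names(peaks)) &&
      !anyNA(peaks$summit_start)) {
    data.frame(chrom = peaks$chrom, start = peaks$summit_start,
               end = peaks$summit_end, stringsAsFactors = FALSE)
  } else {
    peaks[, c("chrom", "start", "end")]
  }
}

#' Merge two scored peak sets
#'
#' Overlapping peaks across (and within) the two sets collapse to the single
#' highest-score member of each overlap group; ties go to the earlier start.
#'
#' @param peaks_a,peaks_b data.frames with chrom, start, end, score.
#' @return merged data.frame, sorted by (chrom, start).
#' @export
merge_peak_sets <- function(peaks_a, peaks_b) {
  common <- intersect(names(peaks_a), names(peaks_b))
  all <- rbind(peaks_a[, common, drop = FALSE],
               peaks_b[, common, drop = FALSE])
  if (nrow(all) == 0L) return(all)
  gr <- GenomicRanges::GRanges(all$chrom,
    IRanges::IRanges(all$start + 1L, all$end))
  grp <- GenomicRanges::findOverlaps(gr, GenomicRanges::reduce(gr),
                                     select = "first")
  keep <- vapply(split(seq_len(nrow(all)), grp), function(idx) {
    idx[order(-all$score[idx], all$start[idx])][1L]
  }, integer(1))
  out <- all[sort(keep), , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-component Gaussian mixture threshold (1-D EM)
#'
#' Fits a two-component normal mixture by EM (components initialised at the
#' lower/upper quartiles, common tolerance 1e-6 on the log-likelihood,
#' at most 500 iterations) and returns the point between the two fitted
#' means where the weighted component densities are equal — the Bayes
#' boundary of the fitted model. Fits whose means end up closer than half
#' the pooled standard deviation are flagged degenerate and yield no
#' threshold.
#'
#' @param values numeric sample (>= 100 values).
#' @param seed RNG seed (jitters the quantile initialisation).
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return object of class `gmm2_threshold`: threshold, means, sds, weights,
#'   converged, degenerate, loglik, responsibilities of component 2.
#' @export
fit_two_gaussian_threshold <- function(values, seed = 1L, tol = 1e-6,
                                       max_iter = 500L) {
  if (length(values) < 100L) stop("need at least 100 values")
  x <- as.numeric(values)
  set.seed(seed)
  q <- quantile(x, c(0.25, 0.75))
  mu <- as.numeric(q) + rnorm(2L, 0, 1e-3 * max(diff(range(x)), 1e-12))
  s <- rep(max(sd(x) / 2, 1e-6), 2L)
  w <- c(0.5, 0.5)
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], s[1])
    d2 <- w[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d2 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    n2 <- sum(r); n1 <- length(x) - n2
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum((1 - r) * x) / n1, sum(r * x) / n2)
    s <- sqrt(c(sum((1 - r) * (x - mu[1])^2) / n1,
                sum(r * (x - mu[2])^2) / n2))
    s <- pmax(s, 1e-6 * max(diff(range(x)), 1e-12) + 1e-12)
    w <- c(n1, n2) / length(x)
  }
  ord <- order(mu)
  mu <- mu[ord]; s <- s[ord]; w <- w[ord]
  pooled <- sqrt(mean(s^2))
  # degenerate when the means (nearly) coincide, or when the fitted mixture
  # density is unimodal between them -- EM on a unimodal sample splits it
  # into two overlapping components whose mixture has no interior valley,
  # and a "threshold" between such components would be meaningless
  degenerate <- (mu[2] - mu[1]) < 0.5 * pooled
  if (!degenerate) {
    grid <- seq(mu[1], mu[2], length.out = 256L)
    fmix <- w[1] * dnorm(grid, mu[1], s[1]) + w[2] * dnorm(grid, mu[2], s[2])
    degenerate <- min(fmix) >= min(fmix[1L], fmix[256L]) * 0.999
  }
  thr <- NA_real_
  if (!degenerate) {
    f <- function(z) log(w[1]) + dnorm(z, mu[1], s[1], log = TRUE) -
      log(w[2]) - dnorm(z, mu[2], s[2], log = TRUE)
    lo <- mu[1]; hi <- mu[2]
    if (f(lo) > 0 && f(hi) < 0) {
      thr <- stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
    } else {
      grid <- seq(lo, hi, length.out = 1024L)
      thr <- grid[which.min(abs(vapply(grid, f, numeric(1))))]
    }
  }
  structure(list(threshold = thr, means = mu, sds = s, weights = w,
                 converged = converged, degenerate = degenerate,
                 loglik = ll_old, posterior_high = if (ord[1] == 1L) r else 1 - r),
            class = "gmm2_threshold")
}

#' @export
print.gmm2_threshold <- function(x, ...) {
  if (x$degenerate) {
    cat("Two-Gaussian threshold: degenerate fit (means",
        sprintf("%.3f/%.3f", x$means[1], x$means[2]), "too close)\n")
  } else {
    cat(sprintf(
      "Two-Gaussian threshold: %.3f (means %.2f/%.2f, sd %.2f/%.2f, w %.2f/%.2f)\n",
      x$threshold, x$means[1], x$means[2], x$sds[1], x$sds[2],
      x$weights[1], x$weights[2]))
  }
  invisible(x)
}

#' Remove promoter-like peaks by their H3K4me3 signal
#'
#' Computes per-peak H3K4me3 RPKM (maximum over the supplied states), fits
#' the two-Gaussian mixture to the level distribution, and discards peaks
#' above the threshold; survivors are the enhancer set.
#'
#' @param peaks merged peak data.frame (chrom, start, end, score).
#' @param k4me3_tags named list of tag sets per cell state.
#' @param totals named numeric of library sizes matching `k4me3_tags`.
#' @param threshold optional manual threshold overriding the mixture fit.
#' @param seed seed for the mixture fit.
#' @return list: `enhancers` (peak rows kept, with `k4me3_level`),
#'   `removed`, `fit` (the `gmm2_threshold`), `threshold`.
#' @export
filter_peaks_to_enhancers <- function(peaks, k4me3_tags, totals = NULL,
                                      threshold = NULL, seed = 1L) {
  if (is.null(totals)) totals <- vapply(k4me3_tags, nrow, numeric(1))
  sig_iv <- peak_signal_intervals(peaks)
  lv <- sapply(names(k4me3_tags), function(st) {
    interval_rpkm(k4me3_tags[[st]], sig_iv, totals[[st]])
  })
  level <- if (is.matrix(lv)) apply(lv, 1L, max) else as.numeric(lv)
  fit <- NULL
  if (is.null(threshold)) {
    fit <- fit_two_gaussian_threshold(level, seed = seed)
    if (fit$degenerate) {
      stop("H3K4me3 level mixture is degenerate; supply a manual threshold")
    }
    threshold <- fit$threshold
  }
  keep <- level <= threshold
  enh <- peaks[keep, , drop = FALSE]
  enh$k4me3_level <- level[keep]
  rownames(enh) <- NULL
  list(enhancers = enh, removed = peaks[!keep, , drop = FALSE],
       fit = fit, threshold = threshold)
}

#' False-positive signal threshold from random background regions
#'
#' Samples `n_regions` non-overlapping windows of `region_length` uniformly
#' from the genome (seeded), computes each region's RPKM, and returns the
#' smallest value among the top 10% (nearest-rank ceiling: the
#' `ceiling(n/10)` largest values).
#'
#' @param tags tag data.frame.
#' @param chrom_sizes named chromosome lengths.
#' @param n_regions number of background regions (>= 10).
#' @param region_length region width in bp.
#' @param seed RNG seed.
#' @param total total mapped tags.
#' @return list: threshold, levels, regions, n_regions, region_length, seed.
#' @export
background_threshold <- function(tags, chrom_sizes, n_regions,
                                 region_length = 1000L, seed = 1L,
                                 total = nrow(tags)) {
  if (n_regions < 10L) stop("need at least 10 background regions")
  set.seed(seed)
  regions <- sample_nonoverlapping_regions(chrom_sizes, n_regions,
                                           region_length)
  levels <- interval_rpkm(tags, regions, total)
  list(threshold = top_decile_min(levels), levels = levels,
       regions = regions, n_regions = n_regions,
       region_length = region_length, seed = seed)
}

#' Smallest value among the top 10% (nearest-rank ceiling)
#' @param levels numeric vector.
#' @export
top_decile_min <- function(levels) {
  k <- ceiling(length(levels) / 10)
  min(sort(levels, decreasing = TRUE)[seq_len(k)])
}

sample_nonoverlapping_regions <- function(chrom_sizes, n, width,
                                          max_tries = 50L) {
  capacity <- sum(pmax(as.numeric(chrom_sizes) - width, 0))
  if (capacity < n * width) stop("genome too small for a non-overlapping sample")
  chosen <- vector("list", n)
  occupied <- lapply(chrom_sizes, function(...) IRanges::IRanges())
  probs <- pmax(as.numeric(chrom_sizes) - width, 0)
  k <- 0L; tries <- 0L
  while (k < n) {
    tries <- tries + 1L
    if (tries > max_tries * n) stop("could not place non-overlapping regions")
    ch <- sample(names(chrom_sizes), 1L, prob = probs)
    start <- sample.int(as.integer(chrom_sizes[[ch]]) - width, 1L) - 1L
    cand <- IRanges::IRanges(start + 1L, start + width)
    if (length(IRanges::findOverlaps(cand, occupied[[ch]])) == 0L) {
      k <- k + 1L
      chosen[[k]] <- data.frame(chrom = ch, start = start,
                                end = start + width, stringsAsFactors = FALSE)
      occupied[[ch]] <- c(occupied[[ch]], cand)
    }
  }
  do.call(rbind, chosen)
}

#' Classify enhancer chromatin states
#'
#' Per cell state: `off` if the H3K4me1 level is at or below `t_k4me1`;
#' otherwise `active` if H3K27ac exceeds `t_k27ac`, else `poised`.
#'
#' @param k4me1_levels,k27ac_levels matrices (enhancers x states) of RPKM.
#' @param t_k4me1,t_k27ac thresholds.
#' @return list: `states` (character matrix enhancers x states),
#'   `transitions` (3 x 3 matrix A -> B when exactly two states given).
#' @export
classify_enhancer_states <- function(k4me1_levels, k27ac_levels,
                                     t_k4me1, t_k27ac) {
  k4 <- as.matrix(k4me1_levels); k27 <- as.matrix(k27ac_levels)
  stopifnot(identical(dim(k4), dim(k27)))
  if (is.na(t_k4me1) || is.na(t_k27ac)) stop("missing enhancer thresholds")
  states <- matrix("off", nrow(k4), ncol(k4), dimnames = dimnames(k4))
  on <- k4 > t_k4me1
  states[on & k27 > t_k27ac] <- "active"
  states[on & k27 <= t_k27ac] <- "poised"
  transitions <- NULL
  if (ncol(states) == 2L) {
    lev <- c("active", "poised", "off")
    transitions <- table(factor(states[, 1L], lev), factor(states[, 2L], lev))
  }
  list(states = states, transitions = transitions)
}

#' Assign each enhancer its nearest gene by TSS distance
#'
#' Distance is |enhancer midpoint - TSS|, ties broken by lexicographically
#' smaller gene id. The signed distance is strand-aware: positive when the
#' enhancer lies downstream of the TSS in the gene's direction of
#' transcription.
#'
#' @param enhancers data.frame chrom, start, end.
#' @param genes annotation (gene_id, chrom, strand, tss).
#' @return data.frame gene_id, distance, signed_distance (NA rows for
#'   enhancers on gene-free chromosomes).
#' @export
assign_nearest_gene <- function(enhancers, genes) {
  mid <- (enhancers$start + enhancers$end) %/% 2L
  out <- data.frame(gene_id = NA_character_, distance = NA_real_,
                    signed_distance = NA_real_,
                    stringsAsFactors = FALSE)[rep(1L, nrow(enhancers)), ]
  rownames(out) <- NULL
  for (i in seq_len(nrow(enhancers))) {
    g <- genes[genes$chrom == enhancers$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    d <- abs(mid[i] - g$tss)
    j <- which(d == min(d))
    if (length(j) > 1L) j <- j[order(g$gene_id[j])][1L]
    rel <- mid[i] - g$tss[j]
    out$gene_id[i] <- g$gene_id[j]
    out$distance[i] <- d[j]
    out$signed_distance[i] <- if (g$strand[j] == "+") rel else -rel
  }
  out
}

#' Promoter-enhancer synergy table
#'
#' Retains genes whose expression log2 fold change has the same sign as
#' their enhancer's H3K27ac log2 fold change, with both magnitudes at least
#' `log2(fc_min)`; rows are ordered descending by enhancer H3K27ac log2 FC
#' and partitioned into up/down sets. Promoter H3K27ac/H3K9ac fold changes
#' ride along.
#'
#' @param synergy_input data.frame with gene_id, log2fc_expr,
#'   log2fc_enh_k27ac, and optional promoter FC columns.
#' @param fc_min minimum fold change on both axes (default 1.5).
#' @return list: `table` (ordered), `up`, `down` (gene id vectors),
#'   `empty` flag.
#' @export
promoter_enhancer_synergy <- function(synergy_input, fc_min = 1.5) {
  need <- c("gene_id", "log2fc_expr", "log2fc_enh_k27ac")
  if (!all(need %in% names(synergy_input))) {
    stop("synergy input needs columns: ", paste(need, collapse = ", "))
  }
  x <- synergy_input
  lf <- log2(fc_min)
  keep <- !is.na(x$log2fc_expr) & !is.na(x$log2fc_enh_k27ac) &
    sign(x$log2fc_expr) == sign(x$log2fc_enh_k27ac) &
    x$log2fc_expr != 0 & x$log2fc_enh_k27ac != 0 &
    abs(x$log2fc_expr) >= lf & abs(x$log2fc_enh_k27ac) >= lf
  tab <- x[keep, , drop = FALSE]
  tab <- tab[order(-tab$log2fc_enh_k27ac), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab,
       up = tab$gene_id[tab$log2fc_enh_k27ac > 0],
       down = tab$gene_id[tab$log2fc_enh_k27ac < 0],
       empty = nrow(tab) == 0L)
}
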