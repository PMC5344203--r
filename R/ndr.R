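# Nucleosome-depleted regions: promoter NDR occupancy and its coupling to
# expression; nucleosome-free stretches (>= 150 bp) inside enhancers and the
# eviction / 5'-shift / 3'-shift formation modes.

#' Promoter NDR occupancy
#'
#' The promoter NDR window is the strand-aware interval [-200, +50] around
#' the TSS: `[tss - 200, tss + 51)` for `+` strand genes, `[tss - 50,
#' tss + 201)` for `-` strand genes (251 bp; the inclusive right endpoint is
#' a stated convention, adjustable via `window_us`/`window_ds`). Occupancy
#' is the extended-read (147 bp footprint) coverage summed over the window,
#' expressed as RPKM of fractional reads.
#'
#' @param dyads dyad data.frame (chrom, dyad) for one cell state.
#' @param genes annotation (gene_id, chrom, strand, tss).
#' @param chrom_sizes named chromosome lengths.
#' @param total total mapped reads of the library.
#' @param window_us,window_ds upstream/downstream window bounds in bp
#'   (defaults 200 and 50, both inclusive).
#' @return data.frame gene_id, chrom, start, end, occupancy, clipped flag.
#' @export
promoter_ndr_occupancy <- function(dyads, genes, chrom_sizes,
                                   total = nrow(dyads),
                                   window_us = 200L, window_ds = 50L) {
  cov <- footprint_coverage(dyads, chrom_sizes)
  n <- nrow(genes)
  start <- ifelse(genes$strand == "+", genes$tss - window_us,
                  genes$tss - window_ds)
  end <- ifelse(genes$strand == "+", genes$tss + window_ds + 1L,
                genes$tss + window_us + 1L)
  occ <- numeric(n); clipped <- logical(n)
  for (i in seq_len(n)) {
    ch <- genes$chrom[i]
    len <- as.integer(chrom_sizes[[ch]])
    a <- max(0L, start[i]); b <- min(len, end[i])
    clipped[i] <- a != start[i] || b != end[i]
    s <- if (b > a && ch %in% names(cov)) {
      sum(as.numeric(S4Vectors::window(cov[[ch]], a + 1L, b)))
    } else 0
    width <- end[i] - start[i]
    occ[i] <- s / 147 * 1e9 / (width * max(total, 1L))
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             occupancy = occ, clipped = clipped, stringsAsFactors = FALSE)
}

#' Associate promoter NDR occupancy with expression
#'
#' Spearman correlation of NDR occupancy against FPKM (per state), plus an
#' optional two-group Wilcoxon rank-sum comparison of occupancy between a
#' gene group and the rest.
#'
#' @param ndr data.frame with gene_id and occupancy.
#' @param expression data.frame with gene_id and an `fpkm` column.
#' @param group optional character vector of gene ids forming the focal
#'   group for the Wilcoxon comparison.
#' @return list: rho, p_value (correlation test), n, and optionally
#'   wilcox_p / group sizes.
#' @export
ndr_expression_association <- function(ndr, expression, group = NULL) {
  m <- merge(ndr[, c("gene_id", "occupancy")],
             expression[, c("gene_id", "fpkm")], by = "gene_id")
  if (nrow(m) < 3L) stop("fewer than 3 genes join the two tables")
  ct <- suppressWarnings(cor.test(m$occupancy, m$fpkm, method = "spearman"))
  out <- list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(m))
  if (!is.null(group)) {
    in_grp <- m$gene_id %in% group
    if (any(in_grp) && any(!in_grp)) {
      wt <- wilcox.test(m$occupancy[in_grp], m$occupancy[!in_grp],
                        exact = FALSE)
      out$wilcox_p <- wt$p.value
      out$n_group <- sum(in_grp)
      out$n_other <- sum(!in_grp)
    }
  }
  out
}

#' Scan enhancers for nucleosome-free regions
#'
#' Within each enhancer, the maximal sub-intervals not intersected by any
#' call footprint `[dyad - 73, dyad + 74)` are collected; those of length
#' >= `min_len` are reported. Footprints extending beyond the enhancer
#' still block the positions they cover inside it; NDR boundaries are
#' clipped to the enhancer.
#'
#' @param enhancers data.frame with enhancer_id (optional), chrom, start,
#'   end.
#' @param calls nucleosome calls (chrom, dyad).
#' @param min_len minimum NDR length (bp).
#' @return data.frame enhancer_id, chrom, start, end, length.
#' @export
scan_enhancer_ndrs <- function(enhancers, calls, min_len = 150L) {
  ids <- enhancers$enhancer_id %||% sprintf("enh%d", seq_len(nrow(enhancers)))
  out <- list()
  for (i in seq_len(nrow(enhancers))) {
    ch <- enhancers$chrom[i]
    e <- IRanges::IRanges(enhancers$start[i] + 1L, enhancers$end[i])
    d <- calls$dyad[calls$chrom == ch]
    fp <- IRanges::IRanges(d - 73L + 1L, d + 73L + 1L)
    gaps <- IRanges::setdiff(e, fp)
    gaps <- gaps[IRanges::width(gaps) >= min_len]
    if (length(gaps)) {
      out[[length(out) + 1L]] <- data.frame(
        enhancer_id = ids[i], chrom = ch,
        start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps),
        length = IRanges::width(gaps), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(enhancer_id = character(), chrom = character(),
               start = integer(), end = integer(), length = integer(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Length histogram summary of an NDR set
#' @param ndrs output of [scan_enhancer_ndrs()].
#' @param breaks histogram breakpoints in bp.
#' @return table of counts per length class plus the 150-250 bp fraction.
#' @export
ndr_length_summary <- function(ndrs, breaks = c(150, 250, 350, 450, Inf)) {
  h <- table(cut(ndrs$length, c(breaks), right = FALSE,
                 include.lowest = TRUE))
  frac_mono <- if (nrow(ndrs)) mean(ndrs$length >= 150 & ndrs$length <= 250)
    else NA_real_
  list(histogram = h, frac_150_250 = frac_mono)
}

#' Label NDR formation modes (eviction / shift5 / shift3)
#'
#' Each NDR is labeled from its own paired-state differential: state-A and
#' state-B footprint coverage around the NDR midpoint are smoothed with a
#' Gaussian kernel and subtracted. The most negative excursion near the NDR
#' marks where occupancy was lost; the most positive excursion within the
#' window marks where it reappeared. Lost occupancy with no substantial
#' gain nearby is `eviction`; a gain peak upstream of the loss peak is
#' `shift5`, downstream `shift3`; profiles with no appreciable loss (the
#' region was already open in state A) are `ambiguous`. NDRs are then
#' K-means-partitioned by their central state-B occupancy profiles (the
#' heatmap view of the three formation patterns) and each cluster takes the
#' majority label of its members; that consensus is the reported mode --
#' pooling profiles across a cluster averages out the per-element Poisson
#' noise that single-NDR labels suffer at moderate coverage.
#'
#' @param ndrs NDR table from [scan_enhancer_ndrs()].
#' @param dyads_a,dyads_b dyad data.frames for states A and B.
#' @param chrom_sizes named chromosome lengths.
#' @param k number of clusters.
#' @param flank_bp profile half-width around the NDR midpoint.
#' @param bin_bp profile bin width for the clustering matrix.
#' @param cluster_flank_bp half-width of the central profile slice used for
#'   K-means (the window's outer flanks carry position-specific array noise
#'   uninformative about the NDR itself).
#' @param seed K-means seed.
#' @param smooth_sd Gaussian smoothing bandwidth (bp) for the differential.
#' @param min_gain_frac gain/loss peak ratio below which the mode is
#'   eviction (lost occupancy that reappears nowhere nearby was evicted).
#' @param min_loss_frac loss-peak depth, relative to the window's maximum
#'   state-A coverage, below which the label is ambiguous.
#' @return list: `modes` (per NDR: the consensus mode of its cluster),
#'   `member_modes` (the per-NDR differential labels), `clusters` (per
#'   NDR), `cluster_modes` (majority mode per cluster), `displacements`
#'   (gain-loss peak distance per NDR, bp; NA when not a shift),
#'   `profiles` (per-cluster mean A/B binned profiles).
#' @export
cluster_ndr_modes <- function(ndrs, dyads_a, dyads_b, chrom_sizes, k = 3L,
                              flank_bp = 1000L, bin_bp = 50L,
                              cluster_flank_bp = 350L, seed = 1L,
                              smooth_sd = 30, min_gain_frac = 0.4,
                              min_loss_frac = 0.25) {
  if (nrow(ndrs) == 0L) stop("NDR set is empty")
  cov_a <- footprint_coverage(dyads_a, chrom_sizes)
  cov_b <- footprint_coverage(dyads_b, chrom_sizes)
  mid <- (ndrs$start + ndrs$end) %/% 2L
  nb <- (2L * flank_bp) %/% bin_bp
  binprof <- function(cov, i) {
    v <- window_vector(cov[[ndrs$chrom[i]]], mid[i], flank_bp)
    colMeans(matrix(v, nrow = bin_bp))
  }
  A <- t(vapply(seq_len(nrow(ndrs)), function(i) binprof(cov_a, i),
                numeric(nb)))
  B <- t(vapply(seq_len(nrow(ndrs)), function(i) binprof(cov_b, i),
                numeric(nb)))
  mids <- seq(-flank_bp + bin_bp / 2, flank_bp - bin_bp / 2, by = bin_bp)

  # per-NDR semantic label from the smoothed A->B differential
  modes <- character(nrow(ndrs))
  disp <- rep(NA_real_, nrow(ndrs))
  half <- ceiling(3 * smooth_sd)
  kern <- dnorm(seq(-half, half), sd = smooth_sd)
  kern <- kern / sum(kern)
  search_bp <- 400L
  for (i in seq_len(nrow(ndrs))) {
    a <- window_vector(cov_a[[ndrs$chrom[i]]], mid[i], search_bp + half)
    b <- window_vector(cov_b[[ndrs$chrom[i]]], mid[i], search_bp + half)
    as <- as.numeric(stats::filter(a, kern, sides = 2))
    bs <- as.numeric(stats::filter(b, kern, sides = 2))
    keep <- !is.na(as)
    x <- seq(-search_bp - half, search_bp + half - 1L)[keep]
    as <- as[keep]; bs <- bs[keep]
    d <- bs - as
    near <- abs(x) <= ndrs$length[i] / 2 + 50
    if (!any(near) || max(as) <= 0) { modes[i] <- "ambiguous"; next }
    li <- which(near)[which.min(d[near])]
    loss_depth <- -d[li]
    if (loss_depth < min_loss_frac * max(as)) {
      modes[i] <- "ambiguous"
      next
    }
    gi <- which.max(d)
    if (d[gi] < min_gain_frac * loss_depth) {
      modes[i] <- "eviction"
    } else {
      disp[i] <- x[gi] - x[li]
      modes[i] <- if (disp[i] < 0) "shift5" else "shift3"
    }
  }

  # k-means grouping of the central state-B profiles (heatmap view)
  if (nrow(ndrs) <= k) {
    cl <- seq_len(nrow(ndrs))
  } else {
    set.seed(seed)
    central <- abs(mids) <= cluster_flank_bp
    cl <- kmeans(B[, central, drop = FALSE], centers = k, nstart = 25L,
                 iter.max = 100L)$cluster
  }
  cluster_ids <- sort(unique(cl))
  cmodes <- vapply(cluster_ids, function(cid) {
    tt <- sort(table(modes[cl == cid]), decreasing = TRUE)
    names(tt)[1L]
  }, character(1))
  names(cmodes) <- cluster_ids
  profiles <- lapply(cluster_ids, function(cid) {
    list(a = colMeans(A[cl == cid, , drop = FALSE]),
         b = colMeans(B[cl == cid, , drop = FALSE]), mids = mids)
  })
  names(profiles) <- cluster_ids
  list(modes = unname(cmodes[as.character(cl)]), member_modes = modes,
       clusters = cl, cluster_modes = cmodes, displacements = disp,
       profiles = profiles)
}
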