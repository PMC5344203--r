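# Cross-state nucleosome dynamics: one-to-one matching of two call sets and
# fixed/shift/loss/gain classification, feature enrichment, and TSS-centered
# composite profiles / difference clustering.

#' Match nucleosome calls between two cell states
#'
#' Two 147-bp footprints overlap by >= 20 bp iff their dyads are <= 127 bp
#' apart; such pairs are matching candidates. The one-to-one matching is the
#' exact optimum: it first maximizes the number of matched pairs and, among
#' those matchings, minimizes the total |dyad_b - dyad_a|. Because both call
#' sets are position-sorted and the cost is convex, an optimal matching is
#' non-crossing and is found by a banded dynamic program (a simple greedy
#' nearest-pair scheme mis-chains coherent shifts larger than half the
#' nucleosome repeat, so it is not used). Matched pairs with zero
#' displacement are `fixed`, other matched pairs `shift`; unmatched calls in
#' A are `loss`, unmatched in B `gain`.
#'
#' @param calls_a,calls_b nucleosome calls (chrom, dyad), sorted by dyad
#'   within chromosome.
#' @param max_shift_bp maximum |dyad_b - dyad_a| for a candidate pair
#'   (127 bp = 20 bp minimum footprint overlap).
#' @return an object of class `nuc_matches`: data.frame with chrom, dyad_a,
#'   dyad_b, status, shift_bp, and a `summary` attribute holding counts and
#'   fractions under union / state-A / state-B denominators.
#' @export
match_nucleosomes <- function(calls_a, calls_b, max_shift_bp = 127L) {
  for (nm in list(calls_a, calls_b)) {
    spl <- split(nm$dyad, nm$chrom)
    if (any(vapply(spl, is.unsorted, logical(1)))) {
      stop("calls must be sorted by dyad within each chromosome")
    }
  }
  chroms <- sort(unique(c(calls_a$chrom, calls_b$chrom)))
  rows <- lapply(chroms, function(ch) {
    match_one_chrom(calls_a$dyad[calls_a$chrom == ch],
                    calls_b$dyad[calls_b$chrom == ch], ch, max_shift_bp)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(res)) {
    res <- data.frame(chrom = character(), dyad_a = integer(),
                      dyad_b = integer(), status = character(),
                      shift_bp = integer(), stringsAsFactors = FALSE)
  }
  counts <- c(fixed = sum(res$status == "fixed"),
              shift = sum(res$status == "shift"),
              loss = sum(res$status == "loss"),
              gain = sum(res$status == "gain"))
  n_union <- sum(counts)               # matched pairs count once
  n_a <- counts[["fixed"]] + counts[["shift"]] + counts[["loss"]]
  n_b <- counts[["fixed"]] + counts[["shift"]] + counts[["gain"]]
  summ <- list(
    counts = counts,
    fractions_union = counts / max(n_union, 1L),
    fractions_a = c(counts[c("fixed", "shift", "loss")] / max(n_a, 1L),
                    gain = NA_real_),
    fractions_b = c(counts[c("fixed", "shift")] / max(n_b, 1L),
                    loss = NA_real_, gain = counts[["gain"]] / max(n_b, 1L)),
    n_union = n_union, n_a = n_a, n_b = n_b
  )
  structure(res, class = c("nuc_matches", "data.frame"), summary = summ)
}

match_one_chrom <- function(da, db, ch, max_shift_bp) {
  pairs <- if (length(da) && length(db)) {
    dp_match(da, db, max_shift_bp)
  } else {
    cbind(a = integer(0), b = integer(0))
  }
  shift <- db[pairs[, "b"]] - da[pairs[, "a"]]
  matched <- data.frame(
    chrom = rep(ch, nrow(pairs)), dyad_a = da[pairs[, "a"]],
    dyad_b = db[pairs[, "b"]],
    status = ifelse(shift == 0L, "fixed", "shift"),
    shift_bp = as.integer(shift), stringsAsFactors = FALSE)
  loss_idx <- setdiff(seq_along(da), pairs[, "a"])
  gain_idx <- setdiff(seq_along(db), pairs[, "b"])
  out <- rbind(
    matched,
    data.frame(chrom = rep(ch, length(loss_idx)), dyad_a = da[loss_idx],
               dyad_b = rep(NA_integer_, length(loss_idx)),
               status = rep("loss", length(loss_idx)),
               shift_bp = rep(NA_integer_, length(loss_idx)),
               stringsAsFactors = FALSE),
    data.frame(chrom = rep(ch, length(gain_idx)),
               dyad_a = rep(NA_integer_, length(gain_idx)),
               dyad_b = db[gain_idx], status = rep("gain", length(gain_idx)),
               shift_bp = rep(NA_integer_, length(gain_idx)),
               stringsAsFactors = FALSE)
  )
  out[order(ifelse(is.na(out$dyad_a), out$dyad_b, out$dyad_a)), , drop = FALSE]
}

# Exact max-cardinality, min-total-distance one-to-one matching of two
# sorted dyad vectors under the |delta| <= max_shift_bp pairing constraint.
# An optimal matching can be chosen non-crossing (uncrossing two pairs never
# raises the L1 cost and preserves feasibility), so a sequence-alignment DP
# applies; unmatched calls cost M > max pair cost, which makes cardinality
# the primary objective. For tractability the calls are first split into
# connected components: a break is placed wherever consecutive sorted
# positions (pooling both states) are more than max_shift_bp apart, which
# can only merge too much, never split a pairable a/b across components.
dp_match <- function(da, db, max_shift_bp) {
  pos <- c(da, db)
  side <- rep(1:2, c(length(da), length(db)))
  idx <- c(seq_along(da), seq_along(db))
  o <- order(pos, side)
  pos <- pos[o]; side <- side[o]; idx <- idx[o]
  comp <- cumsum(c(1L, diff(pos) > max_shift_bp))
  pairs <- matrix(integer(0), 0L, 2L)
  for (cc in unique(comp)) {
    sel <- comp == cc
    ai <- idx[sel & side == 1L]
    bi <- idx[sel & side == 2L]
    if (length(ai) == 0L || length(bi) == 0L) next
    p <- dp_match_component(da[ai], db[bi], max_shift_bp)
    if (nrow(p)) pairs <- rbind(pairs, cbind(ai[p[, 1L]], bi[p[, 2L]]))
  }
  colnames(pairs) <- c("a", "b")
  pairs[order(pairs[, 1L]), , drop = FALSE]
}

dp_match_component <- function(da, db, max_shift_bp) {
  na <- length(da); nb <- length(db)
  # the gap penalty must exceed any achievable total-pair-cost reduction,
  # so that cardinality is maximized before total distance is minimized
  M <- max_shift_bp * (min(na, nb) + 1) + 1
  mv <- matrix(0L, na, nb)
  prev <- as.numeric(0:nb) * M  # row 0: j leading gains
  jM <- as.numeric(seq_len(nb)) * M
  for (i in seq_len(na)) {
    d <- abs(da[i] - db)
    d[d > max_shift_bp] <- Inf
    A <- prev[seq_len(nb)] + d        # pair with b_j
    B <- prev[2:(nb + 1L)] + M        # leave a_i unmatched
    base <- i * M                     # C[i][0]
    E <- cummin(c(base, pmin(A, B) - jM))
    cur <- c(base, E[-1L] + jM)
    cj <- cur[-1L]
    mv[i, ] <- ifelse(cj == A, 1L, ifelse(cj == B, 2L, 3L))
    prev <- cur
  }
  j <- which.min(prev + (nb - 0:nb) * M) - 1L
  out <- matrix(integer(0), 0L, 2L)
  i <- na
  while (i >= 1L && j >= 0L) {
    if (j == 0L) { i <- i - 1L; next }
    m <- mv[i, j]
    if (m == 1L) {
      out <- rbind(out, c(i, j)); i <- i - 1L; j <- j - 1L
    } else if (m == 2L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  out
}

#' @export
print.nuc_matches <- function(x, ...) {
  s <- attr(x, "summary")
  cat("Nucleosome dynamics:", s$n_union, "nucleosomes (union denominator)\n")
  f <- s$fractions_union
  cat(sprintf("  fixed %.1f%%  shift %.1f%%  loss %.1f%%  gain %.1f%%\n",
              100 * f[["fixed"]], 100 * f[["shift"]],
              100 * f[["loss"]], 100 * f[["gain"]]))
  invisible(x)
}

#' Summarize a match set
#' @param object a `nuc_matches` object.
#' @param ... unused.
#' @method summary nuc_matches
#' @export
summary.nuc_matches <- function(object, ...) attr(object, "summary")

#' Nucleosome density per genomic feature class
#'
#' Assigns each call to exactly one of promoter (TSS +/- 1 kb), genic
#' (TSS-to-TES gene body) or intergenic by its dyad, with precedence
#' promoter > genic > intergenic, and reports calls per kb of the total
#' (merged) length of each class.
#'
#' @param calls nucleosome calls (chrom, dyad).
#' @param genes annotation with gene_id, chrom, strand, tss, tes.
#' @param chrom_sizes named chromosome lengths.
#' @param promoter_bp promoter half-width around the TSS.
#' @return data.frame with class, n_calls, length_kb, density (calls/kb).
#' @export
feature_enrichment <- function(calls, genes, chrom_sizes, promoter_bp = 1000L) {
  if (!"tes" %in% names(genes)) stop("annotation must carry a tes column")
  sl <- as.integer(chrom_sizes)
  names(sl) <- names(chrom_sizes)
  prom <- GenomicRanges::GRanges(genes$chrom,
    IRanges::IRanges(pmax(1L, genes$tss - promoter_bp + 1L),
                     genes$tss + promoter_bp), seqlengths = sl)
  prom <- GenomicRanges::trim(prom)
  body_start <- pmin(genes$tss, genes$tes) + 1L
  body_end <- pmax(genes$tss, genes$tes)
  genic <- GenomicRanges::GRanges(genes$chrom,
    IRanges::IRanges(body_start, body_end), seqlengths = sl)
  genic <- GenomicRanges::trim(genic)
  promR <- GenomicRanges::reduce(prom)
  genicR <- GenomicRanges::setdiff(GenomicRanges::reduce(genic), promR)
  genomeR <- GenomicRanges::GRanges(names(sl), IRanges::IRanges(1L, sl))
  interR <- GenomicRanges::setdiff(GenomicRanges::setdiff(genomeR, promR), genicR)
  pts <- GenomicRanges::GRanges(calls$chrom,
    IRanges::IRanges(calls$dyad + 1L, calls$dyad + 1L))
  n <- c(promoter = sum(IRanges::overlapsAny(pts, promR)),
         genic = sum(IRanges::overlapsAny(pts, genicR)),
         intergenic = sum(IRanges::overlapsAny(pts, interR)))
  len_kb <- c(promoter = sum(GenomicRanges::width(promR)),
              genic = sum(GenomicRanges::width(genicR)),
              intergenic = sum(GenomicRanges::width(interR))) / 1000
  data.frame(class = names(n), n_calls = as.integer(n), length_kb = len_kb,
             density = ifelse(len_kb > 0, n / len_kb, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene-by-position TSS-centered signal matrix
#'
#' Rows are genes, columns strand-aware distance bins spanning
#' (-flank_bp, +flank_bp) relative to the TSS (downstream = direction of
#' transcription). The occupancy metric is extended-read (147 bp footprint)
#' coverage converted to RPKM per bin; call_density counts call dyads per
#' bin per million mapped; fuzziness averages call fuzziness per bin
#' (NA where a bin holds no call).
#'
#' @param x a dyad data.frame (occupancy mode) or `nuc_calls`
#'   (call_density / fuzziness modes).
#' @param genes annotation (gene_id, chrom, strand, tss).
#' @param chrom_sizes named chromosome lengths.
#' @param metric one of "occupancy", "call_density", "fuzziness".
#' @param bin_bp bin width; must divide 2 * flank_bp.
#' @param flank_bp half-width of the window around the TSS.
#' @param total_reads library size for per-million normalization.
#' @return numeric matrix genes x bins with distance midpoints as colnames.
#' @export
tss_matrix <- function(x, genes, chrom_sizes,
                       metric = c("occupancy", "call_density", "fuzziness"),
                       bin_bp = 5L, flank_bp = 1000L,
                       total_reads = nrow(x)) {
  metric <- match.arg(metric)
  if ((2L * flank_bp) %% bin_bp != 0L) {
    stop("bin_bp must divide the window width ", 2L * flank_bp)
  }
  nb <- (2L * flank_bp) %/% bin_bp
  mids <- seq(-flank_bp + bin_bp / 2, flank_bp - bin_bp / 2, by = bin_bp)
  m <- matrix(if (metric == "fuzziness") NA_real_ else 0,
              nrow = nrow(genes), ncol = nb,
              dimnames = list(genes$gene_id, mids))
  if (metric == "occupancy") {
    cov <- footprint_coverage(x, chrom_sizes)
    for (i in seq_len(nrow(genes))) {
      ch <- genes$chrom[i]
      if (!ch %in% names(cov)) next
      v <- window_vector(cov[[ch]], genes$tss[i], flank_bp)
      if (genes$strand[i] == "-") v <- rev(v)
      bs <- colMeans(matrix(v, nrow = bin_bp))
      # per-bp fractional reads -> RPKM
      m[i, ] <- bs / 147 * 1e9 / max(total_reads, 1L)
    }
  } else {
    for (i in seq_len(nrow(genes))) {
      sel <- x$chrom == genes$chrom[i] &
        x$dyad >= genes$tss[i] - flank_bp & x$dyad < genes$tss[i] + flank_bp
      if (!any(sel)) next
      rel <- x$dyad[sel] - genes$tss[i]
      if (genes$strand[i] == "-") rel <- -rel - 1L
      b <- (rel + flank_bp) %/% bin_bp + 1L
      b <- pmin(pmax(b, 1L), nb)
      if (metric == "call_density") {
        m[i, ] <- tabulate(b, nbins = nb) * 1e6 / max(total_reads, 1L)
      } else {
        fz <- x$fuzziness[sel]
        mu <- tapply(fz, factor(b, levels = seq_len(nb)), mean)
        m[i, ] <- as.numeric(mu)
      }
    }
  }
  m
}

# Extract a +/- flank window of an Rle coverage around a 0-based center.
window_vector <- function(rle_cov, center, flank) {
  len <- length(rle_cov)
  lo <- center - flank + 1L  # 1-based start of window
  hi <- center + flank
  v <- numeric(2L * flank)
  a <- max(1L, lo); b <- min(len, hi)
  if (b >= a) {
    v[(a - lo + 1L):(b - lo + 1L)] <-
      as.numeric(S4Vectors::window(rle_cov, a, b))
  }
  v
}

#' Composite TSS-centered profile
#'
#' Column average (occupancy, fuzziness) or column sum per million
#' (call_density) of [tss_matrix()], smoothed with a centered moving
#' average. Defaults follow the occupancy convention (5-bp bins, 5-bin
#' moving average); the call-density convention uses bin_bp = 10, ma = 3.
#'
#' @inheritParams tss_matrix
#' @param ma_bins moving-average window (bins).
#' @return data.frame with distance (bin midpoint) and value.
#' @export
tss_composite_profile <- function(x, genes, chrom_sizes,
                                  metric = c("occupancy", "call_density",
                                             "fuzziness"),
                                  bin_bp = 5L, ma_bins = 5L,
                                  flank_bp = 1000L, total_reads = nrow(x)) {
  metric <- match.arg(metric)
  if (metric == "call_density" && missing(bin_bp)) bin_bp <- 10L
  if (metric == "call_density" && missing(ma_bins)) ma_bins <- 3L
  m <- tss_matrix(x, genes, chrom_sizes, metric, bin_bp, flank_bp, total_reads)
  v <- if (metric == "call_density") colSums(m) else
    colMeans(m, na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  ok <- !is.na(v)
  v[ok] <- moving_average(v[ok], ma_bins)
  data.frame(distance = as.numeric(colnames(m)), value = v, row.names = NULL)
}

#' Cluster TSS-centered occupancy differences
#'
#' Computes the per-gene, per-bin difference matrix (state B - state A) and
#' partitions genes by K-means. All-zero differences return a degenerate
#' flag instead of clustering.
#'
#' @param matrix_a,matrix_b gene x bin matrices with identical dimensions
#'   and row order (see [tss_matrix()]).
#' @param k number of clusters.
#' @param seed RNG seed for K-means.
#' @param nstart K-means restarts.
#' @return list with `labels` (named integer vector), `ordered` (difference
#'   matrix with rows ordered by cluster then distance to centroid),
#'   `centers`, and `degenerate` flag.
#' @export
tss_difference_clusters <- function(matrix_a, matrix_b, k = 5L, seed = 1L,
                                    nstart = 50L) {
  if (!identical(dim(matrix_a), dim(matrix_b)) ||
      !identical(rownames(matrix_a), rownames(matrix_b))) {
    stop("matrices must share gene set and binning")
  }
  d <- matrix_b - matrix_a
  if (all(abs(d) < 1e-12)) {
    return(list(labels = setNames(rep(1L, nrow(d)), rownames(d)),
                ordered = d, centers = NULL, degenerate = TRUE))
  }
  if (k == 1L) {
    return(list(labels = setNames(rep(1L, nrow(d)), rownames(d)),
                ordered = d, centers = matrix(colMeans(d), 1L),
                degenerate = FALSE))
  }
  set.seed(seed)
  km <- kmeans(d, centers = k, nstart = nstart, iter.max = 100L)
  dist_to_center <- sqrt(rowSums((d - km$centers[km$cluster, , drop = FALSE])^2))
  ord <- order(km$cluster, dist_to_center)
  list(labels = setNames(km$cluster, rownames(d)),
       ordered = d[ord, , drop = FALSE], centers = km$centers,
       degenerate = FALSE)
}
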