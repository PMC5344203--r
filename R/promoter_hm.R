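# Histone-modification state calling in promoters (TSS +/- 1 kb): RPKM
# quantification, bimodal valley / 1-D k-means thresholds, combinatorial
# state assignment, transition counting, fold-change clustering, and
# H3K4me3/H3K9ac gain-mode classification.

HM_MARKS <- c("H3K4me1", "H3K4me3", "H3K9ac", "H3K27ac", "H3K27me3")

#' Promoter mark levels (RPKM)
#'
#' Counts tags whose 5' position falls inside the promoter
#' `[tss - promoter_bp, tss + promoter_bp)` and converts to RPKM:
#' `count * 1e9 / (width * total)`.
#'
#' @param tags tag data.frame for one mark and cell state.
#' @param genes annotation (gene_id, chrom, strand, tss).
#' @param total total mapped tags of the library.
#' @param promoter_bp promoter half-width.
#' @return named numeric vector of RPKM levels (names = gene ids).
#' @export
promoter_mark_levels <- function(tags, genes, total = nrow(tags),
                                 promoter_bp = 1000L) {
  if (total <= 0) stop("total mapped tags must be positive")
  iv <- data.frame(chrom = genes$chrom,
                   start = genes$tss - promoter_bp,
                   end = genes$tss + promoter_bp)
  setNames(interval_rpkm(tags, iv, total), genes$gene_id)
}

#' Threshold from the valley of a bimodal level distribution
#'
#' Gaussian kernel density (Silverman bandwidth, 512-point grid from 0 to
#' the 99th percentile) is scanned for local maxima; if the second-highest
#' mode reaches at least `guard` of the highest, the threshold is the grid
#' argmin of density strictly between the two modes. Otherwise the
#' distribution is declared unimodal and no threshold is returned — callers
#' should fall back to [kmeans2_threshold()].
#'
#' @param levels numeric sample of promoter levels (>= 100 values).
#' @param mark mark name carried into the result.
#' @param guard minimum relative height of the second mode.
#' @return an `hm_threshold` list: mark, method ("valley"), value, ok flag,
#'   and the mode locations; `ok = FALSE` with `value = NA` if unimodal.
#' @export
valley_threshold <- function(levels, mark = NA_character_, guard = 0.10) {
  if (length(levels) < 100L) stop("need at least 100 values")
  if (length(unique(levels)) < 2L) stop("all values identical; no density")
  hi <- as.numeric(quantile(levels, 0.99))
  if (hi <= min(levels)) stop("degenerate level distribution")
  dens <- density(levels, bw = "nrd0", n = 512L, from = 0, to = hi)
  y <- dens$y
  n <- length(y)
  locmax <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (y[1] > y[2]) locmax <- c(1L, locmax)
  if (y[n] > y[n - 1]) locmax <- c(locmax, n)
  locmax <- locmax[order(-y[locmax])]
  if (length(locmax) < 2L || y[locmax[2]] < guard * y[locmax[1]]) {
    return(hm_threshold(mark, "valley", NA_real_, ok = FALSE,
                        modes = dens$x[locmax[seq_len(min(2, length(locmax)))]]))
  }
  m1 <- min(locmax[1:2]); m2 <- max(locmax[1:2])
  between <- (m1 + 1L):(m2 - 1L)
  thr <- dens$x[between[which.min(y[between])]]
  hm_threshold(mark, "valley", thr, ok = TRUE, modes = sort(dens$x[locmax[1:2]]))
}

#' Threshold from 1-D K-means (k = 2)
#'
#' For marks whose promoter levels are unimodal (e.g. H3K27me3): cluster the
#' levels into two groups and put the threshold midway between the two
#' cluster centers.
#'
#' @inheritParams valley_threshold
#' @param seed RNG seed; `nstart` restarts.
#' @param nstart K-means restarts.
#' @export
kmeans2_threshold <- function(levels, mark = NA_character_, seed = 1L,
                              nstart = 10L) {
  if (length(unique(levels)) < 2L) stop("need at least 2 distinct values")
  set.seed(seed)
  km <- kmeans(levels, centers = 2L, nstart = nstart)
  hm_threshold(mark, "kmeans2", mean(km$centers), ok = TRUE,
               modes = sort(as.numeric(km$centers)))
}

hm_threshold <- function(mark, method, value, ok, modes = NULL) {
  structure(list(mark = mark, method = method, value = value, ok = ok,
                 modes = modes), class = "hm_threshold")
}

#' @export
print.hm_threshold <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("HM threshold [%s, %s]: %.3f RPKM (modes %.2f / %.2f)\n",
                x$mark, x$method, x$value, x$modes[1], x$modes[2]))
  } else {
    cat(sprintf("HM threshold [%s, %s]: no threshold (unimodal)\n",
                x$mark, x$method))
  }
  invisible(x)
}

#' Valley threshold with k-means fallback
#'
#' The cascade applied per mark: valley of the bimodal density when the
#' bimodality guard passes, otherwise the k = 2 K-means midpoint.
#' @inheritParams valley_threshold
#' @param seed seed for the fallback.
#' @export
mark_threshold <- function(levels, mark = NA_character_, seed = 1L) {
  thr <- valley_threshold(levels, mark)
  if (thr$ok) thr else kmeans2_threshold(levels, mark, seed = seed)
}

#' Assign combinatorial promoter states
#'
#' A promoter is marked by a modification iff its level is strictly greater
#' than that mark's threshold (ties fall to unmarked). The state string
#' concatenates the marked mark names in `HM_MARKS` order ("none" if empty);
#' a bivalent flag records H3K4me3+ and H3K27me3+ co-occurrence.
#'
#' @param levels matrix/data.frame genes x marks of RPKM levels.
#' @param thresholds named list of `hm_threshold` (or numeric) per mark.
#' @return list: `marked` (logical matrix), `state` (character vector),
#'   `bivalent` (logical vector).
#' @export
assign_promoter_states <- function(levels, thresholds) {
  levels <- as.matrix(levels)
  marks <- colnames(levels)
  thr <- vapply(marks, function(m) {
    t <- thresholds[[m]]
    if (is.null(t)) stop("missing threshold for mark ", m)
    if (inherits(t, "hm_threshold")) t$value else as.numeric(t)
  }, numeric(1))
  if (anyNA(thr)) stop("NA threshold supplied")
  marked <- sweep(levels, 2L, thr, `>`)
  ordered_marks <- intersect(HM_MARKS, marks)
  state <- apply(marked[, ordered_marks, drop = FALSE], 1L, function(r) {
    if (!any(r)) "none" else paste(ordered_marks[r], collapse = "+")
  })
  bivalent <- if (all(c("H3K4me3", "H3K27me3") %in% marks)) {
    marked[, "H3K4me3"] & marked[, "H3K27me3"]
  } else rep(NA, nrow(levels))
  list(marked = marked, state = state, bivalent = bivalent)
}

#' Promoter state transition counts between cell states
#'
#' @param states_a,states_b character vectors of state strings over the same
#'   gene universe (same names/order).
#' @return square integer matrix over the union of observed states; rows are
#'   state-A categories, columns state-B; the grand total equals the number
#'   of genes.
#' @export
state_transitions <- function(states_a, states_b) {
  if (length(states_a) != length(states_b) ||
      (!is.null(names(states_a)) && !is.null(names(states_b)) &&
       !identical(names(states_a), names(states_b)))) {
    stop("state vectors must cover the same gene universe")
  }
  lev <- sort(unique(c(states_a, states_b)))
  table(factor(states_a, lev), factor(states_b, lev))
}

#' Cluster promoter mark fold-changes
#'
#' Per-mark log2 fold change `log2((b + c) / (a + c))` with pseudocount `c`;
#' genes whose largest absolute log2 FC over all marks reaches
#' `log2(fc_min)` are retained and clustered by K-means on their FC vectors.
#'
#' @param levels_a,levels_b gene x mark level matrices (same dimnames).
#' @param fc_min minimum fold change (default 2 = twofold).
#' @param k number of K-means clusters.
#' @param pseudocount RPKM pseudocount.
#' @param seed RNG seed; `nstart` restarts.
#' @param nstart K-means restarts.
#' @return list: `log2fc` (selected genes x marks), `labels`, `centers`,
#'   `selected` (logical over the input genes), `empty` flag.
#' @export
cluster_mark_fold_changes <- function(levels_a, levels_b, fc_min = 2,
                                      k = 4L, pseudocount = 1, seed = 1L,
                                      nstart = 10L) {
  stopifnot(identical(dim(levels_a), dim(levels_b)))
  fc <- log2((as.matrix(levels_b) + pseudocount) /
               (as.matrix(levels_a) + pseudocount))
  sel <- apply(abs(fc), 1L, max) >= log2(fc_min)
  if (!any(sel)) {
    return(list(log2fc = fc[sel, , drop = FALSE], labels = integer(0),
                centers = NULL, selected = sel, empty = TRUE))
  }
  x <- fc[sel, , drop = FALSE]
  set.seed(seed)
  km <- kmeans(x, centers = min(k, nrow(unique(x))), nstart = nstart,
               iter.max = 100L)
  list(log2fc = x, labels = setNames(km$cluster, rownames(x)),
       centers = km$centers, selected = sel, empty = FALSE)
}

#' Classify how an active mark is gained (or lost) at each promoter
#'
#' For H3K4me3 or H3K9ac: `de_novo` if the promoter was unmarked in state A
#' and marked in state B; `increase_existing` if marked in both and the
#' level rose by at least `fc_min`; `lost` if marked in A but not B;
#' otherwise `unchanged`. Categories are mutually exclusive and exhaustive.
#'
#' @param level_a,level_b numeric level vectors for the mark.
#' @param threshold mark threshold (`hm_threshold` or numeric).
#' @param fc_min fold-change floor for `increase_existing`.
#' @param pseudocount RPKM pseudocount for the fold change.
#' @return character vector of modes.
#' @export
classify_gain_mode <- function(level_a, level_b, threshold, fc_min = 2,
                               pseudocount = 1) {
  thr <- if (inherits(threshold, "hm_threshold")) threshold$value else threshold
  fc <- (level_b + pseudocount) / (level_a + pseudocount)
  mode <- rep("unchanged", length(level_a))
  mode[level_a <= thr & level_b > thr] <- "de_novo"
  mode[level_a > thr & level_b > thr & fc >= fc_min] <- "increase_existing"
  mode[level_a > thr & level_b <= thr] <- "lost"
  mode
}
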