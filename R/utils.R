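# Internal helpers shared across modules.

#' @importFrom stats dnorm density kmeans sd quantile ppois p.adjust cor
#'   cor.test wilcox.test rnorm rpois runif rbinom setNames aggregate
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed for a named RNG stream
#'
#' Each generator stage draws from its own stream, seeded by a hash of the
#' master seed and a stream label, so that e.g. adding a ChIP mark never
#' perturbs the MNase reads.
#'
#' @param seed master integer seed.
#' @param ... character/numeric labels identifying the stream.
#' @return an integer seed in [0, 2^31).
#' @keywords internal
stream_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = ":")
  bytes <- utf8ToInt(label)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647L
  as.integer(h)
}

with_stream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, ...))
  expr
}

#' Population standard deviation
#' @param x numeric vector (length >= 1).
#' @keywords internal
pop_sd <- function(x) {
  if (length(x) == 0L) stop("population sd of zero values is undefined")
  sqrt(mean((x - mean(x))^2))
}

#' Centered moving average with partial windows at the edges
#' @param x numeric vector; `k` odd window size in bins.
#' @keywords internal
moving_average <- function(x, k) {
  stopifnot(k >= 1)
  if (k == 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    mean(x[idx])
  }, numeric(1))
}

#' RPKM over genomic intervals from tag 5' positions
#'
#' level = count * 1e9 / (width * total), the reads-per-kilobase-per-million
#' normalization used for every element-level signal in the pipeline.
#'
#' @param tags tag data.frame (chrom, pos5, strand).
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @param total total mapped tags of the library (defaults to `nrow(tags)`).
#' @return numeric vector of RPKM values, one per interval.
#' @export
interval_rpkm <- function(tags, intervals, total = nrow(tags)) {
  if (total <= 0) stop("total mapped tags must be positive")
  counts <- count_in_intervals(tags$chrom, tags$pos5, intervals)
  counts * 1e9 / ((intervals$end - intervals$start) * total)
}

# Count positions falling in each half-open interval (fast, per chromosome).
count_in_intervals <- function(chrom, pos, intervals) {
  out <- integer(nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    p <- sort(pos[chrom == ch])
    sel <- which(intervals$chrom == ch)
    if (length(p) == 0L) next
    lo <- findInterval(intervals$start[sel] - 0.5, p)
    hi <- findInterval(intervals$end[sel] - 0.5, p)
    out[sel] <- hi - lo
  }
  out
}

# Per-chromosome extended-read (147 bp footprint) coverage as integer Rle.
footprint_coverage <- function(dyads, chrom_sizes) {
  cov <- list()
  for (ch in names(chrom_sizes)) {
    d <- dyads$dyad[dyads$chrom == ch]
    ir <- IRanges::IRanges(start = pmax(1L, d - 73L + 1L),
                           end = pmin(as.integer(chrom_sizes[[ch]]), d + 73L + 1L))
    cov[[ch]] <- IRanges::coverage(ir, width = as.integer(chrom_sizes[[ch]]))
  }
  cov
}

validate_fractions <- function(x, what) {
  if (any(x < 0 | x > 1)) stop(what, " must lie in [0, 1]")
  if (abs(sum(x) - 1) > 1e-9) stop(what, " must sum to 1")
  invisible(x)
}
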