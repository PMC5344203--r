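# Nucleosome positioning from MNase-seq tags.
#
# Each tag is extended toward its 3' end to 147 bp (one nucleosomal DNA
# length); the midpoint of the extension is the inferred dyad. Dyads are
# accumulated into a per-bp histogram, smoothed with a Gaussian kernel, and
# local maxima are accepted greedily (highest first) under a center-to-center
# exclusion zone — the same scheme popularised by GeneTrack, re-implemented
# here with exposed parameters.

#' Convert tags to nucleosome dyad positions
#'
#' A `+` strand tag at 5' position p maps to dyad p + 73; a `-` strand tag to
#' p - 73 (the floor of the 147-bp extension midpoint). Dyads falling outside
#' the chromosome are dropped and counted.
#'
#' @param tags tag data.frame (chrom, pos5, strand).
#' @param chrom_sizes named vector of chromosome lengths (bp); if `NULL`, no
#'   bounds are enforced beyond dyad >= 0.
#' @return data.frame (chrom, dyad) with attribute `n_dropped`.
#' @export
reads_to_dyads <- function(tags, chrom_sizes = NULL) {
  dyad <- ifelse(tags$strand == "+", tags$pos5 + 73L, tags$pos5 - 73L)
  df <- data.frame(chrom = tags$chrom, dyad = as.integer(dyad),
                   stringsAsFactors = FALSE)
  ok <- df$dyad >= 0L
  if (!is.null(chrom_sizes)) {
    ok <- ok & df$chrom %in% names(chrom_sizes) &
      df$dyad < unname(chrom_sizes[df$chrom])
  }
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Call nucleosomes from dyad positions
#'
#' Smooths the per-bp dyad histogram with a Gaussian kernel (truncated at
#' +/- 4 sigma, evaluated on a 1-bp grid), takes local maxima as candidates,
#' and accepts them greedily in descending smoothed height, rejecting any
#' candidate closer than `exclusion_bp` (center-to-center) to an accepted
#' call. Each dyad is then assigned to the nearest accepted call within
#' 73 bp (ties to the leftmost call); calls keep their member read count,
#' occupancy (reads per million mapped) and fuzziness (population standard
#' deviation of member dyad coordinates).
#'
#' @param dyads data.frame (chrom, dyad) from [reads_to_dyads()].
#' @param sigma Gaussian smoothing bandwidth in bp.
#' @param exclusion_bp minimum center-to-center distance between calls.
#' @param min_reads minimum member reads for a call to be reported.
#' @param total_reads total mapped reads for occupancy normalization
#'   (defaults to `nrow(dyads)`).
#' @param chrom_sizes optional named chromosome lengths; defaults to the
#'   maximum dyad per chromosome.
#' @return data.frame of class `nuc_calls` with columns chrom, dyad,
#'   read_count, occupancy, fuzziness.
#' @export
call_nucleosomes <- function(dyads, sigma = 20, exclusion_bp = 147L,
                             min_reads = 3L, total_reads = nrow(dyads),
                             chrom_sizes = NULL) {
  stopifnot(sigma > 0, exclusion_bp >= 1)
  out <- list()
  for (ch in sort(unique(dyads$chrom))) {
    d <- dyads$dyad[dyads$chrom == ch]
    if (length(d) == 0L) next
    len <- if (!is.null(chrom_sizes)) as.integer(chrom_sizes[[ch]]) else max(d) + 1L
    centers <- find_peak_centers(d, len, sigma, exclusion_bp)
    if (length(centers) == 0L) next
    memb <- assign_members(d, centers)
    counts <- tabulate(memb$call, nbins = length(centers))
    fuzz <- vapply(seq_along(centers), function(i) {
      m <- memb$dyad[memb$call == i]
      if (length(m) == 0L) NA_real_ else pop_sd(m)
    }, numeric(1))
    keep <- counts >= min_reads
    if (!any(keep)) next
    out[[ch]] <- data.frame(chrom = ch, dyad = centers[keep],
                            read_count = counts[keep],
                            fuzziness = fuzz[keep],
                            stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), dyad = integer(), read_count = integer(),
               fuzziness = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res$occupancy <- if (nrow(res)) res$read_count * 1e6 / total_reads else numeric(0)
  res <- res[, c("chrom", "dyad", "read_count", "occupancy", "fuzziness")]
  res <- res[order(res$chrom, res$dyad), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("nuc_calls", "data.frame"),
            total_reads = total_reads, sigma = sigma,
            exclusion_bp = exclusion_bp, min_reads = min_reads)
}

# Smoothed-histogram local maxima accepted greedily under exclusion.
find_peak_centers <- function(d, len, sigma, exclusion_bp) {
  h <- tabulate(d + 1L, nbins = len)
  half <- ceiling(4 * sigma)
  kern <- dnorm(seq(-half, half), sd = sigma)
  s <- stats::filter(h, kern, sides = 2)
  s[is.na(s)] <- 0
  n <- length(s)
  if (n < 3L) return(integer(0))
  s <- as.numeric(s)
  # local maxima: strictly above the previous bp, at least equal to the next
  # (leftmost point of a plateau wins)
  cand <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
  cand <- cand[s[cand] > 0]
  if (length(cand) == 0L) return(integer(0))
  ord <- cand[order(-s[cand], cand)]
  accepted <- integer(0)
  for (p in ord) {
    if (length(accepted) == 0L || min(abs(accepted - p)) >= exclusion_bp) {
      accepted <- c(accepted, p)
    }
  }
  sort(accepted) - 1L  # back to 0-based coordinates
}

# Assign each dyad to the nearest call center within 73 bp (ties: leftmost).
assign_members <- function(d, centers) {
  idx <- findInterval(d, centers)
  left <- pmax(idx, 1L)
  right <- pmin(idx + 1L, length(centers))
  dl <- abs(d - centers[left])
  dr <- abs(d - centers[right])
  call <- ifelse(dl <= dr, left, right)
  dist <- pmin(dl, dr)
  keep <- dist <= 73L
  list(dyad = d[keep], call = call[keep])
}

#' @export
print.nuc_calls <- function(x, ...) {
  cat("Nucleosome calls:", nrow(x), "calls on",
      length(unique(x$chrom)), "chromosome(s)\n")
  cat(sprintf("  sigma=%g bp, exclusion=%d bp, min_reads=%d, total mapped=%g\n",
              attr(x, "sigma"), attr(x, "exclusion_bp"),
              attr(x, "min_reads"), attr(x, "total_reads")))
  if (nrow(x)) {
    cat(sprintf("  median fuzziness %.1f bp, median read count %d\n",
                stats::median(x$fuzziness), as.integer(stats::median(x$read_count))))
  }
  invisible(x)
}

#' Non-overlapping windowed nucleosome occupancy
#'
#' Tiles each chromosome with fixed windows from position 0, counts tag dyads
#' per window and normalizes to reads per million mapped.
#'
#' @param dyads data.frame (chrom, dyad).
#' @param chrom_sizes named chromosome lengths (bp).
#' @param window_bp window width (150/300/500 give consistent genome scans).
#' @param total_reads total mapped reads (defaults to `nrow(dyads)`).
#' @return data.frame chrom, start, end, count, occupancy.
#' @export
window_occupancy <- function(dyads, chrom_sizes, window_bp = 500L,
                             total_reads = nrow(dyads)) {
  stopifnot(window_bp >= 1)
  out <- lapply(names(chrom_sizes), function(ch) {
    len <- as.integer(chrom_sizes[[ch]])
    nwin <- ceiling(len / window_bp)
    start <- (seq_len(nwin) - 1L) * window_bp
    d <- dyads$dyad[dyads$chrom == ch]
    cnt <- tabulate(d %/% window_bp + 1L, nbins = nwin)
    data.frame(chrom = ch, start = start,
               end = pmin(start + window_bp, len), count = cnt,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$occupancy <- if (total_reads > 0) res$count * 1e6 / total_reads else 0
  rownames(res) <- NULL
  res
}

#' Fuzziness of one nucleosome call
#'
#' Population standard deviation of the dyad coordinates of the reads
#' defining the nucleosome; a single-read call has fuzziness 0.
#'
#' @param member_dyads dyad coordinates of the member reads (length >= 1).
#' @export
fuzziness_of <- function(member_dyads) {
  if (length(member_dyads) == 0L) {
    stop("fuzziness is undefined for a call with no member reads")
  }
  pop_sd(member_dyads)
}
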