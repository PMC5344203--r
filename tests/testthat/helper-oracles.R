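# Independent oracles and shared fixtures for the test suite.

# Exhaustive matching oracle: maximize matched pairs, then minimize total
# |dyad_b - dyad_a|, under the pairing constraint |delta| <= maxs.
oracle_match <- function(da, db, maxs = 127) {
  best <- list(card = -1L, cost = Inf)
  rec <- function(i, used_b, card, cost) {
    if (i > length(da)) {
      if (card > best$card || (card == best$card && cost < best$cost)) {
        best <<- list(card = card, cost = cost)
      }
      return(invisible())
    }
    rec(i + 1L, used_b, card, cost)
    for (j in seq_along(db)) {
      if (!used_b[j] && abs(da[i] - db[j]) <= maxs) {
        used_b[j] <- TRUE
        rec(i + 1L, used_b, card + 1L, cost + abs(da[i] - db[j]))
        used_b[j] <- FALSE
      }
    }
  }
  rec(1L, logical(length(db)), 0L, 0)
  best
}

# Brute-force nucleosome-free gap computation inside one enhancer: scan
# every position and collect maximal runs not covered by any footprint.
oracle_ndr_gaps <- function(start, end, dyads, min_len = 150L) {
  pos <- start:(end - 1L)
  blocked <- rep(FALSE, length(pos))
  for (d in dyads) {
    hit <- pos >= d - 73L & pos <= d + 73L
    blocked <- blocked | hit
  }
  runs <- rle(!blocked)
  out <- NULL
  at <- start
  for (k in seq_along(runs$lengths)) {
    if (runs$values[k] && runs$lengths[k] >= min_len) {
      out <- rbind(out, c(at, at + runs$lengths[k]))
    }
    at <- at + runs$lengths[k]
  }
  if (is.null(out)) {
    matrix(integer(0), 0L, 2L)
  } else {
    out
  }
}

# Shared synthetic data set (full default genome), built once per test run.
.fixtures <- new.env()
shared_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- simulate_chromatin(synthetic_config(seed = 7))
  }
  .fixtures$sim
}

shared_calls <- function() {
  if (is.null(.fixtures$calls)) {
    sim <- shared_sim()
    cs <- sim$annotation$chrom_sizes
    .fixtures$dyads <- lapply(sim$mnase, reads_to_dyads, chrom_sizes = cs)
    .fixtures$calls <- lapply(.fixtures$dyads, call_nucleosomes,
                              chrom_sizes = cs)
  }
  list(dyads = .fixtures$dyads, calls = .fixtures$calls,
       sim = .fixtures$sim)
}

make_calls <- function(dyads, chrom = "chr1") {
  data.frame(chrom = rep(chrom, length(dyads)), dyad = as.integer(dyads),
             stringsAsFactors = FALSE)
}

make_tags <- function(chrom, pos5, strand) {
  data.frame(chrom = chrom, pos5 = as.integer(pos5), strand = strand,
             stringsAsFactors = FALSE)
}
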