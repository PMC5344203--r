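# Enhancer identification: Poisson sliding-window peaks, peak merging,
# mixture threshold, promoter-like filtering, background thresholds,
# state classification, nearest genes, synergy.

test_that("a planted enrichment region becomes exactly one peak", {
  set.seed(40)
  cs <- c(chr1 = 200000L)
  bg <- make_tags("chr1", sample.int(200000L, 200L) - 1L,
                  sample(c("+", "-"), 200L, TRUE))      # 1 tag/kb
  hot <- make_tags("chr1", sample(100000:101999, 20L * 2L, TRUE),
                   sample(c("+", "-"), 40L, TRUE))      # 2 kb at 10x
  tags <- rbind(bg, hot)
  pk <- call_mark_peaks(tags, cs, window_bp = 1000L, step_bp = 100L,
                        fdr = 0.001)
  expect_equal(nrow(pk), 1L)
  # the peak covers the planted region, up to one window of overhang
  expect_lte(pk$start, 100000L)
  expect_gte(pk$end, 102000L)
  expect_lte(pk$end - pk$start, 2000L + 2L * 1000L)
  # independent check of the windowed Poisson + BH computation
  starts <- seq(0L, 199000L, 100L)
  cnt <- vapply(starts, function(s0)
    sum(tags$pos5 >= s0 & tags$pos5 < s0 + 1000L), integer(1))
  lam <- nrow(tags) / 200000 * 1000
  padj <- p.adjust(ppois(cnt - 1L, lam, lower.tail = FALSE), "BH")
  sig <- starts[padj <= 0.001]
  expect_equal(min(sig), pk$start)
  expect_equal(max(sig) + 1000L, pk$end)

  expect_equal(nrow(call_mark_peaks(bg[0, ], cs)), 0L)
})

test_that("nearby significant windows merge into one peak", {
  set.seed(41)
  cs <- c(chr1 = 100000L)
  hot1 <- make_tags("chr1", sample(40000:40999, 40, TRUE), "+")
  hot2 <- make_tags("chr1", sample(42500:43499, 40, TRUE), "+")
  bg <- make_tags("chr1", sample.int(100000L, 100L) - 1L, "+")
  pk <- call_mark_peaks(rbind(hot1, hot2, bg), cs)
  expect_equal(nrow(pk), 1L)  # separated < 1000 bp -> merged
})

test_that("peak-set merging keeps the highest-scoring overlap member", {
  pa <- data.frame(chrom = "chr1", start = 100L, end = 600L, score = 10)
  pb <- data.frame(chrom = "chr1", start = 400L, end = 900L, score = 7)
  m <- merge_peak_sets(pa, pb)
  expect_equal(nrow(m), 1L)
  expect_equal(m$score, 10)
  expect_equal(m$start, 100L)

  disj <- merge_peak_sets(pa, data.frame(chrom = "chr1", start = 5000L,
                                         end = 5600L, score = 3))
  expect_equal(nrow(disj), 2L)
  ident <- merge_peak_sets(pa, pa)
  expect_equal(nrow(ident), 1L)
})

test_that("two-Gaussian EM threshold separates and flags correctly", {
  set.seed(12)
  v <- c(rnorm(2500, 2, 0.5), rnorm(2500, 8, 1))
  fit <- fit_two_gaussian_threshold(v, seed = 3)
  expect_false(fit$degenerate)
  expect_true(fit$converged)
  expect_gt(fit$threshold, 3.5); expect_lt(fit$threshold, 6.5)
  truth <- rep(c(FALSE, TRUE), each = 2500)
  expect_gte(mean((v > fit$threshold) == truth), 0.98)
  # independent oracle: a model-based mixture fit recovers the same means
  suppressMessages(library(mclust))
  mc <- Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(unname(mc$parameters$mean)), fit$means, tolerance = 0.05)

  expect_true(fit_two_gaussian_threshold(rnorm(5000, 5, 1),
                                         seed = 3)$degenerate)
  pm <- fit_two_gaussian_threshold(rep(c(0, 10), each = 100), seed = 1)
  expect_equal(pm$threshold, 5, tolerance = 0.01)
})

test_that("promoter-like peaks are removed by the H3K4me3 filter", {
  # 300 peaks, 30% promoter-like with 10x H3K4me3 signal
  set.seed(42)
  n <- 300L
  cs <- c(chr1 = 1000000L)
  starts <- seq(1000L, by = 3000L, length.out = n)
  peaks <- data.frame(chrom = "chr1", start = starts, end = starts + 1000L,
                      score = 5)
  promoter_like <- rep(c(TRUE, FALSE), c(90L, 210L))
  cnt <- ifelse(promoter_like, 50L, 5L)
  pos <- unlist(lapply(seq_len(n), function(i)
    sample(starts[i]:(starts[i] + 999L), cnt[i], TRUE)))
  k4me3 <- list(A = make_tags("chr1", pos, "+"))
  fl <- filter_peaks_to_enhancers(peaks, k4me3)
  removed_promoterlike <- sum(promoter_like & !seq_len(n) %in%
                                which(peaks$start %in% fl$enhancers$start))
  expect_gte(mean(promoter_like[!peaks$start %in% fl$enhancers$start]),
             0.95)  # what was removed is promoter-like
  expect_gte(sum(promoter_like & !peaks$start %in% fl$enhancers$start) /
               sum(promoter_like), 0.95)  # >= 95% of promoter-like removed
  expect_lte(sum(!promoter_like & !peaks$start %in% fl$enhancers$start) /
               sum(!promoter_like), 0.05)  # <= 5% true enhancers lost

  # all-zero H3K4me3 -> degenerate mixture -> abort with diagnostics
  zero <- list(A = make_tags("chr1", 1L, "+"))
  expect_error(filter_peaks_to_enhancers(peaks, zero), "degenerate")
  # manual threshold override honored exactly
  manual <- filter_peaks_to_enhancers(peaks, k4me3, threshold = 1e9)
  expect_equal(nrow(manual$enhancers), n)
})

test_that("background threshold implements nearest-rank top decile", {
  expect_equal(top_decile_min(1:100), 91)
  expect_equal(top_decile_min(rep(0, 50)), 0)
  expect_equal(top_decile_min(c(5, 1, 9, 3)), 9)  # ceil(4/10) = 1 value

  set.seed(43)
  cs <- c(chr1 = 3000000L)
  tags <- make_tags("chr1", sample.int(3000000L, 6000L) - 1L, "+")  # 2/kb
  bg <- background_threshold(tags, cs, n_regions = 400L, seed = 9)
  expect_equal(bg$threshold, top_decile_min(bg$levels))
  expect_equal(nrow(bg$regions), 400L)
  # regions are non-overlapping
  o <- order(bg$regions$start)
  expect_true(all(diff(bg$regions$start[o]) >= 1000L))
  # threshold sits near the analytic Poisson(2) upper decile
  reads_at_thr <- bg$threshold * 1000 * nrow(tags) / 1e9
  expect_gte(reads_at_thr, qpois(0.85, 2))
  expect_lte(reads_at_thr, qpois(0.97, 2))

  expect_error(background_threshold(tags, c(chr1 = 5000L), 400L), "small")
  expect_error(background_threshold(tags, cs, 5L), "10")
})

test_that("enhancer states follow the two-threshold rule", {
  k4 <- matrix(c(6, 6, 4, 6, 6, 4), 3, 2,
               dimnames = list(NULL, c("A", "B")))
  k27 <- matrix(c(5, 3, 9, 5, 5, 9), 3, 2,
                dimnames = list(NULL, c("A", "B")))
  cls <- classify_enhancer_states(k4, k27, t_k4me1 = 5.5, t_k27ac = 4.5)
  expect_equal(unname(cls$states[, "A"]), c("active", "poised", "off"))
  expect_equal(unname(cls$states[, "B"]), c("active", "active", "off"))
  expect_equal(sum(cls$transitions), 3)
  # re-running classification is idempotent
  cls2 <- classify_enhancer_states(k4, k27, 5.5, 4.5)
  expect_identical(cls, cls2)
  expect_error(classify_enhancer_states(k4, k27, NA, 4.5), "missing")
})

test_that("nearest-gene assignment minimizes TSS distance with ties by id", {
  genes <- data.frame(gene_id = c("gB", "gA", "gC"), chrom = "chr1",
                      strand = c("+", "-", "+"),
                      tss = c(3000L, 8000L, 6000L))
  enh <- data.frame(chrom = "chr1", start = 4500L, end = 5500L)
  ng <- assign_nearest_gene(enh, genes)
  expect_equal(ng$gene_id, "gC")  # midpoint 5000; distances 2000/3000/1000
  expect_equal(ng$distance, 1000)
  expect_equal(ng$signed_distance, -1000)  # upstream of gC (+ strand)

  tie <- assign_nearest_gene(data.frame(chrom = "chr1", start = 4000L,
                                        end = 5000L),
                             genes[1:2, ])  # midpoint 4500: 1500 vs 3500
  expect_equal(tie$gene_id, "gB")
  eq <- assign_nearest_gene(data.frame(chrom = "chr1", start = 5000L,
                                       end = 6000L),
                            genes[1:2, ])  # midpoint 5500: 2500 vs 2500
  expect_equal(eq$gene_id, "gA")  # lexicographic tie-break

  none <- assign_nearest_gene(data.frame(chrom = "chrX", start = 0L,
                                         end = 100L), genes)
  expect_true(is.na(none$gene_id))
})

test_that("synergy keeps sign-concordant genes ordered by enhancer FC", {
  x <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                  log2fc_expr = c(2, -1, 1.5, 0, 2),
                  log2fc_enh_k27ac = c(1, 1.2, 2.5, 1, -2))
  syn <- promoter_enhancer_synergy(x, fc_min = 1.5)
  expect_equal(syn$table$gene_id, c("g3", "g1"))  # descending enhancer FC
  expect_equal(syn$up, c("g3", "g1"))
  expect_equal(syn$down, character(0))
  expect_false(syn$empty)
  # opposite signs and zero fold changes never pass
  expect_false("g2" %in% syn$table$gene_id)
  expect_false("g4" %in% syn$table$gene_id)
  expect_true(promoter_enhancer_synergy(x[0, ])$empty)
})

test_that("the read-level cascade recovers planted enhancer states", {
  cc <- shared_calls()
  sim <- cc$sim
  cs <- sim$annotation$chrom_sizes
  k1 <- sim$chip$H3K4me1; k27 <- sim$chip$H3K27ac
  pa <- call_mark_peaks(k1$NSC, cs)
  pb <- call_mark_peaks(k1$neuron, cs)
  merged <- merge_peak_sets(pa, pb)
  fl <- filter_peaks_to_enhancers(merged, sim$chip$H3K4me3)
  enh <- fl$enhancers
  expect_gte(nrow(enh), 50L)
  # output is invariant under permutation of peak input order
  perm <- merged[sample.int(nrow(merged)), ]
  perm <- perm[order(perm$chrom, perm$start), ]
  expect_identical(filter_peaks_to_enhancers(perm,
                                             sim$chip$H3K4me3)$enhancers,
                   enh)

  bg1 <- background_threshold(k1$neuron, cs, nrow(enh), seed = 11,
                              total = nrow(k1$neuron))
  bg2 <- background_threshold(k27$neuron, cs, nrow(enh), seed = 12,
                              total = nrow(k27$neuron))
  iv <- enh[, c("chrom", "summit_start", "summit_end")]
  names(iv) <- c("chrom", "start", "end")
  k4l <- cbind(A = interval_rpkm(k1$NSC, iv, nrow(k1$NSC)),
               B = interval_rpkm(k1$neuron, iv, nrow(k1$neuron)))
  k27l <- cbind(A = interval_rpkm(k27$NSC, iv, nrow(k27$NSC)),
                B = interval_rpkm(k27$neuron, iv, nrow(k27$neuron)))
  cls <- classify_enhancer_states(k4l, k27l, bg1$threshold, bg2$threshold)
  expect_equal(sum(cls$transitions), nrow(enh))

  tre <- sim$annotation$enhancers
  est <- sim$truth$enhancer_states
  hit <- vapply(seq_len(nrow(enh)), function(i) {
    j <- which(tre$chrom == enh$chrom[i] &
                 pmin(enh$end[i], tre$end) - pmax(enh$start[i], tre$start) > 0)
    if (length(j)) j[1] else NA_integer_
  }, integer(1))
  idx <- which(!is.na(hit))
  expect_gte(length(idx), 40L)
  expect_equal(unname(cls$states[idx, 1]), est$state_a[hit[idx]])
  expect_equal(unname(cls$states[idx, 2]), est$state_b[hit[idx]])
})
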