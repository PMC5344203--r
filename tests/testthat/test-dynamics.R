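# Cross-state matching and classification, feature enrichment, TSS
# profiles and difference clustering.

test_that("matching classifies the canonical example geometries", {
  m <- match_nucleosomes(make_calls(c(1000L)), make_calls(c(1000L)))
  expect_equal(m$status, "fixed")

  m <- match_nucleosomes(make_calls(c(1000L)), make_calls(c(1100L)))
  expect_equal(m$status, "shift")
  expect_equal(m$shift_bp, 100L)  # 47 bp footprint overlap >= 20

  m <- match_nucleosomes(make_calls(c(1000L)), make_calls(c(1140L)))
  expect_setequal(m$status, c("loss", "gain"))  # |delta| 140 > 127

  m <- match_nucleosomes(make_calls(c(1000L)), make_calls(c(1010L, 1120L)))
  expect_equal(m$dyad_b[m$status == "shift"], 1010L)
  expect_equal(m$dyad_b[m$status == "gain"], 1120L)
})

test_that("matching equals the exhaustive minimum-distance oracle", {
  set.seed(42)
  for (t in 1:120) {
    na <- sample(1:8, 1); nb <- sample(1:8, 1)
    da <- sort(sample(0:900, na)); db <- sort(sample(0:900, nb))
    m <- match_nucleosomes(make_calls(da), make_calls(db))
    s <- summary(m)
    o <- oracle_match(da, db)
    expect_equal(s$counts[["fixed"]] + s$counts[["shift"]], o$card)
    expect_equal(sum(abs(m$shift_bp), na.rm = TRUE), o$cost)
  }
})

test_that("match set partitions both call sets", {
  cc <- shared_calls()
  m <- match_nucleosomes(cc$calls[[1]], cc$calls[[2]])
  s <- summary(m)
  expect_equal(s$counts[["fixed"]] + s$counts[["shift"]] +
                 s$counts[["loss"]], nrow(cc$calls[[1]]))
  expect_equal(s$counts[["fixed"]] + s$counts[["shift"]] +
                 s$counts[["gain"]], nrow(cc$calls[[2]]))
  expect_equal(sum(s$fractions_union), 1)
})

test_that("swapping the inputs maps loss to gain and negates shifts", {
  set.seed(43)
  for (t in 1:25) {
    da <- sort(sample(seq(0, 4000, 10), 12))
    db <- sort(sample(seq(0, 4000, 10), 10))
    m1 <- summary(match_nucleosomes(make_calls(da), make_calls(db)))
    m2 <- summary(match_nucleosomes(make_calls(db), make_calls(da)))
    expect_equal(m1$counts[["loss"]], m2$counts[["gain"]])
    expect_equal(m1$counts[["gain"]], m2$counts[["loss"]])
    expect_equal(m1$counts[["shift"]], m2$counts[["shift"]])
  }
})

test_that("unsorted call sets are rejected", {
  bad <- data.frame(chrom = "chr1", dyad = c(500L, 100L))
  expect_error(match_nucleosomes(bad, make_calls(100L)), "sorted")
})

test_that("planted dynamics fractions are recovered end-to-end", {
  cfg <- synthetic_config(n_genes = 0L, n_enhancers = 0L, seed = 3)
  ann <- build_annotation(cfg)
  truth <- plant_nucleosome_truth(ann, cfg)
  calls <- lapply(1:2, function(si) {
    tags <- sample_mnase_reads(truth, cfg, si, ann$chrom_sizes)
    call_nucleosomes(reads_to_dyads(tags, ann$chrom_sizes),
                     chrom_sizes = ann$chrom_sizes)
  })
  f <- summary(match_nucleosomes(calls[[1]], calls[[2]]))$fractions_union
  planted <- table(truth$nucleosomes$label) / nrow(truth$nucleosomes)
  # loss and gain recover within 3 points; fixed leaks into shift under
  # calling noise (called dyads rarely agree to the exact bp), so the
  # matched total is compared for those two classes combined
  expect_lt(abs(f[["loss"]] - planted[["loss"]]), 0.03)
  expect_lt(abs(f[["gain"]] - planted[["gain"]]), 0.03)
  expect_lt(abs((f[["fixed"]] + f[["shift"]]) -
                  (planted[["fixed"]] + planted[["shift"]])), 0.03)
})

test_that("feature classes partition calls with promoter precedence", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(5000L, 15000L),
                      tes = c(8000L, 12000L))
  cs <- c(chr1 = 40000L)
  # 10 dyads inside promoters, total promoter length 4 kb -> 2.5 per kb
  calls <- data.frame(chrom = "chr1",
                      dyad = c(seq(4200L, 5800L, length.out = 10),
                               7000L, 13000L,  # genic (g1 body / g2 body)
                               30000L, 35000L))  # intergenic
  fe <- feature_enrichment(calls, genes, cs)
  expect_equal(fe$n_calls[fe$class == "promoter"], 10L)
  expect_equal(fe$density[fe$class == "promoter"], 10 / 4)
  expect_equal(fe$n_calls[fe$class == "genic"], 2L)
  expect_equal(fe$n_calls[fe$class == "intergenic"], 2L)
  # a dyad in the promoter/genic overlap counts as promoter
  fe2 <- feature_enrichment(data.frame(chrom = "chr1", dyad = 5500L),
                            genes, cs)
  expect_equal(fe2$n_calls[fe2$class == "promoter"], 1L)
  expect_equal(fe2$n_calls[fe2$class == "genic"], 0L)
  # class lengths partition the genome
  expect_equal(sum(fe$length_kb), 40)
})

test_that("uniform dyads give near-equal feature densities", {
  genes <- data.frame(gene_id = sprintf("g%d", 1:8), chrom = "chr1",
                      strand = "+", tss = seq(10000L, 80000L, 10000L),
                      tes = seq(10000L, 80000L, 10000L) + 4000L)
  set.seed(20)
  calls <- data.frame(chrom = "chr1",
                      dyad = sample.int(100000L, 10000L, replace = TRUE))
  fe <- feature_enrichment(calls, genes, c(chr1 = 100000L))
  expect_true(all(abs(fe$density / mean(fe$density) - 1) < 0.1))
})

test_that("TSS composite profile is flat for uniform tags", {
  genes <- data.frame(gene_id = sprintf("g%d", 1:20), chrom = "chr1",
                      strand = rep(c("+", "-"), 10),
                      tss = seq(5000L, 100000L, 5000L))
  set.seed(21)
  dyads <- data.frame(chrom = "chr1",
                      dyad = sample.int(110000L, 1e6, replace = TRUE))
  prof <- tss_composite_profile(dyads, genes, c(chr1 = 110000L),
                                "occupancy", total_reads = 1e6)
  cv <- sd(prof$value) / mean(prof$value)
  expect_lt(cv, 0.05)
  expect_equal(nrow(prof), 400L)  # 2000 / 5-bp bins
})

test_that("profile extrema localize a planted NDR and +1 nucleosome", {
  cc <- shared_calls()
  sim <- cc$sim
  prof <- tss_composite_profile(cc$dyads[[2]], sim$annotation$genes,
                                sim$annotation$chrom_sizes, "occupancy",
                                total_reads = nrow(sim$mnase[[2]]))
  # neurons: every NDR is nucleosome-free; the promoter-proximal minimum
  # falls inside [-200, +50], the +1 nucleosome peak within [+25, +125]
  central <- prof[abs(prof$distance) <= 500, ]
  expect_true(central$distance[which.min(central$value)] >= -200 &&
                central$distance[which.min(central$value)] <= 50)
  # the +1 nucleosome: strongest signal downstream of the NDR
  inner <- prof[prof$distance > -50 & prof$distance < 200, ]
  expect_true(inner$distance[which.max(inner$value)] >= 25 &&
                inner$distance[which.max(inner$value)] <= 125)
})

test_that("profile modes: call density and fuzziness", {
  cc <- shared_calls()
  sim <- cc$sim
  cd <- tss_composite_profile(cc$calls[[1]], sim$annotation$genes,
                              sim$annotation$chrom_sizes, "call_density",
                              bin_bp = 10L, ma_bins = 3L,
                              total_reads = nrow(sim$mnase[[1]]))
  expect_equal(nrow(cd), 200L)
  fz <- tss_composite_profile(cc$calls[[1]], sim$annotation$genes,
                              sim$annotation$chrom_sizes, "fuzziness",
                              bin_bp = 50L, ma_bins = 1L,
                              total_reads = nrow(sim$mnase[[1]]))
  expect_true(all(fz$value[!is.na(fz$value)] >= 0))
  expect_error(tss_composite_profile(cc$calls[[1]], sim$annotation$genes,
                                     sim$annotation$chrom_sizes,
                                     "occupancy", bin_bp = 3L),
               "divide")
})

test_that("difference clustering recovers planted archetypes", {
  set.seed(13)
  arch <- list(c(rep(0, 100), rep(5, 100)), c(rep(5, 100), rep(0, 100)),
               rep(5, 200), rep(-5, 200), c(rep(-5, 100), rep(5, 100)))
  D <- do.call(rbind, lapply(arch, function(a) {
    matrix(rep(a, each = 100), 100, byrow = FALSE) +
      matrix(rnorm(100 * 200, 0, 0.5), 100)
  }))
  rownames(D) <- sprintf("g%03d", seq_len(nrow(D)))
  A <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  cl <- tss_difference_clusters(A, D, k = 5, seed = 3)
  ari <- mclust::adjustedRandIndex(cl$labels, rep(1:5, each = 100))
  expect_gte(ari, 0.9)
  expect_false(cl$degenerate)
  expect_false(is.unsorted(cl$labels[rownames(cl$ordered)]))

  # identical matrices -> degenerate flag; k = 1 -> one label
  d0 <- tss_difference_clusters(A, A, k = 5, seed = 3)
  expect_true(d0$degenerate)
  d1 <- tss_difference_clusters(A, D, k = 1, seed = 3)
  expect_equal(unique(d1$labels), 1L)
})
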