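# Synthetic-data generator: annotation geometry, planted truth, read
# sampling, expression coupling, determinism.

test_that("annotation geometry honors promoter and enhancer constraints", {
  cfg <- synthetic_config(n_genes = 100L, n_enhancers = 20L, seed = 3)
  ann <- build_annotation(cfg)
  expect_equal(nrow(ann$genes), 100L)
  expect_equal(nrow(ann$enhancers), 20L)
  expect_true(all(c("+", "-") %in% ann$genes$strand))
  # promoters (+/- 1 kb) never overlap: TSSs on a chromosome >= 2 kb apart
  for (ch in unique(ann$genes$chrom)) {
    tss <- sort(ann$genes$tss[ann$genes$chrom == ch])
    if (length(tss) > 1L) expect_true(all(diff(tss) >= 2000L))
  }
  # enhancers >= 2 kb from every TSS
  for (i in seq_len(nrow(ann$enhancers))) {
    tss <- ann$genes$tss[ann$genes$chrom == ann$enhancers$chrom[i]]
    d <- pmin(abs(tss - ann$enhancers$start[i]),
              abs(tss - ann$enhancers$end[i]))
    expect_true(all(d >= 2000L))
  }
})

test_that("zero-element and capacity edge cases behave", {
  cfg <- synthetic_config(n_genes = 10L, n_enhancers = 0L, seed = 1)
  expect_equal(nrow(build_annotation(cfg)$enhancers), 0L)
  tight <- synthetic_config(n_chroms = 1L, chrom_length = 5e4,
                            n_genes = 50L, n_enhancers = 0L, seed = 1)
  expect_error(build_annotation(tight), "too short")
})

test_that("identical config and seed reproduce byte-identical outputs", {
  cfg <- synthetic_config(n_genes = 20L, n_enhancers = 5L,
                          chrom_length = 2e5, seed = 9)
  s1 <- simulate_chromatin(cfg, marks = "H3K4me3")
  s2 <- simulate_chromatin(cfg, marks = "H3K4me3")
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$truth$nucleosomes, s2$truth$nucleosomes)
  expect_identical(as.data.frame(s1$mnase[[1]]), as.data.frame(s2$mnase[[1]]))
  expect_identical(s1$expression, s2$expression)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f2))))
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(synthetic_config(dynamics_fractions = c(
    fixed = 0.5, shift = 0.4, loss = 0.05, gain = 0.02)), "sum to 1")
  expect_error(synthetic_config(shift_range = c(0L, 120L)), "shift_range")
  expect_error(synthetic_config(shift_range = c(1L, 128L)), "shift_range")
  expect_error(synthetic_config(coverage = 0), "coverage")
})

test_that("planted dynamics labels agree with direct dyad-map comparison", {
  cfg <- synthetic_config(n_genes = 0L, n_enhancers = 0L,
                          chrom_length = 3e5, n_chroms = 1L, seed = 4)
  truth <- plant_nucleosome_truth(build_annotation(cfg), cfg)
  nt <- truth$nucleosomes
  # label semantics recovered by comparing the two dyad columns directly
  expect_true(all(nt$label[is.na(nt$dyad_b)] == "loss"))
  expect_true(all(nt$label[is.na(nt$dyad_a)] == "gain"))
  both <- !is.na(nt$dyad_a) & !is.na(nt$dyad_b)
  delta <- nt$dyad_b[both] - nt$dyad_a[both]
  expect_true(all((delta == 0L) == (nt$label[both] == "fixed")))
  shifts <- abs(delta[nt$label[both] == "shift"])
  expect_true(all(shifts >= cfg$shift_range[1] & shifts <= cfg$shift_range[2]))
  # configured fractions are met up to block-quota rounding
  frac <- table(nt$label)[c("fixed", "shift", "loss", "gain")] / nrow(nt)
  expect_true(all(abs(frac - cfg$dynamics_fractions[names(frac)]) < 0.02))
})

test_that("all-fixed fractions give two identical maps", {
  cfg <- synthetic_config(n_genes = 0L, n_enhancers = 0L,
                          chrom_length = 1e5, n_chroms = 1L,
                          dynamics_fractions = c(fixed = 1, shift = 0,
                                                 loss = 0, gain = 0),
                          seed = 2)
  nt <- plant_nucleosome_truth(build_annotation(cfg), cfg)$nucleosomes
  expect_identical(nt$dyad_a, nt$dyad_b)
  expect_true(all(nt$label == "fixed"))
})

test_that("MNase read sampling matches its generative model", {
  cfg <- synthetic_config(n_genes = 0L, n_enhancers = 0L,
                          chrom_length = 2e5, n_chroms = 1L,
                          coverage = 20, seed = 6)
  ann <- build_annotation(cfg)
  truth <- plant_nucleosome_truth(ann, cfg)
  tags <- sample_mnase_reads(truth, cfg, 1, ann$chrom_sizes)
  n_nuc <- sum(!is.na(truth$nucleosomes$dyad_a))
  expect_lt(abs(nrow(tags) - 20 * n_nuc), 3 * sqrt(20 * n_nuc) + 3 * 20)
  expect_true(all(tags$pos5 >= 0 & tags$pos5 < cfg$chrom_length))

  # zero fuzziness: every read dyad equals a planted dyad
  cfg0 <- synthetic_config(n_genes = 0L, n_enhancers = 0L,
                           chrom_length = 1e5, n_chroms = 1L,
                           fuzziness_bp = 0, seed = 6)
  ann0 <- build_annotation(cfg0)
  tr0 <- plant_nucleosome_truth(ann0, cfg0)
  t0 <- sample_mnase_reads(tr0, cfg0, 1, ann0$chrom_sizes)
  dy <- reads_to_dyads(t0, ann0$chrom_sizes)
  expect_true(all(dy$dyad %in% tr0$nucleosomes$dyad_a))

  # planted fuzziness is recovered as the per-nucleosome read-dyad sd
  cfg2 <- synthetic_config(n_genes = 0L, n_enhancers = 0L,
                           chrom_length = 2e5, n_chroms = 1L,
                           coverage = 200, fuzziness_bp = 20, seed = 6)
  ann2 <- build_annotation(cfg2)
  tr2 <- plant_nucleosome_truth(ann2, cfg2)
  t2 <- sample_mnase_reads(tr2, cfg2, 1, ann2$chrom_sizes)
  dy2 <- reads_to_dyads(t2, ann2$chrom_sizes)
  planted <- tr2$nucleosomes$dyad_a[!is.na(tr2$nucleosomes$dyad_a)][10:19]
  sds <- vapply(planted, function(p) {
    sd(dy2$dyad[abs(dy2$dyad - p) <= 73])
  }, numeric(1))
  expect_true(all(abs(sds - 20) <= 3))
})

test_that("promoter ChIP levels are bimodal when planted bimodal", {
  sim <- shared_sim()
  tags <- sim$chip$H3K4me3$NSC
  lv <- promoter_mark_levels(tags, sim$annotation$genes, nrow(tags))
  thr <- valley_threshold(as.numeric(lv))
  expect_true(thr$ok)  # a valley exists between the two modes
  # zero elements and zero background give an empty stream
  cfg0 <- synthetic_config(n_genes = 0L, n_enhancers = 0L,
                           chrom_length = 1e5, n_chroms = 1L,
                           chip_background_per_kb = 0, seed = 2)
  ann0 <- build_annotation(cfg0)
  tr0 <- plant_nucleosome_truth(ann0, cfg0)
  expect_equal(nrow(sample_hm_reads(ann0, tr0, cfg0, "H3K9ac", 1)), 0L)
})

test_that("expression is coupled to planted NDR occupancy as configured", {
  cfg <- synthetic_config(n_genes = 200L, n_enhancers = 0L,
                          chrom_length = 6e5, seed = 8,
                          expression_coupling = 1)
  ann <- build_annotation(cfg)
  truth <- plant_nucleosome_truth(ann, cfg)
  expr <- sample_expression(ann, truth, cfg)
  occ <- truth$ndr_occupancy[expr$gene_id]
  rho <- cor(occ, expr$fpkm_NSC, method = "spearman")
  expect_lt(rho, -0.5)

  cfg0 <- synthetic_config(n_genes = 200L, n_enhancers = 0L,
                           chrom_length = 6e5, seed = 8,
                           expression_coupling = 0)
  tr0 <- plant_nucleosome_truth(ann, cfg0)
  e0 <- sample_expression(ann, tr0, cfg0)
  rho0 <- cor(tr0$ndr_occupancy[e0$gene_id], e0$fpkm_NSC,
              method = "spearman")
  expect_lt(abs(rho0), 0.15)

  # no noise, no coupling, no synergy cases: all genes share one FPKM
  cfg1 <- synthetic_config(n_genes = 50L, n_enhancers = 0L,
                           chrom_length = 3e5, seed = 8,
                           expression_coupling = 0, expression_noise_sd = 0)
  ann1 <- build_annotation(cfg1)
  tr1 <- plant_nucleosome_truth(ann1, cfg1)
  e1 <- sample_expression(ann1, tr1, cfg1)
  expect_equal(length(unique(round(e1$fpkm_NSC, 9))), 1L)
})

test_that("synergy genes get expression change matching enhancer K27ac", {
  sim <- shared_sim()
  syn <- sim$truth$synergy
  if (nrow(syn)) {
    expr <- sim$expression
    j <- match(syn$gene_id, expr$gene_id)
    fc <- log2((expr$fpkm_neuron[j] + 1) / (expr$fpkm_NSC[j] + 1))
    expect_true(all(sign(fc) == syn$sign))
  }
  # truth files round-trip through TSV
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  nt <- read.table(file.path(d, "truth_nucleosomes.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(nt), nrow(sim$truth$nucleosomes))
  expect_equal(nt$dyad_a, sim$truth$nucleosomes$dyad_a)
})
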