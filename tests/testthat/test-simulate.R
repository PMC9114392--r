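test_that("a null configuration plants nothing and keeps conditions balanced", {
  sim <- simulate_apa_dataset(sim_config(
    n_multi_utr_genes = 800, n_single_utr_genes = 200,
    frac_gene_up = 0, frac_su_up = 0, pau_shift = 0, seed = 42))
  expect_equal(sum(sim$truth$planted_gene_up), 0)
  expect_equal(sum(sim$truth$planted_su_up), 0)
  expect_true(all(sim$truth$planted_category %in% c("gene_not_up")))
  byc <- tapply(sim$counts$count, sim$counts$condition, sum)
  expect_lt(abs(log2(byc[["B"]] / byc[["A"]])), 0.1)
})

test_that("the generator output satisfies its structural contract", {
  sim <- simulate_apa_dataset(sim_config(
    n_multi_utr_genes = 50, n_single_utr_genes = 10, seed = 7))
  expect_silent(validate_isoform_table(sim$counts))
  expect_setequal(unique(sim$truth$gene_id), unique(sim$counts$gene_id))
  # TPM sums to 1e6 per sample
  tot <- tapply(sim$counts$tpm, sim$counts$sample, sum)
  expect_equal(as.numeric(tot), rep(1e6, 6), tolerance = 1e-9)
  # SU + LU = gene total for multi-UTR genes
  multi <- sim$counts[sim$counts$isoform_class != "SINGLE", ]
  expect_true(all(multi$count >= 0))
})

test_that("planted gene-level fold changes are recovered on average", {
  # Monte-Carlo check against the generative mean over 20 seeds
  obs <- vapply(1:20, function(s) {
    sim <- simulate_apa_dataset(sim_config(
      n_multi_utr_genes = 4000, n_single_utr_genes = 1000,
      gene_log2fc = 1, frac_su_up = 0, pau_shift = 0, seed = s))
    gc <- gene_counts_of(sim$counts)
    m <- tidyr::pivot_wider(gc[, c("gene_id", "sample", "count")],
                            names_from = sample, values_from = count)
    up <- m$gene_id %in% sim$truth$gene_id[sim$truth$planted_gene_up]
    a <- rowMeans(m[up, c("A_1", "A_2", "A_3")])
    b <- rowMeans(m[up, c("B_1", "B_2", "B_3")])
    mean(log2(b / a))
  }, numeric(1))
  expect_lt(abs(mean(obs) - 1), 0.1)
})

test_that("identical seeds give bitwise identical datasets", {
  cfg <- sim_config(n_multi_utr_genes = 300, n_single_utr_genes = 50,
                    seed = 123)
  s1 <- simulate_apa_dataset(cfg)
  s2 <- simulate_apa_dataset(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_apa_dataset(sim_config(n_multi_utr_genes = 300,
                                        n_single_utr_genes = 50, seed = 124))
  expect_false(identical(s1$counts$count, s3$counts$count))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(pau_baseline = 0.9, pau_shift = 0.2),
               "pau_baseline \\+ pau_shift")
  expect_error(sim_config(enhancer_background_rate = 0.5,
                          enhancer_relative_risk = 3),
               "relative_risk")
  expect_error(sim_config(n_replicates_per_condition = 1),
               "n_replicates_per_condition")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
})

test_that("enhancer flags follow background rate and relative risk", {
  truth <- tibble::tibble(
    gene_id = sprintf("g%05d", 1:10000),
    planted_gene_up = rep(c(TRUE, FALSE), c(5000, 5000)),
    planted_su_up = FALSE
  )
  enh <- assign_enhancers(truth, background_rate = 0.10,
                          relative_risk = 3, seed = 5)
  frac_planted <- mean(enh$enhancer[truth$planted_gene_up])
  frac_bg <- mean(enh$enhancer[!truth$planted_gene_up])
  expect_lt(abs(frac_planted - 0.30), 0.02)
  expect_lt(abs(frac_bg - 0.10), 0.02)

  # relative risk 1: no difference beyond binomial noise
  enh1 <- assign_enhancers(truth, 0.10, 1, seed = 6)
  d <- abs(mean(enh1$enhancer[truth$planted_gene_up]) -
             mean(enh1$enhancer[!truth$planted_gene_up]))
  expect_lt(d, 3 * sqrt(2 * 0.1 * 0.9 / 5000))

  # zero background: nothing flagged
  enh0 <- assign_enhancers(truth, 0, 5, seed = 7)
  expect_false(any(enh0$enhancer))

  expect_error(assign_enhancers(truth, 0.6, 2, seed = 1), "<= 1")
})

test_that("decay series follow e^(kt) exactly without noise", {
  s <- simulate_decay_series(k = log(0.5), y0 = 100,
                             timepoints = c(0, 1, 2), cv_noise = 0)
  expect_equal(s$abundance, c(100, 50, 25), tolerance = 1e-12)
  expect_error(simulate_decay_series(k = 0.1), "k")
  expect_error(simulate_decay_series(k = -1, timepoints = c(1, 2)),
               "include 0")
})

test_that("noisy decay series recover the half-life in the median", {
  # ln(0.5)/-0.3466 = 2.0 h
  t_half <- vapply(1:100, function(s) {
    ser <- simulate_decay_series(k = -0.3466, timepoints = c(0, 2, 4, 8),
                                 cv_noise = 0.05, seed = s)
    fit_decay(ser)$half_life
  }, numeric(1))
  expect_lt(abs(median(t_half) - 2.0) / 2.0, 0.02)
})
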