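test_that("size factors reproduce the hand-computed median-of-ratios values", {
  m <- cbind(s1 = c(10, 30, 50), s2 = c(20, 60, 100))
  sf <- compute_size_factors(m)
  expect_equal(sf$size_factor, c(sqrt(0.5), sqrt(2)), tolerance = 1e-10)

  # identical samples
  m2 <- cbind(a = c(5, 8, 2), b = c(5, 8, 2), c = c(5, 8, 2))
  expect_equal(compute_size_factors(m2)$size_factor, rep(1, 3))

  # single sample
  expect_equal(compute_size_factors(cbind(x = c(3, 9)))$size_factor, 1)

  expect_error(compute_size_factors(cbind(a = c(0, 1), b = c(1, 0))),
               "positive")
})

test_that("size factors agree with the DESeq2 median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(1)
  m <- matrix(rnbinom(200 * 4, mu = 100, size = 5), ncol = 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  ours <- compute_size_factors(m)$size_factor
  ref <- unname(DESeq2::estimateSizeFactorsForMatrix(m))
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("size factors are equivariant under scaling one sample", {
  set.seed(2)
  m <- matrix(rnbinom(300 * 3, mu = 50, size = 10) + 1, ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  sf0 <- compute_size_factors(m)$size_factor
  m2 <- m
  m2[, 2] <- m2[, 2] * 4
  sf1 <- compute_size_factors(m2)$size_factor
  # scaled sample's factor scales; the reference shift 4^(1/3) hits all
  expect_equal(sf1[2] / sf0[2] / (sf1[1] / sf0[1]), 4, tolerance = 1e-8)
})

test_that("rescale_tpm divides by factors and cancels planted imbalance", {
  iso <- toy_isoform_table()
  sf1 <- tibble::tibble(sample = unique(iso$sample), size_factor = 1)
  out <- rescale_tpm(iso, sf1)
  expect_equal(out$tpm_norm, out$tpm)

  expect_equal(unname(rescale_tpm(cbind(s = 10), c(s = 2))[1, 1]), 5)

  # constructed imbalance: multiply sample expression by (0.5, 2), then
  # rescaling by those factors restores the condition fold change to ~1
  m <- cbind(x = c(100, 50, 20), y = c(100, 50, 20))
  skew <- sweep(m, 2, c(0.5, 2), "*")
  back <- rescale_tpm(skew, c(x = 0.5, y = 2))
  expect_equal(back[, "y"] / back[, "x"], rep(1, 3), ignore_attr = TRUE)

  expect_error(rescale_tpm(m, c(x = 0.5)), "match|cover")
})

test_that("PAU is SU/(SU+LU) with NA on zero coverage and dPAU = B - A", {
  iso <- toy_isoform_table()
  iso$tpm_norm <- iso$tpm
  pau <- compute_pau(iso)
  # G1 sample A_1: 60/(60+40)
  expect_equal(pau$pau_A_1[pau$gene_id == "G1"], 0.6)
  # G2 is stable at ~0.1
  expect_equal(pau$pau_A_1[pau$gene_id == "G2"], 0.1)
  expect_equal(pau$dpau,
               (pau$pau_B_1 + pau$pau_B_2) / 2 -
                 (pau$pau_A_1 + pau$pau_A_2) / 2)

  # zero SU
  iso0 <- iso
  iso0$count[iso0$isoform_id == "G1_P"] <- 0L
  iso0$tpm_norm[iso0$isoform_id == "G1_P"] <- 0
  p0 <- compute_pau(iso0)
  expect_equal(p0$pau_A_1[p0$gene_id == "G1"], 0)

  # zero both isoforms in every sample -> NA and degenerate flag
  isoNA <- iso
  sel <- isoNA$gene_id == "G1"
  isoNA$count[sel] <- 0L
  isoNA$tpm_norm[sel] <- 0
  pNA <- compute_pau(isoNA)
  expect_true(is.na(pNA$pau_A[pNA$gene_id == "G1"]))
  expect_true(is.na(pNA$dpau[pNA$gene_id == "G1"]))
  expect_true(pNA$degenerate[pNA$gene_id == "G1"])
  expect_false(pNA$degenerate[pNA$gene_id == "G2"])
})

test_that("PAU is invariant to rescaling both isoforms and SUI is the same", {
  iso <- toy_isoform_table()
  iso$tpm_norm <- iso$tpm
  base <- compute_pau(iso)
  for (const in c(0.25, 7, 1000)) {
    scaled <- iso
    scaled$tpm_norm <- scaled$tpm_norm * const
    expect_equal(compute_pau(scaled)$pau_A, base$pau_A, tolerance = 1e-12)
  }
  expect_identical(compute_sui(iso), base)
  # SU and LU shares sum to one wherever defined
  su_share <- base$pau_A_1
  lu_share <- 1 - base$pau_A_1
  expect_equal(su_share + lu_share, rep(1, nrow(base)), tolerance = 1e-12)
})

test_that("the multi-UTR filter keeps >1-isoform genes above the TPM cutoff", {
  tab <- tibble::tibble(
    gene_id = rep(c("M1", "M2", "S1"), times = c(4, 4, 2)),
    isoform_id = c("M1_P", "M1_D", "M1_P", "M1_D",
                   "M2_P", "M2_D", "M2_P", "M2_D", "S1_S", "S1_S"),
    sample = c("A_1", "A_1", "B_1", "B_1",
               "A_1", "A_1", "B_1", "B_1", "A_1", "B_1"),
    tpm = c(1.0, 1.0, 1.55, 1.55,   # M1: gene TPM 2.0 then 3.1 -> kept
            1.45, 1.45, 1.45, 1.45, # M2: gene TPM 2.9, 2.9 -> dropped
            100, 100)               # S1: single isoform -> dropped
  )
  kept <- filter_multi_utr(tab, min_tpm = 3)
  expect_equal(kept$gene_id, "M1")
  # boundary: exactly 3 TPM satisfies "at least 3"
  tab3 <- tab
  tab3$tpm[tab3$gene_id == "M2"] <- 1.5
  expect_setequal(filter_multi_utr(tab3, min_tpm = 3)$gene_id,
                  c("M1", "M2"))
})

test_that("SU fold change uses condition means with a pseudocount", {
  iso <- toy_isoform_table()
  iso$tpm_norm <- iso$tpm
  fc <- su_expression_fc(iso, pseudocount = 0)
  su <- iso[iso$isoform_class == "SU" & iso$gene_id == "G1", ]
  expected <- mean(su$tpm[su$condition == "B"]) /
    mean(su$tpm[su$condition == "A"])
  expect_equal(fc$su_fc[fc$gene_id == "G1"], expected)
  # pseudocount keeps zero-expression genes finite
  iso0 <- iso
  iso0$tpm_norm[iso0$gene_id == "G2" & iso0$isoform_class == "SU"] <- 0
  fc0 <- su_expression_fc(iso0, pseudocount = 0.01)
  expect_equal(fc0$su_fc[fc0$gene_id == "G2"], 1)
})
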