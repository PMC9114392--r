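test_that("contingency_chisq matches the closed-form worked examples", {
  hom <- contingency_chisq(10, 10, 10, 10)
  expect_equal(hom$chisq, 0)
  expect_equal(hom$p_value, 1)

  t1 <- contingency_chisq(30, 70, 10, 90)
  expect_equal(t1$chisq, 12.5, tolerance = 1e-12)

  t2 <- contingency_chisq(10, 10, 10, 90)
  expect_equal(t2$chisq, 19.2, tolerance = 1e-12)
  expect_equal(t2$odds_ratio, 9)
  expect_equal(t2$frac1, 0.5)
  expect_equal(t2$frac2, 0.1)

  expect_error(contingency_chisq(0, 0, 5, 5), "margin")
})

test_that("contingency_chisq equals stats::chisq.test with matching options", {
  res <- contingency_chisq(12, 34, 5, 49)
  ref <- suppressWarnings(
    chisq.test(matrix(c(12, 34, 5, 49), 2, byrow = TRUE), correct = FALSE))
  expect_equal(res$chisq, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  resc <- contingency_chisq(12, 34, 5, 49, correct = TRUE)
  refc <- suppressWarnings(
    chisq.test(matrix(c(12, 34, 5, 49), 2, byrow = TRUE), correct = TRUE))
  expect_equal(resc$chisq, unname(refc$statistic), tolerance = 1e-12)
})

test_that("enrichment_by_category reproduces the toy 50% vs 10% comparison", {
  cats <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:120),
    category = rep(c("su_up", "gene_not_up"), c(20, 100))
  )
  enh <- tibble::tibble(
    gene_id = cats$gene_id,
    enhancer = c(rep(TRUE, 10), rep(FALSE, 10),   # SU up: 10/20
                 rep(TRUE, 10), rep(FALSE, 90))   # control: 10/100
  )
  out <- enrichment_by_category(cats, enh)
  su <- out[out$category == "su_up", ]
  expect_equal(su$fraction, 0.5)
  expect_equal(out$fraction[out$category == "gene_not_up"], 0.1)
  expect_equal(su$chisq, 19.2, tolerance = 1e-12)
})

test_that("genes absent from the enhancer map count as not associated", {
  cats <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                         category = c("su_up", "su_up",
                                      "gene_not_up", "gene_not_up"))
  enh <- tibble::tibble(gene_id = c("a", "c"), enhancer = c(TRUE, TRUE))
  expect_message(out <- enrichment_by_category(cats, enh), "2 categorized")
  expect_equal(out$n_enh[out$category == "su_up"], 1L)
})

test_that("an empty reference category is an error", {
  cats <- tibble::tibble(gene_id = c("a", "b"),
                         category = c("su_up", "su_up"))
  enh <- tibble::tibble(gene_id = c("a", "b"), enhancer = c(TRUE, FALSE))
  expect_error(enrichment_by_category(cats, enh), "empty")
})

test_that("make_strata tiles [-4, 1] into 13 equal-width intervals", {
  st <- make_strata(c(-4, -1, 0.5), n_strata = 13, upper = 1)
  expect_equal(nrow(st), 13)
  w <- 5 / 13
  expect_equal(st$upper - st$lower, rep(w, 13), tolerance = 1e-12)
  expect_equal(st$lower[1], -4)
  expect_equal(st$upper[13], 1)
  # contiguous tiling
  expect_equal(st$lower[-1], st$upper[-13], tolerance = 1e-12)
  expect_error(make_strata(c(2, 3), upper = 1), "lower bound")
})

test_that("stratum assignment is half-open with a closed top interval", {
  edges <- attr(make_strata(-4, n_strata = 13, upper = 1), "edges")
  asg <- apaflow:::assign_stratum(c(-4, 1.0, 1.2, -4.5), edges)
  expect_equal(asg[1], 1L)     # lower bound included
  expect_equal(asg[2], 13L)    # upper bound closed into the last stratum
  expect_equal(asg[3], 0L)     # above the bound: excluded
  expect_equal(asg[4], 0L)     # below the bound: excluded
})

test_that("stratified matching draws equal per-stratum counts per repeat", {
  withr::with_seed(23, {
    n1 <- 60; n0 <- 300
    cats <- tibble::tibble(
      gene_id = sprintf("g%04d", seq_len(n1 + n0)),
      category = rep(c("su_up", "gene_not_up"), c(n1, n0)))
    lfc <- tibble::tibble(
      gene_id = cats$gene_id,
      log2fc = c(runif(n1, -2, 0.9), runif(n0, -3, 1.5)))
    enh <- tibble::tibble(gene_id = cats$gene_id,
                          enhancer = runif(n1 + n0) < 0.2)
  })
  res <- stratified_enrichment(cats, enh, lfc, n_repeats = 4, seed = 5)
  expect_equal(nrow(res), 4)
  for (r in seq_len(4)) {
    picks <- res$samples[[r]]
    counts <- table(picks$group, picks$stratum)
    expect_equal(unname(counts["su_up", ]), unname(counts["gene_not_up", ]))
    # min rule: neither group exceeds its available genes per stratum
    expect_false(any(duplicated(picks$gene_id)))
  }
  # repeats are deterministic given the master seed
  res2 <- stratified_enrichment(cats, enh, lfc, n_repeats = 4, seed = 5)
  expect_identical(res$samples, res2$samples)
  expect_false(identical(
    res$samples,
    stratified_enrichment(cats, enh, lfc, n_repeats = 4, seed = 6)$samples))
})

test_that("identical groups give equal fractions and X^2 = 0", {
  ids <- sprintf("g%03d", 1:40)
  cats <- tibble::tibble(gene_id = c(ids, paste0(ids, "r")),
                         category = rep(c("su_up", "gene_not_up"), each = 40))
  lfc <- tibble::tibble(gene_id = cats$gene_id, log2fc = rep(seq(-2, 0.8,
                                                                 length.out = 40), 2))
  enh <- tibble::tibble(gene_id = cats$gene_id,
                        enhancer = rep(c(TRUE, FALSE), 40))
  res <- stratified_enrichment(cats, enh, lfc, n_repeats = 2, seed = 3)
  expect_equal(res$frac_group, res$frac_reference)
  expect_equal(res$chisq, rep(0, 2))
})

test_that("min rule: the smaller group bounds the per-stratum sample", {
  cats <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:8),
    category = rep(c("su_up", "gene_not_up"), c(3, 5)))
  lfc <- tibble::tibble(gene_id = cats$gene_id, log2fc = rep(0.5, 8))
  enh <- tibble::tibble(gene_id = cats$gene_id, enhancer = FALSE)
  res <- suppressWarnings(
    stratified_enrichment(cats, enh, lfc, n_strata = 1, n_repeats = 1,
                          seed = 1))
  expect_equal(res$n_matched, 3)
})
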