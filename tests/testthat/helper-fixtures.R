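# small builders and independent oracles used across test files

# long isoform table for two multi-UTR genes and one single-UTR gene,
# 2 conditions x 2 replicates, counts chosen by hand
toy_isoform_table <- function() {
  samples <- tibble::tibble(
    sample = c("A_1", "A_2", "B_1", "B_2"),
    condition = c("A", "A", "B", "B"),
    replicate = c(1L, 2L, 1L, 2L)
  )
  rows <- tibble::tribble(
    ~gene_id, ~isoform_id, ~isoform_class, ~counts,
    "G1", "G1_P", "SU", c(60L, 66L, 150L, 140L),
    "G1", "G1_D", "LU", c(40L, 44L, 50L, 60L),
    "G2", "G2_P", "SU", c(10L, 12L, 11L, 9L),
    "G2", "G2_D", "LU", c(90L, 88L, 89L, 91L),
    "G3", "G3_S", "SINGLE", c(200L, 210L, 190L, 205L)
  )
  out <- tidyr::unnest(
    dplyr::mutate(rows, sample = list(samples$sample)),
    c(sample, counts)
  )
  out <- dplyr::left_join(out, samples, by = "sample")
  out <- dplyr::rename(out, count = counts)
  out <- dplyr::group_by(out, sample)
  out <- dplyr::mutate(out, tpm = count / sum(count) * 1e6)
  dplyr::ungroup(out)[, c("gene_id", "isoform_id", "isoform_class",
                          "sample", "condition", "replicate", "count",
                          "tpm")]
}

# literal step-up definition: q_(i) = min_{j >= i} m * p_(j) / j, then
# map back to input order
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Pearson chi-square via the expected-counts formulation
brute_chisq <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  n <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - expd)^2 / expd)
}

# gene-level count tibble from an isoform table
gene_counts_of <- function(iso) {
  dplyr::summarise(
    dplyr::group_by(iso, gene_id, sample, condition),
    count = sum(count), .groups = "drop")
}
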