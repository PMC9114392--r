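#' Simulation configuration for two-condition isoform count data
#'
#' Builds and validates the parameter set for [simulate_apa_dataset()]. The
#' generator emulates a replicated two-condition bulk RNA-seq design
#' (condition `A` = progenitor-like reference, condition `B` = the
#' differentiated state in which effects are planted): per-gene totals are
#' negative binomial around a log-normally distributed baseline, and each
#' multi-UTR gene's total is split between its short-3'UTR (SU) and
#' long-3'UTR (LU) isoform by a beta-binomial with condition-specific SU
#' usage (PAU).
#'
#' Defaults describe a moderately deep library of well-expressed genes with
#' distal-dominant baseline usage (`pau_baseline = 0.10`): a planted usage
#' shift of `pau_shift = 0.2` then corresponds to a genuine >2-fold increase
#' of the SU isoform, the kind of event the downstream classifier is built
#' to call.
#'
#' @param n_multi_utr_genes,n_single_utr_genes Number of multi-UTR genes
#'   (one SU + one LU isoform each) and single-UTR genes (one isoform).
#' @param n_replicates_per_condition Replicates per condition (>= 2).
#' @param baseline_mean Median expected total count per gene in condition A.
#' @param baseline_sdlog Log-normal spread (sdlog) of per-gene baselines.
#' @param nb_dispersion Negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2).
#' @param frac_gene_up Fraction of genes with a planted gene-level log2 fold
#'   change (applied to multi- and single-UTR genes alike).
#' @param gene_log2fc Planted gene-level log2 fold change (B vs A).
#' @param frac_su_up Fraction of multi-UTR genes with a planted SU-usage
#'   shift (drawn independently of `frac_gene_up`).
#' @param pau_baseline Baseline PAU (SU usage fraction) in condition A.
#' @param pau_shift Planted dPAU; `pau_baseline + pau_shift` must lie in
#'   `[0, 1]`.
#' @param bb_overdispersion Beta-binomial intraclass correlation rho of the
#'   SU/LU split; `0` degenerates to a plain binomial split.
#' @param enhancer_background_rate Probability that an unaffected gene is
#'   enhancer-associated.
#' @param enhancer_relative_risk Multiplier on that probability for genes
#'   with any planted effect; `rate * rr` must be <= 1.
#' @param library_size_factors Per-sample positive multipliers (length
#'   `2 * n_replicates_per_condition`), or `NULL` for all 1.
#' @param isoform_length_kb Isoform length used in the TPM computation; a
#'   single value (default 1 kb for every isoform, under which length
#'   cancels) or one value per isoform row.
#' @param seed Integer RNG seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return A validated `sim_config` list.
#' @seealso [simulate_apa_dataset()]
#' @export
sim_config <- function(n_multi_utr_genes = 4000,
                       n_single_utr_genes = 1000,
                       n_replicates_per_condition = 3,
                       baseline_mean = 300,
                       baseline_sdlog = 0.8,
                       nb_dispersion = 0.05,
                       frac_gene_up = 0.15,
                       gene_log2fc = 1.5,
                       frac_su_up = 0.15,
                       pau_baseline = 0.10,
                       pau_shift = 0.2,
                       bb_overdispersion = 0.01,
                       enhancer_background_rate = 0.10,
                       enhancer_relative_risk = 3,
                       library_size_factors = NULL,
                       isoform_length_kb = 1,
                       seed = 1L) {
  check_number(n_multi_utr_genes, "n_multi_utr_genes", 1, Inf, integer = TRUE)
  check_number(n_single_utr_genes, "n_single_utr_genes", 0, Inf, integer = TRUE)
  check_number(n_replicates_per_condition, "n_replicates_per_condition",
               2, Inf, integer = TRUE)
  check_number(baseline_mean, "baseline_mean", lower = 1e-12)
  check_number(baseline_sdlog, "baseline_sdlog", lower = 0)
  check_number(nb_dispersion, "nb_dispersion", lower = 0)
  check_number(frac_gene_up, "frac_gene_up", 0, 1)
  check_number(gene_log2fc, "gene_log2fc")
  check_number(frac_su_up, "frac_su_up", 0, 1)
  check_number(pau_baseline, "pau_baseline", 0, 1)
  check_number(pau_shift, "pau_shift", -1, 1)
  if (pau_baseline + pau_shift < 0 || pau_baseline + pau_shift > 1) {
    abort("`pau_baseline + pau_shift` must lie in [0, 1].",
          class = "apaflow_config_error")
  }
  check_number(bb_overdispersion, "bb_overdispersion", 0, 0.999)
  check_number(enhancer_background_rate, "enhancer_background_rate", 0, 1)
  check_number(enhancer_relative_risk, "enhancer_relative_risk", lower = 0)
  if (enhancer_background_rate * enhancer_relative_risk > 1) {
    abort("`enhancer_background_rate * enhancer_relative_risk` must be <= 1.",
          class = "apaflow_config_error")
  }
  n_samples <- 2L * n_replicates_per_condition
  if (is.null(library_size_factors)) {
    library_size_factors <- rep(1, n_samples)
  }
  if (length(library_size_factors) != n_samples ||
      any(!is.finite(library_size_factors)) ||
      any(library_size_factors <= 0)) {
    abort(sprintf(
      "`library_size_factors` must be %d positive numbers.", n_samples
    ), class = "apaflow_config_error")
  }
  check_number(seed, "seed", integer = TRUE)
  if (any(isoform_length_kb <= 0)) {
    abort("`isoform_length_kb` must be positive.",
          class = "apaflow_config_error")
  }
  structure(list(
    n_multi_utr_genes = as.integer(n_multi_utr_genes),
    n_single_utr_genes = as.integer(n_single_utr_genes),
    n_replicates_per_condition = as.integer(n_replicates_per_condition),
    baseline_mean = baseline_mean,
    baseline_sdlog = baseline_sdlog,
    nb_dispersion = nb_dispersion,
    frac_gene_up = frac_gene_up,
    gene_log2fc = gene_log2fc,
    frac_su_up = frac_su_up,
    pau_baseline = pau_baseline,
    pau_shift = pau_shift,
    bb_overdispersion = bb_overdispersion,
    enhancer_background_rate = enhancer_background_rate,
    enhancer_relative_risk = enhancer_relative_risk,
    library_size_factors = as.double(library_size_factors),
    isoform_length_kb = isoform_length_kb,
    seed = as.integer(seed)
  ), class = "sim_config")
}
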