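# beta-binomial draws; rho = 0 degenerates to binomial
rbetabinom <- function(n_trials, prob, rho) {
  m <- length(n_trials)
  if (rho <= 0) return(rbinom(m, n_trials, prob))
  theta <- (1 - rho) / rho
  p <- rbeta(m, prob * theta, (1 - prob) * theta)
  rbinom(m, n_trials, p)
}

#' Simulate a two-condition isoform-level count dataset with known truth
#'
#' Draws per-gene totals from a negative binomial whose mean is
#' `baseline * 2^(gene_log2fc)` in condition B for planted gene-up genes and
#' `baseline` otherwise, multiplied by the per-sample library size factor.
#' Multi-UTR totals are split SU/LU by a beta-binomial with SU usage
#' `pau_baseline`, shifted by `pau_shift` in condition B for planted SU-up
#' genes. TPM treats all isoforms as the configured length, scaled per
#' sample to one million. Enhancer flags are assigned via
#' [assign_enhancers()]. The result is a deterministic function of the
#' configuration (all draws come from one seeded stream consumed in a fixed
#' documented order: baselines, planted indicators, totals, SU splits,
#' enhancers).
#'
#' @param config A [sim_config()] object.
#' @return A list of class `apa_sim` with elements
#'   \describe{
#'     \item{counts}{long isoform tibble: `gene_id`, `isoform_id`,
#'       `isoform_class`, `sample`, `condition`, `replicate`, `count`,
#'       `tpm`.}
#'     \item{truth}{per-gene tibble: planted indicators, planted category,
#'       planted log2FC / dPAU, baseline mean, enhancer flag.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_apa_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  nm <- cfg$n_multi_utr_genes
  ns <- cfg$n_single_utr_genes
  ng <- nm + ns
  nrep <- cfg$n_replicates_per_condition
  nsmp <- 2L * nrep
  gene_id <- c(sprintf("MG%05d", seq_len(nm)),
               if (ns > 0) sprintf("SG%05d", seq_len(ns)))
  gene_class <- rep(c("multi", "single"), c(nm, ns))
  smp <- tibble::tibble(
    sample = paste0(rep(c("A", "B"), each = nrep), "_", rep(seq_len(nrep), 2)),
    condition = rep(c("A", "B"), each = nrep),
    replicate = rep(seq_len(nrep), 2)
  )

  res <- withr::with_seed(cfg$seed, {
    baseline <- rlnorm(ng, log(cfg$baseline_mean), cfg$baseline_sdlog)
    planted_gene_up <- stats::runif(ng) < cfg$frac_gene_up
    planted_su_up <- c(stats::runif(nm) < cfg$frac_su_up, rep(FALSE, ns))
    log2fc <- ifelse(planted_gene_up, cfg$gene_log2fc, 0)

    # totals: genes x samples
    mu <- outer(baseline, rep(1, nsmp)) *
      2^outer(log2fc, as.numeric(smp$condition == "B")) *
      outer(rep(1, ng), cfg$library_size_factors)
    total <- matrix(
      if (cfg$nb_dispersion > 0) {
        rnbinom(ng * nsmp, mu = as.vector(mu), size = 1 / cfg$nb_dispersion)
      } else {
        stats::rpois(ng * nsmp, as.vector(mu))
      },
      nrow = ng
    )

    # SU/LU split for multi-UTR genes
    pau <- outer(rep(cfg$pau_baseline, nm), rep(1, nsmp)) +
      outer(ifelse(planted_su_up[seq_len(nm)], cfg$pau_shift, 0),
            as.numeric(smp$condition == "B"))
    su <- matrix(rbetabinom(as.vector(total[seq_len(nm), , drop = FALSE]),
                            as.vector(pau), cfg$bb_overdispersion),
                 nrow = nm)
    enh_seed <- floor(derive_seed(cfg$seed, 104729))
    list(baseline = baseline, planted_gene_up = planted_gene_up,
         planted_su_up = planted_su_up, log2fc = log2fc,
         total = total, su = su, enh_seed = enh_seed)
  })

  lu <- res$total[seq_len(nm), , drop = FALSE] - res$su

  # long count table: multi-UTR SU + LU rows, then single-UTR rows
  mids <- gene_id[seq_len(nm)]
  iso_ids <- c(mids, mids, if (ns > 0) gene_id[nm + seq_len(ns)])
  iso_cls <- c(rep("SU", nm), rep("LU", nm), rep("SINGLE", ns))
  cnt <- rbind(res$su, lu,
               res$total[nm + seq_len(ns), , drop = FALSE])
  counts <- tibble::tibble(
    gene_id = rep(iso_ids, nsmp),
    isoform_id = paste0(rep(iso_ids, nsmp),
                        rep(ifelse(iso_cls == "SU", "_P",
                                   ifelse(iso_cls == "LU", "_D", "_S")), nsmp)),
    isoform_class = rep(iso_cls, nsmp),
    sample = rep(smp$sample, each = length(iso_ids)),
    condition = rep(smp$condition, each = length(iso_ids)),
    replicate = rep(smp$replicate, each = length(iso_ids)),
    count = as.integer(cnt)
  )

  # TPM: rate = count / length_kb, scaled to 1e6 per sample
  len <- rep(cfg$isoform_length_kb, length.out = length(iso_ids))
  counts$length_kb <- rep(len, nsmp)
  counts <- dplyr::mutate(
    dplyr::group_by(counts, .data$sample),
    tpm = (.data$count / .data$length_kb) /
      sum(.data$count / .data$length_kb) * 1e6
  )
  counts <- dplyr::arrange(dplyr::ungroup(counts),
                           .data$sample, .data$gene_id, .data$isoform_id)
  counts$length_kb <- NULL

  truth <- tibble::tibble(
    gene_id = gene_id,
    gene_class = gene_class,
    baseline_mean = res$baseline,
    planted_gene_up = res$planted_gene_up,
    planted_su_up = res$planted_su_up,
    planted_log2fc = res$log2fc,
    planted_dpau = ifelse(res$planted_su_up, cfg$pau_shift, 0),
    planted_category = dplyr::case_when(
      gene_class == "single" & res$planted_gene_up ~ "gene_up",
      gene_class == "single" ~ "gene_not_up",
      res$planted_gene_up & res$planted_su_up ~ "gene_and_su_up",
      res$planted_su_up ~ "su_up",
      res$planted_gene_up ~ "gene_up",
      TRUE ~ "gene_not_up"
    )
  )
  enh <- assign_enhancers(truth,
                          background_rate = cfg$enhancer_background_rate,
                          relative_risk = cfg$enhancer_relative_risk,
                          seed = res$enh_seed)
  truth$enhancer <- enh$enhancer[match(truth$gene_id, enh$gene_id)]

  structure(list(counts = counts, truth = truth, config = cfg),
            class = "apa_sim")
}

#' Assign cell type-specific enhancer flags to genes
#'
#' Independent Bernoulli flags emulating an enhancer target-gene list:
#' unaffected genes are enhancer-associated with probability
#' `background_rate`, genes carrying any planted effect (gene-level or
#' SU-usage) with probability `background_rate * relative_risk`.
#'
#' @param truth A data frame with `gene_id` and logical `planted_gene_up`,
#'   `planted_su_up` columns (as produced by [simulate_apa_dataset()]).
#' @param background_rate Probability for unaffected genes, in `[0, 1]`.
#' @param relative_risk Multiplier for planted-effect genes;
#'   `background_rate * relative_risk` must be <= 1.
#' @param seed RNG seed.
#' @return Tibble `gene_id`, `enhancer` (logical, `TRUE` = associated).
#' @export
assign_enhancers <- function(truth, background_rate, relative_risk,
                             seed = 1L) {
  check_columns(truth, c("gene_id", "planted_gene_up", "planted_su_up"),
                "truth table")
  if (nrow(truth) == 0) {
    abort("`truth` must be non-empty.", class = "apaflow_config_error")
  }
  check_number(background_rate, "background_rate", 0, 1)
  check_number(relative_risk, "relative_risk", lower = 0)
  if (background_rate * relative_risk > 1) {
    abort("`background_rate * relative_risk` must be <= 1.",
          class = "apaflow_config_error")
  }
  affected <- truth$planted_gene_up | truth$planted_su_up
  p <- ifelse(affected, background_rate * relative_risk, background_rate)
  flag <- withr::with_seed(seed, stats::runif(nrow(truth)) < p)
  tibble::tibble(gene_id = truth$gene_id, enhancer = flag)
}

#' Simulate an exponential mRNA decay time course
#'
#' Generates relative abundances `y(t) = y0 * exp(k t)` under multiplicative
#' log-normal noise with coefficient of variation `cv_noise` (mean-one
#' noise), emulating a transcription-shutoff decay experiment.
#'
#' @param k Decay rate per hour; must be negative (growth is not modeled).
#' @param y0 Abundance at time zero.
#' @param timepoints Hours; must include 0.
#' @param cv_noise Coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param seed RNG seed.
#' @return Tibble `t_hours`, `abundance`.
#' @seealso [fit_decay()]
#' @export
simulate_decay_series <- function(k, y0 = 1, timepoints = c(0, 2, 4, 8),
                                  cv_noise = 0, seed = 1L) {
  check_number(k, "k", upper = -1e-12)
  check_number(y0, "y0", lower = 1e-12)
  check_number(cv_noise, "cv_noise", lower = 0)
  if (!any(timepoints == 0)) {
    abort("`timepoints` must include 0.", class = "apaflow_config_error")
  }
  y <- y0 * exp(k * timepoints)
  if (cv_noise > 0) {
    sdlog <- sqrt(log(1 + cv_noise^2))
    noise <- withr::with_seed(
      seed, rlnorm(length(timepoints), -sdlog^2 / 2, sdlog))
    y <- y * noise
  }
  tibble::tibble(t_hours = as.double(timepoints), abundance = y)
}
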