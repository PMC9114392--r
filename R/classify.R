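#' Classification thresholds
#'
#' The printed decision thresholds of the four-way multi-UTR gene
#' classification: gene-level fold change > 2 at 10% FDR for "gene up";
#' SU TPM fold change > 2, dPAU > 0.1, usage p < 0.05 and usage FDR < 10%
#' for "SU up"; and the control ("not SU up") requirement of SU fold
#' change < 2, dPAU < 0.1 and usage p > 0.05. All inequalities are strict,
#' so boundary values fall into `unclassified`.
#'
#' @param gene_fc,gene_fdr Gene-up criteria (fold change, BH q cutoff).
#' @param su_fc SU expression fold-change cutoff.
#' @param dpau dPAU cutoff (fraction scale, i.e. 0.1 = 10 points of usage).
#' @param usage_p,usage_fdr Usage-test p and BH q cutoffs.
#' @return Named list of thresholds.
#' @export
apa_thresholds <- function(gene_fc = 2, gene_fdr = 0.10, su_fc = 2,
                           dpau = 0.1, usage_p = 0.05, usage_fdr = 0.10) {
  for (nm in c("gene_fc", "su_fc")) {
    check_number(get(nm), nm, lower = 0)
  }
  for (nm in c("gene_fdr", "usage_p", "usage_fdr")) {
    check_number(get(nm), nm, 0, 1)
  }
  check_number(dpau, "dpau", -1, 1)
  list(gene_fc = gene_fc, gene_fdr = gene_fdr, su_fc = su_fc, dpau = dpau,
       usage_p = usage_p, usage_fdr = usage_fdr)
}

apa_categories <- c("gene_not_up", "gene_up", "su_up", "gene_and_su_up",
                    "unclassified")

#' Four-way classification of multi-UTR genes
#'
#' Combines the gene-level differential result, the usage test, dPAU and
#' the SU expression fold change into the mutually exclusive categories
#' `gene_not_up`, `gene_up`, `su_up`, `gene_and_su_up` and `unclassified`:
#' \itemize{
#'   \item gene-up criterion: gene fold change > `gene_fc` (log2FC > 1 at
#'     the default) AND gene q < `gene_fdr`;
#'   \item SU-up criterion: SU fold change > `su_fc` AND dPAU > `dpau` AND
#'     usage p < `usage_p` AND usage q < `usage_fdr`;
#'   \item control (not-SU-up) criterion: SU fold change < `su_fc` AND
#'     dPAU < `dpau` AND usage p > `usage_p`.
#' }
#' Genes meeting the gene-up criterion split binarily into
#' `gene_and_su_up` (SU-up criterion also met) or `gene_up` — a gene that
#' doubles its expression at constant usage necessarily doubles its SU
#' isoform, so requiring SU FC < 2 there would empty the gene-up group.
#' Genes failing the gene-up criterion become `su_up` when the SU-up
#' criterion holds, `gene_not_up` when the control criterion holds, and
#' `unclassified` otherwise (e.g. a slight, non-significant SU increase,
#' or a missing usage result); unclassified genes are excluded from group
#' comparisons.
#'
#' @param de Gene-level results from [nb_gene_test()] (needs `gene_id`,
#'   `log2fc`, `q_value`).
#' @param usage Usage results from [usage_test()] (needs `gene_id`,
#'   `p_value`, `q_value`).
#' @param pau PAU table from [compute_pau()] (needs `gene_id`, `dpau`).
#' @param su_fc SU fold changes from [su_expression_fc()] (needs
#'   `gene_id`, `su_fc`).
#' @param gene_ids Genes to classify (default: the genes of `usage`); every
#'   id must be present in all four inputs.
#' @param thresholds From [apa_thresholds()].
#' @return Tibble: `gene_id`, `category` (factor over the five levels) and
#'   the supporting quantities `gene_log2fc`, `gene_q`, `su_fc`, `dpau`,
#'   `usage_p`, `usage_q`.
#' @export
classify_genes <- function(de, usage, pau, su_fc, gene_ids = NULL,
                           thresholds = apa_thresholds()) {
  check_columns(de, c("gene_id", "log2fc", "q_value"), "gene-level results")
  check_columns(usage, c("gene_id", "p_value", "q_value"), "usage results")
  check_columns(pau, c("gene_id", "dpau"), "PAU table")
  check_columns(su_fc, c("gene_id", "su_fc"), "SU fold-change table")
  ids <- gene_ids %||% usage$gene_id
  if (is.data.frame(ids)) ids <- ids$gene_id
  for (inp in list(de = de, usage = usage, pau = pau, su_fc = su_fc)) {
    missing <- setdiff(ids, inp$gene_id)
    if (length(missing) > 0) {
      abort(sprintf("gene id(s) absent from an input: %s.",
                    paste(head(missing, 10), collapse = ", ")),
            class = "apaflow_input_error")
    }
  }
  th <- thresholds
  out <- tibble::tibble(
    gene_id = ids,
    gene_log2fc = de$log2fc[match(ids, de$gene_id)],
    gene_q = de$q_value[match(ids, de$gene_id)],
    su_fc = su_fc$su_fc[match(ids, su_fc$gene_id)],
    dpau = pau$dpau[match(ids, pau$gene_id)],
    usage_p = usage$p_value[match(ids, usage$gene_id)],
    usage_q = usage$q_value[match(ids, usage$gene_id)]
  )
  gene_up <- !is.na(out$gene_q) &
    out$gene_log2fc > log2(th$gene_fc) & out$gene_q < th$gene_fdr
  su_up <- !is.na(out$usage_p) & !is.na(out$usage_q) & !is.na(out$dpau) &
    out$su_fc > th$su_fc & out$dpau > th$dpau &
    out$usage_p < th$usage_p & out$usage_q < th$usage_fdr
  control <- !is.na(out$usage_p) & !is.na(out$dpau) &
    out$su_fc < th$su_fc & out$dpau < th$dpau & out$usage_p > th$usage_p
  # gene-up genes split binarily by the SU-up criterion; the control
  # criterion (and hence the unclassified exclusion zone) applies within
  # the gene-not-up group only
  out$category <- factor(dplyr::case_when(
    gene_up & su_up ~ "gene_and_su_up",
    gene_up ~ "gene_up",
    su_up ~ "su_up",
    control ~ "gene_not_up",
    TRUE ~ "unclassified"
  ), levels = apa_categories)
  out[, c("gene_id", "category", "gene_log2fc", "gene_q", "su_fc", "dpau",
          "usage_p", "usage_q")]
}
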