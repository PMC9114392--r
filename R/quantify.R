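#' Median-of-ratios size factors
#'
#' Per-sample normalization constants computed the median-of-ratios way: a
#' pseudo-reference sample is built as the per-gene geometric mean across
#' samples (over genes positive in every sample), and each sample's factor
#' is the median of its count-to-reference ratios.
#'
#' @param gene_counts Either a gene x sample matrix/data frame of
#'   non-negative integer counts, or a long tibble with columns `gene_id`,
#'   `sample`, `count`.
#' @return Tibble `sample`, `size_factor` (positive; samples in input
#'   order).
#' @examples
#' m <- cbind(s1 = c(10, 30, 50), s2 = c(20, 60, 100))
#' compute_size_factors(m)
#' @export
compute_size_factors <- function(gene_counts) {
  m <- as_gene_matrix(gene_counts, "count")
  if (ncol(m) == 1L) {
    return(tibble::tibble(sample = colnames(m), size_factor = 1))
  }
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    abort(paste("no gene has positive counts in every sample;",
                "median-of-ratios is undefined",
                "(pseudo-reference fallback is disabled)."),
          class = "apaflow_input_error")
  }
  logref <- rowMeans(log(m[pos, , drop = FALSE]))
  sf <- apply(log(m[pos, , drop = FALSE]) - logref, 2,
              function(x) exp(median(x)))
  tibble::tibble(sample = colnames(m), size_factor = unname(sf))
}

# accept matrix / wide df / long tibble and return gene x sample matrix
as_gene_matrix <- function(x, value = "count") {
  if (is.matrix(x)) {
    if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
    return(x)
  }
  if (is.data.frame(x) && all(c("gene_id", "sample", value) %in% names(x))) {
    return(long_to_matrix(tibble::as_tibble(x), value))
  }
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    m <- as.matrix(x[, num, drop = FALSE])
    rn <- if ("gene_id" %in% names(x)) x$gene_id else rownames(x)
    rownames(m) <- rn
    return(m)
  }
  abort("cannot interpret input as a gene x sample table.",
        class = "apaflow_input_error")
}

#' Rescale TPM by size factors
#'
#' Divides each sample's TPM column by its size factor, the normalization
#' applied before fold-change and PAU computations.
#'
#' @param tpm Gene x sample matrix, or long tibble with `gene_id`, `sample`
#'   and a `tpm` column.
#' @param size_factors Tibble from [compute_size_factors()] or a named
#'   numeric vector (one positive factor per sample).
#' @return Same shape as the input; long tibbles gain a `tpm_norm` column,
#'   matrices are returned rescaled.
#' @export
rescale_tpm <- function(tpm, size_factors) {
  sf <- if (is.data.frame(size_factors)) {
    setNames(size_factors$size_factor, size_factors$sample)
  } else {
    size_factors
  }
  if (any(sf <= 0) || any(!is.finite(sf))) {
    abort("size factors must be positive and finite.",
          class = "apaflow_input_error")
  }
  if (is.data.frame(tpm) && all(c("sample", "tpm") %in% names(tpm))) {
    miss <- setdiff(unique(tpm$sample), names(sf))
    if (length(miss) > 0) {
      abort(sprintf("no size factor for sample(s): %s.",
                    paste(miss, collapse = ", ")),
            class = "apaflow_input_error")
    }
    out <- tibble::as_tibble(tpm)
    out$tpm_norm <- out$tpm / unname(sf[out$sample])
    return(out)
  }
  m <- as_gene_matrix(tpm, "tpm")
  if (is.null(names(sf))) {
    if (length(sf) != ncol(m)) {
      abort("size factor length does not match the number of samples.",
            class = "apaflow_input_error")
    }
    names(sf) <- colnames(m)
  }
  if (!all(colnames(m) %in% names(sf))) {
    abort("size factor names do not cover all samples.",
          class = "apaflow_input_error")
  }
  sweep(m, 2, sf[colnames(m)], "/")
}

#' Poly(A) site usage (PAU) and its between-condition difference (dPAU)
#'
#' PAU is the SU share of a multi-UTR gene's 3'UTR isoform expression,
#' `SU / (SU + LU)`, computed per sample on the chosen expression basis and
#' averaged (unweighted) over replicates per condition;
#' `dPAU = PAU_B - PAU_A`. The same quantity is known as the short-3'UTR
#' index (SUI). Samples where `SU + LU = 0` give `NA`, and a condition mean
#' is `NA` when all of its replicates are `NA` (such genes are flagged
#' `degenerate` and excluded downstream).
#'
#' @param df A validated isoform table (see [validate_isoform_table()]);
#'   single-UTR rows are ignored.
#' @param basis Expression basis: `"tpm_norm"` (default; requires the
#'   column, e.g. from [rescale_tpm()]), `"tpm"`, or `"count"`.
#' @param pooled Use pooled counts within condition instead of the
#'   replicate-mean PAU (alternative convention; default `FALSE`).
#' @return Tibble with one row per multi-UTR gene: per-sample `pau_<sample>`
#'   columns, condition means `pau_A`/`pau_B`, `dpau`, and a `degenerate`
#'   flag.
#' @export
compute_pau <- function(df, basis = c("tpm_norm", "tpm", "count"),
                        pooled = FALSE) {
  basis <- match.arg(basis)
  check_columns(df, c("gene_id", "isoform_class", "sample", "condition",
                      basis), "isoform table")
  iso <- dplyr::filter(tibble::as_tibble(df),
                       .data$isoform_class %in% c("SU", "LU"))
  if (nrow(iso) == 0) {
    abort("no multi-UTR (SU/LU) rows present.",
          class = "apaflow_input_error")
  }
  w <- tidyr::pivot_wider(
    iso[, c("gene_id", "sample", "condition", "isoform_class", basis)],
    names_from = "isoform_class", values_from = dplyr::all_of(basis)
  )
  w$pau <- ifelse(w$SU + w$LU > 0, w$SU / (w$SU + w$LU), NA_real_)
  per_cond <- if (pooled) {
    dplyr::summarise(
      dplyr::group_by(w, .data$gene_id, .data$condition),
      pau = ifelse(sum(.data$SU + .data$LU) > 0,
                   sum(.data$SU) / sum(.data$SU + .data$LU), NA_real_),
      .groups = "drop"
    )
  } else {
    dplyr::summarise(
      dplyr::group_by(w, .data$gene_id, .data$condition),
      pau = if (all(is.na(.data$pau))) NA_real_ else
        mean(.data$pau, na.rm = TRUE),
      .groups = "drop"
    )
  }
  cond_wide <- tidyr::pivot_wider(per_cond, names_from = "condition",
                                  values_from = "pau", names_prefix = "pau_")
  samp_wide <- tidyr::pivot_wider(w[, c("gene_id", "sample", "pau")],
                                  names_from = "sample",
                                  values_from = "pau", names_prefix = "pau_")
  out <- dplyr::left_join(samp_wide, cond_wide, by = "gene_id")
  conds <- sort(unique(iso$condition))
  ca <- paste0("pau_", conds[1]); cb <- paste0("pau_", conds[2])
  out$dpau <- out[[cb]] - out[[ca]]
  out$degenerate <- is.na(out[[ca]]) | is.na(out[[cb]])
  dplyr::arrange(out, .data$gene_id)
}

#' Short-3'UTR index (SUI)
#'
#' Alias for [compute_pau()]: the SU fraction of total 3'UTR isoform
#' expression is the same quantity under either name.
#' @inheritParams compute_pau
#' @return See [compute_pau()].
#' @export
compute_sui <- compute_pau

#' Filter to expressed multi-UTR genes
#'
#' Keeps genes with more than one annotated isoform whose total expression
#' reaches `min_tpm` TPM in at least one sample (the gene-level reading of
#' the expression filter; set `level = "isoform"` to require a single
#' isoform to reach the cutoff instead).
#'
#' @param df Isoform table with `gene_id`, `isoform_id`, `sample`, `tpm`.
#' @param min_tpm Minimum TPM reached in at least one sample (default 3).
#' @param level Apply the TPM cutoff to the gene total (default) or to
#'   individual isoforms.
#' @return Tibble `gene_id` of retained multi-UTR genes.
#' @export
filter_multi_utr <- function(df, min_tpm = 3, level = c("gene", "isoform")) {
  level <- match.arg(level)
  check_columns(df, c("gene_id", "isoform_id", "sample", "tpm"),
                "isoform table")
  df <- tibble::as_tibble(df)
  n_iso <- dplyr::summarise(
    dplyr::group_by(df, .data$gene_id),
    n_isoforms = dplyr::n_distinct(.data$isoform_id), .groups = "drop")
  expr <- if (level == "gene") {
    per <- dplyr::summarise(dplyr::group_by(df, .data$gene_id, .data$sample),
                            tpm = sum(.data$tpm), .groups = "drop")
    dplyr::summarise(dplyr::group_by(per, .data$gene_id),
                     max_tpm = max(.data$tpm), .groups = "drop")
  } else {
    dplyr::summarise(dplyr::group_by(df, .data$gene_id),
                     max_tpm = max(.data$tpm), .groups = "drop")
  }
  keep <- dplyr::inner_join(n_iso, expr, by = "gene_id")
  keep <- dplyr::filter(keep, .data$n_isoforms > 1, .data$max_tpm >= min_tpm)
  dplyr::arrange(keep[, "gene_id"], .data$gene_id)
}

#' Condition fold change of SU isoform expression
#'
#' Mean normalized SU TPM in condition B over condition A, with a small
#' pseudocount in numerator and denominator so unexpressed genes yield a
#' finite value rather than a division by zero.
#'
#' @param df Isoform table carrying a `tpm_norm` column (see
#'   [rescale_tpm()]); set `basis` to use another column.
#' @param pseudocount Added to both condition means (default 0.01 TPM).
#' @param basis Expression column to use.
#' @return Tibble `gene_id`, `su_mean_A`, `su_mean_B`, `su_fc`.
#' @export
su_expression_fc <- function(df, pseudocount = 0.01, basis = "tpm_norm") {
  check_columns(df, c("gene_id", "isoform_class", "condition", basis),
                "isoform table")
  su <- dplyr::filter(tibble::as_tibble(df), .data$isoform_class == "SU")
  m <- dplyr::summarise(
    dplyr::group_by(su, .data$gene_id, .data$condition),
    mean_expr = mean(.data[[basis]]), .groups = "drop")
  w <- tidyr::pivot_wider(m, names_from = "condition",
                          values_from = "mean_expr", names_prefix = "su_mean_")
  conds <- sort(unique(su$condition))
  ca <- paste0("su_mean_", conds[1]); cb <- paste0("su_mean_", conds[2])
  w$su_fc <- (w[[cb]] + pseudocount) / (w[[ca]] + pseudocount)
  dplyr::arrange(w, .data$gene_id)
}
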