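# internal helpers shared across modules

# Deterministic 32-bit sub-seed from a master seed and a stream index.
# Keeps results reproducible when one call spawns several random stages.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  ((abs(as.double(seed)) %% 1e6) * 2017 + as.double(stream) * 7919 + 1) %%
    2147483629
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(sprintf("`%s` must be supplied.", name), class = "apaflow_config_error")
  }
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= lower && x <= upper && (!integer || x == round(x))
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single %s in [%s, %s]; got %s.",
      name, if (integer) "integer" else "number",
      format(lower), format(upper), paste(format(x), collapse = ", ")
    ), class = "apaflow_config_error")
  }
  invisible(x)
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")),
          class = "apaflow_input_error")
  }
  invisible(df)
}

#' Validate an isoform-level count table
#'
#' Checks the long-format contract used throughout the package: one row per
#' isoform per sample, with non-negative integer `count`, non-negative `tpm`,
#' exactly two conditions, and (for multi-UTR genes) exactly one `SU` and one
#' `LU` isoform.
#'
#' @param df A data frame with columns `gene_id`, `isoform_id`,
#'   `isoform_class` (`"SU"`, `"LU"` or `"SINGLE"`), `sample`, `condition`,
#'   `replicate`, `count`, `tpm`.
#' @param require_two_conditions Require exactly two condition labels
#'   (needed by the testing operations; readers of partial tables may relax).
#' @return The validated table as a tibble, invisibly classed.
#' @export
validate_isoform_table <- function(df, require_two_conditions = TRUE) {
  check_columns(df, c("gene_id", "isoform_id", "isoform_class", "sample",
                      "condition", "replicate", "count", "tpm"),
                "isoform table")
  df <- tibble::as_tibble(df)
  if (any(df$count < 0) || any(df$count != round(df$count))) {
    bad <- which(df$count < 0 | df$count != round(df$count))
    abort(sprintf("counts must be non-negative integers (rows: %s).",
                  paste(head(bad, 5), collapse = ", ")),
          class = "apaflow_input_error")
  }
  if (any(df$tpm < 0)) {
    abort("tpm must be non-negative.", class = "apaflow_input_error")
  }
  if (!all(df$isoform_class %in% c("SU", "LU", "SINGLE"))) {
    abort("isoform_class must be one of SU, LU, SINGLE.",
          class = "apaflow_input_error")
  }
  dup <- duplicated(df[, c("gene_id", "isoform_id", "sample")])
  if (any(dup)) {
    pair <- df[dup, c("gene_id", "isoform_id", "sample")][1, ]
    rows <- which(df$gene_id == pair$gene_id &
                    df$isoform_id == pair$isoform_id &
                    df$sample == pair$sample)
    abort(sprintf(
      "duplicate (gene, isoform, sample) key %s/%s/%s at rows %s.",
      pair$gene_id, pair$isoform_id, pair$sample,
      paste(rows, collapse = ", ")
    ), class = "apaflow_input_error")
  }
  conds <- unique(df$condition)
  if (require_two_conditions && length(conds) != 2L) {
    abort(sprintf("exactly two conditions required; found: %s.",
                  paste(conds, collapse = ", ")),
          class = "apaflow_input_error")
  }
  # SU/LU structure per gene
  cls <- dplyr::distinct(df, .data$gene_id, .data$isoform_id,
                         .data$isoform_class)
  chk <- dplyr::summarise(
    dplyr::group_by(cls, .data$gene_id),
    n_su = sum(.data$isoform_class == "SU"),
    n_lu = sum(.data$isoform_class == "LU"),
    n_single = sum(.data$isoform_class == "SINGLE"),
    .groups = "drop"
  )
  bad <- chk$gene_id[!((chk$n_su == 1 & chk$n_lu == 1 & chk$n_single == 0) |
                         (chk$n_su == 0 & chk$n_lu == 0 & chk$n_single == 1))]
  if (length(bad) > 0) {
    abort(sprintf(
      "each gene needs either one SU + one LU isoform or one SINGLE isoform; offending gene(s): %s.",
      paste(head(bad, 5), collapse = ", ")
    ), class = "apaflow_input_error")
  }
  df
}

# gene x sample wide matrix from a long (gene_id, sample, value) tibble
long_to_matrix <- function(df, value) {
  wide <- tidyr::pivot_wider(df[, c("gene_id", "sample", value)],
                             names_from = "sample",
                             values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  m
}
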