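#' Read an isoform-level count table from TSV
#'
#' Expects a UTF-8 tab-separated file with header columns `gene_id`,
#'  `isoform_id`, `sample`, `condition`, `replicate`, `count`, `tpm` and
#' optionally `isoform_class`. When the class column is absent, isoforms
#' whose id ends in `_P` (the proximal-site naming convention of QAPA-style
#' output) are labeled `SU`; the other isoform of a two-isoform gene
#' becomes `LU`, and sole isoforms `SINGLE`. A `pau` column given in
#' percent is converted to the fraction scale with `pau_scale = "percent"`.
#'
#' @param path TSV path.
#' @param pau_scale Scale of a `pau` column, if present: `"fraction"`
#'   (default) or `"percent"`.
#' @return Validated long isoform tibble (see [validate_isoform_table()]).
#' @export
read_isoform_table <- function(path, pau_scale = c("fraction", "percent")) {
  pau_scale <- match.arg(pau_scale)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        na = "NA")
  check_columns(df, c("gene_id", "isoform_id", "sample", "condition",
                      "replicate", "count", "tpm"),
                sprintf("isoform table '%s'", path))
  if (any(!is.finite(df$count)) ||
      any(df$count != round(df$count), na.rm = TRUE)) {
    bad <- which(!is.finite(df$count) | df$count != round(df$count))
    abort(sprintf("non-integer counts in '%s' (line(s) %s).",
                  path, paste(head(bad + 1L, 5), collapse = ", ")),
          class = "apaflow_input_error")
  }
  df$count <- as.integer(df$count)
  df$condition <- as.character(df$condition)
  if (!"isoform_class" %in% names(df)) {
    iso <- dplyr::distinct(df, .data$gene_id, .data$isoform_id)
    n_iso <- table(iso$gene_id)
    counts_per_gene <- as.integer(n_iso[iso$gene_id])
    iso$isoform_class <- ifelse(
      counts_per_gene == 1, "SINGLE",
      ifelse(stringr::str_ends(iso$isoform_id, "_P"), "SU", "LU"))
    df <- dplyr::left_join(df, iso, by = c("gene_id", "isoform_id"))
  }
  if ("pau" %in% names(df) && pau_scale == "percent") {
    df$pau <- df$pau / 100
  }
  validate_isoform_table(df)
}

#' Read a gene-level enhancer association map from TSV
#'
#' Accepts either a single-column gene list (every listed gene is
#' enhancer-associated) or a two-column `gene_id` / flag file with values
#' in `{0, 1, true, false, TRUE, FALSE}`. Duplicated gene ids are
#' deduplicated with a warning. Genes absent from the map default to not
#' associated at join time.
#'
#' @param path TSV path.
#' @return Tibble `gene_id`, `enhancer` (logical).
#' @export
read_enhancer_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        na = "NA")
  if (nrow(df) == 0) {
    abort(sprintf("enhancer map '%s' is empty.", path),
          class = "apaflow_input_error")
  }
  if (ncol(df) == 1) {
    names(df) <- "gene_id"
    df$enhancer <- TRUE
  } else {
    names(df)[1:2] <- c("gene_id", "enhancer")
    raw <- tolower(as.character(df$enhancer))
    if (!all(raw %in% c("0", "1", "true", "false"))) {
      abort(sprintf(
        "enhancer flags in '%s' must be 0/1/true/false; got: %s.",
        path, paste(head(setdiff(unique(raw), c("0","1","true","false")), 3),
                    collapse = ", ")),
        class = "apaflow_input_error")
    }
    df$enhancer <- raw %in% c("1", "true")
  }
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$gene_id)) {
    warn(sprintf("duplicate gene ids in '%s' deduplicated (first kept).",
                 path))
    df <- df[!duplicated(df$gene_id), ]
  }
  tibble::as_tibble(df[, c("gene_id", "enhancer")])
}

#' Write a table as TSV
#'
#' All tables are written UTF-8, tab-separated, with a header row and `NA`
#' encoded as `NA`; reals are formatted with full precision so a write /
#' read round trip is value-preserving.
#'
#' @param df Data frame (list-columns are dropped with a message).
#' @param path Output path.
#' @return `df`, invisibly.
#' @export
write_apa_tsv <- function(df, path) {
  is_list <- vapply(df, is.list, logical(1))
  if (any(is_list)) {
    inform(sprintf("dropping list-column(s) %s from '%s'.",
                   paste(names(df)[is_list], collapse = ", "),
                   basename(path)))
    df <- df[, !is_list, drop = FALSE]
  }
  fct <- vapply(df, is.factor, logical(1))
  df[fct] <- lapply(df[fct], as.character)
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(df)
}

#' Read a pipeline or simulation configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
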