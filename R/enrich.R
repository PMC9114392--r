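#' Pearson chi-square on a 2x2 table
#'
#' The closed-form Pearson statistic
#' `X^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` for a 2x2 contingency
#' table laid out as group 1 = (`a` positive, `b` negative), group 2 =
#' (`c` positive, `d` negative). No continuity correction is applied by
#' default; `correct = TRUE` switches to the Yates-corrected statistic for
#' sensitivity analysis. The odds ratio is `ad / bc` (`Inf`/`NA` on zero
#' cells, flagged).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param correct Apply the Yates continuity correction.
#' @return One-row tibble: `n`, `frac1` (= a/(a+b)), `frac2` (= c/(c+d)),
#'   `chisq`, `p_value` (chi-square, 1 df), `odds_ratio`, `zero_cell`
#'   flag, `corrected`.
#' @examples
#' contingency_chisq(10, 10, 10, 90)  # X^2 = 19.2, OR = 9
#' @export
contingency_chisq <- function(a, b, c, d, correct = FALSE) {
  for (nm in c("a", "b", "c", "d")) {
    check_number(get(nm), nm, lower = 0, integer = TRUE)
  }
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (n == 0 || any(margins == 0)) {
    abort("chi-square test undefined: a table margin is zero.",
          class = "apaflow_input_error")
  }
  dev <- abs(a * d - b * c)
  if (correct) dev <- max(dev - n / 2, 0)
  chisq <- n * dev^2 / prod(margins)
  zero_cell <- any(c(a, b, c, d) == 0)
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else {
    (a * d) / (b * c)
  }
  tibble::tibble(
    n = n, frac1 = a / (a + b), frac2 = c / (c + d),
    chisq = chisq, p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
    odds_ratio = or, zero_cell = zero_cell, corrected = correct
  )
}

#' Enhancer-association enrichment per gene category
#'
#' For each non-reference category, tests whether the fraction of
#' enhancer-associated genes differs from the reference category with a
#' 2x2 Pearson chi-square ([contingency_chisq()]). Genes categorized but
#' absent from the enhancer map are treated as not associated (their count
#' is reported via a message). `unclassified` genes are excluded.
#'
#' @param categories Output of [classify_genes()] (needs `gene_id`,
#'   `category`).
#' @param enhancers Tibble `gene_id`, `enhancer` (logical), e.g. from
#'   [assign_enhancers()] or [read_enhancer_map()].
#' @param reference Reference category name (default `"gene_not_up"`).
#' @param correct Passed to [contingency_chisq()].
#' @return Tibble with one row per category (reference first): `category`,
#'   `n`, `n_enh`, `fraction`, and for non-reference rows `chisq`,
#'   `p_value`, `odds_ratio` vs the reference. Empty categories yield `NA`
#'   rows.
#' @export
enrichment_by_category <- function(categories, enhancers,
                                   reference = "gene_not_up",
                                   correct = FALSE) {
  check_columns(categories, c("gene_id", "category"), "category table")
  check_columns(enhancers, c("gene_id", "enhancer"), "enhancer map")
  cats <- dplyr::filter(tibble::as_tibble(categories),
                        .data$category != "unclassified")
  cats$category <- as.character(cats$category)
  if (!reference %in% cats$category) {
    abort(sprintf("reference category '%s' is empty.", reference),
          class = "apaflow_input_error")
  }
  flag <- enhancers$enhancer[match(cats$gene_id, enhancers$gene_id)]
  n_missing <- sum(is.na(flag))
  if (n_missing > 0) {
    inform(sprintf(
      "%d categorized gene(s) absent from the enhancer map; treated as not associated.",
      n_missing))
    flag[is.na(flag)] <- FALSE
  }
  cats$enhancer <- flag
  tab <- dplyr::summarise(dplyr::group_by(cats, .data$category),
                          n = dplyr::n(), n_enh = sum(.data$enhancer),
                          .groups = "drop")
  tab$fraction <- tab$n_enh / tab$n
  ref <- tab[tab$category == reference, ]
  others <- setdiff(intersect(apa_categories, unique(cats$category)),
                    reference)
  rows <- purrr::map_dfr(others, function(cat) {
    r <- tab[tab$category == cat, ]
    if (nrow(r) == 0 || r$n == 0) {
      return(tibble::tibble(category = cat, n = 0L, n_enh = 0L,
                            fraction = NA_real_, chisq = NA_real_,
                            p_value = NA_real_, odds_ratio = NA_real_))
    }
    cs <- tryCatch(
      contingency_chisq(r$n_enh, r$n - r$n_enh,
                        ref$n_enh, ref$n - ref$n_enh, correct = correct),
      apaflow_input_error = function(e) NULL)
    tibble::tibble(category = cat, n = r$n, n_enh = as.integer(r$n_enh),
                   fraction = r$fraction,
                   chisq = if (is.null(cs)) NA_real_ else cs$chisq,
                   p_value = if (is.null(cs)) NA_real_ else cs$p_value,
                   odds_ratio = if (is.null(cs)) NA_real_ else cs$odds_ratio)
  })
  out <- dplyr::bind_rows(
    tibble::tibble(category = reference, n = ref$n,
                   n_enh = as.integer(ref$n_enh), fraction = ref$fraction,
                   chisq = NA_real_, p_value = NA_real_,
                   odds_ratio = NA_real_),
    rows
  )
  out
}

#' Equal-width strata over the SU-up expression range
#'
#' Builds `n_strata` half-open intervals `[lo, lo + w)` of equal width over
#' `[min(log2fc of the SU-up genes), upper]`, the last interval closed at
#' the upper bound. Genes outside the bounds are excluded from matching.
#'
#' @param su_up_log2fc Gene-level log2 fold changes of the SU-up group
#'   (non-empty numeric vector, or a data frame with a `log2fc` column).
#' @param n_strata Number of strata (default 13).
#' @param upper Upper bound of the stratified range (default 1).
#' @return Tibble `stratum`, `lower`, `upper`; the break vector is
#'   attached as attribute `"edges"`.
#' @export
make_strata <- function(su_up_log2fc, n_strata = 13, upper = 1.0) {
  if (is.data.frame(su_up_log2fc)) su_up_log2fc <- su_up_log2fc$log2fc
  su_up_log2fc <- su_up_log2fc[!is.na(su_up_log2fc)]
  if (length(su_up_log2fc) == 0) {
    abort("the SU-up group is empty; strata are undefined.",
          class = "apaflow_input_error")
  }
  check_number(n_strata, "n_strata", 1, Inf, integer = TRUE)
  lower <- min(su_up_log2fc)
  if (lower >= upper) {
    abort(sprintf("lower bound (%.3f) must be below the upper bound (%.3f).",
                  lower, upper), class = "apaflow_input_error")
  }
  edges <- seq(lower, upper, length.out = n_strata + 1)
  out <- tibble::tibble(stratum = seq_len(n_strata),
                        lower = edges[-length(edges)], upper = edges[-1])
  attr(out, "edges") <- edges
  out
}

# stratum index per value; 0 = outside [lower, upper]
assign_stratum <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[is.na(x) | x < edges[1] | x > edges[length(edges)]] <- 0L
  idx
}

#' Stratified expression-matched enrichment resampling
#'
#' Controls the enhancer-enrichment comparison between the SU-up and
#' control (`gene_not_up`) groups for their difference in gene expression
#' change: the log2 fold-change range is divided into equal-width strata
#' ([make_strata()]); within each stratum both groups are subsampled
#' without replacement to the size of the smaller group; the matched pools
#' are then compared for their enhancer-associated fractions with a
#' Pearson chi-square. The procedure is repeated `n_repeats` times with
#' deterministically derived sub-seeds.
#'
#' @param categories Output of [classify_genes()].
#' @param enhancers Tibble `gene_id`, `enhancer` (logical).
#' @param log2fc Tibble `gene_id`, `log2fc` (gene-level, e.g. from
#'   [nb_gene_test()]).
#' @param group,reference Category names to match (defaults `"su_up"` vs
#'   `"gene_not_up"`).
#' @param n_strata,upper Passed to [make_strata()].
#' @param n_repeats Number of resampling repeats (default 3).
#' @param seed Master seed; repeat `r` uses a sub-seed derived from it.
#' @return Tibble with one row per repeat: `repeat_id`, `sub_seed`,
#'   `n_matched` (genes per group), `frac_group`, `frac_reference`,
#'   `chisq`, `p_value`, `odds_ratio`, and a list-column `samples` of the
#'   matched gene ids (`gene_id`, `group`, `stratum`). The strata table is
#'   attached as attribute `"strata"`, counts of out-of-bounds genes as
#'   `"n_excluded"`.
#' @export
stratified_enrichment <- function(categories, enhancers, log2fc,
                                  group = "su_up",
                                  reference = "gene_not_up",
                                  n_strata = 13, upper = 1.0,
                                  n_repeats = 3, seed = 1L) {
  check_columns(categories, c("gene_id", "category"), "category table")
  check_columns(enhancers, c("gene_id", "enhancer"), "enhancer map")
  check_columns(log2fc, c("gene_id", "log2fc"), "log2fc table")
  check_number(n_repeats, "n_repeats", 1, Inf, integer = TRUE)
  cats <- tibble::as_tibble(categories)
  g1 <- cats$gene_id[cats$category == group]
  g0 <- cats$gene_id[cats$category == reference]
  if (length(g1) == 0 || length(g0) == 0) {
    abort("both the SU-up and the reference group must be non-empty.",
          class = "apaflow_input_error")
  }
  lfc <- setNames(log2fc$log2fc, log2fc$gene_id)
  strata <- make_strata(unname(lfc[g1]), n_strata = n_strata, upper = upper)
  edges <- attr(strata, "edges")
  s1 <- assign_stratum(unname(lfc[g1]), edges)
  s0 <- assign_stratum(unname(lfc[g0]), edges)
  n_excluded <- c(group = sum(s1 == 0), reference = sum(s0 == 0))
  flag <- setNames(enhancers$enhancer, enhancers$gene_id)

  reps <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    sub_seed <- floor(derive_seed(seed, r))
    picks <- withr::with_seed(sub_seed, {
      purrr::map_dfr(seq_len(n_strata), function(s) {
        in1 <- g1[s1 == s]; in0 <- g0[s0 == s]
        m <- min(length(in1), length(in0))
        if (m == 0) return(NULL)
        dplyr::bind_rows(
          tibble::tibble(gene_id = sample(in1, m), group = group,
                         stratum = s),
          tibble::tibble(gene_id = sample(in0, m), group = reference,
                         stratum = s)
        )
      })
    })
    if (is.null(picks) || nrow(picks) == 0) {
      abort("no stratum has genes from both groups; matching impossible.",
            class = "apaflow_input_error")
    }
    e1 <- flag[picks$gene_id[picks$group == group]]
    e0 <- flag[picks$gene_id[picks$group == reference]]
    e1[is.na(e1)] <- FALSE; e0[is.na(e0)] <- FALSE
    cs <- tryCatch(
      contingency_chisq(sum(e1), sum(!e1), sum(e0), sum(!e0)),
      apaflow_input_error = function(e) NULL)
    tibble::tibble(
      repeat_id = r, sub_seed = sub_seed, n_matched = length(e1),
      frac_group = mean(e1), frac_reference = mean(e0),
      chisq = if (is.null(cs)) NA_real_ else cs$chisq,
      p_value = if (is.null(cs)) NA_real_ else cs$p_value,
      odds_ratio = if (is.null(cs)) NA_real_ else cs$odds_ratio,
      samples = list(picks)
    )
  })
  attr(reps, "strata") <- strata
  attr(reps, "n_excluded") <- n_excluded
  reps
}
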