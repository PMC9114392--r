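#' @describeIn fit_decay Tidy the fitted parameters.
#' @param x A `decay_fit`.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "half_life"),
    estimate = c(x$k, x$half_life)
  )
}

#' @describeIn fit_decay One-row fit summary.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, half_life = x$half_life, stable = x$stable,
    sse = x$sse, converged = x$converged, n = x$n
  )
}

#' @describeIn run_pipeline Per-category call counts and headline
#'   enrichment numbers for a pipeline run.
#' @param x An `apa_run`.
#' @param ... Unused.
#' @export
glance.apa_run <- function(x, ...) {
  tally <- table(x$categories$category)
  out <- tibble::as_tibble(as.list(setNames(as.integer(tally),
                                            paste0("n_", names(tally)))))
  out$n_multi_utr <- nrow(x$multi_utr_genes)
  if (!is.null(x$stratified)) {
    out$strat_frac_group <- mean(x$stratified$frac_group)
    out$strat_frac_reference <- mean(x$stratified$frac_reference)
    out$strat_median_p <- median(x$stratified$p_value)
  }
  out
}

#' @describeIn run_pipeline The category table with supporting values
#'   (one row per classified gene).
#' @export
tidy.apa_run <- function(x, ...) {
  x$categories
}
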