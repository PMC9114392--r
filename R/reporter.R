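#' Transcriptional activity from dual-luciferase readouts
#'
#' Renilla luminescence normalized by the co-transfected firefly control,
#' per replicate. The ratio is invariant to common rescaling of both
#' channels, which removes transfection-efficiency differences.
#'
#' @param df Plate tibble with columns `renilla` and `firefly` (both
#'   positive), typically also construct identifiers and `replicate`.
#' @return The input tibble with an added `activity` column
#'   (`renilla / firefly`).
#' @seealso [reporter_summary()], [cpa_activity()]
#' @export
transcriptional_activity <- function(df) {
  check_columns(df, c("renilla", "firefly"), "plate table")
  if (any(df$firefly <= 0)) {
    abort("firefly readouts must be positive.",
          class = "apaflow_input_error")
  }
  if (any(df$renilla <= 0)) {
    abort("renilla readouts must be positive.",
          class = "apaflow_input_error")
  }
  out <- tibble::as_tibble(df)
  out$activity <- out$renilla / out$firefly
  out
}

#' Summarize replicate activities per construct
#'
#' @param df Output of [transcriptional_activity()].
#' @param ... Grouping columns (defaults to `construct_id` if present).
#' @return Tibble with `n`, `mean_activity`, `sd_activity` per group.
#' @export
reporter_summary <- function(df, ...) {
  check_columns(df, "activity", "activity table")
  groups <- rlang::enquos(...)
  if (length(groups) == 0 && "construct_id" %in% names(df)) {
    groups <- rlang::quos(.data$construct_id)
  }
  dplyr::summarise(dplyr::group_by(df, !!!groups),
                   n = dplyr::n(),
                   mean_activity = mean(.data$activity),
                   sd_activity = stats::sd(.data$activity),
                   .groups = "drop")
}

#' CPA activity of a test polyadenylation site
#'
#' The 3' end processing (cleavage/polyadenylation) efficiency of a test
#' PAS, operationalized as the ratio of the reporter activity of the
#' test-PAS construct over the SV40-PAS construct under the same promoter.
#' With replicate activities, the value is the ratio of means and its
#' standard deviation is propagated by the delta method.
#'
#' @param test,sv40 Replicate activity vectors (or single values) for the
#'   test-PAS and the SV40-PAS construct.
#' @param test_context,sv40_context Optional context identifiers (promoter
#'   / enhancer); if both given they must match.
#' @return One-row tibble: `value`, `sd` (`NA` without replicates),
#'   `n_test`, `n_ref`.
#' @export
cpa_activity <- function(test, sv40, test_context = NULL,
                         sv40_context = NULL) {
  if (!is.null(test_context) && !is.null(sv40_context) &&
      !identical(test_context, sv40_context)) {
    abort(sprintf(
      "test and SV40 constructs come from different contexts ('%s' vs '%s').",
      test_context, sv40_context), class = "apaflow_input_error")
  }
  if (any(test <= 0) || any(sv40 <= 0)) {
    abort("activities must be positive.", class = "apaflow_input_error")
  }
  mt <- mean(test); ms <- mean(sv40)
  value <- mt / ms
  sd_out <- if (length(test) > 1 && length(sv40) > 1) {
    # delta method on the ratio of the two means
    value * sqrt(var(test) / length(test) / mt^2 +
                   var(sv40) / length(sv40) / ms^2)
  } else {
    NA_real_
  }
  tibble::tibble(value = value, sd = sd_out,
                 n_test = length(test), n_ref = length(sv40))
}

#' Read-through fraction past a polyadenylation site
#'
#' Signal measured downstream of the PAS (read-through transcripts)
#' normalized to the total transcript signal measured upstream.
#'
#' @param downstream,upstream Non-negative signal values; `upstream` must
#'   be positive. A zero `downstream` value is returned as 0 and flagged
#'   below detection.
#' @return One-row tibble `read_through`, `below_detection`.
#' @export
read_through_fraction <- function(downstream, upstream) {
  if (any(upstream <= 0)) {
    abort("upstream (total) signal must be positive.",
          class = "apaflow_input_error")
  }
  if (any(downstream < 0)) {
    abort("downstream signal must be non-negative.",
          class = "apaflow_input_error")
  }
  tibble::tibble(read_through = downstream / upstream,
                 below_detection = downstream == 0)
}

#' Fit an exponential decay to a transcription-shutoff time course
#'
#' Abundances are normalized to the time-zero value, then
#' `y = exp(k t)` is fitted by nonlinear least squares with the rate
#' initialized from the log-linear regression of `log(y)` on `t`. The
#' half-life is `ln(0.5) / k`. A non-negative fitted rate is flagged
#' `stable` (half-life `Inf`).
#'
#' @param df Tibble with `t_hours` and positive `abundance`, including a
#'   `t_hours == 0` row; at least 3 timepoints.
#' @return Object of class `decay_fit`: list with `k`, `half_life`,
#'   `stable`, `sse`, `converged`, `n`, and the normalized `data`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' fit_decay(simulate_decay_series(k = -0.3466, timepoints = 0:4))
#' @export
fit_decay <- function(df) {
  check_columns(df, c("t_hours", "abundance"), "decay series")
  df <- dplyr::arrange(tibble::as_tibble(df), .data$t_hours)
  if (nrow(df) < 3) {
    abort("at least 3 timepoints are required.",
          class = "apaflow_input_error")
  }
  if (!any(df$t_hours == 0)) {
    abort("the series must include t = 0.", class = "apaflow_input_error")
  }
  if (any(df$abundance <= 0)) {
    abort("abundances must be positive (log-linear initialization).",
          class = "apaflow_input_error")
  }
  y <- df$abundance / df$abundance[df$t_hours == 0][1]
  t <- df$t_hours
  k0 <- unname(coef(lm(log(y) ~ 0 + t))[1])
  fit <- tryCatch(
    nls(y ~ exp(k * t), start = list(k = k0),
        control = list(maxiter = 200, tol = 1e-10, minFactor = 1e-12,
                       scaleOffset = 1)),
    error = function(e) NULL)
  k <- if (is.null(fit)) k0 else unname(coef(fit)[["k"]])
  if (abs(k) < 1e-12) k <- 0
  sse <- sum((y - exp(k * t))^2)
  stable <- k >= 0
  structure(list(
    k = k,
    half_life = if (stable) Inf else log(0.5) / k,
    stable = stable,
    sse = sse,
    converged = !is.null(fit),
    n = nrow(df),
    data = tibble::tibble(t_hours = t, abundance = y)
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential decay fit (", x$n, " timepoints)\n", sep = "")
  cat(sprintf("  k = %.4f /h, half-life = %s h%s\n", x$k,
              if (is.finite(x$half_life)) sprintf("%.3f", x$half_life)
              else "Inf",
              if (x$stable) " [stable]" else ""))
  invisible(x)
}

#' Nascent transcript fraction
#'
#' Ratio of metabolically labeled (nascent) transcript abundance to total
#' transcript abundance, a proxy for the transcript production rate. Both
#' inputs must be on the same normalization (e.g. spike-in scaled);
#' rescaling both by a common factor leaves the fraction unchanged.
#'
#' @param nascent,total Positive abundances.
#' @return Numeric fraction(s) `nascent / total`.
#' @export
nascent_fraction <- function(nascent, total) {
  if (any(total <= 0)) {
    abort("total abundance must be positive.",
          class = "apaflow_input_error")
  }
  if (any(nascent < 0)) {
    abort("nascent abundance must be non-negative.",
          class = "apaflow_input_error")
  }
  nascent / total
}

#' Long-3'UTR isoform fraction
#'
#' Fraction of the long-3'UTR (LU) isoform over the total mRNA of the
#' gene; same calculus as [nascent_fraction()].
#'
#' @param lu,total Abundances; `total` positive, `lu` non-negative.
#' @return Numeric fraction(s) `lu / total`.
#' @export
lu_fraction <- function(lu, total) {
  if (any(total <= 0)) {
    abort("total abundance must be positive.",
          class = "apaflow_input_error")
  }
  if (any(lu < 0)) {
    abort("LU abundance must be non-negative.",
          class = "apaflow_input_error")
  }
  lu / total
}

#' Band a knock-down screen hit by its CPA activity change
#'
#' Welch's two-sided unequal-variance t-test between knock-down and
#' control CPA activity replicates; a significant change whose absolute
#' mean difference exceeds `strong_delta` is banded `strong`, a
#' significant smaller change `significant`, anything else `none`.
#'
#' @param cpa_kd,cpa_ctrl Replicate CPA activities (>= 3 each).
#' @param alpha Significance level (default 0.05).
#' @param strong_delta Absolute change defining the strong band
#'   (default 0.30).
#' @return One-row tibble: `band` (factor none/significant/strong),
#'   `delta` (KD mean - ctrl mean), `p_value`, `mean_kd`, `mean_ctrl`.
#' @export
classify_screen_hit <- function(cpa_kd, cpa_ctrl, alpha = 0.05,
                                strong_delta = 0.30) {
  if (length(cpa_kd) < 3 || length(cpa_ctrl) < 3) {
    abort("at least 3 replicates per group are required.",
          class = "apaflow_input_error")
  }
  delta <- mean(cpa_kd) - mean(cpa_ctrl)
  p <- if (stats::sd(cpa_kd) == 0 && stats::sd(cpa_ctrl) == 0) {
    if (delta == 0) 1 else 0
  } else {
    t.test(cpa_kd, cpa_ctrl, var.equal = FALSE)$p.value
  }
  band <- if (p < alpha && abs(delta) > strong_delta) {
    "strong"
  } else if (p < alpha) {
    "significant"
  } else {
    "none"
  }
  tibble::tibble(
    band = factor(band, levels = c("none", "significant", "strong")),
    delta = delta, p_value = p,
    mean_kd = mean(cpa_kd), mean_ctrl = mean(cpa_ctrl)
  )
}
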