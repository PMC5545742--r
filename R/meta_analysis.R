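#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-sample regression estimates with weights `w_i = 1 / se_i^2`
#' (one over the square of the standard error), the weighting that
#' minimizes the imprecision of the pooled estimate:
#' combined B = sum(w B) / sum(w), combined SE = 1 / sqrt(sum(w)),
#' 95% CI = B +/- 1.96 SE, two-sided p from the normal approximation.
#' Heterogeneity is quantified by Cochran's Q, I-squared, and a chi-square
#' p on k - 1 df.
#'
#' @param estimates Numeric vector of per-sample slopes B (length k >= 2).
#' @param ses Matching standard errors, all > 0.
#' @return A one-row data.frame of class `meta_result`: combined_B,
#'   combined_se, ci_low, ci_high, p_value, q_statistic, i_squared, p_het,
#'   k.
#' @export
meta_combine <- function(estimates, ses) {
  k <- length(estimates)
  if (k < 2L) stop("need at least 2 samples")
  if (length(ses) != k) stop("estimates and ses must have equal length")
  if (any(ses <= 0)) stop("all standard errors must be > 0")
  w <- 1 / ses^2
  B <- sum(w * estimates) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- B / se
  het <- heterogeneity(estimates, ses)
  out <- data.frame(
    combined_B = B, combined_se = se,
    ci_low = B - 1.96 * se, ci_high = B + 1.96 * se,
    p_value = 2 * stats::pnorm(-abs(z)),
    q_statistic = het$q_statistic, i_squared = het$i_squared,
    p_het = het$p_het, k = k
  )
  class(out) <- c("meta_result", class(out))
  out
}

#' Heterogeneity of per-sample estimates
#'
#' Cochran's `Q = sum(w_i (B_i - B_pooled)^2)` against chi-square on k - 1
#' df, and `I2 = max(0, (Q - (k - 1)) / Q) * 100`, the percentage of
#' between-sample variance not attributable to chance (floored at 0).
#'
#' @inheritParams meta_combine
#' @return A list: q_statistic, i_squared (percent), p_het.
#' @export
heterogeneity <- function(estimates, ses) {
  k <- length(estimates)
  if (k < 2L) stop("need at least 2 samples")
  if (any(ses <= 0)) stop("all standard errors must be > 0")
  w <- 1 / ses^2
  B <- sum(w * estimates) / sum(w)
  q <- sum(w * (estimates - B)^2)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  list(q_statistic = q, i_squared = i2,
       p_het = stats::pchisq(q, df = k - 1, lower.tail = FALSE))
}

#' Meta-analyze per-platform association tables
#'
#' Row-wise fixed-effect pooling of two or more association result tables
#' that share a `phenotype` column (one row per phenotype), producing the
#' combined-sample table layout: combined B, CI bounds, p, plus
#' heterogeneity.
#'
#' @param ... Two or more `association_result`-style data.frames with
#'   columns `phenotype`, `estimate`, `se`.
#' @return data.frame, one `meta_result` row per shared phenotype.
#' @export
meta_analyze_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]]))
    tabs <- tabs[[1]]
  if (length(tabs) < 2L) stop("need at least 2 tables")
  shared <- Reduce(intersect, lapply(tabs, function(t) t$phenotype))
  out <- lapply(shared, function(ph) {
    est <- vapply(tabs, function(t) t$estimate[t$phenotype == ph], numeric(1))
    se <- vapply(tabs, function(t) t$se[t$phenotype == ph], numeric(1))
    cbind(phenotype = ph, meta_combine(est, se))
  })
  do.call(rbind, out)
}
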