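#' Flag outliers by z-score
#'
#' Single-pass screen: values more than 3 SDs from the mean are flagged for
#' exclusion (no re-screening after removal). A constant vector yields no
#' outliers, with a warning.
#'
#' @param values Numeric vector (NAs pass through as not-outlier).
#' @param z_cut Absolute z-score cutoff (default 3).
#' @return Logical inclusion mask, TRUE = keep.
#' @export
detect_outliers <- function(values, z_cut = 3) {
  ok <- !is.na(values)
  if (sum(ok) < 3L) stop("need at least 3 non-missing values")
  s <- stats::sd(values[ok])
  if (s == 0) {
    warning("constant vector: no outliers flagged")
    return(rep(TRUE, length(values)))
  }
  z <- (values - mean(values[ok])) / s
  is.na(z) | abs(z) <= z_cut
}

#' Covariate-adjusted linear association
#'
#' Ordinary least squares of phenotype on predictor plus covariates (age
#' and sex in the cohort analyses), with intercept and listwise deletion.
#' Reports the unstandardized slope B with its SE, t-based 95% CI and
#' two-sided p, the standardized beta (B scaled by the predictor/phenotype
#' SD ratio), and the incremental variance explained, delta r-squared =
#' r2(full model) - r2(covariates only).
#'
#' @param phenotype Numeric outcome vector.
#' @param predictor Numeric predictor (score or dosage).
#' @param covariates Optional data.frame/matrix of covariates, aligned rows.
#' @param phenotype_name Label carried into the result.
#' @return A one-row data.frame of class `association_result`: phenotype,
#'   estimate, se, ci_low, ci_high, p_value, standardized_beta, delta_r2,
#'   n_used.
#' @export
fit_association <- function(phenotype, predictor, covariates = NULL,
                            phenotype_name = "phenotype") {
  n <- length(phenotype)
  stopifnot(length(predictor) == n)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
  }
  complete <- !is.na(phenotype) & !is.na(predictor)
  if (!is.null(covariates))
    complete <- complete & stats::complete.cases(covariates)
  y <- phenotype[complete]
  x <- predictor[complete]
  cv <- if (is.null(covariates)) NULL else covariates[complete, , drop = FALSE]
  n_used <- length(y)
  n_par <- 2L + if (is.null(cv)) 0L else ncol(cv)
  if (n_used <= n_par + 1L) stop("too few complete observations")
  if (stats::sd(x) == 0) stop("constant predictor")

  X <- cbind(`(Intercept)` = 1, predictor = x,
             if (!is.null(cv)) data.matrix(cv))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  df <- n_used - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se_all <- sqrt(diag(XtXinv) * sigma2)
  B <- fit$coefficients[["predictor"]]
  se <- se_all[which(colnames(X) == "predictor")]
  tval <- B / se
  p <- 2 * stats::pt(-abs(tval), df)
  tc <- stats::qt(0.975, df)

  r2_full <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  r2_cov <- if (is.null(cv)) 0 else {
    f0 <- stats::lm.fit(cbind(1, data.matrix(cv)), y)
    1 - sum(f0$residuals^2) / sum((y - mean(y))^2)
  }

  out <- data.frame(
    phenotype = phenotype_name,
    estimate = B, se = se,
    ci_low = B - tc * se, ci_high = B + tc * se,
    p_value = p,
    standardized_beta = B * stats::sd(x) / stats::sd(y),
    delta_r2 = max(0, r2_full - r2_cov),
    n_used = n_used,
    stringsAsFactors = FALSE
  )
  class(out) <- c("association_result", class(out))
  out
}

#' Single-variant association
#'
#' [fit_association()] with a risk-allele dosage (0-2) as predictor, the
#' model used for the index-SNP analyses.
#'
#' @inheritParams fit_association
#' @param dosage Risk-allele dosage vector in {0, 1, 2}.
#' @return An `association_result` row.
#' @export
single_variant_association <- function(dosage, phenotype, covariates = NULL,
                                       phenotype_name = "phenotype") {
  fit_association(phenotype, dosage, covariates, phenotype_name)
}

#' Compare scores between diagnosis groups
#'
#' One-way ANOVA of scores across groups (e.g. healthy controls vs broad
#' and narrow psychosis), with all pairwise Tukey honest-significant-
#' difference comparisons as follow-up.
#'
#' @param scores Numeric vector.
#' @param groups Factor or character group labels, aligned with `scores`.
#' @return A list: `f_statistic`, `p_value`, `tukey` (data.frame:
#'   comparison, diff, ci_low, ci_high, p_adj).
#' @export
compare_groups <- function(scores, groups) {
  groups <- factor(groups)
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need >= 2 groups with >= 2 members each")
  fit <- stats::aov(scores ~ groups)
  a <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  list(
    f_statistic = a[["F value"]][1],
    p_value = a[["Pr(>F)"]][1],
    tukey = data.frame(comparison = rownames(tk),
                       diff = tk[, "diff"], ci_low = tk[, "lwr"],
                       ci_high = tk[, "upr"], p_adj = tk[, "p adj"],
                       row.names = NULL, stringsAsFactors = FALSE)
  )
}

#' Bonferroni correction over cognitive domains
#'
#' `min(1, p * n_domains)`; the cohort analysis corrects over five domains
#' (IQ, working memory, visual declarative memory, attention, social
#' cognition).
#'
#' @param p P-value(s) in (0, 1].
#' @param n_domains Number of domains tested (default 5).
#' @return Adjusted p-value(s), capped at 1.
#' @export
bonferroni <- function(p, n_domains = 5) {
  if (n_domains < 1) stop("n_domains must be >= 1")
  pmin(1, p * n_domains)
}

#' Post hoc power for an incremental-r-squared effect
#'
#' Power of the 1-df partial F test for a predictor explaining an
#' additional `r2` of outcome variance after `n_covariates` covariates:
#' Cohen's f2 = r2 / (1 - r2), noncentrality ncp = f2 * n (total-n
#' convention), power = P(F'(1, n - n_covariates - 2; ncp) > F_crit).
#'
#' @param n Sample size.
#' @param r2 Incremental variance explained, in (0, 1).
#' @param alpha Test size in (0, 1).
#' @param n_covariates Covariates already in the model (default 0).
#' @return A list of class `power_spec`: n, r2, alpha, f2, ncp, df_denom,
#'   power.
#' @export
posthoc_power <- function(n, r2, alpha = 0.05, n_covariates = 0) {
  if (r2 <= 0 || r2 >= 1) stop("r2 must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n <= n_covariates + 2) stop("n must exceed n_covariates + 2")
  f2 <- r2 / (1 - r2)
  ncp <- f2 * n
  df2 <- n - n_covariates - 2
  fcrit <- stats::qf(1 - alpha, 1, df2)
  power <- stats::pf(fcrit, 1, df2, ncp = ncp, lower.tail = FALSE)
  structure(list(n = n, r2 = r2, alpha = alpha, f2 = f2, ncp = ncp,
                 df_denom = df2, power = power),
            class = "power_spec")
}

#' @export
print.power_spec <- function(x, ...) {
  cat(sprintf("power %.3f to detect incremental r2 = %g at n = %d, alpha = %g\n",
              x$power, x$r2, as.integer(x$n), x$alpha))
  invisible(x)
}

#' Monte-Carlo power for the covariate-adjusted score test
#'
#' Empirical check of [posthoc_power()]: simulates `n_reps` regressions of
#' a Gaussian outcome on a Gaussian predictor explaining `r2` of variance
#' and counts two-sided rejections at `alpha`.
#'
#' @inheritParams posthoc_power
#' @param n_reps Number of simulated regressions.
#' @return Rejection proportion.
#' @export
monte_carlo_power <- function(n, r2, alpha = 0.05, n_reps = 10000) {
  b <- sqrt(r2 / (1 - r2))
  rej <- 0L
  df <- n - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  for (i in seq_len(n_reps)) {
    x <- stats::rnorm(n)
    y <- b * x + stats::rnorm(n)
    r <- stats::cor(x, y)
    tval <- r * sqrt(df / (1 - r^2))
    if (abs(tval) > tcrit) rej <- rej + 1L
  }
  rej / n_reps
}
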