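test_that("outlier screen flags |z| > 3 and leaves constant vectors alone", {
  v <- c(rep(0, 99), 100)
  keep <- detect_outliers(v)
  expect_equal(which(!keep), 100)

  expect_warning(k2 <- detect_outliers(rep(5, 10)), "constant")
  expect_true(all(k2))

  set.seed(31)
  z <- rnorm(10000)
  frac <- mean(!detect_outliers(z))
  expect_lt(abs(frac - 2 * pnorm(-3)), 0.002)

  expect_error(detect_outliers(c(1, NA, NA)), "at least 3")
})

test_that("association fit recovers a noiseless slope exactly", {
  x <- seq(-2, 2, length.out = 40)
  r <- fit_association(2 * x, x)
  expect_equal(r$estimate, 2, tolerance = 1e-10)
  expect_equal(r$delta_r2, 1, tolerance = 1e-10)
  expect_lt(r$p_value, 1e-20)
  expect_equal(r$n_used, 40)
})

test_that("association fit agrees with lm() on random covariate-adjusted instances", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(20:50, 1)
    x <- rnorm(n); age <- runif(n, 18, 65); sex <- rbinom(n, 1, 0.5)
    y <- 0.3 * x + 0.02 * age + 0.2 * sex + rnorm(n)
    r <- fit_association(y, x, data.frame(age = age, sex = sex))
    fit <- lm(y ~ x + age + sex)
    sm <- summary(fit)
    expect_equal(r$estimate, unname(coef(fit)["x"]), tolerance = 1e-8)
    expect_equal(r$se, sm$coefficients["x", "Std. Error"], tolerance = 1e-8)
    expect_equal(r$p_value, sm$coefficients["x", "Pr(>|t|)"],
                 tolerance = 1e-8)
    ci <- confint(fit)["x", ]
    expect_equal(c(r$ci_low, r$ci_high), unname(ci), tolerance = 1e-8)
    r2cov <- summary(lm(y ~ age + sex))$r.squared
    expect_equal(r$delta_r2, sm$r.squared - r2cov, tolerance = 1e-8)
    expect_equal(r$standardized_beta, r$estimate * sd(x) / sd(y),
                 tolerance = 1e-12)
  }
})

test_that("delta r2 is invariant to predictor rescaling; standardized beta to both", {
  set.seed(17)
  n <- 200
  x <- rnorm(n); age <- runif(n, 18, 65); sex <- rbinom(n, 1, 0.5)
  y <- 0.5 * x + 0.01 * age + rnorm(n)
  cv <- data.frame(age = age, sex = sex)
  r1 <- fit_association(y, x, cv)
  r2 <- fit_association(y, 10 * x + 3, cv)
  expect_equal(r1$delta_r2, r2$delta_r2, tolerance = 1e-10)
  expect_equal(r1$standardized_beta, r2$standardized_beta, tolerance = 1e-10)
  r3 <- fit_association(5 * y - 2, 10 * x + 3, cv)
  expect_equal(r1$standardized_beta, r3$standardized_beta, tolerance = 1e-10)
})

test_that("degenerate designs fail loudly", {
  y <- rnorm(30)
  expect_error(fit_association(y, rep(1, 30)), "constant predictor")
  x <- rnorm(30)
  expect_error(fit_association(y, x, data.frame(a = x, b = 2 * x)),
               "collinear")
  expect_error(single_variant_association(rep(1L, 30), y),
               "constant predictor")
})

test_that("permutation null: p-values are calibrated at the 5% level", {
  set.seed(2024)
  n <- 60
  x <- rnorm(n); y <- rnorm(n)
  reps <- 2000
  p <- numeric(reps)
  for (i in seq_len(reps)) p[i] <- fit_association(y, sample(x))$p_value
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("single-variant association recovers a planted per-allele effect", {
  set.seed(8)
  signs <- replicate(100, {
    n <- 1000
    d <- rbinom(n, 2, 0.3)
    y <- -0.1 * d + rnorm(n)
    sign(single_variant_association(d, y)$estimate)
  })
  expect_gte(mean(signs == -1), 0.95)
})

test_that("group comparison: ANOVA F/p and Tukey adjustment behave", {
  g2 <- rep(c("a", "b"), each = 5)
  eq <- compare_groups(rep(1:5, 2), g2)
  expect_equal(eq$f_statistic, 0, tolerance = 1e-12)
  expect_equal(eq$p_value, 1, tolerance = 1e-12)

  set.seed(14)
  x <- c(rnorm(500), rnorm(500), rnorm(500, 0.5))
  gl <- rep(c("control", "narrow", "broad"), each = 500)
  r <- compare_groups(x, gl)
  expect_lt(r$p_value, 0.001)
  sep <- r$tukey[grepl("broad", r$tukey$comparison), ]
  # group with shifted mean separates from both others
  shifted <- r$tukey[r$tukey$comparison %in%
                       c("control-broad", "narrow-broad",
                         "broad-control", "broad-narrow"), ]
  expect_true(all(shifted$p_adj < 0.01))

  # Tukey-adjusted p >= unadjusted pairwise t p
  for (rep in 1:10) {
    xx <- rnorm(60)
    gg <- rep(c("a", "b", "c"), each = 20)
    rr <- compare_groups(xx, gg)
    praw <- t.test(xx[gg == "a"], xx[gg == "b"], var.equal = TRUE)$p.value
    pair <- rr$tukey$p_adj[rr$tukey$comparison %in% c("b-a", "a-b")]
    expect_gte(pair + 1e-12, praw)
  }

  expect_error(compare_groups(1:5, c("a", "a", "a", "a", "b")), ">= 2")
})

test_that("Bonferroni over domains multiplies and caps", {
  expect_equal(bonferroni(0.002, 5), 0.01)
  expect_equal(bonferroni(0.5, 5), 1)
  expect_equal(bonferroni(0.03, 1), 0.03)
  expect_error(bonferroni(0.05, 0), "n_domains")
})

test_that("noncentral-F power: limits and monotonicity", {
  # r2 -> 0 gives power -> alpha
  expect_equal(posthoc_power(500, 1e-10, 0.05)$power, 0.05, tolerance = 1e-4)
  # strictly increasing in n
  ns <- seq(100, 5000, by = 200)
  pw <- vapply(ns, function(n) posthoc_power(n, 0.01)$power, numeric(1))
  expect_true(all(diff(pw) > 0))
  # internal consistency of the derived power fields
  ps <- posthoc_power(988, 0.01, 0.05)
  expect_equal(ps$f2, 0.01 / 0.99, tolerance = 1e-12)
  expect_equal(ps$ncp, ps$f2 * 988, tolerance = 1e-12)
  expect_error(posthoc_power(988, 1.2), "r2")
  expect_error(posthoc_power(3, 0.01, n_covariates = 2), "exceed")
})
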