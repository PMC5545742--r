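test_that("harmonization aligns, flips, and drops palindromic / mismatched variants", {
  d <- matrix(c(2L, 1L, 0L,
                0L, 1L, 2L,
                1L, 1L, 1L,
                2L, 0L, 1L), nrow = 3)
  g <- toy_genotypes(d,
                     counted = c("G", "C", "A", "G"),
                     other   = c("A", "T", "T", "A"))
  ss <- toy_sumstats(or = c(1.5, 0.8, 1.2, 2.0),
                     p = c(0.001, 0.01, 0.2, 0.4),
                     effect = c("G", "T", "A", "C"),
                     other  = c("A", "C", "T", "T"))
  h <- harmonize(ss, g)
  # rs001 direct, rs002 flipped, rs003 palindromic A/T, rs004 mismatched
  expect_setequal(h$aligned$variant_id, c("rs001", "rs002"))
  expect_equal(h$aligned$weight[h$aligned$variant_id == "rs001"], log(1.5))
  expect_false(h$aligned$flip[h$aligned$variant_id == "rs001"])
  expect_true(h$aligned$flip[h$aligned$variant_id == "rs002"])
  expect_equal(h$report$reason[h$report$variant_id == "rs003"], "palindromic")
  expect_equal(h$report$reason[h$report$variant_id == "rs004"],
               "allele-mismatch")

  g2 <- toy_genotypes(d)
  ss2 <- toy_sumstats(or = rep(1.5, 4), p = rep(0.1, 4),
                      effect = rep("C", 4), other = rep("T", 4))
  expect_error(harmonize(ss2[0, ], g2), "overlapping")
})

test_that("P thresholding is strict and threshold sets are nested", {
  al <- data.frame(variant_id = paste0("v", 1:5),
                   p_value = c(1e-6, 0.05, 0.04, 0.5, 0.49),
                   stringsAsFactors = FALSE)
  expect_equal(threshold_variants(al, 0.05), c("v1", "v3"))  # 0.05 excluded
  expect_equal(threshold_variants(al, 1.0), paste0("v", 1:5))
  expect_error(threshold_variants(al, 0), "p_cut")

  set.seed(9)
  alr <- data.frame(variant_id = paste0("r", 1:500),
                    p_value = runif(500), stringsAsFactors = FALSE)
  s1 <- threshold_variants(alr, 1e-5)
  s2 <- threshold_variants(alr, 0.05)
  s3 <- threshold_variants(alr, 0.5)
  expect_true(all(s1 %in% s2) && all(s2 %in% s3))
})

test_that("score arithmetic matches hand-computed values and the null is 0", {
  # two variants, ORs 1.5 / 0.8, dosages 2 / 1:
  # raw = 2 ln 1.5 + 1 ln 0.8 = 0.5878; per-allele mean = raw / 4
  g <- toy_genotypes(matrix(c(2L, 1L), nrow = 1))
  ss <- toy_sumstats(or = c(1.5, 0.8), p = c(0.01, 0.01))
  h <- harmonize(ss, g)
  raw <- compute_scores(g, h$aligned, h$aligned$variant_id, "raw_sum")
  expect_equal(unname(raw$score), 2 * log(1.5) + log(0.8), tolerance = 1e-12)
  expect_equal(unname(raw$score), 0.5877867, tolerance = 1e-6)
  pam <- compute_scores(g, h$aligned, h$aligned$variant_id, "per_allele_mean")
  expect_equal(unname(pam$score), 0.5877867 / 4, tolerance = 1e-6)
  expect_equal(pam$n_variants_used, 2L)

  # all ORs 1 -> all scores exactly 0 in both modes
  ss1 <- toy_sumstats(or = c(1, 1), p = c(0.2, 0.3))
  h1 <- harmonize(ss1, g)
  expect_equal(unname(compute_scores(g, h1$aligned, h1$aligned$variant_id,
                                     "raw_sum")$score), 0)
  expect_equal(unname(compute_scores(g, h1$aligned, h1$aligned$variant_id,
                                     "per_allele_mean")$score), 0)

  # empty set: zero scores, n = 0, warning
  expect_warning(z <- compute_scores(g, h$aligned, character(0)), "empty")
  expect_equal(unname(z$score), 0)
  expect_equal(z$n_variants_used, 0L)
})

test_that("scores match the brute-force double-loop oracle on random instances", {
  set.seed(123)
  for (rep in 1:25) {
    n <- sample(5:20, 1); m <- sample(5:50, 1)
    d <- matrix(rbinom(n * m, 2, runif(1, 0.1, 0.5)), n, m)
    if (rep %% 3 == 0) d[sample(length(d), max(1, n * m %/% 20))] <- NA
    g <- toy_genotypes(d)
    flip <- runif(m) < 0.3
    counted <- ifelse(flip, "A", "G"); other <- ifelse(flip, "G", "A")
    g <- toy_genotypes(d, counted = counted, other = other)
    ss <- toy_sumstats(or = exp(rnorm(m, 0, 0.3)), p = runif(m))
    h <- harmonize(ss, g)
    for (mode in c("raw_sum", "per_allele_mean")) {
      got <- compute_scores(g, h$aligned, h$aligned$variant_id, mode)
      want <- oracle_scores(d, h$aligned$weight, h$aligned$flip, mode)
      expect_equal(unname(got$score), want, tolerance = 1e-12)
    }
  }
})

test_that("scores are invariant under allele-coding flips", {
  set.seed(77)
  n <- 50; m <- 20
  d <- matrix(rbinom(n * m, 2, 0.3), n, m)
  g <- toy_genotypes(d)
  ss <- toy_sumstats(or = exp(rnorm(m, 0, 0.2)), p = runif(m))
  h <- harmonize(ss, g)
  s0 <- compute_scores(g, h$aligned, h$aligned$variant_id, "raw_sum")

  flip_cols <- sample(m, 8)
  d2 <- d; d2[, flip_cols] <- 2L - d2[, flip_cols]
  counted <- g$counted_allele; other <- g$other_allele
  counted[flip_cols] <- "A"; other[flip_cols] <- "G"
  g2 <- toy_genotypes(d2, counted = unname(counted), other = unname(other))
  h2 <- harmonize(ss, g2)
  s2 <- compute_scores(g2, h2$aligned, h2$aligned$variant_id, "raw_sum")
  expect_equal(s2$score, s0$score, tolerance = 1e-12)
})

test_that("index-variant exclusion removes listed ids and ignores absent ones", {
  vs <- c("rs1702294", "rs000001", "rs000002")
  expect_setequal(suppressMessages(exclude_index_variant(vs, "rs1702294")),
                  c("rs000001", "rs000002"))
  expect_identical(exclude_index_variant(vs, character(0)), vs)
  expect_identical(exclude_index_variant(vs, "rs999999"), vs)
})

test_that("per-allele mean scores decrease from strict to loose thresholds when effects shrink with P", {
  set.seed(5)
  n <- 400
  # planted panel: |log OR| decreases as P grows
  or <- c(exp(0.5), exp(0.2), exp(0.05))
  p <- c(1e-6, 0.01, 0.3)
  d <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  g <- toy_genotypes(d)
  ss <- toy_sumstats(or = or, p = p)
  sets <- score_thresholds(g, ss, thresholds = c(1e-5, 0.05, 0.5))
  means <- vapply(sets, function(s) mean(s$score), numeric(1))
  expect_true(all(diff(means) < 0))
})
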