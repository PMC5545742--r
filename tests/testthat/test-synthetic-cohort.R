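test_that("gene generation respects bounds, determinism, and the empty case", {
  cfg <- tiny_config(n_genes = 50, chrom_lengths = c("1" = 1e7))
  g1 <- generate_genes(cfg)
  g2 <- generate_genes(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 50)
  expect_true(all(g1$start >= 1 & g1$start < g1$end & g1$end <= 1e7))
  expect_true(all(g1$chrom == "1"))

  expect_equal(nrow(generate_genes(tiny_config(n_genes = 0))), 0)
  expect_error(generate_genes(tiny_config(chrom_lengths = c("1" = 30000))),
               "configuration error")
})

test_that("variant panel bookkeeping: counts, ids, MAF range, decoys", {
  cfg <- tiny_config(n_genes = 10, snps_per_gene_region = 5,
                     n_decoy_snps = 20)
  genes <- generate_genes(cfg)
  panel <- generate_snps_and_sumstats(genes, cfg)
  expect_equal(nrow(panel$variants), 10 * 5 + 20)
  expect_false(anyDuplicated(panel$variants$variant_id) > 0)
  expect_true(all(panel$variants$maf > 0 & panel$variants$maf <= 0.5))
  expect_true(all(panel$variants$ref != panel$variants$alt))
  expect_equal(sum(!panel$variants$in_window), 20)
  # decoys really sit outside every flanked window
  w <- build_windows(genes, cfg$flank)
  out <- panel$variants[!panel$variants$in_window, ]
  expect_length(oracle_select(out, w), 0)
})

test_that("null panels have unit odds ratios and uniform P-values", {
  cfg0 <- tiny_config(frac_effect_snps = 0)
  panel0 <- generate_snps_and_sumstats(generate_genes(cfg0), cfg0)
  expect_true(all(panel0$sumstats$odds_ratio == 1))

  # effect_log_or_sd = 0: Wald z is standard normal, P uniform on (0,1)
  cfgU <- tiny_config(n_genes = 20, snps_per_gene_region = 100,
                      n_decoy_snps = 0, effect_log_or_sd = 0, seed = 5L)
  panelU <- generate_snps_and_sumstats(generate_genes(cfgU), cfgU)
  expect_gte(nrow(panelU$sumstats), 2000)
  ks <- ks.test(panelU$sumstats$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("genotypes are Hardy-Weinberg binomial draws on the target MAF", {
  cfg <- tiny_config(n_individuals = 10000, seed = 3L)
  v <- data.frame(variant_id = c("rsA", "rsB"), chrom = "1",
                  pos = c(100, 200), ref = "A", alt = "G",
                  maf = c(0.5, 0.01), in_window = TRUE,
                  stringsAsFactors = FALSE)
  g <- generate_genotypes(v, cfg)
  expect_true(all(g$dosage %in% 0:2))
  # MAF 0.5: mean dosage within 3 binomial SEs of 1
  expect_gt(mean(g$dosage[, "rsA"]), 0.97)
  expect_lt(mean(g$dosage[, "rsA"]), 1.03)
  # MAF 0.01 at n=10000: heterozygote fraction near 2pq
  p <- 0.01
  het <- mean(g$dosage[, "rsB"] == 1)
  se <- sqrt(2 * p * (1 - p) * (1 - 2 * p * (1 - p)) / 10000)
  expect_lt(abs(het - 2 * p * (1 - p)), 3 * se)
  # empirical allele frequency within 3 SE of target
  af <- mean(g$dosage[, "rsB"]) / 2
  expect_lt(abs(af - p), 3 * sqrt(p * (1 - p) / (2 * 10000)))

  expect_false(anyNA(g$dosage))
  gm <- generate_genotypes(v, tiny_config(n_individuals = 2000,
                                          missing_rate = 0.1, seed = 3L))
  expect_gt(mean(is.na(gm$dosage)), 0.05)
  expect_error(generate_genotypes(transform(v, maf = 0), cfg), "MAF")
})

test_that("phenotype generator plants the requested incremental r2", {
  # null: score coefficient is exactly 0
  cfg0 <- tiny_config(target_incremental_r2 = 0, n_individuals = 500)
  c0 <- simulate_cohort(cfg0)
  expect_equal(cor(c0$phenotypes$phenotype, c0$phenotypes$true_score), 0,
               tolerance = 0.15)

  # strong effect, no covariates: r2 of phenotype ~ true score near 0.5
  cfgB <- tiny_config(target_incremental_r2 = 0.5, age_beta = 0,
                      sex_beta = 0, n_individuals = 2000, seed = 21L)
  cb <- simulate_cohort(cfgB)
  r2 <- summary(lm(phenotype ~ true_score, cb$phenotypes))$r.squared
  expect_gt(r2, 0.45)
  expect_lt(r2, 0.55)

  expect_error(cohort_config(target_incremental_r2 = 1), "target_incremental_r2")
})

test_that("whole-cohort simulation is deterministic given the seed", {
  a <- simulate_cohort(tiny_config(seed = 99L))
  b <- simulate_cohort(tiny_config(seed = 99L))
  expect_identical(a$genes, b$genes)
  expect_identical(a$sumstats, b$sumstats)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$phenotypes, b$phenotypes)
  d <- simulate_cohort(tiny_config(seed = 100L))
  expect_false(identical(a$phenotypes$phenotype, d$phenotypes$phenotype))
})

test_that("platform split assigns the configured proportion to sample A", {
  cfg <- tiny_config(n_individuals = 1000, platform_split = 0.3)
  ph <- simulate_cohort(cfg)$phenotypes
  expect_equal(sum(ph$platform == "A"), 300)
  expect_true(all(ph$age >= 18 & ph$age <= 65))
  expect_true(all(ph$sex %in% 0:1))
})
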