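#' Configuration for a synthetic genotype-phenotype cohort
#'
#' Collects every knob of the synthetic cohort generator: genome layout,
#' variant density, planted GWAS effects, and the phenotype model. The
#' generator draws biallelic autosomal SNPs in Hardy-Weinberg equilibrium,
#' plants log-odds-ratio effects on a fraction of in-window variants, and
#' builds Gaussian phenotypes in which the true (planted-weight) score
#' explains a configurable incremental fraction of variance after age and
#' sex.
#'
#' @param n_individuals Number of individuals.
#' @param n_genes Number of genes to place on the autosomes.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp;
#'   names must be autosome labels `"1"`..`"22"`.
#' @param snps_per_gene_region SNPs simulated inside each gene's flanked
#'   window.
#' @param n_decoy_snps SNPs placed outside every gene window (negative
#'   controls for variant selection).
#' @param maf_range Length-2 vector, minor-allele-frequency bounds in
#'   (0, 0.5].
#' @param frac_effect_snps Fraction of in-window SNPs given a nonzero
#'   planted log odds ratio.
#' @param effect_log_or_sd Standard deviation of planted log odds ratios.
#' @param log_or_se Wald standard error used to simulate GWAS P-values.
#' @param target_incremental_r2 Phenotype variance fraction attributable to
#'   the true score after covariates, in [0, 1).
#' @param age_beta,sex_beta Covariate effects on the phenotype (per year of
#'   age; for female vs male).
#' @param platform_split Proportion of individuals assigned to genotyping
#'   subsample "A"; the rest are "B".
#' @param missing_rate Genotype missingness rate in [0, 1).
#' @param flank Window flank in bp used when placing in-window SNPs.
#' @param seed Master seed; each generation stage derives its own stream
#'   from it by a fixed offset, so stages are independently reproducible.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 1000,
                          n_genes = 20,
                          chrom_lengths = c("1" = 5e7, "2" = 5e7),
                          snps_per_gene_region = 5,
                          n_decoy_snps = 20,
                          maf_range = c(0.05, 0.5),
                          frac_effect_snps = 0.5,
                          effect_log_or_sd = 0.1,
                          log_or_se = 0.05,
                          target_incremental_r2 = 0.02,
                          age_beta = 0.01,
                          sex_beta = 0.1,
                          platform_split = 0.5,
                          missing_rate = 0,
                          flank = 20000,
                          seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_genes = as.integer(n_genes),
    chrom_lengths = chrom_lengths,
    snps_per_gene_region = as.integer(snps_per_gene_region),
    n_decoy_snps = as.integer(n_decoy_snps),
    maf_range = as.numeric(maf_range),
    frac_effect_snps = as.numeric(frac_effect_snps),
    effect_log_or_sd = as.numeric(effect_log_or_sd),
    log_or_se = as.numeric(log_or_se),
    target_incremental_r2 = as.numeric(target_incremental_r2),
    age_beta = as.numeric(age_beta),
    sex_beta = as.numeric(sex_beta),
    platform_split = as.numeric(platform_split),
    missing_rate = as.numeric(missing_rate),
    flank = as.numeric(flank),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_individuals < 1L) stop("n_individuals must be >= 1")
  if (cfg$n_genes < 0L) stop("n_genes must be >= 0")
  if (length(cfg$chrom_lengths) == 0L) stop("chrom_lengths must be non-empty")
  if (!all(names(cfg$chrom_lengths) %in% as.character(1:22)))
    stop("chrom_lengths names must be autosome labels \"1\"..\"22\"")
  if (cfg$snps_per_gene_region < 1L) stop("snps_per_gene_region must be >= 1")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] > cfg$maf_range[2] ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5)
    stop("maf_range must be ordered and within (0, 0.5]")
  if (cfg$frac_effect_snps < 0 || cfg$frac_effect_snps > 1)
    stop("frac_effect_snps must be in [0, 1]")
  if (cfg$effect_log_or_sd < 0) stop("effect_log_or_sd must be >= 0")
  if (cfg$log_or_se <= 0) stop("log_or_se must be > 0")
  if (cfg$target_incremental_r2 < 0 || cfg$target_incremental_r2 >= 1)
    stop("target_incremental_r2 must be in [0, 1)")
  if (cfg$platform_split <= 0 || cfg$platform_split >= 1)
    stop("platform_split must be in (0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (cfg$flank < 0) stop("flank must be >= 0")
  invisible(cfg)
}

# Per-stage substream offsets from the master seed. Kept small so the
# derived seed stays a valid 32-bit integer.
.stage_seed <- function(cfg, stage) {
  offs <- c(genes = 101L, snps = 211L, genotypes = 307L, phenotypes = 401L)
  as.integer((cfg$seed + offs[[stage]]) %% .Machine$integer.max)
}

#' Place genes on the autosomes
#'
#' Draws `n_genes` non-degenerate intervals uniformly within the configured
#' chromosomes. Gene lengths are uniform on 5-50 kb; intervals are 1-based
#' closed and always fit inside their chromosome.
#'
#' @param config A [cohort_config()].
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   sorted by (chrom, start).
#' @export
generate_genes <- function(config) {
  validate_cohort_config(config)
  if (config$n_genes == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric()))
  }
  set.seed(.stage_seed(config, "genes"))
  min_len <- 5000
  max_len <- 50000
  if (any(config$chrom_lengths <= max_len))
    stop("configuration error: gene length can exceed a chromosome length")
  chroms <- sample(names(config$chrom_lengths), config$n_genes, replace = TRUE)
  len <- round(stats::runif(config$n_genes, min_len, max_len))
  start <- vapply(seq_len(config$n_genes), function(i) {
    floor(stats::runif(1, 1, config$chrom_lengths[[chroms[i]]] - len[i]))
  }, numeric(1))
  genes <- data.frame(
    gene_id = sprintf("GENE%04d", seq_len(config$n_genes)),
    chrom = chroms,
    start = start,
    end = start + len,
    stringsAsFactors = FALSE
  )
  genes[order(suppressWarnings(as.integer(genes$chrom)), genes$start), ,
        drop = FALSE]
}

# draw an allele pair, avoiding strand-ambiguous (palindromic) A/T and C/G
# pairs so harmonization keeps every simulated variant by default
.draw_allele_pairs <- function(n) {
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  idx <- sample.int(nrow(pairs), n, replace = TRUE)
  pairs[idx, , drop = FALSE]
}

#' Simulate a variant panel and its GWAS summary statistics
#'
#' Places `snps_per_gene_region` SNPs inside each gene's flanked window and
#' `n_decoy_snps` outside all windows. A fraction `frac_effect_snps` of
#' in-window SNPs receives a planted log odds ratio drawn
#' Normal(0, `effect_log_or_sd`); all other variants (including decoys) have
#' log OR 0. The reported odds ratio is exp(planted log OR); the reported
#' P-value comes from a simulated two-sided Wald z on the planted log OR
#' with standard error `log_or_se`, so larger planted effects tend to have
#' smaller P and null variants have uniform P.
#'
#' @param genes Gene table from [generate_genes()].
#' @param config A [cohort_config()].
#' @return A list with `variants` (variant_id, chrom, pos, ref, alt, maf,
#'   in_window) and `sumstats` (variant_id, chrom, pos, effect_allele,
#'   other_allele, odds_ratio, p_value, planted_log_or).
#' @export
generate_snps_and_sumstats <- function(genes, config) {
  validate_cohort_config(config)
  set.seed(.stage_seed(config, "snps"))
  n_in <- nrow(genes) * config$snps_per_gene_region
  n_out <- config$n_decoy_snps

  windows <- if (nrow(genes) > 0) build_windows(genes, config$flank) else genes

  pos_in <- integer(0); chrom_in <- character(0)
  if (n_in > 0) {
    for (i in seq_len(nrow(windows))) {
      p <- sort(sample(seq(windows$start[i], windows$end[i]),
                       config$snps_per_gene_region))
      pos_in <- c(pos_in, p)
      chrom_in <- c(chrom_in, rep(windows$chrom[i], config$snps_per_gene_region))
    }
  }

  # decoys: rejection-sample positions until they fall outside every window
  pos_out <- integer(0); chrom_out <- character(0)
  while (length(pos_out) < n_out) {
    need <- n_out - length(pos_out)
    ch <- sample(names(config$chrom_lengths), need, replace = TRUE)
    pp <- floor(stats::runif(need, 1, config$chrom_lengths[ch]))
    keep <- vapply(seq_len(need), function(j) {
      if (nrow(windows) == 0) return(TRUE)
      w <- windows[windows$chrom == ch[j], , drop = FALSE]
      !any(w$start <= pp[j] & pp[j] <= w$end)
    }, logical(1))
    pos_out <- c(pos_out, pp[keep])
    chrom_out <- c(chrom_out, ch[keep])
  }

  chrom <- c(chrom_in, chrom_out)
  pos <- c(pos_in, pos_out)
  in_window <- c(rep(TRUE, n_in), rep(FALSE, n_out))
  n <- length(pos)
  if (n == 0L) {
    empty <- data.frame(variant_id = character(), chrom = character(),
                        pos = numeric(), ref = character(), alt = character(),
                        maf = numeric(), in_window = logical())
    ss <- data.frame(variant_id = character(), chrom = character(),
                     pos = numeric(), effect_allele = character(),
                     other_allele = character(), odds_ratio = numeric(),
                     p_value = numeric(), planted_log_or = numeric())
    return(list(variants = empty, sumstats = ss))
  }

  ids <- sprintf("rs%06d", seq_len(n))
  if (anyDuplicated(ids)) stop("generation error: duplicate variant ids")
  alleles <- .draw_allele_pairs(n)
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])

  log_or <- numeric(n)
  if (config$frac_effect_snps > 0 && n_in > 0) {
    n_eff <- round(config$frac_effect_snps * n_in)
    eff_idx <- sample(seq_len(n_in), n_eff)
    log_or[eff_idx] <- stats::rnorm(n_eff, 0, config$effect_log_or_sd)
  }
  z <- log_or / config$log_or_se + stats::rnorm(n)
  p <- 2 * stats::pnorm(-abs(z))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  ord <- order(suppressWarnings(as.integer(chrom)), pos)
  variants <- data.frame(
    variant_id = ids, chrom = chrom, pos = pos,
    ref = alleles[, 1], alt = alleles[, 2],
    maf = maf, in_window = in_window, stringsAsFactors = FALSE
  )[ord, , drop = FALSE]
  rownames(variants) <- NULL

  sumstats <- data.frame(
    variant_id = variants$variant_id, chrom = variants$chrom,
    pos = variants$pos,
    effect_allele = variants$alt, other_allele = variants$ref,
    odds_ratio = exp(log_or[ord]), p_value = p[ord],
    planted_log_or = log_or[ord], stringsAsFactors = FALSE
  )
  list(variants = variants, sumstats = sumstats)
}

#' Draw Hardy-Weinberg genotypes for a variant panel
#'
#' Dosages count the ALT (effect) allele and are drawn Binomial(2, MAF)
#' independently per individual and variant. Missingness, when configured,
#' is injected completely at random and recorded as NA.
#'
#' @param variants Variant table from [generate_snps_and_sumstats()].
#' @param config A [cohort_config()].
#' @return A `genotype_matrix`: list with `dosage` (individuals x variants
#'   integer matrix, NA = missing), `individual_id`, `variant_id`, and
#'   `counted_allele`/`other_allele` per variant (ALT is counted).
#' @export
generate_genotypes <- function(variants, config) {
  validate_cohort_config(config)
  if (any(variants$maf <= 0 | variants$maf > 0.5))
    stop("MAFs must be in (0, 0.5]")
  set.seed(.stage_seed(config, "genotypes"))
  n <- config$n_individuals
  m <- nrow(variants)
  dos <- matrix(stats::rbinom(n * m, 2L, rep(variants$maf, each = n)),
                nrow = n, ncol = m)
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    dos[miss] <- NA_integer_
  }
  genotype_matrix(
    dosage = dos,
    individual_id = sprintf("IND%05d", seq_len(n)),
    variant_id = variants$variant_id,
    counted_allele = variants$alt,
    other_allele = variants$ref
  )
}

#' Construct a genotype matrix object
#'
#' The package's container for hard-call effect-allele dosages: an
#' individuals x variants integer matrix in {0, 1, 2} with NA for missing
#' calls, plus the allele counted by the dosage for each variant.
#'
#' @param dosage Integer matrix, individuals in rows, variants in columns.
#' @param individual_id,variant_id Row / column identifiers.
#' @param counted_allele,other_allele Per-variant alleles; `counted_allele`
#'   is the allele the dosage counts.
#' @return A list of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, individual_id, variant_id,
                            counted_allele, other_allele) {
  stopifnot(is.matrix(dosage),
            nrow(dosage) == length(individual_id),
            ncol(dosage) == length(variant_id),
            length(counted_allele) == length(variant_id),
            length(other_allele) == length(variant_id))
  ok <- dosage %in% c(0L, 1L, 2L, NA)
  if (!all(ok)) stop("dosages must be in {0,1,2} or NA")
  rownames(dosage) <- individual_id
  colnames(dosage) <- variant_id
  structure(list(dosage = dosage,
                 individual_id = individual_id,
                 variant_id = variant_id,
                 counted_allele = stats::setNames(counted_allele, variant_id),
                 other_allele = stats::setNames(other_allele, variant_id)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Simulate phenotypes carrying a planted score effect
#'
#' Builds `phenotype = age_beta * age + sex_beta * sex + b * true_score + e`
#' where `true_score` is the planted-weight polygenic score (dosage times
#' planted log OR, summed over variants), and `b` and Var(e) are solved so
#' the expected incremental r-squared of the score after the covariates
#' equals `target_incremental_r2`. Age is uniform on [18, 65] (the study
#' inclusion range), sex is Bernoulli(0.5), and the platform label splits
#' the cohort into genotyping subsamples "A" and "B".
#'
#' @param genotypes A `genotype_matrix` aligned with `sumstats` on
#'   variant id.
#' @param sumstats Summary-statistic table with `planted_log_or`.
#' @param config A [cohort_config()].
#' @return data.frame: individual_id, age, sex (0/1), platform ("A"/"B"),
#'   group ("control"/"narrow"/"broad"), true_score, phenotype.
#' @export
generate_phenotypes <- function(genotypes, sumstats, config) {
  validate_cohort_config(config)
  if (!identical(genotypes$variant_id, sumstats$variant_id))
    stop("genotypes and sumstats must be aligned on variant id")
  set.seed(.stage_seed(config, "phenotypes"))
  n <- nrow(genotypes$dosage)

  dos <- genotypes$dosage
  if (anyNA(dos)) {
    af <- colMeans(dos, na.rm = TRUE) / 2
    for (j in which(colSums(is.na(dos)) > 0))
      dos[is.na(dos[, j]), j] <- 2 * af[j]
  }
  true_score <- as.numeric(dos %*% sumstats$planted_log_or)

  age <- stats::runif(n, 18, 65)
  sex <- stats::rbinom(n, 1L, 0.5)
  platform <- ifelse(seq_len(n) <= round(config$platform_split * n), "A", "B")
  group <- sample(c("control", "narrow", "broad"), n, replace = TRUE,
                  prob = c(0.2, 0.4, 0.4))

  r2 <- config$target_incremental_r2
  cov_part <- config$age_beta * age + config$sex_beta * sex
  v_cov <- stats::var(cov_part)
  v_s <- stats::var(true_score)
  if (r2 > 0 && v_s == 0)
    stop("target_incremental_r2 > 0 requires a non-degenerate true score")

  # total variance T = v_cov + 1; score contributes r2 * T, noise the rest
  v_tot <- v_cov + 1
  b <- if (r2 > 0) sqrt(r2 * v_tot / v_s) else 0
  v_eps <- v_tot - v_cov - r2 * v_tot
  if (v_eps <= 0)
    stop("covariate effects too large for the requested incremental r2")

  phenotype <- cov_part + b * true_score +
    stats::rnorm(n, 0, sqrt(v_eps))

  data.frame(
    individual_id = genotypes$individual_id,
    age = age, sex = sex, platform = platform, group = group,
    true_score = true_score, phenotype = phenotype,
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete cohort
#'
#' Runs all four generation stages (genes, variant panel plus summary
#' statistics, genotypes, phenotypes) from one config.
#'
#' @param config A [cohort_config()].
#' @return A list: `config`, `genes`, `variants`, `sumstats`, `genotypes`,
#'   `phenotypes`.
#' @export
simulate_cohort <- function(config) {
  genes <- generate_genes(config)
  panel <- generate_snps_and_sumstats(genes, config)
  genotypes <- generate_genotypes(panel$variants, config)
  phenotypes <- generate_phenotypes(genotypes, panel$sumstats, config)
  list(config = config, genes = genes, variants = panel$variants,
       sumstats = panel$sumstats, genotypes = genotypes,
       phenotypes = phenotypes)
}
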