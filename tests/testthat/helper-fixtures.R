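# In-code fixtures shared across the suite.

# small cohort config; override fields via ...
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_individuals = 200, n_genes = 6, chrom_lengths = c("1" = 1e7, "2" = 1e7),
    snps_per_gene_region = 3, n_decoy_snps = 8, seed = 11L
  )
  defaults[names(args)] <- args
  do.call(cohort_config, defaults)
}

# deterministic hand-built genotype matrix
toy_genotypes <- function(dosage, counted = NULL, other = NULL) {
  m <- ncol(dosage)
  genotype_matrix(
    dosage = dosage,
    individual_id = sprintf("I%02d", seq_len(nrow(dosage))),
    variant_id = sprintf("rs%03d", seq_len(m)),
    counted_allele = counted %||% rep("G", m),
    other_allele = other %||% rep("A", m)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built summary statistics matching toy_genotypes ids
toy_sumstats <- function(or, p, effect = NULL, other = NULL) {
  m <- length(or)
  data.frame(
    variant_id = sprintf("rs%03d", seq_len(m)),
    chrom = rep("1", m), pos = seq_len(m) * 1000,
    effect_allele = effect %||% rep("G", m),
    other_allele = other %||% rep("A", m),
    odds_ratio = or, p_value = p,
    stringsAsFactors = FALSE
  )
}

# brute-force score oracle: explicit double loop over individuals/variants,
# independent of the matrix-algebra path in compute_scores
oracle_scores <- function(dosage, weights, flip, normalization) {
  n <- nrow(dosage); m <- ncol(dosage)
  d <- dosage
  for (j in seq_len(m)) {
    if (flip[j]) d[, j] <- 2 - d[, j]
    if (anyNA(d[, j])) {
      af <- mean(d[, j], na.rm = TRUE) / 2
      d[is.na(d[, j]), j] <- 2 * af
    }
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(m)) s <- s + d[i, j] * weights[j]
    out[i] <- s
  }
  if (normalization == "per_allele_mean") out / (2 * m) else out
}

# brute-force interval-overlap oracle: all pairs variant x window
oracle_select <- function(variants, windows) {
  hit <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    for (j in seq_len(nrow(windows))) {
      if (variants$chrom[i] == windows$chrom[j] &&
          windows$start[j] <= variants$pos[i] &&
          variants$pos[i] <= windows$end[j]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  variants$variant_id[hit]
}

# one in-memory pass of the analysis chain on a simulated cohort:
# simulate -> windows -> select -> harmonize -> threshold -> score ->
# covariate-adjusted association. Returns the association row.
run_chain <- function(config, p_cut = 1, normalization = "per_allele_mean") {
  cohort <- simulate_cohort(config)
  windows <- build_windows(cohort$genes, config$flank)
  sel <- select_variants(cohort$variants, windows)
  h <- harmonize(cohort$sumstats, cohort$genotypes)
  vs <- intersect(threshold_variants(h$aligned, p_cut), sel)
  s <- suppressWarnings(
    compute_scores(cohort$genotypes, h$aligned, vs, normalization))
  fit_association(cohort$phenotypes$phenotype, unname(s$score),
                  cohort$phenotypes[, c("age", "sex")])
}
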