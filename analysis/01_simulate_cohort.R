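#!/usr/bin/env Rscript
# Simulate the study-style cohort: ~1000 individuals genotyped on two
# platforms (subsamples A and B), a panel of gene-set SNPs with planted
# GWAS effects, and a continuous cognitive phenotype in which the true
# pathway score explains ~2% of variance after age and sex.
library(pathprs)

out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- cohort_config(
  n_individuals = 1000,
  n_genes = 40,
  chrom_lengths = c("1" = 5e7, "2" = 5e7, "3" = 5e7),
  snps_per_gene_region = 5,
  n_decoy_snps = 40,
  target_incremental_r2 = 0.02,
  platform_split = 0.5,
  seed = 2026L
)
cohort <- simulate_cohort(cfg)

write_gene_annotation(cohort$genes, file.path(out, "genes.tsv"))
write_sumstats(cohort$sumstats, file.path(out, "sumstats.tsv"))
write_vcf(cohort$genotypes, cohort$variants, file.path(out, "genotypes.vcf"))
write_phenotypes(cohort$phenotypes, file.path(out, "phenotypes.tsv"))

cat(sprintf("cohort: %d individuals (%d on platform A), %d genes, %d variants (%d in gene windows)\n",
            nrow(cohort$genotypes$dosage),
            sum(cohort$phenotypes$platform == "A"),
            nrow(cohort$genes), nrow(cohort$variants),
            sum(cohort$variants$in_window)))
cat(sprintf("planted nonzero log-OR variants: %d; target incremental r2: %.3f\n",
            sum(cohort$sumstats$planted_log_or != 0),
            cfg$target_incremental_r2))
cat("wrote", out, "\n")
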