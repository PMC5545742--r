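#!/usr/bin/env Rscript
# Fixed-effect inverse-variance meta-analysis of the per-platform estimates
# at each score threshold, with Cochran's Q / I-squared heterogeneity and a
# Bonferroni correction over five cognitive domains.
library(pathprs)

a <- read.delim("results/assoc_A.tsv")
b <- read.delim("results/assoc_B.tsv")

rows <- list()
for (th in unique(a$threshold)) {
  ra <- a[a$threshold == th, ]
  rb <- b[b$threshold == th, ]
  m <- meta_combine(c(ra$estimate, rb$estimate), c(ra$se, rb$se))
  m$p_bonferroni <- bonferroni(m$p_value, n_domains = 5)
  rows[[length(rows) + 1L]] <- cbind(threshold = th, m)
}
meta <- do.call(rbind, rows)
utils::write.table(meta, "results/meta.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
print(meta[, c("threshold", "combined_B", "ci_low", "ci_high", "p_value",
               "p_bonferroni", "q_statistic", "i_squared", "p_het")],
      digits = 3)
cat("wrote results/meta.tsv\n")
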