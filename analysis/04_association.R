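#!/usr/bin/env Rscript
# Covariate-adjusted association of phenotype on each threshold score,
# separately per genotyping platform (outliers screened at |z| > 3; age and
# sex as covariates of no interest), mirroring the per-subsample regressions
# that feed the meta-analysis.
library(pathprs)

scores <- read.delim("results/scores.tsv")
pheno <- read.delim("results/cohort/phenotypes.tsv")
stopifnot(identical(scores$individual_id, pheno$individual_id))

score_cols <- grep("^score_", names(scores), value = TRUE)
rows <- list()
for (pl in sort(unique(pheno$platform))) {
  in_pl <- pheno$platform == pl
  y <- pheno$phenotype[in_pl]
  keep <- detect_outliers(y)
  cat(sprintf("platform %s: n = %d, %d outlier(s) excluded\n",
              pl, sum(in_pl), sum(!keep)))
  for (sc in score_cols) {
    r <- fit_association(y[keep], scores[[sc]][in_pl][keep],
                         pheno[in_pl, c("age", "sex")][keep, ],
                         phenotype_name = "phenotype")
    r$threshold <- sub("score_p", "", sc)
    r$platform <- pl
    rows[[length(rows) + 1L]] <- r
  }
}
assoc <- do.call(rbind, rows)
for (pl in unique(assoc$platform)) {
  f <- sprintf("results/assoc_%s.tsv", pl)
  utils::write.table(assoc[assoc$platform == pl, ], f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cat("wrote", f, "\n")
}
print(assoc[, c("platform", "threshold", "estimate", "se", "p_value",
                "standardized_beta", "delta_r2", "n_used")], digits = 3)
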