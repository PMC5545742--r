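#!/usr/bin/env Rscript
# Map the gene set to 20 kb flanked windows and select the panel variants
# that fall inside any window; decoy variants outside the set must drop out.
library(pathprs)

genes <- read_gene_annotation("results/cohort/genes.tsv")
ss <- read_sumstats("results/cohort/sumstats.tsv")

resolved <- resolve_gene_list(genes$gene_id, genes)
cat(sprintf("gene list: %d resolved to unique autosomal loci, %d rejected\n",
            nrow(resolved$genes), nrow(resolved$rejected)))

windows <- build_windows(resolved$genes, flank = 20000)
variants <- data.frame(variant_id = ss$variant_id, chrom = ss$chrom,
                       pos = ss$pos, stringsAsFactors = FALSE)
selected <- select_variants(variants, windows)

dir.create("results", showWarnings = FALSE)
utils::write.table(windows, "results/windows.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
writeLines(selected, "results/selected_variants.txt")
cat(sprintf("windows: %d (20 kb flank); %d of %d variants selected\n",
            nrow(windows), length(selected), nrow(variants)))
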