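#' Write genotypes as VCF v4.2
#'
#' Emits biallelic records with a GT-only FORMAT, unphased ("0/1" style);
#' missing calls become "./.". The dosage counts the ALT allele, so ALT is
#' written as the counted allele and REF as the other allele.
#'
#' @param genotypes A `genotype_matrix`.
#' @param variants Variant table with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt` aligned with the genotype columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, variants, path) {
  stopifnot(identical(genotypes$variant_id, variants$variant_id))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pathprs",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$individual_id), collapse = "\t")
  )
  lines <- vapply(seq_len(nrow(variants)), function(j) {
    d <- genotypes$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(variants$chrom[j], format(variants$pos[j], scientific = FALSE),
            variants$variant_id[j], variants$ref[j], variants$alt[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses GT fields with `vcfR`; biallelic records only, multiallelic
#' records are skipped with a message. The ALT allele is the counted
#' allele.
#'
#' @param path VCF file path.
#' @return A `genotype_matrix`.
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message("skipping ", sum(multi), " multiallelic record(s)")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    out <- rep(NA_integer_, length(g))
    ok <- !is.na(g) & !grepl(".", g, fixed = TRUE)
    alleles <- strsplit(gsub("|", "/", g[ok], fixed = TRUE), "/", fixed = TRUE)
    out[ok] <- vapply(alleles, function(a) sum(a == "1"), integer(1))
    out
  }
  dos <- apply(gt, 1, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = ncol(gt))
  genotype_matrix(
    dosage = dos,
    individual_id = colnames(gt),
    variant_id = fix$ID,
    counted_allele = fix$ALT,
    other_allele = fix$REF
  )
}

#' Write / read GWAS summary statistics as TSV
#'
#' Columns: snp, chr, pos, a1_effect, a2_other, or, p.
#'
#' @param sumstats Summary-statistic table.
#' @param path File path.
#' @return `path` invisibly (writer); summary-statistic data.frame with
#'   package-internal column names (reader).
#' @export
write_sumstats <- function(sumstats, path) {
  out <- data.frame(snp = sumstats$variant_id, chr = sumstats$chrom,
                    pos = sumstats$pos, a1_effect = sumstats$effect_allele,
                    a2_other = sumstats$other_allele,
                    or = sumstats$odds_ratio, p = sumstats$p_value)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chr = "character"))
  data.frame(variant_id = x$snp, chrom = x$chr, pos = x$pos,
             effect_allele = x$a1_effect, other_allele = x$a2_other,
             odds_ratio = x$or, p_value = x$p, stringsAsFactors = FALSE)
}

#' Write / read a gene annotation table (1-based inclusive TSV)
#'
#' @param genes Gene interval table (`gene_id`, `chrom`, `start`, `end`).
#' @param path File path.
#' @return `path` invisibly (writer); gene data.frame (reader).
#' @export
write_gene_annotation <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_annotation
#' @export
read_gene_annotation <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' Write a set of threshold scores as one TSV
#'
#' One row per individual, one score column and one n_snps column per
#' threshold.
#'
#' @param score_sets Named list of `score_set`s from [score_thresholds()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(score_sets, path) {
  out <- data.frame(individual_id = names(score_sets[[1]]$score),
                    stringsAsFactors = FALSE)
  for (nm in names(score_sets)) {
    s <- score_sets[[nm]]
    out[[paste0("score_", nm)]] <- unname(s$score)
    out[[paste0("n_snps_", nm)]] <- s$n_variants_used
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phenotype / covariate table as TSV
#'
#' @param phenotypes Phenotype data.frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
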