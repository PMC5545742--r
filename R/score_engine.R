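.is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & comp[a1] == a2
}

#' Harmonize GWAS effect alleles with genotype coding
#'
#' Aligns each summary-statistic record with the allele counted by the
#' genotype dosage. If the counted allele equals the effect allele the
#' dosage is used as is; if it equals the other allele the dosage is
#' reflected (2 - d) at scoring time. Strand-ambiguous palindromic variants
#' (A/T, C/G) and variants whose allele pairs do not match are dropped with
#' a reason code.
#'
#' @param sumstats Summary-statistic table (`variant_id`, `effect_allele`,
#'   `other_allele`, `odds_ratio`, `p_value`).
#' @param genotypes A `genotype_matrix`.
#' @return A list: `aligned` data.frame (variant_id, weight = ln OR,
#'   p_value, flip) restricted to usable variants, and `report` data.frame
#'   of dropped variants (variant_id, reason).
#' @export
harmonize <- function(sumstats, genotypes) {
  shared <- intersect(sumstats$variant_id, genotypes$variant_id)
  if (length(shared) == 0L)
    stop("no overlapping variants between summary statistics and genotypes")
  ss <- sumstats[match(shared, sumstats$variant_id), , drop = FALSE]
  counted <- genotypes$counted_allele[shared]
  other <- genotypes$other_allele[shared]

  reason <- rep(NA_character_, length(shared))
  pal <- .is_palindromic(ss$effect_allele, ss$other_allele)
  reason[pal] <- "palindromic"

  same <- counted == ss$effect_allele & other == ss$other_allele
  flipped <- counted == ss$other_allele & other == ss$effect_allele
  reason[is.na(reason) & !(same | flipped)] <- "allele-mismatch"

  keep <- is.na(reason)
  aligned <- data.frame(
    variant_id = shared[keep],
    weight = log(ss$odds_ratio[keep]),
    p_value = ss$p_value[keep],
    flip = flipped[keep],
    stringsAsFactors = FALSE
  )
  report <- data.frame(variant_id = shared[!keep], reason = reason[!keep],
                       stringsAsFactors = FALSE)
  list(aligned = aligned, report = report)
}

#' Threshold variants on discovery-GWAS P-value
#'
#' Retains variants with `p_value` strictly below the cutoff (the score
#' definition uses P < threshold, so a P exactly at the cutoff is
#' excluded). Sets at increasing cutoffs are nested.
#'
#' @param aligned Aligned table from [harmonize()] (needs `variant_id`,
#'   `p_value`).
#' @param p_cut P-value cutoff in (0, 1].
#' @return Character vector of variant ids passing the cutoff.
#' @export
threshold_variants <- function(aligned, p_cut) {
  if (p_cut <= 0 || p_cut > 1) stop("p_cut must be in (0, 1]")
  aligned$variant_id[aligned$p_value < p_cut]
}

#' Remove index variants from a scoring set
#'
#' Drops listed index SNPs (for the miR-137 pathway analysis, the MIR137
#' locus variant rs1702294) from the scoring set so the score captures only
#' the downstream gene set. Absent ids are no-ops.
#'
#' @param variant_set Character vector of variant ids.
#' @param index_ids Ids to remove.
#' @return The set without the index variants.
#' @export
exclude_index_variant <- function(variant_set, index_ids) {
  removed <- intersect(variant_set, index_ids)
  if (length(removed))
    message("excluding index variant(s): ", paste(removed, collapse = ", "))
  setdiff(variant_set, index_ids)
}

#' Compute weighted polygenic scores
#'
#' For each individual, sums the harmonized risk-allele dosage times the
#' log odds ratio over the variant set:
#' `score_i = sum_j d'_ij * ln(OR_j)`, where `d'` is the dosage after any
#' allele flip (2 - d). Missing dosages are mean-imputed as twice the
#' in-sample effect-allele frequency before summation. `per_allele_mean`
#' normalization divides the raw sum by 2 x (number of variants used).
#'
#' @param genotypes A `genotype_matrix`.
#' @param aligned Aligned weights from [harmonize()].
#' @param variant_set Variant ids to score (subset of `aligned$variant_id`).
#' @param normalization `"per_allele_mean"` (default) or `"raw_sum"`.
#' @return A list of class `score_set`: `score` (named numeric per
#'   individual), `n_variants_used`, `normalization`, `threshold`
#'   (attached by the caller, NA here).
#' @export
compute_scores <- function(genotypes, aligned, variant_set,
                           normalization = c("per_allele_mean", "raw_sum")) {
  normalization <- match.arg(normalization)
  if (!all(variant_set %in% aligned$variant_id))
    stop("variant_set must be a subset of the harmonized variants")
  n_ind <- nrow(genotypes$dosage)
  if (length(variant_set) == 0L) {
    warning("empty variant set: all scores are 0")
    return(structure(list(
      score = stats::setNames(rep(0, n_ind), genotypes$individual_id),
      n_variants_used = 0L, normalization = normalization,
      threshold = NA_real_), class = "score_set"))
  }
  al <- aligned[match(variant_set, aligned$variant_id), , drop = FALSE]
  dos <- genotypes$dosage[, al$variant_id, drop = FALSE]
  storage.mode(dos) <- "double"
  # reflect dosage where the counted allele is the non-effect allele
  if (any(al$flip)) dos[, al$flip] <- 2 - dos[, al$flip, drop = FALSE]
  # mean-impute missing dosages at the in-sample effect-allele frequency
  if (anyNA(dos)) {
    af <- colMeans(dos, na.rm = TRUE) / 2
    for (j in which(colSums(is.na(dos)) > 0))
      dos[is.na(dos[, j]), j] <- 2 * af[j]
  }
  raw <- as.numeric(dos %*% al$weight)
  score <- if (normalization == "per_allele_mean")
    raw / (2 * length(variant_set)) else raw
  if (!all(is.finite(score))) stop("non-finite scores")
  structure(list(
    score = stats::setNames(score, genotypes$individual_id),
    n_variants_used = length(variant_set),
    normalization = normalization,
    threshold = NA_real_), class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("score_set: %d individuals, %d variants, %s%s\n",
              length(x$score), x$n_variants_used, x$normalization,
              if (is.na(x$threshold)) "" else
                sprintf(", P<%g", x$threshold)))
  invisible(x)
}

#' Score a cohort at several P-value thresholds
#'
#' Harmonizes, thresholds, optionally removes index variants, and scores;
#' one `score_set` per threshold. Threshold sets are nested by
#' construction.
#'
#' @param genotypes A `genotype_matrix`.
#' @param sumstats Summary-statistic table.
#' @param thresholds Numeric vector of P cutoffs (default the score
#'   analysis triple `1e-5`, `0.05`, `0.5`).
#' @param exclude Index variant ids to drop from every scoring set.
#' @param normalization Passed to [compute_scores()].
#' @return Named list of `score_set`s, names `"p<threshold>"`.
#' @export
score_thresholds <- function(genotypes, sumstats,
                             thresholds = c(1e-5, 0.05, 0.5),
                             exclude = character(0),
                             normalization = "per_allele_mean") {
  h <- harmonize(sumstats, genotypes)
  out <- list()
  for (p in sort(thresholds)) {
    vs <- threshold_variants(h$aligned, p)
    vs <- exclude_index_variant(vs, exclude)
    s <- suppressWarnings(
      compute_scores(genotypes, h$aligned, vs, normalization))
    s$threshold <- p
    out[[paste0("p", format(p, scientific = FALSE))]] <- s
  }
  out
}
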