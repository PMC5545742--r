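#' Configuration for an end-to-end pipeline run
#'
#' Either synthetic mode (a [cohort_config()] drives generation) or real
#' mode (paths to a gene list, gene annotation TSV, summary-statistic TSV,
#' VCF, and phenotype TSV).
#'
#' @param cohort A [cohort_config()] for synthetic mode, or NULL.
#' @param gene_list_path,annotation_path,sumstats_path,vcf_path,pheno_path
#'   Input file paths for real mode (ignored in synthetic mode).
#' @param phenotype_cols Phenotype column names to analyze; default
#'   `"phenotype"`.
#' @param thresholds P-value cutoffs, ascending (default 1e-5, 0.05, 0.5 —
#'   the three score thresholds of the main analysis).
#' @param flank Window flank in bp (default 20000).
#' @param normalization Score normalization mode.
#' @param exclude Index variant ids removed from every scoring set.
#' @param n_domains Bonferroni domain count (default 5).
#' @param seed Seed for synthetic mode.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = NULL,
                       gene_list_path = NULL, annotation_path = NULL,
                       sumstats_path = NULL, vcf_path = NULL,
                       pheno_path = NULL,
                       phenotype_cols = "phenotype",
                       thresholds = c(1e-5, 0.05, 0.5),
                       flank = 20000,
                       normalization = "per_allele_mean",
                       exclude = character(0),
                       n_domains = 5,
                       seed = 1L) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must be in (0, 1]")
  if (flank < 0) stop("flank must be >= 0")
  if (is.null(cohort) &&
      (is.null(sumstats_path) || is.null(vcf_path) || is.null(pheno_path)))
    stop("either a cohort config (synthetic mode) or input paths are required")
  structure(list(cohort = cohort, gene_list_path = gene_list_path,
                 annotation_path = annotation_path,
                 sumstats_path = sumstats_path, vcf_path = vcf_path,
                 pheno_path = pheno_path, phenotype_cols = phenotype_cols,
                 thresholds = thresholds, flank = flank,
                 normalization = normalization, exclude = exclude,
                 n_domains = n_domains, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys map to [run_config()] arguments; a `cohort:` block maps
#' to [cohort_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) {
    if (!is.null(y$cohort$chrom_lengths))
      y$cohort$chrom_lengths <- unlist(y$cohort$chrom_lengths)
    y$cohort <- do.call(cohort_config, y$cohort)
  }
  do.call(run_config, y)
}

#' Run the full gene-set score pipeline
#'
#' simulate (or load) -> windows -> harmonize/threshold/score ->
#' per-platform association -> inverse-variance meta-analysis, writing
#' every table plus a machine-readable manifest with content hashes into
#' `out_dir`. Identical config and seed give identical manifest hashes.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return A list: `manifest` (data.frame file/md5), paths of the outputs,
#'   and the in-memory `scores`, `assoc` and `meta` tables.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", file = log_path,
                            append = TRUE, sep = "")
  cat("", file = log_path)

  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$cohort)) {
      stage <- "simulate"
      cohort <- simulate_cohort(config$cohort)
      genes <- cohort$genes
      variants <- cohort$variants[, c("variant_id", "chrom", "pos")]
      sumstats <- cohort$sumstats
      genotypes <- cohort$genotypes
      phenotypes <- cohort$phenotypes
      write_gene_annotation(genes, file.path(out_dir, "genes.tsv"))
      write_sumstats(sumstats, file.path(out_dir, "sumstats.tsv"))
      write_vcf(genotypes, cohort$variants,
                file.path(out_dir, "genotypes.vcf"))
      write_phenotypes(phenotypes, file.path(out_dir, "phenotypes.tsv"))
      logf("simulate: %d individuals, %d genes, %d variants",
           nrow(genotypes$dosage), nrow(genes), nrow(sumstats))
    } else {
      stage <- "load"
      annotation <- read_gene_annotation(config$annotation_path)
      gene_ids <- if (!is.null(config$gene_list_path))
        readLines(config$gene_list_path) else annotation$gene_id
      resolved <- resolve_gene_list(gene_ids, annotation)
      genes <- resolved$genes
      logf("load: %d genes resolved, %d rejected", nrow(genes),
           nrow(resolved$rejected))
      sumstats <- read_sumstats(config$sumstats_path)
      genotypes <- read_vcf_genotypes(config$vcf_path)
      phenotypes <- utils::read.delim(config$pheno_path,
                                      stringsAsFactors = FALSE)
      variants <- data.frame(variant_id = sumstats$variant_id,
                             chrom = sumstats$chrom, pos = sumstats$pos,
                             stringsAsFactors = FALSE)
    }

    stage <- "windows"
    windows <- build_windows(genes, config$flank)
    selected <- select_variants(variants, windows)
    logf("windows: %d windows (flank %g bp), %d of %d variants selected",
         nrow(windows), config$flank, length(selected), nrow(variants))

    stage <- "score"
    h <- harmonize(sumstats, genotypes)
    logf("harmonize: %d aligned, %d dropped (%s)", nrow(h$aligned),
         nrow(h$report), paste(unique(h$report$reason), collapse = ","))
    score_sets <- list()
    for (p in config$thresholds) {
      vs <- intersect(threshold_variants(h$aligned, p), selected)
      vs <- exclude_index_variant(vs, config$exclude)
      s <- suppressWarnings(
        compute_scores(genotypes, h$aligned, vs, config$normalization))
      s$threshold <- p
      score_sets[[paste0("p", format(p, scientific = FALSE))]] <- s
      logf("score: P<%g uses %d variants", p, s$n_variants_used)
    }
    scores_path <- file.path(out_dir, "scores.tsv")
    write_scores(score_sets, scores_path)

    stage <- "association"
    phenotypes <- phenotypes[match(genotypes$individual_id,
                                   phenotypes$individual_id), , drop = FALSE]
    covars <- phenotypes[, c("age", "sex"), drop = FALSE]
    platforms <- sort(unique(phenotypes$platform))
    assoc <- list()
    for (nm in names(score_sets)) {
      for (pl in platforms) {
        rows <- phenotypes$platform == pl
        for (ph in config$phenotype_cols) {
          y <- phenotypes[[ph]][rows]
          keep <- detect_outliers(y)
          # a threshold can leave no (or only zero-weight) variants, giving a
          # constant score: record an NA row rather than aborting the run
          r <- tryCatch(
            fit_association(y[keep], score_sets[[nm]]$score[rows][keep],
                            covars[rows, , drop = FALSE][keep, ,
                                                         drop = FALSE],
                            phenotype_name = ph),
            error = function(e) {
              if (!grepl("constant predictor", conditionMessage(e))) stop(e)
              logf("association: constant score at P<%g (%s), skipped",
                   score_sets[[nm]]$threshold, pl)
              data.frame(phenotype = ph, estimate = NA_real_, se = NA_real_,
                         ci_low = NA_real_, ci_high = NA_real_,
                         p_value = NA_real_, standardized_beta = NA_real_,
                         delta_r2 = NA_real_, n_used = sum(keep),
                         stringsAsFactors = FALSE)
            })
          r$threshold <- score_sets[[nm]]$threshold
          r$platform <- pl
          assoc[[length(assoc) + 1L]] <- r
        }
      }
    }
    assoc <- do.call(rbind, assoc)
    assoc_paths <- character(0)
    for (pl in platforms) {
      p_out <- file.path(out_dir, sprintf("assoc_%s.tsv", pl))
      utils::write.table(assoc[assoc$platform == pl, , drop = FALSE], p_out,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      assoc_paths <- c(assoc_paths, p_out)
    }

    stage <- "meta"
    meta <- list()
    for (p in config$thresholds) {
      sub <- assoc[assoc$threshold == p, , drop = FALSE]
      for (ph in config$phenotype_cols) {
        rows <- sub[sub$phenotype == ph & !is.na(sub$estimate), , drop = FALSE]
        if (nrow(rows) < 2L) {
          m <- data.frame(combined_B = NA_real_, combined_se = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p_value = NA_real_, q_statistic = NA_real_,
                          i_squared = NA_real_, p_het = NA_real_,
                          k = nrow(rows))
          m$p_bonferroni <- NA_real_
          meta[[length(meta) + 1L]] <- cbind(phenotype = ph, threshold = p, m)
          next
        }
        m <- meta_combine(rows$estimate, rows$se)
        m$p_bonferroni <- bonferroni(m$p_value, config$n_domains)
        meta[[length(meta) + 1L]] <- cbind(phenotype = ph, threshold = p, m)
      }
    }
    meta <- do.call(rbind, meta)
    meta_path <- file.path(out_dir, "meta.tsv")
    utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    list(scores = score_sets, assoc = assoc, meta = meta,
         paths = c(scores_path, assoc_paths, meta_path))
  }, error = function(e) {
    logf("FAILED at stage %s: %s", stage, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  stage <- "manifest"
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, c("manifest.json", "run.log")))
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  res
}
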