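#' Resolve a gene list against an annotation table
#'
#' Keeps genes that map to exactly one autosomal locus. Genes absent from
#' the annotation, annotated at more than one locus, or annotated off the
#' autosomes are rejected with a reason code, mirroring the usual loss of
#' list members when an expression-derived gene set is mapped to genomic
#' coordinates.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param annotation data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive coordinates).
#' @return A list: `genes` (resolved intervals, sorted by chrom then start)
#'   and `rejected` (gene_id, reason in "absent"/"ambiguous"/"non-autosomal").
#' @export
resolve_gene_list <- function(gene_ids, annotation) {
  if (nrow(annotation) == 0L) stop("annotation is empty")
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(annotation)))
  autosomes <- as.character(1:22)

  kept <- list(); rej_id <- character(0); rej_reason <- character(0)
  for (g in unique(gene_ids)) {
    rows <- annotation[annotation$gene_id == g, , drop = FALSE]
    if (nrow(rows) == 0L) {
      rej_id <- c(rej_id, g); rej_reason <- c(rej_reason, "absent")
    } else if (nrow(rows) > 1L) {
      rej_id <- c(rej_id, g); rej_reason <- c(rej_reason, "ambiguous")
    } else if (!rows$chrom %in% autosomes) {
      rej_id <- c(rej_id, g); rej_reason <- c(rej_reason, "non-autosomal")
    } else {
      kept[[g]] <- rows
    }
  }
  genes <- if (length(kept)) do.call(rbind, kept) else
    data.frame(gene_id = character(), chrom = character(),
               start = numeric(), end = numeric())
  genes <- genes[order(as.integer(genes$chrom), genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  list(genes = genes,
       rejected = data.frame(gene_id = rej_id, reason = rej_reason,
                             stringsAsFactors = FALSE))
}

#' Flank gene intervals into scoring windows
#'
#' Extends every gene by `flank` bp on both sides, boundary-inclusive, and
#' clips the start at 1. Windows are deliberately not merged: per-gene
#' attribution is preserved, and de-duplication happens at variant
#' selection.
#'
#' @param genes data.frame of gene intervals (`gene_id`, `chrom`, `start`,
#'   `end`; 1-based closed).
#' @param flank Flank in bp (default 20000, i.e. variants within 20 kb of a
#'   gene are in its window).
#' @return data.frame of windows with the same columns.
#' @export
build_windows <- function(genes, flank = 20000) {
  if (flank < 0) stop("flank must be >= 0")
  data.frame(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = pmax(1, genes$start - flank),
    end = genes$end + flank,
    stringsAsFactors = FALSE
  )
}

#' Select variants falling in any gene window
#'
#' A variant is selected iff `window.start <= pos <= window.end` for at
#' least one window on its chromosome (closed-interval overlap on both
#' ends); a variant covered by several overlapping windows is returned
#' once. The interval query is done with `GenomicRanges::findOverlaps`.
#'
#' @param variants data.frame with `variant_id`, `chrom`, `pos` (1-based).
#' @param windows data.frame of windows from [build_windows()].
#' @return Character vector of selected variant ids (unique, in variant
#'   table order).
#' @export
select_variants <- function(variants, windows) {
  if (nrow(variants) == 0L || nrow(windows) == 0L) return(character(0))
  v <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1)
  )
  w <- GenomicRanges::GRanges(
    seqnames = windows$chrom,
    ranges = IRanges::IRanges(start = windows$start, end = windows$end)
  )
  hits <- GenomicRanges::findOverlaps(v, w)
  idx <- sort(unique(S4Vectors::queryHits(hits)))
  variants$variant_id[idx]
}

#' Greedy LD pruning by genotype correlation
#'
#' Scans variants left to right (position-sorted input order) and, within a
#' sliding window of `window_size` already-kept variants, drops the later
#' variant of any pair whose squared genotype correlation exceeds
#' `r2_threshold`. Off by default in the pipeline: the main analysis scores
#' all in-window variants without pruning.
#'
#' @param genotypes A `genotype_matrix`.
#' @param selected Character vector of variant ids to prune (assumed
#'   position-sorted).
#' @param r2_threshold Squared-correlation cutoff in (0, 1].
#' @param window_size Number of preceding kept variants compared against.
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(genotypes, selected, r2_threshold = 0.8,
                     window_size = 50) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must be in (0, 1]")
  sel <- selected[selected %in% genotypes$variant_id]
  if (length(sel) <= 1L) return(sel)
  dos <- genotypes$dosage[, sel, drop = FALSE]
  kept <- character(0)
  for (id in sel) {
    cmp <- utils::tail(kept, window_size)
    drop <- FALSE
    for (k in cmp) {
      r <- suppressWarnings(stats::cor(dos[, id], dos[, k],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && r * r > r2_threshold) { drop <- TRUE; break }
      # at threshold 1 exact duplicate columns (r^2 == 1) are still pruned
      if (r2_threshold == 1 && !is.na(r) &&
          isTRUE(all.equal(dos[, id], dos[, k]))) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, id)
  }
  kept
}
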