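# Variant- and genotype-level QC: per-call GQ/DP masking, synonymous removal,
# and the per-(source, ancestry) frequency filter.

#' Mask low-quality genotype calls
#'
#' Sets calls failing the strict quality thresholds (GQ > `gq_min` and
#' DP > `dp_min` required, i.e. a call with GQ equal to the threshold is
#' masked) to missing, and drops variants left without any non-missing
#' alternate call.
#'
#' @param rare list with integer matrices `gt`, `gq`, `dp` (variants x
#'   samples; `gt` counts alternate alleles) and a `variants` data.frame
#' @param gq_min,dp_min strict lower bounds (default GQ > 90, DP > 10)
#' @return list: `rare` (masked, possibly with fewer variants), `report`
#'   (calls masked, variants dropped)
#' @export
mask_low_quality_genotypes <- function(rare, gq_min = 90, dp_min = 10) {
  gt <- rare$gt
  if (is.null(rare$gq) || is.null(rare$dp))
    stop("genotype data lack GQ/DP fields", call. = FALSE)
  for (field in c("gq", "dp")) {
    bad <- which(rowSums(is.na(rare[[field]])) > 0)
    if (length(bad) > 0)
      stop(sprintf("missing %s values at record %s", toupper(field),
                   rownames(gt)[bad[1]] %||% bad[1]), call. = FALSE)
  }
  fail <- rare$gq <= gq_min | rare$dp <= dp_min
  n_masked <- sum(fail & !is.na(gt))
  gt[fail] <- NA_integer_
  keep <- rowSums(gt > 0, na.rm = TRUE) >= 1
  out <- list(gt = gt[keep, , drop = FALSE],
              gq = rare$gq[keep, , drop = FALSE],
              dp = rare$dp[keep, , drop = FALSE],
              variants = rare$variants[keep, , drop = FALSE])
  list(rare = out,
       report = list(calls_masked = n_masked,
                     variants_in = nrow(rare$gt),
                     variants_dropped = sum(!keep)))
}

#' Recompute cohort-internal allele frequency from masked genotypes
#'
#' Alternate-allele frequency per variant with missing calls excluded from the
#' denominator. On the X chromosome male calls contribute a single allele
#' (hemizygous genotypes are coded homozygous, so a male count of 2 is one
#' alternate allele).
#'
#' @param rare masked rare-genotype list (see [mask_low_quality_genotypes()])
#' @param sex character vector aligned with the sample columns
#' @return numeric vector of frequencies, named by variant
#' @export
compute_cohort_af <- function(rare, sex) {
  gt <- rare$gt
  male <- is_female(sex) == FALSE
  is_x <- rare$variants$chrom == "X"
  called <- !is.na(gt)
  alt <- gt
  alt[!called] <- 0L
  ploidy <- matrix(2L, nrow(gt), ncol(gt))
  if (any(is_x)) {
    ploidy[is_x, male] <- 1L
    alt[is_x, male] <- pmin(alt[is_x, male], 1L)
  }
  af <- rowSums(alt) / rowSums(ploidy * called)
  names(af) <- rownames(gt)
  af
}

#' Remove synonymous variants
#'
#' @param annotations annotation data.frame with a `consequence` column
#' @export
drop_synonymous <- function(annotations) {
  annotations[annotations$consequence != "synonymous_variant", , drop = FALSE]
}

#' Per-ancestry frequency filter
#'
#' A variant survives only if its allele frequency is at or below the gene
#' set's ceiling in every (source, ancestry) cell where a frequency is
#' recorded; missing cells do not fail the filter. Frequency columns are all
#' columns starting with `af_`.
#'
#' @param annotations annotation data.frame with `gene` and `af_*` columns
#' @param maf_thresholds named ceilings per gene set (default 1e-5 ADPKD,
#'   1e-3 COL4A)
#' @return the surviving rows
#' @export
apply_frequency_filter <- function(annotations,
                                   maf_thresholds = default_maf_thresholds()) {
  genes <- gene_panel()
  gs <- genes$gene_set[match(annotations$gene, genes$gene)]
  if (any(is.na(gs)))
    stop("unknown gene: ",
         paste(unique(annotations$gene[is.na(gs)]), collapse = ", "),
         call. = FALSE)
  thr <- maf_thresholds[gs]
  af_cols <- grep("^af_", names(annotations), value = TRUE)
  if (length(af_cols) == 0) return(annotations)
  af <- as.matrix(annotations[, af_cols, drop = FALSE])
  exceeds <- rowSums(af > thr, na.rm = TRUE) > 0
  annotations[!exceeds, , drop = FALSE]
}

#' Run the full variant QC chain with a filter report
#'
#' Order: genotype-level GQ/DP masking (variants losing every alternate call
#' are dropped), then synonymous removal, then the frequency filter (with the
#' cohort-internal frequency recomputed from masked genotypes and added as
#' source `af_internal` when `sex` is supplied). Each variant is attributed to
#' the first filter that removes it, so the report counts partition the input.
#'
#' @inheritParams mask_low_quality_genotypes
#' @param annotations annotation table covering (at least) the VCF variants
#' @param maf_thresholds per-gene-set frequency ceilings
#' @param sex sample sexes (enables cohort-AF recomputation)
#' @return list: `rare` (masked genotypes restricted to survivors),
#'   `annotations` (surviving rows, with `af_internal`), `report`
#' @export
filter_variants <- function(rare, annotations,
                            maf_thresholds = default_maf_thresholds(),
                            gq_min = 90, dp_min = 10, sex = NULL) {
  n_input <- nrow(annotations)
  masked <- mask_low_quality_genotypes(rare, gq_min, dp_min)
  rare <- masked$rare
  ann <- annotations[annotations$variant_id %in% rare$variants$variant_id, ,
                     drop = FALSE]
  n_after_mask <- nrow(ann)
  if (!is.null(sex)) {
    af <- compute_cohort_af(rare, sex)
    ann$af_internal <- unname(af[ann$variant_id])
  }
  ann2 <- drop_synonymous(ann)
  n_syn <- nrow(ann) - nrow(ann2)
  ann3 <- apply_frequency_filter(ann2, maf_thresholds)
  n_maf <- nrow(ann2) - nrow(ann3)
  keep <- rare$variants$variant_id %in% ann3$variant_id
  rare <- list(gt = rare$gt[keep, , drop = FALSE],
               gq = rare$gq[keep, , drop = FALSE],
               dp = rare$dp[keep, , drop = FALSE],
               variants = rare$variants[keep, , drop = FALSE])
  report <- list(input = n_input,
                 removed_masking = n_input - n_after_mask,
                 removed_synonymous = n_syn,
                 removed_maf = n_maf,
                 surviving = nrow(ann3),
                 calls_masked = masked$report$calls_masked)
  stopifnot(report$input == report$removed_masking + report$removed_synonymous +
              report$removed_maf + report$surviving)
  list(rare = rare, annotations = ann3, report = report)
}
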