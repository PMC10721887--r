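# Qualifying-variant classification under the tiered evidence models M1-M3,
# and per-participant dominant / recessive genotype calling.

#' Is a variant predicted loss-of-function?
#'
#' TRUE for stop-gain, frameshift, stop-lost, start-lost, and essential
#' splice (acceptor/donor) consequences. Non-essential `splice_region_variant`
#' calls do not qualify.
#'
#' @param consequence character vector of consequence terms
#' @export
is_plof <- function(consequence) consequence %in% plof_consequence_set()

#' Is a missense variant predicted deleterious?
#'
#' Requires REVEL strictly above 0.70 and a damaging verdict from all five
#' predictors (SIFT, PolyPhen2-HDIV, PolyPhen2-HVAR, LRT, MutationTaster).
#' Missing REVEL scores or predictor verdicts fail the test (conservative:
#' keeps the predicted-deleterious set specific).
#'
#' @param annotations annotation data.frame
#' @param revel_threshold strict lower bound on REVEL (default 0.70)
#' @export
is_deleterious_missense <- function(annotations, revel_threshold = 0.70) {
  pred_cols <- c("sift", "polyphen2_hdiv", "polyphen2_hvar", "lrt",
                 "mutation_taster")
  miss <- annotations$consequence == "missense_variant"
  revel_ok <- !is.na(annotations$revel) & annotations$revel > revel_threshold
  dmg <- rep(TRUE, nrow(annotations))
  for (p in pred_cols) {
    v <- annotations[[p]]
    dmg <- dmg & !is.na(v) & v == "damaging"
  }
  miss & revel_ok & dmg
}

assertion_vocab <- function() c("P", "LP", "B", "LB", "VUS", "none")

check_assertions <- function(annotations) {
  for (col in c("clinvar_assertion", "varsome_assertion")) {
    bad <- setdiff(unique(annotations[[col]]), assertion_vocab())
    if (length(bad) > 0)
      stop("unknown ", col, " value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify variants into a qualifying-variant set
#'
#' Evidence models:
#' \itemize{
#'   \item M1: pLOF, plus ClinVar "P" asserted by at least two independent
#'     submitters without a pathogenicity conflict.
#'   \item M2: pLOF, plus ClinVar "P" or "LP" under the same submitter and
#'     conflict rules (a strict superset of M1).
#'   \item M3: pLOF, plus predicted-deleterious missense (REVEL > 0.70 and
#'     5/5 damaging predictors). M3 does not necessarily contain M1: a "P"
#'     variant failing the missense criteria is in M1 but not M3.
#' }
#' A variant labeled B or LB by ClinVar or Varsome is vetoed from every
#' model. Varsome enters only through this veto; its P/LP assertions never
#' qualify a variant. Input variants are assumed to have passed
#' [filter_variants()].
#'
#' @param annotations filtered annotation data.frame
#' @param model "M1", "M2", or "M3"
#' @param revel_threshold strict REVEL bound for the M3 missense rule
#' @return the annotation rows forming the QV set, with a `qv_reason` column
#' @export
classify_variants <- function(annotations, model = c("M1", "M2", "M3"),
                              revel_threshold = 0.70) {
  model <- match.arg(model)
  check_assertions(annotations)
  benign <- annotations$clinvar_assertion %in% c("B", "LB") |
    annotations$varsome_assertion %in% c("B", "LB")
  plof <- is_plof(annotations$consequence)
  multi_clean <- annotations$clinvar_n_submitters >= 2 &
    !annotations$clinvar_conflict_flag
  clin <- switch(model,
    M1 = annotations$clinvar_assertion == "P" & multi_clean,
    M2 = annotations$clinvar_assertion %in% c("P", "LP") & multi_clean,
    M3 = is_deleterious_missense(annotations, revel_threshold))
  qual <- (plof | clin) & !benign
  out <- annotations[qual, , drop = FALSE]
  reason_plof <- plof[qual]
  out$qv_reason <- ifelse(reason_plof, "pLOF",
                          switch(model, M1 = "ClinVar_P", M2 = "ClinVar_P_LP",
                                 M3 = "deleterious_missense"))
  out
}

#' Call per-participant carrier status for a QV set
#'
#' Dominant carrier: at least one qualifying alternate allele. Recessive
#' genotype: a homozygous qualifying genotype, two or more distinct
#' heterozygous qualifying variants in the same autosomal gene (compound
#' heterozygote called from unphased data, so in-cis pairs are possible false
#' positives), or a male with a qualifying allele on the X chromosome
#' (hemizygous). A heterozygous X call in a male is a data inconsistency:
#' it raises a warning, is flagged, and is treated as carrying.
#'
#' @param qv_set QV annotation rows (from [classify_variants()])
#' @param rare masked rare-genotype list
#' @param sex character vector aligned with the genotype sample columns
#' @param model model tag recorded in the output
#' @return data.frame, one row per participant: `dominant_carrier`,
#'   `recessive_genotype`, `zygosity` (het/hom/comp_het/hemi), supporting
#'   variant ids, `x_het_male` flag
#' @export
call_carriers <- function(qv_set, rare, sex, model = "M1") {
  rows <- which(rare$variants$variant_id %in% qv_set$variant_id)
  gt <- rare$gt[rows, , drop = FALSE]
  vinfo <- rare$variants[rows, , drop = FALSE]
  male <- !is_female(sex)
  n <- ncol(gt)
  gt0 <- gt; gt0[is.na(gt0)] <- 0L
  is_x <- vinfo$chrom == "X"

  x_het <- male & colSums(gt0[is_x, , drop = FALSE] == 1L) > 0
  if (any(x_het))
    warning(sum(x_het), " male participant(s) with heterozygous X calls; ",
            "treated as carriers and flagged", call. = FALSE)

  dominant <- colSums(gt0 >= 1L) >= 1L
  hom <- colSums(gt0 == 2L & !is_x) >= 1L
  hemi <- male & colSums(gt0[is_x, , drop = FALSE] >= 1L) >= 1L
  comp_het <- rep(FALSE, n)
  for (g in unique(vinfo$gene[!is_x])) {
    grows <- which(vinfo$gene == g & !is_x)
    if (length(grows) >= 2)
      comp_het <- comp_het |
        colSums(gt0[grows, , drop = FALSE] == 1L) >= 2L
  }
  recessive <- hom | hemi | comp_het
  zyg <- rep(NA_character_, n)
  zyg[dominant] <- "het"
  zyg[comp_het] <- "comp_het"
  zyg[hom] <- "hom"
  zyg[hemi] <- "hemi"
  support <- rep("", n)
  carriers <- which(dominant)
  for (p in carriers) {
    support[p] <- paste(vinfo$variant_id[gt0[, p] >= 1L], collapse = ";")
  }
  data.frame(participant_id = colnames(gt) %||% seq_len(n),
             model = model,
             dominant_carrier = dominant,
             recessive_genotype = recessive,
             zygosity = zyg,
             supporting_variants = support,
             x_het_male = x_het,
             stringsAsFactors = FALSE)
}

#' Penetrance of a qualifying genotype
#'
#' The probability of disease conditioned on carrier status: cases divided by
#' cases plus controls among carriers, with a Wilson 95 percent binomial
#' confidence interval. Undefined (NA, with a message) when there are no
#' carriers with case/control labels.
#'
#' @param carrier logical carrier indicator
#' @param label case/control/excluded labels aligned with `carrier`
#' @export
penetrance <- function(carrier, label) {
  use <- carrier & label %in% c("case", "control")
  n <- sum(use)
  if (n == 0) {
    message("penetrance undefined: no labeled carriers")
    return(data.frame(carriers = 0L, cases = 0L, penetrance = NA_real_,
                      lower = NA_real_, upper = NA_real_))
  }
  x <- sum(label[use] == "case")
  ci <- wilson_ci(x, n)
  data.frame(carriers = n, cases = x, penetrance = x / n,
             lower = ci[["lower"]], upper = ci[["upper"]])
}
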