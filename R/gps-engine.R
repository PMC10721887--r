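# Polygenic score computation, P+T model building, and the ancestry/APOL1
# calibration chain producing the standardized score and its tertiles.

#' Raw polygenic score (sum semantics)
#'
#' \eqn{raw_i = \sum_m w_m \, d_{im}} over the weights-table variants present
#' in the dosage matrix. Dosages are assumed oriented to the effect allele.
#' Missing dosages contribute 0 under the default sum semantics; an optional
#' mean-imputation mode substitutes the variant's mean dosage.
#'
#' @param dosages samples x variants matrix
#' @param weights data.frame: variant_id, effect_allele, weight
#' @param missing "zero" (default) or "mean"
#' @return numeric score per sample; attribute `n_unmatched` counts weights
#'   variants absent from the dosages
#' @export
gps_score <- function(dosages, weights, missing = c("zero", "mean")) {
  missing <- match.arg(missing)
  if (anyDuplicated(weights$variant_id))
    stop("duplicate variant ids in weights table", call. = FALSE)
  if (any(!is.finite(weights$weight)))
    stop("non-finite weights", call. = FALSE)
  hit <- weights$variant_id %in% colnames(dosages)
  n_unmatched <- sum(!hit)
  if (n_unmatched > 0.5 * nrow(weights))
    stop("more than half of the weights variants are unmatched (",
         n_unmatched, " of ", nrow(weights), ")", call. = FALSE)
  w <- weights[hit, , drop = FALSE]
  d <- dosages[, w$variant_id, drop = FALSE]
  if (anyNA(d)) {
    if (missing == "zero") d[is.na(d)] <- 0
    else {
      mu <- colMeans(d, na.rm = TRUE)
      for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
    }
  }
  out <- as.numeric(d %*% w$weight)
  names(out) <- rownames(dosages)
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Build a pruning-and-thresholding (P+T) weights table
#'
#' Greedy selection by ascending p-value: a variant enters only if its
#' squared correlation with every already-selected variant within `window`
#' positions is at most `r2_max` and its p-value is at most `p_max`. Weights
#' are the discovery betas, unchanged — the selection step never re-estimates
#' them.
#'
#' @param sumstats data.frame: variant_id, beta, p (effect_allele optional)
#' @param dosages genotype matrix for LD (samples x variants)
#' @param r2_max,p_max selection thresholds (defaults 0.2 and 0.03)
#' @param window positional window (in variants, by dosage column order)
#'   within which r^2 is enforced
#' @return weights data.frame: variant_id, effect_allele, weight, p
#' @export
pt_clump <- function(sumstats, dosages, r2_max = 0.2, p_max = 0.03,
                     window = 500L) {
  ss <- sumstats[sumstats$p <= p_max & sumstats$variant_id %in%
                   colnames(dosages), , drop = FALSE]
  ss <- ss[order(ss$p, ss$variant_id), , drop = FALSE]
  pos <- match(ss$variant_id, colnames(dosages))
  sel <- integer(0)
  for (k in seq_len(nrow(ss))) {
    near <- sel[abs(pos[sel] - pos[k]) <= window]
    ok <- TRUE
    for (j in near) {
      r <- suppressWarnings(stats::cor(dosages[, pos[k]], dosages[, pos[j]]))
      if (!is.na(r) && r^2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) sel <- c(sel, k)
  }
  out <- data.frame(variant_id = ss$variant_id[sel],
                    effect_allele = ss$effect_allele[sel] %||%
                      rep("A", length(sel)),
                    weight = ss$beta[sel], p = ss$p[sel],
                    stringsAsFactors = FALSE)
  out[order(match(out$variant_id, colnames(dosages))), , drop = FALSE]
}

#' Ancestry calibration of the raw score (mean and variance)
#'
#' Fit on the reference panel only: (i) a linear model of the raw score on
#' the PCs gives the ancestry-predicted mean, which is subtracted; (ii) a
#' linear model of the log squared residual on the PCs gives the
#' ancestry-predicted variance, whose square root divides the centered score.
#' Cohort samples are transformed with the reference fits. With
#' `variance = FALSE` only the mean is adjusted and the reference residual
#' standard deviation is used globally.
#'
#' @param raw cohort raw scores
#' @param cohort_pcs cohort samples x PCs
#' @param ref_raw reference raw scores (same weights)
#' @param ref_pcs reference samples x PCs
#' @param n_pcs PCs used (default all supplied)
#' @param variance adjust variance as well as mean (default TRUE)
#' @return list: `cohort` (adjusted cohort scores), `reference` (adjusted
#'   reference scores), fitted models
#' @export
ancestry_adjust <- function(raw, cohort_pcs, ref_raw, ref_pcs,
                            n_pcs = ncol(ref_pcs), variance = TRUE) {
  n_pcs <- min(n_pcs, ncol(ref_pcs))
  if (length(ref_raw) < 10 * n_pcs)
    stop("reference too small: need at least 10 samples per PC", call. = FALSE)
  rp <- as.data.frame(ref_pcs[, seq_len(n_pcs), drop = FALSE])
  names(rp) <- paste0("PC", seq_len(n_pcs))
  cp <- as.data.frame(cohort_pcs[, seq_len(n_pcs), drop = FALSE])
  names(cp) <- names(rp)
  fit_mu <- stats::lm(y ~ ., data = cbind(y = ref_raw, rp))
  res_ref <- ref_raw - stats::predict(fit_mu, rp)
  res_coh <- raw - stats::predict(fit_mu, cp)
  if (variance) {
    fit_v <- stats::lm(y ~ ., data = cbind(y = log(res_ref^2 + 1e-12), rp))
    # smearing factor corrects the log-scale bias so reference sd ~ 1
    smear <- mean(res_ref^2 / exp(stats::predict(fit_v, rp)))
    sd_ref <- sqrt(exp(stats::predict(fit_v, rp)) * smear)
    sd_coh <- sqrt(exp(stats::predict(fit_v, cp)) * smear)
  } else {
    fit_v <- NULL
    s <- stats::sd(res_ref)
    sd_ref <- rep(s, length(ref_raw))
    sd_coh <- rep(s, length(raw))
  }
  list(cohort = res_coh / sd_coh, reference = res_ref / sd_ref,
       mean_model = fit_mu, variance_model = fit_v)
}

#' APOL1 adjustment and final standardization
#'
#' Residualizes the recessive APOL1 risk-genotype indicator out of the
#' ancestry-adjusted score (the association is removed, not re-weighted),
#' then standardizes to mean 0, sd 1 in the fitting frame and assigns
#' cohort-wide tertiles. Missing APOL1 data are treated as non-risk with a
#' logged count.
#'
#' @param adjusted ancestry-adjusted scores
#' @param apol1_risk logical risk-genotype indicator (NA allowed)
#' @return data.frame: score_adjusted, score_standardized, tertile
#' @export
apol1_adjust_standardize <- function(adjusted, apol1_risk) {
  risk <- apol1_risk
  n_missing <- sum(is.na(risk))
  if (n_missing > 0) {
    message(n_missing, " participants missing APOL1 data; indicator set to 0")
    risk[is.na(risk)] <- FALSE
  }
  fit <- stats::lm(adjusted ~ risk)
  res <- stats::residuals(fit)
  std <- (res - mean(res)) / stats::sd(res)
  data.frame(score_adjusted = adjusted,
             score_standardized = std,
             tertile = assign_tertiles(std))
}

#' Cohort-wide score tertiles
#'
#' Cut points at the empirical 33.3 and 66.7 percentiles of the whole
#' distribution (carriers and noncarriers share the same cuts, so strata are
#' comparable on one scale). Ties at a cut point go to the lower tertile.
#'
#' @param scores standardized scores (length >= 3, non-degenerate)
#' @return integer tertile labels 1-3
#' @export
assign_tertiles <- function(scores) {
  if (length(scores) < 3) stop("need at least 3 scores", call. = FALSE)
  cuts <- stats::quantile(scores, c(1, 2) / 3, names = FALSE)
  if (diff(range(scores)) == 0 || cuts[1] == cuts[2])
    stop("degenerate score distribution: tertiles undefined", call. = FALSE)
  as.integer(cut(scores, c(-Inf, cuts, Inf), labels = FALSE))
}
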