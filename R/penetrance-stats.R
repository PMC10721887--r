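# Association models: carrier and per-SD GPS effects, tertile-stratified odds
# ratios against the noncarrier middle tertile, GPS-by-carrier interaction,
# fixed-effects meta-analysis, and discrimination/variance-explained metrics.

#' Firth-penalized logistic regression
#'
#' Maximum penalized likelihood with Jeffreys-prior correction: the score is
#' augmented by \eqn{h_i (1/2 - p_i)} with \eqn{h_i} the hat diagonal, which
#' keeps estimates finite under separation and sparse cells. Standard errors
#' come from the Fisher information at the penalized optimum.
#'
#' @param X design matrix (including intercept)
#' @param y 0/1 outcome
#' @param max_iter,tol IRLS controls
#' @return list: coefficients, se, converged
#' @export
firth_logistic <- function(X, y, max_iter = 200, tol = 1e-8) {
  X <- as.matrix(X)
  beta <- numeric(ncol(X))
  info <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    XW <- X * w
    info <- crossprod(X, XW)
    inv <- solve(info)
    h <- rowSums((X %*% inv) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    delta <- drop(inv %*% U)
    # step-halving guards the early iterations
    while (max(abs(delta)) > 5) delta <- delta / 2
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  se <- sqrt(diag(solve(info)))
  list(coefficients = stats::setNames(beta, colnames(X)),
       se = stats::setNames(se, colnames(X)), converged = converged)
}

# Maximum-likelihood logistic fit with separation detection and Firth
# fallback. Returns one row per coefficient: term, estimate, se, z, p.
fit_logistic <- function(formula, data, firth = c("auto", "never", "always")) {
  firth <- match.arg(firth)
  method <- "ML"
  fit <- suppressWarnings(stats::glm(formula, data = data,
                                     family = stats::binomial()))
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))$coefficients
  separated <- !fit$converged ||
    any(abs(cf) > 15, na.rm = TRUE) ||
    any(sm[, "Std. Error"] > 20, na.rm = TRUE)
  if (firth == "always" || (firth == "auto" && separated)) {
    if (firth == "auto")
      warning("separation or unstable fit detected; using Firth penalization",
              call. = FALSE)
    mf <- stats::model.frame(formula, data)
    y <- as.numeric(stats::model.response(mf))
    X <- stats::model.matrix(formula, mf)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    ff <- firth_logistic(X, y)
    method <- "Firth"
    out <- data.frame(term = names(ff$coefficients),
                      estimate = ff$coefficients, se = ff$se,
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    ok <- !is.na(cf)
    out <- data.frame(term = names(cf)[ok], estimate = cf[ok],
                      se = sm[names(cf)[ok], "Std. Error"],
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  out$z <- out$estimate / out$se
  out$p <- 2 * stats::pnorm(-abs(out$z))
  attr(out, "method") <- method
  attr(out, "fit") <- if (method == "ML") fit else NULL
  out
}

covariate_formula <- function(base, covariates, data) {
  present <- covariates[covariates %in% names(data)]
  # constant covariates (e.g. a single batch) carry no information
  present <- present[vapply(present, function(v)
    length(unique(data[[v]])) > 1, logical(1))]
  stats::as.formula(paste(base, if (length(present) > 0)
    paste("+", paste(present, collapse = " + ")) else ""))
}

default_covariates <- function(n_pcs = 4, diabetes = TRUE) {
  c("age", "sex", if (diabetes) "diabetes", "batch",
    if (n_pcs > 0) paste0("PC", seq_len(n_pcs)))
}

effect_row <- function(tab, term, stratum, cohort, n_cases, n_controls) {
  r <- tab[tab$term == term, , drop = FALSE]
  if (nrow(r) == 0) {
    return(data.frame(stratum = stratum, cohort = cohort, logOR = NA_real_,
                      se = NA_real_, or = NA_real_, ci_lower = NA_real_,
                      ci_upper = NA_real_, p = NA_real_, n_cases = n_cases,
                      n_controls = n_controls, method = attr(tab, "method"),
                      stringsAsFactors = FALSE))
  }
  data.frame(stratum = stratum, cohort = cohort, logOR = r$estimate,
             se = r$se, or = exp(r$estimate),
             ci_lower = exp(r$estimate - 1.96 * r$se),
             ci_upper = exp(r$estimate + 1.96 * r$se), p = r$p,
             n_cases = n_cases, n_controls = n_controls,
             method = attr(tab, "method"), stringsAsFactors = FALSE)
}

#' Carrier vs noncarrier CKD association
#'
#' Logistic regression of case status on carrier status with adjustment for
#' age, sex, diabetes, batch, and ancestry PCs. Separation or unstable fits
#' (tiny carrier strata) fall back to Firth penalization with a warning.
#'
#' @param data model data.frame with `case` (0/1), `carrier` (logical), and
#'   the covariate columns
#' @param covariates covariate names to adjust for (those absent are skipped)
#' @param cohort label recorded in the output
#' @return one-row `StratifiedEffect`-style data.frame
#' @export
fit_carrier_model <- function(data, covariates = default_covariates(),
                              cohort = "cohort") {
  f <- covariate_formula("case ~ carrier", covariates, data)
  tab <- fit_logistic(f, data)
  effect_row(tab, "carrierTRUE", "carrier_vs_noncarrier", cohort,
             sum(data$case == 1 & data$carrier),
             sum(data$case == 0 & data$carrier))
}

#' Per-SD GPS effect, separately in carriers and noncarriers
#'
#' The score is scaled by the control-group standard deviation (effect per
#' SD of the GPS distribution in controls), then a logistic model is fit in
#' each carrier stratum with an identical covariate set. Strata with fewer
#' than 10 cases are flagged low-power.
#'
#' @param data model data.frame with `case`, `carrier`, `score`, covariates
#' @inheritParams fit_carrier_model
#' @export
fit_gps_model_by_stratum <- function(data,
                                     covariates = default_covariates(),
                                     cohort = "cohort") {
  sd_ctrl <- stats::sd(data$score[data$case == 0])
  data$score_sd <- data$score / sd_ctrl
  out <- list()
  for (str in c("noncarrier", "carrier")) {
    sub <- data[data$carrier == (str == "carrier"), , drop = FALSE]
    f <- covariate_formula("case ~ score_sd", covariates, sub)
    tab <- fit_logistic(f, sub)
    row <- effect_row(tab, "score_sd", paste0("per_sd_", str), cohort,
                      sum(sub$case == 1), sum(sub$case == 0))
    row$low_power <- row$n_cases < 10
    out[[str]] <- row
  }
  do.call(rbind, out)
}

#' Tertile-stratified odds ratios against the noncarrier middle tertile
#'
#' One logistic fit with a six-level stratum factor (noncarrier T1/T2/T3,
#' carrier T1/T2/T3), reference = noncarrier T2, adjusted for the supplied
#' covariates (by default age, sex, batch, and ancestry PCs — no diabetes,
#' matching the stratified-penetrance analysis). An empty carrier tertile is
#' reported as an NA row, never silently dropped.
#'
#' @param data model data.frame with `case`, `carrier`, `tertile`, covariates
#' @inheritParams fit_carrier_model
#' @return data.frame with one row per stratum (reference OR = 1)
#' @export
tertile_or <- function(data,
                       covariates = default_covariates(diabetes = FALSE),
                       cohort = "cohort") {
  levs <- c("noncarrier_T2", "noncarrier_T1", "noncarrier_T3",
            paste0("carrier_T", 1:3))
  data$stratum <- factor(paste0(ifelse(data$carrier, "carrier", "noncarrier"),
                                "_T", data$tertile), levels = levs)
  if (sum(data$stratum == "noncarrier_T2", na.rm = TRUE) == 0)
    stop("reference stratum (noncarrier middle tertile) is empty",
         call. = FALSE)
  present <- levs[levs %in% unique(as.character(data$stratum))]
  data$stratum <- factor(as.character(data$stratum), levels = present)
  f <- covariate_formula("case ~ stratum", covariates, data)
  firth_mode <- if (any(table(data$stratum, data$case) < 5)) "always" else "auto"
  tab <- suppressWarnings(fit_logistic(f, data, firth = firth_mode))
  rows <- lapply(levs, function(lv) {
    ncase <- sum(data$case == 1 & data$stratum == lv, na.rm = TRUE)
    nctrl <- sum(data$case == 0 & data$stratum == lv, na.rm = TRUE)
    if (lv == "noncarrier_T2") {
      return(data.frame(stratum = lv, cohort = cohort, logOR = 0, se = 0,
                        or = 1, ci_lower = 1, ci_upper = 1, p = NA_real_,
                        n_cases = ncase, n_controls = nctrl,
                        method = attr(tab, "method"), stringsAsFactors = FALSE))
    }
    effect_row(tab, paste0("stratum", lv), lv, cohort, ncase, nctrl)
  })
  do.call(rbind, rows)
}

#' GPS-by-carrier interaction test
#'
#' Adds the carrier-by-score product to the main-effects model and reports
#' the Wald test of the product coefficient.
#'
#' @inheritParams fit_gps_model_by_stratum
#' @return one-row data.frame: estimate, se, p for the product term
#' @export
interaction_test <- function(data, covariates = default_covariates(),
                             cohort = "cohort") {
  sd_ctrl <- stats::sd(data$score[data$case == 0])
  data$score_sd <- data$score / sd_ctrl
  f <- covariate_formula("case ~ carrier * score_sd", covariates, data)
  tab <- fit_logistic(f, data)
  r <- tab[tab$term == "carrierTRUE:score_sd", , drop = FALSE]
  data.frame(cohort = cohort, estimate = r$estimate, se = r$se, p = r$p,
             method = attr(tab, "method"), stringsAsFactors = FALSE)
}

#' Fixed-effects (inverse-variance) meta-analysis
#'
#' Pools log odds ratios across cohorts with weights \eqn{w_k = 1/SE_k^2}:
#' pooled \eqn{\hat\beta = \sum w_k \beta_k / \sum w_k},
#' \eqn{SE = (\sum w_k)^{-1/2}}. Estimates with non-finite SE are dropped
#' with a warning. Cochran's Q is reported as a heterogeneity note.
#'
#' @param beta per-cohort log odds ratios
#' @param se per-cohort standard errors
#' @param cohorts optional labels
#' @return one-row data.frame: logOR, se, or, ci, p, k, Q, Q_p
#' @export
meta_fixed <- function(beta, se, cohorts = NULL) {
  ok <- is.finite(beta) & is.finite(se) & se > 0
  if (any(!ok)) warning(sum(!ok), " estimate(s) with non-finite SE dropped",
                        call. = FALSE)
  beta <- beta[ok]; se <- se[ok]
  if (length(beta) == 0)
    stop("no usable estimates to pool", call. = FALSE)
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  q <- sum(w * (beta - b)^2)
  data.frame(logOR = b, se = s, or = exp(b),
             ci_lower = exp(b - 1.96 * s), ci_upper = exp(b + 1.96 * s),
             p = 2 * stats::pnorm(-abs(b / s)),
             k = length(beta), Q = q,
             Q_p = if (length(beta) > 1)
               stats::pchisq(q, length(beta) - 1, lower.tail = FALSE)
             else NA_real_,
             stringsAsFactors = FALSE)
}

nagelkerke_r2 <- function(fit) {
  n <- length(fit$y)
  r2_cs <- 1 - exp((fit$deviance - fit$null.deviance) / n)
  r2_cs / (1 - exp(-fit$null.deviance / n))
}

#' GPS discrimination and incremental variance explained
#'
#' AUROC for the full model (GPS plus covariates, via fitted probabilities)
#' and for the GPS alone (crude), with DeLong confidence intervals, plus the
#' incremental Nagelkerke pseudo-R^2: full model minus covariates-only model.
#'
#' @inheritParams fit_gps_model_by_stratum
#' @return one-row data.frame: auc_full (with CI), auc_crude (with CI),
#'   incremental_r2
#' @export
performance_metrics <- function(data, covariates = default_covariates(),
                                cohort = "cohort") {
  if (length(unique(data$case)) < 2)
    stop("need both cases and controls", call. = FALSE)
  f_full <- covariate_formula("case ~ score", covariates, data)
  f_cov <- covariate_formula("case ~ 1", covariates, data)
  fit_full <- stats::glm(f_full, data = data, family = stats::binomial())
  fit_cov <- stats::glm(f_cov, data = data, family = stats::binomial())
  roc_full <- pROC::roc(data$case, stats::fitted(fit_full), quiet = TRUE,
                        direction = "<", levels = c(0, 1))
  roc_crude <- pROC::roc(data$case, data$score, quiet = TRUE,
                         direction = "<", levels = c(0, 1))
  ci_f <- as.numeric(pROC::ci.auc(roc_full))
  ci_c <- as.numeric(pROC::ci.auc(roc_crude))
  data.frame(cohort = cohort,
             auc_full = ci_f[2], auc_full_lower = ci_f[1],
             auc_full_upper = ci_f[3],
             auc_crude = ci_c[2], auc_crude_lower = ci_c[1],
             auc_crude_upper = ci_c[3],
             incremental_r2 = nagelkerke_r2(fit_full) - nagelkerke_r2(fit_cov),
             stringsAsFactors = FALSE)
}
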