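#' Estimated GFR by the 2009 CKD-EPI creatinine equation
#'
#' Computes eGFR in ml/min/1.73 m^2 from serum creatinine using the 2009
#' CKD-EPI equation:
#' \deqn{141 \cdot \min(Scr/\kappa, 1)^{\alpha} \cdot \max(Scr/\kappa, 1)^{-1.209}
#'   \cdot 0.993^{Age} \cdot 1.018[\mathrm{female}] \cdot 1.159[\mathrm{Black}]}
#' with \eqn{\kappa} = 0.7 (female) / 0.9 (male) and \eqn{\alpha} = -0.329
#' (female) / -0.411 (male). The race coefficient is driven by an explicit
#' indicator argument and is never inferred from other data.
#'
#' @param creatinine_mg_dl serum creatinine, mg/dL (> 0)
#' @param age_years age in years (> 0)
#' @param sex character vector, "female"/"male" (or "F"/"M")
#' @param black_indicator logical; applies the 1.159 coefficient when TRUE
#' @return numeric vector of eGFR values (ml/min/1.73 m^2)
#' @seealso [egfr_ckdepi_2021()] for the race-free 2021 refit
#' @export
egfr_ckdepi_2009 <- function(creatinine_mg_dl, age_years, sex,
                             black_indicator = FALSE) {
  check_egfr_inputs(creatinine_mg_dl, age_years)
  fem <- is_female(sex)
  kappa <- ifelse(fem, 0.7, 0.9)
  alpha <- ifelse(fem, -0.329, -0.411)
  r <- creatinine_mg_dl / kappa
  141 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.209) * 0.993^age_years *
    ifelse(fem, 1.018, 1) * ifelse(rep_len(black_indicator, length(r)), 1.159, 1)
}

#' Estimated GFR by the 2021 race-free CKD-EPI creatinine equation
#'
#' \deqn{142 \cdot \min(Scr/\kappa, 1)^{\alpha} \cdot \max(Scr/\kappa, 1)^{-1.200}
#'   \cdot 0.9938^{Age} \cdot 1.012[\mathrm{female}]}
#' with \eqn{\kappa} = 0.7/0.9 and \eqn{\alpha} = -0.241/-0.302 (female/male).
#'
#' @inheritParams egfr_ckdepi_2009
#' @export
egfr_ckdepi_2021 <- function(creatinine_mg_dl, age_years, sex) {
  check_egfr_inputs(creatinine_mg_dl, age_years)
  fem <- is_female(sex)
  kappa <- ifelse(fem, 0.7, 0.9)
  alpha <- ifelse(fem, -0.241, -0.302)
  r <- creatinine_mg_dl / kappa
  142 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.200) * 0.9938^age_years *
    ifelse(fem, 1.012, 1)
}

check_egfr_inputs <- function(scr, age) {
  bad_scr <- !is.na(scr) & scr <= 0
  bad_age <- !is.na(age) & age <= 0
  if (any(bad_scr)) stop("creatinine must be positive", call. = FALSE)
  if (any(bad_age)) stop("age must be positive", call. = FALSE)
  invisible(TRUE)
}

is_female <- function(sex) {
  s <- tolower(as.character(sex))
  out <- s %in% c("female", "f", "2")
  male <- s %in% c("male", "m", "1")
  if (any(!out & !male)) stop("sex must code female/male", call. = FALSE)
  out
}

#' Invert the 2009 CKD-EPI equation for a target eGFR
#'
#' Returns the serum creatinine (mg/dL) that yields exactly the requested eGFR
#' under [egfr_ckdepi_2009()] for the given covariates. The equation is
#' continuous and strictly decreasing in creatinine, so the inverse is unique;
#' the branch (above/below kappa) is chosen by comparing the target with the
#' eGFR at the knot. Used by the cohort simulator so that downstream
#' case/control decisions are deterministic given the sampled target eGFR.
#'
#' @param egfr target eGFR (ml/min/1.73 m^2)
#' @inheritParams egfr_ckdepi_2009
#' @export
creatinine_for_egfr_2009 <- function(egfr, age_years, sex,
                                     black_indicator = FALSE) {
  fem <- is_female(sex)
  kappa <- ifelse(fem, 0.7, 0.9)
  alpha <- ifelse(fem, -0.329, -0.411)
  base <- 141 * 0.993^age_years * ifelse(fem, 1.018, 1) *
    ifelse(rep_len(black_indicator, length(egfr)), 1.159, 1)
  c_ratio <- egfr / base   # = min(r,1)^alpha * max(r,1)^-1.209
  # target below the knot value (ratio < 1) => Scr > kappa
  ifelse(c_ratio < 1,
         kappa * c_ratio^(-1 / 1.209),
         kappa * c_ratio^(1 / alpha))
}

#' Default billing-code prefixes indicating chronic kidney disease
#'
#' Prefix-matched against a participant's diagnosis/procedure codes when
#' screening controls. A compact default standing in for the full validated
#' e-phenotype code list; override via the `ckd_codes` argument of
#' [assign_case_control()].
#' @export
default_ckd_codes <- function() {
  c("585", "586", "403", "404", "V42.0", "V45.1", "39.95", "55.6")
}

#' Default diabetes (type I or II) code prefixes
#' @export
default_diabetes_codes <- function() c("250")

codes_match_prefix <- function(code_strings, prefixes) {
  if (length(prefixes) == 0) stop("code prefix list is empty", call. = FALSE)
  vapply(strsplit(ifelse(is.na(code_strings), "", code_strings), ";",
                  fixed = TRUE),
         function(cc) {
           cc <- cc[nzchar(cc)]
           any(vapply(prefixes, function(p) any(startsWith(cc, p)), logical(1)))
         },
         logical(1))
}

#' Assign CKD case/control/excluded labels
#'
#' Applies the e-phenotype: cases have eGFR below 60 ml/min/1.73 m^2 or a
#' renal-replacement-therapy record; controls have eGFR above 90 and no CKD
#' billing codes; participants with eGFR in the 60-90 band (age-related decline
#' zone), with eGFR > 90 but CKD codes, or with no usable creatinine and no RRT
#' are excluded. Exactly one label per participant.
#'
#' @param phenotypes data.frame with columns `participant_id`, `age`, `sex`,
#'   `creatinine_mg_dl` (NA allowed; semicolon-separated lists allowed, the
#'   median is used), `rrt_flag`, `icd9_codes`, and (for the 2009 equation)
#'   `black_indicator`
#' @param equation "2009" or "2021"
#' @param ckd_codes code prefixes excluding a participant from the control pool
#' @return data.frame: participant_id, egfr, equation, label
#' @export
assign_case_control <- function(phenotypes, equation = c("2009", "2021"),
                                ckd_codes = default_ckd_codes()) {
  equation <- match.arg(equation)
  scr <- median_creatinine(phenotypes$creatinine_mg_dl)
  rrt <- isTRUE_vec(phenotypes$rrt_flag)
  egfr <- rep(NA_real_, nrow(phenotypes))
  ok <- !is.na(scr)
  if (any(ok)) {
    egfr[ok] <- if (equation == "2009") {
      egfr_ckdepi_2009(scr[ok], phenotypes$age[ok], phenotypes$sex[ok],
                       isTRUE_vec(phenotypes$black_indicator)[ok])
    } else {
      egfr_ckdepi_2021(scr[ok], phenotypes$age[ok], phenotypes$sex[ok])
    }
  }
  has_ckd_code <- codes_match_prefix(phenotypes$icd9_codes, ckd_codes)
  label <- rep("excluded", nrow(phenotypes))
  label[rrt | (!is.na(egfr) & egfr < 60)] <- "case"
  is_control <- !rrt & !is.na(egfr) & egfr > 90 & !has_ckd_code
  label[is_control] <- "control"
  data.frame(participant_id = phenotypes$participant_id,
             egfr = egfr, equation = paste0("CKD-EPI-", equation),
             label = label, stringsAsFactors = FALSE)
}

median_creatinine <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(strsplit(ifelse(is.na(x), "", as.character(x)), ";", fixed = TRUE),
         function(v) {
           v <- suppressWarnings(as.numeric(v[nzchar(v)]))
           v <- v[is.finite(v)]
           if (length(v) == 0) NA_real_ else stats::median(v)
         }, numeric(1))
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(FALSE)
  out <- as.logical(x)
  out[is.na(out)] <- FALSE
  out
}

#' Derive model covariates from the phenotype table
#'
#' Returns age, sex, a diabetes flag (any diagnosis code matching the
#' configured prefixes; both `icd9_codes` and a dedicated `diabetes_codes`
#' column are scanned), and batch.
#'
#' @param phenotypes phenotype data.frame (see [assign_case_control()])
#' @param diabetes_codes code prefixes defining diabetes
#' @export
derive_covariates <- function(phenotypes,
                              diabetes_codes = default_diabetes_codes()) {
  if (length(diabetes_codes) == 0)
    stop("diabetes code list must not be empty", call. = FALSE)
  dm <- codes_match_prefix(phenotypes$icd9_codes, diabetes_codes)
  if (!is.null(phenotypes$diabetes_codes))
    dm <- dm | codes_match_prefix(phenotypes$diabetes_codes, diabetes_codes)
  data.frame(participant_id = phenotypes$participant_id,
             age = phenotypes$age,
             sex = as.character(phenotypes$sex),
             diabetes = dm,
             batch = as.character(phenotypes$batch),
             stringsAsFactors = FALSE)
}
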