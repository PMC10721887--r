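#' Simulation configuration for the synthetic two-cohort study
#'
#' Defines the study conditions under which the pipeline is exercised: two
#' cohorts that differ in ancestry mix (predominantly-European vs diverse) and
#' age range, rare qualifying variants in the ADPKD (`PKD1`, `PKD2`) and
#' COL4A (`COL4A3`, `COL4A4`, `COL4A5`) gene sets, block-correlated common
#' variants carrying a polygenic score, an APOL1 recessive risk genotype, and
#' a logistic disease model with planted log-odds-ratios.
#'
#' Disease liability is generated on the logistic (not probit) scale so the
#' planted coefficients are directly recoverable by logistic regression:
#' \deqn{\mathrm{logit}\, P(\mathrm{CKD}) = \beta_0 + \beta_c\,\mathrm{carrier}
#'  + \beta_g\,\mathrm{GPS} + \beta_i\,\mathrm{carrier}\times\mathrm{GPS}
#'  + \beta_a\,\mathrm{APOL1} + \mathrm{age/sex/diabetes\ terms}}
#' where GPS is the true within-ancestry standardized score. The intercept is
#' calibrated numerically per cohort so the mean case probability equals
#' `baseline_case_rate`.
#'
#' @param n_cohort1,n_cohort2 participants per cohort
#' @param ancestry_mix1,ancestry_mix2 named proportions over
#'   EUR/AFR/EAS/SAS/AMR; must sum to 1
#' @param age_range1,age_range2 uniform age ranges (years)
#' @param n_rare_per_gene rare variants simulated per gene
#' @param carrier_frequency named per-gene-set probability that a participant
#'   carries a strict (M1-class) qualifying variant
#' @param n_common_variants number of common score markers (AR(1)-correlated
#'   in LD blocks of `ld_block_size` with parameter `ld_rho`)
#' @param n_pca_variants number of additional common markers reserved for
#'   ancestry PCA and kinship (disjoint from the score weights, so ancestry
#'   axes carry no within-group score signal)
#' @param planted_carrier_logOR named per-gene-set carrier log odds ratios
#' @param planted_gps_logOR_per_SD log OR per SD of the standardized score
#' @param planted_interaction_logOR carrier-by-GPS product coefficient
#'   (ADPKD set); default 0
#' @param baseline_case_rate target marginal CKD case probability per cohort
#' @param apol1_risk_genotype_freq named per-ancestry probability of the
#'   recessive APOL1 risk genotype (G1/G1, G2/G2, or G1/G2)
#' @param apol1_logOR planted APOL1 risk-genotype log OR
#' @param missing_creatinine_rate fraction of participants with no usable
#'   creatinine measurement
#' @param excluded_band_rate fraction of non-cases assigned a target eGFR in
#'   the 60-90 exclusion band
#' @param rrt_rate fraction of cases with a renal-replacement-therapy record
#' @param diabetes_prev diabetes prevalence
#' @param age_logOR_per_decade,male_logOR,diabetes_logOR covariate effects
#' @param ld_rho,ld_block_size LD structure of the common variants
#' @param fst Balding-Nichols differentiation of allele frequencies between
#'   ancestry groups (drives PC separation)
#' @param panel_n named reference-panel sizes per ancestry (1000-Genomes-like)
#' @param maf_thresholds named per-gene-set rare-variant frequency ceilings;
#'   the generator keeps surviving-class variants under these ceilings (in the
#'   annotation sources and in the cohort-recomputed frequency) and the
#'   pipeline filter applies them
#' @param seed master seed; every stage derives its own stream from it
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_cohort1 = 165000L,
                       n_cohort2 = 35000L,
                       ancestry_mix1 = c(EUR = 0.94, AFR = 0.02, EAS = 0.01,
                                         SAS = 0.02, AMR = 0.01),
                       ancestry_mix2 = c(EUR = 0.43, AFR = 0.25, EAS = 0.05,
                                         SAS = 0.05, AMR = 0.22),
                       age_range1 = c(40, 69),
                       age_range2 = c(18, 89),
                       n_rare_per_gene = 40L,
                       carrier_frequency = c(adpkd = 6e-4, col4a = 3e-3),
                       n_common_variants = 500L,
                       n_pca_variants = 800L,
                       planted_carrier_logOR = c(adpkd = log(17),
                                                 col4a = log(1.37)),
                       planted_gps_logOR_per_SD = log(1.7),
                       planted_interaction_logOR = 0,
                       baseline_case_rate = 0.03,
                       apol1_risk_genotype_freq = c(EUR = 1e-4, AFR = 0.12,
                                                    EAS = 1e-4, SAS = 1e-4,
                                                    AMR = 0.01),
                       apol1_logOR = log(2),
                       missing_creatinine_rate = 0.05,
                       excluded_band_rate = 0.25,
                       rrt_rate = 0.10,
                       diabetes_prev = 0.12,
                       age_logOR_per_decade = log(1.6),
                       male_logOR = log(1.2),
                       diabetes_logOR = log(2.5),
                       ld_rho = 0.35,
                       ld_block_size = 25L,
                       fst = 0.10,
                       panel_n = c(EUR = 503, AFR = 661, EAS = 504,
                                   SAS = 489, AMR = 347),
                       maf_thresholds = default_maf_thresholds(),
                       seed = 1L) {
  cfg <- list(n_cohort1 = as.integer(n_cohort1),
              n_cohort2 = as.integer(n_cohort2),
              ancestry_mix1 = ancestry_mix1, ancestry_mix2 = ancestry_mix2,
              age_range1 = age_range1, age_range2 = age_range2,
              n_rare_per_gene = as.integer(n_rare_per_gene),
              carrier_frequency = carrier_frequency,
              n_common_variants = as.integer(n_common_variants),
              n_pca_variants = as.integer(n_pca_variants),
              planted_carrier_logOR = planted_carrier_logOR,
              planted_gps_logOR_per_SD = planted_gps_logOR_per_SD,
              planted_interaction_logOR = planted_interaction_logOR,
              baseline_case_rate = baseline_case_rate,
              apol1_risk_genotype_freq = apol1_risk_genotype_freq,
              apol1_logOR = apol1_logOR,
              missing_creatinine_rate = missing_creatinine_rate,
              excluded_band_rate = excluded_band_rate,
              rrt_rate = rrt_rate,
              diabetes_prev = diabetes_prev,
              age_logOR_per_decade = age_logOR_per_decade,
              male_logOR = male_logOR,
              diabetes_logOR = diabetes_logOR,
              ld_rho = ld_rho, ld_block_size = as.integer(ld_block_size),
              fst = fst, panel_n = panel_n,
              maf_thresholds = maf_thresholds,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_cohort1 > 0 && cfg$n_cohort2 > 0,
              "cohort sizes must be positive")
  for (m in list(cfg$ancestry_mix1, cfg$ancestry_mix2)) {
    assert_that(is_prob(m) && abs(sum(m) - 1) < 1e-8,
                "ancestry proportions must lie in [0,1] and sum to 1")
    assert_that(all(names(m) %in% ancestry_groups()),
                "unknown ancestry group in mixture")
  }
  assert_that(is_prob(cfg$carrier_frequency) &&
                setequal(names(cfg$carrier_frequency), c("adpkd", "col4a")),
              "carrier_frequency must be named probabilities for adpkd/col4a")
  assert_that(is_prob(c(cfg$baseline_case_rate, cfg$missing_creatinine_rate,
                        cfg$excluded_band_rate, cfg$rrt_rate,
                        cfg$diabetes_prev, cfg$apol1_risk_genotype_freq)),
              "all rates must be probabilities in [0,1]")
  assert_that(cfg$n_rare_per_gene > 0 && cfg$n_common_variants > 0,
              "variant counts must be positive")
  assert_that(is_prob(cfg$maf_thresholds) &&
                setequal(names(cfg$maf_thresholds), c("adpkd", "col4a")),
              "maf_thresholds must be named probabilities for adpkd/col4a")
  n_total <- cfg$n_cohort1 + cfg$n_cohort2
  exp_carriers <- n_total * cfg$carrier_frequency
  if (any(exp_carriers < 1)) {
    stop("underpowered stratum: expected carrier count below 1 for gene set(s) ",
         paste(names(exp_carriers)[exp_carriers < 1], collapse = ", "),
         call. = FALSE)
  }
  invisible(cfg)
}

ancestry_groups <- function() c("EUR", "AFR", "EAS", "SAS", "AMR")

#' Gene panel analyzed by the pipeline
#'
#' The two ADPKD genes and three COL4A-nephropathy genes with their
#' chromosomes (COL4A5 is X-linked) and gene-set membership.
#' @export
gene_panel <- function() {
  data.frame(
    gene = c("PKD1", "PKD2", "COL4A3", "COL4A4", "COL4A5"),
    chrom = c("16", "4", "2", "2", "X"),
    gene_set = c("adpkd", "adpkd", "col4a", "col4a", "col4a"),
    stringsAsFactors = FALSE)
}

#' Default per-gene-set rare-variant MAF ceilings
#'
#' 1e-5 for the autosomal-dominant ADPKD genes and 1e-3 for the COL4A genes
#' (whose most severe phenotype is recessive).
#' @export
default_maf_thresholds <- function() c(adpkd = 1e-5, col4a = 1e-3)
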