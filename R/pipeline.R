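# End-to-end orchestration: simulate -> filter -> classify -> phenotype ->
# ancestry -> score -> association statistics -> PheWAS, with a manifest.

#' Run the full penetrance pipeline on a synthetic cohort
#'
#' Executes every stage on a simulated two-cohort study and returns the
#' per-cohort and meta-analyzed statistics. Stages can be toggled; the
#' kinship screen is skipped automatically above `kinship_max_n` samples
#' (all-pairs estimation is quadratic in the cohort size).
#'
#' @param config a [sim_config()] (ignored when `cohort` is supplied)
#' @param cohort optionally a pre-simulated `penetrax_cohort`
#' @param model qualifying-variant model for the headline analyses
#' @param gene_set "adpkd" or "col4a"
#' @param inheritance "dominant" or "recessive" carrier definition
#' @param equation CKD-EPI equation, "2009" (primary) or "2021"
#' @param n_pcs_assoc ancestry PCs in association models (default 4)
#' @param n_pcs_phewas ancestry PCs in the PheWAS models (default 5)
#' @param do_phewas,do_kinship stage toggles (`do_kinship = NULL` = auto)
#' @param kinship_max_n sample-count ceiling for the kinship stage
#' @return object of class `penetrax_result`: filter report, QV sets,
#'   carrier calls, labels, scores, per-cohort and meta statistics, PheWAS,
#'   and a manifest
#' @export
run_pipeline <- function(config = sim_config(), cohort = NULL,
                         model = "M1", gene_set = "adpkd",
                         inheritance = c("dominant", "recessive"),
                         equation = c("2009", "2021"),
                         n_pcs_assoc = 4, n_pcs_phewas = 5,
                         do_phewas = TRUE, do_kinship = NULL,
                         kinship_max_n = 5000) {
  inheritance <- match.arg(inheritance)
  equation <- match.arg(equation)
  stages <- character(0)
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config)
  } else {
    config <- cohort$config
  }
  stages <- c(stages, "simulate")

  # --- variant QC ----------------------------------------------------------
  filt <- filter_variants(cohort$rare, cohort$annotations,
                          maf_thresholds = config$maf_thresholds,
                          sex = cohort$phenotypes$sex)
  stages <- c(stages, "filter")

  # --- QV classification and carrier calling -------------------------------
  genes <- gene_panel()
  qv <- list(); carriers <- list()
  for (m in c("M1", "M2", "M3")) {
    qv[[m]] <- classify_variants(filt$annotations, m)
    for (gs in c("adpkd", "col4a")) {
      qs <- qv[[m]][qv[[m]]$gene %in% genes$gene[genes$gene_set == gs], ,
                    drop = FALSE]
      carriers[[paste(m, gs, sep = "_")]] <-
        suppressWarnings(call_carriers(qs, filt$rare,
                                       cohort$phenotypes$sex, m))
    }
  }
  stages <- c(stages, "qv")

  # --- phenotyping ---------------------------------------------------------
  labels <- assign_case_control(cohort$phenotypes, equation)
  covars <- derive_covariates(cohort$phenotypes)
  stages <- c(stages, "phenotype")

  # --- ancestry ------------------------------------------------------------
  panel <- cohort$reference_panel
  # ancestry axes are built on markers outside the score model, so the
  # calibration never regresses out within-group score signal
  pca_cols <- setdiff(colnames(panel$dosages), cohort$weights$variant_id)
  pruned <- suppressWarnings(ld_prune(panel$dosages[, pca_cols,
                                                    drop = FALSE]))
  proj <- project_pcs(panel$dosages[, pruned, drop = FALSE],
                      cohort$dosages[, pruned, drop = FALSE], n_pcs = 10)
  anc <- classify_ancestry(proj$ref_pcs, panel$labels, proj$cohort_pcs,
                           seed = stage_seed(config$seed, "rf"))
  stages <- c(stages, "ancestry")

  n_total <- nrow(cohort$phenotypes)
  kept_ids <- cohort$phenotypes$participant_id
  if (is.null(do_kinship)) do_kinship <- n_total <= kinship_max_n
  if (do_kinship && n_total <= kinship_max_n) {
    kin <- king_kinship(cohort$dosages[, pruned, drop = FALSE])
    kept_ids <- exclude_related(kin, kept_ids)
    stages <- c(stages, "kinship")
  } else {
    kin <- NULL
    message("kinship stage skipped (n = ", n_total, " above ceiling ",
            kinship_max_n, ")")
  }

  # --- polygenic score -----------------------------------------------------
  raw <- gps_score(cohort$dosages, cohort$weights)
  ref_raw <- gps_score(panel$dosages, cohort$weights)
  adj <- ancestry_adjust(raw, proj$cohort_pcs, ref_raw, proj$ref_pcs)
  scored <- apol1_adjust_standardize(adj$cohort, cohort$apol1$risk_genotype)
  stages <- c(stages, "gps")

  # --- association statistics ---------------------------------------------
  key <- paste(model, gene_set, sep = "_")
  carrier_flag <- if (inheritance == "dominant")
    carriers[[key]]$dominant_carrier else carriers[[key]]$recessive_genotype
  frame <- data.frame(
    participant_id = cohort$phenotypes$participant_id,
    cohort = cohort$phenotypes$cohort,
    case = as.integer(labels$label == "case"),
    label = labels$label,
    carrier = carrier_flag,
    score = scored$score_standardized,
    age = covars$age, sex = covars$sex, diabetes = covars$diabetes,
    batch = covars$batch,
    stringsAsFactors = FALSE)
  for (k in seq_len(max(n_pcs_assoc, n_pcs_phewas)))
    frame[[paste0("PC", k)]] <- proj$cohort_pcs[, k]
  frame <- frame[frame$participant_id %in% kept_ids, , drop = FALSE]
  analysis <- frame[frame$label %in% c("case", "control"), , drop = FALSE]

  cov_assoc <- default_covariates(n_pcs_assoc)
  cov_tert <- default_covariates(n_pcs_assoc, diabetes = FALSE)
  per_cohort <- list(); stats <- list()
  for (ch in unique(analysis$cohort)) {
    d <- analysis[analysis$cohort == ch, , drop = FALSE]
    d$tertile <- assign_tertiles(d$score)
    per_cohort[[ch]] <- list(
      carrier = suppressWarnings(fit_carrier_model(d, cov_assoc, ch)),
      gps = suppressWarnings(fit_gps_model_by_stratum(d, cov_assoc, ch)),
      tertile = suppressWarnings(tertile_or(d, cov_tert, ch)),
      interaction = suppressWarnings(interaction_test(d, cov_assoc, ch)),
      performance = performance_metrics(d, cov_assoc, ch),
      penetrance = penetrance(d$carrier, d$label))
  }
  stats$carrier_meta <- with(
    do.call(rbind, lapply(per_cohort, `[[`, "carrier")),
    meta_fixed(logOR, se, cohort))
  gps_all <- do.call(rbind, lapply(per_cohort, `[[`, "gps"))
  stats$gps_meta <- lapply(
    split(gps_all, gps_all$stratum),
    function(s) meta_fixed(s$logOR, s$se, s$cohort))
  tert_all <- do.call(rbind, lapply(per_cohort, `[[`, "tertile"))
  stats$tertile_meta <- do.call(rbind, lapply(
    split(tert_all, tert_all$stratum), function(s) {
      if (all(!is.finite(s$se)) || all(s$stratum == "noncarrier_T2")) {
        return(data.frame(stratum = s$stratum[1], logOR = if
               (s$stratum[1] == "noncarrier_T2") 0 else NA_real_,
               se = NA_real_, or = if (s$stratum[1] == "noncarrier_T2") 1
               else NA_real_, ci_lower = NA, ci_upper = NA, p = NA,
               k = 0L, Q = NA, Q_p = NA, stringsAsFactors = FALSE))
      }
      cbind(stratum = s$stratum[1],
            suppressWarnings(meta_fixed(s$logOR, s$se, s$cohort)))
    }))
  int_all <- do.call(rbind, lapply(per_cohort, `[[`, "interaction"))
  stats$interaction_meta <- meta_fixed(int_all$estimate, int_all$se,
                                       int_all$cohort)
  stats <- c(stats, list(per_cohort = per_cohort))
  stages <- c(stages, "stats")

  # --- PheWAS --------------------------------------------------------------
  phewas <- NULL
  if (do_phewas) {
    mapped <- suppressMessages(map_codes(cohort$phenotypes$icd9_codes,
                                         cohort$phecode_map))
    res <- list()
    for (ch in unique(frame$cohort)) {
      idx <- which(cohort$phenotypes$participant_id %in%
                     frame$participant_id[frame$cohort == ch])
      res[[ch]] <- run_phewas(
        mapped$status[idx, , drop = FALSE],
        carrier_flag[idx],
        cbind(covars[idx, , drop = FALSE],
              stats::setNames(as.data.frame(
                proj$cohort_pcs[idx, seq_len(n_pcs_phewas), drop = FALSE]),
                paste0("PC", seq_len(n_pcs_phewas)))),
        cohort = ch)
    }
    phewas <- meta_phewas(res, mapped$map)
    phewas$per_cohort <- res
    stages <- c(stages, "phewas")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("penetrax")),
    seed = config$seed,
    n_participants = n_total,
    n_kept_after_kinship = length(kept_ids),
    model = model, gene_set = gene_set, inheritance = inheritance,
    equation = equation,
    stages_completed = stages,
    stats_hash = result_hash(stats))

  structure(list(cohort = cohort, filter = filt, qv = qv,
                 carriers = carriers, labels = labels,
                 ancestry = anc, kinship = kin, kept_ids = kept_ids,
                 scores = cbind(participant_id =
                                  cohort$phenotypes$participant_id,
                                score_raw = raw, scored),
                 frame = frame, analysis_frame = analysis,
                 stats = stats, phewas = phewas, manifest = manifest),
            class = "penetrax_result")
}

# stable content hash of the statistics tables (for rerun identity checks)
result_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' @exportS3Method base::print
print.penetrax_result <- function(x, ...) {
  cat("penetrax pipeline result (", x$manifest$model, ", ",
      x$manifest$gene_set, ", ", x$manifest$inheritance, ")\n", sep = "")
  cat("  stages:", paste(x$manifest$stages_completed, collapse = " -> "), "\n")
  m <- x$stats$carrier_meta
  cat(sprintf("  carrier OR (meta): %.2f (95%% CI %.2f-%.2f)\n",
              m$or, m$ci_lower, m$ci_upper))
  invisible(x)
}
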