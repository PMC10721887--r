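# Synthetic two-cohort generator with planted monogenic, polygenic, ancestry,
# and APOL1 effects. All randomness is funneled through per-stage streams
# derived from the master seed so that identical configs reproduce byte-
# identical outputs.

plof_consequence_set <- function() {
  c("stop_gained", "frameshift_variant", "stop_lost", "start_lost",
    "splice_acceptor_variant", "splice_donor_variant")
}

# truth classes and the evidence-model sets they imply
truth_class_models <- function() {
  list(M1 = c("plof", "p_multi"),
       M2 = c("plof", "p_multi", "lp_multi"),
       M3 = c("plof", "dmis"))
}

# --- common variants -------------------------------------------------------

sim_common_variant_info <- function(cfg) {
  set.seed(stage_seed(cfg$seed, "common-variants"))
  m_score <- cfg$n_common_variants
  m_pca <- cfg$n_pca_variants %||% 0L
  assert_that(m_score >= 10, "need at least 10 common variants")
  groups <- ancestry_groups()
  m_bg <- m_score - 2L + m_pca  # last two score markers tag APOL1 G1/G2
  p0 <- stats::runif(m_bg, 0.05, 0.95)
  fst <- cfg$fst
  freq <- vapply(groups, function(g) {
    pmin(pmax(stats::rbeta(m_bg, p0 * (1 - fst) / fst,
                           (1 - p0) * (1 - fst) / fst), 0.01), 0.99)
  }, numeric(m_bg))
  q <- sqrt(cfg$apol1_risk_genotype_freq[groups])
  freq <- rbind(freq, 0.7 * q, 0.3 * q)
  block <- c(ceiling(seq_len(m_bg) / cfg$ld_block_size),
             ceiling(m_bg / cfg$ld_block_size) + 1:2)
  m <- m_bg + 2L
  ids <- c(sprintf("cv%05d", seq_len(m_score - 2L)),
           if (m_pca > 0) sprintf("pv%05d", seq_len(m_pca)),
           "APOL1_G1", "APOL1_G2")
  info <- data.frame(
    variant_id = ids,
    role = c(rep("score", m_score - 2L), rep("pca", m_pca),
             "apol1_tag", "apol1_tag"),
    chrom = as.character(1 + (block - 1) %% 22),
    pos = 1e6 + 5000 * seq_len(m),
    effect_allele = "A", other_allele = "G",
    block = block,
    stringsAsFactors = FALSE)
  colnames(freq) <- groups
  list(info = info, freq = freq)
}

# AR(1) latent-Gaussian haplotypes within LD blocks, thresholded at each
# individual's ancestry-specific allele frequency.
sim_dosage_matrix <- function(cv, ancestry, cfg, stage, apol1) {
  set.seed(stage_seed(cfg$seed, stage))
  n <- length(ancestry)
  m <- nrow(cv$info)
  anc_idx <- match(ancestry, colnames(cv$freq))
  dos <- matrix(0L, nrow = n, ncol = m,
                dimnames = list(NULL, cv$info$variant_id))
  rho <- cfg$ld_rho
  s <- sqrt(1 - rho^2)
  m_bg <- m - 2L
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  for (j in seq_len(m_bg)) {
    if (j > 1 && cv$info$block[j] != cv$info$block[j - 1]) {
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    } else if (j > 1) {
      z1 <- rho * z1 + s * stats::rnorm(n)
      z2 <- rho * z2 + s * stats::rnorm(n)
    }
    thr <- stats::qnorm(cv$freq[j, ])[anc_idx]
    dos[, j] <- (z1 < thr) + (z2 < thr)
  }
  dos[, m - 1L] <- apol1$g1
  dos[, m] <- apol1$g2
  dos
}

sim_apol1 <- function(ancestry, cfg, stage) {
  set.seed(stage_seed(cfg$seed, stage))
  q <- sqrt(cfg$apol1_risk_genotype_freq)[ancestry]
  a1 <- stats::runif(length(ancestry)); a2 <- stats::runif(length(ancestry))
  allele <- function(u) ifelse(u < 0.7 * q, 1L, ifelse(u < q, 2L, 0L))
  x1 <- allele(a1); x2 <- allele(a2)
  list(g1 = (x1 == 1L) + (x2 == 1L), g2 = (x1 == 2L) + (x2 == 2L))
}

#' APOL1 recessive risk genotype indicator
#'
#' TRUE when a participant carries two risk alleles in any combination
#' (G1/G1, G2/G2, or G1/G2).
#' @param g1,g2 counts of G1 and G2 risk alleles (0-2 each, g1+g2 <= 2)
#' @export
apol1_risk_genotype <- function(g1, g2) (g1 + g2) >= 2L

# --- score weights ---------------------------------------------------------

sim_weights <- function(cv, cfg) {
  set.seed(stage_seed(cfg$seed, "weights"))
  score_rows <- which(cv$info$role == "score")
  tag_rows <- which(cv$info$role == "apol1_tag")
  w <- numeric(length(score_rows))
  nz <- sort(sample(length(score_rows), floor(0.6 * length(score_rows))))
  w[nz] <- stats::rnorm(length(nz), 0, 0.08)
  # APOL1 tag markers carry small positive weights: the raw score is
  # contaminated by the APOL1 locus, which the adjustment step must remove
  rows <- c(score_rows, tag_rows)
  data.frame(variant_id = cv$info$variant_id[rows],
             effect_allele = cv$info$effect_allele[rows],
             weight = c(w, 0.08, 0.08), stringsAsFactors = FALSE)
}

# --- rare variant catalog --------------------------------------------------

rare_class_allocation <- function(n) {
  base <- c(plof = 12, p_multi = 6, lp_multi = 3, dmis = 4, dmis_blb = 1,
            dmis_4of5 = 2, dmis_lowrevel = 1, revel_boundary = 1,
            plof_blb = 2, p_single = 2, p_conflict = 2, synonymous = 2,
            common = 1, vus = 1)
  if (n >= length(base)) {
    cnt <- pmax(floor(n * base / sum(base)), 1L)
    while (sum(cnt) > n) cnt[which.max(cnt)] <- cnt[which.max(cnt)] - 1L
    while (sum(cnt) < n) cnt[which.min(cnt / base)] <- cnt[which.min(cnt / base)] + 1L
  } else {
    cnt <- rep(0L, length(base)); names(cnt) <- names(base)
    pick <- rep(names(base), length.out = n)
    for (p in pick) cnt[p] <- cnt[p] + 1L
  }
  cnt
}

sim_rare_catalog <- function(cfg) {
  set.seed(stage_seed(cfg$seed, "rare-catalog"))
  genes <- gene_panel()
  thr <- cfg$maf_thresholds
  rows <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes$gene[gi]
    cnt <- rare_class_allocation(cfg$n_rare_per_gene)
    cls <- rep(names(cnt), cnt)
    k <- length(cls)
    ceiling_af <- thr[[genes$gene_set[gi]]]
    maf <- stats::runif(k, 0.1 * ceiling_af, 0.9 * ceiling_af)
    # the benign-common class sits well above the configured ceiling so the
    # frequency filter always removes it
    maf[cls == "common"] <- stats::runif(sum(cls == "common"),
                                         min(2 * ceiling_af, 0.2),
                                         min(4 * ceiling_af, 0.4))
    consequence <- rep("missense_variant", k)
    consequence[cls %in% c("plof", "plof_blb")] <-
      sample(plof_consequence_set(), sum(cls %in% c("plof", "plof_blb")),
             replace = TRUE)
    consequence[cls == "synonymous"] <- "synonymous_variant"
    consequence[cls == "vus"] <- "splice_region_variant"
    revel <- rep(NA_real_, k)
    revel[cls == "p_multi"] <- 0.20
    revel[cls %in% c("dmis", "dmis_blb", "dmis_4of5")] <-
      round(stats::runif(sum(cls %in% c("dmis", "dmis_blb", "dmis_4of5")),
                         0.75, 0.99), 3)
    revel[cls == "dmis_lowrevel"] <- 0.65
    revel[cls == "revel_boundary"] <- 0.70
    revel[cls %in% c("common", "vus")] <- 0.30
    dmg_all <- cls %in% c("dmis", "dmis_blb", "dmis_lowrevel", "revel_boundary")
    pred <- matrix("tolerated", k, 5,
                   dimnames = list(NULL, c("sift", "polyphen2_hdiv",
                                           "polyphen2_hvar", "lrt",
                                           "mutation_taster")))
    pred[dmg_all, ] <- "damaging"
    four <- cls == "dmis_4of5"
    pred[four, 1:4] <- "damaging"; pred[four, 5] <- "tolerated"
    pred[cls %in% c("plof", "plof_blb", "synonymous"), ] <- "missing"
    clinvar <- rep("none", k); nsub <- rep(0L, k); conflict <- rep(FALSE, k)
    varsome <- rep("none", k)
    clinvar[cls == "p_multi"] <- "P"
    nsub[cls == "p_multi"] <- sample(2:4, sum(cls == "p_multi"), replace = TRUE)
    clinvar[cls == "p_single"] <- "P"; nsub[cls == "p_single"] <- 1L
    clinvar[cls == "p_conflict"] <- "P"
    nsub[cls == "p_conflict"] <- 3L; conflict[cls == "p_conflict"] <- TRUE
    clinvar[cls == "lp_multi"] <- "LP"
    nsub[cls == "lp_multi"] <- sample(2:3, sum(cls == "lp_multi"), replace = TRUE)
    clinvar[cls == "common"] <- "P"; nsub[cls == "common"] <- 2L
    clinvar[cls == "vus"] <- "VUS"; nsub[cls == "vus"] <- 1L
    # benign vetoes split between the two databases
    iblb <- which(cls %in% c("plof_blb", "dmis_blb"))
    for (i in seq_along(iblb)) {
      if (i %% 2 == 0) {
        clinvar[iblb[i]] <- "LB"; nsub[iblb[i]] <- 1L
      } else varsome[iblb[i]] <- "LB"
    }
    varsome[cls == "dmis"] <- sample(c("VUS", "none"), sum(cls == "dmis"),
                                     replace = TRUE)
    rows[[gi]] <- data.frame(
      variant_id = sprintf("rv_%s_%03d", g, seq_len(k)),
      gene = g, chrom = genes$chrom[gi],
      pos = 1000 * seq_len(k) + gi * 1e6,
      ref = "C", alt = "T",
      consequence = consequence, revel = revel,
      pred, clinvar_assertion = clinvar, clinvar_n_submitters = nsub,
      clinvar_conflict_flag = conflict, varsome_assertion = varsome,
      truth_class = cls, stringsAsFactors = FALSE)
  }
  cat <- do.call(rbind, rows)
  rownames(cat) <- NULL
  # per-(source, ancestry) observed frequencies: small wobble around the true
  # MAF, shared truth across sources so the any-cell frequency filter is exact
  set.seed(stage_seed(cfg$seed, "rare-afs"))
  base_maf <- numeric(nrow(cat))
  for (gi in seq_len(nrow(genes))) {
    idx <- cat$gene == genes$gene[gi]
    ceiling_af <- thr[[genes$gene_set[gi]]]
    base_maf[idx] <- stats::runif(sum(idx), 0.1 * ceiling_af, 0.9 * ceiling_af)
    is_common <- idx & cat$truth_class == "common"
    base_maf[is_common] <- stats::runif(sum(is_common),
                                        min(2 * ceiling_af, 0.2),
                                        min(4 * ceiling_af, 0.4))
  }
  row_ceiling <- thr[genes$gene_set[match(cat$gene, genes$gene)]]
  row_ceiling[cat$truth_class == "common"] <- 0.5
  for (a in ancestry_groups()) {
    anc_maf <- pmin(base_maf * exp(stats::rnorm(nrow(cat), 0, 0.05)),
                    row_ceiling)
    for (src in c("gnomad", "cohort1", "cohort2"))
      cat[[paste0("af_", src, "_", a)]] <- signif(anc_maf, 6)
  }
  cat$maf_true <- base_maf
  cat
}

# --- rare genotypes --------------------------------------------------------

# A per-variant carrier cap keeps the cohort-recomputed allele frequency of
# every surviving-class variant at or below its gene set's MAF ceiling, so the
# frequency filter never removes a variant the truth record counts on.
fodder_rows <- function(catalog) {
  unlist(lapply(unique(catalog$gene), function(g) {
    which(catalog$gene == g & catalog$truth_class == "plof")[4]
  }))
}

sim_rare_genotypes <- function(catalog, participants, cfg) {
  set.seed(stage_seed(cfg$seed, "rare-genotypes"))
  n <- nrow(participants)
  m <- nrow(catalog)
  gt <- matrix(0L, m, n, dimnames = list(catalog$variant_id,
                                         participants$participant_id))
  male <- participants$sex == "male"
  genes <- gene_panel()
  m1_class <- truth_class_models()$M1
  fodder <- fodder_rows(catalog)   # reserved for masked-call planting
  for (gs in c("adpkd", "col4a")) {
    gene_names <- genes$gene[genes$gene_set == gs]
    cap <- max(1L, floor(2 * n * cfg$maf_thresholds[[gs]]))
    vrows <- setdiff(which(catalog$gene %in% gene_names &
                             catalog$truth_class %in% m1_class), fodder)
    capacity <- rep(cap, length(vrows))
    carrier <- which(stats::runif(n) < cfg$carrier_frequency[[gs]])
    for (p in carrier) {
      open <- which(capacity > 0)
      if (length(open) == 0) break   # capacity exhausted: truncate the tail
      j <- open[sample.int(length(open), 1L)]
      v <- vrows[j]
      if (catalog$chrom[v] == "X" && male[p]) {
        gt[v, p] <- 2L     # hemizygous male written haploid-as-homozygous
      } else gt[v, p] <- 1L
      capacity[j] <- capacity[j] - 1L
    }
  }
  # low-level carriers of every other class so each rule branch has data
  sprinkle_classes <- setdiff(unique(catalog$truth_class),
                              c(m1_class, "common"))
  for (v in setdiff(which(catalog$truth_class %in% sprinkle_classes), fodder)) {
    gs <- genes$gene_set[match(catalog$gene[v], genes$gene)]
    cap <- max(1L, floor(2 * n * cfg$maf_thresholds[[gs]]))
    who <- sample.int(n, min(3L, cap, n))
    hemi <- catalog$chrom[v] == "X" & male[who]
    gt[v, who] <- ifelse(hemi, 2L, 1L)
  }
  for (v in which(catalog$truth_class == "common")) {
    gt[v, ] <- stats::rbinom(n, 2L, catalog$maf_true[v])
  }
  gt
}

# deterministic edge-case plants exercising zygosity and QC branches
plant_edge_cases <- function(gt, gq, dp, catalog, participants) {
  n <- ncol(gt)
  male <- participants$sex == "male"
  female_ids <- which(!male)
  male_ids <- which(male)
  plof3 <- which(catalog$gene == "COL4A3" & catalog$truth_class == "plof")
  plof4 <- which(catalog$gene == "COL4A4" & catalog$truth_class == "plof")
  plof5 <- which(catalog$gene == "COL4A5" & catalog$truth_class == "plof")
  if (length(female_ids) < 16 || length(male_ids) < 2 ||
      length(plof3) < 4 || length(plof4) < 4 || length(plof5) < 4) {
    return(list(gt = gt, gq = gq, dp = dp, plants = list()))
  }
  plants <- list()
  # compound heterozygote: two distinct het QVs in COL4A3, female
  p <- female_ids[1]
  gt[plof3[1], p] <- 1L; gt[plof3[2], p] <- 1L
  plants$comp_het <- participants$participant_id[p]
  # in-cis pair (unphased comp-het false positive), COL4A4, female
  p <- female_ids[2]
  gt[plof4[1], p] <- 1L; gt[plof4[2], p] <- 1L
  plants$in_cis_pair <- participants$participant_id[p]
  # homozygote, COL4A3
  p <- female_ids[3]
  gt[plof3[3], p] <- 2L
  plants$homozygote <- participants$participant_id[p]
  # hemizygous male, COL4A5
  p <- male_ids[1]
  gt[plof5[1], p] <- 2L
  plants$hemizygote <- participants$participant_id[p]
  # data error: heterozygous X call in a male (classifier must warn)
  p <- male_ids[2]
  gt[plof5[2], p] <- 1L
  plants$x_het_male <- participants$participant_id[p]
  # masked-call fodder: alternate calls failing GQ/DP thresholds
  masked <- list()
  for (g in unique(catalog$gene)) {
    vrow <- which(catalog$gene == g & catalog$truth_class == "plof")[4]
    if (is.na(vrow)) next
    p1 <- female_ids[4 + match(g, unique(catalog$gene))]
    p2 <- female_ids[10 + match(g, unique(catalog$gene))]
    gt[vrow, p1] <- 1L; gq[vrow, p1] <- 90L          # boundary: GQ == 90 fails
    gt[vrow, p2] <- 1L; dp[vrow, p2] <- 8L
    masked[[g]] <- participants$participant_id[c(p1, p2)]
  }
  plants$masked_calls <- masked
  list(gt = gt, gq = gq, dp = dp, plants = plants)
}

# carrier truth per evidence model from pass-QC genotypes and true classes
truth_carrier_table <- function(gt_pass, catalog, participants) {
  male <- participants$sex == "male"
  models <- truth_class_models()
  out <- data.frame(participant_id = participants$participant_id,
                    stringsAsFactors = FALSE)
  for (gs in c("adpkd", "col4a")) {
    gene_names <- gene_panel()$gene[gene_panel()$gene_set == gs]
    for (mod in names(models)) {
      rows <- which(catalog$gene %in% gene_names &
                      catalog$truth_class %in% models[[mod]])
      sub <- gt_pass[rows, , drop = FALSE]
      dom <- colSums(sub >= 1L, na.rm = TRUE) >= 1L
      hom <- colSums(sub == 2L & catalog$chrom[rows] != "X", na.rm = TRUE) >= 1L
      xrows <- catalog$chrom[rows] == "X"
      hemi <- male & colSums(sub[xrows, , drop = FALSE] >= 1L, na.rm = TRUE) >= 1L
      comphet <- rep(FALSE, ncol(sub))
      for (g in setdiff(gene_names, "COL4A5")) {
        grows <- which(catalog$gene[rows] == g)
        if (length(grows) >= 2)
          comphet <- comphet |
            colSums(sub[grows, , drop = FALSE] == 1L, na.rm = TRUE) >= 2L
      }
      out[[paste0("dom_", gs, "_", mod)]] <- dom
      out[[paste0("rec_", gs, "_", mod)]] <- (hom | hemi | comphet) & dom
    }
  }
  out
}

# --- phenotype generation --------------------------------------------------

calibrate_intercept <- function(eta, target) {
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target
  stats::uniroot(f, c(-20, 10), tol = 1e-10)$root
}

sim_phenotypes <- function(participants, truth_carriers, gps_true, apol1_risk,
                           cfg) {
  set.seed(stage_seed(cfg$seed, "phenotypes"))
  n <- nrow(participants)
  male <- participants$sex == "male"
  dm <- participants$diabetes
  ca <- truth_carriers$dom_adpkd_M1
  cc <- truth_carriers$dom_col4a_M1
  eta <- cfg$planted_carrier_logOR[["adpkd"]] * ca +
    cfg$planted_carrier_logOR[["col4a"]] * cc +
    cfg$planted_gps_logOR_per_SD * gps_true +
    cfg$planted_interaction_logOR * ca * gps_true +
    cfg$apol1_logOR * apol1_risk +
    cfg$age_logOR_per_decade * (participants$age - 55) / 10 +
    cfg$male_logOR * male +
    cfg$diabetes_logOR * dm
  case <- logical(n)
  for (ch in unique(participants$cohort)) {
    idx <- participants$cohort == ch
    b0 <- calibrate_intercept(eta[idx], cfg$baseline_case_rate)
    case[idx] <- stats::runif(sum(idx)) < stats::plogis(b0 + eta[idx])
  }
  # renal replacement therapy among cases; a slice of RRT cases keeps
  # preserved eGFR (case via procedure record alone)
  rrt <- case & stats::runif(n) < cfg$rrt_rate
  egfr_target <- numeric(n)
  egfr_target[case] <- stats::runif(sum(case), 15, 59)
  rrt_preserved <- rrt & stats::runif(n) < 0.2
  egfr_target[rrt_preserved] <- stats::runif(sum(rrt_preserved), 61, 89)
  noncase <- !case
  band <- noncase & stats::runif(n) < cfg$excluded_band_rate
  egfr_target[band] <- stats::runif(sum(band), 61, 89)
  ctrl <- noncase & !band
  egfr_target[ctrl] <- stats::runif(sum(ctrl), 91, 130)
  black <- participants$ancestry == "AFR"
  creat <- round(creatinine_for_egfr_2009(egfr_target, participants$age,
                                          participants$sex, black), 4)
  miss <- stats::runif(n) < cfg$missing_creatinine_rate
  creat[miss] <- NA_real_

  # diagnosis code multisets
  codes <- vector("list", n)
  add <- function(i, code, times = 2L) {
    codes[[i]] <<- c(codes[[i]], rep(code, times))
  }
  map <- synthetic_phecode_map()
  background_pool <- map$icd9[!grepl("^(585|586|753|250)", map$icd9)]
  nbg <- stats::rpois(n, 1.2)
  ckd_coded <- case & stats::runif(n) < 0.7
  miscoded_ctrl <- ctrl & !miss & stats::runif(n) < 0.01
  # carrier-enriched phecodes with a small background rate in noncarriers so
  # per-phecode fits stay away from complete separation
  cystic <- stats::runif(n) < ifelse(ca, 0.30, 0.002)
  hematuria <- stats::runif(n) < ifelse(cc, 0.25, 0.004)
  for (i in seq_len(n)) {
    if (nbg[i] > 0)
      codes[[i]] <- sample(background_pool, nbg[i], replace = TRUE)
    if (dm[i]) add(i, "250.00")
    if (ckd_coded[i]) add(i, "585.3")
    if (miscoded_ctrl[i]) add(i, "585.9")
    if (cystic[i]) add(i, "753.1")
    if (hematuria[i]) add(i, "599.7")
  }
  icd <- vapply(codes, function(x) paste(x, collapse = ";"), character(1))

  label <- ifelse(rrt, "case",
           ifelse(is.na(creat), "excluded",
           ifelse(case & egfr_target < 60, "case",
           ifelse(!case & !band & !miscoded_ctrl, "control", "excluded"))))
  # a non-RRT case whose target eGFR was preserved cannot happen (cases draw
  # <60 unless RRT), so labels above cover every branch exactly once
  pheno <- data.frame(
    participant_id = participants$participant_id,
    cohort = participants$cohort,
    age = participants$age,
    sex = participants$sex,
    creatinine_mg_dl = creat,
    icd9_codes = icd,
    rrt_flag = rrt,
    diabetes_codes = ifelse(dm, "250.00;250.00", ""),
    batch = participants$batch,
    black_indicator = black,
    stringsAsFactors = FALSE)
  list(phenotypes = pheno,
       truth = data.frame(participant_id = participants$participant_id,
                          case = case, label = label,
                          egfr_target = egfr_target,
                          stringsAsFactors = FALSE))
}

# --- reference panel -------------------------------------------------------

#' Simulate a labeled ancestry reference panel with PC loadings
#'
#' Generates a 1000-Genomes-like panel on the supplied (or freshly drawn)
#' common-variant set, with discrete ancestry labels and allele-frequency
#' differentiation sufficient for principal components to separate the groups.
#' Loadings come from a PCA of the panel itself.
#'
#' @param config a [sim_config()]
#' @param cv optional common-variant info (shared with a cohort simulation)
#' @param groups ancestry groups to include; defaults to all groups with
#'   positive mass in either cohort mixture
#' @param n_pcs number of PCs in the returned loadings
#' @return list: `dosages` (samples x variants), `labels`, `variant_info`,
#'   `pca` (center/scale/rotation), `pcs`
#' @export
simulate_reference_panel <- function(config, cv = NULL, groups = NULL,
                                     n_pcs = 10) {
  if (is.null(groups)) {
    mix <- config$ancestry_mix1[ancestry_groups()] %||% 0
    mix2 <- config$ancestry_mix2[ancestry_groups()]
    mass <- ifelse(is.na(mix), 0, mix) + ifelse(is.na(mix2), 0, mix2)
    groups <- ancestry_groups()[mass > 0]
  }
  if (length(groups) < 2)
    stop("reference panel needs at least 2 ancestry groups", call. = FALSE)
  sizes <- config$panel_n[groups]
  if (any(is.na(sizes) | sizes < 50))
    stop("reference panel needs at least 50 samples per group", call. = FALSE)
  if (is.null(cv)) cv <- sim_common_variant_info(config)
  labels <- rep(groups, sizes)
  apol1 <- sim_apol1(labels, config, "panel-apol1")
  dos <- sim_dosage_matrix(cv, labels, config, "panel-dosages", apol1)
  rownames(dos) <- sprintf("REF%04d", seq_along(labels))
  keep <- which(apply(dos, 2, stats::var) > 0)
  pca <- stats::prcomp(dos[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  n_pcs <- min(n_pcs, ncol(pca$rotation))
  list(dosages = dos, labels = labels, variant_info = cv$info,
       apol1 = apol1,
       pca = list(variants = colnames(dos)[keep],
                  center = pca$center, scale = pca$scale,
                  rotation = pca$rotation[, seq_len(n_pcs), drop = FALSE]),
       pcs = pca$x[, seq_len(n_pcs), drop = FALSE])
}

# --- main entry ------------------------------------------------------------

#' Simulate the full two-cohort synthetic study
#'
#' Generates every input the pipeline consumes: rare-variant genotypes with
#' per-call GQ/DP, an annotation table populating every qualifying-variant
#' rule branch (single-submitter and conflicting ClinVar records, benign
#' vetoes, REVEL boundary values, essential and non-essential splice
#' variants), common-variant dosages with block LD, a score weights table, a
#' phenotype table with back-computed creatinine, a labeled ancestry
#' reference panel, a phecode map, and a truth record.
#'
#' Deterministic edge cases are always planted: a compound heterozygote, an
#' unphased in-cis pair, a homozygote, a hemizygous male, a heterozygous
#' X-chromosome call in a male (data error), and alternate calls failing the
#' GQ/DP thresholds.
#'
#' @param config a [sim_config()]
#' @return object of class `penetrax_cohort`
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "participants"))
  n <- config$n_cohort1 + config$n_cohort2
  cohort <- rep(c("cohort1", "cohort2"), c(config$n_cohort1, config$n_cohort2))
  ancestry <- character(n)
  i1 <- cohort == "cohort1"
  ancestry[i1] <- sample(names(config$ancestry_mix1), config$n_cohort1,
                         replace = TRUE, prob = config$ancestry_mix1)
  ancestry[!i1] <- sample(names(config$ancestry_mix2), config$n_cohort2,
                          replace = TRUE, prob = config$ancestry_mix2)
  age <- numeric(n)
  age[i1] <- round(stats::runif(config$n_cohort1, config$age_range1[1],
                                config$age_range1[2]), 1)
  age[!i1] <- round(stats::runif(config$n_cohort2, config$age_range2[1],
                                 config$age_range2[2]), 1)
  participants <- data.frame(
    participant_id = sprintf("P%07d", seq_len(n)),
    cohort = cohort,
    ancestry = ancestry,
    sex = sample(c("female", "male"), n, replace = TRUE),
    age = age,
    batch = paste0(substr(cohort, 7, 7), "B",
                   sample(1:2, n, replace = TRUE)),
    diabetes = stats::runif(n) < config$diabetes_prev,
    stringsAsFactors = FALSE)

  apol1 <- sim_apol1(participants$ancestry, config, "apol1")
  apol1_risk <- apol1_risk_genotype(apol1$g1, apol1$g2)

  cv <- sim_common_variant_info(config)
  dosages <- sim_dosage_matrix(cv, participants$ancestry, config,
                               "cohort-dosages", apol1)
  rownames(dosages) <- participants$participant_id
  weights <- sim_weights(cv, config)

  # true standardized score: weighted sum over the score markers only
  # (APOL1 tag contamination excluded), z-scored within ancestry
  score_ids <- cv$info$variant_id[cv$info$role == "score"]
  wmap <- stats::setNames(weights$weight, weights$variant_id)
  clean <- as.numeric(dosages[, score_ids, drop = FALSE] %*%
                        wmap[score_ids])
  mu <- stats::ave(clean, participants$ancestry)
  sd_a <- stats::ave(clean, participants$ancestry,
                     FUN = function(x) stats::sd(x))
  gps_true <- (clean - mu) / sd_a

  catalog <- sim_rare_catalog(config)
  gt <- sim_rare_genotypes(catalog, participants, config)
  set.seed(stage_seed(config$seed, "rare-quality"))
  gq <- matrix(sample(91:99, length(gt), replace = TRUE), nrow(gt), ncol(gt),
               dimnames = dimnames(gt))
  dp <- matrix(sample(11:60, length(gt), replace = TRUE), nrow(gt), ncol(gt),
               dimnames = dimnames(gt))
  planted <- plant_edge_cases(gt, gq, dp, catalog, participants)
  gt <- planted$gt; gq <- planted$gq; dp <- planted$dp

  gt_pass <- gt
  gt_pass[gq <= 90L | dp <= 10L] <- 0L
  truth_carriers <- truth_carrier_table(gt_pass, catalog, participants)

  ph <- sim_phenotypes(participants, truth_carriers, gps_true, apol1_risk,
                       config)

  panel <- simulate_reference_panel(config, cv = cv)

  structure(list(
    config = config,
    participants = participants,
    phenotypes = ph$phenotypes,
    rare = list(gt = gt, gq = gq, dp = dp,
                variants = catalog[, c("variant_id", "gene", "chrom", "pos",
                                       "ref", "alt")]),
    annotations = catalog[, setdiff(names(catalog), c("truth_class",
                                                      "maf_true"))],
    dosages = dosages,
    common_variants = cv$info,
    weights = weights,
    apol1 = data.frame(participant_id = participants$participant_id,
                       g1 = apol1$g1, g2 = apol1$g2,
                       risk_genotype = apol1_risk,
                       stringsAsFactors = FALSE),
    reference_panel = panel,
    phecode_map = synthetic_phecode_map(),
    truth = list(
      participants = cbind(
        participants[, c("participant_id", "cohort", "ancestry")],
        gps_true = gps_true,
        apol1_risk = apol1_risk,
        ph$truth[, c("case", "label", "egfr_target")],
        truth_carriers[, -1]),
      variants = catalog[, c("variant_id", "gene", "truth_class", "maf_true")],
      common_freq = cv$freq,
      plants = planted$plants)
  ), class = "penetrax_cohort")
}

#' @exportS3Method base::print
print.penetrax_cohort <- function(x, ...) {
  cat("penetrax synthetic cohort\n")
  cat("  participants:", nrow(x$participants),
      sprintf("(%s)", paste(table(x$participants$cohort), collapse = " + ")), "\n")
  cat("  rare variants:", nrow(x$rare$variants),
      " common markers:", ncol(x$dosages), "\n")
  cat("  planted ADPKD M1 carriers:", sum(x$truth$participants$dom_adpkd_M1),
      " COL4A M1 carriers:", sum(x$truth$participants$dom_col4a_M1), "\n")
  invisible(x)
}
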