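# shared fixture builders: everything is generated in code at test time,
# except the hand-labeled qualifying-variant fixture shipped in extdata

# a small, fast simulation configuration; rare-variant frequency ceilings are
# relaxed so carriers are plantable at desk-scale n
small_config <- function(n1 = 1200, n2 = 400, seed = 7, ...) {
  sim_config(n_cohort1 = n1, n_cohort2 = n2,
             carrier_frequency = c(adpkd = 0.02, col4a = 0.03),
             maf_thresholds = c(adpkd = 0.05, col4a = 0.05),
             n_common_variants = 150, n_pca_variants = 200,
             seed = seed, ...)
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "penetrax")
  if (p == "") p <- file.path("..", "..", "inst", "extdata", file)
  p
}

read_qv_fixture <- function() {
  read.table(fixture_path("qv_annotation_fixture.tsv"), sep = "\t",
             header = TRUE, stringsAsFactors = FALSE)
}

# a tiny rare-genotype object built by hand
toy_rare <- function(gt, gq = NULL, dp = NULL, chrom = NULL, gene = NULL) {
  m <- nrow(gt); n <- ncol(gt)
  if (is.null(rownames(gt))) rownames(gt) <- sprintf("v%02d", seq_len(m))
  if (is.null(colnames(gt))) colnames(gt) <- sprintf("s%02d", seq_len(n))
  if (is.null(gq)) gq <- matrix(99L, m, n, dimnames = dimnames(gt))
  if (is.null(dp)) dp <- matrix(30L, m, n, dimnames = dimnames(gt))
  list(gt = gt, gq = gq, dp = dp,
       variants = data.frame(variant_id = rownames(gt),
                             gene = gene %||% rep("PKD1", m),
                             chrom = chrom %||% rep("16", m),
                             pos = seq_len(m) * 100, ref = "C", alt = "T",
                             stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# logistic-model draws straight from the generative disease model, for
# calibration studies that do not need genotypes
sim_outcome_frame <- function(n, beta_carrier, beta_gps, beta_int = 0,
                              carrier_freq = 0.01, base_rate = 0.03) {
  carrier <- runif(n) < carrier_freq
  score <- rnorm(n)
  age <- runif(n, 40, 69)
  sex <- sample(c("female", "male"), n, TRUE)
  diabetes <- runif(n) < 0.12
  eta <- beta_carrier * carrier + beta_gps * score +
    beta_int * carrier * score + log(1.6) * (age - 55) / 10 +
    log(1.2) * (sex == "male") + log(2.5) * diabetes
  b0 <- uniroot(function(b) mean(plogis(b + eta)) - base_rate, c(-20, 5))$root
  data.frame(case = as.integer(runif(n) < plogis(b0 + eta)),
             carrier = carrier, score = score, age = age, sex = sex,
             diabetes = diabetes, batch = "B1", stringsAsFactors = FALSE)
}
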