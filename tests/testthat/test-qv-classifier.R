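# qualifying-variant rules and dominant/recessive genotype calling

test_that("every rule branch of the shipped fixture gets its hand label", {
  fx <- read_qv_fixture()
  for (m in c("M1", "M2", "M3")) {
    got <- fx$variant_id %in% classify_variants(fx, m)$variant_id
    expect_equal(got, fx[[paste0("expected_", m)]],
                 label = paste("model", m))
  }
})

test_that("pLOF vocabulary covers essential splice but not splice-region", {
  expect_true(all(is_plof(c("stop_gained", "frameshift_variant", "stop_lost",
                            "start_lost", "splice_acceptor_variant",
                            "splice_donor_variant"))))
  expect_false(any(is_plof(c("splice_region_variant", "missense_variant",
                             "synonymous_variant", "intron_variant"))))
})

test_that("deleterious-missense needs REVEL > 0.70 and 5/5 damaging", {
  base <- data.frame(consequence = "missense_variant", revel = 0.8,
                     sift = "damaging", polyphen2_hdiv = "damaging",
                     polyphen2_hvar = "damaging", lrt = "damaging",
                     mutation_taster = "damaging", stringsAsFactors = FALSE)
  expect_true(is_deleterious_missense(base))
  expect_false(is_deleterious_missense(transform(base, revel = 0.70)))
  expect_false(is_deleterious_missense(transform(base, revel = NA)))
  expect_false(is_deleterious_missense(transform(base, sift = "tolerated")))
  expect_false(is_deleterious_missense(transform(base, lrt = "missing")))
  expect_false(is_deleterious_missense(
    transform(base, consequence = "stop_gained")))
})

test_that("M1 is a subset of M2; unknown assertions error", {
  fx <- read_qv_fixture()
  m1 <- classify_variants(fx, "M1")$variant_id
  m2 <- classify_variants(fx, "M2")$variant_id
  expect_true(all(m1 %in% m2))
  bad <- transform(fx[1, ], clinvar_assertion = "Pathogenic")
  expect_error(classify_variants(bad, "M1"), "unknown clinvar")
})

test_that("carrier calling handles het, comp-het, hom, and hemizygous", {
  fx <- read_qv_fixture()
  rare <- read_rare_vcf(fixture_path("qv_genotype_fixture.vcf"))
  sexes <- read.table(fixture_path("qv_fixture_sex.tsv"), header = TRUE,
                      stringsAsFactors = FALSE)
  rare <- mask_low_quality_genotypes(rare)$rare
  get <- function(cc, id) cc[cc$participant_id == id, ]

  m2 <- classify_variants(fx, "M2")
  cc2 <- call_carriers(m2, rare, sexes$sex, "M2")
  # two distinct het QVs in COL4A3 under M2 -> compound het
  expect_true(get(cc2, "S_COMPHET_F")$recessive_genotype)
  expect_equal(get(cc2, "S_COMPHET_F")$zygosity, "comp_het")

  m1 <- classify_variants(fx, "M1")
  cc1 <- call_carriers(m1, rare, sexes$sex, "M1")
  # under M1 only one of the pair qualifies -> dominant het only
  expect_true(get(cc1, "S_COMPHET_F")$dominant_carrier)
  expect_false(get(cc1, "S_COMPHET_F")$recessive_genotype)
  # hemizygous male on COL4A5
  expect_true(get(cc1, "S_HEMI_M")$recessive_genotype)
  expect_equal(get(cc1, "S_HEMI_M")$zygosity, "hemi")
  # plain PKD1 het: dominant, not recessive
  expect_true(get(cc1, "S_HET_F")$dominant_carrier)
  expect_false(get(cc1, "S_HET_F")$recessive_genotype)
  # masked call never creates a carrier
  expect_false(get(cc1, "S_MASKED_F")$dominant_carrier)
  expect_false(get(cc1, "S_REF_F")$dominant_carrier)

  m3 <- classify_variants(fx, "M3")
  expect_warning(cc3 <- call_carriers(m3, rare, sexes$sex, "M3"),
                 "heterozygous X")
  # autosomal homozygote
  expect_true(get(cc3, "S_HOM_F")$recessive_genotype)
  expect_equal(get(cc3, "S_HOM_F")$zygosity, "hom")
  # het X call in a male is flagged and treated as carrying
  expect_true(get(cc3, "S_XHET_M")$x_het_male)
  expect_true(get(cc3, "S_XHET_M")$dominant_carrier)

  # invariant: recessive implies dominant, in every model
  for (cc in list(cc1, cc2, cc3))
    expect_true(all(!cc$recessive_genotype | cc$dominant_carrier))
})

test_that("classification on the simulated truth is exact", {
  cfg <- small_config(seed = 13)
  co <- simulate_cohort(cfg)
  filt <- filter_variants(co$rare, co$annotations,
                          maf_thresholds = cfg$maf_thresholds,
                          sex = co$phenotypes$sex)
  truth <- co$truth$variants
  models <- list(M1 = c("plof", "p_multi"),
                 M2 = c("plof", "p_multi", "lp_multi"),
                 M3 = c("plof", "dmis"))
  for (m in names(models)) {
    got <- filt$annotations$variant_id %in%
      classify_variants(filt$annotations, m)$variant_id
    want <- truth$truth_class[match(filt$annotations$variant_id,
                                    truth$variant_id)] %in% models[[m]]
    expect_equal(got, want, label = paste("model", m))
    # carrier calls reproduce the truth table for both gene sets
    for (gs in c("adpkd", "col4a")) {
      qs <- classify_variants(filt$annotations, m)
      qs <- qs[qs$gene %in% gene_panel()$gene[gene_panel()$gene_set == gs], ]
      cc <- suppressWarnings(call_carriers(qs, filt$rare,
                                           co$phenotypes$sex, m))
      tp <- co$truth$participants
      expect_equal(cc$dominant_carrier, tp[[paste0("dom_", gs, "_", m)]],
                   label = paste(m, gs, "dominant"))
      expect_equal(cc$recessive_genotype, tp[[paste0("rec_", gs, "_", m)]],
                   label = paste(m, gs, "recessive"))
    }
  }
  # monotonicity: carrier counts never decrease from M1 to M2
  tp <- co$truth$participants
  expect_gte(sum(tp$dom_adpkd_M2), sum(tp$dom_adpkd_M1))
  expect_gte(sum(tp$dom_col4a_M2), sum(tp$dom_col4a_M1))
})

test_that("penetrance is the case fraction among carriers with a Wilson CI", {
  # counts from a carrier table: 41 cases, 81 controls
  carrier <- rep(TRUE, 130)
  label <- c(rep("case", 41), rep("control", 81), rep("excluded", 8))
  p <- penetrance(carrier, label)
  expect_equal(p$penetrance, 41 / 122, tolerance = 1e-12)
  expect_equal(p$carriers, 122L)
  expect_true(p$lower < 41 / 122 && 41 / 122 < p$upper)
  # zero cases among carriers
  expect_equal(penetrance(rep(TRUE, 10), rep("control", 10))$penetrance, 0)
  # no carriers -> undefined, reported as such
  expect_message(p0 <- penetrance(rep(FALSE, 5), rep("case", 5)), "undefined")
  expect_true(is.na(p0$penetrance))
})

test_that("simulated penetrance tracks the planted conditional risk", {
  # no exclusion band or missing labs, so the labeled fraction among
  # carriers estimates the marginal carrier risk directly
  cfg <- small_config(n1 = 6000, n2 = 2000, seed = 23,
                      excluded_band_rate = 0, missing_creatinine_rate = 0,
                      rrt_rate = 0)
  co <- simulate_cohort(cfg)
  tr <- co$truth$participants
  carrier <- tr$dom_adpkd_M1
  # planted conditional risk from the generative model itself (oracle)
  p <- penetrance(carrier, tr$label)
  planted <- mean(tr$case[carrier])
  # only the ~1% miscoded controls leave the denominator
  expect_lt(abs(p$penetrance - planted), 0.02)
  # and the planted value sits in the plausible range for beta_c = log(17)
  expect_gt(p$penetrance, 0.15)
  expect_lt(p$penetrance, 0.6)
})
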