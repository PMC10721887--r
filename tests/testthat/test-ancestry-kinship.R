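# LD pruning, PC projection, random-forest ancestry, KING kinship

test_that("pruning removes one of a perfectly correlated pair, keeps independents", {
  set.seed(41)
  x <- rbinom(500, 2, 0.4)
  dos <- cbind(a = x, b = x, c = rbinom(500, 2, 0.4))
  kept <- ld_prune(dos, window = 10, step = 5)
  expect_true("a" %in% kept)        # the later duplicate is dropped
  expect_false("b" %in% kept)
  expect_true("c" %in% kept)
  # mutually independent variants: all kept
  ind <- sapply(1:20, function(i) rbinom(2000, 2, 0.5))
  colnames(ind) <- sprintf("i%02d", 1:20)
  expect_equal(ld_prune(ind, window = 20, step = 5), colnames(ind))
  # monomorphic variants removed first with a warning
  expect_warning(ld_prune(cbind(mono = rep(1, 100), poly = rbinom(100, 2, .5)),
                          window = 5, step = 1), "monomorphic")
})

test_that("pruned output passes a brute-force all-pairs r^2 audit", {
  cfg <- small_config(seed = 3)
  co <- simulate_cohort(cfg)
  dos <- co$dosages
  w <- 40L; s <- 10L; thr <- 0.05
  kept <- suppressWarnings(ld_prune(dos, window = w, step = s,
                                    r2_threshold = thr))
  pos <- match(kept, colnames(dos))
  # exhaustive check: every kept pair inside any window obeys the bound
  for (i in seq_along(pos)) {
    near <- which(abs(pos - pos[i]) < w & pos > pos[i])
    for (j in near) {
      r2 <- cor(dos[, pos[i]], dos[, pos[j]])^2
      expect_lte(r2, thr + 1e-12)
    }
  }
  expect_gt(length(kept), 10)
})

test_that("projection reproduces reference PCs and is sign-invariant", {
  cfg <- small_config(seed = 9)
  panel <- simulate_reference_panel(cfg)
  proj <- project_pcs(panel$dosages, panel$dosages, n_pcs = 5)
  # projecting the reference onto itself reproduces its PCs exactly
  expect_equal(abs(proj$cohort_pcs), abs(proj$ref_pcs), tolerance = 1e-8)
  # two simulated clusters land with their own group
  lab <- panel$labels
  d1 <- apply(proj$ref_pcs[, 1:4], 2, function(pc)
    abs(mean(pc[lab == "EUR"]) - mean(pc[lab == "AFR"])))
  expect_gt(max(d1), 1)   # at least one PC separates the groups
  expect_error(project_pcs(panel$dosages[, 1:50], panel$dosages[, 1:50]),
               "fewer than 100")
})

test_that("random forest assigns well-separated ancestries accurately", {
  cfg <- small_config(seed = 15)
  co <- simulate_cohort(cfg)
  panel <- co$reference_panel
  pca_cols <- setdiff(colnames(panel$dosages), co$weights$variant_id)
  pruned <- suppressWarnings(ld_prune(panel$dosages[, pca_cols, drop = FALSE]))
  proj <- project_pcs(panel$dosages[, pruned, drop = FALSE],
                      co$dosages[, pruned, drop = FALSE])
  cls <- classify_ancestry(proj$ref_pcs, panel$labels, proj$cohort_pcs,
                           seed = 99)
  expect_gt(cls$holdout_accuracy, 0.95)
  truth <- co$truth$participants$ancestry
  expect_gt(mean(cls$assignments$ancestry == truth), 0.95)
  # sign flip of a PC leaves assignments unchanged
  flip <- proj$cohort_pcs; flip[, 1] <- -flip[, 1]
  ref_flip <- proj$ref_pcs; ref_flip[, 1] <- -ref_flip[, 1]
  cls2 <- classify_ancestry(ref_flip, panel$labels, flip, seed = 99)
  # forests are not exactly mirror-symmetric at split midpoints, so allow
  # a handful of boundary samples to move
  expect_gt(mean(cls2$assignments$ancestry == cls$assignments$ancestry), 0.99)
  # a sample at a cluster centroid gets that label with high probability;
  # a point far from every cluster is flagged uncertain
  centroid <- t(colMeans(proj$ref_pcs[panel$labels == "AFR", , drop = FALSE]))
  far <- matrix(apply(proj$ref_pcs, 2, max) * 3, 1)
  cls3 <- classify_ancestry(proj$ref_pcs, panel$labels,
                            rbind(centroid, far), seed = 99)
  expect_equal(cls3$assignments$ancestry[1], "AFR")
  expect_gt(cls3$assignments$probability[1], 0.9)
})

test_that("reference panel precondition errors fire", {
  cfg <- small_config()
  expect_error(simulate_reference_panel(cfg, groups = "EUR"),
               "at least 2 ancestry groups")
  cfg2 <- small_config()
  cfg2$panel_n["EUR"] <- 30
  expect_error(simulate_reference_panel(cfg2),
               "at least 50 samples per group")
})

test_that("KING kinship separates duplicates, relatives, and unrelateds", {
  set.seed(77)
  m <- 800
  p <- runif(m, 0.1, 0.9)
  hap <- function() rbinom(m, 1, p)
  g_unrel1 <- hap() + hap()
  g_unrel2 <- hap() + hap()
  shared <- hap()
  g_parent <- shared + hap()
  g_child <- shared + hap()      # one IBD haplotype: first-degree-ish
  dos <- rbind(A = g_unrel1, B = g_unrel1,      # duplicate pair
               C = g_parent, D = g_child,       # related pair
               E = g_unrel2)
  kin <- king_kinship(dos)
  k <- function(i, j) kin$kinship[(kin$id1 == i & kin$id2 == j) |
                                    (kin$id1 == j & kin$id2 == i)]
  expect_gt(k("A", "B"), 0.45)
  expect_lt(abs(k("C", "D") - 0.25), 0.08)
  expect_lt(k("A", "E"), 0.0442)
  expect_lt(k("B", "E"), 0.0442)

  # duplicated sample: exactly one of the pair is dropped
  kept <- exclude_related(kin, rownames(dos), threshold = 0.0442)
  expect_false(all(c("A", "B") %in% kept))
  expect_true(any(c("A", "B") %in% kept))
  expect_true("E" %in% kept)

  # triad A-B, B-C related: dropping B suffices (greedy minimality)
  tri <- data.frame(id1 = c("A", "B"), id2 = c("B", "C"),
                    kinship = c(0.3, 0.3), stringsAsFactors = FALSE)
  expect_setequal(exclude_related(tri, c("A", "B", "C")), c("A", "C"))

  # idempotence: re-excluding the kept set changes nothing
  kin_kept <- kin[kin$id1 %in% kept & kin$id2 %in% kept, ]
  expect_setequal(exclude_related(kin_kept, kept), kept)
})

test_that("simulated unrelateds survive the 0.0442 screen", {
  set.seed(101)
  m <- 8000   # enough markers that estimator noise stays inside the threshold
  p <- runif(m, 0.1, 0.9)
  dos <- t(replicate(25, rbinom(m, 2, p)))
  rownames(dos) <- sprintf("u%02d", 1:25)
  kin <- king_kinship(dos)
  expect_equal(exclude_related(kin, rownames(dos)), rownames(dos))
})
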