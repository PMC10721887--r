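# scoring, P+T selection, ancestry/APOL1 calibration, tertiles

test_that("raw score is the weighted dosage sum with sum-mode missingness", {
  dos <- matrix(c(0, 1, 2), 1, 3,
                dimnames = list("s1", c("v1", "v2", "v3")))
  w <- data.frame(variant_id = c("v1", "v2", "v3"), effect_allele = "A",
                  weight = c(0.1, -0.2, 0.3))
  expect_equal(as.numeric(gps_score(dos, w)), 0 * 0.1 + 1 * -0.2 + 2 * 0.3)
  # all-zero weights
  expect_equal(as.numeric(gps_score(dos, transform(w, weight = 0))), 0)
  # linearity in the weights
  expect_equal(as.numeric(gps_score(dos, transform(w, weight = weight * 3))),
               3 * as.numeric(gps_score(dos, w)))
  # missing dosage contributes 0 in sum mode, the variant mean in mean mode
  dos2 <- rbind(dos, s2 = c(NA, 1, 1))
  expect_equal(as.numeric(gps_score(dos2, w))[2], -0.2 + 0.3)
  expect_equal(as.numeric(gps_score(dos2, w, missing = "mean"))[2],
               0 * 0.1 + 1 * -0.2 + 1 * 0.3)
  expect_error(gps_score(dos, rbind(w, w[1, ])), "duplicate")
})

test_that("allele flips leave the score rank order unchanged", {
  set.seed(19)
  dos <- matrix(rbinom(500, 2, 0.4), 50, 10,
                dimnames = list(NULL, sprintf("v%02d", 1:10)))
  w <- data.frame(variant_id = colnames(dos), effect_allele = "A",
                  weight = rnorm(10))
  s1 <- gps_score(dos, w)
  flip <- c(1, 4, 7)
  dos2 <- dos; dos2[, flip] <- 2 - dos2[, flip]
  w2 <- w; w2$weight[flip] <- -w2$weight[flip]
  s2 <- gps_score(dos2, w2)
  # flipped orientation shifts every score by a constant
  expect_equal(stats::cor(s1, s2), 1, tolerance = 1e-12)
  expect_equal(order(s1), order(s2))
})

test_that("unmatched weights are counted; majority unmatched errors", {
  dos <- matrix(0, 2, 2, dimnames = list(NULL, c("v1", "v2")))
  w3 <- data.frame(variant_id = c("v1", "v2", "zz"), effect_allele = "A",
                   weight = 1)
  expect_equal(attr(gps_score(dos, w3), "n_unmatched"), 1L)
  w4 <- data.frame(variant_id = c("v1", "x", "y", "z"), effect_allele = "A",
                   weight = 1)
  expect_error(gps_score(dos, w4), "unmatched")
})

test_that("P+T keeps the smaller-p member of correlated pairs", {
  set.seed(29)
  x <- rbinom(400, 2, 0.5)
  dos <- cbind(v1 = x, v2 = x, v3 = rbinom(400, 2, 0.5))
  ss <- data.frame(variant_id = c("v1", "v2", "v3"),
                   beta = c(0.2, 0.5, -0.1), p = c(0.01, 0.001, 0.02))
  out <- pt_clump(ss, dos)
  expect_setequal(out$variant_id, c("v2", "v3"))   # v2 wins on p
  expect_equal(out$weight[out$variant_id == "v2"], 0.5)  # betas unchanged
  # all p above the threshold -> empty table
  expect_equal(nrow(pt_clump(transform(ss, p = 0.5), dos)), 0)
})

test_that("P+T output passes a brute-force pairwise r^2 audit", {
  cfg <- small_config(seed = 21)
  co <- simulate_cohort(cfg)
  dos <- co$dosages[, 1:100]
  set.seed(22)
  ss <- data.frame(variant_id = colnames(dos), beta = rnorm(100, 0, 0.1),
                   p = runif(100, 0, 0.06))
  out <- pt_clump(ss, dos, r2_max = 0.2, p_max = 0.03, window = 50)
  expect_true(all(out$p <= 0.03))
  pos <- match(out$variant_id, colnames(dos))
  for (i in seq_along(pos)) {
    for (j in which(abs(pos - pos[i]) <= 50 & pos > pos[i])) {
      expect_lte(cor(dos[, pos[i]], dos[, pos[j]])^2, 0.2 + 1e-12)
    }
  }
})

test_that("ancestry adjustment removes planted group mean differences", {
  set.seed(33)
  n <- 2000
  grp <- rep(c(0, 1), each = n)           # two groups, means differ by 1.5
  pc <- cbind(PC1 = grp + rnorm(2 * n, 0, 0.05),
              PC2 = rnorm(2 * n, 0, 0.05))
  raw <- 1.5 * grp + rnorm(2 * n, 0, sqrt(1 + grp))  # variance differs too
  ref <- sample(2 * n, 1500)
  adj <- ancestry_adjust(raw[-ref], pc[-ref, ], raw[ref], pc[ref, ])
  m0 <- mean(adj$cohort[grp[-ref] == 0]); m1 <- mean(adj$cohort[grp[-ref] == 1])
  expect_lt(abs(m0 - m1), 0.05 * 3)       # group means aligned
  s0 <- sd(adj$cohort[grp[-ref] == 0]); s1 <- sd(adj$cohort[grp[-ref] == 1])
  expect_lt(abs(s0 - s1), 0.15)           # variances aligned
  # adjusted reference: mean ~ 0, sd ~ 1 overall and per group
  expect_lt(abs(mean(adj$reference)), 0.05)
  expect_lt(abs(sd(adj$reference) - 1), 0.05)
  # PCs carrying no information -> adjustment ~ global standardization
  pc_null <- matrix(rnorm(4 * n), 2 * n, 2, dimnames = list(NULL, c("PC1", "PC2")))
  raw2 <- rnorm(2 * n)
  adj2 <- ancestry_adjust(raw2[-ref], pc_null[-ref, ], raw2[ref],
                          pc_null[ref, ])
  glob <- (raw2[-ref] - mean(raw2[ref])) / sd(raw2[ref])
  expect_gt(cor(adj2$cohort, glob), 0.999)
  expect_error(ancestry_adjust(raw2[1:5], pc_null[1:5, ], raw2[1:15],
                               pc_null[1:15, ]), "reference too small")
})

test_that("APOL1 risk genotype is recessive over G1/G2 combinations", {
  g1 <- c(2, 0, 1, 1, 0, 0)
  g2 <- c(0, 2, 1, 0, 1, 0)
  expect_equal(apol1_risk_genotype(g1, g2),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("APOL1 residualization decorrelates score and risk genotype", {
  set.seed(51)
  n <- 50000
  risk <- runif(n) < 0.05
  adj <- rnorm(n) + 0.4 * risk          # contaminated score
  out <- apol1_adjust_standardize(adj, risk)
  expect_lt(abs(cor(out$score_standardized, risk)), 0.01)
  expect_equal(mean(out$score_standardized), 0, tolerance = 1e-8)
  expect_equal(sd(out$score_standardized), 1, tolerance = 1e-8)
  # missing APOL1 treated as non-risk, with a message
  risk2 <- risk; risk2[1:100] <- NA
  expect_message(apol1_adjust_standardize(adj, risk2), "missing APOL1")
})

test_that("tertile cuts match the analytic normal tertiles", {
  set.seed(61)
  x <- rnorm(100000)
  t3 <- assign_tertiles(x)
  cuts <- c(max(x[t3 == 1]), max(x[t3 == 2]))
  expect_equal(cuts, c(qnorm(1 / 3), qnorm(2 / 3)), tolerance = 0.02)
  # partition: sizes equal up to rounding
  expect_lt(diff(range(table(t3))), 5)
  # three distinct values -> one per tertile
  expect_equal(sort(assign_tertiles(c(5, -1, 2))), c(1, 2, 3),
               ignore_attr = TRUE)
  expect_equal(assign_tertiles(c(5, -1, 2)), c(3, 1, 2))
  expect_error(assign_tertiles(rep(1, 10)), "degenerate")
  expect_error(assign_tertiles(c(1, 2)), "at least 3")
})
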