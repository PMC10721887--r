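# logistic effects, meta-analysis, interaction, discrimination metrics

test_that("covariate-free 2x2 logistic fit reproduces the closed-form OR", {
  d <- data.frame(case = rep(c(1, 0, 1, 0), c(10, 90, 1, 99)),
                  carrier = rep(c(TRUE, FALSE), c(100, 100)))
  eff <- fit_carrier_model(d, covariates = character(0))
  expect_equal(eff$or, (10 * 99) / (90 * 1), tolerance = 1e-6)
  expect_equal(eff$logOR, log(11), tolerance = 1e-6)
  expect_equal(eff$n_cases, 10)
  expect_equal(eff$n_controls, 90)
})

test_that("fixed-effects pooling matches the hand inverse-variance oracle", {
  m <- meta_fixed(c(0.5878, 0.3365), c(0.0113, 0.0146))
  # hand computation: w = 1/se^2; pooled = sum(w b)/sum(w)
  expect_equal(m$logOR, 0.4936574, tolerance = 1e-7)
  expect_equal(m$se, sqrt(1 / (1 / 0.0113^2 + 1 / 0.0146^2)),
               tolerance = 1e-10)
  expect_equal(m$or, 1.638, tolerance = 1e-3)
  # single estimate -> identity
  m1 <- meta_fixed(0.3, 0.1)
  expect_equal(m1$logOR, 0.3)
  expect_equal(m1$se, 0.1)
  # two equal estimates -> same estimate, smaller SE
  m2 <- meta_fixed(c(0.3, 0.3), c(0.1, 0.1))
  expect_equal(m2$logOR, 0.3)
  expect_equal(m2$se, 0.1 / sqrt(2))
  # order invariance and between-bounds
  set.seed(71)
  for (i in 1:20) {
    b <- rnorm(3); s <- runif(3, 0.05, 0.5)
    pa <- meta_fixed(b, s); pb <- meta_fixed(rev(b), rev(s))
    expect_equal(pa$logOR, pb$logOR)
    expect_gte(pa$logOR, min(b)); expect_lte(pa$logOR, max(b))
  }
  expect_warning(m3 <- meta_fixed(c(0.2, 0.5), c(0.1, Inf)), "dropped")
  expect_equal(m3$logOR, 0.2)
  expect_error(suppressWarnings(meta_fixed(0.2, Inf)), "no usable")
})

test_that("pooling agrees with an independent meta-analysis package", {
  skip_if_not_installed("metafor")
  set.seed(73)
  for (i in 1:10) {
    b <- rnorm(4, 0.4, 0.3); s <- runif(4, 0.05, 0.4)
    ours <- meta_fixed(b, s)
    ref <- metafor::rma(yi = b, sei = s, method = "FE")
    expect_equal(ours$logOR, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(ours$se, as.numeric(ref$se), tolerance = 1e-10)
  }
})

test_that("Firth penalization returns finite estimates under separation", {
  # complete separation: ML diverges, Firth does not
  d <- data.frame(y = c(rep(0, 20), rep(1, 20)),
                  x = c(rep(0, 20), rep(1, 20)))
  X <- cbind(1, d$x)
  ff <- firth_logistic(X, d$y)
  expect_true(ff$converged)
  expect_true(all(is.finite(ff$coefficients)))
  expect_lt(abs(ff$coefficients[2]), 10)
  # on a well-behaved problem Firth is close to ML
  set.seed(83)
  n <- 2000
  x <- rnorm(n); y <- rbinom(n, 1, plogis(-1 + 0.7 * x))
  fit <- glm(y ~ x, family = binomial())
  ff2 <- firth_logistic(cbind(1, x), y)
  expect_equal(unname(ff2$coefficients[2]), unname(coef(fit)[2]),
               tolerance = 0.02)
})

test_that("per-SD scaling uses the control-group SD and is scale-invariant", {
  set.seed(87)
  d <- sim_outcome_frame(20000, beta_carrier = log(5), beta_gps = log(1.7),
                         carrier_freq = 0.02)
  g1 <- fit_gps_model_by_stratum(d, covariates = c("age", "sex", "diabetes"))
  d2 <- transform(d, score = score * 2)   # doubling the scale
  g2 <- fit_gps_model_by_stratum(d2, covariates = c("age", "sex", "diabetes"))
  expect_equal(g1$logOR, g2$logOR, tolerance = 1e-8)   # per-SD OR unchanged
  expect_equal(g1$stratum, c("per_sd_noncarrier", "per_sd_carrier"))
  # noncarrier recovery near the planted value
  nc <- g1[g1$stratum == "per_sd_noncarrier", ]
  expect_lt(abs(nc$logOR - log(1.7)), 1.96 * nc$se + 0.05)
})

test_that("shuffled scores give a null per-SD effect", {
  set.seed(91)
  d <- sim_outcome_frame(8000, beta_carrier = 0, beta_gps = log(1.7),
                         carrier_freq = 0.5)
  d$score <- sample(d$score)
  g <- fit_gps_model_by_stratum(d, covariates = c("age", "sex"))
  expect_true(all(abs(g$logOR) < 3 * g$se + 0.05))
})

test_that("tertile model uses the noncarrier middle tertile as reference", {
  set.seed(93)
  d <- sim_outcome_frame(30000, beta_carrier = log(8), beta_gps = log(2),
                         carrier_freq = 0.03)
  d$tertile <- assign_tertiles(d$score)
  out <- tertile_or(d, covariates = c("age", "sex"))
  expect_equal(nrow(out), 6)
  ref <- out[out$stratum == "noncarrier_T2", ]
  expect_equal(ref$or, 1)
  # planted monotone model -> monotone carrier tertile ORs
  ors <- out$or[match(paste0("carrier_T", 1:3), out$stratum)]
  expect_true(ors[1] < ors[2] && ors[2] < ors[3])
  # noncarrier gradient follows the score too
  expect_lt(out$or[out$stratum == "noncarrier_T1"], 1)
  expect_gt(out$or[out$stratum == "noncarrier_T3"], 1)
  # an empty carrier tertile is reported as NA, not dropped
  d2 <- d[!(d$carrier & d$tertile == 1), ]
  out2 <- suppressWarnings(tertile_or(d2, covariates = c("age", "sex")))
  expect_equal(nrow(out2), 6)
  expect_true(is.na(out2$or[out2$stratum == "carrier_T1"]))
})

test_that("null tertile gradient stays flat", {
  set.seed(97)
  d <- sim_outcome_frame(20000, beta_carrier = log(8), beta_gps = 0,
                         carrier_freq = 0.05)
  d$tertile <- assign_tertiles(d$score)
  out <- tertile_or(d, covariates = c("age", "sex"))
  cr <- out[match(paste0("carrier_T", 1:3), out$stratum), ]
  # all carrier tertiles within each other's CIs
  expect_lt(max(cr$logOR) - min(cr$logOR),
            1.96 * sqrt(max(cr$se)^2 + min(cr$se)^2))
})

test_that("interaction test finds planted products and respects the null", {
  set.seed(101)
  d <- sim_outcome_frame(40000, beta_carrier = log(5), beta_gps = log(1.5),
                         beta_int = log(1.5), carrier_freq = 0.05)
  it <- interaction_test(d, covariates = c("age", "sex", "diabetes"))
  expect_lt(abs(it$estimate - log(1.5)), 1.96 * it$se + 0.05)
  expect_lt(it$p, 0.05)   # large n, strong product: detected
})

test_that("estimates are invariant to affine covariate relabeling", {
  set.seed(103)
  d <- sim_outcome_frame(10000, beta_carrier = log(4), beta_gps = log(1.5),
                         carrier_freq = 0.05)
  e1 <- fit_carrier_model(d, covariates = c("age", "sex"))
  d2 <- transform(d, age = (age - 50) / 10)
  e2 <- fit_carrier_model(d2, covariates = c("age", "sex"))
  expect_equal(e1$logOR, e2$logOR, tolerance = 1e-8)
  expect_equal(e1$se, e2$se, tolerance = 1e-8)
})

test_that("discrimination metrics behave at the null and at separation", {
  set.seed(107)
  n <- 4000
  d <- data.frame(case = rbinom(n, 1, 0.3), score = rnorm(n),
                  age = runif(n, 40, 70),
                  sex = sample(c("female", "male"), n, TRUE))
  pm <- performance_metrics(d, covariates = c("age", "sex"))
  expect_lt(abs(pm$auc_crude - 0.5), 0.03)
  expect_lt(abs(pm$incremental_r2), 0.01)
  # perfectly separating score
  d2 <- d; d2$score <- d2$case + 0.001 * rnorm(n)
  pm2 <- suppressWarnings(performance_metrics(d2, covariates = c("age", "sex")))
  expect_equal(pm2$auc_crude, 1.0, tolerance = 1e-6)
  expect_error(performance_metrics(transform(d, case = 1),
                                   covariates = "age"), "both cases")
})

test_that("planted logistic AUROC matches the binormal approximation", {
  set.seed(109)
  n <- 30000
  beta <- log(2)
  score <- rnorm(n)
  y <- rbinom(n, 1, plogis(qlogis(0.1) + beta * score))
  d <- data.frame(case = y, score = score, age = 50, sex = "female")
  pm <- performance_metrics(d, covariates = character(0))
  # binormal oracle: AUC ~ pnorm(delta / sqrt(2)) with delta the
  # case-control mean separation of the score
  delta <- mean(score[y == 1]) - mean(score[y == 0])
  s2 <- (var(score[y == 1]) + var(score[y == 0]))
  expect_equal(pm$auc_crude, pnorm(delta / sqrt(s2)), tolerance = 0.01)
})
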