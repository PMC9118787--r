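test_that("fit_crosslag trivial structures", {
  # all cross-time and cross-variable correlations zero
  m0 <- diag(4)
  m0[1, 2] <- m0[2, 1] <- 0.3
  fit <- fit_crosslag(m0, 426)
  expect_equal(fit$rho1, 0); expect_equal(fit$rho2, 0)
  expect_equal(fit$r1, 0); expect_equal(fit$r2, 0)
  expect_equal(fit$r3, 0.3)

  # r3 = 0: paths reduce to simple correlations
  m <- implied_crosslag_corr(0.1, 0.15, 0.5, 0.4, 0)
  fit <- fit_crosslag(m, 426)
  expect_equal(fit$rho1, m[2, 3])
  expect_equal(fit$rho2, m[1, 4])
  expect_equal(fit$r1, m[1, 3])
  expect_equal(fit$r2, m[2, 4])

  bad <- diag(4); bad[1, 2] <- bad[2, 1] <- 1
  expect_error(fit_crosslag(bad, 100), "collinear")
  npsd <- matrix(0.99, 4, 4) * (1 - diag(4)) + diag(4)
  npsd[1, 2] <- npsd[2, 1] <- -0.99
  expect_error(fit_crosslag(npsd, 100), "positive semidefinite")
})

test_that("closed-form paths and SEs equal OLS on standardized data", {
  set.seed(40)
  X <- draw_crosslag_data(426, 0.05, 0.15, 0.6, 0.5, 0.2)
  S <- cor(X)
  fit <- fit_crosslag(S, 426)
  Z <- scale(X)
  m1 <- lm(Z[, 3] ~ Z[, 1] + Z[, 2])
  m2 <- lm(Z[, 4] ~ Z[, 1] + Z[, 2])
  expect_equal(fit$r1, unname(coef(m1)[2]), tolerance = 1e-8)
  expect_equal(fit$rho1, unname(coef(m1)[3]), tolerance = 1e-8)
  expect_equal(fit$rho2, unname(coef(m2)[2]), tolerance = 1e-8)
  expect_equal(fit$r2, unname(coef(m2)[3]), tolerance = 1e-8)
  expect_equal(fit$se_rho1, summary(m1)$coefficients[3, 2], tolerance = 1e-8)
  expect_equal(fit$se_rho2, summary(m2)$coefficients[2, 2], tolerance = 1e-8)
  expect_equal(fit$p_rho2, summary(m2)$coefficients[2, 4], tolerance = 1e-8)
})

test_that("fit indices behave at the boundaries", {
  set.seed(41)
  X <- draw_crosslag_data(300, 0, 0.1, 0.5, 0.5, 0.1)
  S <- cor(X)
  sat <- fit_crosslag(S, 300, saturated = TRUE)
  expect_equal(sat$srmr, 0)
  expect_equal(sat$cfi, 1)
  expect_equal(sat$T, 0)
  fit <- fit_crosslag(S, 300)
  expect_gte(fit$srmr, 0)
  expect_true(fit$cfi >= 0 && fit$cfi <= 1)
  if (fit$T <= fit$df) expect_equal(fit$cfi, 1)
})

test_that("bh_fdr implements the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.03), 0.03)
  set.seed(42)
  p <- runif(50)
  q <- bh_fdr(p)
  o <- order(p)
  expect_equal(q[o], sort(q))          # permutation equivariance
  expect_equal(q, p.adjust(p, "BH"))   # reference implementation
  expect_true(all(q >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("screen_features flags by family and survives per-feature failure", {
  tr <- synthetic_truth(n_participants = 150, n_species = 12, rho2 = 0.3,
                        seed = 43)
  cohort <- assemble_cohort(generate_cohort(tr))
  res <- screen_features(cohort, alpha_fdr = 0.25)
  expect_equal(nrow(res), length(cohort$feature_ids))
  expect_equal(res$q_rho1, p.adjust(res$p_rho1, "BH"))
  expect_equal(res$q_rho2, p.adjust(res$p_rho2, "BH"))
  expect_identical(res$sig_rho2, res$q_rho2 < 0.25)

  # a constant feature cannot be Z-scored: warned and dropped from the family
  broken <- cohort
  broken$features_baseline[, 2] <- 0
  expect_warning(res2 <- screen_features(broken), "failed")
  expect_equal(nrow(res2), length(cohort$feature_ids) - 1)
  expect_false(cohort$feature_ids[2] %in% res2$feature_id)
})

test_that("sex_heterogeneity computes Cochran-Q", {
  resf <- data.frame(feature_id = c("a", "b"), rho2 = c(0.5, 0.2),
                     se_rho2 = c(0.1, 0.1))
  resm <- data.frame(feature_id = c("a", "b"), rho2 = c(-0.5, 0.2),
                     se_rho2 = c(0.1, 0.1))
  het <- sex_heterogeneity(resf, resm)
  # hand-computed: w = (100, 100), pooled = 0, Q = 100(0.5^2) + 100(0.5^2)
  # = (b1 - b2)^2 / (se1^2 + se2^2) = 1 / 0.02 = 50
  expect_equal(het$Q[het$feature_id == "a"], 50)
  expect_equal(het$Q[het$feature_id == "b"], 0)
  expect_equal(het$p_heterogeneity[het$feature_id == "b"], 1)
  swapped <- sex_heterogeneity(resm, resf)
  expect_equal(swapped$Q, het$Q)
  resm2 <- resm[1, ]
  expect_warning(sex_heterogeneity(resf, resm2), "skipped")
})

test_that("WC sensitivity tracks BMI when WC is an affine transform", {
  tr <- synthetic_truth(n_participants = 150, n_species = 15, rho2 = 0.25,
                        seed = 44)
  cohort <- assemble_cohort(generate_cohort(tr))
  cohort$data$baseline_wc <- 2 * cohort$data$baseline_bmi + 30
  cohort$data$followup_wc <- 2 * cohort$data$followup_bmi + 30
  out <- sensitivity_wc(cohort)
  expect_gt(out$cor_rho1, 0.999)
  expect_gt(out$cor_rho2, 0.999)
  # scripted double-run oracle
  direct_wc <- screen_features(cohort, exposure = "wc")
  expect_equal(out$wc$rho2, direct_wc$rho2)
})
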