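make_test_cohort <- function(n = 250, n_species = 15, seed = 50, ...) {
  assemble_cohort(generate_cohort(synthetic_truth(
    n_participants = n, n_species = n_species, seed = seed, ...)))
}

test_that("fit_pattern_model recovers an injected group shift and matches OLS", {
  cohort <- make_test_cohort(400, seed = 51)
  fid <- mediator_id(cohort)
  fi <- match(fid, cohort$feature_ids)
  pat <- weight_change_pattern(cohort$data$baseline_bmi,
                               cohort$data$followup_bmi)
  shift <- -0.5 * sd(cohort$features_followup[, fi])
  cohort$features_followup[, fi] <- cohort$features_followup[, fi] +
    shift * (pat == "stable_adiposity")
  res <- fit_pattern_model(cohort, fid)
  row <- res[res$term == "stable_adiposity", ]
  expect_lt(row$ci95_low, -0.5 + 0.25)
  expect_gt(row$ci95_high, -0.5 - 0.25)
  expect_lt(row$p, 0.01)

  # normal-equations oracle for all coefficients
  keep <- pat != "excluded_underweight"
  pf <- droplevels(factor(pat[keep], levels = levels(pat)))
  d <- cohort$data[keep, ]
  Xd <- model.matrix(~ pf)[, -1, drop = FALSE]
  C <- cbind(d$baseline_age, as.numeric(d$baseline_sex == "male"),
             d$baseline_smoking, d$baseline_alcohol, d$baseline_education,
             d$baseline_income, d$baseline_physical_activity,
             d$baseline_energy_intake, d$baseline_bristol,
             d$followup_interval,
             zscore(cohort$features_baseline[keep, fi]))
  X <- cbind(1, Xd, C)
  y <- zscore(cohort$features_followup[keep, fi])
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(res$beta, unname(beta[2:(1 + ncol(Xd))]), tolerance = 1e-10)
  expect_equal(res$ci95_high - res$beta,
               res$beta - res$ci95_low, tolerance = 1e-8)
})

test_that("pattern effects vanish when BMI history is shuffled", {
  cohort <- make_test_cohort(300, seed = 52, rho2 = 0)
  set.seed(52)
  perm <- sample(nrow(cohort$data))
  cohort$data$baseline_bmi <- cohort$data$baseline_bmi[perm]
  cohort$data$followup_bmi <- cohort$data$followup_bmi[perm]
  res <- fit_pattern_model(cohort, mediator_id(cohort))
  expect_true(all(abs(res$beta) < 4 * res$se))
})

test_that("pattern_screen applies BH within contrasts", {
  cohort <- make_test_cohort(150, n_species = 8, seed = 53)
  res <- pattern_screen(cohort, cohort$feature_ids[1:5])
  for (ct in unique(res$term)) {
    i <- res$term == ct
    expect_equal(res$fdr[i], p.adjust(res$p[i], "BH"))
  }
})

test_that("mixed model reduces to pooled OLS without between-participant variance", {
  cohort <- make_test_cohort(200, seed = 54, icc_phenotype = 0)
  fid <- mediator_id(cohort)
  fit <- fit_mixed_assoc(cohort, fid, "homa_ir")
  d <- cohort$data
  fi <- match(fid, cohort$feature_ids)
  y <- zscore(log(c(d$baseline_homa_ir, d$followup_homa_ir)))
  m <- zscore(c(cohort$features_baseline[, fi], cohort$features_followup[, fi]))
  C <- rbind(
    cbind(d$baseline_age, as.numeric(d$baseline_sex == "male"),
          d$baseline_smoking, d$baseline_alcohol, d$baseline_education,
          d$baseline_income, d$baseline_physical_activity,
          d$baseline_energy_intake),
    cbind(d$followup_age, as.numeric(d$followup_sex == "male"),
          d$followup_smoking, d$followup_alcohol, d$followup_education,
          d$followup_income, d$followup_physical_activity,
          d$followup_energy_intake))
  ols <- lm(y ~ m + C)
  expect_equal(fit$beta, unname(coef(ols)["m"]), tolerance = 1e-6)
  expect_equal(fit$n_obs, 2 * fit$n_participants)
})

test_that("mixed model fixed effects match a GLS oracle at estimated components", {
  cohort <- make_test_cohort(200, seed = 55, beta_assoc = -0.08)
  fid <- mediator_id(cohort)
  fit <- fit_mixed_assoc(cohort, fid, "homa_ir")
  expect_lt(fit$beta, 0)

  # rebuild the stacked design, then GLS with the lmer-estimated components
  d <- cohort$data
  fi <- match(fid, cohort$feature_ids)
  y <- zscore(log(c(d$baseline_homa_ir, d$followup_homa_ir)))
  m <- zscore(c(cohort$features_baseline[, fi], cohort$features_followup[, fi]))
  Cb <- cbind(d$baseline_age, as.numeric(d$baseline_sex == "male"),
              d$baseline_smoking, d$baseline_alcohol, d$baseline_education,
              d$baseline_income, d$baseline_physical_activity,
              d$baseline_energy_intake)
  Cf <- cbind(d$followup_age, as.numeric(d$followup_sex == "male"),
              d$followup_smoking, d$followup_alcohol, d$followup_education,
              d$followup_income, d$followup_physical_activity,
              d$followup_energy_intake)
  X <- cbind(1, m, rbind(Cb, Cf))
  n <- nrow(d)
  icc <- fit$icc
  # V is block 2x2 per participant: unit diagonal, icc off-diagonal (scaled)
  # invert analytically: for [[1,r],[r,1]], inverse = 1/(1-r^2) [[1,-r],[-r,1]]
  r <- icc
  a <- 1 / (1 - r^2); b <- -r / (1 - r^2)
  # whitened cross-products accumulated over participants
  XtVX <- matrix(0, ncol(X), ncol(X)); XtVy <- numeric(ncol(X))
  for (i in seq_len(n)) {
    idx <- c(i, n + i)
    Xi <- X[idx, , drop = FALSE]; yi <- y[idx]
    Vi_inv <- matrix(c(a, b, b, a), 2)
    XtVX <- XtVX + t(Xi) %*% Vi_inv %*% Xi
    XtVy <- XtVy + t(Xi) %*% Vi_inv %*% yi
  }
  beta_gls <- solve(XtVX, XtVy)
  expect_equal(fit$beta, beta_gls[2], tolerance = 1e-6)
})

test_that("mixed model recovers the generating intraclass correlation", {
  cohort <- make_test_cohort(426, seed = 56, icc_phenotype = 0.5)
  fit <- fit_mixed_assoc(cohort, mediator_id(cohort), "homa_ir")
  expect_lt(abs(fit$icc - 0.5), 0.05)
})

test_that("mixed_screen applies per-phenotype BH families", {
  cohort <- make_test_cohort(120, n_species = 6, seed = 57)
  res <- mixed_screen(cohort, cohort$feature_ids[1:4],
                      phenotypes = c("homa_ir", "hba1c"))
  for (ph in c("homa_ir", "hba1c")) {
    i <- res$phenotype == ph
    expect_equal(res$fdr[i], p.adjust(res$p[i], "BH"))
  }
})

test_that("exposure models: median split, weight group, null diet", {
  cohort <- make_test_cohort(300, seed = 58,
                             mediation = list(alpha = 0, b = 0,
                                              c_prime = 0.3,
                                              outcome = "homa_ir"))
  g <- median_split(cohort$data$baseline_vegetable)
  expect_lte(abs(sum(g == "lower") - sum(g == "higher")), 1)
  expect_error(median_split(rep(1, 10)), "degenerate")

  # injected adiposity -> HOMA-IR effect recovered with positive sign
  res <- fit_exposure_model(cohort, "weight_group", "homa_ir")
  row <- res[res$term == "adiposity", ]
  expect_gt(row$beta, 0)
  expect_lt(row$p, 0.05)

  # null dietary factors: nothing survives FDR at 0.05
  diet <- diet_screen(cohort)
  expect_true(all(diet$fdr >= 0.05))
  expect_equal(nrow(diet), 5 * 4)
})

test_that("compute_vif matches the definition and handles collinearity", {
  # orthogonal polynomial basis: columns mutually orthogonal and zero-mean
  Q <- unclass(poly(1:200, 4))
  expect_equal(unname(compute_vif(Q)), rep(1, 4), tolerance = 1e-10)
  set.seed(59)

  X <- matrix(rnorm(100 * 5), 100, 5)
  X[, 3] <- 0.8 * X[, 1] + 0.3 * X[, 2] + 0.2 * rnorm(100)
  v <- compute_vif(X)
  for (j in 1:5) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-10)
  }
  Xd <- cbind(X, X[, 1])
  expect_true(is.infinite(compute_vif(Xd)[1]))
})
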