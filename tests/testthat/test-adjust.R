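test_that("residualize matches the normal equations and is orthogonal", {
  set.seed(21)
  n <- 100
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("c", 1:8)))
  y <- rnorm(n)
  r <- residualize(y, X)
  Xi <- cbind(1, X)
  beta <- solve(crossprod(Xi), crossprod(Xi, y))
  expect_equal(r, as.vector(y - Xi %*% beta), tolerance = 1e-10)
  for (j in 1:8) expect_lt(abs(cor(r, X[, j])), 1e-8)

  # y exactly linear in covariates -> residual 0
  y2 <- 2 + X %*% runif(8)
  expect_lt(max(abs(residualize(as.vector(y2), X))), 1e-10)

  X2 <- cbind(X, dup = X[, 1] * 2)
  expect_error(residualize(y, X2), "collinear.*dup")
})

test_that("zscore standardizes with the sample SD", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(22)
  x <- rnorm(50, 10, 4)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore(z), z)
  expect_error(zscore(rep(3, 10)), "constant")
})

test_that("partial_corr formula equals the residual-correlation route", {
  set.seed(23)
  n <- 200
  z <- rnorm(n)
  x <- 0.5 * z + rnorm(n)
  y <- -0.3 * z + 0.4 * x + rnorm(n)
  pc <- partial_corr(x, y, z)
  rx <- residualize(x, cbind(z)); ry <- residualize(y, cbind(z))
  expect_equal(pc, cor(rx, ry), tolerance = 1e-12)
  expect_error(partial_corr(z, y, z), "collinear")
  # z independent of x and y: partial correlation close to the raw one
  z2 <- rnorm(5000); x2 <- rnorm(5000); y2 <- 0.5 * x2 + rnorm(5000)
  expect_equal(partial_corr(x2, y2, z2), cor(x2, y2), tolerance = 0.02)
})

test_that("build_panel produces a valid interval-partialled correlation matrix", {
  tr <- synthetic_truth(n_participants = 200, n_species = 30, rho2 = 0.2,
                        seed = 30)
  sim <- generate_cohort(tr)
  cohort <- assemble_cohort(sim)
  pan <- build_panel(cohort, mediator_id(cohort))
  expect_equal(pan$corr, t(pan$corr))
  expect_equal(unname(diag(pan$corr)), rep(1, 4))
  expect_gt(min(eigen(pan$corr, symmetric = TRUE)$values), -1e-10)
  expect_equal(pan$n, nrow(cohort$data))
  # Z columns have mean 0, SD 1 over the analysis set
  expect_lt(max(abs(colMeans(pan$panel[, 1:4]))), 1e-8)
  expect_equal(unname(apply(pan$panel[, 1:4], 2, sd)), rep(1, 4),
               tolerance = 1e-8)

  # independent pipeline oracle: residualize -> zscore -> pairwise partials
  d <- cohort$data
  fi <- match(mediator_id(cohort), cohort$feature_ids)
  conf <- cbind(d$baseline_age, as.numeric(d$baseline_sex == "male"),
                d$baseline_smoking, d$baseline_alcohol, d$baseline_education,
                d$baseline_income, d$baseline_physical_activity,
                d$baseline_energy_intake)
  confb <- cbind(conf, d$baseline_bristol)
  zz <- cbind(zscore(residualize(d$baseline_bmi, conf)),
              zscore(residualize(cohort$features_baseline[, fi], confb)),
              zscore(residualize(d$followup_bmi, conf)),
              zscore(residualize(cohort$features_followup[, fi], confb)))
  oracle <- diag(4)
  for (i in 1:3) for (j in (i + 1):4)
    oracle[i, j] <- oracle[j, i] <-
      partial_corr(zz[, i], zz[, j], d$followup_interval)
  expect_equal(unname(pan$corr), oracle, tolerance = 1e-12)
})

test_that("residualization + Z-scoring is invariant to affine covariate rescaling", {
  tr <- synthetic_truth(n_participants = 150, n_species = 20, seed = 31)
  cohort <- assemble_cohort(generate_cohort(tr))
  pan1 <- build_panel(cohort, mediator_id(cohort))
  cohort2 <- cohort
  cohort2$data$baseline_age <- cohort2$data$baseline_age * 12 + 7
  cohort2$data$baseline_energy_intake <-
    cohort2$data$baseline_energy_intake / 239 - 1
  pan2 <- build_panel(cohort2, mediator_id(cohort2))
  expect_equal(pan2$corr, pan1$corr, tolerance = 1e-10)
})

test_that("build_panel approximates latent correlations when confounding is off", {
  tr <- synthetic_truth(n_participants = 400, n_species = 40,
                        rho2 = 0.2, r3 = 0.15, seed = 32,
                        confounder_effects = list(bmi = numeric(0),
                                                  feature = numeric(0)),
                        zero_inflation = 1)
  sim <- generate_cohort(tr)
  cohort <- assemble_cohort(sim)
  pan <- build_panel(cohort, mediator_id(cohort))
  lat <- cor(sim$latents[, c("B1", "F1", "B2", "F2")])
  expect_lt(max(abs(unname(pan$corr) - unname(lat))), 0.06)
})
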