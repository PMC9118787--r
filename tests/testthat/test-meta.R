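test_that("random_effects_meta: degenerate, hand-computed, and limit cases", {
  two <- random_effects_meta(c(0.4, 0.4), c(0.12, 0.12))
  expect_equal(two$beta_pooled, 0.4)
  expect_equal(two$q, 0)
  expect_equal(two$i2, 0)
  expect_equal(two$tau2, 0)
  expect_equal(two$se_pooled, 0.12 / sqrt(2))

  # hand computation via the DerSimonian-Laird formulas:
  # w = (100, 100); b_FE = 0.2; Q = 100(0.1^2 + 0.1^2) = 2;
  # tau2 = (2 - 1) / (200 - 20000/200) = 0.01
  dl <- random_effects_meta(c(0.3, 0.1), c(0.1, 0.1))
  expect_equal(dl$q, 2, tolerance = 1e-12)
  expect_equal(dl$beta_pooled, 0.2, tolerance = 1e-12)
  expect_equal(dl$tau2, 0.01, tolerance = 1e-12)
  expect_equal(dl$i2, 50, tolerance = 1e-12)

  # tau2 = 0 -> random-effects equals fixed-effect pooling exactly
  b <- c(0.2, 0.21, 0.2); s <- c(0.3, 0.3, 0.3)
  re <- random_effects_meta(b, s)
  w <- 1 / s^2
  expect_equal(re$tau2, 0)
  expect_equal(re$beta_pooled, sum(w * b) / sum(w))

  # I2 and Q invariant to common rescaling of betas and SEs
  sc <- random_effects_meta(10 * c(0.3, 0.1), 10 * c(0.1, 0.1))
  expect_equal(sc$q, dl$q, tolerance = 1e-12)
  expect_equal(sc$i2, dl$i2, tolerance = 1e-12)

  expect_error(random_effects_meta(0.3, 0.1), "at least 2")
  expect_error(random_effects_meta(c(0.3, 0.1), c(0, 0.1)), "positive")
})

test_that("replication_decision enforces all four clauses", {
  disc <- data.frame(feature_id = "a", beta = 0.5, se = 0.1)
  good <- data.frame(feature_id = "a", beta = 0.45, se = 0.12)
  expect_true(replication_decision(disc, good)$replicated)
  # opposite signs: vetoed regardless of p_meta
  flip <- data.frame(feature_id = "a", beta = -0.5, se = 0.01)
  expect_false(replication_decision(disc, flip)$replicated)

  # 10-feature fixture against a brute-force four-clause evaluation
  set.seed(70)
  d10 <- data.frame(feature_id = letters[1:10],
                    beta = rnorm(10, 0.2, 0.3), se = runif(10, 0.05, 0.2))
  r10 <- data.frame(feature_id = letters[1:10],
                    beta = rnorm(10, 0.2, 0.3), se = runif(10, 0.1, 0.4))
  res <- replication_decision(d10, r10)
  for (i in 1:10) {
    m <- random_effects_meta(c(d10$beta[i], r10$beta[i]),
                             c(d10$se[i], r10$se[i]))
    oracle <- m$p_meta < 0.05 && m$p_heterogeneity > 0.05 && m$i2 < 50 &&
      (sign(d10$beta[i]) == sign(r10$beta[i]))
    expect_identical(res$replicated[i], oracle)
  }

  # monotone in precision: shrinking both SEs never flips replicated -> not
  # through the p_meta clause
  shrunk <- replication_decision(
    transform(d10, se = se / 2), transform(r10, se = se / 2))
  gain_only <- res$replicated & shrunk$pass_heterogeneity & shrunk$pass_i2
  expect_true(all(!gain_only | shrunk$pass_p_meta))
})

test_that("replication_regression matches a normal-equations oracle", {
  tr <- synthetic_truth(rho2 = 0.3, seed = 71, n_species = 15)
  rep_sim <- generate_replication_cohort(tr, n = 43)
  cohort <- assemble_cohort(rep_sim, criteria = NULL)
  expect_equal(nrow(cohort$data), 43)
  fid <- mediator_id(cohort)
  res <- replication_regression(cohort, fid)
  d <- cohort$data
  fi <- match(fid, cohort$feature_ids)
  X <- cbind(1, zscore(d$baseline_bmi), d$baseline_age,
             as.numeric(d$baseline_sex == "male"),
             as.numeric(d$baseline_race == "white"),
             d$followup_interval, zscore(cohort$features_baseline[, fi]))
  y <- zscore(cohort$features_followup[, fi])
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(res$beta, beta[2], tolerance = 1e-10)
})

test_that("meta-analysis of shared truth beats discovery alone in power", {
  tr <- synthetic_truth(rho2 = 0.3, seed = 72, n_participants = 150,
                        n_species = 10)
  ord <- vapply(1:30, function(i) {
    disc <- assemble_cohort(generate_cohort(tr, seed = 400 + i))
    repl <- assemble_cohort(generate_replication_cohort(tr, seed = 500 + i),
                            criteria = NULL)
    f <- mediator_id(disc)
    pan <- build_panel(disc, f)
    dfit <- fit_crosslag(pan$corr, pan$n)
    rfit <- replication_regression(repl, f)
    m <- random_effects_meta(c(dfit$rho2, rfit$beta),
                             c(dfit$se_rho2, rfit$se))
    c(p_meta = m$p_meta, p_disc = dfit$p_rho2, rep = m$p_meta < 0.05 &
        m$p_heterogeneity > 0.05 & m$i2 < 50 & m$direction_consistent)
  }, numeric(3))
  expect_lt(median(ord[1, ]), median(ord[2, ]))
  # true-positive replication rate clearly above a null false-positive rate
  null_tr <- synthetic_truth(rho2 = 0, seed = 73, n_participants = 150,
                             n_species = 10)
  null_rep <- vapply(1:30, function(i) {
    disc <- assemble_cohort(generate_cohort(null_tr, seed = 600 + i))
    repl <- assemble_cohort(generate_replication_cohort(null_tr,
                                                        seed = 700 + i),
                            criteria = NULL)
    f <- mediator_id(disc)
    pan <- build_panel(disc, f)
    dfit <- fit_crosslag(pan$corr, pan$n)
    rfit <- replication_regression(repl, f)
    m <- random_effects_meta(c(dfit$rho2, rfit$beta),
                             c(dfit$se_rho2, rfit$se))
    m$p_meta < 0.05 && m$p_heterogeneity > 0.05 && m$i2 < 50 &&
      m$direction_consistent
  }, logical(1))
  expect_gt(mean(ord[3, ]), mean(null_rep))
})
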