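#' Causal mediation of adiposity on insulin resistance through a microbe
#'
#' Linear-model mediation with baseline overweight/obesity as the binary
#' exposure, the follow-up log abundance of one feature as the mediator, and
#' a follow-up insulin-resistance phenotype as the outcome:
#' \itemize{
#'   \item mediator model: `M = a0 + alpha X + phi M_base + gamma' C + e`
#'   \item outcome model: `Y = b0 + c' X + b M + psi Y_base + theta' C + e`
#' }
#' Point estimates are the product-of-coefficients decomposition
#' ACME = alpha b, ADE = c', Total = alpha b + c'. Uncertainty is
#' quasi-Bayesian Monte Carlo: `n_sims` joint draws of each model's
#' coefficients from their estimated sampling normal, percentile 95% CIs,
#' and two-sided p = 2 min(Pr(draw <= 0), Pr(draw >= 0)). The proportion
#' mediated is ACME / Total (signed); its CI uses the draw-wise ratio and is
#' reported only when at least 95% of the Total draws share one sign
#' (otherwise flagged unstable).
#'
#' @param cohort a `paired_cohort` with features attached.
#' @param mediator_feature feature id of the mediator.
#' @param outcome phenotype name (see [fit_mixed_assoc()]); skewed
#'   phenotypes are log-transformed.
#' @param n_sims number of quasi-Bayesian draws (default 1000).
#' @param seed required integer seed; the same seed reproduces the CIs
#'   bit-identically.
#' @param standardize Z-score mediator and outcome (default `TRUE`,
#'   matching the SD-unit reporting convention); set `FALSE` to work on the
#'   raw log scales.
#' @param confounders covariates entering both models; default
#'   [gnhs_confounders()] plus Bristol score and the follow-up interval.
#' @param interaction include an exposure x mediator interaction in the
#'   outcome model; ACME is then reported under both exposure arms
#'   (`acme_control`, `acme_treated`) with their average as `acme`.
#' @return One-row data frame of class `mediation_result` with point
#'   estimates, CIs, p-values, `prop_mediated` (point and draw median),
#'   `prop_ci_stable`, `n_sims`, `seed`, `n`.
#' @export
fit_mediation <- function(cohort, mediator_feature, outcome = "homa_ir",
                          n_sims = 1000, seed, standardize = TRUE,
                          confounders = c(gnhs_confounders(), "bristol"),
                          interaction = FALSE) {
  stopifnot(inherits(cohort, "paired_cohort"))
  stop_if_not(!missing(seed), "an explicit seed is required")
  fi <- match(mediator_feature, cohort$feature_ids)
  stop_if_not(!is.na(fi), "unknown feature: %s", mediator_feature)
  d <- cohort$data
  skewed <- c("homa_ir", "fasting_insulin", "fasting_glucose")
  tr <- function(x) if (outcome %in% skewed) log(x) else x
  sc <- if (standardize) zscore else identity

  x <- as.numeric(is_adiposity(d$baseline_bmi))
  stop_if_not(length(unique(x)) == 2, "exposure is not binary in this cohort")
  M <- sc(cohort$features_followup[, fi])
  M_base <- sc(cohort$features_baseline[, fi])
  Y <- sc(tr(d[[paste0("followup_", outcome)]]))
  Y_base <- sc(tr(d[[paste0("baseline_", outcome)]]))
  C <- cbind(covariate_matrix(cohort, confounders),
             interval = d$followup_interval)

  mdat <- data.frame(M = M, x = x, M_base = M_base, C)
  ydat <- data.frame(Y = Y, x = x, M = M, Y_base = Y_base, C)
  fit_m <- stats::lm(M ~ ., data = mdat)
  fit_y <- if (interaction) stats::lm(Y ~ . + x:M, data = ydat)
           else stats::lm(Y ~ ., data = ydat)

  alpha <- stats::coef(fit_m)["x"]
  b <- stats::coef(fit_y)["M"]
  cprime <- stats::coef(fit_y)["x"]
  bint <- if (interaction) stats::coef(fit_y)["x:M"] else 0

  draws <- with_seed(seed, {
    dm <- MASS::mvrnorm(n_sims, stats::coef(fit_m), stats::vcov(fit_m))
    dy <- MASS::mvrnorm(n_sims, stats::coef(fit_y), stats::vcov(fit_y))
    list(alpha = dm[, "x"], b = dy[, "M"], cprime = dy[, "x"],
         bint = if (interaction) dy[, "x:M"] else rep(0, n_sims))
  })
  acme0_d <- draws$alpha * draws$b
  acme1_d <- draws$alpha * (draws$b + draws$bint)
  acme_d <- (acme0_d + acme1_d) / 2
  ade_d <- draws$cprime
  tot_d <- acme_d + ade_d

  ci <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  pval <- function(v) min(1, 2 * min(mean(v <= 0), mean(v >= 0)))
  acme <- unname(alpha * (b + bint / 2))
  ade <- unname(cprime)
  total <- acme + ade
  stable <- max(mean(tot_d > 0), mean(tot_d < 0)) >= 0.95
  prop_d <- acme_d / tot_d
  prop_ci <- if (stable) ci(prop_d) else c(NA_real_, NA_real_)
  aci <- ci(acme_d); dci <- ci(ade_d); tci <- ci(tot_d)

  out <- data.frame(exposure = "adiposity", mediator_feature = mediator_feature,
                    outcome = outcome,
                    acme = acme, acme_ci_low = aci[1], acme_ci_high = aci[2],
                    p_acme = pval(acme_d),
                    ade = ade, ade_ci_low = dci[1], ade_ci_high = dci[2],
                    p_ade = pval(ade_d),
                    total = total, total_ci_low = tci[1],
                    total_ci_high = tci[2], p_total = pval(tot_d),
                    prop_mediated = if (abs(total) > 1e-12) acme / total else NA_real_,
                    prop_mediated_median = if (stable) stats::median(prop_d) else NA_real_,
                    prop_ci_low = prop_ci[1], prop_ci_high = prop_ci[2],
                    prop_ci_stable = stable,
                    acme_control = unname(alpha * b),
                    acme_treated = unname(alpha * (b + bint)),
                    n_sims = n_sims, seed = seed, n = nrow(d),
                    stringsAsFactors = FALSE)
  class(out) <- c("mediation_result", "data.frame")
  out
}

#' Mediation screen over mediator-outcome pairs
#'
#' Runs [fit_mediation()] over every mediator x outcome combination and
#' applies BH FDR to the ACME p-values within the screened family.
#' Deterministic given `seed` (each pair gets a sub-seed derived from it).
#'
#' @param cohort a `paired_cohort` with features attached.
#' @param mediator_list feature ids to test as mediators.
#' @param outcome_list phenotypes to test as outcomes.
#' @param n_sims,seed,... passed to [fit_mediation()].
#' @return Data frame of [fit_mediation()] rows plus `fdr`.
#' @export
mediation_screen <- function(cohort, mediator_list, outcome_list = "homa_ir",
                             n_sims = 1000, seed, ...) {
  stop_if_not(!missing(seed), "an explicit seed is required")
  stop_if_not(length(mediator_list) >= 1 && length(outcome_list) >= 1,
              "need at least one mediator-outcome pair")
  grid <- expand.grid(m = mediator_list, o = outcome_list,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i)
    fit_mediation(cohort, grid$m[i], grid$o[i], n_sims = n_sims,
                  seed = seed + i, ...))
  res <- do.call(rbind, rows)
  res$fdr <- bh_fdr(res$p_acme)
  rownames(res) <- NULL
  res
}
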