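#' Random-effects meta-analysis (DerSimonian-Laird)
#'
#' Inverse-variance random-effects pooling of k study estimates with the
#' closed-form DerSimonian-Laird between-study variance:
#' fixed weights w_i = 1/se_i^2; Q = sum w_i (b_i - b_FE)^2;
#' tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w)); random weights
#' w*_i = 1/(se_i^2 + tau^2); pooled beta = sum w* b / sum w*,
#' se = 1/sqrt(sum w*); I^2 = max(0, (Q - (k-1))/Q) x 100;
#' p_heterogeneity from chi-square with k-1 df.
#'
#' @param betas numeric study estimates (k >= 2).
#' @param ses positive finite standard errors.
#' @param feature_id optional label.
#' @return One-row data frame of class `meta_result` with `beta_pooled`,
#'   `se_pooled`, `p_meta`, `tau2`, `q`, `p_heterogeneity`, `i2` (percent),
#'   `direction_consistent`, `k`.
#' @export
random_effects_meta <- function(betas, ses, feature_id = NA_character_) {
  k <- length(betas)
  stop_if_not(k >= 2, "need at least 2 studies")
  stop_if_not(length(ses) == k, "length mismatch")
  stop_if_not(all(is.finite(betas)) && all(is.finite(ses)) && all(ses > 0),
              "SEs must be finite and positive")
  w <- 1 / ses^2
  b_fe <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - b_fe)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (ses^2 + tau2)
  beta <- sum(ws * betas) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  i2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  out <- data.frame(feature_id = feature_id, beta_pooled = beta,
                    se_pooled = se,
                    p_meta = 2 * stats::pnorm(-abs(beta / se)),
                    tau2 = tau2, q = Q,
                    p_heterogeneity = stats::pchisq(Q, df = k - 1,
                                                    lower.tail = FALSE),
                    i2 = i2,
                    direction_consistent = all(betas > 0) || all(betas < 0),
                    k = k, stringsAsFactors = FALSE)
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Replication decision rule
#'
#' A discovery association is declared replicated when all four clauses
#' hold: p_meta < 0.05, p_heterogeneity > 0.05, I^2 < 50%, and the same
#' direction of association in both cohorts.
#'
#' @param discovery,replication data frames with `feature_id`, `beta`, `se`
#'   (matched on `feature_id`).
#' @return Data frame with the [random_effects_meta()] columns plus
#'   per-clause pass flags (`pass_p_meta`, `pass_heterogeneity`, `pass_i2`,
#'   `pass_direction`) and `replicated`.
#' @export
replication_decision <- function(discovery, replication) {
  common <- intersect(discovery$feature_id, replication$feature_id)
  stop_if_not(length(common) >= 1, "no shared features")
  d <- discovery[match(common, discovery$feature_id), ]
  r <- replication[match(common, replication$feature_id), ]
  rows <- lapply(seq_along(common), function(i)
    random_effects_meta(c(d$beta[i], r$beta[i]), c(d$se[i], r$se[i]),
                        feature_id = common[i]))
  res <- do.call(rbind, rows)
  res$pass_p_meta <- res$p_meta < 0.05
  res$pass_heterogeneity <- res$p_heterogeneity > 0.05
  res$pass_i2 <- res$i2 < 50
  res$pass_direction <- res$direction_consistent
  res$replicated <- res$pass_p_meta & res$pass_heterogeneity &
    res$pass_i2 & res$pass_direction
  rownames(res) <- NULL
  res
}

#' Replication-cohort prospective regression
#'
#' HMP-style design with the exposure measured at baseline only: OLS of the
#' Z-scored follow-up log abundance on Z-scored baseline BMI, adjusted for
#' age, sex, race (white/not white), follow-up interval, and the Z-scored
#' baseline abundance. Coefficients are standardized (SD outcome per SD
#' exposure).
#'
#' @param cohort a `paired_cohort` (e.g. from
#'   [generate_replication_cohort()]) with features attached.
#' @param feature_id feature to model.
#' @param covariates replication covariate set; default
#'   `c("age", "sex", "race")`.
#' @return One-row data frame with `feature_id`, `beta`, `se`, `ci95_low`,
#'   `ci95_high`, `p`, `n`.
#' @export
replication_regression <- function(cohort, feature_id,
                                   covariates = c("age", "sex", "race")) {
  stopifnot(inherits(cohort, "paired_cohort"))
  fi <- match(feature_id, cohort$feature_ids)
  stop_if_not(!is.na(fi), "unknown feature: %s", feature_id)
  d <- cohort$data
  C <- covariate_matrix(cohort, setdiff(covariates, "race"))
  if ("race" %in% covariates) {
    race <- d$baseline_race
    stop_if_not(!is.null(race), "race column required for the HMP covariate set")
    C <- cbind(C, race_white = as.numeric(race == "white"))
  }
  df <- data.frame(y = zscore(cohort$features_followup[, fi]),
                   bmi = zscore(d$baseline_bmi), C,
                   interval = d$followup_interval,
                   baseline_feature = zscore(cohort$features_baseline[, fi]))
  fit <- stats::lm(y ~ ., data = df)
  out <- extract_lm_terms(fit, "bmi")
  out$term <- NULL
  out$feature_id <- feature_id
  out[, c("feature_id", setdiff(names(out), "feature_id"))]
}

#' Replication screen over features
#'
#' @param cohort replication `paired_cohort` with features attached.
#' @param feature_ids features to model; default all attached.
#' @param ... passed to [replication_regression()].
#' @return Data frame, one row per feature, ready for
#'   [replication_decision()].
#' @export
replication_screen <- function(cohort, feature_ids = cohort$feature_ids, ...) {
  res <- do.call(rbind, lapply(feature_ids, function(f)
    replication_regression(cohort, f, ...)))
  rownames(res) <- NULL
  res
}
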