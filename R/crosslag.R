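#' Cross-lagged panel model from a 4x4 correlation matrix
#'
#' Two-wave, two-variable cross-lagged path model over (BMI1, F1, BMI2, F2):
#' \deqn{BMI_2 = r_1 BMI_1 + \rho_1 F_1 + e_1}
#' \deqn{F_2 = \rho_2 BMI_1 + r_2 F_1 + e_2}
#' with baseline synchronous correlation r3 = corr(BMI1, F1). Because both
#' equations share the same standardized regressors, the maximum-likelihood
#' path estimates have the closed form
#' rho1 = (r_F1,BMI2 - r3 r_BMI1,BMI2) / (1 - r3^2) (and symmetrically for
#' the other three paths), and equal equation-by-equation OLS on any
#' standardized dataset generating the same correlation matrix.
#'
#' Standard errors are normal-theory OLS standard errors of the standardized
#' regressions at sample size `n` (t reference, df = n - 3). Fit indices use
#' the path model with the follow-up disturbance covariance fixed at 0
#' (df = 1): the model-implied matrix equals the sample matrix except the
#' (BMI2, F2) entry; the ML discrepancy is
#' T = (n-1)\[ln|Sigma| - ln|S| + tr(S Sigma^-1) - 4\]; SRMR is the root
#' mean square of the 10 lower-triangle residuals; CFI compares T against
#' the independence baseline (all off-diagonals 0, df = 6).
#'
#' @param corr4 4x4 correlation matrix ordered (BMI1, F1, BMI2, F2), e.g.
#'   from [build_panel()].
#' @param n analysis sample size (> 10).
#' @param feature_id optional label carried into the result.
#' @param saturated if `TRUE`, free the follow-up disturbance covariance
#'   (df = 0): paths and SEs unchanged, T = SRMR = 0, CFI = 1.
#' @return A one-row data frame of class `crosslag_result` with columns
#'   `feature_id`, `rho1`, `se_rho1`, `p_rho1`, `rho2`, `se_rho2`, `p_rho2`,
#'   `r1`, `se_r1`, `p_r1`, `r2`, `se_r2`, `p_r2`, `r3`, `T`, `srmr`, `cfi`,
#'   `df`, `n`.
#' @export
fit_crosslag <- function(corr4, n, feature_id = NA_character_,
                         saturated = FALSE) {
  corr4 <- as.matrix(corr4)
  stop_if_not(all(dim(corr4) == c(4, 4)), "corr4 must be 4x4")
  stop_if_not(max(abs(corr4 - t(corr4))) < 1e-8, "corr4 must be symmetric")
  stop_if_not(max(abs(diag(corr4) - 1)) < 1e-8, "corr4 must have unit diagonal")
  ev <- eigen((corr4 + t(corr4)) / 2, symmetric = TRUE, only.values = TRUE)$values
  stop_if_not(min(ev) > -1e-10, "corr4 is not positive semidefinite")
  stop_if_not(n > 10, "need n > 10")
  r3 <- corr4[1, 2]
  stop_if_not(abs(r3) < 1 - 1e-10, "baseline predictors are collinear (|r3| = 1)")
  den <- 1 - r3^2

  # paths: regression of each follow-up variable on the two baseline ones
  rho1 <- (corr4[2, 3] - r3 * corr4[1, 3]) / den
  r1   <- (corr4[1, 3] - r3 * corr4[2, 3]) / den
  rho2 <- (corr4[1, 4] - r3 * corr4[2, 4]) / den
  r2   <- (corr4[2, 4] - r3 * corr4[1, 4]) / den

  r2_bmi2  <- r1 * corr4[1, 3] + rho1 * corr4[2, 3]    # R^2, BMI2 equation
  r2_feat2 <- rho2 * corr4[1, 4] + r2 * corr4[2, 4]    # R^2, F2 equation
  se_bmi2  <- sqrt(pmax(1 - r2_bmi2, 0) / ((n - 3) * den))
  se_feat2 <- sqrt(pmax(1 - r2_feat2, 0) / ((n - 3) * den))
  pval <- function(b, se) 2 * stats::pt(-abs(b / se), df = n - 3)

  if (saturated) {
    Tstat <- 0; srmr <- 0; cfi <- 1; df <- 0
  } else {
    s24 <- corr4[3, 4]
    sigma24 <- r1 * rho2 + rho1 * r2 + r3 * (r1 * r2 + rho1 * rho2)
    Sigma <- corr4
    Sigma[3, 4] <- Sigma[4, 3] <- sigma24
    Tstat <- (n - 1) * (determinant(Sigma)$modulus -
                          determinant(corr4)$modulus +
                          sum(diag(corr4 %*% solve(Sigma))) - 4)
    Tstat <- max(as.numeric(Tstat), 0)
    srmr <- sqrt((s24 - sigma24)^2 / 10)
    df <- 1
    t_base <- (n - 1) * (-as.numeric(determinant(corr4)$modulus))
    denom <- max(t_base - 6, Tstat - df, 0)
    cfi <- if (denom == 0) 1 else 1 - max(Tstat - df, 0) / denom
  }

  out <- data.frame(feature_id = feature_id,
                    rho1 = rho1, se_rho1 = se_bmi2, p_rho1 = pval(rho1, se_bmi2),
                    rho2 = rho2, se_rho2 = se_feat2, p_rho2 = pval(rho2, se_feat2),
                    r1 = r1, se_r1 = se_bmi2, p_r1 = pval(r1, se_bmi2),
                    r2 = r2, se_r2 = se_feat2, p_r2 = pval(r2, se_feat2),
                    r3 = r3, T = Tstat, srmr = srmr, cfi = cfi, df = df, n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("crosslag_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' q_(i) = min_(j >= i) m p_(j) / j, capped at 1; ties share the q-value of
#' their group.
#'
#' @param p_values numeric p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  stop_if_not(!anyNA(p_values) && all(p_values >= 0 & p_values <= 1),
              "p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  o <- order(p_values, decreasing = TRUE)
  q <- pmin(1, cummin(m / seq(m, 1) * p_values[o]))
  q[order(o)]
}

#' Cross-lagged screen over a feature set
#'
#' Fits the cross-lagged model per feature via [build_panel()] and
#' [fit_crosslag()], then applies BH FDR separately to the rho1 family
#' (feature -> BMI) and the rho2 family (BMI -> feature). Features whose fit
#' fails are recorded with a warning and excluded from the FDR families.
#'
#' @param cohort a `paired_cohort` with features attached.
#' @param feature_ids features to screen; default all attached features.
#' @param alpha_fdr significance threshold on the q-values (default 0.25,
#'   the per-species screen level).
#' @param ... passed to [build_panel()] (`exposure`, `confounders`, ...).
#' @return Data frame, one row per feature, with the [fit_crosslag()]
#'   columns plus `q_rho1`, `q_rho2`, `sig_rho1`, `sig_rho2`.
#' @export
screen_features <- function(cohort, feature_ids = cohort$feature_ids,
                            alpha_fdr = 0.25, ...) {
  stop_if_not(length(feature_ids) >= 1, "no features to screen")
  rows <- lapply(feature_ids, function(f) {
    tryCatch({
      pan <- build_panel(cohort, f, ...)
      fit_crosslag(pan$corr, pan$n, feature_id = f)
    }, error = function(e) {
      warning(sprintf("feature %s failed: %s", f, conditionMessage(e)))
      NULL
    })
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  stop_if_not(length(rows) >= 1, "all feature fits failed")
  res <- do.call(rbind, rows)
  res$q_rho1 <- bh_fdr(res$p_rho1)
  res$q_rho2 <- bh_fdr(res$p_rho2)
  res$sig_rho1 <- res$q_rho1 < alpha_fdr
  res$sig_rho2 <- res$q_rho2 < alpha_fdr
  rownames(res) <- NULL
  res
}

#' Cochran-Q heterogeneity between sex strata
#'
#' Inverse-variance-weighted Cochran-Q test of equality of a coefficient
#' across two strata fits, per feature, with BH FDR across features.
#'
#' @param result_female,result_male [screen_features()] outputs for the two
#'   strata (matched on `feature_id`; unmatched features are skipped with a
#'   warning).
#' @param param which coefficient to compare: `"rho2"` (default) or
#'   `"rho1"`.
#' @return Data frame with `feature_id`, stratum estimates/SEs, `Q`,
#'   `p_heterogeneity`, `q_heterogeneity`.
#' @export
sex_heterogeneity <- function(result_female, result_male, param = c("rho2", "rho1")) {
  param <- match.arg(param)
  common <- intersect(result_female$feature_id, result_male$feature_id)
  missing <- setdiff(union(result_female$feature_id, result_male$feature_id),
                     common)
  if (length(missing) > 0)
    warning("features missing from one stratum skipped: ",
            paste(missing, collapse = ", "))
  stop_if_not(length(common) >= 1, "no features present in both strata")
  f <- result_female[match(common, result_female$feature_id), ]
  m <- result_male[match(common, result_male$feature_id), ]
  beta <- cbind(f[[param]], m[[param]])
  se <- cbind(f[[paste0("se_", param)]], m[[paste0("se_", param)]])
  w <- 1 / se^2
  bbar <- rowSums(w * beta) / rowSums(w)
  Q <- rowSums(w * (beta - bbar)^2)
  p <- stats::pchisq(Q, df = 1, lower.tail = FALSE)
  data.frame(feature_id = common,
             beta_female = beta[, 1], se_female = se[, 1],
             beta_male = beta[, 2], se_male = se[, 2],
             Q = Q, p_heterogeneity = p, q_heterogeneity = bh_fdr(p),
             stringsAsFactors = FALSE)
}

#' Waist-circumference sensitivity analysis
#'
#' Reruns the cross-lagged screen with WC as the adiposity variable and
#' reports the Pearson correlations of the BMI-based and WC-based
#' coefficient vectors.
#'
#' @param cohort a `paired_cohort` with features attached and `wc` metadata.
#' @param feature_ids features to screen; default all.
#' @param ... passed to [screen_features()].
#' @return List with `cor_rho1`, `cor_rho2`, and the two screen tables
#'   (`bmi`, `wc`).
#' @export
sensitivity_wc <- function(cohort, feature_ids = cohort$feature_ids, ...) {
  res_bmi <- screen_features(cohort, feature_ids, exposure = "bmi", ...)
  res_wc <- screen_features(cohort, feature_ids, exposure = "wc", ...)
  common <- intersect(res_bmi$feature_id, res_wc$feature_id)
  b <- res_bmi[match(common, res_bmi$feature_id), ]
  w <- res_wc[match(common, res_wc$feature_id), ]
  list(cor_rho1 = if (length(common) > 2) stats::cor(b$rho1, w$rho1) else NA_real_,
       cor_rho2 = if (length(common) > 2) stats::cor(b$rho2, w$rho2) else NA_real_,
       bmi = res_bmi, wc = res_wc)
}
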