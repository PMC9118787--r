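#' OLS residualization against covariates
#'
#' Residuals of `y` from an ordinary-least-squares fit on the covariates plus
#' an intercept. Residuals are exactly orthogonal to every covariate column.
#'
#' @param y numeric response vector (complete cases only).
#' @param covariate_matrix numeric matrix, one column per covariate (no
#'   intercept column).
#' @return Numeric residual vector.
#' @export
residualize <- function(y, covariate_matrix) {
  X <- cbind(`(Intercept)` = 1, as.matrix(covariate_matrix))
  stop_if_not(!anyNA(y) && !anyNA(X), "complete cases required")
  stop_if_not(length(y) == nrow(X), "length mismatch")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  qr.resid(qx, y)
}

#' Z-score standardization
#'
#' `(x - mean(x)) / sd(x)` with the sample (n-1 denominator) standard
#' deviation.
#'
#' @param x numeric vector with positive variance.
#' @return Standardized vector with mean 0 and SD 1.
#' @export
zscore <- function(x) {
  stop_if_not(!anyNA(x), "NA in input")
  s <- stats::sd(x)
  stop_if_not(is.finite(s) && s > 0, "constant vector cannot be Z-scored")
  (x - mean(x)) / s
}

#' First-order partial correlation
#'
#' Correlation of `x` and `y` with `z` partialled out:
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, equal to the
#' Pearson correlation of the OLS residuals of `x` on `z` and `y` on `z`.
#'
#' @param x,y,z numeric vectors of common length >= 4.
#' @return Scalar partial correlation.
#' @export
partial_corr <- function(x, y, z) {
  n <- length(x)
  stop_if_not(length(y) == n && length(z) == n, "length mismatch")
  stop_if_not(n >= 4, "need n >= 4")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  stop_if_not(abs(rxz) < 1 - 1e-12 && abs(ryz) < 1 - 1e-12,
              "x or y is collinear with z; partial correlation undefined")
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Build the adjusted cross-lag panel for one feature
#'
#' Implements the preprocessing contract of the cross-lagged analysis:
#' baseline and follow-up BMI (or WC) are residualized on the confounders;
#' the feature's baseline and follow-up log abundances are residualized on
#' the confounders plus the Bristol stool score; all four residual vectors
#' are Z-scored; and the 4x4 correlation matrix is computed with the
#' follow-up time interval partialled out of every pair.
#'
#' Interval partialling is implemented by residualizing the four Z-scored
#' vectors on the interval and correlating the residuals, which equals
#' first-order pairwise partialling on the shared interval variable and
#' guarantees a positive-semidefinite matrix.
#'
#' @param cohort a `paired_cohort` with features attached
#'   ([attach_features()]).
#' @param feature_id feature to analyse (must match `cohort$feature_ids`).
#' @param confounders covariate names for the anthropometric variable;
#'   default [gnhs_confounders()].
#' @param extra_feature_confounders additional covariates for the feature
#'   regressions; default `"bristol"`.
#' @param exposure `"bmi"` or `"wc"`: which adiposity measure enters the
#'   panel.
#' @param interval_mode `"partial"` (default: pairwise partial correlations
#'   on the interval) or `"covariate"` (interval added to the
#'   residualization covariates instead).
#' @return List with `corr` (4x4 matrix over BMI1, F1, BMI2, F2), `panel`
#'   (data frame of the four Z-scored columns plus `interval`), `n`, and
#'   `feature_id`.
#' @export
build_panel <- function(cohort, feature_id,
                        confounders = gnhs_confounders(),
                        extra_feature_confounders = "bristol",
                        exposure = c("bmi", "wc"),
                        interval_mode = c("partial", "covariate")) {
  stopifnot(inherits(cohort, "paired_cohort"))
  exposure <- match.arg(exposure)
  interval_mode <- match.arg(interval_mode)
  stop_if_not(!is.null(cohort$feature_ids), "cohort has no features attached")
  fi <- match(feature_id, cohort$feature_ids)
  stop_if_not(!is.na(fi), "unknown feature: %s", feature_id)

  C_bmi <- covariate_matrix(cohort, confounders)
  C_feat <- covariate_matrix(cohort, c(confounders, extra_feature_confounders))
  interval <- cohort$data$followup_interval
  if (interval_mode == "covariate") {
    C_bmi <- cbind(C_bmi, interval = interval)
    C_feat <- cbind(C_feat, interval = interval)
  }
  x1 <- cohort$data[[paste0("baseline_", exposure)]]
  x2 <- cohort$data[[paste0("followup_", exposure)]]
  f1 <- cohort$features_baseline[, fi]
  f2 <- cohort$features_followup[, fi]
  z <- cbind(bmi1 = zscore(residualize(x1, C_bmi)),
             feat1 = zscore(residualize(f1, C_feat)),
             bmi2 = zscore(residualize(x2, C_bmi)),
             feat2 = zscore(residualize(f2, C_feat)))
  if (interval_mode == "partial") {
    resid_z <- apply(z, 2, residualize, covariate_matrix = cbind(interval))
    corr <- stats::cor(resid_z)
  } else {
    corr <- stats::cor(z)
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  stop_if_not(min(ev) > -1e-10, "panel correlation matrix is not PSD")
  list(corr = corr,
       panel = data.frame(z, interval = interval),
       n = nrow(z), feature_id = feature_id)
}
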