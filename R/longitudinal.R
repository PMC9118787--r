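#' Weight-change-pattern model for one microbial feature
#'
#' OLS of the Z-scored follow-up feature on weight-change-pattern dummies
#' (reference: stable normal), the standard confounders, the Bristol stool
#' score, the follow-up interval, and the Z-scored baseline feature.
#' Participants underweight at either visit are excluded.
#'
#' @param cohort a `paired_cohort` with features attached.
#' @param feature_id feature to model; may also be a diversity column name
#'   if `values` is supplied.
#' @param values optional list with numeric `baseline`/`followup` vectors to
#'   model instead of an attached feature (e.g. diversity indices).
#' @param confounders covariate names; default [gnhs_confounders()].
#' @return Data frame of class `pattern_model_result`, one row per pattern
#'   contrast, with `term`, `beta`, `se`, `ci95_low`, `ci95_high`, `p`, `n`.
#'   Empty pattern groups are skipped with a warning.
#' @export
fit_pattern_model <- function(cohort, feature_id, values = NULL,
                              confounders = gnhs_confounders()) {
  stopifnot(inherits(cohort, "paired_cohort"))
  if (is.null(values)) {
    fi <- match(feature_id, cohort$feature_ids)
    stop_if_not(!is.na(fi), "unknown feature: %s", feature_id)
    fb <- cohort$features_baseline[, fi]
    ff <- cohort$features_followup[, fi]
  } else {
    fb <- values$baseline; ff <- values$followup
  }
  pat <- weight_change_pattern(cohort$data$baseline_bmi,
                               cohort$data$followup_bmi)
  keep <- pat != "excluded_underweight"
  pat <- droplevels(factor(pat[keep],
                           levels = c("stable_normal", "normal_to_adiposity",
                                      "adiposity_to_normal", "stable_adiposity")))
  empty <- setdiff(c("normal_to_adiposity", "adiposity_to_normal",
                     "stable_adiposity"), levels(pat))
  if (length(empty) > 0)
    warning("empty pattern group(s) skipped: ", paste(empty, collapse = ", "))
  C <- covariate_matrix(cohort, c(confounders, "bristol"))[keep, , drop = FALSE]
  df <- data.frame(y = zscore(ff[keep]), pattern = pat, C,
                   interval = cohort$data$followup_interval[keep],
                   baseline_feature = zscore(fb[keep]))
  fit <- stats::lm(y ~ ., data = df)
  extract_lm_terms(fit, grep("^pattern", names(stats::coef(fit)), value = TRUE),
                   rename = function(x) sub("^pattern", "", x),
                   result_class = "pattern_model_result")
}

#' Screen pattern contrasts across features with BH FDR
#'
#' @param cohort a `paired_cohort` with features attached.
#' @param feature_ids features to model; default all attached.
#' @param ... passed to [fit_pattern_model()].
#' @return Data frame, one row per feature x contrast, with BH FDR applied
#'   across features separately within each contrast.
#' @export
pattern_screen <- function(cohort, feature_ids = cohort$feature_ids, ...) {
  rows <- lapply(feature_ids, function(f) {
    r <- fit_pattern_model(cohort, f, ...)
    r$feature_id <- f
    r
  })
  res <- do.call(rbind, rows)
  res$fdr <- NA_real_
  for (ct in unique(res$term)) {
    i <- res$term == ct
    res$fdr[i] <- bh_fdr(res$p[i])
  }
  rownames(res) <- NULL
  res
}

#' Repeated-measures microbe-phenotype mixed model
#'
#' Random-intercept-per-participant linear mixed model (REML) of a Z-scored
#' insulin-resistance phenotype on the Z-scored log abundance of one
#' feature, stacking both visits (two rows per participant), adjusted for
#' the standard confounders. Skewed phenotypes (HOMA-IR, fasting insulin,
#' fasting glucose) are log-transformed before Z-scoring; HbA1c is not.
#' Inference is Wald with a normal reference.
#'
#' @param cohort a `paired_cohort` with features attached.
#' @param feature_id feature to model.
#' @param phenotype one of `"homa_ir"`, `"fasting_insulin"`,
#'   `"fasting_glucose"`, `"hba1c"`.
#' @param confounders covariate names; default [gnhs_confounders()].
#' @param include_time add visit as a fixed effect (default `FALSE`).
#' @return One-row data frame of class `mixed_model_result` with
#'   `feature_id`, `phenotype`, `beta`, `se`, `ci95_low`, `ci95_high`, `p`,
#'   `icc`, `n_obs`, `n_participants`.
#' @export
fit_mixed_assoc <- function(cohort, feature_id,
                            phenotype = c("homa_ir", "fasting_insulin",
                                          "fasting_glucose", "hba1c"),
                            confounders = gnhs_confounders(),
                            include_time = FALSE) {
  stopifnot(inherits(cohort, "paired_cohort"))
  phenotype <- match.arg(phenotype)
  fi <- match(feature_id, cohort$feature_ids)
  stop_if_not(!is.na(fi), "unknown feature: %s", feature_id)
  stacked <- stack_visits(cohort, phenotype, confounders)
  stacked$m <- zscore(c(cohort$features_baseline[, fi],
                        cohort$features_followup[, fi]))
  rhs <- paste(c("m", confounders, if (include_time) "visit", "(1 | pid)"),
               collapse = " + ")
  fit <- lme4::lmer(stats::as.formula(paste("y ~", rhs)), data = stacked,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  co <- lme4::fixef(fit)["m"]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[which(names(lme4::fixef(fit)) == "m")]
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_id <- vc$vcov[vc$grp == "pid"]
  v_res <- vc$vcov[vc$grp == "Residual"]
  z <- co / se
  out <- data.frame(feature_id = feature_id, phenotype = phenotype,
                    beta = unname(co), se = unname(se),
                    ci95_low = unname(co - 1.959963984540054 * se),
                    ci95_high = unname(co + 1.959963984540054 * se),
                    p = 2 * stats::pnorm(-abs(unname(z))),
                    icc = v_id / (v_id + v_res),
                    n_obs = nrow(stacked),
                    n_participants = length(unique(stacked$pid)),
                    stringsAsFactors = FALSE)
  class(out) <- c("mixed_model_result", "data.frame")
  out
}

# Two rows per participant: Z-scored (log) phenotype + visit-specific covariates.
stack_visits <- function(cohort, phenotype, confounders) {
  d <- cohort$data
  skewed <- c("homa_ir", "fasting_insulin", "fasting_glucose")
  grab <- function(visit) d[[paste0(visit, "_", phenotype)]]
  y <- c(grab("baseline"), grab("followup"))
  stop_if_not(!anyNA(y), "missing %s values", phenotype)
  if (phenotype %in% skewed) {
    stop_if_not(all(y > 0), "%s must be positive for the log transform", phenotype)
    y <- log(y)
  }
  Cb <- covariate_matrix(cohort, confounders, visit = "baseline")
  Cf <- covariate_matrix(cohort, confounders, visit = "followup")
  out <- data.frame(pid = rep(d$participant_id, 2),
                    visit = rep(c("baseline", "follow_up"), each = nrow(d)),
                    y = zscore(y), rbind(Cb, Cf))
  out
}

#' Screen microbe-phenotype mixed models with BH FDR
#'
#' @param cohort a `paired_cohort` with features attached.
#' @param feature_ids features to model.
#' @param phenotypes phenotypes to model; FDR is applied across features
#'   separately within each phenotype. Non-converged fits are excluded from
#'   the family with a warning.
#' @param ... passed to [fit_mixed_assoc()].
#' @return Data frame, one row per feature x phenotype, with `fdr`.
#' @export
mixed_screen <- function(cohort, feature_ids,
                         phenotypes = c("homa_ir", "fasting_insulin",
                                        "fasting_glucose", "hba1c"), ...) {
  rows <- list()
  for (ph in phenotypes) for (f in feature_ids) {
    r <- tryCatch(fit_mixed_assoc(cohort, f, ph, ...), error = function(e) {
      warning(sprintf("mixed model %s/%s failed: %s", f, ph,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(r)) rows[[length(rows) + 1]] <- r
  }
  stop_if_not(length(rows) >= 1, "all mixed-model fits failed")
  res <- do.call(rbind, rows)
  res$fdr <- NA_real_
  for (ph in unique(res$phenotype)) {
    i <- res$phenotype == ph
    res$fdr[i] <- bh_fdr(res$p[i])
  }
  rownames(res) <- NULL
  res
}

#' Median split of a continuous exposure
#'
#' Values less than or equal to the median go to the `lower` group.
#'
#' @param x numeric vector.
#' @return Factor with levels `lower`, `higher`.
#' @export
median_split <- function(x) {
  stop_if_not(!anyNA(x), "NA in exposure")
  g <- factor(ifelse(x <= stats::median(x), "lower", "higher"),
              levels = c("lower", "higher"))
  stop_if_not(nlevels(droplevels(g)) == 2, "degenerate split: exposure constant")
  g
}

#' Prospective exposure-outcome model
#'
#' OLS of a Z-scored follow-up phenotype on a categorical exposure (a
#' median-split dietary factor or the baseline weight group) plus
#' covariates, the follow-up interval, and optionally the Z-scored baseline
#' phenotype. Skewed phenotypes are log-transformed before Z-scoring.
#'
#' @param cohort a `paired_cohort`.
#' @param exposure either `"weight_group"` (baseline WGOC class:
#'   normal/adiposity, underweight retained as its own level) or the name of
#'   a baseline metadata column to median-split (e.g. `"vegetable"`).
#' @param outcome phenotype name (see [fit_mixed_assoc()]).
#' @param confounders covariate names; default [gnhs_confounders()].
#' @param adjust_baseline_outcome include the baseline phenotype (default
#'   `TRUE`).
#' @return Data frame of class `linear_model_result`, one row per exposure
#'   contrast.
#' @export
fit_exposure_model <- function(cohort, exposure, outcome = "homa_ir",
                               confounders = gnhs_confounders(),
                               adjust_baseline_outcome = TRUE) {
  stopifnot(inherits(cohort, "paired_cohort"))
  d <- cohort$data
  skewed <- c("homa_ir", "fasting_insulin", "fasting_glucose")
  tr <- function(x) if (outcome %in% skewed) log(x) else x
  y <- zscore(tr(d[[paste0("followup_", outcome)]]))
  if (identical(exposure, "weight_group")) {
    wg <- classify_weight(d$baseline_bmi)
    x <- factor(ifelse(wg == "underweight", "underweight",
                       ifelse(wg == "normal", "normal", "adiposity")),
                levels = c("normal", "underweight", "adiposity"))
  } else {
    col <- d[[paste0("baseline_", exposure)]]
    stop_if_not(!is.null(col), "unknown exposure column: %s", exposure)
    x <- median_split(col)
  }
  C <- covariate_matrix(cohort, confounders)
  df <- data.frame(y = y, exposure = x, C, interval = d$followup_interval)
  if (adjust_baseline_outcome)
    df$baseline_outcome <- zscore(tr(d[[paste0("baseline_", outcome)]]))
  fit <- stats::lm(y ~ ., data = df)
  extract_lm_terms(fit, grep("^exposure", names(stats::coef(fit)), value = TRUE),
                   rename = function(x) sub("^exposure", "", x),
                   result_class = "linear_model_result")
}

#' Dietary median-split screen with BH FDR
#'
#' @param cohort a `paired_cohort`.
#' @param diet_vars baseline dietary columns to median-split.
#' @param outcomes phenotypes; FDR applied across dietary factors within
#'   each outcome.
#' @param ... passed to [fit_exposure_model()].
#' @return Data frame, one row per diet factor x outcome, with `fdr`.
#' @export
diet_screen <- function(cohort,
                        diet_vars = c("vegetable", "fruit", "fish",
                                      "red_meat", "dairy"),
                        outcomes = c("homa_ir", "fasting_insulin",
                                     "fasting_glucose", "hba1c"), ...) {
  rows <- list()
  for (oc in outcomes) for (dv in diet_vars) {
    r <- fit_exposure_model(cohort, dv, oc, ...)
    r <- r[r$term == "higher", , drop = FALSE]
    r$diet_factor <- dv
    r$outcome <- oc
    rows[[length(rows) + 1]] <- r
  }
  res <- do.call(rbind, rows)
  res$fdr <- NA_real_
  for (oc in unique(res$outcome)) {
    i <- res$outcome == oc
    res$fdr[i] <- bh_fdr(res$p[i])
  }
  rownames(res) <- NULL
  res
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing covariate j on all the others
#' (with intercept). VIF > 10 conventionally flags collinearity. Perfect
#' collinearity yields `Inf`, not an error.
#'
#' @param covariate_matrix numeric matrix with >= 2 columns and more rows
#'   than columns.
#' @return Named numeric vector of VIFs.
#' @export
compute_vif <- function(covariate_matrix) {
  X <- as.matrix(covariate_matrix)
  stop_if_not(ncol(X) >= 2, "need >= 2 covariates")
  stop_if_not(nrow(X) > ncol(X), "need n > p")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    res <- qr.resid(qr(Z), y)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - sum(res^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

# Shared coefficient extraction for the OLS result tables.
extract_lm_terms <- function(fit, terms, rename = identity,
                             result_class = "linear_model_result") {
  sm <- summary(fit)$coefficients
  terms <- terms[terms %in% rownames(sm)]
  dfres <- fit$df.residual
  tcrit <- stats::qt(0.975, dfres)
  out <- data.frame(term = rename(terms),
                    beta = sm[terms, 1], se = sm[terms, 2],
                    ci95_low = sm[terms, 1] - tcrit * sm[terms, 2],
                    ci95_high = sm[terms, 1] + tcrit * sm[terms, 2],
                    p = sm[terms, 4], n = length(fit$residuals),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c(result_class, "data.frame")
  out
}
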