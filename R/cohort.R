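#' Standard confounder set for the discovery cohort
#'
#' The eight anthropometry-model confounders used throughout: age, sex,
#' smoking status, alcohol status, education, income, physical activity, and
#' total energy intake. Microbial-feature models additionally adjust for the
#' Bristol stool score.
#'
#' @return Character vector of metadata column names.
#' @export
gnhs_confounders <- function() {
  c("age", "sex", "smoking", "alcohol", "education", "income",
    "physical_activity", "energy_intake")
}

#' WGOC weight classification
#'
#' Chinese Working Group on Obesity cut-offs, with half-open intervals so the
#' positive line is partitioned: underweight < 18.5, normal \[18.5, 24),
#' overweight \[24, 28), obesity >= 28.
#'
#' @param bmi numeric vector of BMI values (kg/m^2); all must be positive
#'   (NA allowed, propagated).
#' @return Factor with levels `underweight`, `normal`, `overweight`,
#'   `obesity`.
#' @export
classify_weight <- function(bmi) {
  stop_if_not(all(bmi > 0, na.rm = TRUE), "BMI must be positive")
  cut(bmi, breaks = c(0, 18.5, 24, 28, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obesity"))
}

#' Adiposity flag (overweight or obesity)
#'
#' @inheritParams classify_weight
#' @return Logical vector: `TRUE` when BMI >= 24.
#' @export
is_adiposity <- function(bmi) {
  classify_weight(bmi) %in% c("overweight", "obesity") & !is.na(bmi)
}

#' Long-term weight-change pattern
#'
#' Crosses the adiposity flag at the two visits; participants underweight at
#' either visit are set aside as `excluded_underweight`.
#'
#' @param bmi_baseline,bmi_followup numeric BMI at the two visits.
#' @return Factor with levels `stable_normal`, `normal_to_adiposity`,
#'   `adiposity_to_normal`, `stable_adiposity`, `excluded_underweight`.
#' @export
weight_change_pattern <- function(bmi_baseline, bmi_followup) {
  stop_if_not(length(bmi_baseline) == length(bmi_followup),
              "BMI vectors must have equal length")
  c1 <- classify_weight(bmi_baseline)
  c2 <- classify_weight(bmi_followup)
  a1 <- c1 %in% c("overweight", "obesity")
  a2 <- c2 %in% c("overweight", "obesity")
  out <- ifelse(c1 == "underweight" | c2 == "underweight",
                "excluded_underweight",
                ifelse(a1,
                       ifelse(a2, "stable_adiposity", "adiposity_to_normal"),
                       ifelse(a2, "normal_to_adiposity", "stable_normal")))
  factor(out, levels = c("stable_normal", "normal_to_adiposity",
                         "adiposity_to_normal", "stable_adiposity",
                         "excluded_underweight"))
}

#' HOMA-IR from fasting insulin and glucose
#'
#' Homeostasis model assessment of insulin resistance (HOMA1-IR):
#' insulin (uU/mL) x glucose (mmol/L) / 22.5.
#'
#' @param fasting_insulin fasting insulin in uU/mL, positive.
#' @param fasting_glucose fasting glucose in mmol/L, positive.
#' @return Numeric HOMA-IR values.
#' @export
compute_homa_ir <- function(fasting_insulin, fasting_glucose) {
  stop_if_not(all(fasting_insulin > 0, na.rm = TRUE) &&
                all(fasting_glucose > 0, na.rm = TRUE),
              "insulin and glucose must be positive")
  fasting_insulin * fasting_glucose / 22.5
}

#' Pair participant-visit records and apply exclusion criteria
#'
#' Pairs the baseline and follow-up rows of a long metadata table and removes
#' participants meeting any exclusion criterion: missing BMI at either visit,
#' missing follow-up interval, or diabetes medication at either visit.
#' Participants without exactly one row per visit are dropped with a warning.
#'
#' @param records data frame with one row per participant-visit, containing
#'   at least `participant_id`, `visit` (`"baseline"`/`"follow_up"`), `bmi`,
#'   `followup_interval` (carried on the baseline row), and
#'   `diabetes_medication` (0/1). Any further columns are carried through.
#' @param criteria subset of
#'   `c("missing_bmi", "missing_interval", "diabetes_medication")`.
#' @return A `paired_cohort`: list with `data` (wide data frame, one row per
#'   retained participant with `baseline_*`/`followup_*` columns plus
#'   `followup_interval`), and an `exclusion_log` attribute-style element
#'   with per-criterion counts (overlapping flags are removed once; the log
#'   also records the size of their union).
#' @export
apply_exclusions <- function(records,
                             criteria = c("missing_bmi", "missing_interval",
                                          "diabetes_medication")) {
  criteria <- if (is.null(criteria) || length(criteria) == 0) character(0)
              else match.arg(criteria, several.ok = TRUE)
  stop_if_not(all(c("participant_id", "visit", "bmi") %in% names(records)),
              "records need participant_id, visit and bmi columns")
  wide <- pair_records(records)
  n_unpaired <- attr(wide, "n_unpaired")
  if (n_unpaired > 0)
    warning(sprintf("%d participant(s) without exactly two visits excluded",
                    n_unpaired))
  flags <- list()
  if ("missing_bmi" %in% criteria)
    flags$missing_bmi <- is.na(wide$baseline_bmi) | is.na(wide$followup_bmi)
  if ("missing_interval" %in% criteria && "followup_interval" %in% names(wide))
    flags$missing_interval <- is.na(wide$followup_interval) |
      wide$followup_interval <= 0
  if ("diabetes_medication" %in% criteria &&
      "baseline_diabetes_medication" %in% names(wide))
    flags$diabetes_medication <-
      (wide$baseline_diabetes_medication %in% 1) |
      (wide$followup_diabetes_medication %in% 1)
  any_flag <- Reduce(`|`, flags, rep(FALSE, nrow(wide)))
  log <- c(n_input_pairs = nrow(wide), n_unpaired = n_unpaired,
           vapply(flags, sum, integer(1)),
           n_excluded_union = sum(any_flag),
           n_final = sum(!any_flag))
  out <- list(data = wide[!any_flag, , drop = FALSE],
              feature_ids = NULL, features_baseline = NULL,
              features_followup = NULL, exclusion_log = log)
  class(out) <- "paired_cohort"
  out
}

# Long records -> wide (baseline_*/followup_*) one-row-per-participant frame.
pair_records <- function(records) {
  records$visit <- as.character(records$visit)
  stop_if_not(all(records$visit %in% c("baseline", "follow_up")),
              "visit must be 'baseline' or 'follow_up'")
  b <- records[records$visit == "baseline", , drop = FALSE]
  f <- records[records$visit == "follow_up", , drop = FALSE]
  dup <- unique(c(b$participant_id[duplicated(b$participant_id)],
                  f$participant_id[duplicated(f$participant_id)]))
  keep_ids <- setdiff(intersect(b$participant_id, f$participant_id), dup)
  n_unpaired <- length(unique(records$participant_id)) - length(keep_ids)
  keep_ids <- sort(keep_ids)
  b <- b[match(keep_ids, b$participant_id), , drop = FALSE]
  f <- f[match(keep_ids, f$participant_id), , drop = FALSE]
  vars <- setdiff(names(records), c("participant_id", "visit",
                                    "followup_interval"))
  wide <- data.frame(participant_id = b$participant_id,
                     stringsAsFactors = FALSE)
  for (v in vars) {
    wide[[paste0("baseline_", v)]] <- b[[v]]
    wide[[paste0("followup_", v)]] <- f[[v]]
  }
  if ("followup_interval" %in% names(records)) {
    iv <- b$followup_interval
    miss <- is.na(iv)
    iv[miss] <- f$followup_interval[miss]
    wide$followup_interval <- iv
  }
  rownames(wide) <- NULL
  attr(wide, "n_unpaired") <- n_unpaired
  wide
}

#' Attach feature matrices to a paired cohort
#'
#' Aligns per-sample feature values (typically log-transformed relative
#' abundances) with a paired cohort using the `baseline_sample_id` /
#' `followup_sample_id` metadata columns.
#'
#' @param cohort a `paired_cohort` from [apply_exclusions()].
#' @param baseline,followup features x samples numeric matrices (e.g. the
#'   output of [log_transform()]) with sample ids as column names, or
#'   [abundance_table()] objects.
#' @return The cohort with `feature_ids`, `features_baseline`, and
#'   `features_followup` (participants x features matrices) filled in.
#' @export
attach_features <- function(cohort, baseline, followup) {
  stopifnot(inherits(cohort, "paired_cohort"))
  get_mat <- function(x) if (inherits(x, "abundance_table")) x$values else as.matrix(x)
  mb <- get_mat(baseline); mf <- get_mat(followup)
  stop_if_not(identical(rownames(mb), rownames(mf)),
              "baseline and follow-up tables must share one feature index")
  sb <- cohort$data$baseline_sample_id
  sf <- cohort$data$followup_sample_id
  stop_if_not(!is.null(sb) && !is.null(sf),
              "cohort metadata lacks sample_id columns")
  stop_if_not(all(sb %in% colnames(mb)) && all(sf %in% colnames(mf)),
              "cohort sample ids missing from the feature matrices")
  cohort$feature_ids <- rownames(mb)
  cohort$features_baseline <- t(mb[, sb, drop = FALSE])
  cohort$features_followup <- t(mf[, sf, drop = FALSE])
  rownames(cohort$features_baseline) <- cohort$data$participant_id
  rownames(cohort$features_followup) <- cohort$data$participant_id
  cohort
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("<paired_cohort> %d participants, %s features\n",
              nrow(x$data),
              if (is.null(x$feature_ids)) "no" else length(x$feature_ids)))
  invisible(x)
}

# Numeric covariate matrix from baseline metadata columns; sex coded male=1.
covariate_matrix <- function(cohort, vars, visit = "baseline") {
  df <- cohort$data
  cols <- lapply(vars, function(v) {
    col <- df[[paste0(visit, "_", v)]]
    stop_if_not(!is.null(col), "missing covariate column: %s", v)
    if (v == "sex" && !is.numeric(col)) col <- as.numeric(col == "male")
    as.numeric(col)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- vars
  m
}
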