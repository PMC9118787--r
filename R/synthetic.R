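#' Generating truth for a synthetic paired-visit cohort
#'
#' Bundles the parameters of the synthetic-data generator: cohort scale
#' (participants, species, follow-up interval), the standardized cross-lag
#' paths of the designated feature, confounder effects, mediation paths,
#' phenotype variance structure, and zero inflation. Defaults mirror the
#' discovery-cohort scale: 426 participants, 171 species, ~3.15-year
#' follow-up, age 63.6 (5.4) years, 31.9% male, BMI 23.4 (3.1) kg/m^2.
#'
#' The designated feature (index 1) carries the cross-lag structure: latent
#' standardized (BMI1, F1) with correlation `r3`, then
#' `BMI2 = r1 BMI1 + rho1 F1 + e1` and `F2 = rho2 BMI1 + r2 F1 + e2` with
#' disturbance variances chosen so all four latents have unit variance.
#' Mediation paths act on the raw scales: `alpha` shifts the follow-up log
#' abundance of the mediator per unit exposure (baseline adiposity), `b` is
#' the log-outcome change per unit log abundance, `c_prime` the direct
#' log-outcome change per unit exposure.
#'
#' @param n_participants,n_species cohort dimensions.
#' @param rho1,rho2,r1,r2,r3 standardized cross-lag, tracking, and
#'   synchronous paths for the designated feature.
#' @param feature_log_mean,feature_log_sd location/scale mapping the
#'   designated feature's standardized latent to natural-log fractional
#'   abundance.
#' @param confounder_effects list with named numeric vectors `bmi` and
#'   `feature`: additive effects of standardized confounders on the latent
#'   BMI and feature scales (injected before compositional rendering).
#' @param mediation list with `alpha`, `b`, `c_prime`, and `outcome`.
#' @param beta_assoc cross-sectional microbe-phenotype effect (log-outcome
#'   units per log-abundance unit) applied at both visits; used by
#'   mixed-model scenarios.
#' @param icc_phenotype intraclass correlation of the phenotype noise
#'   (participant random intercept share); `sigma_phenotype` is the total
#'   noise SD on the log scale.
#' @param zero_inflation per-species detection probability for background
#'   species (scalar or length `n_species`; the designated feature is always
#'   detected).
#' @param bg_log_mean,bg_log_sd,bg_sd background species log-abundance
#'   base-mean distribution and within-species SD.
#' @param interval_mean,interval_sd follow-up interval distribution (years).
#' @param bmi_mean,bmi_sd,age_mean,age_sd,p_male anthropometric and
#'   demographic marginals.
#' @param seed default seed used by [generate_cohort()].
#' @return A validated list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_participants = 426, n_species = 171,
                            rho1 = 0, rho2 = 0, r1 = 0.85, r2 = 0.5, r3 = 0.1,
                            feature_log_mean = -6, feature_log_sd = 2,
                            confounder_effects = list(
                              bmi = c(age = 0.1, sex = 0.15,
                                      physical_activity = -0.1,
                                      energy_intake = 0.1),
                              feature = c(age = -0.1, bristol = 0.1)),
                            mediation = list(alpha = 0, b = 0, c_prime = 0,
                                             outcome = "homa_ir"),
                            beta_assoc = 0,
                            icc_phenotype = 0.5, sigma_phenotype = 0.5,
                            zero_inflation = 0.7,
                            bg_log_mean = -6, bg_log_sd = 1.5, bg_sd = 1,
                            interval_mean = 3.15, interval_sd = 0.3,
                            bmi_mean = 23.4, bmi_sd = 3.1,
                            age_mean = 63.6, age_sd = 5.4, p_male = 0.319,
                            seed = 1L) {
  truth <- as.list(environment())
  stop_if_not(n_participants >= 20 && n_species >= 2, "cohort too small")
  stop_if_not(icc_phenotype >= 0 && icc_phenotype < 1,
              "icc_phenotype must lie in [0, 1)")
  stop_if_not(all(zero_inflation > 0 & zero_inflation <= 1),
              "detection probabilities must lie in (0, 1]")
  stop_if_not(interval_mean > 0, "interval_mean must be positive")
  imp <- implied_crosslag_corr(rho1, rho2, r1, r2, r3)
  ev <- eigen(imp, symmetric = TRUE, only.values = TRUE)$values
  stop_if_not(min(ev) > -1e-10,
              "implied latent correlation matrix is not PSD")
  v1 <- 1 - (r1^2 + rho1^2 + 2 * r1 * rho1 * r3)
  v2 <- 1 - (rho2^2 + r2^2 + 2 * rho2 * r2 * r3)
  stop_if_not(v1 > 0 && v2 > 0,
              "cross-lag paths leave no positive disturbance variance")
  truth$implied_corr <- imp
  class(truth) <- "synthetic_truth"
  truth
}

#' Model-implied latent correlation matrix of (BMI1, F1, BMI2, F2)
#'
#' @param rho1,rho2,r1,r2,r3 standardized paths (see [synthetic_truth()]).
#' @return 4x4 correlation matrix.
#' @export
implied_crosslag_corr <- function(rho1, rho2, r1, r2, r3) {
  m <- diag(4)
  dimnames(m) <- list(c("bmi1", "feat1", "bmi2", "feat2"),
                      c("bmi1", "feat1", "bmi2", "feat2"))
  m[1, 2] <- m[2, 1] <- r3
  m[1, 3] <- m[3, 1] <- r1 + rho1 * r3
  m[2, 3] <- m[3, 2] <- rho1 + r1 * r3
  m[1, 4] <- m[4, 1] <- rho2 + r2 * r3
  m[2, 4] <- m[4, 2] <- r2 + rho2 * r3
  m[3, 4] <- m[4, 3] <- r1 * rho2 + rho1 * r2 + r3 * (r1 * r2 + rho1 * rho2)
  m
}

#' Generate a synthetic paired-visit cohort
#'
#' Draws a complete discovery-style cohort from a [synthetic_truth()]:
#' confounders, latent cross-lag structure, anthropometry, a compositional
#' species table per visit (background species log-normal, detection-limit
#' zeros by thresholding, closure to 100%), insulin-resistance phenotypes
#' with a participant random intercept, dietary intakes, and follow-up
#' intervals. Deterministic given the seed.
#'
#' @param truth a [synthetic_truth()].
#' @param seed integer seed; defaults to `truth$seed`.
#' @return List of class `synthetic_cohort` with `abundance_baseline` and
#'   `abundance_followup` ([abundance_table()], percent mode), `metadata`
#'   (long data frame, one row per participant-visit), `truth`, and
#'   `latents` (per-participant generating values, for recovery tests).
#' @export
generate_cohort <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed(seed, {
    n <- truth$n_participants
    pid <- sprintf("P%04d", seq_len(n))
    conf <- draw_confounders(n, truth)
    lat <- draw_crosslag_latents(n, truth)

    # additive confounding on the latent scale, shared across visits
    conf_num <- conf[, c("age", "sex", "smoking", "alcohol", "education",
                         "income", "physical_activity", "energy_intake",
                         "bristol")]
    conf_num$sex <- as.numeric(conf_num$sex == "male")
    conf_std <- scale(as.matrix(conf_num))
    eff <- function(v) {
      if (length(v) == 0) return(rep(0, n))
      as.vector(conf_std[, names(v), drop = FALSE] %*% v)
    }
    bmi_shift <- eff(truth$confounder_effects$bmi)
    feat_shift <- eff(truth$confounder_effects$feature)

    bmi1 <- truth$bmi_mean + truth$bmi_sd * (lat$B1 + bmi_shift)
    bmi2 <- truth$bmi_mean + truth$bmi_sd * (lat$B2 + bmi_shift)
    wc_noise <- stats::rnorm(n)
    wc1 <- 85.3 + 8.7 * (0.8 * (lat$B1 + bmi_shift) + 0.6 * wc_noise)
    wc2 <- 85.3 + 8.7 * (0.8 * (lat$B2 + bmi_shift) + 0.6 * wc_noise)
    X <- as.numeric(is_adiposity(bmi1))
    interval <- pmax(stats::rnorm(n, truth$interval_mean, truth$interval_sd),
                     0.1)

    # designated feature's log absolute abundance; mediation alpha acts on
    # the follow-up value, per unit of baseline adiposity
    l1_base <- truth$feature_log_mean +
      truth$feature_log_sd * (lat$F1 + feat_shift)
    l1_fu <- truth$feature_log_mean +
      truth$feature_log_sd * (lat$F2 + feat_shift) +
      truth$mediation$alpha * X

    tabs <- render_composition(l1_base, l1_fu, truth)
    phen <- draw_phenotypes(l1_base, l1_fu, X, truth)

    meta <- rbind(
      visit_frame(pid, "baseline", conf, bmi1, wc1, interval, phen$base,
                  offset_age = 0),
      visit_frame(pid, "follow_up", conf, bmi2, wc2, NA_real_, phen$fu,
                  offset_age = interval))
    rownames(meta) <- NULL
    structure(list(abundance_baseline = tabs$baseline,
                   abundance_followup = tabs$followup,
                   metadata = meta, truth = truth,
                   latents = data.frame(participant_id = pid, lat,
                                        X = X, l1_base = l1_base,
                                        l1_fu = l1_fu,
                                        y_base = phen$base$log_outcome,
                                        y_fu = phen$fu$log_outcome)),
              class = "synthetic_cohort")
  })
}

draw_confounders <- function(n, truth) {
  sex <- ifelse(stats::runif(n) < truth$p_male, "male", "female")
  male <- sex == "male"
  data.frame(
    age = stats::rnorm(n, truth$age_mean, truth$age_sd),
    sex = sex,
    smoking = as.integer(male & stats::runif(n) < 0.228),
    alcohol = as.integer(stats::runif(n) < ifelse(male, 0.199, 0.028)),
    education = sample(1:3, n, replace = TRUE, prob = c(0.235, 0.48, 0.285)),
    income = sample(1:4, n, replace = TRUE, prob = c(0.012, 0.21, 0.64, 0.138)),
    physical_activity = pmax(stats::rnorm(n, 40.8, 13.7), 1),
    energy_intake = pmax(stats::rnorm(n, 1760, 460), 500),
    bristol = sample(1:7, n, replace = TRUE,
                     prob = c(0.02, 0.08, 0.25, 0.35, 0.20, 0.08, 0.02)),
    vegetable = stats::rlnorm(n, log(355), 0.5),
    fruit = stats::rlnorm(n, log(130), 0.7),
    fish = stats::rlnorm(n, log(42), 0.6),
    red_meat = stats::rlnorm(n, log(77), 0.5),
    dairy = stats::rlnorm(n, log(13), 1.0),
    stringsAsFactors = FALSE)
}

draw_crosslag_latents <- function(n, truth) {
  r3 <- truth$r3
  B1 <- stats::rnorm(n)
  F1 <- r3 * B1 + sqrt(1 - r3^2) * stats::rnorm(n)
  v1 <- 1 - (truth$r1^2 + truth$rho1^2 + 2 * truth$r1 * truth$rho1 * r3)
  v2 <- 1 - (truth$rho2^2 + truth$r2^2 + 2 * truth$rho2 * truth$r2 * r3)
  B2 <- truth$r1 * B1 + truth$rho1 * F1 + sqrt(v1) * stats::rnorm(n)
  F2 <- truth$rho2 * B1 + truth$r2 * F1 + sqrt(v2) * stats::rnorm(n)
  data.frame(B1 = B1, F1 = F1, B2 = B2, F2 = F2)
}

# Embed the designated feature among log-normal background species, apply
# detection-limit zeros, and close each sample to 100%.
render_composition <- function(l1_base, l1_fu, truth) {
  n <- length(l1_base)
  S <- truth$n_species
  p_detect <- rep(truth$zero_inflation, length.out = S)
  m_s <- stats::rnorm(S, truth$bg_log_mean, truth$bg_log_sd)
  m_s[1] <- truth$feature_log_mean
  one_visit <- function(l1, tag) {
    L <- matrix(m_s, nrow = S, ncol = n) +
      truth$bg_sd * matrix(stats::rnorm(S * n), nrow = S)
    L[1, ] <- l1
    A <- exp(L)
    if (S > 1) {
      thr <- m_s + truth$bg_sd * stats::qnorm(1 - p_detect)
      A[-1, ][L[-1, , drop = FALSE] < thr[-1]] <- 0
    }
    A <- sweep(A, 2, colSums(A), "/") * 100
    rownames(A) <- species_taxonomy(S)
    colnames(A) <- sprintf("P%04d_%s", seq_len(n), tag)
    abundance_table(A, mode = "percent", level = "species")
  }
  list(baseline = one_visit(l1_base, "B"), followup = one_visit(l1_fu, "F"))
}

species_taxonomy <- function(S) {
  ids <- c("s__Lachnospiraceae_bacterium_3_1_57FAA_CT1",
           "s__Clostridium_hathewayi",
           "s__Adlercreutzia_equolifaciens",
           "s__Parabacteroides_unclassified",
           "s__Lachnospiraceae_bacterium_7_1_58FAA",
           "s__Megamonas_unclassified")
  if (S > length(ids))
    ids <- c(ids, sprintf("s__background_species_%03d",
                          seq_len(S - length(ids))))
  paste0("k__Bacteria|p__Firmicutes|g__genus|", ids[seq_len(S)])
}

draw_phenotypes <- function(l1_base, l1_fu, X, truth) {
  n <- length(X)
  mu <- log(1.5)
  s_u <- sqrt(truth$icc_phenotype) * truth$sigma_phenotype
  s_e <- sqrt(1 - truth$icc_phenotype) * truth$sigma_phenotype
  u <- stats::rnorm(n, 0, s_u)
  dm <- truth$feature_log_mean
  y_base <- mu + truth$beta_assoc * (l1_base - dm) + u + stats::rnorm(n, 0, s_e)
  y_fu <- mu + truth$beta_assoc * (l1_fu - dm) +
    truth$mediation$c_prime * X + truth$mediation$b * (l1_fu - dm) +
    u + stats::rnorm(n, 0, s_e)
  one <- function(y) {
    homa <- exp(y)
    glucose <- stats::rlnorm(n, log(5.1), 0.07)
    insulin <- homa * 22.5 / glucose
    data.frame(log_outcome = y, homa_ir = homa,
               fasting_glucose = glucose, fasting_insulin = insulin,
               hba1c = 5.65 + 0.5 * (y - mu) + stats::rnorm(n, 0, 0.3))
  }
  list(base = one(y_base), fu = one(y_fu))
}

visit_frame <- function(pid, visit, conf, bmi, wc, interval, phen, offset_age) {
  data.frame(participant_id = pid, visit = visit,
             sample_id = sprintf("%s_%s", pid,
                                 if (visit == "baseline") "B" else "F"),
             age = conf$age + offset_age, sex = conf$sex,
             smoking = conf$smoking, alcohol = conf$alcohol,
             education = conf$education, income = conf$income,
             physical_activity = conf$physical_activity,
             energy_intake = conf$energy_intake, bristol = conf$bristol,
             bmi = bmi, wc = wc,
             fasting_insulin = phen$fasting_insulin,
             fasting_glucose = phen$fasting_glucose,
             homa_ir = phen$homa_ir, hba1c = phen$hba1c,
             diabetes_medication = 0L,
             vegetable = conf$vegetable, fruit = conf$fruit,
             fish = conf$fish, red_meat = conf$red_meat, dairy = conf$dairy,
             followup_interval = interval,
             stringsAsFactors = FALSE)
}

#' Generate an HMP-style replication cohort
#'
#' Same latent cross-lag machinery as [generate_cohort()] with the
#' replication design: small n (default 43), ages uniform in 18-40, a race
#' column (white / not white), a ~1-year interval, and BMI measured at
#' baseline only (follow-up BMI is `NA`).
#'
#' @param truth a [synthetic_truth()]; cohort-scale fields other than the
#'   paths are overridden by the replication design.
#' @param n number of participants (default 43).
#' @param seed integer seed; defaults to `truth$seed + 1`.
#' @return A `synthetic_cohort` list (see [generate_cohort()]).
#' @export
generate_replication_cohort <- function(truth, n = 43, seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed(seed, {
    pid <- sprintf("H%03d", seq_len(n))
    lat <- draw_crosslag_latents(n, truth)
    bmi1 <- 24 + 3 * lat$B1
    interval <- pmax(stats::rnorm(n, 1, 0.1), 0.1)
    l1_base <- truth$feature_log_mean + truth$feature_log_sd * lat$F1
    l1_fu <- truth$feature_log_mean + truth$feature_log_sd * lat$F2
    tabs <- render_composition(l1_base, l1_fu, truth)
    colnames(tabs$baseline$values) <- sprintf("%s_B", pid)
    colnames(tabs$followup$values) <- sprintf("%s_F", pid)
    base <- data.frame(participant_id = pid, visit = "baseline",
                       sample_id = sprintf("%s_B", pid),
                       age = stats::runif(n, 18, 40),
                       sex = ifelse(stats::runif(n) < 0.5, "male", "female"),
                       race = ifelse(stats::runif(n) < 0.8, "white",
                                     "not_white"),
                       bmi = bmi1, followup_interval = interval,
                       stringsAsFactors = FALSE)
    fu <- base
    fu$visit <- "follow_up"
    fu$sample_id <- sprintf("%s_F", pid)
    fu$age <- base$age + interval
    fu$bmi <- NA_real_
    fu$followup_interval <- NA_real_
    structure(list(abundance_baseline = tabs$baseline,
                   abundance_followup = tabs$followup,
                   metadata = rbind(base, fu), truth = truth,
                   latents = data.frame(participant_id = pid, lat,
                                        l1_base = l1_base, l1_fu = l1_fu)),
              class = "synthetic_cohort")
  })
}

#' Assemble a simulated cohort into an analysis-ready `paired_cohort`
#'
#' Convenience wrapper chaining the standard preprocessing: joint prevalence
#' filtering over both visits' samples, zero-replaced log transform, pairing
#' with exclusion criteria, and feature attachment.
#'
#' @param sim a `synthetic_cohort` from [generate_cohort()] or
#'   [generate_replication_cohort()].
#' @param min_abund,min_prev prevalence-filter thresholds
#'   (see [filter_prevalence()]).
#' @param zero_replacement see [log_transform()].
#' @param criteria exclusion criteria passed to [apply_exclusions()];
#'   `NULL` disables flag-based exclusion (used for replication cohorts
#'   where follow-up BMI is absent by design).
#' @return A `paired_cohort` with log-abundance features attached.
#' @export
assemble_cohort <- function(sim, min_abund = NULL, min_prev = 0.10,
                            zero_replacement = 1e-5,
                            criteria = c("missing_bmi", "missing_interval",
                                         "diabetes_medication")) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  joint <- abundance_table(cbind(sim$abundance_baseline$values,
                                 sim$abundance_followup$values),
                           mode = sim$abundance_baseline$mode,
                           level = sim$abundance_baseline$level)
  kept <- rownames(filter_prevalence(joint, min_abund, min_prev)$values)
  sub <- function(tab) abundance_table(tab$values[kept, , drop = FALSE],
                                       mode = tab$mode, level = tab$level)
  lb <- log_transform(sub(sim$abundance_baseline), zero_replacement)
  lf <- log_transform(sub(sim$abundance_followup), zero_replacement)
  cohort <- apply_exclusions(sim$metadata, criteria = criteria)
  attach_features(cohort, lb, lf)
}

#' Deterministic participant roster with the study's exclusion scenario
#'
#' Builds a 505-pair roster carrying the documented exclusion flags: 37
#' participants missing BMI at one visit, 2 missing the follow-up interval,
#' and 40 on diabetes medication at one visit (disjoint by default), so
#' that [apply_exclusions()] leaves the 426-participant analysis set.
#'
#' @param overlap if `TRUE`, the first diabetes-medication participant also
#'   misses BMI, making the flag sets overlap (removed once; the union
#'   shrinks by one).
#' @return Long data frame of participant-visit records.
#' @export
make_fixture_roster <- function(overlap = FALSE) {
  n <- 505
  pid <- sprintf("G%04d", seq_len(n))
  one <- function(visit) {
    data.frame(participant_id = pid, visit = visit,
               bmi = 22 + (seq_len(n) %% 7),
               diabetes_medication = 0L,
               followup_interval = if (visit == "baseline") 3.15 else NA_real_,
               stringsAsFactors = FALSE)
  }
  b <- one("baseline"); f <- one("follow_up")
  miss_bmi <- 1:37
  b$bmi[miss_bmi[miss_bmi %% 2 == 1]] <- NA
  f$bmi[miss_bmi[miss_bmi %% 2 == 0]] <- NA
  b$followup_interval[38:39] <- NA
  med <- 40:79
  b$diabetes_medication[med[med %% 2 == 0]] <- 1L
  f$diabetes_medication[med[med %% 2 == 1]] <- 1L
  if (overlap) b$bmi[40] <- NA
  rbind(b, f)
}
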