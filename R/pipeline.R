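#' Subset a paired cohort by participant
#'
#' @param cohort a `paired_cohort`.
#' @param keep logical or integer index over participants.
#' @return The subsetted `paired_cohort`.
#' @export
subset_cohort <- function(cohort, keep) {
  stopifnot(inherits(cohort, "paired_cohort"))
  cohort$data <- cohort$data[keep, , drop = FALSE]
  if (!is.null(cohort$features_baseline)) {
    cohort$features_baseline <- cohort$features_baseline[keep, , drop = FALSE]
    cohort$features_followup <- cohort$features_followup[keep, , drop = FALSE]
  }
  cohort
}

#' Validate a pipeline configuration
#'
#' @param config named list (or path to a JSON file) with entries:
#'   `sim` (a `synthetic_cohort`) or `abundance_baseline` /
#'   `abundance_followup` / `metadata` paths; `out_dir`; `seed`; optional
#'   `families`, `confounders`, `min_abund`, `min_prev`,
#'   `zero_replacement`, `fdr_species` (default 0.25), `fdr` (default
#'   0.05), `mediators`, `replication` (a `synthetic_cohort`).
#' @return The completed config list; errors name any missing confounder
#'   column or out-of-range threshold.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  stop_if_not(is.list(config), "config must be a list or JSON path")
  defaults <- list(seed = 1L, families = c("diversity", "crosslag",
                                           "patterns", "phenotypes", "diet",
                                           "mediation", "meta"),
                   confounders = gnhs_confounders(), min_prev = 0.10,
                   min_abund = NULL, zero_replacement = 1e-5,
                   fdr_species = 0.25, fdr = 0.05, mediators = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  stop_if_not(!is.null(config$out_dir), "config$out_dir is required")
  for (th in c("fdr_species", "fdr", "min_prev"))
    stop_if_not(config[[th]] > 0 && config[[th]] <= 1,
                "threshold %s must lie in (0, 1]", th)
  if (is.null(config$sim)) {
    for (p in c("abundance_baseline", "abundance_followup", "metadata")) {
      stop_if_not(!is.null(config[[p]]), "config$%s is required", p)
      stop_if_not(file.exists(config[[p]]), "file not found: %s", config[[p]])
    }
    meta <- utils::read.csv(config$metadata, stringsAsFactors = FALSE)
  } else {
    meta <- config$sim$metadata
  }
  missing_cols <- setdiff(c(config$confounders, "bristol"), names(meta))
  stop_if_not(length(missing_cols) == 0,
              "metadata lacks confounder column(s): %s",
              paste(missing_cols, collapse = ", "))
  config
}

#' Run the full analysis pipeline
#'
#' Executes the stages in the study's order on one conforming dataset:
#' prevalence filter and log transform, exclusions, alpha/beta diversity,
#' cross-lagged screen (with sex-stratified heterogeneity and the WC
#' sensitivity analysis), weight-change-pattern models, mixed-effect
#' microbe-phenotype models, dietary median-split models, mediation on
#' qualifying features, and meta-analytic replication when a second cohort
#' is supplied. Every random stage is seeded from `config$seed`; two runs
#' with the same config produce byte-identical outputs.
#'
#' @param config see [validate_config()].
#' @return Invisibly, a named list of the stage result data frames; TSV
#'   files and `run_log.txt` are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("templag %s", as.character(utils::packageVersion("templag"))),
                 sprintf("R %s", getRversion()),
                 sprintf("seed %d", as.integer(config$seed)))
  note <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))
  emit <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("%s: %d rows", name, nrow(df))
  }
  results <- list()

  if (is.null(config$sim)) {
    ab <- read_abundance_table(config$abundance_baseline, rank_filter = "s__")
    af <- read_abundance_table(config$abundance_followup, rank_filter = "s__")
    meta <- utils::read.csv(config$metadata, stringsAsFactors = FALSE)
    sim <- structure(list(abundance_baseline = ab, abundance_followup = af,
                          metadata = meta), class = "synthetic_cohort")
  } else {
    sim <- config$sim
  }
  cohort <- assemble_cohort(sim, min_abund = config$min_abund,
                            min_prev = config$min_prev,
                            zero_replacement = config$zero_replacement)
  note("cohort: %d participants, %d features after filtering",
       nrow(cohort$data), length(cohort$feature_ids))
  note("exclusions: %s",
       paste(names(cohort$exclusion_log), cohort$exclusion_log,
             sep = "=", collapse = ", "))

  fam <- config$families
  if ("diversity" %in% fam) {
    div <- rbind(alpha_diversity(sim$abundance_baseline),
                 alpha_diversity(sim$abundance_followup))
    emit(div, "alpha_diversity")
    joint <- cbind(sim$abundance_baseline$values, sim$abundance_followup$values)
    ord <- pcoa(bray_curtis(joint), n_axes = 2)
    emit(data.frame(sample_id = rownames(ord$coordinates),
                    ord$coordinates), "pcoa")
    results$diversity <- div
  }

  screen <- NULL
  if ("crosslag" %in% fam) {
    screen <- screen_features(cohort, alpha_fdr = config$fdr_species,
                              confounders = config$confounders)
    emit(screen, "crosslag")
    note("FDR family sizes: rho1=%d rho2=%d", nrow(screen), nrow(screen))
    strat <- lapply(c(female = "female", male = "male"), function(sx) {
      sub <- subset_cohort(cohort, cohort$data$baseline_sex == sx)
      conf <- setdiff(config$confounders, "sex")
      # drop covariates without variation inside the stratum
      conf <- conf[apply(covariate_matrix(sub, conf), 2, stats::sd) > 0]
      tryCatch(screen_features(sub, alpha_fdr = config$fdr_species,
                               confounders = conf),
               error = function(e) NULL)
    })
    res_female <- strat$female
    res_male <- strat$male
    if (!is.null(res_female) && !is.null(res_male))
      emit(sex_heterogeneity(res_female, res_male), "sex_heterogeneity")
    if ("baseline_wc" %in% names(cohort$data)) {
      wc <- sensitivity_wc(cohort, confounders = config$confounders)
      emit(wc$wc, "crosslag_wc")
      note("WC sensitivity: cor(rho1)=%.3f cor(rho2)=%.3f",
           wc$cor_rho1, wc$cor_rho2)
    }
    results$crosslag <- screen
  }

  identified <- if (!is.null(screen))
    screen$feature_id[screen$sig_rho1 | screen$sig_rho2] else character(0)
  note("identified features (FDR < %.2f): %d", config$fdr_species,
       length(identified))

  if ("patterns" %in% fam && length(identified) > 0) {
    pat <- pattern_screen(cohort, identified, confounders = config$confounders)
    emit(pat, "weight_patterns")
    results$patterns <- pat
  }
  phen <- NULL
  if ("phenotypes" %in% fam && length(identified) > 0) {
    phen <- mixed_screen(cohort, identified, confounders = config$confounders)
    emit(phen, "phenotype_assoc")
    results$phenotypes <- phen
  }
  if ("diet" %in% fam) {
    diet <- diet_screen(cohort, confounders = config$confounders)
    emit(diet, "diet")
    results$diet <- diet
  }
  if ("mediation" %in% fam) {
    mediators <- config$mediators
    if (is.null(mediators) && !is.null(screen) && !is.null(phen)) {
      ok_phen <- unique(phen$feature_id[phen$fdr < config$fdr])
      mediators <- intersect(screen$feature_id[screen$sig_rho2], ok_phen)
    }
    if (length(mediators) > 0) {
      med <- mediation_screen(cohort, mediators, seed = config$seed,
                              confounders = c(config$confounders, "bristol"))
      emit(med, "mediation")
      results$mediation <- med
    } else {
      note("mediation: no qualifying mediators; stage skipped")
    }
  }
  if ("meta" %in% fam && !is.null(config$replication) && !is.null(screen)) {
    rep_cohort <- assemble_cohort(config$replication, criteria = NULL,
                                  min_abund = config$min_abund,
                                  min_prev = config$min_prev,
                                  zero_replacement = config$zero_replacement)
    shared <- intersect(cohort$feature_ids, rep_cohort$feature_ids)
    disc <- data.frame(feature_id = screen$feature_id, beta = screen$rho2,
                       se = screen$se_rho2)
    repl <- replication_screen(rep_cohort, shared)
    meta_res <- replication_decision(disc, repl)
    emit(meta_res, "meta_replication")
    results$meta <- meta_res
  }

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(results)
}
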