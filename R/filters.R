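#' Prevalence/abundance feature filter
#'
#' Keeps features detected at or above a minimum relative abundance in at
#' least a minimum fraction of samples (the species quality-control rule:
#' 0.01% abundance in at least 10% of samples). Feature and sample ordering
#' are preserved.
#'
#' @param table an [abundance_table()].
#' @param min_abund abundance floor on the table's own scale. Default 0.01
#'   for percent tables (i.e. 0.01%) and 1e-4 for fraction tables.
#' @param min_prev minimum prevalence as a fraction of samples; a feature
#'   must reach `min_abund` in at least `ceiling(min_prev * n_samples)`
#'   samples. Default 0.10.
#' @return A filtered [abundance_table()]. Emits a warning (not an error) if
#'   no feature survives.
#' @export
filter_prevalence <- function(table, min_abund = NULL, min_prev = 0.10) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(min_abund)) min_abund <- if (table$mode == "percent") 0.01 else 1e-4
  stop_if_not(min_abund > 0 && min_prev > 0 && min_prev <= 1,
              "thresholds must be positive (min_prev in (0,1])")
  need <- ceiling(min_prev * ncol(table$values))
  keep <- rowSums(table$values >= min_abund) >= need
  if (!any(keep)) warning("no feature passed the prevalence filter")
  abundance_table(table$values[keep, , drop = FALSE],
                  mode = table$mode, level = table$level)
}

#' Zero-replaced natural-log transform
#'
#' Replaces exact zeros by a small constant and takes natural logs, on the
#' fraction scale. Percent tables are converted to fractions first, so the
#' conventional replacement constants (1e-5 for species profiles, 1e-9 for
#' pathway profiles) always refer to fractional relative abundance.
#'
#' @param table an [abundance_table()] (or a non-negative numeric matrix
#'   already on the fraction scale).
#' @param zero_replacement positive constant substituted for zeros before the
#'   log; default 1e-5 (species). Use 1e-9 for pathway tables.
#' @return Matrix of natural-log abundances, same dimnames as the input.
#' @export
log_transform <- function(table, zero_replacement = 1e-5) {
  stop_if_not(zero_replacement > 0, "zero_replacement must be > 0")
  if (inherits(table, "abundance_table")) {
    x <- table$values
    if (table$mode == "percent") x <- x / 100
  } else {
    x <- as.matrix(table)
  }
  if (anyNA(x) || any(x < 0)) stop("input must be non-negative", call. = FALSE)
  x[x == 0] <- zero_replacement
  log(x)
}
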