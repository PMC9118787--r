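#' Relative-abundance table
#'
#' Container for a features x samples table of relative abundances, as
#' produced by merging per-sample taxonomic (MetaPhlAn-style) or pathway
#' (HUMAnN-style) profiles. Values are either percentages in \[0, 100\]
#' ("percent" mode) or fractions in \[0, 1\] ("fraction" mode); the mode is
#' auto-detected from per-sample sums and stored so downstream thresholds are
#' always applied on one declared scale.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids character feature identifiers (e.g. pipe-delimited
#'   clade names); default `rownames(values)`.
#' @param sample_ids character sample identifiers; default `colnames(values)`.
#' @param mode `"auto"` (detect from column sums), `"percent"`, or
#'   `"fraction"`.
#' @param level taxonomic rank tag, e.g. `"species"` or `"pathway"`.
#' @return An object of class `abundance_table`: a list with elements
#'   `values`, `mode`, and `level`.
#' @export
abundance_table <- function(values, feature_ids = rownames(values),
                            sample_ids = colnames(values),
                            mode = c("auto", "percent", "fraction"),
                            level = "species") {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) && nrow(values) == 0) feature_ids <- character(0)
  if (is.null(sample_ids) && ncol(values) == 0) sample_ids <- character(0)
  stop_if_not(!is.null(feature_ids) && !is.null(sample_ids),
              "abundance_table requires feature and sample ids")
  stop_if_not(length(feature_ids) == nrow(values) &&
                length(sample_ids) == ncol(values),
              "id lengths do not match the value matrix")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(values)) stop("abundance values contain NA", call. = FALSE)
  if (any(values < 0)) stop("negative abundance values", call. = FALSE)
  dimnames(values) <- list(feature_ids, sample_ids)
  cs <- colSums(values)
  if (mode == "auto") {
    # percent tables sum near 100 per sample, fraction tables near 1
    mode <- if (stats::median(cs) > 2) "percent" else "fraction"
  }
  cap <- if (mode == "percent") 100 else 1
  stop_if_not(all(cs <= cap + 1e-6),
              "per-sample sums exceed %s for %s mode", cap, mode)
  structure(list(values = values, mode = mode, level = level),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d features x %d samples (%s, level=%s)\n",
              nrow(x$values), ncol(x$values), x$mode, x$level))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read a merged abundance table
#'
#' Parses MetaPhlAn-style merged TSVs (first column `clade_name`, `#SampleID`,
#' or similar; remaining columns numeric per-sample abundances) and
#' HUMAnN-style pathway tables (`PWY-XXXX: description` row ids).
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect `"metaphlan"` or `"humann"`; sets the default `level` tag.
#' @param rank_filter optional clade-rank marker such as `"s__"`: keep rows
#'   whose id contains the marker but no finer rank (for `"s__"`, rows with a
#'   strain marker `"t__"` are dropped).
#' @param mode passed to [abundance_table()].
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, dialect = c("metaphlan", "humann"),
                                 rank_filter = NULL,
                                 mode = c("auto", "percent", "fraction")) {
  dialect <- match.arg(dialect)
  stop_if_not(file.exists(path), "file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  stop_if_not(ncol(raw) >= 2, "expected a feature-id column plus sample columns")
  ids <- as.character(raw[[1]])
  num <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage.mode(num) <- "double")
  if (anyNA(num)) {
    bad <- which(apply(is.na(num), 1, any))
    stop(sprintf("malformed numeric values at data line(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  if (any(num < 0)) stop("negative abundance values in file", call. = FALSE)
  level <- if (dialect == "humann") "pathway" else "clade"
  if (!is.null(rank_filter)) {
    finer <- c("k__" = "p__", "p__" = "c__", "c__" = "o__", "o__" = "f__",
               "f__" = "g__", "g__" = "s__", "s__" = "t__")
    keep <- grepl(rank_filter, ids, fixed = TRUE)
    if (rank_filter %in% names(finer))
      keep <- keep & !grepl(finer[[rank_filter]], ids, fixed = TRUE)
    ids <- ids[keep]
    num <- num[keep, , drop = FALSE]
    if (rank_filter == "s__") level <- "species"
  }
  abundance_table(num, feature_ids = ids, sample_ids = colnames(num),
                  mode = mode, level = level)
}

#' Write an abundance table as TSV
#'
#' @param table an [abundance_table()].
#' @param path output path.
#' @param id_column header name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path, id_column = "clade_name") {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
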