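#' Per-sample alpha diversity
#'
#' Observed species, Shannon index (natural log), Simpson index (1 - sum
#' p_i^2), and Pielou's evenness (H / ln S, defined 0 for a single species),
#' computed on per-sample relative abundances renormalized to sum 1 over the
#' retained features.
#'
#' @param table an [abundance_table()] or non-negative features x samples
#'   matrix.
#' @return Data frame with columns `sample_id`, `observed_species`,
#'   `shannon`, `simpson`, `pielou`.
#' @export
alpha_diversity <- function(table) {
  x <- if (inherits(table, "abundance_table")) table$values else as.matrix(table)
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  cs <- colSums(x)
  if (any(cs == 0)) stop("all-zero sample(s): ",
                         paste(colnames(x)[cs == 0], collapse = ", "),
                         call. = FALSE)
  p <- sweep(x, 2, cs, "/")
  observed <- colSums(p > 0)
  shannon <- apply(p, 2, function(q) { q <- q[q > 0]; -sum(q * log(q)) })
  simpson <- 1 - colSums(p^2)
  pielou <- ifelse(observed > 1, shannon / log(observed), 0)
  data.frame(sample_id = colnames(x) %||% as.character(seq_len(ncol(x))),
             observed_species = observed, shannon = shannon,
             simpson = simpson, pielou = pielou,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(a, b) = sum |a_i - b_i| / sum (a_i + b_i), computed over samples
#' (columns).
#'
#' @param table an [abundance_table()] or non-negative features x samples
#'   matrix.
#' @return Symmetric samples x samples matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  x <- if (inherits(table, "abundance_table")) table$values else as.matrix(table)
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  zero <- colSums(x) == 0
  if (sum(zero) >= 2)
    stop("Bray-Curtis undefined between all-zero samples", call. = FALSE)
  d <- as.matrix(vegan::vegdist(t(x), method = "bray"))
  dimnames(d) <- list(colnames(x), colnames(x))
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Eigendecomposition of the double-centered Gower matrix. Axes are ordered
#' by decreasing eigenvalue; negative eigenvalues are reported but excluded
#' from the coordinates. For reproducibility each axis's sign is fixed so
#' that its largest-magnitude coordinate is positive.
#'
#' @param d square symmetric non-negative distance matrix with zero diagonal
#'   (or a `dist` object).
#' @param n_axes number of coordinate axes to return (default 2; truncated
#'   to the number of positive eigenvalues).
#' @return An `ordination_result`: list with `coordinates` (samples x axes,
#'   columns `PCo1`, `PCo2`, ...), `eigenvalues` (all, non-increasing), and
#'   `n_axes`.
#' @export
pcoa <- function(d, n_axes = 2) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    stop_if_not(nrow(d) == ncol(d), "distance matrix must be square")
    stop_if_not(max(abs(d - t(d))) < 1e-8, "distance matrix must be symmetric")
    stop_if_not(all(diag(d) == 0), "distance matrix must have zero diagonal")
    stop_if_not(all(d >= 0), "distances must be non-negative")
  }
  dd <- stats::as.dist(d)
  n <- attr(dd, "Size")
  fit <- stats::cmdscale(dd, k = min(n_axes, n - 1), eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  coords <- fit$points
  k <- min(n_axes, sum(eig > 1e-8 * max(abs(eig))), ncol(coords))
  coords <- coords[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    s <- sign(coords[which.max(abs(coords[, j])), j])
    if (s < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = eig,
                 n_axes = ncol(coords)),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  rel <- x$eigenvalues / sum(pmax(x$eigenvalues, 0))
  cat(sprintf("<ordination_result> %d samples, %d axes; leading eigenvalues: %s\n",
              nrow(x$coordinates), x$n_axes,
              paste(sprintf("%.3f", utils::head(rel, 3)), collapse = ", ")))
  invisible(x)
}
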