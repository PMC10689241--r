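#' Overlap-score adjacency matrix between feature bins
#'
#' Feature values are split into `n_bins` groups (equal-width bins over the
#' range by default, or equal-count bins). For every ordered pair of bin
#' groups (U, V), the overlap score OS_{U->V}(k) is the fraction of the k
#' nearest neighbors of points of U — neighbors searched within the
#' restricted set `U union V` minus the query point — that belong to V.
#' Diagonal entries are defined as 0 (no self-edges). Empty bins are
#' dropped (recorded in the result).
#'
#' @param coords point coordinates (matrix; the space in which neighbors
#'   are Euclidean — original waveform space, a reduced embedding, or a
#'   feature space).
#' @param feature numeric feature value per point.
#' @param n_bins number of bins (default 10).
#' @param k neighbors per point (default `3 * n_bins`, clamped per bin
#'   pair so it never exceeds the restricted set size minus one).
#' @param bin_mode `"width"` (equal-width, the literal reading of "ten
#'   equal bins") or `"count"` (equal-count).
#' @return list with `A` (adjacency matrix over non-empty bins, zero
#'   diagonal), `bins` (per-point bin id), `edges`, `k`, `dropped_bins`.
#' @export
overlap_score_matrix <- function(coords, feature, n_bins = 10, k = NULL,
                                 bin_mode = c("width", "count")) {
  bin_mode <- match.arg(bin_mode)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(feature), n_bins >= 2)
  if (any(!is.finite(feature))) stop("feature values must be finite")
  k <- k %||% (3 * n_bins)
  stopifnot(k >= 1)

  if (bin_mode == "width") {
    edges <- seq(min(feature), max(feature), length.out = n_bins + 1)
  } else {
    edges <- stats::quantile(feature, probs = seq(0, 1, length.out = n_bins + 1))
    edges <- unique(as.numeric(edges))
    if (length(edges) < 3) stop("feature has too few distinct values to bin")
  }
  bins <- findInterval(feature, edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  counts <- tabulate(bins, nbins = length(edges) - 1)
  nonempty <- which(counts > 0)
  if (length(nonempty) < 2) stop("fewer than 2 non-empty bins")
  dropped <- setdiff(seq_along(counts), nonempty)

  nb <- length(nonempty)
  D <- as.matrix(stats::dist(coords))
  A <- .si_overlap_cpp(D, match(bins, nonempty), nb, k)
  rownames(A) <- colnames(A) <- paste0("bin", nonempty)
  list(A = A, bins = bins, edges = edges, k = k, dropped_bins = dropped)
}

#' Structure Index from an overlap adjacency matrix
#'
#' `SI = max(0, 1 - (2 / (n^2 - n)) * sum(A))`: one minus the mean
#' weighted out-degree of the bin-overlap graph after scaling. 1 means
#' perfectly separated feature bins (no k-NN mixing), 0 a random feature
#' distribution (full mixing); small-sample asymmetry of k-NN graphs can
#' push the raw value slightly negative, hence the clamp at 0.
#'
#' @param A square adjacency matrix with zero diagonal (or the list
#'   returned by [overlap_score_matrix()]).
#' @return SI value in [0, 1].
#' @export
structure_index <- function(A) {
  if (is.list(A)) A <- A$A
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  n <- nrow(A)
  max(0, 1 - 2 / (n^2 - n) * sum(A))
}

#' Structure Index with shuffle significance
#'
#' The observed SI is compared against a null distribution obtained by
#' permuting the feature values over points (destroying any spatial
#' organization while keeping the marginal distribution). The one-sided
#' p-value comes from a one-sample t-test of the shuffle distribution
#' against the observed value (`method = "t"`), or from the empirical rank
#' (`method = "empirical"`).
#'
#' @inheritParams overlap_score_matrix
#' @param n_shuffles permutations (default 100; 0 skips the test).
#' @param seed RNG seed for the permutations.
#' @param method p-value method.
#' @return list with `si`, `A`, `shuffles` (null SI values), `p`, `k`,
#'   `n_bins`.
#' @export
si_significance <- function(coords, feature, n_bins = 10, k = NULL,
                            n_shuffles = 100, seed = NULL,
                            bin_mode = c("width", "count"),
                            method = c("t", "empirical")) {
  bin_mode <- match.arg(bin_mode)
  method <- match.arg(method)
  if (length(unique(feature)) < 2) stop("constant feature: SI undefined")
  if (!is.null(seed)) set.seed(seed)
  os <- overlap_score_matrix(coords, feature, n_bins, k, bin_mode)
  si <- structure_index(os$A)
  if (n_shuffles <= 0) {
    return(list(si = si, A = os$A, shuffles = numeric(0), p = NA_real_,
                k = os$k, n_bins = n_bins))
  }
  shuffles <- vapply(seq_len(n_shuffles), function(s) {
    fs <- sample(feature)
    structure_index(overlap_score_matrix(coords, fs, n_bins, k, bin_mode)$A)
  }, 0)
  p <- if (method == "t") {
    if (stats::sd(shuffles) == 0) as.numeric(si <= mean(shuffles))
    else stats::t.test(shuffles, mu = si, alternative = "less")$p.value
  } else {
    (1 + sum(shuffles >= si)) / (n_shuffles + 1)
  }
  list(si = si, A = os$A, shuffles = shuffles, p = p, k = os$k,
       n_bins = n_bins)
}

#' SI report over all columns of a feature table
#'
#' Convenience batch mode: one SI (with optional shuffle test) per feature
#' column, in a given coordinate space.
#'
#' @param coords matrix of point coordinates.
#' @param features data frame of per-point features.
#' @param ... passed to [si_significance()].
#' @return data frame with `feature`, `si`, `p`.
#' @export
si_table <- function(coords, features, ...) {
  rows <- lapply(names(features), function(nm) {
    r <- si_significance(coords, features[[nm]], ...)
    data.frame(feature = nm, si = r$si, p = r$p)
  })
  do.call(rbind, rows)
}
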