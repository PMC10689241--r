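#' Remove density outliers from a point cloud
#'
#' Points whose mean distance to their k nearest neighbors exceeds the
#' given percentile of that statistic are removed. Deterministic.
#'
#' @param cloud `ripple_cloud` or numeric matrix.
#' @param k neighbors (default 10).
#' @param pct percentile in (50, 100]; 100 removes nothing.
#' @return list with `X` (filtered matrix), `removed` (row indices),
#'   `kept` (row indices).
#' @export
remove_outliers <- function(cloud, k = 10, pct = 95) {
  X <- cloud_matrix(cloud)
  if (nrow(X) <= k) stop("cloud must have more than k points")
  stopifnot(pct > 50, pct <= 100)
  nn <- RANN::nn2(X, k = k + 1)
  score <- rowMeans(nn$nn.dists[, -1, drop = FALSE])
  if (pct == 100) {
    removed <- integer(0)
  } else {
    removed <- which(score > stats::quantile(score, pct / 100))
  }
  kept <- setdiff(seq_len(nrow(X)), removed)
  list(X = X[kept, , drop = FALSE], removed = removed, kept = kept)
}

#' Vietoris-Rips persistence barcodes with bootstrapped subsamples
#'
#' Computes Rips persistence (homology groups H0-H2) on subsamples of the
#' cloud. H0 is exact on the full edge filtration (union-find); H1/H2 are
#' computed by boundary-matrix reduction over Z/2 on the filtration
#' truncated at `threshold`, with classes still alive at the threshold
#' right-censored (death = `Inf`). The default threshold is a multiple of
#' the median 15-NN distance, which comfortably exceeds the death radius of
#' sample-scale features while keeping the simplex count tractable.
#'
#' Subsamples are uniform random draws for component counting
#' (`maxdim = 0`) and farthest-point (maxmin) landmark sets when loops or
#' cavities are sought: at desk scales (a few hundred points per
#' replicate) coverage-uniform landmarks resolve small topological
#' features that uniform random subsamples miss, while for components the
#' density information random draws preserve is what matters.
#'
#' @param cloud `ripple_cloud` or matrix.
#' @param maxdim highest homology dimension (0, 1 or 2).
#' @param subsample points per replicate (capped at 1500 for maxdim <= 1,
#'   450 for maxdim 2 to bound the simplex count).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed fixing the subsamples.
#' @param threshold truncation radius, or `NULL` for the automatic rule.
#' @param threshold_mult multiplier of the median 15-NN distance used by
#'   the automatic rule (3 for maxdim <= 1, 2 for maxdim 2).
#' @param sample_method `"maxmin"` or `"random"`; default `"random"` for
#'   `maxdim = 0`, `"maxmin"` otherwise.
#' @param max_simplices guard on triangle/tetrahedron counts.
#' @return list of `rips_barcode` objects (one per replicate), each with
#'   matrices `H0`, `H1`, `H2` of birth/death pairs, the `threshold`, and
#'   the subsample indices.
#' @export
persistence_barcodes <- function(cloud, maxdim = 2, subsample = NULL,
                                 n_boot = 1, seed = NULL, threshold = NULL,
                                 threshold_mult = NULL,
                                 sample_method = NULL,
                                 max_simplices = 5e7) {
  X <- cloud_matrix(cloud)
  sample_method <- sample_method %||%
    (if (maxdim == 0) "random" else "maxmin")
  stopifnot(sample_method %in% c("maxmin", "random"))
  stopifnot(maxdim %in% 0:2)
  if (!is.null(seed)) set.seed(seed)
  cap <- if (maxdim >= 2) 450L else 1500L
  m <- min(subsample %||% cap, cap, nrow(X))
  # maxmin landmarks only equalize spacing when they thin the cloud; a
  # landmark set as large as the cloud inherits its spacing tail
  if (sample_method == "maxmin" && nrow(X) >= 50)
    m <- min(m, ceiling(0.75 * nrow(X)))
  mult <- threshold_mult %||% (if (maxdim >= 2) 2 else 3)

  lapply(seq_len(n_boot), function(b) {
    idx <- if (m >= nrow(X)) seq_len(nrow(X))
           else if (sample_method == "maxmin")
             maxmin_subsample(X, m, start = sample.int(nrow(X), 1))
           else sample.int(nrow(X), m)
    D <- as.matrix(stats::dist(X[idx, , drop = FALSE]))
    thr <- threshold %||% {
      knn <- apply(D, 1, function(r) sort(r)[min(16, length(r))])
      min(mult * stats::median(knn), max(D))
    }
    r <- .rips_cpp(D, maxdim, thr, max_simplices)
    structure(list(H0 = r$H0, H1 = r$H1, H2 = r$H2,
                   threshold = r$threshold, subsample = idx, replicate = b),
              class = "rips_barcode")
  })
}

#' @export
print.rips_barcode <- function(x, ...) {
  cat(sprintf("<rips_barcode: n=%d, threshold=%.3g; bars H0=%d H1=%s H2=%s>\n",
              length(x$subsample), x$threshold, nrow(x$H0),
              if (is.null(x$H1)) "-" else nrow(x$H1),
              if (is.null(x$H2)) "-" else nrow(x$H2)))
  invisible(x)
}

#' Betti numbers from a barcode via a bar-significance rule
#'
#' Censored bars (death beyond the truncation radius, including the
#' infinite H0 bar) are always significant. The default `"dominance"`
#' rule works differently per group. For H0 it counts components: the
#' infinite bar plus every single-linkage merge whose radius lies well
#' above the bulk (at least `min_ratio[1]` times the median merge radius)
#' *and* whose dying component carries at least a `min_mass` fraction of
#' the points — sampling stragglers merge late but carry almost no mass,
#' while real clusters carry both signatures. For H1/H2 it counts the
#' finite bars above the largest *relative* gap of the sorted persistence
#' spectrum: noise persistences decay smoothly with consecutive ratios
#' near 1, while real loops and cavities sit a multiplicative break
#' (`min_ratio[2]`) above the noise continuum; only gaps in the upper
#' half of the spectrum qualify. `"gap"` places the cut at the largest
#' additive gap and `"frac"` keeps bars longer than half the longest;
#' both are retained for sensitivity checks.
#'
#' @param barcode a `rips_barcode`.
#' @param rule `"dominance"`, `"gap"` or `"frac"`.
#' @param min_ratio length-2 numeric: minimum multiple of the median merge
#'   radius for an H0 component, and minimum relative persistence break
#'   for H1/H2 features.
#' @param min_mass minimum fraction of points a dying H0 component must
#'   carry to count as a cluster.
#' @return named integer vector `c(b0, b1, b2)` (only the computed groups)
#'   with the rule recorded in `attr(, "rule")`.
#' @export
betti_numbers <- function(barcode, rule = c("dominance", "gap", "frac"),
                          min_ratio = c(2.5, 1.6), min_mass = 0.05) {
  rule <- match.arg(rule)
  thr <- barcode$threshold
  # bars above the largest relative gap in the upper half of the sorted
  # values; 0 when no break exceeds rho
  gap_count <- function(vals, rho) {
    d <- sort(vals[vals > 0], decreasing = TRUE)
    if (length(d) < 3) return(0L)
    elig <- which(d >= stats::median(d))
    elig <- elig[elig < length(d)]
    ratios <- d[elig] / d[elig + 1]
    if (max(ratios) >= rho) as.integer(elig[which.max(ratios)]) else 0L
  }
  count_h0 <- function(bars) {
    cens <- sum(!is.finite(bars[, 2]))
    fin <- is.finite(bars[, 2]) & bars[, 2] > 0
    d <- bars[fin, 2]
    if (length(d) < 3) return(as.integer(cens + length(d)))
    n_pts <- length(d) + 1
    mass <- if (ncol(bars) >= 3) bars[fin, 3] else rep(n_pts, length(d))
    big <- d >= min_ratio[1] * stats::median(d) &
      mass >= max(3, min_mass * n_pts)
    as.integer(cens + sum(big))
  }
  count_group <- function(bars, is_h0 = FALSE) {
    if (is.null(bars)) return(NA_integer_)
    if (nrow(bars) == 0) return(0L)
    if (is_h0 && rule == "dominance") return(count_h0(bars))
    cens <- !is.finite(bars[, 2])
    p_fin <- if (is_h0) bars[!cens, 2] else bars[!cens, 2] - bars[!cens, 1]
    p_fin <- p_fin[p_fin > 0]
    n_sig <- sum(cens)
    if (length(p_fin) > 0) {
      n_sig <- n_sig + switch(rule,
        dominance = {
          if (length(p_fin) < 3)
            sum(p_fin > 0.5 * max(c(p_fin, thr - bars[cens, 1])))
          else gap_count(p_fin, min_ratio[2])
        },
        gap = {
          p_all <- sort(c(p_fin, thr - bars[cens, 1]), decreasing = TRUE)
          if (length(p_all) < 2) length(p_fin)
          else {
            g <- p_all[-length(p_all)] - p_all[-1]
            cut <- which.max(g)
            max(0L, cut - sum(cens))
          }
        },
        frac = sum(p_fin > 0.5 * max(c(p_fin, thr - bars[cens, 1]))))
    }
    as.integer(n_sig)
  }
  out <- c(b0 = count_group(barcode$H0, is_h0 = TRUE),
           b1 = count_group(barcode$H1),
           b2 = count_group(barcode$H2))
  out <- out[!is.na(out)]
  attr(out, "rule") <- rule
  out
}

#' Angle-based intrinsic dimension (ABID)
#'
#' For every point, the k nearest neighbors define unit difference vectors
#' whose pairwise squared cosines estimate the local dimension: isotropic
#' directions in d dimensions satisfy `E[cos^2 theta] = 1/d`, so
#' `d_hat(x) = k (k - 1) / sum_{i != j} cos^2 theta_ij` (self-pairs
#' excluded). The aggregate estimate is the median over points, invariant
#' to rotation, translation and uniform scaling of the cloud.
#'
#' @param cloud `ripple_cloud` or matrix.
#' @param k neighbors (default 50; must be >= 10).
#' @return list with `estimate` (median), `per_point`, `k`,
#'   `method = "abid"`.
#' @export
abid_dimension <- function(cloud, k = 50) {
  X <- cloud_matrix(cloud)
  n <- nrow(X)
  stopifnot(k >= 10, n > k)
  nn <- RANN::nn2(X, k = k + 1)
  est <- numeric(n)
  for (i in seq_len(n)) {
    idx <- nn$nn.idx[i, -1]
    V <- X[idx, , drop = FALSE] - matrix(X[i, ], k, ncol(X), byrow = TRUE)
    nv <- sqrt(rowSums(V^2))
    nz <- nv > 0          # duplicate points contribute no direction
    V <- V[nz, , drop = FALSE] / nv[nz]
    kk <- nrow(V)
    if (kk < 2) { est[i] <- NA_real_; next }
    G <- tcrossprod(V)
    est[i] <- kk * (kk - 1) / (sum(G^2) - kk)
  }
  est <- est[is.finite(est)]
  list(estimate = stats::median(est), per_point = est, k = k,
       method = "abid")
}
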