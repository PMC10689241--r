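#' Reduce a waveform cloud to a low-dimensional embedding
#'
#' Dimensionality reduction to the intrinsic dimension (4 for
#' experimental-like ripple data). UMAP (via uwot, spectral initialization
#' for run-to-run stability), Isomap (vegan) and PCA are supported; UMAP
#' and PCA keep a fitted handle so new events can be projected later.
#' Backend reconstruction parameters stay at their defaults and are
#' recorded.
#'
#' @param cloud `ripple_cloud` or matrix.
#' @param method `"umap"`, `"isomap"` or `"pca"`.
#' @param d target dimension (default 4).
#' @param seed RNG seed.
#' @param n_neighbors UMAP/Isomap neighborhood size.
#' @return an `swr_embedding`: list with `coords` (N x d), `method`, `d`,
#'   `seed`, `model` (fitted handle or `NULL`), `src` (source matrix).
#' @export
reduce_embedding <- function(cloud, method = c("umap", "isomap", "pca"),
                             d = 4, seed = NULL, n_neighbors = 15) {
  method <- match.arg(method)
  X <- cloud_matrix(cloud)
  stopifnot(d >= 2, d <= ncol(X))
  if (!is.null(seed)) set.seed(seed)
  model <- NULL
  coords <- switch(method,
    umap = {
      m <- uwot::umap(X, n_components = d, n_neighbors = n_neighbors,
                      init = "spectral", ret_model = TRUE, n_threads = 1,
                      n_sgd_threads = 1)
      model <- m
      m$embedding
    },
    isomap = {
      m <- vegan::isomap(stats::dist(X), ndim = d, k = n_neighbors)
      m$points[, seq_len(d), drop = FALSE]
    },
    pca = {
      m <- stats::prcomp(X, rank. = d)
      model <- m
      m$x[, seq_len(d), drop = FALSE]
    })
  colnames(coords) <- paste0("dim", seq_len(d))
  structure(list(coords = coords, method = method, d = d, seed = seed,
                 model = model, src = X,
                 n_neighbors = n_neighbors),
            class = "swr_embedding")
}

#' @export
print.swr_embedding <- function(x, ...) {
  cat(sprintf("<swr_embedding: %s, %d points x %d dims>\n", x$method,
              nrow(x$coords), x$d))
  invisible(x)
}

embedding_coords <- function(x) {
  if (inherits(x, "swr_embedding")) x$coords else as.matrix(x)
}

# voxel ids anchored at the coordinate-wise minimum
voxel_ids <- function(coords, voxel_size) {
  idx <- floor(sweep(coords, 2, apply(coords, 2, min)) / voxel_size)
  apply(idx, 1, paste, collapse = "_")
}

#' Spatial correlation between two features over embedding voxels
#'
#' The embedding is partitioned into voxels of the given size; per-voxel
#' means of both features are Pearson-correlated over voxels meeting the
#' minimum occupancy.
#'
#' @param embedding `swr_embedding` or coordinate matrix.
#' @param feature_a,feature_b per-event feature values.
#' @param voxel_size voxel edge length in embedding units.
#' @param min_occupancy minimum events per voxel (default 5).
#' @return list with `r2`, `r`, `p` (two-sided, against zero correlation),
#'   `n_voxels`.
#' @export
voxel_spatial_correlation <- function(embedding, feature_a, feature_b,
                                      voxel_size = 1, min_occupancy = 5) {
  coords <- embedding_coords(embedding)
  stopifnot(nrow(coords) == length(feature_a),
            length(feature_a) == length(feature_b))
  vid <- voxel_ids(coords, voxel_size)
  counts <- table(vid)
  keep <- names(counts)[counts >= min_occupancy]
  if (length(unique(vid)) < 2)
    stop("all events fall in one voxel: voxel size too large")
  if (length(keep) < 10)
    stop("fewer than 10 sufficiently occupied voxels")
  ma <- tapply(feature_a, vid, mean)[keep]
  mb <- tapply(feature_b, vid, mean)[keep]
  ct <- stats::cor.test(ma, mb)
  list(r2 = unname(ct$estimate^2), r = unname(ct$estimate), p = ct$p.value,
       n_voxels = length(keep))
}

#' Validate the voxel size with an anticorrelated/random toy model
#'
#' For each candidate size, feature pairs with known expected correlation
#' are simulated on the actual embedding: an anticorrelated pair (a smooth
#' spatial field plus unit noise against its negative plus independent
#' noise; expected voxel R2 = 1) and a random pair (independent noise;
#' expected R2 = 0). The optimal size minimizes
#' `(R2_anti - 1)^2 + R2_rand^2`: voxels too small average too few events
#' and inflate the random R2, voxels too large lose spatial resolution.
#'
#' @param embedding `swr_embedding` or coordinate matrix.
#' @param sizes candidate voxel sizes (>= 2 values).
#' @param n_rep simulation repetitions per size.
#' @param min_occupancy minimum events per voxel.
#' @param seed RNG seed.
#' @return list with `optimal` size and `table` of per-size mean R2 and
#'   score.
#' @export
validate_voxel_size <- function(embedding, sizes, n_rep = 10,
                                min_occupancy = 5, seed = NULL) {
  coords <- embedding_coords(embedding)
  stopifnot(length(sizes) >= 2)
  if (!is.null(seed)) set.seed(seed)
  g <- as.numeric(scale(coords[, 1]))    # smooth field: first embedding axis
  n <- nrow(coords)
  rows <- lapply(sizes, function(sz) {
    r2a <- r2r <- rep(NA_real_, n_rep)
    for (r in seq_len(n_rep)) {
      fa <- g + stats::rnorm(n); fb <- -g + stats::rnorm(n)
      ra <- stats::rnorm(n); rb <- stats::rnorm(n)
      va <- tryCatch(voxel_spatial_correlation(coords, fa, fb, sz,
                                               min_occupancy),
                     error = function(e) NULL)
      vr <- tryCatch(voxel_spatial_correlation(coords, ra, rb, sz,
                                               min_occupancy),
                     error = function(e) NULL)
      if (!is.null(va)) r2a[r] <- va$r2
      if (!is.null(vr)) r2r[r] <- vr$r2
    }
    data.frame(size = sz, r2_anti = mean(r2a, na.rm = TRUE),
               r2_rand = mean(r2r, na.rm = TRUE),
               usable = !all(is.na(r2a)) && !all(is.na(r2r)))
  })
  tab <- do.call(rbind, rows)
  tab$score <- ifelse(tab$usable, (tab$r2_anti - 1)^2 + tab$r2_rand^2, Inf)
  list(optimal = tab$size[which.min(tab$score)], table = tab)
}

#' Density-contour region of interest on a 2D embedding projection
#'
#' Events whose feature value lies in `range` are selected (at least 30)
#' and their bivariate Gaussian kernel density is estimated on a 200 x 200
#' grid with Scott's bandwidth. The density mass is partitioned into 10
#' iso-proportion levels: level j encloses the top j/10 of the total mass
#' (level 6 or 7 typically balances over- and under-smoothing). The
#' polygons of the chosen level and a membership predicate are returned.
#'
#' @param coords2d N x 2 coordinates (an embedding projection).
#' @param feature per-event feature values.
#' @param range feature value range defining the selection.
#' @param level contour level index, 1..10 (mass proportion `level / 10`).
#' @param grid_n grid resolution per axis (default 200).
#' @return a `contour_roi`: list with `polygons` (list of x/y paths),
#'   `height` (density at the level), `level`, `grid`, `selected` (event
#'   indices), `feature_range`.
#' @export
density_roi <- function(coords2d, feature, range, level = 7, grid_n = 200) {
  coords2d <- as.matrix(coords2d)
  stopifnot(ncol(coords2d) == 2, level %in% 1:10)
  sel <- which(feature >= range[1] & feature <= range[2])
  if (length(sel) < 30) stop("fewer than 30 events in the feature range")
  P <- coords2d[sel, , drop = FALSE]
  n <- nrow(P)
  scott <- function(v) stats::sd(v) * n^(-1 / 6)
  kd <- MASS::kde2d(P[, 1], P[, 2], n = grid_n,
                    h = 4 * c(scott(P[, 1]), scott(P[, 2])),
                    lims = c(range(P[, 1]), range(P[, 2])))
  mass <- kd$z / sum(kd$z)
  o <- order(kd$z, decreasing = TRUE)
  cum <- cumsum(mass[o])
  # density height below which the top level/10 of mass lies
  cut_idx <- which(cum >= level / 10)[1]
  height <- kd$z[o][cut_idx]
  polys <- grDevices::contourLines(kd$x, kd$y, kd$z, levels = height)
  structure(list(polygons = polys, height = height, level = level,
                 grid = kd, selected = sel, feature_range = range),
            class = "contour_roi")
}

#' Membership of points in a density-contour ROI
#'
#' A point belongs to the ROI when the ROI's density surface, evaluated at
#' the nearest grid node, reaches the ROI's level height. Intersect
#' several ROIs by combining the logical results.
#'
#' @param roi a `contour_roi`.
#' @param points2d N x 2 coordinates.
#' @return logical vector.
#' @export
roi_membership <- function(roi, points2d) {
  points2d <- as.matrix(points2d)
  gx <- roi$grid$x; gy <- roi$grid$y
  ix <- pmin(pmax(findInterval(points2d[, 1], gx), 1), length(gx))
  iy <- pmin(pmax(findInterval(points2d[, 2], gy), 1), length(gy))
  inside <- roi$grid$z[cbind(ix, iy)] >= roi$height
  inside & points2d[, 1] >= min(gx) & points2d[, 1] <= max(gx) &
    points2d[, 2] >= min(gy) & points2d[, 2] <= max(gy)
}

#' Centroid distances between event groups with bootstrap and shuffle
#'
#' Group centroids are mean coordinates; distances are Euclidean, either
#' in chosen 2D projections or in the full embedding dimension. The
#' bootstrap resamples an equal number of events per group (with
#' replacement); the shuffle permutes group labels over events. The
#' one-sided p-value is the fraction of shuffles with a distance at least
#' the observed one.
#'
#' @param embedding `swr_embedding` or coordinate matrix.
#' @param labels group label per event (2+ groups).
#' @param projections list of axis index pairs, or `NULL` for the full
#'   space.
#' @param n_boot bootstrap repetitions.
#' @param sample_size events drawn per group and repetition (groups below
#'   this size are excluded, with a message).
#' @param n_shuffles label permutations.
#' @param seed RNG seed.
#' @return data frame: group pair, projection, observed distance,
#'   bootstrap mean and s.d., shuffle mean and s.d., p.
#' @export
centroid_analysis <- function(embedding, labels, projections = NULL,
                              n_boot = 100, sample_size = 50,
                              n_shuffles = 100, seed = NULL) {
  coords <- embedding_coords(embedding)
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(labels)
  sizes <- table(labels)
  keep_groups <- names(sizes)[sizes >= sample_size]
  if (length(keep_groups) < 2)
    stop("need at least 2 groups with >= sample_size events")
  if (length(keep_groups) < length(sizes))
    message("excluded groups below sample size: ",
            paste(setdiff(names(sizes), keep_groups), collapse = ", "))
  keep <- labels %in% keep_groups
  coords <- coords[keep, , drop = FALSE]
  labels <- labels[keep]

  projs <- projections %||% list(seq_len(ncol(coords)))
  pname <- vapply(projs, function(p)
    if (length(p) == ncol(coords)) "full" else paste(p, collapse = "x"), "")
  pairs <- utils::combn(keep_groups, 2, simplify = FALSE)

  cdist <- function(cc, ll, g1, g2, ax) {
    c1 <- colMeans(cc[ll == g1, ax, drop = FALSE])
    c2 <- colMeans(cc[ll == g2, ax, drop = FALSE])
    sqrt(sum((c1 - c2)^2))
  }
  rows <- list()
  for (pp in seq_along(projs)) {
    ax <- projs[[pp]]
    for (pr in pairs) {
      g1 <- pr[1]; g2 <- pr[2]
      obs <- cdist(coords, labels, g1, g2, ax)
      boot <- vapply(seq_len(n_boot), function(b) {
        i1 <- sample(which(labels == g1), sample_size, replace = TRUE)
        i2 <- sample(which(labels == g2), sample_size, replace = TRUE)
        cc <- coords[c(i1, i2), , drop = FALSE]
        ll <- rep(c(g1, g2), each = sample_size)
        cdist(cc, ll, g1, g2, ax)
      }, 0)
      shuf <- vapply(seq_len(n_shuffles), function(s)
        cdist(coords, sample(labels), g1, g2, ax), 0)
      rows[[length(rows) + 1]] <- data.frame(
        group1 = g1, group2 = g2, projection = pname[pp], distance = obs,
        boot_mean = mean(boot), boot_sd = stats::sd(boot),
        shuffle_mean = mean(shuf), shuffle_sd = stats::sd(shuf),
        p = (1 + sum(shuf >= obs)) / (n_shuffles + 1))
    }
  }
  do.call(rbind, rows)
}

#' Rigid alignment of two embeddings through shared feature bins
#'
#' The shared feature is split into `n_bins` equal-width bins over the
#' union of both ranges; the center of mass of each bin's events is
#' computed in both embeddings, and the optimal rotation and translation
#' mapping embedding B's bin centers onto embedding A's are found in
#' closed form (Kabsch / orthogonal Procrustes on the centered bin
#' centers, determinant forced to +1).
#'
#' @param emb_a,emb_b `swr_embedding` objects or coordinate matrices (same
#'   dimension).
#' @param feature_a,feature_b per-event shared feature values.
#' @param n_bins number of feature bins (default 20; at least 3 bins must
#'   be non-empty in both datasets).
#' @return list with `R` (rotation), `T` (translation), `aligned`
#'   (embedding B coordinates mapped into A's frame), `residuals` per bin,
#'   `bins_used`.
#' @export
align_embeddings <- function(emb_a, emb_b, feature_a, feature_b,
                             n_bins = 20) {
  A <- embedding_coords(emb_a); B <- embedding_coords(emb_b)
  stopifnot(ncol(A) == ncol(B), nrow(A) == length(feature_a),
            nrow(B) == length(feature_b))
  rng <- range(c(feature_a, feature_b))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  ba <- findInterval(feature_a, edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  bb <- findInterval(feature_b, edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  shared <- intersect(unique(ba), unique(bb))
  if (length(shared) < 3) stop("fewer than 3 shared non-empty feature bins")
  Pa <- t(vapply(shared, function(b) colMeans(A[ba == b, , drop = FALSE]),
                 numeric(ncol(A))))
  Pb <- t(vapply(shared, function(b) colMeans(B[bb == b, , drop = FALSE]),
                 numeric(ncol(B))))
  ca <- colMeans(Pa); cb <- colMeans(Pb)
  H <- crossprod(sweep(Pb, 2, cb), sweep(Pa, 2, ca))
  sv <- svd(H)
  S <- diag(ncol(A))
  S[ncol(A), ncol(A)] <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% S %*% t(sv$u)
  Tr <- ca - as.numeric(R %*% cb)
  aligned <- sweep(B %*% t(R), 2, Tr, `+`)
  fitted_centers <- sweep(Pb %*% t(R), 2, Tr, `+`)
  list(R = R, T = Tr, aligned = aligned,
       residuals = sqrt(rowSums((fitted_centers - Pa)^2)),
       bins_used = shared)
}

#' Project new events into an existing embedding with error baselines
#'
#' New waveforms are projected through the reference embedding's fitted
#' handle (UMAP transform or PCA rotation). To judge whether displacements
#' of new groups are meaningful, two baselines are computed from a pooled
#' re-embedding of the reference plus control events: the alignment error
#' (displacement of the reference events between the original and the
#' pooled embedding, after rigid alignment on the shared events) and the
#' fitting error (displacement of the projected control events from their
#' pooled-embedding location).
#'
#' @param embedding a fitted `swr_embedding` (method umap or pca).
#' @param new_cloud `ripple_cloud` or matrix of new events (same D).
#' @param control_cloud held-out events drawn from the reference
#'   distribution (same D).
#' @param seed RNG seed for the pooled re-embedding.
#' @return list with `coords` (new events in the reference frame),
#'   `fitting_error`, `alignment_error` (per-event distance
#'   distributions).
#' @export
embed_new_events <- function(embedding, new_cloud, control_cloud,
                             seed = NULL) {
  stopifnot(inherits(embedding, "swr_embedding"))
  if (is.null(embedding$model))
    stop("embedding has no fitted handle (use method 'umap' or 'pca')")
  Xn <- cloud_matrix(new_cloud); Xc <- cloud_matrix(control_cloud)
  D <- ncol(embedding$src)
  if (ncol(Xn) != D || ncol(Xc) != D)
    stop("waveform dimension mismatch with the reference embedding")
  project <- function(M) {
    if (embedding$method == "umap")
      uwot::umap_transform(M, embedding$model, n_threads = 1)
    else
      sweep(M, 2, embedding$model$center) %*%
        embedding$model$rotation[, seq_len(embedding$d)]
  }
  coords_new <- project(Xn)
  coords_ctrl <- project(Xc)

  if (!is.null(seed)) set.seed(seed)
  pooled <- reduce_embedding(rbind(embedding$src, Xc),
                             method = embedding$method, d = embedding$d,
                             seed = seed, n_neighbors = embedding$n_neighbors)
  n_ref <- nrow(embedding$src)
  # rigid alignment of the pooled embedding onto the reference frame,
  # fitted on the shared (reference) events
  Pa <- embedding$coords
  Pb <- pooled$coords[seq_len(n_ref), , drop = FALSE]
  ca <- colMeans(Pa); cb <- colMeans(Pb)
  H <- crossprod(sweep(Pb, 2, cb), sweep(Pa, 2, ca))
  sv <- svd(H)
  S <- diag(ncol(Pa)); S[ncol(Pa), ncol(Pa)] <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% S %*% t(sv$u)
  Tr <- ca - as.numeric(R %*% cb)
  pooled_al <- sweep(pooled$coords %*% t(R), 2, Tr, `+`)

  alignment_error <- sqrt(rowSums((pooled_al[seq_len(n_ref), , drop = FALSE] -
                                   Pa)^2))
  fitting_error <- sqrt(rowSums((pooled_al[n_ref + seq_len(nrow(Xc)), ,
                                           drop = FALSE] - coords_ctrl)^2))
  list(coords = coords_new, coords_control = coords_ctrl,
       fitting_error = fitting_error, alignment_error = alignment_error)
}
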