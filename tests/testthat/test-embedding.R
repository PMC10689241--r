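test_that("PCA embedding of a noiseless plane reconstructs it", {
  set.seed(1)
  P <- cbind(runif(300), runif(300))
  X <- embed_highdim(P)
  emb <- reduce_embedding(X, method = "pca", d = 2, seed = 1)
  rec <- emb$coords %*% t(emb$model$rotation[, 1:2])
  rec <- sweep(rec, 2, -emb$model$center)
  expect_lt(max(abs(rec - X)), 1e-8)
  expect_error(reduce_embedding(X, method = "sammon"))
})

test_that("feature structure survives dimensionality reduction", {
  rs <- generate_ripple_set(800, noise_rms = 0, seed = 3)
  f <- rs$features$frequency
  si_orig <- si_significance(rs$cloud$X, f, n_shuffles = 0)$si
  for (m in c("pca", "umap")) {
    emb <- reduce_embedding(rs$cloud, method = m, d = 3, seed = 1)
    si_red <- si_significance(emb$coords, f, n_shuffles = 0)$si
    expect_lt(abs(si_red - si_orig), 0.15)
  }
  # run-to-run stability: SI agrees within 0.05 despite coordinate changes
  e1 <- reduce_embedding(rs$cloud, method = "umap", d = 3, seed = 11)
  e2 <- reduce_embedding(rs$cloud, method = "umap", d = 3, seed = 99)
  s1 <- si_significance(e1$coords, f, n_shuffles = 0)$si
  s2 <- si_significance(e2$coords, f, n_shuffles = 0)$si
  expect_lt(abs(s1 - s2), 0.05)
})

test_that("voxel correlation has its closed-form extremes", {
  set.seed(4)
  coords <- matrix(runif(2000 * 2, 0, 10), 2000, 2)
  a <- coords[, 1] + coords[, 2]
  r <- voxel_spatial_correlation(coords, a, -a, voxel_size = 1)
  expect_equal(r$r2, 1, tolerance = 1e-12)

  b <- rnorm(2000)
  rr <- voxel_spatial_correlation(coords, a, b, voxel_size = 1)
  expect_lt(rr$r2, 0.1)

  # hand-set voxel means: correlation equals the direct correlation
  g <- matrix(0, 100, 2)
  g[, 1] <- rep(seq(0.5, 9.5, 1), each = 10)   # 10 voxels x 10 events
  g[, 2] <- 0.5
  va <- rep(rnorm(10), each = 10)
  vb <- rep(rnorm(10), each = 10)
  rv <- voxel_spatial_correlation(g, va, vb, voxel_size = 1,
                                  min_occupancy = 5)
  expect_equal(rv$r2,
               stats::cor(unique(va), unique(vb))^2, tolerance = 1e-12)

  expect_error(voxel_spatial_correlation(coords, a, -a, voxel_size = 100),
               "one voxel")
})

test_that("voxel-size validation reproduces the expected trade-off", {
  rs <- generate_ripple_set(1200, noise_rms = 0, seed = 5)
  emb <- reduce_embedding(rs$cloud, method = "pca", d = 4, seed = 1)
  sizes <- c(0.5, 2, 8)
  v <- validate_voxel_size(emb, sizes, n_rep = 5, seed = 2)
  expect_true(v$optimal %in% sizes)
  expect_equal(v$table$size, sizes)
  # the diagnostic table itself is the oracle: recompute the score
  expect_equal(v$table$score,
               ifelse(v$table$usable,
                      (v$table$r2_anti - 1)^2 + v$table$r2_rand^2, Inf))
  expect_equal(v$optimal, v$table$size[which.min(v$table$score)])
  # anticorrelated recovery must beat the random pair at the optimum
  opt <- v$table[v$table$size == v$optimal, ]
  expect_gt(opt$r2_anti, 0.6)
  expect_lt(opt$r2_rand, 0.3)
})

test_that("density contours nest and ROIs select conjunctive events", {
  set.seed(6)
  pts <- matrix(rnorm(1000 * 2), 1000, 2)
  f <- rep(1, 1000)
  rois <- lapply(c(4, 6, 8), function(l)
    density_roi(pts, f, c(0, 2), level = l))
  m4 <- roi_membership(rois[[1]], pts)
  m6 <- roi_membership(rois[[2]], pts)
  m8 <- roi_membership(rois[[3]], pts)
  expect_true(all(m4 <= m6))              # level-4 region inside level-6
  expect_true(all(m6 <= m8))
  expect_gt(mean(m6), 0.35)               # ~60% of density mass
  expect_lt(mean(m6), 0.85)

  # two separated blobs at a high level give two polygon paths
  two <- rbind(matrix(rnorm(500 * 2, 0, 0.5), 500, 2),
               matrix(rnorm(500 * 2, 6, 0.5), 500, 2))
  roi2 <- density_roi(two, rep(1, 1000), c(0, 2), level = 6)
  expect_gte(length(roi2$polygons), 2)

  expect_error(density_roi(pts, f, c(5, 6), level = 6), "30 events")

  # conjunctive ROI purity on synthetic ripples
  rs <- generate_ripple_set(2000, noise_rms = 0, seed = 7)
  emb <- reduce_embedding(rs$cloud, method = "pca", d = 2, seed = 1)
  fr <- rs$features$frequency; am <- rs$features$amplitude
  hi_f <- density_roi(emb$coords, fr, c(180, 240), level = 7)
  lo_a <- density_roi(emb$coords, am, c(2, 3), level = 7)
  sel <- roi_membership(hi_f, emb$coords) & roi_membership(lo_a, emb$coords)
  expect_gt(sum(sel), 20)
  purity <- mean(fr[sel] >= 160 & am[sel] <= 3.4)
  expect_gte(purity, 0.8)
})

test_that("centroid statistics behave for identical and offset groups", {
  set.seed(8)
  base <- matrix(rnorm(200 * 3), 200, 3)
  coords <- rbind(base, base)
  labels <- rep(c("a", "b"), each = 200)
  r <- centroid_analysis(coords, labels, n_boot = 20, sample_size = 50,
                         n_shuffles = 50, seed = 1)
  expect_equal(r$distance, 0, tolerance = 1e-12)
  expect_gt(r$p, 0.5)

  # offset along axis 1 only: detected there, not in the 2x3 projection
  off <- rbind(base, sweep(base, 2, c(3, 0, 0), `+`))
  r2 <- centroid_analysis(off, labels, projections = list(c(1, 2), c(2, 3)),
                          n_boot = 20, sample_size = 50, n_shuffles = 50,
                          seed = 2)
  d12 <- r2$distance[r2$projection == "1x2"]
  d23 <- r2$distance[r2$projection == "2x3"]
  expect_equal(d12, 3, tolerance = 0.3)
  expect_lt(d23, 0.5)
  expect_lt(r2$p[r2$projection == "1x2"], 0.05)

  expect_error(centroid_analysis(base, rep("a", 200)), "2 groups")
})

test_that("rigid alignment recovers planted transforms exactly", {
  set.seed(9)
  A <- matrix(rnorm(500 * 4), 500, 4)
  f <- rnorm(500)
  id <- align_embeddings(A, A, f, f)
  expect_lt(max(abs(id$R - diag(4))), 1e-8)
  expect_lt(max(abs(id$T)), 1e-8)

  off <- sweep(A, 2, c(1, -2, 0.5, 3), `+`)
  ao <- align_embeddings(off, A, f, f)
  expect_equal(as.numeric(ao$T), c(1, -2, 0.5, 3), tolerance = 1e-8)

  R0 <- qr.Q(qr(matrix(rnorm(16), 4)))
  if (det(R0) < 0) R0[, 1] <- -R0[, 1]
  B <- A %*% t(R0)                        # rotated copy
  al <- align_embeddings(A, B, f, f)
  expect_lt(max(abs(al$aligned - A)), 1e-6)
  expect_lt(max(abs(crossprod(al$R) - diag(4))), 1e-8)
  expect_gt(det(al$R), 0)
  expect_lt(max(al$residuals), 1e-6)

  expect_error(align_embeddings(A, B, f, f + 100), "shared")
})

test_that("new events project into an existing embedding with error baselines", {
  rs <- generate_ripple_set(700, noise_rms = 0, seed = 10)
  ref_idx <- 1:500
  emb <- reduce_embedding(rs$cloud$X[ref_idx, ], method = "pca", d = 3,
                          seed = 1)
  held <- rs$cloud$X[501:700, ]
  r <- embed_new_events(emb, held, held, seed = 2)
  expect_equal(nrow(r$coords), 200)
  # training events project back onto themselves
  self <- embed_new_events(emb, rs$cloud$X[ref_idx, ], held, seed = 2)
  expect_lt(max(abs(self$coords - emb$coords)), 1e-8)
  # held-out events from the same distribution: fitting error comparable
  # to the alignment baseline
  expect_lt(stats::median(r$fitting_error),
            10 * stats::median(r$alignment_error) + 0.05)

  bad <- matrix(rnorm(10 * 50), 10, 50)
  expect_error(embed_new_events(emb, bad, held), "dimension mismatch")
})
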