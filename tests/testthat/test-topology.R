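# Closed-form barcodes for tiny fixtures validate the Rips engine against
# hand-derivable answers; larger fixtures check Betti recovery on objects
# of known topology.

rips_of <- function(X, maxdim = 2, threshold = NULL) {
  persistence_barcodes(X, maxdim = maxdim, threshold = threshold,
                       seed = 1)[[1]]
}

test_that("barcodes of exactly solvable complexes are exact", {
  # regular hexagon on the unit circle: one loop born at the side length,
  # filled at the inscribed-triangle side sqrt(3)
  hexa <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6))
  bc <- rips_of(hexa, maxdim = 1, threshold = 3)
  expect_equal(nrow(bc$H1), 1)
  expect_equal(bc$H1[1, ], c(1, sqrt(3)), tolerance = 1e-12)

  # unit square: loop born at 1, filled at the diagonal
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  bc <- rips_of(sq, maxdim = 1, threshold = 3)
  expect_equal(bc$H1[1, ], c(1, sqrt(2)), tolerance = 1e-12)

  # octahedron: sphere surface appears at sqrt(2), cavity fills at 2
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  bc <- rips_of(octa, maxdim = 2, threshold = 3)
  expect_equal(nrow(bc$H2), 1)
  expect_equal(bc$H2[1, ], c(sqrt(2), 2), tolerance = 1e-12)
  expect_equal(nrow(bc$H1), 0)
})

test_that("H0 deaths reproduce single-linkage merge heights", {
  set.seed(10)
  X <- matrix(rnorm(60 * 5), 60, 5)
  bc <- rips_of(X, maxdim = 0)
  hc <- stats::hclust(stats::dist(X), method = "single")
  expect_equal(sort(bc$H0[is.finite(bc$H0[, 2]), 2]), sort(hc$height),
               tolerance = 1e-12)
  expect_equal(sum(!is.finite(bc$H0[, 2])), 1)   # one infinite bar
})

test_that("Betti numbers recover ground-truth object topology", {
  # outlier trimming precedes persistence, as in the analysis pipeline
  trim <- function(X) remove_outliers(X, k = 10, pct = 95)$X
  for (s in 1:5) {
    set.seed(s)
    # single Gaussian blob: (1, 0, 0)
    blob <- embed_highdim(matrix(rnorm(300 * 3), 300, 3), noise_total_sd = 0.01)
    b <- betti_numbers(rips_of(trim(blob), maxdim = 1))
    expect_equal(unname(b[c("b0", "b1")]), c(1L, 0L))

    # two separated blobs: (2, 0, 0)
    blobs <- embed_highdim(rbind(matrix(rnorm(150 * 3), 150, 3),
                                 matrix(rnorm(150 * 3, 8), 150, 3)))
    b2 <- betti_numbers(rips_of(trim(blobs), maxdim = 1))
    expect_equal(unname(b2[c("b0", "b1")]), c(2L, 0L))

    # noisy circle in 127D: (1, 1)
    circ <- embed_highdim(circle_points(600), noise_total_sd = 0.01)
    bc <- betti_numbers(rips_of(trim(circ), maxdim = 1))
    expect_equal(unname(bc[c("b0", "b1")]), c(1L, 1L))
  }
})

test_that("a torus in 127D shows one component, two loops, one cavity", {
  for (s in 1:2) {
    tor <- generate_geometric_object("torus", n_points = 2000, seed = s)
    fo <- remove_outliers(tor$X, k = 10, pct = 95)
    bc <- persistence_barcodes(fo$X, maxdim = 2, subsample = 450,
                               seed = s)[[1]]
    b <- betti_numbers(bc)
    expect_equal(as.integer(b), c(1L, 2L, 1L))
  }
})

test_that("outlier removal targets the injected outliers only", {
  set.seed(6)
  blob <- matrix(rnorm(200 * 4), 200, 4)
  far <- matrix(rnorm(5 * 4, mean = 40), 5, 4)
  X <- rbind(blob, far)
  r <- remove_outliers(X, k = 10, pct = 95)
  expect_true(all(201:205 %in% r$removed))

  r100 <- remove_outliers(X, k = 10, pct = 100)
  expect_equal(length(r100$removed), 0)

  # duplicated rows have zero-distance neighbors and are never removed
  # before unique rows
  Xd <- rbind(blob, blob[1:20, ], far)
  rd <- remove_outliers(Xd, k = 10, pct = 95)
  expect_false(any(c(1:20, 201:220) %in% rd$removed))

  expect_error(remove_outliers(blob[1:5, ], k = 10), "more than k")
})

test_that("ABID estimates are correct, invariant and stable", {
  # colinear: all cosines 1
  line <- generate_geometric_object("line", 500, noise_sd = 0, seed = 1)
  expect_equal(abid_dimension(line$X, k = 20)$estimate, 1, tolerance = 0.2)

  # invariance to rotation, translation, uniform scaling
  rs <- generate_ripple_set(400, seed = 2)
  e0 <- abid_dimension(rs$cloud, k = 30)$estimate
  Q <- qr.Q(qr(matrix(rnorm(127 * 127), 127)))
  Xr <- 3.7 * rs$cloud$X %*% Q + 11
  expect_equal(abid_dimension(Xr, k = 30)$estimate, e0, tolerance = 1e-6)

  # three generative parameters: estimate rounds to 3, stable across
  # window lengths (10% band)
  r25 <- generate_ripple_set(1500, noise_rms = 0, seed = 4)
  a25 <- abid_dimension(r25$cloud, k = 50)$estimate
  expect_equal(round(a25), 3)
  r20 <- generate_ripple_set(1500, noise_rms = 0, window_ms = 20, seed = 4)
  a20 <- abid_dimension(r20$cloud, k = 50)$estimate
  expect_lt(abs(a20 - a25) / a25, 0.1)

  # 5D hyperball within +-0.5
  ball <- generate_geometric_object("hyperball", 2000, seed = 5)
  expect_lt(abs(abid_dimension(ball$X, k = 50)$estimate - 5), 0.5)

  expect_error(abid_dimension(rs$cloud, k = 5), "k >= 10")
})
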