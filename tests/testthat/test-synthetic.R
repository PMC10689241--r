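test_that("noiseless ripples follow the closed-form waveform", {
  rs <- generate_ripple_set(1, freq_range = c(149, 151), noise_rms = 0,
                            seed = 3)
  f <- rs$features
  t <- (-63:63) / 2500
  sigma <- f$duration * 0.010
  expected <- f$amplitude * exp(-t^2 / (2 * sigma^2)) *
    sin(2 * pi * f$frequency * t - pi / 2)
  expect_equal(as.numeric(rs$cloud$X[1, ]), expected, tolerance = 1e-12)
  # trough at the center sample, symmetric envelope
  expect_equal(rs$cloud$X[1, 64], -f$amplitude)
  env <- abs(rs$cloud$X[1, ])
  expect_lt(abs(sum(env[1:63]) - sum(env[65:127])) / sum(env), 0.2)
})

test_that("feature draws are uniform and independent", {
  rs <- generate_ripple_set(2000, seed = 11)
  f <- rs$features
  expect_gt(stats::ks.test(f$frequency, "punif", 80, 240)$p.value, 0.01)
  expect_gt(stats::ks.test(f$amplitude, "punif", 2, 5)$p.value, 0.01)
  expect_gt(stats::ks.test(f$duration, "punif", 0.5, 2)$p.value, 0.01)
  expect_lt(abs(stats::cor(f$frequency, f$amplitude)), 0.08)
})

test_that("added noise changes the per-sample RMS as specified", {
  set.seed(5)
  clean <- generate_ripple_set(500, noise_rms = 0, seed = 9)
  noisy <- generate_ripple_set(500, noise_rms = 0.3, seed = 9)
  resid <- noisy$cloud$X - clean$cloud$X
  expect_equal(sqrt(mean(resid^2)), 0.3, tolerance = 0.05)
  # same seed, zero noise: bit-for-bit reproducible
  again <- generate_ripple_set(500, noise_rms = 0, seed = 9)
  expect_identical(clean$cloud$X, again$cloud$X)
})

test_that("clustered ripples are separable after outlier trimming", {
  rs <- generate_ripple_set(2000, mode = "clustered", noise_rms = 0, seed = 4)
  fo <- remove_outliers(rs$cloud, k = 10, pct = 95)
  D <- as.matrix(dist(fo$X))
  cl <- rs$features$cluster[fo$kept]
  diag(D) <- Inf
  # max intra-cluster nearest-neighbor distance
  intra_nn <- max(vapply(seq_len(nrow(D)), function(i)
    min(D[i, cl == cl[i]]), 0))
  inter_min <- min(D[outer(cl, cl, "!=")])
  expect_gt(inter_min, intra_nn)
})

test_that("degenerate ripple-set configurations are rejected", {
  expect_error(generate_ripple_set(10, mode = "clustered",
                                   freq_clusters = list(c(80, 120), c(110, 150))),
               "disjoint")
  expect_error(generate_ripple_set(10, freq_range = c(80, 240), rate = 300),
               "Nyquist")
  expect_error(generate_ripple_set(10, freq_range = c(200, 150)),
               "non-degenerate")
})

test_that("geometric objects have the advertised structure", {
  line <- generate_geometric_object("line", n_points = 200, noise_sd = 0,
                                    seed = 1)
  # noiseless line: rank-1 cloud, first PC explains everything
  pv <- stats::prcomp(line$X)$sdev^2
  expect_gt(pv[1] / sum(pv), 1 - 1e-10)
  expect_equal(line$intrinsic_dim, 1)

  tor <- generate_geometric_object("torus", n_points = 500, seed = 2)
  # distances preserved by the orthonormal embedding (up to noise)
  d3 <- dist(tor$params); dD <- dist(tor$X)
  expect_equal(as.numeric(dD), as.numeric(d3), tolerance = 0.02)

  expect_error(generate_geometric_object("klein"), "arg")
  # reproducibility under seed
  a <- generate_geometric_object("hyperball", 100, seed = 5)
  b <- generate_geometric_object("hyperball", 100, seed = 5)
  expect_identical(a$X, b$X)
})

test_that("laminar session programs couplings exactly", {
  cp <- default_coupling()
  cp$g_amp <- c(0, 0, 0, 0)       # SR coupled to frequency only
  cp$g_dur <- c(0, 0, 0, 0)
  cp$base <- c(0, 0, 0, 0)
  cp$g_freq <- c(0, 0, -1, 0)
  sess <- generate_laminar_session(n_events = 50, coupling = cp,
                                   noise_sd = 0, seed = 3)
  expect_equal(stats::cor(sess$csd_true[, "SR"], sess$events$frequency), -1,
               tolerance = 1e-12)
  expect_true(all(sess$csd_true[, c("SO", "SP", "SLM")] == 0))
})

test_that("recovered CSD matches the programmed layer values", {
  # amp 0: pure laminar potentials, no ripple leaking into neighbor CSD
  sess <- generate_laminar_session(n_events = 30, noise_sd = 0,
                                   amp_range = c(0, 0), seed = 8)
  rec <- sess$recording
  got <- vapply(seq_len(nrow(sess$events)), function(e) {
    pk <- sess$events$peak[e]
    prof <- compute_csd(rec$signal[, (pk - 5):(pk + 5), drop = FALSE],
                        depths = rec$depths, layers = rec$layers,
                        peak_sample = 6)
    prof$layer_summary["SR"]
  }, 0)
  # interior SR channel CSD equals the programmed value (up to the
  # micrometer grid scaling used when integrating the potential)
  scale <- got / sess$csd_true[, "SR"]
  expect_lt(stats::sd(scale) / abs(mean(scale)), 1e-6)
})

test_that("over-dense event trains are rejected", {
  expect_error(generate_laminar_session(n_events = 10, gap_ms = 40),
               "gap")
})
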