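test_that("spectral entropy has its closed-form extremes", {
  expect_equal(spectral_entropy(rep(1, 32)), 5)       # uniform over 32 bins
  expect_equal(spectral_entropy(c(0, 7, 0, 0)), 0)    # single bin
  # uniform is maximal among random spectra of the same length
  set.seed(1)
  for (i in 1:20)
    expect_lte(spectral_entropy(runif(32)), 5)
  expect_error(spectral_entropy(c(-1, 2)))
})

test_that("ripple frequency is recovered to within half a spectral bin", {
  rate <- 2500
  t <- (-63:63) / rate
  tone <- sin(2 * pi * 150 * t)
  sf <- spectral_features(tone, rate)
  expect_lte(abs(sf$frequency - 150), 5)

  # bias across the full band on noiseless synthetic ripples
  rs <- generate_ripple_set(60, noise_rms = 0, seed = 21)
  freq_hat <- apply(rs$cloud$X, 1, function(w)
    spectral_features(w, rate)$frequency)
  expect_lte(stats::median(abs(freq_hat - rs$features$frequency)), 5)
  expect_lte(mean(abs(freq_hat - rs$features$frequency) <= 10), 1)

  expect_error(spectral_features(numeric(127), rate), "zero")
})

test_that("amplitude and duration measures track the generator", {
  sess <- generate_laminar_session(n_events = 25, noise_sd = 0, seed = 13)
  det <- detect_ripples(sess$recording, detection_config(threshold_sd = 2),
                        sp_channel = 3)
  fe <- filter_and_envelope(sess$recording$signal[3, ], 2500)
  idx <- vapply(det$events$peak, function(p)
    which.min(abs(sess$events$peak - p)), 0L)
  amp_hat <- vapply(det$events$peak, function(p)
    amplitude_duration(fe$filtered, fe$envelope, p, 2500)$amplitude, 0)
  rel_err <- abs(amp_hat - sess$events$amplitude[idx]) /
    sess$events$amplitude[idx]
  expect_lt(stats::median(rel_err), 0.05)

  # AUC duration grows monotonically with the envelope width
  auc_of <- function(dur) {
    rs <- generate_ripple_set(1, freq_range = c(149, 151),
                              dur_range = c(dur, dur), noise_rms = 0,
                              window_ms = 100, seed = 2)
    w <- as.numeric(rs$cloud$X[1, ])
    pk <- which.min(w)
    amplitude_duration(w, abs(w), pk, 2500)$duration_auc
  }
  aucs <- vapply(c(0.5, 1, 1.5, 2), auc_of, 0)
  expect_true(all(diff(aucs) > 0))
})

test_that("slopes recover programmed ramps and symmetry", {
  rate <- 2500
  n <- 500
  ramp <- 0.4 * seq_len(n) / rate * 1000        # slope 0.4 units/ms
  sl <- event_slopes(ramp, NULL, peak = 250, rate = rate,
                     filtered_slow = list(sp = ramp, sr = NULL))
  expect_equal(sl$slope_to_peak_ripple, 0.4, tolerance = 1e-8)
  expect_equal(sl$slope_from_peak_ripple, 0.4, tolerance = 1e-8)
  expect_true(is.na(sl$slope_to_peak_sw))

  tri <- (250 - abs(seq_len(500) - 250)) / rate * 1000
  st <- event_slopes(tri, tri, peak = 250, rate = rate,
                     filtered_slow = list(sp = tri, sr = tri))
  expect_equal(st$slope_to_peak_ripple, -st$slope_from_peak_ripple,
               tolerance = 1e-6)
  # in-passband sinusoid: fitted slope matches the analytic derivative
  t <- seq_len(5 * rate) / rate
  s4 <- sin(2 * pi * 4 * t)
  pk <- which.min(abs(t - 2.5))                 # near a zero crossing
  sl4 <- event_slopes(s4, NULL, pk, rate)
  analytic <- 2 * pi * 4 * cos(2 * pi * 4 * 2.5) / 1000  # units/ms
  expect_equal(sl4$slope_to_peak_ripple, analytic, tolerance = 0.15)
})

test_that("CSD annihilates affine potentials and recovers curvature", {
  depths <- 100 * (0:7)
  n_t <- 5
  affine <- outer(3 + 0.02 * depths, rep(1, n_t))
  r <- compute_csd(affine, depths)
  expect_true(all(abs(r$csd[2:7, ]) < 1e-12))
  expect_true(all(is.na(r$csd[c(1, 8), ])))

  quad <- outer(depths^2, rep(1, n_t))
  rq <- compute_csd(quad, depths)
  expect_equal(unique(round(rq$csd[2:7, 1], 10)), 2)   # d2(d^2)/dd2 = 2

  expect_error(compute_csd(affine[1:2, ], depths[1:2]), "3 channels")
  expect_error(compute_csd(affine, rev(depths) * c(1, -1, 1, 1, 1, 1, 1, 1)),
               "monotone")

  # programmed SR sink: sign and magnitude recovered through the recording
  # (ripple amplitude 0 so the SP oscillation cannot leak into SR CSD)
  sess <- generate_laminar_session(n_events = 10, noise_sd = 0,
                                   amp_range = c(0, 0), seed = 4)
  pk <- sess$events$peak[1]
  prof <- compute_csd(sess$recording$signal[, (pk - 3):(pk + 3)],
                      depths = sess$recording$depths,
                      layers = sess$recording$layers, peak_sample = 4)
  h2 <- sess$grid_step_um^2
  expect_equal(unname(prof$layer_summary["SR"] * h2),
               unname(sess$csd_true[1, "SR"]), tolerance = 1e-8)
  expect_match(prof$sign_convention, "sinks negative")
})
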