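test_that("noise-epoch masking flags exactly the injected artifact", {
  set.seed(2)
  n <- 2500 * 12
  sig <- matrix(rnorm(2 * n, 0, 1), 2, n)
  rec <- lfp_recording(sig, 2500)
  expect_true(all(remove_noise_epochs(rec)))

  # 20-s.d. artifact confined to the 6th one-second epoch
  art <- sig
  art[, (5 * 2500 + 100):(5 * 2500 + 300)] <- 25
  rec2 <- lfp_recording(art, 2500)
  keep <- remove_noise_epochs(rec2)
  epoch <- rep(seq_len(12), each = 2500)
  expect_true(all(!keep[epoch == 6]))
  expect_true(all(keep[epoch != 6]))

  expect_error(remove_noise_epochs(rec, k_sd = 0))
  rec1 <- lfp_recording(sig[1, , drop = FALSE], 2500)
  expect_warning(keep1 <- remove_noise_epochs(rec1), "single-channel")
  expect_true(all(keep1))
})

test_that("SP channel selection follows ripple and MUA band power", {
  sess <- make_session(n_events = 40, seed = 3)
  expect_equal(select_sp_channel(sess$recording), 3)

  one <- lfp_recording(matrix(rnorm(5000), 1), 2500)
  expect_equal(select_sp_channel(one), 1)

  x <- rnorm(5000)
  two <- lfp_recording(rbind(x, x), 2500)
  expect_equal(select_sp_channel(two), 1)   # documented tie-break

  expect_error(select_sp_channel(lfp_recording(matrix(0, 2, 100), 2500)),
               "zero")
})

test_that("band-pass is zero-phase and the tone envelope is flat", {
  rate <- 2500
  t <- seq_len(6 * rate) / rate
  tone <- sin(2 * pi * 150 * t)
  fe <- filter_and_envelope(tone, rate)
  core <- (rate):(5 * rate)    # away from edges
  # passband identity and zero group delay
  expect_equal(fe$filtered[core], tone[core], tolerance = 0.02)
  cc <- stats::ccf(fe$filtered[core], tone[core], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # envelope of a unit tone is ~1 and flat within 5%
  expect_lt(max(abs(fe$envelope[core] - 1)), 0.05)

  # stopband attenuation > 40 dB at 20 Hz
  slow <- sin(2 * pi * 20 * t)
  fs <- filter_and_envelope(slow, rate)
  att <- 20 * log10(stats::sd(fs$filtered[core]) / stats::sd(slow[core]))
  expect_lt(att, -40)

  expect_error(filter_and_envelope(tone, rate,
                                   detection_config(band = c(70, 1300))),
               "Nyquist")
  expect_error(filter_and_envelope(tone[1:1000], rate), "filter order")
})

test_that("threshold, merging and centering behave on boundary fixtures", {
  rate <- 2000                       # 15 ms = exactly 30 samples
  n <- 6000
  bump <- function(at, len = 20) { e <- numeric(n); e[at:(at + len - 1)] <- 1; e }
  center_of <- function(ev) ev$peak

  run <- function(sep_samples) {    # sub-threshold samples between events
    env <- bump(2000) + bump(2019 + sep_samples + 1)
    detect_and_center(-env, env, rate)
  }
  expect_equal(nrow(run(20)), 1)     # 10 ms apart: merged
  expect_equal(nrow(run(40)), 2)     # 20 ms apart: separate
  expect_equal(nrow(run(30)), 2)     # exactly 15 ms: strictly-closer rule
  expect_equal(nrow(run(29)), 1)     # just under 15 ms: merged

  # flat trace: no events, not an error
  expect_equal(nrow(detect_and_center(numeric(n), numeric(n), rate)), 0)
  expect_error(detect_and_center(numeric(n), numeric(n), rate,
                                 keep = rep(FALSE, n)), "mask")

  # centering picks the filtered-trace minimum near the envelope peak
  env <- bump(3000, 30)
  filt <- numeric(n); filt[3011] <- -2; filt[3100] <- -5  # deeper but outside
  ev <- detect_and_center(filt, env, rate)
  expect_equal(center_of(ev), 3011)

  # config rejects thresholds outside the consensus 2-5 range
  expect_error(detection_config(threshold_sd = 6), "2, 5")
  expect_error(detection_config(threshold_sd = 1), "2, 5")
})

test_that("detection recovers injected ripples with high fidelity", {
  sess <- make_session(n_events = 70, seed = 1)
  det <- detect_ripples(sess$recording, detection_config(threshold_sd = 2),
                        sp_channel = 3)
  m <- match_events(sess$events$peak, det$events$peak, tol = 25)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)

  # noiseless session, events well above threshold: troughs within 2 ms
  clean <- generate_laminar_session(n_events = 40, noise_sd = 0,
                                    amp_range = c(3, 5), seed = 5)
  det2 <- detect_ripples(clean$recording, detection_config(threshold_sd = 2),
                         sp_channel = 3)
  dmat <- abs(outer(clean$events$peak, det2$events$peak, "-"))
  hit <- apply(dmat, 1, min)
  expect_gte(mean(hit <= 5), 0.95)   # 2 ms at 2500 Hz
})

test_that("detection output is sorted, deterministic and non-overlapping", {
  sess <- make_session(n_events = 30, seed = 6)
  d1 <- detect_ripples(sess$recording, sp_channel = 3)
  d2 <- detect_ripples(sess$recording, sp_channel = 3)
  expect_identical(d1$events, d2$events)
  expect_true(!is.unsorted(d1$events$peak))
  if (nrow(d1$events) > 1)
    expect_true(all(diff(d1$events$onset) > 0))
})
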