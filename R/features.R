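#' Spectral features of a single ripple event
#'
#' The periodogram of the Hann-windowed event waveform is accumulated into
#' 10 Hz bins over the analysis band. The ripple frequency is the center of
#' the bin with maximal residual power after subtracting a fitted
#' exponential decay `a * exp(-b f)` (whitening the 1/f-like background);
#' if the nonlinear fit fails a log-linear 1/f fit is used instead and the
#' fallback is recorded. Spectral entropy is
#' `-sum p(f) log2 p(f)` of the sum-normalized binned spectrum, and the
#' MUA index is the summed binned power in 300-400 Hz.
#'
#' @param waveform event samples (peak-centered window).
#' @param rate sampling rate in Hz.
#' @param band analysis band in Hz (default 70-400).
#' @param bin_hz spectral bin width (default 10 Hz).
#' @return list with `frequency` (Hz), `entropy` (bits), `mua_index`,
#'   `whitening` ("exponential" or "one_over_f").
#' @export
spectral_features <- function(waveform, rate, band = c(70, 400),
                              bin_hz = 10) {
  if (all(waveform == 0)) stop("all-zero waveform: spectrum undefined")
  n <- length(waveform)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann
  x <- (waveform - mean(waveform)) * w
  nfft <- max(512L, 2^ceiling(log2(n)))                    # pad for 10 Hz bins
  sp <- Mod(stats::fft(c(x, numeric(nfft - n))))[1:(nfft / 2)]^2
  f <- (seq_len(nfft / 2) - 1) * rate / nfft

  edges <- seq(band[1], band[2], by = bin_hz)
  centers <- edges[-length(edges)] + bin_hz / 2
  binned <- vapply(seq_along(centers), function(i)
    sum(sp[f >= edges[i] & f < edges[i + 1]]), 0)

  entropy <- spectral_entropy(binned)

  whitening <- "exponential"
  resid <- tryCatch({
    fit <- minpack.lm::nlsLM(
      y ~ a * exp(-b * x),
      data = data.frame(x = centers, y = binned),
      start = list(a = max(binned), b = 1 / diff(band)),
      control = minpack.lm::nls.lm.control(maxiter = 100))
    binned - stats::predict(fit)
  }, error = function(e) {
    whitening <<- "one_over_f"
    co <- stats::coef(stats::lm(log(binned + 1e-12) ~ log(centers)))
    binned - exp(co[1]) * centers^co[2]
  })
  frequency <- centers[which.max(resid)]

  mua <- sum(binned[centers >= 300 & centers <= 400])
  list(frequency = frequency, entropy = entropy, mua_index = mua,
       whitening = whitening)
}

#' Spectral entropy of a binned power spectrum
#'
#' `-sum p log2 p` of the sum-normalized power vector, in bits: 0 for a
#' single-bin spectrum, `log2(n)` for a uniform one.
#'
#' @param power non-negative power per bin.
#' @return entropy in bits.
#' @export
spectral_entropy <- function(power) {
  stopifnot(all(power >= 0), sum(power) > 0)
  p <- power / sum(power)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

#' Amplitude and duration measures of an event
#'
#' Amplitude is the envelope maximum within +-25 ms of the peak. The
#' envelope duration is the width of the envelope above mean + 1 s.d. of
#' the event-local (+-100 ms) envelope. The AUC duration is the area under
#' the max-normalized absolute filtered trace over +-100 ms (arbitrary
#' units; insensitive to amplitude by construction).
#'
#' @param filtered band-passed trace (full session).
#' @param envelope smoothed envelope, same length.
#' @param peak event peak sample (1-based).
#' @param rate sampling rate in Hz.
#' @return list with `amplitude`, `duration_env` (ms), `duration_auc`.
#' @export
amplitude_duration <- function(filtered, envelope, peak, rate) {
  ext <- round(0.100 * rate)
  if (peak - ext < 1 || peak + ext > length(filtered))
    stop("event window exceeds trace bounds")
  near <- (peak - round(0.025 * rate)):(peak + round(0.025 * rate))
  amplitude <- max(envelope[near])

  win <- (peak - ext):(peak + ext)
  env_loc <- envelope[win]
  thr <- mean(env_loc) + stats::sd(env_loc)
  above <- env_loc > thr
  duration_env <- sum(above) / rate * 1000

  a <- abs(filtered[win])
  duration_auc <- sum(a / max(a)) / rate * 1000
  list(amplitude = amplitude, duration_env = duration_env,
       duration_auc = duration_auc)
}

#' Slopes to and from the event peak for ripple and sharp-wave traces
#'
#' Both raw traces are filtered to 1-10 Hz (zero phase) and a least-squares
#' line is fitted on `[peak - 25 ms, peak]` (slope to peak) and
#' `[peak, peak + 25 ms]` (slope from peak), for the pyramidal-layer
#' (ripple) and radiatum (sharp-wave) signals.
#'
#' @param sp_trace raw SP trace.
#' @param sr_trace raw SR trace, or `NULL` when no SR channel exists (the
#'   sharp-wave slopes are then `NA`).
#' @param peak event peak sample.
#' @param rate sampling rate in Hz.
#' @param filtered_slow optional list with precomputed 1-10 Hz versions of
#'   the two traces (avoids refiltering per event).
#' @return named list of four slopes in units per ms.
#' @export
event_slopes <- function(sp_trace, sr_trace, peak, rate,
                         filtered_slow = NULL) {
  half <- round(0.025 * rate)
  if (peak - half < 1 || peak + half > length(sp_trace))
    stop("event window exceeds trace bounds")
  slow <- filtered_slow %||% list(sp = slow_filter(sp_trace, rate),
                                  sr = if (!is.null(sr_trace))
                                         slow_filter(sr_trace, rate))
  fit_slope <- function(y) {
    t_ms <- seq_along(y) / rate * 1000
    unname(stats::coef(stats::lm(y ~ t_ms))[2])
  }
  res <- list(
    slope_to_peak_ripple = fit_slope(slow$sp[(peak - half):peak]),
    slope_from_peak_ripple = fit_slope(slow$sp[peak:(peak + half)]),
    slope_to_peak_sw = NA_real_, slope_from_peak_sw = NA_real_)
  if (!is.null(slow$sr)) {
    res$slope_to_peak_sw <- fit_slope(slow$sr[(peak - half):peak])
    res$slope_from_peak_sw <- fit_slope(slow$sr[peak:(peak + half)])
  }
  res
}

# zero-phase 1-10 Hz band-pass used for slope estimation
slow_filter <- function(trace, rate, order = 512) {
  ord <- min(order, floor((length(trace) - 1) / 3))
  h <- signal::fir1(ord, c(1, 10) / (rate / 2), type = "pass")
  signal::filtfilt(h, trace)
}

#' Current source density profile from a laminar snapshot
#'
#' The CSD is the discrete second spatial derivative of the potential
#' across channels, `(V[i-1] - 2 V[i] + V[i+1]) / h^2`, assuming isotropic
#' tissue conductivity; boundary channels have no estimate. Sinks are
#' negative and sources positive. Per-layer summaries (taken at the event
#' peak sample and averaged over each layer's interior channels) are
#' returned when the recording has at least 8 contiguous channels covering
#' SO to SLM.
#'
#' @param snapshot channels x samples matrix of potentials.
#' @param depths channel depths in micrometers (monotone).
#' @param layers optional layer label per channel.
#' @param peak_sample column at which per-layer summaries are taken
#'   (default: middle sample).
#' @return list with `csd` (channels x samples; boundary rows `NA`),
#'   `layer_summary` (named vector or `NULL`), `sign_convention`.
#' @export
compute_csd <- function(snapshot, depths, layers = NULL, peak_sample = NULL) {
  snapshot <- as.matrix(snapshot)
  n_ch <- nrow(snapshot)
  if (n_ch < 3) stop("CSD requires at least 3 channels")
  if (length(depths) != n_ch) stop("depths must match channel count")
  dd <- diff(depths)
  if (any(dd <= 0) && any(dd >= 0) && !(all(dd > 0) || all(dd < 0)))
    stop("channel depths must be monotone")
  h <- abs(mean(dd))
  csd <- matrix(NA_real_, n_ch, ncol(snapshot))
  for (i in 2:(n_ch - 1))
    csd[i, ] <- (snapshot[i - 1, ] - 2 * snapshot[i, ] + snapshot[i + 1, ]) / h^2

  layer_summary <- NULL
  if (!is.null(layers) && n_ch >= 8 &&
      all(c("SO", "SP", "SR", "SLM") %in% layers)) {
    pk <- peak_sample %||% ceiling(ncol(snapshot) / 2)
    vals <- csd[, pk]
    layer_summary <- vapply(unique(layers), function(l)
      mean(vals[layers == l], na.rm = TRUE), 0)
    names(layer_summary) <- unique(layers)
  }
  list(csd = csd, layer_summary = layer_summary,
       sign_convention = "sinks negative, sources positive")
}

#' Per-event feature table
#'
#' Applies [spectral_features()], [amplitude_duration()] and
#' [event_slopes()] to every detected event of a session.
#'
#' @param rec an [lfp_recording()].
#' @param events event table from [detect_and_center()].
#' @param sp_channel,sr_channel channel indices; SR may be `NULL`.
#' @param cfg a [detection_config()].
#' @param halfwidth_ms waveform window halfwidth for spectral features.
#' @return data frame, one row per event that fits inside the trace
#'   (events too close to the edge are dropped; the count of drops is in
#'   `attr(, "dropped")`).
#' @export
event_features <- function(rec, events, sp_channel, sr_channel = NULL,
                           cfg = detection_config(), halfwidth_ms = 25) {
  fe <- filter_and_envelope(rec$signal[sp_channel, ], rec$rate, cfg)
  half <- ceiling(halfwidth_ms * rec$rate / 1000)
  ext <- round(0.100 * rec$rate)
  n_tr <- ncol(rec$signal)
  ok <- events$peak - ext >= 1 & events$peak + ext <= n_tr
  dropped <- sum(!ok)
  events <- events[ok, , drop = FALSE]

  slow <- list(sp = slow_filter(rec$signal[sp_channel, ], rec$rate),
               sr = if (!is.null(sr_channel))
                      slow_filter(rec$signal[sr_channel, ], rec$rate))
  rows <- lapply(seq_len(nrow(events)), function(i) {
    pk <- events$peak[i]
    wf <- fe$filtered[(pk - half):(pk + half)]
    sf <- spectral_features(wf, rec$rate)
    ad <- amplitude_duration(fe$filtered, fe$envelope, pk, rec$rate)
    sl <- event_slopes(rec$signal[sp_channel, ], NULL, pk, rec$rate,
                       filtered_slow = slow)
    data.frame(peak = pk, frequency = sf$frequency, entropy = sf$entropy,
               mua_index = sf$mua_index, amplitude = ad$amplitude,
               duration_env = ad$duration_env,
               duration_auc = ad$duration_auc,
               slope_to_peak_ripple = sl$slope_to_peak_ripple,
               slope_from_peak_ripple = sl$slope_from_peak_ripple,
               slope_to_peak_sw = sl$slope_to_peak_sw,
               slope_from_peak_sw = sl$slope_from_peak_sw)
  })
  out <- do.call(rbind, rows)
  attr(out, "dropped") <- dropped
  out
}
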