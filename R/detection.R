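#' Laminar LFP recording container
#'
#' @param signal numeric matrix, channels x samples.
#' @param rate sampling rate in Hz.
#' @param depths channel depths in micrometers, monotone.
#' @param layers optional layer label per channel (SO/SP/SR/SLM).
#' @param session session identifier.
#' @return an `lfp_recording` object.
#' @export
lfp_recording <- function(signal, rate, depths = NULL, layers = NULL,
                          session = "session1") {
  signal <- as.matrix(signal)
  stopifnot(rate > 0)
  if (!is.null(depths)) {
    stopifnot(length(depths) == nrow(signal))
    if (is.unsorted(depths) && is.unsorted(rev(depths)))
      stop("channel depths must be monotone")
  }
  if (!is.null(layers)) stopifnot(length(layers) == nrow(signal))
  structure(list(signal = signal, rate = rate, depths = depths,
                 layers = layers, session = session),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording '%s': %d channels x %d samples @ %g Hz>\n",
              x$session, nrow(x$signal), ncol(x$signal), x$rate))
  invisible(x)
}

#' Detection configuration
#'
#' Bundles the parameters of the consensus ripple-detection pipeline:
#' band-pass 70-400 Hz FIR of order 512 applied forward-backward (zero
#' phase), envelope smoothing (fourth-order Savitzky-Golay over 33.4 ms,
#' then moving means of 2.3 and 6.7 ms), a detection threshold between 2
#' and 5 s.d. of the envelope, a 15 ms merge gap and a 30 ms centering
#' window.
#'
#' @param band band-pass edges in Hz.
#' @param filter_order FIR order.
#' @param threshold_sd detection threshold in s.d. multiples; must lie in
#'   [2, 5].
#' @param merge_gap_ms events closer than this are merged.
#' @param center_window_ms full width of the trough-search window around
#'   the envelope peak.
#' @param sg_window_ms,mm_windows_ms envelope smoothing windows.
#' @return a `detection_config` list.
#' @export
detection_config <- function(band = c(70, 400), filter_order = 512,
                             threshold_sd = 3, merge_gap_ms = 15,
                             center_window_ms = 30, sg_window_ms = 33.4,
                             mm_windows_ms = c(2.3, 6.7)) {
  stopifnot(band[1] < band[2])
  if (threshold_sd < 2 || threshold_sd > 5)
    stop("threshold_sd must lie within [2, 5]")
  structure(list(band = band, filter_order = filter_order,
                 threshold_sd = threshold_sd, merge_gap_ms = merge_gap_ms,
                 center_window_ms = center_window_ms,
                 sg_window_ms = sg_window_ms, mm_windows_ms = mm_windows_ms),
            class = "detection_config")
}

#' Mask noisy epochs by cross-channel signal excursions
#'
#' Sums two separated channels and flags whole epochs in which the summed
#' signal deviates more than `k_sd` standard deviations from its mean
#' (masticatory and movement artifacts co-occur on distant channels).
#'
#' @param rec an [lfp_recording()].
#' @param channel_pair indices of the two channels to sum.
#' @param k_sd deviation threshold in s.d. multiples (default 10).
#' @param epoch_s epoch length in seconds (non-overlapping).
#' @return logical keep-mask over samples (`TRUE` = keep).
#' @export
remove_noise_epochs <- function(rec, channel_pair = c(1, nrow(rec$signal)),
                                k_sd = 10, epoch_s = 1) {
  stopifnot(k_sd > 0)
  n <- ncol(rec$signal)
  if (nrow(rec$signal) < 2 || channel_pair[1] == channel_pair[2]) {
    warning("single-channel recording: noise-epoch masking skipped")
    return(rep(TRUE, n))
  }
  s <- rec$signal[channel_pair[1], ] + rec$signal[channel_pair[2], ]
  mu <- mean(s); sdev <- stats::sd(s)
  ep_len <- max(1L, round(epoch_s * rec$rate))
  keep <- rep(TRUE, n)
  starts <- seq(1L, n, by = ep_len)
  for (st in starts) {
    idx <- st:min(n, st + ep_len - 1L)
    if (any(abs(s[idx] - mu) > k_sd * sdev)) keep[idx] <- FALSE
  }
  keep
}

#' Select the pyramidal-layer channel
#'
#' The SP channel carries both the largest ripple-band power (100-250 Hz)
#' and the largest multi-unit band power (300-400 Hz). Channels are ranked
#' in each band and the channel with the best (lowest) rank sum is
#' returned; ties break to the lowest index.
#'
#' @param rec an [lfp_recording()].
#' @return channel index.
#' @export
select_sp_channel <- function(rec) {
  sig <- rec$signal
  if (all(sig == 0)) stop("all-zero recording")
  if (nrow(sig) == 1) return(1L)
  p_rip <- apply(sig, 1, band_power, rate = rec$rate, band = c(100, 250))
  p_mua <- apply(sig, 1, band_power, rate = rec$rate, band = c(300, 400))
  score <- rank(-p_rip, ties.method = "first") +
    rank(-p_mua, ties.method = "first")
  unname(which.min(score))
}

#' Band-pass filter a trace and compute its smoothed envelope
#'
#' Zero-phase band-pass (FIR, applied forward and backward), then the
#' analytic-signal magnitude smoothed with a fourth-order Savitzky-Golay
#' filter and two moving means.
#'
#' @param trace numeric vector.
#' @param rate sampling rate in Hz.
#' @param cfg a [detection_config()].
#' @return list with `filtered` and `envelope` vectors.
#' @export
filter_and_envelope <- function(trace, rate, cfg = detection_config()) {
  if (cfg$band[2] >= rate / 2) stop("band upper edge above Nyquist")
  if (length(trace) <= 3 * cfg$filter_order)
    stop("trace shorter than 3x the filter order")
  h <- signal::fir1(cfg$filter_order, cfg$band / (rate / 2), type = "pass")
  filtered <- signal::filtfilt(h, trace)
  env <- hilbert_envelope(filtered)
  sg_n <- round(cfg$sg_window_ms / 1000 * rate)
  if (sg_n %% 2 == 0) sg_n <- sg_n + 1
  env <- signal::sgolayfilt(env, p = 4, n = max(sg_n, 7))
  for (w_ms in cfg$mm_windows_ms)
    env <- movmean(env, round(w_ms / 1000 * rate))
  env[env < 0] <- 0
  list(filtered = filtered, envelope = env)
}

#' Detect, merge and trough-center ripple events
#'
#' Candidate events are supra-threshold intervals of the envelope
#' (threshold = mean + k s.d. over kept samples). Intervals closer than the
#' merge gap are merged (strictly closer: an exactly-15 ms gap stays
#' separate). Each event is centered on the minimum of the filtered trace
#' within half the centering window around the envelope maximum.
#'
#' @param filtered band-passed trace.
#' @param envelope smoothed envelope, same length.
#' @param rate sampling rate in Hz.
#' @param cfg a [detection_config()].
#' @param keep optional logical mask from [remove_noise_epochs()].
#' @return data frame with 1-based sample columns `onset`, `peak`,
#'   `offset` and their counterparts in seconds (`onset_s`, `peak_s`,
#'   `offset_s`; second 0 = sample 1). Event intervals are half-open
#'   `[onset, offset)`.
#' @export
detect_and_center <- function(filtered, envelope, rate,
                              cfg = detection_config(), keep = NULL) {
  stopifnot(length(filtered) == length(envelope))
  n <- length(envelope)
  keep <- keep %||% rep(TRUE, n)
  if (!any(keep)) stop("empty keep-mask: no samples available")
  mu <- mean(envelope[keep]); sdev <- stats::sd(envelope[keep])
  thr <- mu + cfg$threshold_sd * sdev

  above <- envelope > thr & keep
  if (!any(above)) {
    return(data.frame(onset = integer(0), peak = integer(0),
                      offset = integer(0), onset_s = numeric(0),
                      peak_s = numeric(0), offset_s = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])

  # merge intervals strictly closer than the gap
  gap <- round(cfg$merge_gap_ms / 1000 * rate)
  merged <- list()
  cur <- iv[1, ]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if ((iv[i, 1] - cur[2] - 1L) < gap) cur[2] <- iv[i, 2]
      else { merged[[length(merged) + 1]] <- cur; cur <- iv[i, ] }
    }
  }
  merged[[length(merged) + 1]] <- cur
  iv <- do.call(rbind, merged)

  half <- round(cfg$center_window_ms / 2 / 1000 * rate)
  peaks <- integer(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    seg <- iv[i, 1]:iv[i, 2]
    env_pk <- seg[which.max(envelope[seg])]
    win <- max(1L, env_pk - half):min(n, env_pk + half)
    peaks[i] <- win[which.min(filtered[win])]
  }
  o <- order(peaks)
  data.frame(onset = iv[o, 1], peak = peaks[o], offset = iv[o, 2],
             onset_s = (iv[o, 1] - 1) / rate, peak_s = (peaks[o] - 1) / rate,
             offset_s = (iv[o, 2] - 1) / rate)
}

#' Run the full detection pipeline on a recording
#'
#' Convenience wrapper: noise masking, SP channel selection, filtering,
#' envelope, detection and centering.
#'
#' @param rec an [lfp_recording()].
#' @param cfg a [detection_config()].
#' @param sp_channel pyramidal channel index; selected automatically when
#'   `NULL`.
#' @return list with `events`, `filtered`, `envelope`, `sp_channel`,
#'   `keep`.
#' @export
detect_ripples <- function(rec, cfg = detection_config(), sp_channel = NULL) {
  keep <- if (nrow(rec$signal) >= 2) remove_noise_epochs(rec)
          else rep(TRUE, ncol(rec$signal))
  sp <- sp_channel %||% select_sp_channel(rec)
  fe <- filter_and_envelope(rec$signal[sp, ], rec$rate, cfg)
  ev <- detect_and_center(fe$filtered, fe$envelope, rec$rate, cfg, keep)
  list(events = ev, filtered = fe$filtered, envelope = fe$envelope,
       sp_channel = sp, keep = keep)
}
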