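#' Generate a set of synthetic ripples in waveform space
#'
#' Each event is a Gaussian-windowed sinusoid,
#' `amplitude * exp(-t^2 / (2 sigma^2)) * sin(2 pi f t + phase)`, sampled on
#' the peak-centered analysis window. Frequency, amplitude and envelope
#' width are drawn independently and uniformly, so the noiseless cloud is a
#' three-parameter family embedded in the D-dimensional waveform space
#' (D = 127 at the 2,500 Hz / +-25 ms defaults). `mode = "clustered"` draws
#' the frequency from disjoint ranges instead, producing separated
#' components.
#'
#' @param n number of events (>= 1).
#' @param mode `"continuous"` (single frequency range) or `"clustered"`.
#' @param freq_range frequency range in Hz for continuous mode.
#' @param freq_clusters list of >= 2 disjoint Hz ranges for clustered mode.
#' @param amp_range amplitude range, arbitrary units.
#' @param dur_range envelope s.d. range in units of the base envelope width.
#' @param base_sd_ms base envelope width: Gaussian s.d. in ms at
#'   `duration = 1`. Default 10 ms keeps events inside the window.
#' @param noise_rms RMS of white Gaussian noise added per sample.
#' @param rate sampling rate in Hz.
#' @param window_ms window halfwidth in ms.
#' @param phase carrier phase at the window center; the default `-pi/2`
#'   places the ripple trough at the center sample, matching trough-centered
#'   detection.
#' @param seed optional RNG seed.
#' @return a list with `cloud` (a `ripple_cloud`: matrix `X` of n x D
#'   waveforms plus sampling metadata) and `features` (data frame of the
#'   exact drawn frequency, amplitude and duration per event, and the
#'   cluster index in clustered mode).
#' @export
generate_ripple_set <- function(n,
                                mode = c("continuous", "clustered"),
                                freq_range = c(80, 240),
                                freq_clusters = list(c(80, 100), c(130, 150), c(190, 210)),
                                amp_range = c(2, 5),
                                dur_range = c(0.5, 2),
                                base_sd_ms = 10,
                                noise_rms = 0,
                                rate = 2500,
                                window_ms = 25,
                                phase = -pi / 2,
                                seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, rate > 0, noise_rms >= 0)
  if (!is.null(seed)) set.seed(seed)

  if (mode == "continuous") {
    if (diff(freq_range) <= 0 || diff(amp_range) < 0 || diff(dur_range) < 0)
      stop("continuous mode requires a non-degenerate frequency range")
    fmax <- freq_range[2]
  } else {
    if (length(freq_clusters) < 2)
      stop("clustered mode requires >= 2 frequency ranges")
    rng <- do.call(rbind, freq_clusters)
    o <- order(rng[, 1])
    rng <- rng[o, , drop = FALSE]
    if (any(rng[-1, 1] <= rng[-nrow(rng), 2]))
      stop("cluster frequency ranges must be disjoint")
    fmax <- max(rng[, 2])
  }
  if (rate < 2 * fmax)
    stop("sampling rate below Nyquist for the maximum frequency requested")

  if (mode == "continuous") {
    frequency <- stats::runif(n, freq_range[1], freq_range[2])
    cluster <- rep(NA_integer_, n)
  } else {
    cluster <- sample.int(length(freq_clusters), n, replace = TRUE)
    lo <- vapply(freq_clusters, `[`, 0, 1)
    hi <- vapply(freq_clusters, `[`, 0, 2)
    frequency <- stats::runif(n, lo[cluster], hi[cluster])
  }
  amplitude <- stats::runif(n, amp_range[1], amp_range[2])
  duration <- stats::runif(n, dur_range[1], dur_range[2])

  half_n <- ceiling(window_ms * rate / 1000)
  t <- (-half_n:half_n) / rate
  sigma <- duration * base_sd_ms / 1000
  X <- matrix(0, n, length(t))
  for (i in seq_len(n)) {
    X[i, ] <- amplitude[i] * exp(-t^2 / (2 * sigma[i]^2)) *
      sin(2 * pi * frequency[i] * t + phase)
  }
  if (noise_rms > 0)
    X <- X + matrix(stats::rnorm(length(X), 0, noise_rms), n)

  cloud <- structure(
    list(X = X, rate = rate, halfwidth_ms = window_ms,
         meta = data.frame(event = seq_len(n))),
    class = "ripple_cloud")
  list(cloud = cloud,
       features = data.frame(event = seq_len(n), frequency = frequency,
                             amplitude = amplitude, duration = duration,
                             cluster = cluster))
}

#' Sample a geometric ground-truth object embedded in high dimension
#'
#' Points are drawn uniformly from the object's parametric surface or
#' volume, mapped into `ambient_dim` dimensions by a seeded orthonormal
#' frame (QR of a Gaussian matrix, so intrinsic distances are preserved),
#' and perturbed with isotropic Gaussian noise whose *total* standard
#' deviation is `noise_sd` (per-coordinate s.d. `noise_sd / sqrt(D)`); a
#' per-coordinate reading at the same nominal value would add a
#' perturbation of norm `noise_sd * sqrt(D)`, an order of magnitude larger
#' than the local neighborhood scale of unit-size objects, and destroy the
#' very structure the objects exist to provide.
#'
#' Known intrinsic dimensions: line 1, plane 2, swissroll 2, torus 2
#' (major radius 1, minor 0.3), hyperball 5. The line spans length 10 so
#' that k-NN neighborhoods extend well beyond the noise floor even at dense
#' 1D sampling; the other objects have unit scale.
#'
#' @param kind one of `"torus"`, `"plane"`, `"swissroll"`, `"hyperball"`,
#'   `"line"`.
#' @param n_points number of points (>= 50).
#' @param ambient_dim embedding dimension (default 127).
#' @param noise_sd total ambient noise s.d. (default 0.01).
#' @param seed optional RNG seed.
#' @return list with `X` (n x ambient_dim matrix), `intrinsic_dim`,
#'   `params` (the low-dimensional coordinates before embedding) and `kind`.
#' @export
generate_geometric_object <- function(kind = c("torus", "plane", "swissroll",
                                               "hyperball", "line"),
                                      n_points = 1000,
                                      ambient_dim = 127,
                                      noise_sd = 0.01,
                                      seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_points >= 50, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- n_points

  P <- switch(kind,
    line = matrix(stats::runif(n, 0, 10), n, 1),
    plane = cbind(stats::runif(n), stats::runif(n)),
    torus = {
      R <- 1; r <- 0.3
      th <- stats::runif(n, 0, 2 * pi)
      # rejection sampling for uniform surface area
      ph <- numeric(0)
      while (length(ph) < n) {
        cand <- stats::runif(n, 0, 2 * pi)
        keep <- stats::runif(n) < (R + r * cos(cand)) / (R + r)
        ph <- c(ph, cand[keep])
      }
      ph <- ph[seq_len(n)]
      cbind((R + r * cos(ph)) * cos(th),
            (R + r * cos(ph)) * sin(th),
            r * sin(ph))
    },
    swissroll = {
      # roll parameter weighted by arclength so the surface is uniform
      t0 <- 1.5 * pi; t1 <- 4.5 * pi
      tt <- sqrt(t0^2 + (t1^2 - t0^2) * stats::runif(n))
      cbind(tt * cos(tt), stats::runif(n, 0, 10), tt * sin(tt)) / t1
    },
    hyperball = {
      B <- matrix(stats::rnorm(n * 5), n, 5)
      B / sqrt(rowSums(B^2)) * stats::runif(n)^(1 / 5)
    })

  d <- ncol(P)
  if (ambient_dim < d) stop("ambient_dim below the object's dimension")
  Q <- qr.Q(qr(matrix(stats::rnorm(ambient_dim * d), ambient_dim, d)))
  X <- P %*% t(Q)
  if (noise_sd > 0)
    X <- X + matrix(stats::rnorm(length(X), 0, noise_sd / sqrt(ambient_dim)),
                    nrow(X))
  idim <- c(line = 1, plane = 2, swissroll = 2, torus = 2, hyperball = 5)
  list(X = X, intrinsic_dim = unname(idim[kind]), params = P, kind = kind)
}

#' Default laminar coupling specification
#'
#' Per-layer signed gains mapping the three ripple parameters (scaled to
#' [0, 1] over their generative ranges) to the layer's current source
#' density at the event peak. Sinks are negative, sources positive. The
#' defaults emulate the empirical picture: a frequency- and
#' amplitude-coupled sink at stratum radiatum (CA3 input), an
#' amplitude-coupled source at stratum oriens, and a duration-coupled sink
#' at stratum lacunosum-moleculare (entorhinal input); the pyramidal layer
#' is uncoupled.
#'
#' @param layers character vector of layer names.
#' @return data frame with one row per layer and columns `base`, `g_freq`,
#'   `g_amp`, `g_dur`.
#' @export
default_coupling <- function(layers = c("SO", "SP", "SR", "SLM")) {
  data.frame(
    layer  = layers,
    base   = c( 0.2, 0.0, -0.5,  0.0),
    g_freq = c( 0.0, 0.0, -1.0,  0.0),
    g_amp  = c( 0.8, 0.0, -0.8,  0.0),
    g_dur  = c( 0.0, 0.0,  0.0, -1.0),
    stringsAsFactors = FALSE)
}

#' Simulate a laminar LFP session with programmed feature-CSD couplings
#'
#' Builds an 8-channel recording spanning stratum oriens to stratum
#' lacunosum-moleculare with ripple events on the pyramidal-layer channel.
#' For every event, a target CSD profile is programmed from the coupling
#' specification (layer CSD = base + gains x scaled event features) and the
#' laminar potential is obtained by integrating the discrete Poisson
#' equation twice, so the second spatial derivative of the noiseless
#' potential reproduces the programmed CSD exactly at interior channels.
#' The ripple itself (Gaussian-windowed sinusoid) is added on the SP
#' channel and white noise on all channels.
#'
#' @param n_events number of events.
#' @param coupling data frame as returned by [default_coupling()].
#' @param rate sampling rate in Hz.
#' @param noise_sd Gaussian noise s.d. per channel (signal units).
#' @param gap_ms minimum gap between consecutive event peaks (refractory).
#' @param freq_range,amp_range,dur_range feature ranges, as in
#'   [generate_ripple_set()].
#' @param base_sd_ms base envelope width in ms.
#' @param csd_scale amplitude of the laminar (sharp-wave) potential
#'   relative to unit programmed CSD.
#' @param seed optional RNG seed.
#' @return list with `recording` (an `lfp_recording`), `events` (ground
#'   truth: peak sample, features), `csd_true` (n_events x 4 matrix of
#'   programmed per-layer CSD values) and `coupling`.
#' @export
generate_laminar_session <- function(n_events = 200,
                                     coupling = default_coupling(),
                                     rate = 2500,
                                     noise_sd = 0.05,
                                     gap_ms = 800,
                                     freq_range = c(80, 240),
                                     amp_range = c(2, 5),
                                     dur_range = c(0.5, 2),
                                     base_sd_ms = 10,
                                     csd_scale = 1,
                                     seed = NULL) {
  stopifnot(n_events >= 1, gap_ms > 60)
  if (!is.null(seed)) set.seed(seed)

  layers_ch <- c("SO", "SO", "SP", "SR", "SR", "SR", "SLM", "SLM")
  depths <- 100 * (0:7)
  n_ch <- length(layers_ch)
  gap <- round(gap_ms / 1000 * rate)
  pad <- round(0.15 * rate)
  peaks <- pad + gap * (seq_len(n_events) - 1) +
    sample.int(round(gap / 4), n_events, replace = TRUE)
  n_samp <- max(peaks) + pad
  if (n_events > 1 && min(diff(peaks)) < round(0.06 * rate))
    stop("events denser than the refractory gap allows")

  frequency <- stats::runif(n_events, freq_range[1], freq_range[2])
  amplitude <- stats::runif(n_events, amp_range[1], amp_range[2])
  duration <- stats::runif(n_events, dur_range[1], dur_range[2])
  sc <- function(x, r) if (diff(r) > 0) (x - r[1]) / diff(r) else x * 0

  # programmed per-layer CSD at the event peak
  feat <- cbind(1, sc(frequency, freq_range), sc(amplitude, amp_range),
                sc(duration, dur_range))
  G <- t(as.matrix(coupling[, c("base", "g_freq", "g_amp", "g_dur")]))
  csd_true <- feat %*% G                       # n_events x 4 layers
  colnames(csd_true) <- coupling$layer

  sig <- matrix(stats::rnorm(n_ch * n_samp, 0, noise_sd), n_ch, n_samp)
  h <- diff(depths)[1]

  # channel-level CSD profile per unit layer value
  layer_of <- match(layers_ch, coupling$layer)
  sw_half <- round(0.05 * rate)                 # +-50 ms sharp-wave support
  tt_sw <- (-sw_half:sw_half) / rate
  env_sw <- exp(-tt_sw^2 / (2 * 0.012^2))       # 12 ms s.d. deflection
  # discrete Poisson operator with grounded (V = 0) boundary channels:
  # interior rows demand V[i-1] - 2 V[i] + V[i+1] = c[i], so compute_csd
  # recovers the programmed profile exactly and potentials stay bounded
  A_pois <- diag(n_ch)
  for (i in 2:(n_ch - 1)) A_pois[i, (i - 1):(i + 1)] <- c(1, -2, 1)
  for (e in seq_len(n_events)) {
    c_prof <- csd_true[e, layer_of] * csd_scale
    rhs <- c_prof
    rhs[c(1, n_ch)] <- 0
    v <- solve(A_pois, rhs)
    idx <- peaks[e] + (-sw_half:sw_half)
    sig[, idx] <- sig[, idx] + outer(v, env_sw)

    # ripple on the SP channel, trough at the peak sample
    sigma <- duration[e] * base_sd_ms / 1000
    rip_half <- round(0.03 * rate)
    tt <- (-rip_half:rip_half) / rate
    w <- amplitude[e] * exp(-tt^2 / (2 * sigma^2)) *
      sin(2 * pi * frequency[e] * tt - pi / 2)
    sig[3, peaks[e] + (-rip_half:rip_half)] <-
      sig[3, peaks[e] + (-rip_half:rip_half)] + w
  }

  rec <- lfp_recording(sig, rate, depths = depths, layers = layers_ch,
                       session = "synthetic")
  list(recording = rec,
       events = data.frame(event = seq_len(n_events), peak = peaks,
                           frequency = frequency, amplitude = amplitude,
                           duration = duration),
       csd_true = csd_true,
       coupling = coupling,
       csd_scale = csd_scale,
       grid_step_um = h)
}
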