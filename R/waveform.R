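#' Build the waveform-space point cloud from peak-centered events
#'
#' Each detected event becomes one point: the band-filtered pyramidal-layer
#' trace is z-scored over the whole session (per-session scoring keeps
#' amplitude structure that per-event scoring would erase), resampled to
#' `rate_out`, and cut to 63 samples either side of the peak-aligned center
#' sample at the defaults (2,500 Hz, +-25 ms), giving D = 127 dimensions.
#' Events whose windows cross the trace edge are dropped and counted.
#'
#' @param filtered band-passed SP trace (session).
#' @param events event table with a `peak` column (samples at the trace's
#'   native rate).
#' @param rate native sampling rate of `filtered`, Hz.
#' @param rate_out output sampling rate (default 2,500 Hz).
#' @param halfwidth_ms window halfwidth in ms (default 25; +-20 ms windows
#'   are supported with `halfwidth_ms = 20`).
#' @param zscore_scope `"session"` (default) or `"event"`.
#' @param meta optional per-event metadata data frame (same rows as
#'   `events`), carried along and subset with the kept events.
#' @return a `ripple_cloud`: list with matrix `X` (events x D), `rate`,
#'   `halfwidth_ms`, `meta`, `dropped`.
#' @export
build_waveform_matrix <- function(filtered, events, rate, rate_out = 2500,
                                  halfwidth_ms = 25,
                                  zscore_scope = c("session", "event"),
                                  meta = NULL) {
  zscore_scope <- match.arg(zscore_scope)
  x <- as.numeric(filtered)
  if (zscore_scope == "session") x <- (x - mean(x)) / stats::sd(x)

  if (rate_out != rate) {
    # rational polyphase resampling (anti-aliasing inherent)
    fr <- as.integer(c(rate_out, rate) / gcd_int(rate_out, rate))
    x <- resample_trace(x, fr[1], fr[2])
    peaks <- round((events$peak - 1) * rate_out / rate) + 1
  } else {
    peaks <- events$peak
  }
  half_n <- ceiling(halfwidth_ms * rate_out / 1000)

  ok <- peaks - half_n >= 1 & peaks + half_n <= length(x)
  dropped <- sum(!ok)
  keep_idx <- which(ok)
  X <- t(vapply(keep_idx, function(i)
    x[(peaks[i] - half_n):(peaks[i] + half_n)], numeric(2 * half_n + 1)))
  if (zscore_scope == "event")
    X <- t(apply(X, 1, function(r) (r - mean(r)) / stats::sd(r)))

  m <- if (!is.null(meta)) meta[keep_idx, , drop = FALSE]
       else data.frame(event = keep_idx)
  structure(list(X = X, rate = rate_out, halfwidth_ms = halfwidth_ms,
                 meta = m, dropped = dropped),
            class = "ripple_cloud")
}

gcd_int <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Concatenate waveform clouds from several sessions
#'
#' Row order within each session and metadata alignment are preserved; the
#' sample dimension D must agree.
#'
#' @param ... `ripple_cloud` objects.
#' @return a combined `ripple_cloud`.
#' @export
bind_clouds <- function(...) {
  clouds <- list(...)
  stopifnot(length(clouds) >= 1)
  D <- unique(vapply(clouds, function(cl) ncol(cl$X), 0L))
  if (length(D) != 1) stop("clouds have differing waveform dimension D")
  metas <- lapply(seq_along(clouds), function(i) {
    m <- clouds[[i]]$meta
    m$source_cloud <- i
    m
  })
  structure(list(X = do.call(rbind, lapply(clouds, `[[`, "X")),
                 rate = clouds[[1]]$rate,
                 halfwidth_ms = clouds[[1]]$halfwidth_ms,
                 meta = do.call(rbind, metas),
                 dropped = sum(vapply(clouds, function(cl)
                   cl$dropped %||% 0L, 0))),
            class = "ripple_cloud")
}

#' @export
print.ripple_cloud <- function(x, ...) {
  cat(sprintf("<ripple_cloud: %d events x %d samples @ %g Hz, +-%g ms>\n",
              nrow(x$X), ncol(x$X), x$rate, x$halfwidth_ms))
  invisible(x)
}
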