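# Shared fixtures and independent oracles used across the suite.

# Orthonormal embedding of a low-dimensional parameter matrix into D dims
# (mirrors the generator's construction; used to build known-topology
# fixtures directly).
embed_highdim <- function(P, D = 127, noise_total_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(D * ncol(P)), D, ncol(P))))
  X <- P %*% t(Q)
  if (noise_total_sd > 0)
    X <- X + matrix(stats::rnorm(length(X), 0, noise_total_sd / sqrt(D)),
                    nrow(X))
  X
}

circle_points <- function(n, noise = 0.03) {
  # evenly spaced angles with jitter: a circle sample without the long
  # Poisson gaps that would genuinely disconnect it at this density
  th <- 2 * pi * seq_len(n) / n + stats::rnorm(n, 0, pi / n)
  cbind(cos(th), sin(th)) + matrix(stats::rnorm(2 * n, 0, noise), n)
}

# Brute-force Structure Index oracle: explicit distance matrix, explicit
# neighbor enumeration, independent of the RANN-based production path.
si_bruteforce <- function(coords, feature, n_bins, k) {
  coords <- as.matrix(coords)
  edges <- seq(min(feature), max(feature), length.out = n_bins + 1)
  bins <- findInterval(feature, edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  groups <- sort(unique(bins))
  nb <- length(groups)
  D <- as.matrix(stats::dist(coords))
  A <- matrix(0, nb, nb)
  for (a in seq_len(nb)) for (b in seq_len(nb)) {
    if (a == b) next
    U <- which(bins == groups[a]); V <- which(bins == groups[b])
    pool <- c(U, V)
    kk <- min(k, length(pool) - 1)
    hits <- 0
    for (u in U) {
      cand <- setdiff(pool, u)
      nnb <- cand[order(D[u, cand], cand)][seq_len(kk)]  # ties by index
      hits <- hits + sum(nnb %in% V)
    }
    A[a, b] <- hits / (length(U) * kk)
  }
  list(A = A, si = max(0, 1 - 2 / (nb^2 - nb) * sum(A)))
}

# small laminar session shared by detection/feature/decoder tests
make_session <- function(n_events = 60, seed = 7, ...) {
  generate_laminar_session(n_events = n_events, seed = seed, ...)
}

# match detected peaks to ground-truth events (sample tolerance)
match_events <- function(truth_peaks, det_peaks, tol = 10) {
  dmat <- abs(outer(truth_peaks, det_peaks, "-"))
  list(recall = mean(apply(dmat, 1, min) <= tol),
       precision = mean(apply(dmat, 2, min) <= tol))
}
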