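# Independent brute-force oracles. These deliberately avoid the package's
# code paths: naive per-sample recomputation, exhaustive window enumeration,
# and explicit orthogonal-matrix wavelet transforms.

# moving mean absolute deviation, recomputed naively per sample
oracle_moving_mad <- function(x, fs, window_ms) {
  n <- length(x)
  w <- as.integer(round(window_ms / 1000 * fs))
  out <- numeric(n)
  for (k in seq_len(n)) {
    idx <- max(1L, k - w %/% 2L):min(n, k + (w - 1L) %/% 2L)
    out[k] <- mean(abs(x[idx] - mean(x[idx])))
  }
  out
}

# moving-maximum beat criterion by exhaustive window enumeration: a sample
# qualifies iff it is the earliest argmax of every full window containing it
oracle_detect_beats <- function(x, fs, window_ms) {
  n <- length(x)
  w <- max(2L, as.integer(round(window_ms / 1000 * fs)))
  w <- min(w, n)
  starts <- seq_len(n - w + 1L)
  qualifies <- x > 0
  for (s in starts) {
    win <- s:(s + w - 1L)
    am <- win[which.max(x[win])]      # which.max: earliest on ties
    bad <- setdiff(win, am)
    qualifies[bad] <- FALSE
  }
  (which(qualifies) - 1L) / fs
}

# explicit orthogonal Haar analysis operator down to one detail level:
# M_level = D_{n/2^(L-1)} %*% A_{n/2^(L-2)} %*% ... %*% A_n, so the
# level-restricted reconstruction is t(M) %*% M %*% x
haar_pair_matrix <- function(m, kind) {
  M <- matrix(0, m / 2L, m)
  s <- if (kind == "A") 1 else -1
  for (k in seq_len(m / 2L)) {
    M[k, 2L * k - 1L] <- 1 / sqrt(2)
    M[k, 2L * k] <- s / sqrt(2)
  }
  M
}

oracle_dwt_detail <- function(x, level) {
  n <- length(x)
  stopifnot(n %% 2L^level == 0L)
  M <- diag(n)
  m <- n
  for (lev in seq_len(level - 1L)) {
    M <- haar_pair_matrix(m, "A") %*% M
    m <- m / 2L
  }
  M <- haar_pair_matrix(m, "D") %*% M
  as.vector(t(M) %*% (M %*% x))
}

# undecimated level-L detail by naive per-sample box means
oracle_swt_detail <- function(x, level) {
  n <- length(x)
  bm <- function(m) {
    if (m <= 1L) return(x)
    vapply(seq_len(n), function(k)
      mean(x[max(1L, k - m %/% 2L):min(n, k + (m - 1L) %/% 2L)]), 0)
  }
  bm(2L^(level - 1L)) - bm(2L^level)
}

# dominant oscillation frequency of a beat-indexed series, by periodogram of
# the series resampled onto a uniform grid
oracle_dominant_freq <- function(times, values, resample_hz = 4) {
  grid <- seq(min(times), max(times), by = 1 / resample_hz)
  y <- stats::approx(times, values, xout = grid)$y
  y <- y - mean(y)
  sp <- stats::spec.pgram(stats::ts(y, frequency = resample_hz),
                          plot = FALSE, taper = 0, detrend = FALSE)
  sp$freq[which.max(sp$spec)]
}

default_calibration <- function() calibration_range(15, 80)
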