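#' Raw ballistocardiogram series
#'
#' A uniformly sampled single-channel seat-vibration signal. Each heartbeat
#' ejects blood into the aorta and the recoil shakes the body; a film
#' pressure sensor in the seat pan picks this up as a band-limited
#' oscillatory burst per beat, riding on low-frequency respiratory drift.
#'
#' @param values numeric vector of signal samples (unit-free).
#' @param fs sampling rate in Hz.
#' @return An object of class `raw_bcg`.
#' @export
raw_bcg <- function(values, fs) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive number", call. = FALSE)
  if (!is.numeric(values) || length(values) < 2L)
    stop("a BCG series needs at least 2 samples", call. = FALSE)
  structure(list(values = as.numeric(values), fs = as.numeric(fs)),
            class = "raw_bcg")
}

#' @export
print.raw_bcg <- function(x, ...) {
  cat("<raw_bcg> ", length(x$values), " samples @ ", x$fs, " Hz (",
      round(length(x$values) / x$fs, 2), " s)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.raw_bcg <- function(x, ...) {
  data.frame(time_s = (seq_along(x$values) - 1) / x$fs, value = x$values)
}

# ---- Haar wavelet transforms -------------------------------------------
#
# Two hand-rolled variants of the Haar ("db1") multiresolution:
#
# * a decimated Mallat pyramid (orthonormal filters h = (1,1)/sqrt2,
#   g = (1,-1)/sqrt2), padded by edge replication and trimmed after
#   reconstruction, and
# * an undecimated (a trous / stationary) additive decomposition whose
#   level-j detail is the difference of two centred box means,
#   d_j = box(2^(j-1)) - box(2^j), so that sum(details) + box(2^L) = x
#   exactly. The undecimated detail is shift-invariant, which is what makes
#   sample-accurate beat timing possible; it is the pipeline default.

haar_decompose <- function(x, levels) {
  n0 <- length(x)
  block <- 2L^levels
  if (n0 %% block != 0L)
    x <- c(x, rep(x[n0], block - n0 %% block))
  details <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    odd  <- a[seq(1L, length(a), by = 2L)]
    even <- a[seq(2L, length(a), by = 2L)]
    details[[lev]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  list(details = details, approx = a, n_orig = n0, levels = levels)
}

haar_reconstruct <- function(dec, keep_details = seq_len(dec$levels),
                             keep_approx = TRUE) {
  a <- if (keep_approx) dec$approx else numeric(length(dec$approx))
  for (lev in rev(seq_len(dec$levels))) {
    d <- if (lev %in% keep_details) dec$details[[lev]]
         else numeric(length(dec$details[[lev]]))
    x <- numeric(2L * length(a))
    x[seq(1L, length(x), by = 2L)] <- (a + d) / sqrt(2)
    x[seq(2L, length(x), by = 2L)] <- (a - d) / sqrt(2)
    a <- x
  }
  a[seq_len(dec$n_orig)]
}

# centred box mean with truncated edge windows, O(n) via cumulative sums
box_mean <- function(x, m) {
  n <- length(x)
  if (m <= 1L) return(x)
  lo <- pmax(1L, seq_len(n) - (m %/% 2L))
  hi <- pmin(n, seq_len(n) + ((m - 1L) %/% 2L))
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Wavelet detail denoising of a BCG signal
#'
#' Keeps only the chosen Haar (db1) detail level of the signal; every other
#' detail band and the approximation are discarded. At the default sampling
#' rate of 256 Hz the level-4 detail band spans roughly 8--16 Hz, which
#' brackets the oscillatory heartbeat bursts while suppressing both
#' low-frequency respiratory drift and high-frequency noise.
#'
#' Two transforms are available. The default `"swt"` is the undecimated
#' (a trous, stationary) Haar decomposition, whose level-j detail is the
#' difference of centred box means of widths `2^(j-1)` and `2^j`: a
#' shift-invariant band-pass, so the shape of a reconstructed heartbeat
#' burst does not depend on where it falls relative to a block grid and the
#' envelope peak localises the beat to within a sample. `"dwt"` is the
#' classical decimated orthogonal transform (all other coefficients zeroed
#' before the inverse, pad-and-trim); it is kept for reference but its
#' shift-variance quantises beat timing to the 2^level block grid and makes
#' it unsuitable for interval-accurate beat detection.
#'
#' @param raw a [raw_bcg] object.
#' @param level detail level to keep (default 4).
#' @param method `"swt"` (undecimated, default) or `"dwt"` (decimated).
#' @return A [raw_bcg] with the band-passed signal, same length and rate.
#' @export
wavelet_denoise <- function(raw, level = 4L, method = c("swt", "dwt")) {
  stopifnot(inherits(raw, "raw_bcg"))
  method <- match.arg(method)
  level <- as.integer(level)
  if (level < 1L) stop("level must be >= 1", call. = FALSE)
  if (length(raw$values) < 2L^level)
    stop("signal shorter than one level-", level, " support", call. = FALSE)
  out <- if (method == "swt") {
    box_mean(raw$values, 2L^(level - 1L)) - box_mean(raw$values, 2L^level)
  } else {
    dec <- haar_decompose(raw$values, level)
    haar_reconstruct(dec, keep_details = level, keep_approx = FALSE)
  }
  raw_bcg(out, raw$fs)
}

# ---- envelope extraction ------------------------------------------------

#' Moving mean absolute deviation envelope
#'
#' For every sample, computes the mean absolute deviation of the signal from
#' its own mean over a centred window, emphasising instantaneous amplitude
#' changes: quiet stretches map near zero and each heartbeat burst becomes a
#' smooth nonnegative hump whose apex marks the beat. Windows are truncated
#' (not padded) at the series boundaries.
#'
#' @param signal a [raw_bcg] (typically the output of [wavelet_denoise()]).
#' @param window_ms window length in milliseconds; must span at least 2
#'   samples at the signal's rate. The default (100 ms, about 1.5 cycles of
#'   the heartbeat oscillation) is deliberately shorter than the beat
#'   complex: a window longer than the complex produces a flat-topped
#'   envelope whose maximum is not localised.
#' @return An object of class `heartbeat_envelope` with fields `values`
#'   (nonnegative, same length), `fs`, and `window_ms`.
#' @export
moving_mad <- function(signal, window_ms = 100) {
  stopifnot(inherits(signal, "raw_bcg"))
  if (!is.numeric(window_ms) || length(window_ms) != 1L || window_ms <= 0)
    stop("window_ms must be positive", call. = FALSE)
  x <- signal$values
  n <- length(x)
  w <- as.integer(round(window_ms / 1000 * signal$fs))
  if (w < 2L)
    stop("window must span at least 2 samples at fs = ", signal$fs,
         call. = FALSE)
  lo <- pmax(1L, seq_len(n) - (w %/% 2L))
  hi <- pmin(n, seq_len(n) + ((w - 1L) %/% 2L))
  cs <- c(0, cumsum(x))
  out <- numeric(n)
  for (k in seq_len(n)) {
    i <- lo[k]; j <- hi[k]
    m <- (cs[j + 1L] - cs[i]) / (j - i + 1L)
    out[k] <- mean(abs(x[i:j] - m))
  }
  structure(list(values = out, fs = signal$fs, window_ms = window_ms),
            class = "heartbeat_envelope")
}

#' @export
print.heartbeat_envelope <- function(x, ...) {
  cat("<heartbeat_envelope> ", length(x$values), " samples @ ", x$fs,
      " Hz, window ", x$window_ms, " ms\n", sep = "")
  invisible(x)
}

# ---- beat detection -----------------------------------------------------

#' Moving-maximum heartbeat detection
#'
#' A sample is accepted as a heartbeat when it is the most significant peak
#' of every window of `window_ms` that contains it, i.e. it dominates its
#' whole +/- (window - 1 sample) neighbourhood. Ties are broken in favour of
#' the earliest sample, and a refractory gap of one window is enforced so no
#' two beats are closer than `window_ms`.
#'
#' @param env a `heartbeat_envelope` (or any nonnegative [raw_bcg]-like list
#'   with `values` and `fs`).
#' @param window_ms detection window, default 400 ms.
#' @return Numeric vector of beat times in seconds (possibly empty), strictly
#'   increasing. A flat or all-zero envelope yields no beats.
#' @export
detect_beats <- function(env, window_ms = 400) {
  stopifnot(is.list(env), is.numeric(env$values), is.numeric(env$fs))
  if (any(env$values < 0)) stop("envelope must be nonnegative", call. = FALSE)
  x <- env$values
  n <- length(x)
  w <- max(2L, as.integer(round(window_ms / 1000 * env$fs)))
  # cheap candidate screen: local maxima with positive value (earliest of a
  # plateau: strictly above the left neighbour, at least the right one)
  cand <- which(x > 0)
  cand <- cand[(cand == 1L | x[cand] >  x[pmax(cand - 1L, 1L)]) &
               (cand == n  | x[cand] >= x[pmin(cand + 1L, n)])]
  keep <- logical(length(cand))
  for (ii in seq_along(cand)) {
    i <- cand[ii]
    a <- max(1L, i - w + 1L); b <- min(n, i + w - 1L)
    before <- if (i > a) x[a:(i - 1L)] else numeric(0)
    after  <- if (i < b) x[(i + 1L):b] else numeric(0)
    keep[ii] <- (!length(before) || all(x[i] > before)) &&
                (!length(after)  || all(x[i] >= after))
  }
  idx <- cand[keep]
  # refractory: the dominance criterion already forbids beats within one
  # window; this guard keeps the contract explicit for edge-truncated windows
  if (length(idx) > 1L) {
    acc <- idx[1L]
    for (i in idx[-1L]) if (i - acc[length(acc)] >= w) acc <- c(acc, i)
    idx <- acc
  }
  (idx - 1L) / env$fs
}

# ---- inter-beat intervals ----------------------------------------------

#' Inter-beat interval series
#'
#' @param beat_times strictly increasing beat times in seconds (length n+1
#'   for n intervals).
#' @param valid logical validity flags, one per interval; computed by the
#'   gate in [compute_ibis()] when omitted there.
#' @return An object of class `ibi_series` with `beat_times`, `ibis_ms`
#'   (exact successive differences in ms) and `valid`.
#' @export
ibi_series <- function(beat_times, valid = NULL) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) > 1L && any(diff(beat_times) <= 0))
    stop("beat_times must be strictly increasing", call. = FALSE)
  ibis <- if (length(beat_times) > 1L) diff(beat_times) * 1000 else numeric(0)
  if (is.null(valid)) valid <- rep(TRUE, length(ibis))
  if (length(valid) != length(ibis))
    stop("valid flags must match the number of intervals", call. = FALSE)
  structure(list(beat_times = beat_times, ibis_ms = ibis,
                 valid = as.logical(valid)),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat("<ibi_series> ", length(x$ibis_ms), " intervals (",
      sum(x$valid), " valid)", sep = "")
  if (length(x$ibis_ms))
    cat("; mean valid IBI ",
        round(mean(x$ibis_ms[x$valid]), 1), " ms", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.ibi_series <- function(x) length(x$ibis_ms)

#' Compute gated inter-beat intervals from beat times
#'
#' Successive differences between detected beats, in milliseconds. Each
#' interval is flagged valid when it lies inside the physiological gate
#' (default 300--1500 ms, heart rates 40--200 bpm) and differs from the
#' previous *valid* interval by at most the relative-jump fraction (default
#' 30%), which rejects missed and double-detected beats. The first in-range
#' interval anchors the jump test.
#'
#' @param beat_times strictly increasing beat times in seconds.
#' @param config an [sl_config()] supplying the gate bounds.
#' @return An `ibi_series`; fewer than two beats yield an empty series.
#' @export
compute_ibis <- function(beat_times, config = sl_config()) {
  if (length(beat_times) < 2L) return(ibi_series(beat_times))
  ibis <- diff(beat_times) * 1000
  valid <- logical(length(ibis))
  prev <- NA_real_
  for (k in seq_along(ibis)) {
    ok <- ibis[k] >= config$ibi_gate_lo_ms && ibis[k] <= config$ibi_gate_hi_ms
    if (ok && !is.na(prev))
      ok <- abs(ibis[k] - prev) <= config$ibi_gate_rel_jump * prev
    valid[k] <- ok
    if (ok) prev <- ibis[k]
  }
  ibi_series(beat_times, valid)
}

# ---- recursive HRV estimator -------------------------------------------

#' Running 40-beat IBI/HRV estimator state
#'
#' The system tracks stress through a pair of per-beat recursions over valid
#' inter-beat intervals: a running mean `ibi40` and a running mean absolute
#' deviation `hrv40`, each carrying 39/40 of its previous value, so one
#' "window" corresponds to an exponential memory of about 40 beats. The state
#' is flagged `warm_up` until 40 valid intervals have been consumed.
#'
#' @param ibi40 initial running-mean IBI in ms (`NA` until the first valid
#'   interval seeds it).
#' @param hrv40 initial running deviation in ms (seeded at 0).
#' @param n_seen number of valid intervals consumed.
#' @param window recursion window length in beats (default 40).
#' @return An object of class `hrv_state`.
#' @export
hrv_state <- function(ibi40 = NA_real_, hrv40 = 0, n_seen = 0L,
                      window = 40L) {
  if (!is.na(hrv40) && hrv40 < 0) stop("hrv40 must be >= 0", call. = FALSE)
  structure(list(ibi40 = ibi40, hrv40 = hrv40, n_seen = as.integer(n_seen),
                 window = as.integer(window)),
            class = "hrv_state")
}

#' @export
print.hrv_state <- function(x, ...) {
  cat("<hrv_state> IBI40 = ", round(x$ibi40, 2), " ms, HRV40 = ",
      round(x$hrv40, 3), " ms, n = ", x$n_seen,
      if (is_warm_up(x)) " (warm-up)" else "", "\n", sep = "")
  invisible(x)
}

#' @rdname hrv_state
#' @param state an `hrv_state`.
#' @export
is_warm_up <- function(state) state$n_seen < state$window

#' One step of the recursive HRV estimator
#'
#' Applies, per valid heartbeat,
#' `HRV40' = (39 * HRV40 + |IBI - IBI40|) / 40` followed by
#' `IBI40' = (39 * IBI40 + IBI) / 40`, i.e. the deviation update uses the
#' pre-update running mean. The first valid interval seeds `ibi40` directly
#' with `hrv40` left at 0. An interval flagged invalid leaves the state
#' untouched.
#'
#' @param state an [hrv_state].
#' @param ibi interval in ms.
#' @param valid validity flag from the IBI gate.
#' @return The updated `hrv_state`.
#' @export
update_hrv <- function(state, ibi, valid = TRUE) {
  stopifnot(inherits(state, "hrv_state"))
  if (!isTRUE(valid)) return(state)
  if (!is.numeric(ibi) || length(ibi) != 1L || !is.finite(ibi) || ibi <= 0)
    stop("ibi must be a positive number", call. = FALSE)
  w <- state$window
  if (state$n_seen == 0L || is.na(state$ibi40))
    return(hrv_state(ibi, 0, 1L, w))
  hrv <- ((w - 1) * state$hrv40 + abs(ibi - state$ibi40)) / w
  ibi40 <- ((w - 1) * state$ibi40 + ibi) / w
  hrv_state(ibi40, hrv, state$n_seen + 1L, w)
}

#' Run the HRV recursion over an interval series
#'
#' @param ibis an [ibi_series].
#' @param state starting [hrv_state] (fresh by default).
#' @return A data frame with one row per interval: `beat_time_s`, `ibi_ms`,
#'   `valid`, and the post-update `ibi40`, `hrv40`, `n_seen`, `warm_up`.
#' @export
hrv_trace <- function(ibis, state = hrv_state()) {
  stopifnot(inherits(ibis, "ibi_series"))
  n <- length(ibis$ibis_ms)
  out <- data.frame(beat_time_s = if (n) ibis$beat_times[-1L] else numeric(0),
                    ibi_ms = ibis$ibis_ms, valid = ibis$valid,
                    ibi40 = numeric(n), hrv40 = numeric(n),
                    n_seen = integer(n), warm_up = logical(n))
  for (k in seq_len(n)) {
    state <- update_hrv(state, ibis$ibis_ms[k], ibis$valid[k])
    out$ibi40[k] <- state$ibi40
    out$hrv40[k] <- state$hrv40
    out$n_seen[k] <- state$n_seen
    out$warm_up[k] <- is_warm_up(state)
  }
  attr(out, "state") <- state
  out
}

#' Standard deviation of inter-beat intervals (SDNN)
#'
#' The classical time-domain HRV index: the population (divide-by-n)
#' standard deviation of the valid intervals.
#'
#' @param ibis an [ibi_series].
#' @return SDNN in ms.
#' @export
sdnn <- function(ibis) {
  stopifnot(inherits(ibis, "ibi_series"))
  v <- ibis$ibis_ms[ibis$valid]
  if (length(v) < 2L)
    stop("SDNN needs at least 2 valid intervals", call. = FALSE)
  sqrt(mean((v - mean(v))^2))
}

#' Interval errors of detected beats against ground truth
#'
#' Matches each detected beat to its nearest ground-truth beat within
#' `tol_s`, then compares the interval between consecutive matched
#' detections against the interval between the corresponding consecutive
#' ground-truth beats. Constant detection latency cancels; only interval
#' jitter, missed and spurious beats contribute.
#'
#' @param detected detected beat times, seconds.
#' @param truth ground-truth beat times, seconds.
#' @param tol_s matching tolerance (default 0.15 s).
#' @return A list: `errors_ms` (absolute interval errors for consecutive
#'   matched pairs), `n_matched`, `n_detected`, `n_truth`, `coverage`
#'   (fraction of truth beats with a detection within `tol_s`).
#' @export
ibi_error <- function(detected, truth, tol_s = 0.15) {
  if (!length(detected) || !length(truth))
    return(list(errors_ms = numeric(0), n_matched = 0L,
                n_detected = length(detected), n_truth = length(truth),
                coverage = 0))
  j <- vapply(detected, function(b) {
    k <- which.min(abs(truth - b))
    if (length(k) && abs(truth[k] - b) <= tol_s) k else NA_integer_
  }, integer(1))
  ok <- !is.na(j)
  d <- detected[ok]; j <- j[ok]
  errs <- numeric(0)
  if (length(d) > 1L) {
    consec <- diff(j) == 1L
    errs <- abs(diff(d)[consec] - diff(truth)[j[-length(j)][consec]]) * 1000
  }
  cov <- mean(vapply(truth, function(b) min(abs(detected - b)) <= tol_s,
                     logical(1)))
  list(errors_ms = errs, n_matched = sum(ok), n_detected = length(detected),
       n_truth = length(truth), coverage = cov)
}

# ---- per-user calibration ----------------------------------------------

#' Per-user HRV calibration range
#'
#' @param hrv_min_ms minimum HRV (post-exercise SDNN) in ms.
#' @param hrv_max_ms maximum HRV (relaxed slow-breathing SDNN) in ms.
#' @return An object of class `calibration_range`.
#' @export
calibration_range <- function(hrv_min_ms, hrv_max_ms) {
  if (hrv_min_ms < 0) stop("hrv_min_ms must be >= 0", call. = FALSE)
  if (hrv_max_ms <= hrv_min_ms)
    stop("calibration failed: hrv_max must exceed hrv_min", call. = FALSE)
  structure(list(hrv_min_ms = hrv_min_ms, hrv_max_ms = hrv_max_ms),
            class = "calibration_range")
}

#' @export
print.calibration_range <- function(x, ...) {
  cat("<calibration_range> HRV ", round(x$hrv_min_ms, 2), " - ",
      round(x$hrv_max_ms, 2), " ms\n", sep = "")
  invisible(x)
}

#' Calibrate a user's HRV range from the two-phase protocol
#'
#' The user first relaxes with slow breathing for one minute (maximal HRV),
#' then performs one minute of physical exercise; the SDNN of the following
#' minute gives the minimal HRV. The resulting range is later mapped onto
#' the light parameters.
#'
#' @param relax_ibis [ibi_series] from the relaxed slow-breathing minute.
#' @param exercise_ibis [ibi_series] from the post-exercise minute.
#' @param min_span_s minimum span of valid intervals required per phase.
#' @return A [calibration_range]. An inverted range (relax SDNN not above
#'   post-exercise SDNN) is a calibration-failed error: the protocol run is
#'   unusable.
#' @export
calibrate_range <- function(relax_ibis, exercise_ibis, min_span_s = 60) {
  for (s in list(relax_ibis, exercise_ibis)) {
    stopifnot(inherits(s, "ibi_series"))
    if (sum(s$ibis_ms[s$valid]) / 1000 < min_span_s)
      stop("each calibration phase must span >= ", min_span_s,
           " s of valid intervals", call. = FALSE)
  }
  hi <- sdnn(relax_ibis)
  lo <- sdnn(exercise_ibis)
  if (hi <= lo)
    stop("calibration failed: relax-phase SDNN (", round(hi, 2),
         ") does not exceed exercise-phase SDNN (", round(lo, 2), ")",
         call. = FALSE)
  calibration_range(lo, hi)
}

# ---- full pipeline ------------------------------------------------------

#' Full BCG-to-IBI pipeline
#'
#' Composition of [wavelet_denoise()], [moving_mad()], [detect_beats()] and
#' [compute_ibis()] with the windows and gate of `config`. Deterministic.
#'
#' @param raw a [raw_bcg].
#' @param config an [sl_config()].
#' @return An [ibi_series] (empty for a signal with no detectable beats).
#' @export
process_bcg <- function(raw, config = sl_config()) {
  den <- wavelet_denoise(raw, config$wavelet_level, config$wavelet_method)
  env <- moving_mad(den, config$mad_window_ms)
  beats <- detect_beats(env, config$beat_window_ms)
  compute_ibis(beats, config)
}
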