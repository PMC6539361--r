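# Synthetic sensor generators. Every downstream stage is validated against
# these because no raw seat-sensor recordings are distributed: each generator
# returns its ground truth alongside the signal.

local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Synthesize a ballistocardiogram with known beat times
#'
#' Builds a periodic waveform reflecting the mechanical activity of the
#' heart: one damped-oscillation wavelet per beat (a Gaussian-windowed
#' sinusoid, 15 Hz carrier over a 150 ms support, so its energy falls in the
#' 8--16 Hz Haar level-4 detail band at the default 256 Hz rate), plus a
#' low-frequency respiratory sinusoid and additive white Gaussian noise.
#' Beat times are spaced by the instantaneous 60/HR and returned exactly as
#' ground truth.
#'
#' @param duration length in seconds (> 0).
#' @param hr heart rate in bpm: a single number or a function of time (s)
#'   returning bpm; must stay within 30--180.
#' @param resp_rate respiration rate in Hz.
#' @param resp_amp respiration amplitude in signal units (beat wavelets have
#'   unit amplitude).
#' @param noise_sd additive Gaussian noise SD in signal units.
#' @param fs sampling rate in Hz; must be at least 8 times the 15 Hz beat
#'   carrier so the burst band is representable.
#' @param seed RNG seed; identical arguments give bitwise-identical output.
#' @return A list with `bcg` (a [raw_bcg]) and `truth` (class
#'   `bcg_ground_truth`: `beat_times` s, `resp_rate`, `noise_sd`, `seed`).
#' @examples
#' sim <- gen_bcg(10, hr = 60, resp_amp = 0, noise_sd = 0, seed = 7)
#' diff(sim$truth$beat_times)  # all 1.0 s at 60 bpm
#' @export
gen_bcg <- function(duration, hr = 60, resp_rate = 0.25, resp_amp = 0.5,
                    noise_sd = 0.05, fs = 256, seed = 1L) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  carrier <- 15  # Hz, beat wavelet carrier
  if (fs < 8 * carrier)
    stop("fs must be at least ", 8 * carrier,
         " Hz to represent the beat band", call. = FALSE)
  hr_fun <- if (is.function(hr)) hr else function(t) rep(hr, length(t))
  # beat schedule: t_{k+1} = t_k + 60 / HR(t_k)
  beats <- numeric(0)
  t <- 0.3
  while (t < duration) {
    h <- hr_fun(t)[1]
    if (!is.finite(h) || h < 30 || h > 180)
      stop("heart rate must stay within 30-180 bpm (got ", h, ")",
           call. = FALSE)
    beats <- c(beats, t)
    t <- t + 60 / h
  }
  n <- as.integer(round(duration * fs))
  tt <- (seq_len(n) - 1) / fs
  support <- 0.150                 # s, wavelet support
  sigma <- support / 6             # Gaussian window SD
  sig <- numeric(n)
  half <- as.integer(ceiling(support / 2 * fs))
  for (tb in beats) {
    c0 <- as.integer(round(tb * fs)) + 1L
    idx <- max(1L, c0 - half):min(n, c0 + half)
    dt <- tt[idx] - tb
    sig[idx] <- sig[idx] + exp(-dt^2 / (2 * sigma^2)) * sin(2 * pi * carrier * dt)
  }
  if (resp_amp != 0)
    sig <- sig + resp_amp * sin(2 * pi * resp_rate * tt)
  if (noise_sd > 0)
    sig <- sig + local_seed(seed, stats::rnorm(n, 0, noise_sd))
  truth <- structure(list(beat_times = beats, resp_rate = resp_rate,
                          noise_sd = noise_sd, seed = as.integer(seed)),
                     class = "bcg_ground_truth")
  list(bcg = raw_bcg(sig, fs), truth = truth)
}

#' Synthesize a breathing-modulated inter-beat interval stream
#'
#' Emulates respiratory sinus arrhythmia: intervals oscillate around a base
#' value with a sinusoid at the breathing rate (shorter on inhalation, longer
#' on exhalation) plus optional Gaussian jitter. This is the input that
#' drives HRV-biofeedback rendering.
#'
#' @param duration stream length in seconds.
#' @param base_ibi base interval in ms (recommended within the 550--1150 ms
#'   display range).
#' @param rsa_depth oscillation amplitude in ms (>= 0).
#' @param breath_rate breathing rate in Hz.
#' @param noise_sd interval jitter SD in ms.
#' @param seed RNG seed.
#' @return An [ibi_series] with all intervals flagged valid.
#' @export
gen_ibi_stream <- function(duration, base_ibi = 850, rsa_depth = 100,
                           breath_rate = 0.1, noise_sd = 0, seed = 1L) {
  if (!is.numeric(base_ibi) || base_ibi <= 0)
    stop("base_ibi must be positive", call. = FALSE)
  if (rsa_depth < 0) stop("rsa_depth must be >= 0", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  local_seed(seed, {
    times <- 0
    ibis <- numeric(0)
    t <- 0
    while (t < duration) {
      ibi <- base_ibi + rsa_depth * sin(2 * pi * breath_rate * t)
      if (noise_sd > 0) ibi <- ibi + stats::rnorm(1, 0, noise_sd)
      ibi <- max(ibi, 1)
      ibis <- c(ibis, ibi)
      t <- t + ibi / 1000
      times <- c(times, t)
    }
    ibi_series(times)
  })
}

# ---- posture archetypes -------------------------------------------------

#' Built-in sitting-posture archetypes
#'
#' Seven hand-designed mean pressure patterns over the six seat sensors.
#' Channels f1--f3 are the left triplet (front, mid, rear) and f4--f6 the
#' right triplet, mirroring the symmetric left/right sensor layout of the
#' seat pad. `lean_left` loads the left triplet more than the right (and
#' symmetrically for `lean_right`); `empty` stays below the occupancy
#' threshold.
#'
#' @return Named list of archetypes, each with `label`, `mean` (6 nonnegative
#'   sensor-unit values) and default `spread` (per-channel noise SD).
#' @export
posture_archetypes <- function() {
  means <- list(
    upright      = c(60, 60, 60, 60, 60, 60),
    lean_left    = c(85, 85, 85, 25, 25, 25),
    lean_right   = c(25, 25, 25, 85, 85, 85),
    lean_forward = c(90, 60, 25, 90, 60, 25),
    slouch_back  = c(25, 60, 90, 25, 60, 90),
    edge_sit     = c(95, 20,  2, 95, 20,  2),
    empty        = c( 1,  1,  1,  1,  1,  1)
  )
  sp <- archetype_spread()
  lapply(names(means), function(nm)
    # an unloaded seat reads near zero with only the sensor noise floor
    structure(list(label = nm, mean = means[[nm]],
                   spread = if (nm == "empty") 2 else sp),
              class = "posture_archetype")) |>
    stats::setNames(names(means))
}

#' Per-channel noise spread as a fraction of the mean archetype separation
#'
#' The reference spread for generator defaults: `frac` times the mean
#' pairwise Euclidean distance between the archetype mean vectors.
#'
#' @param frac fraction of the mean separation (default 0.10).
#' @return Per-channel SD in sensor units.
#' @export
archetype_spread <- function(frac = 0.10) {
  means <- list(
    c(60, 60, 60, 60, 60, 60), c(85, 85, 85, 25, 25, 25),
    c(25, 25, 25, 85, 85, 85), c(90, 60, 25, 90, 60, 25),
    c(25, 60, 90, 25, 60, 90), c(95, 20, 2, 95, 20, 2),
    c(1, 1, 1, 1, 1, 1))
  frac * mean(stats::dist(do.call(rbind, means)))
}

#' Generate labelled pressure frames from a posture archetype
#'
#' Frames are the archetype mean plus independent per-channel Gaussian
#' noise, clipped at zero (a force sensor cannot read negative pressure).
#'
#' @param archetype an archetype name (see [posture_archetypes()]) or an
#'   archetype object.
#' @param n_frames number of frames (>= 1).
#' @param seed RNG seed.
#' @param spread per-channel noise SD; defaults to the archetype's own.
#' @param rate_hz frame rate used for the time stamps.
#' @param t0 time of the first frame in seconds.
#' @return Data frame with `time_s`, `f1`..`f6`, `label`.
#' @export
gen_pressure <- function(archetype, n_frames, seed = 1L, spread = NULL,
                         rate_hz = 10, t0 = 0) {
  if (is.character(archetype)) {
    all_a <- posture_archetypes()
    if (!archetype %in% names(all_a))
      stop("unknown archetype: ", archetype, call. = FALSE)
    archetype <- all_a[[archetype]]
  }
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (is.null(spread)) spread <- archetype$spread
  if (any(spread < 0)) stop("spread must be nonnegative", call. = FALSE)
  x <- local_seed(seed, {
    m <- matrix(stats::rnorm(n_frames * 6L, mean = rep(archetype$mean,
                                                       each = n_frames),
                             sd = spread), ncol = 6L)
    pmax(m, 0)
  })
  df <- as.data.frame(x)
  names(df) <- paste0("f", 1:6)
  cbind(data.frame(time_s = t0 + (seq_len(n_frames) - 1) / rate_hz),
        df, data.frame(label = archetype$label))
}

#' Generate a labelled multi-archetype training set
#'
#' Convenience wrapper drawing `n_per_class` frames from every archetype
#' (one derived sub-seed per class).
#'
#' @param n_per_class frames per archetype.
#' @param seed RNG seed.
#' @param spread shared per-channel SD; defaults to [archetype_spread()].
#' @return Data frame with `time_s`, `f1`..`f6`, `label`.
#' @export
gen_pressure_set <- function(n_per_class = 200, seed = 1L, spread = NULL) {
  arch <- posture_archetypes()
  out <- lapply(seq_along(arch), function(i)
    gen_pressure(arch[[i]], n_per_class, seed = seed * 131L + i,
                 spread = spread))
  do.call(rbind, out)
}

# ---- session scripts ----------------------------------------------------

upright_segment <- function(from_s, to_s, seed, rate_hz = 10,
                            expected = "ambient") {
  n <- as.integer(round((to_s - from_s) * rate_hz))
  df <- gen_pressure("upright", n, seed = seed, rate_hz = rate_hz,
                     t0 = from_s)
  df$expected_mode <- expected
  df
}

# linear blend between upright and a lateral-lean archetype; s in [-1, 1],
# positive = lean right
blend_frames <- function(from_s, shifts, seed, rate_hz = 10,
                         expected = "stretch") {
  arch <- posture_archetypes()
  up <- arch$upright$mean
  sp <- arch$upright$spread * 0.3
  m <- t(vapply(shifts, function(s) {
    lean <- if (s >= 0) arch$lean_right$mean else arch$lean_left$mean
    up * (1 - abs(s)) + lean * abs(s)
  }, numeric(6)))
  noise <- local_seed(seed, matrix(stats::rnorm(length(m), 0, sp),
                                   ncol = 6L))
  df <- as.data.frame(pmax(m + noise, 0))
  names(df) <- paste0("f", 1:6)
  cbind(data.frame(time_s = from_s + (seq_along(shifts) - 1) / rate_hz),
        df,
        data.frame(label = ifelse(abs(shifts) > 0.4,
                                  ifelse(shifts > 0, "lean_right", "lean_left"),
                                  "upright"),
                   expected_mode = expected))
}

#' Generate a scripted closed-loop session
#'
#' Produces a merged timeline of pressure frames (10 Hz) and an IBI stream
#' with ground-truth mode annotations, for driving and checking the
#' end-to-end simulator:
#'
#' * `sedentary_buildup`: 35 min of continuous upright sitting with quiet
#'   heart dynamics; expected mode is the ambient intervention throughout.
#' * `stretch_break`: 60 s sitting, then a lateral weight-shifting exercise
#'   segment (two left/right cycles of ramp--hold--return), then sitting.
#' * `breathing_break`: 60 s sitting with flat intervals, then 120 s of slow
#'   breathing (0.1 Hz respiratory sinus arrhythmia) while sitting still,
#'   then sitting.
#'
#' @param scenario one of `"sedentary_buildup"`, `"stretch_break"`,
#'   `"breathing_break"`.
#' @param seed RNG seed; identical seed gives an identical script.
#' @return A list of class `session_script`: `pressure` (data frame with
#'   `time_s`, `f1`..`f6`, `label`, `expected_mode`), `ibis` (an
#'   [ibi_series]), `events` (data frame `time_s`, `event`), plus `scenario`
#'   and `seed`.
#' @export
gen_session_script <- function(scenario, seed = 1L) {
  rate <- 10
  if (scenario == "sedentary_buildup") {
    dur <- 35 * 60
    pr <- upright_segment(0, dur, seed)
    ib <- gen_ibi_stream(dur, base_ibi = 900, rsa_depth = 15,
                         breath_rate = 0.25, noise_sd = 8, seed = seed + 1L)
    ev <- data.frame(time_s = numeric(0), event = character(0))
  } else if (scenario == "stretch_break") {
    # 0-60 sit; 60-140 two left/right stretch cycles; 140-180 sit
    ramp <- function(sgn) c(seq(0, sgn * 0.8, length.out = 40),  # 4 s ramp
                            rep(sgn * 0.8, 50),                  # 5 s hold
                            seq(sgn * 0.8, 0, length.out = 20))  # 2 s return
    cyc <- c(ramp(-1), ramp(1))                                  # left then right
    shifts <- c(cyc, cyc)                                        # 2 reps, 44 s
    pr <- rbind(
      upright_segment(0, 60, seed),
      blend_frames(60, shifts, seed + 2L),
      upright_segment(60 + length(shifts) / rate, 180, seed + 3L))
    ib <- gen_ibi_stream(180, base_ibi = 850, rsa_depth = 10,
                         breath_rate = 0.25, noise_sd = 5, seed = seed + 1L)
    ev <- data.frame(time_s = 60 + length(shifts) / rate,
                     event = "exercise_end")
  } else if (scenario == "breathing_break") {
    pr <- rbind(upright_segment(0, 60, seed),
                upright_segment(60, 180, seed + 2L, expected = "breathing"),
                upright_segment(180, 210, seed + 3L))
    ib_flat <- gen_ibi_stream(60, base_ibi = 850, rsa_depth = 5,
                              breath_rate = 0.25, noise_sd = 2,
                              seed = seed + 1L)
    ib_slow <- gen_ibi_stream(150, base_ibi = 850, rsa_depth = 120,
                              breath_rate = 0.1, noise_sd = 5,
                              seed = seed + 4L)
    t_off <- max(ib_flat$beat_times)
    ib <- ibi_series(c(ib_flat$beat_times, t_off + ib_slow$beat_times[-1L]))
    ev <- data.frame(time_s = 180, event = "exercise_end")
  } else {
    stop("unknown scenario: ", scenario, call. = FALSE)
  }
  structure(list(pressure = pr, ibis = ib, events = ev,
                 scenario = scenario, seed = as.integer(seed)),
            class = "session_script")
}

#' @export
print.session_script <- function(x, ...) {
  cat("<session_script> '", x$scenario, "': ", nrow(x$pressure),
      " pressure frames over ", round(max(x$pressure$time_s), 1), " s, ",
      length(x$ibis$ibis_ms), " intervals, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
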