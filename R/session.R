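# Closed-loop simulation: feeds a scripted timeline of pressure frames and
# heartbeats through occupancy tracking, the sedentary clock, the HRV
# recursion and microbreak detection, dispatching each tick to the proper
# light renderer.

#' Run a scripted session through the full mode state machine
#'
#' Iterates the script's 10 Hz pressure timeline. Per tick the simulator
#' updates occupancy and the sedentary clock, consumes any heartbeats that
#' occurred since the last tick into the HRV recursion, and runs the mode
#' machine: in ambient mode it renders the intervention mapping and polls
#' [detect_exercise_start()] (at 2 Hz) over the trailing 5 s of frames; a
#' detected stretch start opens a [stretch_session()] driven by the live
#' lateral-shift index; a detected breathing start switches to biofeedback
#' rendering of the latest interval. An exercise ends on the script's
#' `exercise_end` event or when the stretch rep target is met; completion
#' resets the sedentary clock, so the display falls back to its
#' almost-invisible resting state.
#'
#' @param script a [gen_session_script()] result.
#' @param calibration a [calibration_range].
#' @param model optional trained [ann_model] used to attach posture labels
#'   to the timeline (classification does not gate the mode machine, which
#'   works off the lateral-shift index and HRV slope).
#' @param config an [sl_config()].
#' @param keep_frames keep every rendered [light_frame] (list column
#'   `frame`); disable for long scripts to save memory.
#' @return A data frame of class `session_timeline`: `time_s`, `mode`,
#'   `hue`, `sat`, `bri`, `seated_min`, `hrv40`, `posture` (if a model was
#'   given) and optionally `frame`.
#' @export
run_session <- function(script, calibration, model = NULL,
                        config = sl_config(), keep_frames = FALSE) {
  stopifnot(inherits(script, "session_script"))
  if (is.null(calibration))
    stop("calibration required to run a session", call. = FALSE)
  pr <- script$pressure
  n <- nrow(pr)
  dt <- if (n > 1L) stats::median(diff(pr$time_s)) else 0.1
  beats <- script$ibis
  clock <- sedentary_clock()
  hstate <- hrv_state(window = config$hrv_window_beats)
  mode <- "ambient"
  stretch <- NULL
  last_end_t <- -Inf
  beat_ptr <- 1L
  last_ibi <- config$biofeedback_ibi_lo_ms
  detect_every <- max(1L, as.integer(round(0.5 / dt)))
  win_n <- as.integer(ceiling(5 / dt)) + 1L
  hrv_t <- numeric(0); hrv_v <- numeric(0)
  posture_lab <- if (!is.null(model)) classify(model, pr)$label else NULL

  out_mode <- character(n); out_hue <- numeric(n)
  out_sat <- numeric(n); out_bri <- numeric(n)
  out_seated <- numeric(n); out_hrv <- numeric(n)
  frames <- if (keep_frames) vector("list", n) else NULL

  n_ibi <- length(beats$ibis_ms)
  for (k in seq_len(n)) {
    t <- pr$time_s[k]
    frame_k <- as.numeric(pr[k, paste0("f", 1:6)])
    occ <- occupancy(frame_k, config$occupancy_threshold)
    # consume heartbeats up to t
    while (beat_ptr <= n_ibi && beats$beat_times[beat_ptr + 1L] <= t) {
      hstate <- update_hrv(hstate, beats$ibis_ms[beat_ptr],
                           beats$valid[beat_ptr])
      if (beats$valid[beat_ptr]) {
        last_ibi <- beats$ibis_ms[beat_ptr]
        if (!is_warm_up(hstate)) {   # warm-up estimates would mimic a rise
          hrv_t <- c(hrv_t, beats$beat_times[beat_ptr + 1L])
          hrv_v <- c(hrv_v, hstate$hrv40)
        }
      }
      beat_ptr <- beat_ptr + 1L
    }
    exercise_done <- FALSE
    ended_by_script <- nrow(script$events) > 0L &&
      any(script$events$event == "exercise_end" & script$events$time_s <= t)

    if (mode == "stretch") {
      res <- stretch_step(stretch, lateral_shift_index(frame_k), dt, config)
      stretch <- res$session
      lf <- res$frame
      if (ended_by_script || stretch$reps_done >= config$stretch_reps) {
        mode <- "ambient"; stretch <- NULL; exercise_done <- TRUE
        last_end_t <- t
      }
    } else if (mode == "breathing") {
      lf <- biofeedback_frame(last_ibi, hstate$hrv40, calibration,
                              config$hue_biofeedback, config)
      if (ended_by_script) {
        mode <- "ambient"; exercise_done <- TRUE
        last_end_t <- t
      }
    } else {
      lf <- NULL
    }
    # tick k covers (t[k-1], t[k]]; the first frame opens the session
    if (k > 1L || exercise_done)
      clock <- update_sedentary(clock, occ, dt, exercise_done,
                                config$unoccupied_reset_s)

    if (mode == "ambient") {
      if (k %% detect_every == 0L && k >= win_n && !ended_by_script &&
          t - last_end_t >= config$exercise_cooldown_s) {
        recent <- pr[(k - win_n + 1L):k, ]
        htr <- if (length(hrv_t))
          data.frame(beat_time_s = hrv_t, hrv40 = hrv_v) else NULL
        started <- detect_exercise_start(recent, htr, calibration, config)
        if (started == "stretch") {
          mode <- "stretch"
          stretch <- stretch_session(seed = script$seed)
        } else if (started == "breathing") {
          mode <- "breathing"
        }
      }
      if (is.null(lf) || exercise_done)
        lf <- intervention_frame(clock$seated_minutes,
                                 if (hstate$n_seen > 0) hstate$hrv40
                                 else calibration$hrv_max_ms,
                                 calibration, config)
    }
    out_mode[k] <- if (!is.null(lf) && lf$mode_tag != "intervention")
      lf$mode_tag else "ambient"
    out_hue[k] <- lf$hsb[["hue"]]; out_sat[k] <- lf$hsb[["sat"]]
    out_bri[k] <- lf$hsb[["bri"]]
    out_seated[k] <- clock$seated_minutes
    out_hrv[k] <- if (hstate$n_seen > 0) hstate$hrv40 else NA_real_
    if (keep_frames) frames[[k]] <- lf
  }
  out <- data.frame(time_s = pr$time_s, mode = out_mode, hue = out_hue,
                    sat = out_sat, bri = out_bri, seated_min = out_seated,
                    hrv40 = out_hrv)
  if (!is.null(posture_lab)) out$posture <- posture_lab
  if (keep_frames) out$frame <- I(frames)
  class(out) <- c("session_timeline", class(out))
  out
}

#' @export
print.session_timeline <- function(x, ...) {
  r <- rle(x$mode)
  cat("<session_timeline> ", nrow(x), " ticks over ",
      round(max(x$time_s), 1), " s; mode sequence: ",
      paste(r$values, collapse = " -> "), "\n", sep = "")
  invisible(x)
}
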