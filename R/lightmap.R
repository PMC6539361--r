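# Ambient-display rendering: affine signal-to-light mappings for the three
# modes, HSB colour handling, and the stretch-guidance state machine driving
# the 28-LED strip.

#' Clamped affine range mapping
#'
#' Maps `x` affinely from `[src_lo, src_hi]` onto `[dst_lo, dst_hi]` and
#' clamps the result to the destination range. An inverted source
#' (`src_lo > src_hi`) is supported and realises the "maximum-to-minimum"
#' mappings (e.g. high HRV onto low saturation).
#'
#' @param x input value(s).
#' @param src_lo,src_hi source range endpoints (must differ).
#' @param dst_lo,dst_hi destination range endpoints.
#' @return Mapped value(s), clamped to the destination range.
#' @examples
#' linmap(1150, 550, 1150, 10, 255)  # 255
#' linmap(850, 550, 1150, 10, 255)   # 132.5
#' @export
linmap <- function(x, src_lo, src_hi, dst_lo, dst_hi) {
  if (src_lo == src_hi)
    stop("source range endpoints must differ", call. = FALSE)
  y <- dst_lo + (x - src_lo) * (dst_hi - dst_lo) / (src_hi - src_lo)
  pmin(pmax(y, min(dst_lo, dst_hi)), max(dst_lo, dst_hi))
}

#' Convert HSB control values to an 8-bit RGB triple
#'
#' Standard HSV conversion with hue in degrees and saturation/brightness on
#' the LED-native 0--255 scale (rescaled internally to 0--1); exact at the
#' colour-wheel corners.
#'
#' @param hue degrees in \[0, 360\] (360 wraps to 0).
#' @param sat,bri saturation and brightness in \[0, 255\].
#' @return Integer vector `c(r, g, b)`, each 0--255.
#' @export
hsb_to_rgb <- function(hue, sat, bri) {
  if (!is.finite(hue) || hue < 0 || hue > 360)
    stop("hue must lie in [0, 360]", call. = FALSE)
  if (sat < 0 || sat > 255 || bri < 0 || bri > 255)
    stop("saturation and brightness must lie in [0, 255]", call. = FALSE)
  col <- grDevices::hsv((hue %% 360) / 360, sat / 255, bri / 255)
  as.integer(grDevices::col2rgb(col)[, 1L])
}

#' One rendered frame of the 28-LED ambient strip
#'
#' @param hue,sat,bri HSB control values (hue degrees, sat/bri 0--255; may be
#'   fractional, LED channels are rounded at conversion).
#' @param mode_tag name of the producing mode.
#' @param leds optional 28 x 3 integer matrix of per-LED RGB values; by
#'   default all LEDs share the HSB colour.
#' @param n_leds strip length (28).
#' @return An object of class `light_frame` with `leds`, `hsb`, `mode_tag`.
#' @export
light_frame <- function(hue, sat, bri, mode_tag = "ambient", leds = NULL,
                        n_leds = 28L) {
  if (is.null(leds)) {
    rgb <- hsb_to_rgb(hue, round(sat), round(bri))
    leds <- matrix(rgb, n_leds, 3L, byrow = TRUE)
  }
  leds <- as.matrix(leds)
  if (nrow(leds) != n_leds || ncol(leds) != 3L)
    stop("a frame must carry exactly ", n_leds, " RGB triples",
         call. = FALSE)
  if (any(leds < 0) || any(leds > 255))
    stop("LED channels must lie in 0-255", call. = FALSE)
  structure(list(leds = leds,
                 hsb = c(hue = hue, sat = sat, bri = bri),
                 mode_tag = mode_tag),
            class = "light_frame")
}

#' @export
print.light_frame <- function(x, ...) {
  cat("<light_frame> [", x$mode_tag, "] hue ", round(x$hsb[["hue"]]),
      " deg, sat ", round(x$hsb[["sat"]], 1), ", bri ",
      round(x$hsb[["bri"]], 1), "; ", nrow(x$leds), " LEDs\n", sep = "")
  invisible(x)
}

#' Ambient intervention frame
#'
#' The always-on nudge display: accumulated sitting time from 10 to 30 min
#' maps onto brightness 10--255, and the running HRV from the user's
#' calibrated maximum down to the minimum maps onto saturation 10--255 --
#' so a long-seated, high-stress (low HRV) state renders as a bright,
#' saturated orange, while a recently rested, relaxed state is almost
#' invisible.
#'
#' @param seated_minutes accumulated continuous sitting in minutes.
#' @param hrv40 running HRV estimate in ms.
#' @param calibration a [calibration_range] (required).
#' @param config an [sl_config()].
#' @return A uniform orange [light_frame].
#' @export
intervention_frame <- function(seated_minutes, hrv40, calibration,
                               config = sl_config()) {
  if (is.null(calibration))
    stop("calibration required for the intervention mapping", call. = FALSE)
  bri <- linmap(seated_minutes, config$sedentary_min_min,
                config$sedentary_max_min,
                config$brightness_lo, config$brightness_hi)
  sat <- linmap(hrv40, calibration$hrv_max_ms, calibration$hrv_min_ms,
                config$intervention_sat_lo, config$intervention_sat_hi)
  light_frame(config$hue_intervention, sat, bri, "intervention",
              n_leds = config$n_leds)
}

#' Breathing-biofeedback frame
#'
#' During slow-breathing microbreaks the light breathes with the user: the
#' current inter-beat interval from 550 to 1150 ms maps onto brightness
#' 10--255 (bright at long intervals, i.e. inhalation-to-exhalation swing of
#' respiratory sinus arrhythmia), and the running HRV from the calibrated
#' minimum to maximum maps onto saturation 10--250, so a highly saturated
#' colour signals improved HRV. Note the 250 saturation ceiling, deliberately
#' different from the intervention mode's 255.
#'
#' @param ibi_ms current valid inter-beat interval in ms.
#' @param hrv40 running HRV estimate in ms.
#' @param calibration a [calibration_range] (required).
#' @param base_hue the user-chosen relaxation colour, degrees.
#' @param config an [sl_config()].
#' @return A uniform [light_frame] in the user's colour.
#' @export
biofeedback_frame <- function(ibi_ms, hrv40, calibration,
                              base_hue = sl_config()$hue_biofeedback,
                              config = sl_config()) {
  if (is.null(calibration))
    stop("calibration required for the biofeedback mapping", call. = FALSE)
  bri <- linmap(ibi_ms, config$biofeedback_ibi_lo_ms,
                config$biofeedback_ibi_hi_ms,
                config$brightness_lo, config$brightness_hi)
  sat <- linmap(hrv40, calibration$hrv_min_ms, calibration$hrv_max_ms,
                config$biofeedback_sat_lo, config$biofeedback_sat_hi)
  light_frame(base_hue, sat, bri, "breathing", n_leds = config$n_leds)
}

# ---- stretch guidance state machine ------------------------------------

#' Initialise a stretch-guidance session
#'
#' The guided lower-back stretch alternates lateral trunk leans: a wipe
#' animation cues the target side, the colour morphs from blue to green as
#' the user shifts weight toward it, a sparkle pattern rewards reaching the
#' target, and after a few seconds' hold the cue switches to the opposite
#' side.
#'
#' @param seed RNG seed for the sparkle pattern.
#' @param start_side first cued side (`"left"` or `"right"`).
#' @return An object of class `stretch_session`: `phase` (one of `cue_left`,
#'   `cue_right`, `moving`, `hold`, `switch`), `target_side`, `hold_elapsed`,
#'   `reps_done`, `rng_seed`, plus internal phase timing.
#' @export
stretch_session <- function(seed = 1L, start_side = "left") {
  stopifnot(start_side %in% c("left", "right"))
  structure(list(phase = paste0("cue_", start_side),
                 target_side = start_side, start_side = start_side,
                 hold_elapsed = 0, reps_done = 0L,
                 rng_seed = as.integer(seed),
                 phase_elapsed = 0, tick = 0L,
                 sparkle_bri = rep(255, 28L)),
            class = "stretch_session")
}

#' @export
print.stretch_session <- function(x, ...) {
  cat("<stretch_session> phase ", x$phase, ", target ", x$target_side,
      ", reps ", x$reps_done, "\n", sep = "")
  invisible(x)
}

render_wipe <- function(session, config) {
  n <- config$n_leds
  seg <- config$wipe_segment_leds
  span <- n + seg
  pos <- (session$phase_elapsed * config$wipe_speed_led_s) %% span
  # segment trails the travelling head; LED 1 is the left end of the strip
  idx <- floor(pos) - seq_len(seg) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  if (session$target_side == "left") idx <- n + 1L - idx
  on <- rep(FALSE, n)
  on[idx] <- TRUE
  hue <- config$hue_stretch_blue
  dim_rgb <- hsb_to_rgb(hue, 255, 25)
  lit_rgb <- hsb_to_rgb(hue, 255, 255)
  leds <- matrix(dim_rgb, n, 3L, byrow = TRUE)
  if (any(on)) leds[on, ] <- matrix(lit_rgb, sum(on), 3L, byrow = TRUE)
  light_frame(hue, 255, 255, "stretch", leds = leds, n_leds = n)
}

render_sparkle <- function(session, config) {
  n <- config$n_leds
  hue <- config$hue_stretch_green
  bri <- session$sparkle_bri
  leds <- t(vapply(seq_len(n),
                   function(i) hsb_to_rgb(hue, 255, round(bri[i])),
                   integer(3)))
  light_frame(hue, 255, max(bri), "stretch", leds = leds, n_leds = n)
}

#' Advance the stretch-guidance state machine by one tick
#'
#' Phase cycle per side: `cue_*` (wipe animation toward the target side)
#' -> `moving` once the user starts shifting (hue interpolates blue to green
#' with progress toward the lateral-shift threshold) -> `hold` at/above the
#' threshold (seeded per-LED sparkle; progress pauses if the user backs off)
#' -> after `hold_duration_s`, `switch`: the target side flips, the colour
#' resets to blue, and `reps_done` increments once per completed left/right
#' cycle.
#'
#' @param session a [stretch_session()].
#' @param lateral_shift signed weight-shift index in \[-1, 1\]
#'   ([lateral_shift_index()]): positive = right.
#' @param dt tick duration in seconds (> 0).
#' @param config an [sl_config()].
#' @return List with the updated `session` and the rendered `frame`.
#' @export
stretch_step <- function(session, lateral_shift, dt,
                         config = sl_config()) {
  stopifnot(inherits(session, "stretch_session"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (!is.finite(lateral_shift) || abs(lateral_shift) > 1)
    stop("lateral_shift must lie in [-1, 1]", call. = FALSE)
  thr <- config$lateral_shift_threshold
  toward <- if (session$target_side == "right") lateral_shift
            else -lateral_shift
  toward <- max(0, toward)
  progress <- min(toward / thr, 1)
  session$tick <- session$tick + 1L
  session$phase_elapsed <- session$phase_elapsed + dt

  if (session$phase == "switch") {
    session$phase <- paste0("cue_", session$target_side)
    session$phase_elapsed <- 0
  }

  if (session$phase %in% c("cue_left", "cue_right")) {
    if (toward > 0.05) {
      session$phase <- "moving"
      session$phase_elapsed <- 0
    } else {
      return(list(session = session, frame = render_wipe(session, config)))
    }
  }

  if (session$phase == "moving") {
    if (progress >= 1) {
      session$phase <- "hold"
      session$hold_elapsed <- 0
      session$sparkle_bri <- sparkle_update(rep(255, config$n_leds),
                                            session, config, init = TRUE)
    } else {
      hue <- config$hue_stretch_blue +
        (config$hue_stretch_green - config$hue_stretch_blue) * progress
      return(list(session = session,
                  frame = light_frame(hue, 255, 255, "stretch",
                                      n_leds = config$n_leds)))
    }
  }

  if (session$phase == "hold") {
    if (toward < 0.8 * thr) {            # backed off before completing
      session$phase <- "moving"
      session$hold_elapsed <- 0
      return(stretch_step_rerender(session, progress, config))
    }
    session$hold_elapsed <- session$hold_elapsed + dt
    session$sparkle_bri <- sparkle_update(session$sparkle_bri, session,
                                          config)
    frame <- render_sparkle(session, config)
    if (session$hold_elapsed >= config$hold_duration_s) {
      completed <- session$target_side
      session$phase <- "switch"
      session$target_side <- if (completed == "left") "right" else "left"
      session$hold_elapsed <- 0
      session$phase_elapsed <- 0
      if (session$target_side == session$start_side)
        session$reps_done <- session$reps_done + 1L
      frame <- light_frame(config$hue_stretch_blue, 255, 255, "stretch",
                           n_leds = config$n_leds)
    }
    return(list(session = session, frame = frame))
  }

  list(session = session, frame = render_wipe(session, config))
}

stretch_step_rerender <- function(session, progress, config) {
  hue <- config$hue_stretch_blue +
    (config$hue_stretch_green - config$hue_stretch_blue) * progress
  list(session = session,
       frame = light_frame(hue, 255, 255, "stretch", n_leds = config$n_leds))
}

# seeded per-LED brightness jitter: a fraction of LEDs re-randomised per
# tick, reproducible from (rng_seed, tick)
sparkle_update <- function(bri, session, config, init = FALSE) {
  n <- config$n_leds
  local_seed((session$rng_seed + 1009L * session$tick) %%
               .Machine$integer.max, {
    if (init) bri <- stats::runif(n, 120, 255)
    k <- max(1L, round(config$sparkle_frac * n))
    idx <- sample.int(n, k)
    bri[idx] <- stats::runif(k, 60, 255)
    bri
  })
}
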