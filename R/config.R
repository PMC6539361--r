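#' Default processing and mapping configuration
#'
#' Central registry of every tunable constant in the pipeline: sampling and
#' window parameters for beat detection, the IBI validity gate, the recursive
#' HRV window, the light-mapping ranges for the three display modes, hue
#' coordinates, and the behavioural thresholds of the mode state machine.
#'
#' The mapping ranges default to the published design values: sedentary time
#' 10--30 min onto brightness 10--255, the calibrated HRV range onto
#' intervention saturation 10--255 (inverted), IBI 550--1150 ms onto
#' biofeedback brightness 10--255, and HRV onto biofeedback saturation
#' 10--250. The 250 vs 255 saturation ceiling asymmetry between the two modes
#' is intentional and preserved.
#'
#' @param ... named overrides of any default field. Unknown names are an
#'   error, which guards against silently ignored typos.
#' @return A validated list of class `sl_config`.
#' @examples
#' cfg <- sl_config()
#' cfg$beat_window_ms
#' sl_config(fs = 128, mad_window_ms = 250)$fs
#' @export
sl_config <- function(...) {
  cfg <- list(
    # signal processing
    fs                      = 256,    # Hz, BCG sampling rate
    wavelet_level           = 4L,     # Haar detail level kept as denoised band
    wavelet_method          = "swt",  # undecimated (shift-invariant) by default
    mad_window_ms           = 100,    # moving-MAD envelope window; must stay
                                      # shorter than the ~150 ms beat complex
                                      # or the envelope top goes flat
    beat_window_ms          = 400,    # moving-maximum beat detection window
    ibi_gate_lo_ms          = 300,    # physiological gate: 40-200 bpm
    ibi_gate_hi_ms          = 1500,
    ibi_gate_rel_jump       = 0.30,   # max fractional jump vs previous valid IBI
    hrv_window_beats        = 40L,    # recursion window; warm-up until n_seen >= this
    # light mappings (printed design ranges)
    sedentary_min_min       = 10,
    sedentary_max_min       = 30,
    brightness_lo           = 10,
    brightness_hi           = 255,
    intervention_sat_lo     = 10,
    intervention_sat_hi     = 255,
    biofeedback_ibi_lo_ms   = 550,
    biofeedback_ibi_hi_ms   = 1150,
    biofeedback_sat_lo      = 10,
    biofeedback_sat_hi      = 250,
    # hues (degrees)
    hue_intervention        = 30,     # orange
    hue_stretch_blue        = 240,
    hue_stretch_green       = 120,
    hue_biofeedback         = 200,    # default user colour, calm blue-cyan
    # behaviour thresholds
    occupancy_threshold     = 72,     # sensor units, ~20% of an upright total load
    lateral_shift_threshold = 0.35,   # |L-R|/(L+R) to count as a stretch target
    stretch_enter_s         = 2,      # sustained shift needed to enter stretch mode
    hrv_slope_frac_per_30s  = 0.10,   # HRV40 rise per 30 s as fraction of calibration range
    hold_duration_s         = 3,      # stretch hold on each side
    stretch_reps            = 2L,     # left/right cycles per guided session
    unoccupied_reset_s      = 60,     # standing this long resets the sedentary clock
    exercise_cooldown_s     = 30,     # no re-detection right after a microbreak
    # rendering
    n_leds                  = 28L,
    tick_hz                 = 20,     # light rendering rate
    wipe_speed_led_s        = 14,     # cue segment translation speed
    wipe_segment_leds       = 6L,
    sparkle_frac            = 0.30,   # LEDs re-randomised per sparkle tick
    seed                    = 1L
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("config overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  structure(cfg, class = "sl_config")
}

validate_config <- function(cfg) {
  chk_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config field '", field, "' must be a positive number",
           call. = FALSE)
  }
  for (f in c("fs", "mad_window_ms", "beat_window_ms", "hrv_window_beats",
              "tick_hz", "n_leds", "hold_duration_s", "unoccupied_reset_s",
              "wipe_speed_led_s", "wipe_segment_leds"))
    chk_pos(f)
  if (!cfg$wavelet_method %in% c("swt", "dwt"))
    stop("wavelet_method must be 'swt' or 'dwt'", call. = FALSE)
  if (cfg$ibi_gate_lo_ms >= cfg$ibi_gate_hi_ms)
    stop("IBI gate must satisfy lo < hi", call. = FALSE)
  if (cfg$ibi_gate_rel_jump <= 0)
    stop("ibi_gate_rel_jump must be positive", call. = FALSE)
  if (cfg$sedentary_min_min >= cfg$sedentary_max_min)
    stop("sedentary mapping range must be increasing", call. = FALSE)
  if (cfg$biofeedback_ibi_lo_ms >= cfg$biofeedback_ibi_hi_ms)
    stop("biofeedback IBI mapping range must be increasing", call. = FALSE)
  if (cfg$lateral_shift_threshold <= 0 || cfg$lateral_shift_threshold >= 1)
    stop("lateral_shift_threshold must lie in (0, 1)", call. = FALSE)
  if (cfg$sparkle_frac < 0 || cfg$sparkle_frac > 1)
    stop("sparkle_frac must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Load a configuration file
#'
#' Reads a JSON or YAML file of overrides; unspecified fields take the
#' defaults of [sl_config()]. Unknown keys and out-of-range values are
#' errors.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file. An empty file (or
#'   empty mapping) yields the full default configuration.
#' @return An `sl_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  over <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) NULL else jsonlite::fromJSON(txt)
  }
  if (is.null(over) || length(over) == 0L) return(sl_config())
  do.call(sl_config, over)
}

#' Save a configuration to JSON
#'
#' @param cfg an `sl_config` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sl_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.sl_config <- function(x, ...) {
  cat("<sl_config> ", length(x), " fields; fs=", x$fs, " Hz, beat window ",
      x$beat_window_ms, " ms, HRV window ", x$hrv_window_beats, " beats\n",
      sep = "")
  invisible(x)
}
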