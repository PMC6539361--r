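# File exchange: CSV dialects for signals, JSON for models and calibration,
# JSON-lines for rendered light timelines.

ts_schemas <- list(
  bcg        = list(cols = c("time_s", "value"), time = "time_s"),
  beats      = list(cols = "beat_time_s", time = "beat_time_s"),
  pressure   = list(cols = c("time_s", paste0("f", 1:6)), time = "time_s",
                    optional = c("label", "expected_mode")),
  ibi        = list(cols = c("beat_time_s", "ibi_ms", "valid"),
                    time = "beat_time_s")
)

#' Read a time-series CSV
#'
#' Validates the header against the named schema and requires a strictly
#' increasing time column; malformed rows are reported with their line
#' number.
#'
#' @param path CSV path.
#' @param schema one of `"bcg"` (`time_s,value`), `"beats"`
#'   (`beat_time_s`), `"pressure"` (`time_s,f1..f6[,label]`), `"ibi"`
#'   (`beat_time_s,ibi_ms,valid`).
#' @return A data frame.
#' @export
read_timeseries <- function(path, schema) {
  sc <- ts_schemas[[schema]]
  if (is.null(sc)) stop("unknown schema: ", schema, call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(sc$cols, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in setdiff(sc$cols, c("label", "valid"))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad))
      stop("parse error in ", path, ", column '", col, "', line ",
           bad[1] + 1L, call. = FALSE)
    df[[col]] <- v
  }
  tv <- df[[sc$time]]
  if (length(tv) > 1L && any(diff(tv) <= 0))
    stop("time column '", sc$time, "' must be strictly increasing in ",
         path, call. = FALSE)
  if ("valid" %in% names(df)) df$valid <- as.logical(df$valid)
  df
}

#' Write a time-series CSV
#'
#' Values round-trip losslessly at better than 6 significant digits.
#'
#' @param df data frame (or [raw_bcg] / [ibi_series], converted to their
#'   CSV dialects).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(df, path) {
  if (inherits(df, "raw_bcg")) df <- as.data.frame(df)
  if (inherits(df, "ibi_series"))
    df <- data.frame(beat_time_s = df$beat_times[-1L], ibi_ms = df$ibis_ms,
                     valid = df$valid)
  utils::write.csv(format(df, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an IBI CSV into an [ibi_series]
#'
#' @param path CSV with `beat_time_s,ibi_ms,valid`. Beat times are taken as
#'   authoritative; the implied first beat is reconstructed from the first
#'   interval.
#' @return An [ibi_series].
#' @export
read_ibis <- function(path) {
  df <- read_timeseries(path, "ibi")
  t0 <- df$beat_time_s[1] - df$ibi_ms[1] / 1000
  ibi_series(c(t0, df$beat_time_s), df$valid)
}

#' Save / load a per-user HRV calibration
#'
#' Stored as JSON `{"hrv_min_ms": ..., "hrv_max_ms": ...}`.
#'
#' @param cal a [calibration_range].
#' @param path JSON path.
#' @return `path` / a [calibration_range].
#' @export
save_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_range"))
  jsonlite::write_json(list(hrv_min_ms = cal$hrv_min_ms,
                            hrv_max_ms = cal$hrv_max_ms),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  j <- jsonlite::fromJSON(path)
  calibration_range(j$hrv_min_ms, j$hrv_max_ms)
}

#' Save / load a trained posture network
#'
#' Persists dimensions, ordered class labels, flat weight arrays,
#' per-channel normalisation, activation, seed and the training loss trace
#' as JSON.
#'
#' @param model an [ann_model].
#' @param path JSON path.
#' @return `path` / an [ann_model].
#' @export
save_ann <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  jsonlite::write_json(list(
    n_in = nrow(model$W), n_hidden = ncol(model$W),
    n_out = length(model$labels), labels = model$labels,
    W = as.vector(model$W), b_h = model$b_h,
    W2 = as.vector(model$W2), b_o = model$b_o,
    norm = model$norm, activation = model$activation,
    seed = model$seed, loss_trace = model$loss_trace),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ann
#' @export
load_ann <- function(path) {
  j <- jsonlite::fromJSON(path)
  m <- ann_model(matrix(j$W, j$n_in, j$n_hidden), j$b_h,
                 matrix(j$W2, j$n_hidden, j$n_out), j$b_o,
                 j$labels, j$norm, j$activation)
  m$loss_trace <- j$loss_trace
  m$seed <- j$seed
  m
}

#' Write a rendered timeline as JSON-lines
#'
#' One object per tick: `{t, mode, hue, sat, bri, leds}` with `leds` a
#' 28-element array of `[r, g, b]` triples (present when the timeline kept
#' its frames).
#'
#' @param timeline a `session_timeline` from [run_session()], or any data
#'   frame with `time_s`, `mode`, `hue`, `sat`, `bri` and optionally a
#'   `frame` list column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frames_jsonl <- function(timeline, path) {
  con <- file(path, "w")
  on.exit(close(con))
  has_frames <- !is.null(timeline$frame)
  for (k in seq_len(nrow(timeline))) {
    rec <- list(t = timeline$time_s[k], mode = timeline$mode[k],
                hue = timeline$hue[k], sat = timeline$sat[k],
                bri = timeline$bri[k])
    if (has_frames)
      rec$leds <- unname(split(timeline$frame[[k]]$leds,
                               seq_len(nrow(timeline$frame[[k]]$leds))))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
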