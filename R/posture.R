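# Sitting-posture classification from the six seat pressure channels with a
# three-layer feedforward network trained by Levenberg-Marquardt, plus
# occupancy detection, the sedentary clock, and microbreak-start detection.

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(u) {
  u <- u - apply(u, 1L, max)
  e <- exp(u)
  e / rowSums(e)
}

#' Three-layer feedforward posture network
#'
#' Input layer: the six pressure channels, normalised per channel by stored
#' calibration maxima so the net adapts to a user's weight range. Hidden
#' layer: logistic-sigmoid units. Output layer: softmax over the posture
#' classes, read as class probabilities. The summations are
#' `Z[n] = sum_i W[i,n] * X[i] + b_h[n]` and
#' `Z'[k] = sum_n W2[n,k] * H[n] + b_o[k]`.
#'
#' @param W 6 x n_hidden input weights.
#' @param b_h hidden biases (length n_hidden).
#' @param W2 n_hidden x K hidden-to-output weights.
#' @param b_o output biases (length K).
#' @param labels ordered class names (length K).
#' @param norm per-channel normalisation maxima (length 6).
#' @param activation `"sigmoid"` (softmax output) or `"identity"` (pure
#'   linear net, used for cross-checking the trainer against least squares).
#' @return An object of class `ann_model`.
#' @export
ann_model <- function(W, b_h, W2, b_o, labels, norm = rep(1, 6),
                      activation = c("sigmoid", "identity")) {
  activation <- match.arg(activation)
  W <- as.matrix(W); W2 <- as.matrix(W2)
  if (nrow(W) != 6L) stop("W must have 6 input rows", call. = FALSE)
  if (ncol(W) != length(b_h) || nrow(W2) != ncol(W) ||
      ncol(W2) != length(b_o) || ncol(W2) != length(labels))
    stop("inconsistent network dimensions", call. = FALSE)
  if (!all(is.finite(W)) || !all(is.finite(W2)) ||
      !all(is.finite(b_h)) || !all(is.finite(b_o)))
    stop("weights must be finite", call. = FALSE)
  structure(list(W = W, b_h = as.numeric(b_h), W2 = W2,
                 b_o = as.numeric(b_o), labels = as.character(labels),
                 norm = as.numeric(norm), activation = activation,
                 loss_trace = NULL, seed = NA_integer_),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat("<ann_model> 6 -> ", ncol(x$W), " -> ", length(x$labels),
      " (", x$activation, "); classes: ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  if (!is.null(x$loss_trace))
    cat("  trained: ", length(x$loss_trace), " accepted LM steps, final SSE ",
        signif(x$loss_trace[length(x$loss_trace)], 4), "\n", sep = "")
  invisible(x)
}

frames_to_matrix <- function(frames) {
  if (is.data.frame(frames)) {
    cols <- paste0("f", 1:6)
    miss <- setdiff(cols, names(frames))
    if (length(miss))
      stop("pressure frames lack column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    as.matrix(frames[, cols])
  } else if (is.matrix(frames)) {
    if (ncol(frames) != 6L)
      stop("pressure frames need 6 channel columns", call. = FALSE)
    frames
  } else {
    if (length(frames) != 6L)
      stop("a pressure frame needs 6 channels", call. = FALSE)
    matrix(as.numeric(frames), 1L, 6L)
  }
}

#' Forward pass of the posture network
#'
#' @param model an [ann_model].
#' @param frames one frame (numeric length 6), a 6-column matrix, or a data
#'   frame with `f1`..`f6`.
#' @return Matrix of class probabilities, one row per frame; rows sum to 1
#'   (for the identity-activation net, raw linear outputs instead).
#' @export
ann_forward <- function(model, frames) {
  stopifnot(inherits(model, "ann_model"))
  X <- frames_to_matrix(frames)
  if (ncol(X) != nrow(model$W)) stop("invalid model: needs 6 inputs",
                                     call. = FALSE)
  X <- sweep(X, 2L, model$norm, "/")
  Z <- X %*% model$W + matrix(model$b_h, nrow(X), length(model$b_h),
                              byrow = TRUE)
  H <- if (model$activation == "sigmoid") sigmoid(Z) else Z
  U <- H %*% model$W2 + matrix(model$b_o, nrow(X), length(model$b_o),
                               byrow = TRUE)
  P <- if (model$activation == "sigmoid") softmax_rows(U) else U
  colnames(P) <- model$labels
  P
}

# parameter packing: theta = c(vec(W), b_h, vec(W2), b_o)
pack_params <- function(m) c(as.vector(m$W), m$b_h, as.vector(m$W2), m$b_o)

unpack_params <- function(theta, n_in, n_h, n_out) {
  i <- 0L
  W  <- matrix(theta[i + seq_len(n_in * n_h)], n_in, n_h); i <- i + n_in * n_h
  bh <- theta[i + seq_len(n_h)]; i <- i + n_h
  W2 <- matrix(theta[i + seq_len(n_h * n_out)], n_h, n_out)
  i <- i + n_h * n_out
  bo <- theta[i + seq_len(n_out)]
  list(W = W, b_h = bh, W2 = W2, b_o = bo)
}

# residuals r = vec(P - Y) and Jacobian J = d vec(P) / d theta, vectorised
# across samples. Row order matches as.vector(): sample index fastest.
lm_residual_jacobian <- function(theta, X, Y, n_h, activation) {
  n_in <- ncol(X); n_out <- ncol(Y); N <- nrow(X)
  p <- unpack_params(theta, n_in, n_h, n_out)
  Z <- X %*% p$W + matrix(p$b_h, N, n_h, byrow = TRUE)
  if (activation == "sigmoid") {
    H <- sigmoid(Z); Hp <- H * (1 - H)
    U <- H %*% p$W2 + matrix(p$b_o, N, n_out, byrow = TRUE)
    P <- softmax_rows(U)
    # S[n,k,m] = dP[n,k]/dU[n,m] = P[n,k] (delta_km - P[n,m])
    S <- array(0, c(N, n_out, n_out))
    for (m in seq_len(n_out)) {
      S[, , m] <- -P * P[, m]
      S[, m, m] <- S[, m, m] + P[, m]
    }
  } else {
    H <- Z; Hp <- matrix(1, N, n_h)
    U <- H %*% p$W2 + matrix(p$b_o, N, n_out, byrow = TRUE)
    P <- U
    S <- array(0, c(N, n_out, n_out))
    for (m in seq_len(n_out)) S[, m, m] <- 1
  }
  NK <- N * n_out
  S_mat <- matrix(S, NK, n_out)            # rows ordered (n fastest, then k)
  rows <- rep(seq_len(N), n_out)
  G <- (S_mat %*% t(p$W2)) * Hp[rows, , drop = FALSE]  # d vec(P)/d Z
  X_exp <- X[rows, , drop = FALSE]
  H_exp <- H[rows, , drop = FALSE]
  J <- matrix(0, NK, length(theta))
  col <- 0L
  for (j in seq_len(n_h)) {               # vec(W): input index fastest
    J[, col + seq_len(n_in)] <- X_exp * G[, j]
    col <- col + n_in
  }
  J[, col + seq_len(n_h)] <- G; col <- col + n_h
  for (m in seq_len(n_out)) {             # vec(W2): hidden index fastest
    J[, col + seq_len(n_h)] <- H_exp * S_mat[, m]
    col <- col + n_h
  }
  J[, col + seq_len(n_out)] <- S_mat
  list(r = as.vector(P - Y), J = J)
}

#' Train the posture network by Levenberg-Marquardt
#'
#' Minimises the sum of squared errors between the network outputs and
#' one-hot class targets by damped Gauss-Newton on the full residual
#' Jacobian: each step solves `(J'J + lambda diag(J'J)) delta = -J'r`. The
#' damping `lambda` starts at 1e-3, divides by 10 after an accepted step and
#' multiplies by 10 after a rejected one; iteration stops when the relative
#' loss change falls below 1e-8, after `max_iter` accepted steps, or with a
#' training-failed error when no acceptable step exists even at the maximum
#' damping. The accepted-step loss trace is stored on the model and is
#' non-increasing by construction.
#'
#' @param frames labelled training frames: a data frame with `f1`..`f6` and
#'   `label`, or a 6-column matrix plus `labels`.
#' @param labels class label per frame (taken from `frames$label` if absent).
#' @param n_hidden hidden units (default 10).
#' @param seed seed for the uniform(-0.5, 0.5) weight initialisation.
#' @param max_iter maximum accepted LM iterations.
#' @param tol relative loss-change stopping tolerance.
#' @param activation see [ann_model()].
#' @param lambda0,lambda_max initial and maximal damping.
#' @param restarts number of seeded random initialisations; the fit with the
#'   lowest final training loss wins. Sum-of-squares training of a sigmoid
#'   net is non-convex and a single start occasionally stalls in a local
#'   minimum that confuses two classes; multi-start is the standard remedy.
#'   Later restarts are skipped once a fit is sharp (residual SSE below 0.05
#'   per sample). Derived start seeds are `seed`, `seed + 7919`, ...
#' @return A trained [ann_model] with `loss_trace` and normalisation maxima
#'   fitted from the training data.
#' @export
train_lm <- function(frames, labels = NULL, n_hidden = 10L, seed = 1L,
                     max_iter = 200L, tol = 1e-8,
                     activation = c("sigmoid", "identity"),
                     lambda0 = 1e-3, lambda_max = 1e10, restarts = 3L) {
  activation <- match.arg(activation)
  if (restarts > 1L) {
    best <- NULL
    for (r in seq_len(restarts)) {
      cand <- train_lm(frames, labels, n_hidden,
                       seed = as.integer(seed) + (r - 1L) * 7919L,
                       max_iter = max_iter, tol = tol,
                       activation = activation, lambda0 = lambda0,
                       lambda_max = lambda_max, restarts = 1L)
      if (is.null(best) ||
          utils::tail(cand$loss_trace, 1) < utils::tail(best$loss_trace, 1))
        best <- cand
      n_obs <- nrow(frames_to_matrix(frames))
      if (utils::tail(best$loss_trace, 1) / n_obs < 0.05) break
    }
    return(best)
  }
  X_raw <- frames_to_matrix(frames)
  if (is.null(labels)) {
    if (!is.data.frame(frames) || is.null(frames$label))
      stop("labels are required", call. = FALSE)
    labels <- frames$label
  }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("training needs at least 2 classes", call. = FALSE)
  norm <- apply(X_raw, 2L, max)
  norm[norm <= 0] <- 1
  X <- sweep(X_raw, 2L, norm, "/")
  Y <- outer(labels, classes, "==") * 1
  n_in <- ncol(X); n_out <- length(classes)
  n_par <- n_in * n_hidden + n_hidden + n_hidden * n_out + n_out
  theta <- local_seed(seed, stats::runif(n_par, -0.5, 0.5))
  rj <- lm_residual_jacobian(theta, X, Y, n_hidden, activation)
  loss <- sum(rj$r^2)
  trace <- loss
  lambda <- lambda0
  for (it in seq_len(max_iter)) {
    A <- crossprod(rj$J)
    g <- crossprod(rj$J, rj$r)
    D <- pmax(diag(A), 1e-12)
    repeat {
      step <- tryCatch(solve(A + lambda * diag(D, nrow(A)), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta + as.vector(step)
        rj_new <- lm_residual_jacobian(cand, X, Y, n_hidden, activation)
        new_loss <- sum(rj_new$r^2)
        if (is.finite(new_loss) && new_loss <= loss) break
      }
      lambda <- lambda * 10
      if (lambda > lambda_max)
        stop("training failed: no acceptable step at maximum damping",
             call. = FALSE)
    }
    rel <- (loss - new_loss) / max(loss, .Machine$double.eps)
    theta <- cand; rj <- rj_new; loss <- new_loss
    trace <- c(trace, loss)
    lambda <- max(lambda / 10, 1e-12)
    if (rel < tol) break
  }
  p <- unpack_params(theta, n_in, n_hidden, n_out)
  model <- ann_model(p$W, p$b_h, p$W2, p$b_o, classes, norm, activation)
  model$loss_trace <- trace
  model$seed <- as.integer(seed)
  model
}

#' Classify pressure frames
#'
#' Argmax over the forward-pass probabilities; ties are broken by class
#' order.
#'
#' @param model a trained [ann_model].
#' @param frames frames as in [ann_forward()].
#' @return Data frame with `label` and `probability`, one row per frame.
#' @export
classify <- function(model, frames) {
  P <- ann_forward(model, frames)
  idx <- apply(P, 1L, which.max)   # which.max: earliest on ties
  data.frame(label = model$labels[idx],
             probability = P[cbind(seq_len(nrow(P)), idx)])
}

#' Seat occupancy test
#'
#' @param frame one pressure frame (numeric length 6, matrix row, or data
#'   frame with `f1`..`f6`).
#' @param threshold total-pressure threshold in sensor units; the default is
#'   about 20% of an upright sitter's total load.
#' @return Logical: total pressure at or above the threshold.
#' @export
occupancy <- function(frame, threshold = sl_config()$occupancy_threshold) {
  X <- frames_to_matrix(frame)
  as.vector(rowSums(X) >= threshold)
}

# ---- sedentary clock ----------------------------------------------------

#' Continuous-sitting clock
#'
#' Accumulates continuous sitting time in minutes. Brief stand-ups pause the
#' accumulation; standing continuously for `unoccupied_reset_s` (default
#' 60 s) or completing a guided exercise resets it to zero.
#'
#' @return An object of class `sedentary_clock` with `seated_minutes`,
#'   `unoccupied_s`, `t` (elapsed seconds).
#' @export
sedentary_clock <- function() {
  structure(list(seated_minutes = 0, unoccupied_s = 0, t = 0),
            class = "sedentary_clock")
}

#' @export
print.sedentary_clock <- function(x, ...) {
  cat("<sedentary_clock> ", round(x$seated_minutes, 2), " min seated (t = ",
      round(x$t, 1), " s)\n", sep = "")
  invisible(x)
}

#' Advance the sedentary clock
#'
#' @param clock a [sedentary_clock()].
#' @param occupied is the seat occupied over this step?
#' @param dt step in seconds (> 0).
#' @param exercise_completed did a guided exercise just complete?
#' @param unoccupied_reset_s continuous standing time that resets the clock.
#' @return The updated clock.
#' @export
update_sedentary <- function(clock, occupied, dt,
                             exercise_completed = FALSE,
                             unoccupied_reset_s = 60) {
  stopifnot(inherits(clock, "sedentary_clock"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  clock$t <- clock$t + dt
  if (exercise_completed) {
    clock$seated_minutes <- 0
    clock$unoccupied_s <- 0
    return(clock)
  }
  if (occupied) {
    clock$seated_minutes <- clock$seated_minutes + dt / 60
    clock$unoccupied_s <- 0
  } else {
    clock$unoccupied_s <- clock$unoccupied_s + dt
    if (clock$unoccupied_s >= unoccupied_reset_s) clock$seated_minutes <- 0
  }
  clock
}

# ---- microbreak-start detection ----------------------------------------

#' Signed lateral weight-shift index
#'
#' `(R - L) / (L + R)` over the left (f1--f3) and right (f4--f6) channel
#' sums: positive values lean right, negative lean left, 0 is balanced.
#' Empty frames return 0.
#'
#' @param frames frames as in [ann_forward()].
#' @return Numeric vector in \[-1, 1\].
#' @export
lateral_shift_index <- function(frames) {
  X <- frames_to_matrix(frames)
  L <- rowSums(X[, 1:3, drop = FALSE])
  R <- rowSums(X[, 4:6, drop = FALSE])
  tot <- L + R
  ifelse(tot > 0, (R - L) / tot, 0)
}

#' Detect the start of a microbreak exercise
#'
#' Watches a recent window of pressure frames and the running HRV trace and
#' decides whether the user has begun one of the two guided microbreaks:
#'
#' * **stretch** -- the absolute lateral weight-shift index exceeds its
#'   threshold continuously for at least `stretch_enter_s` (default 2 s);
#' * **breathing** -- the posture is stable (index stays below threshold)
#'   while the running HRV estimate climbs faster than
#'   `hrv_slope_frac_per_30s` of the calibrated HRV range per 30 s, the
#'   signature of deliberate slow breathing.
#'
#' Stretch takes precedence when both fire. A breathing candidate without a
#' calibration range is an error, since the slope threshold is defined
#' relative to it.
#'
#' @param frames recent pressure frames (data frame with `time_s`,
#'   `f1`..`f6`) spanning at least 5 s.
#' @param hrv recent HRV trace: data frame with `beat_time_s` (or `time_s`)
#'   and `hrv40`.
#' @param calibration a [calibration_range], or `NULL` when not yet
#'   calibrated.
#' @param config an [sl_config()].
#' @return `"stretch"`, `"breathing"`, or `"none"`.
#' @export
detect_exercise_start <- function(frames, hrv = NULL, calibration = NULL,
                                  config = sl_config()) {
  if (is.null(frames$time_s) || diff(range(frames$time_s)) < 5 - 1e-9)
    stop("need at least 5 s of frames", call. = FALSE)
  idx <- lateral_shift_index(frames)
  thr <- config$lateral_shift_threshold
  t_end <- max(frames$time_s)
  recent <- frames$time_s >= t_end - config$stretch_enter_s
  if (sum(recent) >= 2L && all(abs(idx[recent]) > thr))
    return("stretch")
  # breathing: stable posture + rapidly rising HRV40
  if (all(abs(idx) < thr) && !is.null(hrv) && nrow(hrv) >= 5L) {
    tcol <- if (!is.null(hrv$beat_time_s)) hrv$beat_time_s else hrv$time_s
    keep <- tcol >= max(tcol) - 30
    if (sum(keep) >= 5L && diff(range(tcol[keep])) >= 20) {
      slope <- stats::cov(tcol[keep], hrv$hrv40[keep]) /
               stats::var(tcol[keep])          # ms per s
      if (is.finite(slope) && slope > 0) {
        if (is.null(calibration))
          stop("calibration required for breathing detection", call. = FALSE)
        rng <- calibration$hrv_max_ms - calibration$hrv_min_ms
        if (slope * 30 >= config$hrv_slope_frac_per_30s * rng)
          return("breathing")
      }
    }
  }
  "none"
}
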