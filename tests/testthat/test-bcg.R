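test_that("Haar detail denoising vanishes on constants and reconstructs exactly", {
  const <- raw_bcg(rep(3.7, 64), 256)
  for (method in c("swt", "dwt"))
    expect_true(all(abs(wavelet_denoise(const, 4, method)$values) < 1e-12))

  set.seed(11)
  x <- rnorm(160)
  # additive multiresolution: the four detail levels plus the 16-sample
  # smooth reconstitute the signal exactly
  details <- Reduce(`+`, lapply(1:4, function(l)
    wavelet_denoise(raw_bcg(x, 256), l, "swt")$values))
  smooth16 <- vapply(seq_along(x), function(k)
    mean(x[max(1, k - 8):min(length(x), k + 7)]), 0)
  expect_equal(details + smooth16, x, tolerance = 1e-12)

  expect_error(wavelet_denoise(raw_bcg(rnorm(8), 256), 4), "shorter")
})

test_that("decimated Haar transform is orthogonal with perfect reconstruction", {
  set.seed(21)
  x <- rnorm(256)
  dec <- sitlight:::haar_decompose(x, 4)
  parts <- lapply(1:4, function(l)
    sitlight:::haar_reconstruct(dec, keep_details = l, keep_approx = FALSE))
  approx_part <- sitlight:::haar_reconstruct(dec, keep_details = integer(0),
                                             keep_approx = TRUE)
  total <- Reduce(`+`, parts) + approx_part
  expect_lt(max(abs(total - x)) / max(abs(x)), 1e-9)
  # energy preserved across coefficients (orthogonality)
  e_coef <- sum(unlist(dec$details)^2) + sum(dec$approx^2)
  expect_equal(e_coef, sum(x^2), tolerance = 1e-9)
})

test_that("both wavelet variants match independent reference transforms", {
  set.seed(31)
  x <- rnorm(512)
  expect_equal(wavelet_denoise(raw_bcg(x, 256), 4, "dwt")$values,
               oracle_dwt_detail(x, 4), tolerance = 1e-9)
  expect_equal(wavelet_denoise(raw_bcg(x, 256), 4, "swt")$values,
               oracle_swt_detail(x, 4), tolerance = 1e-12)
})

test_that("level-4 detail boosts the beat band against respiratory drift", {
  fs <- 256
  tt <- (0:(8 * fs - 1)) / fs
  resp <- sin(2 * pi * 0.25 * tt)
  burst <- numeric(length(tt))
  for (tb in seq(0.5, 7.5, by = 1)) {
    idx <- which(abs(tt - tb) <= 0.075)
    burst[idx] <- burst[idx] + exp(-(tt[idx] - tb)^2 / (2 * 0.025^2)) *
      sin(2 * pi * 15 * (tt[idx] - tb))
  }
  x <- resp + burst
  band_energy <- function(v, lo, hi) {
    sp <- Mod(stats::fft(v))^2
    f <- (seq_along(v) - 1) * fs / length(v)
    sum(sp[f >= lo & f <= hi])
  }
  ratio <- function(v) band_energy(v, 8, 16) / band_energy(v, 0.1, 0.5)
  den <- wavelet_denoise(raw_bcg(x, fs), 4)$values
  expect_gt(ratio(den) / ratio(x), 100)
  # and the same gain factor computed through the independent reference
  den_ref <- oracle_swt_detail(x, 4)
  expect_equal(ratio(den) / ratio(x), ratio(den_ref) / ratio(x),
               tolerance = 1e-9)
})

test_that("moving MAD handles constants, alternation, and matches brute force", {
  fs <- 100
  const <- moving_mad(raw_bcg(rep(5, 50), fs), 100)
  expect_true(all(abs(const$values) < 1e-12))

  alt <- moving_mad(raw_bcg(rep(c(1, -1), 25), fs), 40)  # 4-sample window
  expect_true(all(abs(alt$values[5:46] - 1) < 1e-12))

  set.seed(42)
  for (i in 1:100) {
    n <- sample(20:120, 1)
    x <- rnorm(n)
    win <- sample(c(30, 50, 100, 170), 1)
    got <- moving_mad(raw_bcg(x, fs), win)$values
    expect_equal(got, oracle_moving_mad(x, fs, win), tolerance = 1e-12)
  }

  expect_error(moving_mad(raw_bcg(rnorm(50), fs), 0), "window")
  expect_error(moving_mad(raw_bcg(rnorm(50), fs), 5), "2 samples")
})

test_that("beat detection matches the exhaustive moving-max oracle", {
  fs <- 100
  env <- numeric(400)
  env[c(101, 201, 301)] <- 1
  got <- detect_beats(list(values = env, fs = fs), 400)
  expect_equal(got, c(1.0, 2.0, 3.0))

  # two peaks 300 ms apart: only the larger survives a 400 ms window
  env2 <- numeric(200)
  env2[100] <- 1; env2[130] <- 0.6
  expect_equal(detect_beats(list(values = env2, fs = fs), 400), 0.99)

  expect_identical(detect_beats(list(values = numeric(300), fs = fs), 400),
                   numeric(0))
  expect_error(detect_beats(list(values = c(-1, 2, 1), fs = fs)),
               "nonnegative")

  set.seed(99)
  for (i in 1:100) {
    n <- sample(30:300, 1)
    env <- pmax(rnorm(n), 0)
    win <- sample(c(200, 400, 700), 1)
    expect_equal(detect_beats(list(values = env, fs = fs), win),
                 oracle_detect_beats(env, fs, win))
  }
})

test_that("IBI computation and the validity gate behave as specified", {
  s <- compute_ibis(c(1.0, 2.0, 3.0))
  expect_equal(s$ibis_ms, c(1000, 1000))
  expect_true(all(s$valid))

  s2 <- compute_ibis(c(1.0, 1.2))
  expect_equal(s2$ibis_ms, 200)
  expect_false(s2$valid)

  expect_length(compute_ibis(1.5)$ibis_ms, 0)
  expect_length(compute_ibis(numeric(0))$ibis_ms, 0)

  # relative-jump gate: 1000 -> 1400 is a >30% jump, rejected
  s3 <- compute_ibis(c(0, 1.0, 2.4, 3.4))
  expect_equal(s3$valid, c(TRUE, FALSE, TRUE))

  expect_error(ibi_series(c(1, 1)), "strictly increasing")
})

test_that("HRV recursion reproduces hand-computed one-step updates", {
  st <- hrv_state(1000, 0, 5)
  expect_equal(update_hrv(st, 1000)$hrv40, 0, tolerance = 1e-12)
  expect_equal(update_hrv(st, 1000)$ibi40, 1000, tolerance = 1e-12)

  st2 <- hrv_state(1000, 40, 5)
  up2 <- update_hrv(st2, 1000)
  expect_equal(up2$hrv40, 39.0, tolerance = 1e-12)
  expect_equal(up2$ibi40, 1000, tolerance = 1e-12)

  st3 <- hrv_state(1000, 0, 5)
  up3 <- update_hrv(st3, 1040)
  expect_equal(up3$hrv40, 1.0, tolerance = 1e-12)
  expect_equal(up3$ibi40, 1001.0, tolerance = 1e-12)

  # first valid interval seeds the mean; invalid intervals are ignored
  fresh <- update_hrv(hrv_state(), 812)
  expect_equal(fresh$ibi40, 812)
  expect_equal(fresh$hrv40, 0)
  expect_identical(update_hrv(st3, 400, valid = FALSE), st3)
  expect_error(update_hrv(st3, -5), "positive")
})

test_that("HRV40 decays geometrically on constant input", {
  h0 <- 25
  st <- hrv_state(800, h0, 50)
  for (n in 1:40) st <- update_hrv(st, 800)
  expect_equal(st$hrv40, h0 * (39 / 40)^40, tolerance = 1e-12)
  expect_equal(st$ibi40, 800, tolerance = 1e-12)
})

test_that("HRV40 steady state approaches the EW mean absolute deviation", {
  mu <- 900; sdev <- 40
  target <- sdev * sqrt(2 / pi)  # E|X - mu| for X ~ N(mu, sdev)
  for (seed in 1:5) {
    set.seed(seed)
    ibis <- rnorm(2000, mu, sdev)
    st <- hrv_state()
    trace <- vapply(ibis, function(x) {
      st <<- update_hrv(st, x)
      st$hrv40
    }, 0)
    # steady state = time average after the transient has washed out
    expect_lt(abs(mean(trace[1001:2000]) - target) / target, 0.10)
  }
})

test_that("warm-up flag clears after 40 valid intervals", {
  st <- hrv_state()
  for (n in 1:39) st <- update_hrv(st, 800 + n)
  expect_true(is_warm_up(st))
  st <- update_hrv(st, 900)
  expect_false(is_warm_up(st))
  expect_identical(st$n_seen, 40L)
})

test_that("SDNN is the population SD of valid intervals", {
  s <- ibi_series(c(0, 0.9, 2.0))  # IBIs 900, 1100
  expect_equal(sdnn(s), 100)
  expect_equal(sdnn(ibi_series(cumsum(c(0, rep(0.8, 10))))), 0)
  set.seed(5)
  v <- 800 + rnorm(50, 0, 30)
  s2 <- ibi_series(cumsum(c(0, v / 1000)))
  two_pass <- sqrt(sum((v - sum(v) / length(v))^2) / length(v))
  expect_equal(sdnn(s2), two_pass, tolerance = 1e-12)
  expect_error(sdnn(ibi_series(c(0, 0.8))), "2 valid")
})

test_that("calibration orders the relaxed and post-exercise SDNN", {
  relax <- gen_ibi_stream(90, base_ibi = 900, rsa_depth = 100,
                          breath_rate = 0.1, seed = 1)
  hard <- gen_ibi_stream(90, base_ibi = 600, rsa_depth = 5,
                         breath_rate = 0.3, noise_sd = 2, seed = 2)
  cal <- calibrate_range(relax, hard)
  expect_gt(cal$hrv_max_ms, cal$hrv_min_ms)
  expect_equal(cal$hrv_max_ms, sdnn(relax))
  expect_equal(cal$hrv_min_ms, sdnn(hard))

  expect_error(calibrate_range(hard, relax), "calibration failed")
  short <- gen_ibi_stream(20, base_ibi = 800, seed = 3)
  expect_error(calibrate_range(short, hard), "span")
  expect_error(calibration_range(50, 20), "exceed")
})

test_that("pipeline recovers clean and noisy synthetic recordings", {
  clean <- gen_bcg(60, hr = 60, resp_amp = 0.5, noise_sd = 0, seed = 4)
  ib <- process_bcg(clean$bcg)
  expect_lt(abs(mean(ib$ibis_ms[ib$valid]) - 1000), 10)

  noisy <- gen_bcg(60, hr = 75, resp_amp = 0.5, noise_sd = 0.2, seed = 5)
  ib2 <- process_bcg(noisy$bcg)
  ev <- ibi_error(ib2$beat_times, noisy$truth$beat_times, tol_s = 0.05)
  expect_gte(ev$coverage, 0.95)

  flat <- raw_bcg(numeric(512), 256)
  expect_length(process_bcg(flat)$ibis_ms, 0)
})

test_that("IBI recovery stays within 10 ms across heart rates", {
  errs <- c()
  for (hr in c(50, 60, 75, 100)) {
    sim <- gen_bcg(60, hr = hr, resp_amp = 0.5, noise_sd = 0.1, seed = hr)
    ib <- process_bcg(sim$bcg)
    ev <- ibi_error(ib$beat_times, sim$truth$beat_times)
    errs <- c(errs, ev$errors_ms)
  }
  expect_lte(mean(errs), 10)
})
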