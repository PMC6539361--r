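test_that("linmap reproduces the printed design endpoints and clamps", {
  expect_equal(linmap(1150, 550, 1150, 10, 255), 255)
  expect_equal(linmap(550, 550, 1150, 10, 255), 10)
  expect_equal(linmap(850, 550, 1150, 10, 255), 132.5)
  expect_equal(linmap(2000, 550, 1150, 10, 255), 255)  # clamp high
  expect_equal(linmap(100, 550, 1150, 10, 255), 10)    # clamp low
  # inverted source: high input maps low
  expect_equal(linmap(80, 80, 15, 10, 255), 10)
  expect_equal(linmap(15, 80, 15, 10, 255), 255)
  expect_error(linmap(1, 5, 5, 0, 10), "differ")
})

test_that("HSB conversion is exact at the colour-wheel corners", {
  expect_identical(hsb_to_rgb(0, 255, 255), c(255L, 0L, 0L))
  expect_identical(hsb_to_rgb(120, 255, 255), c(0L, 255L, 0L))
  expect_identical(hsb_to_rgb(240, 255, 255), c(0L, 0L, 255L))
  expect_identical(hsb_to_rgb(123, 0, 0), c(0L, 0L, 0L))
  expect_identical(hsb_to_rgb(37, 0, 255), c(255L, 255L, 255L))
  expect_error(hsb_to_rgb(400, 10, 10), "hue")
  expect_error(hsb_to_rgb(10, 300, 10), "0, 255")
})

test_that("every rendered frame carries exactly 28 in-range RGB triples", {
  cal <- default_calibration()
  frames <- list(
    intervention_frame(17, 42, cal),
    biofeedback_frame(900, 55, cal),
    stretch_step(stretch_session(1), 0, 0.05)$frame)
  for (f in frames) {
    expect_s3_class(f, "light_frame")
    expect_identical(dim(f$leds), c(28L, 3L))
    expect_true(all(f$leds >= 0 & f$leds <= 255))
  }
  expect_error(light_frame(0, 10, 10, leds = matrix(0, 27, 3)), "28")
})

test_that("intervention mapping hits its endpoints and monotonicity", {
  cal <- default_calibration()   # hrv 15-80 ms
  hot <- intervention_frame(30, 15, cal)
  expect_equal(hot$hsb[["bri"]], 255)
  expect_equal(hot$hsb[["sat"]], 255)
  cool <- intervention_frame(5, 80, cal)
  expect_equal(cool$hsb[["bri"]], 10)   # floors below 10 min
  expect_equal(cool$hsb[["sat"]], 10)
  mid <- intervention_frame(20, 47.5, cal)
  expect_equal(mid$hsb[["bri"]], 132.5)
  expect_equal(mid$hsb[["sat"]], 132.5)
  expect_equal(hot$hsb[["hue"]], 30)    # orange

  bri <- vapply(seq(0, 40, by = 2),
                function(m) intervention_frame(m, 40, cal)$hsb[["bri"]], 0)
  expect_false(is.unsorted(bri))
  sat <- vapply(seq(10, 90, by = 5),
                function(h) intervention_frame(20, h, cal)$hsb[["sat"]], 0)
  expect_false(is.unsorted(rev(sat)))   # saturation falls as HRV rises
  expect_error(intervention_frame(20, 40, NULL), "calibration")
})

test_that("biofeedback mapping hits its endpoints with the 250 ceiling", {
  cal <- default_calibration()
  top <- biofeedback_frame(1150, 80, cal)
  expect_equal(top$hsb[["bri"]], 255)
  expect_equal(top$hsb[["sat"]], 250)
  low <- biofeedback_frame(550, 15, cal)
  expect_equal(low$hsb[["bri"]], 10)
  expect_equal(low$hsb[["sat"]], 10)

  bri <- vapply(seq(500, 1200, by = 50),
                function(i) biofeedback_frame(i, 40, cal)$hsb[["bri"]], 0)
  expect_false(is.unsorted(bri))
  sat <- vapply(seq(10, 90, by = 5),
                function(h) biofeedback_frame(900, h, cal)$hsb[["sat"]], 0)
  expect_false(is.unsorted(sat))        # saturation rises with HRV here
  expect_error(biofeedback_frame(900, 40, NULL), "calibration")
})

test_that("breathing-modulated intervals render brightness at the breath rate", {
  cal <- default_calibration()
  s <- gen_ibi_stream(90, base_ibi = 850, rsa_depth = 120, breath_rate = 0.1,
                      noise_sd = 0, seed = 6)
  bri <- vapply(s$ibis_ms, function(i)
    biofeedback_frame(i, 40, cal)$hsb[["bri"]], 0)
  f <- oracle_dominant_freq(s$beat_times[-1], bri)
  expect_lt(abs(1 / f - 10), 1.5)
})

test_that("stretch state machine walks the cue-move-hold-switch cycle", {
  cfg <- sl_config()
  s <- stretch_session(seed = 3, start_side = "left")
  expect_identical(s$phase, "cue_left")

  # cue phase: no shift keeps cueing, blue
  r <- stretch_step(s, 0, 0.05)
  expect_identical(r$session$phase, "cue_left")
  expect_equal(r$frame$hsb[["hue"]], 240)

  # user starts leaning left: moving, hue interpolates toward green
  r <- stretch_step(r$session, -0.2, 0.05)
  expect_identical(r$session$phase, "moving")
  hue_mid <- r$frame$hsb[["hue"]]
  expect_true(hue_mid < 240 && hue_mid > 120)

  # target reached: hold with a non-uniform sparkle frame
  r <- stretch_step(r$session, -0.5, 0.05)
  expect_identical(r$session$phase, "hold")
  expect_gt(length(unique(r$frame$leds[, 2])), 1)

  # holding through the dwell flips the side and resets to blue
  guard <- 0
  while (r$session$phase == "hold" && guard < 200) {
    r <- stretch_step(r$session, -0.5, 0.05)
    guard <- guard + 1
  }
  expect_identical(r$session$phase, "switch")
  expect_identical(r$session$target_side, "right")
  expect_equal(r$frame$hsb[["hue"]], 240)
  expect_identical(r$session$reps_done, 0L)

  # complete the right side: one full rep
  r <- stretch_step(r$session, 0, 0.05)
  expect_identical(r$session$phase, "cue_right")
  r <- stretch_step(r$session, 0.5, 0.05)   # straight through moving to hold
  expect_identical(r$session$phase, "hold")
  guard <- 0
  while (r$session$phase == "hold" && guard < 200) {
    r <- stretch_step(r$session, 0.5, 0.05)
    guard <- guard + 1
  }
  expect_identical(r$session$target_side, "left")
  expect_identical(r$session$reps_done, 1L)

  expect_error(stretch_step(r$session, 0, -1), "dt")
  expect_error(stretch_step(r$session, 2, 0.05), "lateral_shift")
})

test_that("full phase sequence matches the hand-written transition table", {
  # scripted shift trace at 20 Hz: idle, ramp left, hold, return,
  # ramp right, hold, return
  shift <- c(rep(0, 20), seq(0, -0.6, length.out = 20), rep(-0.6, 70),
             seq(-0.6, 0, length.out = 10), rep(0, 10),
             seq(0, 0.6, length.out = 20), rep(0.6, 70),
             seq(0.6, 0, length.out = 10))
  s <- stretch_session(seed = 1)
  phases <- character(0)
  for (x in shift) {
    r <- stretch_step(s, x, 0.05)
    s <- r$session
    phases <- c(phases, s$phase)
  }
  expect_identical(rle(phases)$values,
                   c("cue_left", "moving", "hold", "switch", "cue_right",
                     "moving", "hold", "switch", "cue_left"))
  expect_identical(s$reps_done, 1L)
  expect_true(all(phases %in% c("cue_left", "cue_right", "moving", "hold",
                                "switch")))
})

test_that("sparkle frames are reproducible for a fixed session seed", {
  run <- function() {
    s <- stretch_session(seed = 42)
    r <- stretch_step(s, -0.5, 0.05)
    for (i in 1:10) r <- stretch_step(r$session, -0.5, 0.05)
    r$frame$leds
  }
  expect_identical(run(), run())
  s2 <- stretch_session(seed = 43)
  r2 <- stretch_step(s2, -0.5, 0.05)
  for (i in 1:10) r2 <- stretch_step(r2$session, -0.5, 0.05)
  expect_false(identical(run(), r2$frame$leds))
})
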