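test_that("common-average re-referencing zeroes the across-channel mean", {
  # already zero-mean input is unchanged
  rec <- new_recording(rbind(rep(1, 100), rep(-1, 100)), 500, c("a", "b"))
  expect_equal(rereference_common_average(rec)$samples, rec$samples)

  # constant offset is removed entirely
  rec2 <- new_recording(matrix(3.5, 4, 100), 500, letters[1:4])
  expect_true(all(rereference_common_average(rec2)$samples == 0))

  set.seed(1)
  rec3 <- new_recording(matrix(rnorm(4000), 4, 1000), 500, letters[1:4])
  out <- rereference_common_average(rec3)
  expect_lt(max(abs(colMeans(out$samples))), 1e-10)

  expect_error(
    rereference_common_average(new_recording(matrix(0, 1, 10), 500, "a")),
    "2 channels"
  )
})

test_that("notch filter removes the line tone and spares the passband", {
  s60 <- sine_recording(60, duration_s = 10)
  out <- notch_filter(s60)
  expect_lt(sd(out$samples[1, ]), 0.1 * sd(s60$samples[1, ])) # >= 20 dB

  s10 <- sine_recording(10, duration_s = 10)
  out10 <- notch_filter(s10)
  expect_equal(sd(out10$samples[1, ]), sd(s10$samples[1, ]), tolerance = 0.1)

  z <- new_recording(matrix(0, 2, 500), 500, c("a", "b"))
  expect_true(all(notch_filter(z)$samples == 0))

  expect_error(notch_filter(sine_recording(10, rate = 100), notch_hz = 60), "Nyquist")
})

test_that("band-pass keeps in-band tones and kills slow drift", {
  s10 <- sine_recording(10, duration_s = 10)
  out <- bandpass_filter(s10, lo = 0.2, hi = 100)
  expect_equal(sd(out$samples[1, ]), sd(s10$samples[1, ]), tolerance = 0.1)

  drift <- new_recording(
    rbind(seq(0, 1, length.out = 5000), seq(0, 1, length.out = 5000)),
    500, c("a", "b")
  )
  outd <- bandpass_filter(drift, lo = 0.2, hi = 100)
  expect_lt(diff(range(outd$samples[1, ])), 0.2 * diff(range(drift$samples[1, ])))

  z <- new_recording(matrix(0, 2, 500), 500, c("a", "b"))
  expect_true(all(bandpass_filter(z)$samples == 0))

  expect_error(bandpass_filter(s10, lo = 300, hi = 400), "Nyquist")
  expect_message(bandpass_filter(s10, lo = 0.2, hi = 250), "clipped")
})

test_that("filtering is zero-phase: a band-limited pulse keeps its peak position", {
  n <- 2000
  t <- (seq_len(n) - n / 2) / 500
  pulse <- exp(-(t * 20)^2) * cos(2 * pi * 15 * t) # 15 Hz Gabor pulse
  rec <- new_recording(rbind(pulse, pulse), 500, c("a", "b"))
  out <- bandpass_filter(notch_filter(rec), lo = 1, hi = 100)
  expect_lte(abs(which.max(out$samples[1, ]) - which.max(pulse)), 1)
})

test_that("artifact screen flags exactly the contaminated segments", {
  set.seed(7)
  rec <- new_recording(matrix(rnorm(4 * 5000, sd = 10), 4, 5000), 500, letters[1:4])
  scr <- artifact_screen(rec)
  expect_false(any(scr$mask)) # clean bounded signal

  # 1-s burst of 10x amplitude in segment 4
  rec2 <- rec
  rec2$samples[2, 1501:2000] <- rec2$samples[2, 1501:2000] * 10
  scr2 <- suppressMessages(artifact_screen(rec2))
  expect_equal(scr2$rejected, 4L)

  # all-rejected input leaves downstream windowing nothing to work on
  rec3 <- rec
  rec3$samples <- rec3$samples * 100
  scr3 <- suppressMessages(artifact_screen(rec3, amp_uv = 10))
  expect_true(all(scr3$mask))
  expect_error(
    windowed_networks(rec3, "alpha", mask = scr3$mask),
    "Fewer than 2"
  )

  expect_error(artifact_screen(rec, amp_uv = -1), "positive")
})

test_that("surface Laplacian annihilates spatially uniform fields", {
  ch <- c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2", "Cz", "Fz")
  t <- seq_len(1000) / 500
  x <- sin(2 * pi * 10 * t)
  rec <- new_recording(matrix(rep(x, 10), 10, byrow = TRUE), 500, ch)
  out <- surface_laplacian(rec)
  expect_lt(sqrt(mean(out$samples^2)), 1e-6 * sqrt(mean(rec$samples^2)))

  # zero in, zero out
  z <- new_recording(matrix(0, 10, 100), 500, ch)
  expect_true(all(surface_laplacian(z)$samples == 0))
})

test_that("surface Laplacian localizes a single active channel", {
  ch <- c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2", "Cz", "Fz")
  x <- matrix(0, 10, 500)
  x[3, ] <- sin(2 * pi * 10 * seq_len(500) / 500) # C3 active
  rec <- new_recording(x, 500, ch)
  out <- surface_laplacian(rec)
  rms <- sqrt(rowMeans(out$samples^2))
  expect_equal(unname(which.max(rms)), 3L)
})

test_that("unknown electrode labels error by name", {
  expect_error(template_positions(c("C3", "QQ9x")), "QQ9x")
  rec <- new_recording(matrix(0, 2, 10), 500, c("C3", "C4"))
  pos <- template_positions("C3")
  expect_error(surface_laplacian(rec, positions = pos), "C4")
})

test_that("template positions sit on the unit sphere with sane geometry", {
  labs <- names(load_ba_map()$channel_ba)
  pos <- template_positions(labs)
  expect_equal(nrow(pos), 116)
  expect_equal(unname(sqrt(rowSums(pos^2))), rep(1, 116), tolerance = 1e-12)
  # no two electrodes collapse onto the same point
  d <- as.matrix(dist(pos))
  diag(d) <- Inf
  expect_gt(min(d), 0.01)
  # left/right symmetry: C3 mirrors C4
  expect_equal(pos["C3", "front"], pos["C4", "front"])
  expect_equal(pos["C3", "right"], -pos["C4", "right"])
  # front of head is in front of the back
  expect_gt(pos["FPz", "front"], pos["O1", "front"])
})

test_that("the five-step chain runs end to end and reports a mask", {
  set.seed(3)
  rec <- simulate_recording(
    channels = c("F3", "F4", "C3", "C4", "P3", "P4"),
    duration_s = 4, noise_sd = 5, seed = 11
  )
  out <- suppressMessages(preprocess_recording(rec))
  expect_s3_class(out$recording, "eeg_recording")
  expect_length(out$mask, 4)
  expect_equal(dim(out$recording$samples), dim(rec$samples))
})
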