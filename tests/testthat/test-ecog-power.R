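test_that("downsampling preserves in-band content and rescales markers", {
  fs <- 10000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- 5 * sin(2 * pi * 100 * t)
  rec <- ecog_recording(rbind(S1E1 = x, S1E2 = x), fs,
                        markers = tibble::tibble(trial_id = 1L,
                                                 condition = "easy",
                                                 onset = 1L, offset = 10000L))
  dn <- downsample(rec, 2000)
  expect_equal(dn$fs, 2000)
  expect_equal(ncol(dn$samples), 2 * 2000)
  # amplitude of a 100 Hz tone preserved within 1% (interior)
  mid <- 1000:3000
  expect_lt(abs(max(abs(dn$samples[1, mid])) - 5) / 5, 0.01)
  # marker at sample 10000 @ 10 kHz -> 2000 @ 2 kHz
  expect_equal(dn$markers$offset, 2000L)
  # identity when target equals current rate
  expect_identical(downsample(rec, fs)$samples, rec$samples)
  expect_error(downsample(rec, 20000), class = "glio_argument_error")
})

test_that("bipolar derivation yields m-1 channels with common-mode rejection", {
  rec <- tiny_recording()
  bp <- bipolar_rereference(rec)
  expect_equal(nrow(bp$samples), 6)           # two 4-electrode strips -> 3 + 3
  expect_equal(sum(bp$channels$strip_id == "S1"), 3)
  # adding a common signal to all channels of a strip changes nothing
  rec2 <- rec
  common <- sin(seq_len(ncol(rec$samples)) / 5)
  for (ch in 1:4) rec2$samples[ch, ] <- rec2$samples[ch, ] + 40 * common
  bp2 <- bipolar_rereference(rec2)
  expect_equal(bp2$samples[1:3, ], bp$samples[1:3, ], tolerance = 1e-10)
  # telescoping: the three derived channels sum to ch1 - ch4
  expect_equal(colSums(bp$samples[1:3, ]),
               rec$samples[1, ] - rec$samples[4, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  # single-channel strip errors, naming the strip
  solo <- ecog_recording(matrix(rnorm(100), 1, 100,
                                dimnames = list("S1E1", NULL)), 100)
  expect_error(bipolar_rereference(solo), "S1", class = "glio_argument_error")
})

test_that("notch stage removes line harmonics and passes neighbours", {
  atten <- function(freq) {
    rec <- tone_recording(freq)
    out <- notch_filter(rec, c(50, 79))
    mid <- 4000:16000
    rms(out$samples[1, mid]) / rms(rec$samples[1, mid])
  }
  expect_lt(atten(50), 0.05)
  expect_lt(atten(79), 0.05)
  expect_lt(atten(100), 0.05)    # 2nd harmonic of 50
  expect_gt(atten(60), 0.90)
  expect_gt(atten(120), 0.90)    # HG content between harmonics survives
  # harmonic enumeration stays below Nyquist
  h <- gliocircuit:::harmonics_below_nyquist(c(50, 79), 2000)
  expect_true(all(h < 1000))
  expect_setequal(h, c(seq(50, 950, by = 50), seq(79, 948, by = 79)))
  rec <- tone_recording(60)
  expect_error(notch_filter(rec, 1000), class = "glio_argument_error")
})

test_that("instantaneous power of an in-band tone is its squared amplitude", {
  rec <- tone_recording(150, amp = 10)       # bipolar-free direct path
  pw <- bandpass_power(rec, c(70, 250))
  mid <- 4000:16000
  expect_lt(max(abs(pw$samples[1, mid] - 100)) / 100, 0.02)
  # zero input -> zero power; doubling amplitude quadruples power
  z <- ecog_recording(matrix(0, 1, 1000, dimnames = list("S1E1", NULL)), 2000)
  expect_equal(max(bandpass_power(z, c(70, 250))$samples), 0)
  rec2 <- tone_recording(150, amp = 20)
  pw2 <- bandpass_power(rec2, c(70, 250))
  expect_equal(mean(pw2$samples[1, mid]) / mean(pw$samples[1, mid]), 4,
               tolerance = 0.01)
  # sign invariance
  recneg <- rec; recneg$samples <- -recneg$samples
  expect_equal(bandpass_power(recneg, c(70, 250))$samples, pw$samples,
               tolerance = 1e-8)
  expect_error(bandpass_power(rec, c(0, 250)), class = "glio_argument_error")
  expect_error(bandpass_power(rec, c(70, 1000)), class = "glio_argument_error")
})

test_that("zero-phase filtering leaves a pulse's power peak in place", {
  fs <- 2000
  t <- seq_len(4 * fs) / fs
  # Gabor burst: sharply peaked envelope at 2 s, carrier off the line harmonics
  x <- exp(-((t - 2) / 0.01)^2) * sin(2 * pi * 187 * t)
  rec <- ecog_recording(matrix(x, 1, dimnames = list("S1E1", NULL)), fs)
  p_raw <- bandpass_power(rec, c(70, 250))$samples[1, ]
  p_notched <- bandpass_power(notch_filter(rec, c(50, 79)), c(70, 250))$samples[1, ]
  expect_lt(abs(which.max(p_raw) - which.max(p_notched)), 3)
})

test_that("trial segmentation applies the per-condition trim rules", {
  fs <- 2000
  n <- 90 * fs
  rec <- structure(list(
    samples = matrix(1, 1, n, dimnames = list("S1E1", NULL)), fs = fs,
    channels = tibble::tibble(channel_id = "S1E1", strip_id = "S1",
                              index_in_strip = 1L),
    markers = tibble::tibble(trial_id = 1:3,
                             condition = c("rest", "hard", "easy"),
                             onset = c(1L, 130001L, 160001L),
                             offset = c(120000L, 154000L, 170000L)),
    provenance = character(), band = "hg"),
    class = c("power_timeseries", "ecog_recording"))
  seg <- segment_trials(rec)
  lens <- setNames(lengths(seg$power), seg$condition)
  expect_equal(unname(lens["rest"]), (60 - 4) * fs)    # 2 s trimmed each end
  expect_equal(unname(lens["hard"]), (12 - 5) * fs)    # 1+3 s start, 1 s end
  expect_equal(unname(lens["easy"]), (5 - 2) * fs)     # 1 s each end
  # a trial shorter than its trim errors and names the trial
  bad <- rec
  bad$markers <- tibble::tibble(trial_id = 9L, condition = "easy",
                                onset = 1L, offset = 3000L)   # 1.5 s
  expect_error(segment_trials(bad), "9", class = "glio_argument_error")
})
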