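test_that("ROI means are extracted per channel with missing markers", {
  plane <- matrix(c(100, 0, 0, 0, 300, 0, 0, 0, 0), 3, 3)
  fake <- list(n_frames = 3, fps = 10,
               frame = function(k) list(rgb = array(rep(plane * k, 3),
                                                    c(3, 3, 3)),
                                        nir = plane * k))
  two <- matrix(FALSE, 3, 3); two[1, 1] <- TRUE; two[2, 2] <- TRUE
  sig <- extract_signals(fake, list(two, NULL, two))
  expect_equal(unname(sig$means[1, ]), rep(200, 4))   # mean of {100, 300}
  expect_true(all(is.na(sig$means[2, ])))
  expect_equal(unname(sig$means[3, "NIR"]), 600)
  # constant frames under any mask return the constant
  const <- list(n_frames = 1, fps = 10,
                frame = function(k) list(rgb = array(1234, c(3, 3, 3)),
                                         nir = matrix(1234, 3, 3)))
  s2 <- extract_signals(const, list(matrix(TRUE, 3, 3)))
  expect_equal(unname(s2$means[1, ]), rep(1234, 4))
  expect_error(extract_signals(fake, list(two)), "length")
})

test_that("segmentation into 10-s windows follows the validity rule", {
  n <- 35 * 100
  m <- matrix(1000, n, 4)
  m[1550, 2] <- NA   # one missing green frame in window 2
  sig <- channel_signal(m, fps = 100)
  segs <- segment_signal(sig)
  expect_length(segs, 3)
  expect_true(segs[[1]]$valid[["G"]])
  expect_false(segs[[2]]$valid[["G"]])
  expect_true(segs[[2]]$valid[["NIR"]])
  expect_length(segment_signal(channel_signal(matrix(1, 990, 4), 100)), 0)
})

test_that("preprocessing removes trends and low frequencies, keeps the passband", {
  fs <- 100; t <- (0:999) / fs
  ramp <- 5 + 3 * t
  expect_lt(max(abs(preprocess_segment(ramp, fs))) / 3, 1e-6)
  lo <- sin(2 * pi * 0.1 * t)
  y_lo <- preprocess_segment(lo, fs)
  mid <- 300:700
  expect_lt(20 * log10(max(abs(y_lo[mid]))), -20)   # > 20 dB attenuation
  hi <- sin(2 * pi * 1.2 * t)
  y_hi <- preprocess_segment(hi, fs)
  expect_gt(20 * log10(max(abs(y_hi[mid]))), -1)    # within 1 dB
  expect_error(preprocess_segment(rnorm(200), fs), "warm-up")
})

test_that("the zero-padded spectrum has the stated resolution and peaks", {
  fs <- 100
  x <- cos(2 * pi * 1.2 * (0:999) / fs)
  sp <- amplitude_spectrum(x, fs)
  expect_equal(sp$bin_bpm, 100 / 8192 * 60)
  expect_lt(abs(estimate_hr(sp) - 72), sp$bin_bpm + 1e-9)
  z <- amplitude_spectrum(numeric(1000), fs)
  expect_true(all(z$amplitude == 0))
  # dominant peak wins; ties break toward lower frequency
  two <- cos(2 * pi * 1.0 * (0:999) / fs) + 2 * cos(2 * pi * 1.5 * (0:999) / fs)
  expect_lt(abs(estimate_hr(amplitude_spectrum(two, fs)) - 90), sp$bin_bpm)
  # out-of-band tone: estimate stays inside the band
  hi <- cos(2 * pi * (250 / 60) * (0:999) / fs)
  expect_lte(estimate_hr(amplitude_spectrum(hi, fs)), 200)
})

test_that("SNR follows the band mask with closed-form values", {
  expect_equal(snr_band_mask(c(64, 118, 70), 60), c(TRUE, TRUE, FALSE))
  f <- seq(30, 200, by = 1)
  base <- list(freq_bpm = f, amplitude = rep(0, length(f)), bin_bpm = 1)
  class(base) <- "amplitude_spectrum"
  pim <- snr_band_mask(f, 60)
  eq <- base
  eq$amplitude[pim] <- sqrt(1 / sum(pim))
  eq$amplitude[!pim] <- sqrt(1 / sum(!pim))
  expect_equal(snr(eq, 60), 0)
  tenx <- base
  tenx$amplitude[pim] <- sqrt(10 / sum(pim))
  tenx$amplitude[!pim] <- sqrt(1 / sum(!pim))
  expect_equal(snr(tenx, 60), 10)
  # zero noise: capped
  pure <- base; pure$amplitude[pim] <- 1
  expect_equal(snr(pure, 60), 80)
  expect_error(snr(base, 250), "band")
})

test_that("SNR responds monotonically to noise and signal amplitude", {
  fs <- 100; t <- (0:999) / fs
  set.seed(3)
  noise <- rnorm(1000, 0, 0.3)
  mk <- function(a) amplitude_spectrum(
    preprocess_segment(a * cos(2 * pi * 1.2 * t) + noise, fs), fs)
  s1 <- snr(mk(1), 72); s2 <- snr(mk(2), 72)
  expect_gt(s2, s1)
  sp_clean <- amplitude_spectrum(preprocess_segment(cos(2 * pi * 1.2 * t), fs), fs)
  expect_gt(snr(sp_clean, 72), s1)
})

test_that("per-segment results combine validity, HR and SNR bookkeeping", {
  fs <- 40; n <- 25 * fs
  t <- (seq_len(n) - 1) / fs
  g <- 1000 + 10 * cos(2 * pi * 1.2 * t)
  m <- matrix(rep(g, 4), n, 4)
  m[430, 4] <- NA    # NIR dropout in segment 2
  res <- segment_results(channel_signal(m, fs), f_ref = 72,
                         config = ppg_config())
  expect_equal(max(res$segment), 2)     # trailing 5 s discarded
  g2 <- res[res$channel == "G", ]
  expect_true(all(g2$valid))
  expect_true(all(abs(g2$hr_bpm - 72) < 1))
  n2 <- res[res$channel == "NIR", ]
  expect_false(n2$valid[2])
  expect_true(is.na(n2$hr_bpm[2]))
  expect_gt(min(res$snr_db, na.rm = TRUE), 0)
})

test_that("scripted heart rates are recovered end to end from true masks", {
  for (hr in c(48, 72, 110)) {
    sc <- scene_script(duration = 30, fps = 30, resolution = c(40, 50),
                       pulse = list(hr_bpm = hr, amplitude = c(3, 10, 2, 8)),
                       noise_sd = 5, seed = 100 + hr)
    v <- render_video_pair(sc)
    masks <- lapply(seq_len(v$n_frames), function(k) v$truth$mask_rgb(k))
    masks_n <- lapply(seq_len(v$n_frames), function(k) v$truth$mask_nir(k))
    sig <- extract_signals(v, masks, masks_n)
    res <- segment_results(sig, f_ref = hr, config = ppg_config())
    gg <- res[res$channel == "G", ]
    expect_true(all(abs(gg$hr_bpm - hr) <= 30 / 8192 * 60 + 1e-9),
                info = paste("hr", hr))
  }
})
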