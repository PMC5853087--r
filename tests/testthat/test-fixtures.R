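test_that("corpus generation is seeded, separable, and validates counts", {
  a <- generate_skin_corpus(1000, 1000, seed = 1)
  b <- generate_skin_corpus(1000, 1000, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_skin_corpus(1000, 1000, seed = 2)))
  expect_error(generate_skin_corpus(0, 10), "positive")
  expect_error(generate_skin_corpus(10, -1), "positive")

  # a model trained on the corpus classifies held-out skin draws well
  model <- cached_skin_model()
  held <- generate_skin_corpus(4900, 4900, seed = 99)
  tpr <- mean(classify_skin(array(held$skin, c(70, 70, 3)), model))
  fpr <- mean(classify_skin(array(held$nonskin, c(70, 70, 3)), model))
  expect_gt(tpr, 0.9)
  expect_lt(fpr, 0.1)
})

test_that("rendered videos are deterministic with the scripted frame count", {
  sc <- scene_script(duration = 0.5, fps = 20, resolution = c(40, 50),
                     seed = 3)
  v1 <- render_video_pair(sc)
  v2 <- render_video_pair(sc)
  expect_equal(v1$n_frames, 10)
  expect_identical(v1$frame(4), v2$frame(4))
  expect_equal(render_video_pair(scene_script(duration = 30, fps = 100,
                                              resolution = c(20, 20)))$n_frames,
               3000)
})

test_that("static scripts give identical frames; pulse appears at the scripted rate", {
  sc0 <- scene_script(duration = 0.3, fps = 20, resolution = c(40, 50),
                      pulse = list(hr_bpm = 72, amplitude = c(0, 0, 0, 0)),
                      noise_sd = 0, seed = 5)
  v0 <- render_video_pair(sc0)
  expect_identical(v0$frame(1), v0$frame(6))

  # spectral peak of the true-mask mean green trace at the scripted HR
  sc <- scene_script(duration = 20, fps = 20, resolution = c(40, 50),
                     pulse = list(hr_bpm = 72, amplitude = c(3, 10, 2, 8)),
                     noise_sd = 0, seed = 5)
  v <- render_video_pair(sc)
  gt <- v$truth$mask_rgb(1)
  g <- vapply(seq_len(v$n_frames),
              function(k) mean(v$frame(k)$rgb[, , 2][gt]), numeric(1))
  sp <- amplitude_spectrum(g - mean(g), fps = 20)
  expect_lt(abs(estimate_hr(sp) - 72), sp$bin_bpm + 1e-9)

  # rendered pulsatile excursion stays within the scripted bound
  expect_lte(max(g) - min(g), 2 * 10 + 1e-6)
  expect_error(scene_script(pulse = list(hr_bpm = 72,
                                         amplitude = c(3, 20, 2, 8))),
               "bound")
})

test_that("NIR ground truth is the RGB mask translated by the viewpoint offset", {
  sc <- scene_script(duration = 0.1, fps = 20, resolution = c(40, 60),
                     nir_offset = c(-7, 4), seed = 9)
  v <- render_video_pair(sc)
  m <- v$truth$mask_rgb(1)
  mn <- v$truth$mask_nir(1)
  h <- nrow(m); w <- ncol(m)
  shifted <- matrix(FALSE, h, w)
  shifted[(1 + 4):h, 1:(w - 7)] <- m[1:(h - 4), (1 + 7):w]
  expect_identical(mn, shifted)
})

test_that("events outside the recording are rejected and occlusions blank the truth", {
  expect_error(scene_script(duration = 10,
                            events = list(list(type = "occlusion", start = 9,
                                               end = 11, color = c(0, 0, 0),
                                               nir = 0))),
               "duration")
  expect_error(scene_script(events = list(list(type = "nonsense", start = 1))),
               "unknown")
  sc <- scene_script(duration = 1, fps = 20, resolution = c(40, 50), seed = 2,
                     events = list(list(type = "occlusion", start = 0.25,
                                        end = 0.5, color = c(60, 60, 60),
                                        nir = 60, extent = "full")))
  v <- render_video_pair(sc)
  expect_true(any(v$truth$mask_rgb(2)))
  expect_false(any(v$truth$mask_rgb(8)))   # t = 0.35 s, occluded
  expect_true(all(v$frame(8)$rgb == 60))
  expect_true(any(v$truth$mask_rgb(12)))   # t = 0.55 s, past the occlusion
})

test_that("video pairs round-trip through PNG frame directories", {
  dir <- withr::local_tempdir()
  sc <- scene_script(duration = 0.15, fps = 20, resolution = c(32, 40),
                     seed = 4)
  v <- render_video_pair(sc)
  write_video_pair(v, dir)
  v2 <- read_video_pair(dir)
  expect_equal(v2$n_frames, v$n_frames)
  expect_equal(v2$fps, v$fps)
  f1 <- v$frame(2); f2 <- v2$frame(2)
  # 16-bit quantization of the 12-bit scale: error below one 12-bit unit
  expect_lt(max(abs(f1$rgb - f2$rgb)), 0.5)
  expect_lt(max(abs(f1$nir - f2$nir)), 0.5)
  expect_identical(v2$truth$mask_rgb(2), v$truth$mask_rgb(2))
  expect_equal(v2$truth$f_ref_bpm, 72)
})
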