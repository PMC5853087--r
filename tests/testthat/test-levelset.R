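test_that("texture is the 5x5 neighbourhood standard deviation", {
  expect_true(all(compute_texture(matrix(7, 10, 10)) == 0))
  set.seed(1)
  m <- matrix(rnorm(81, 100, 20), 9, 9)
  J <- compute_texture(m)
  expect_equal(J[5, 5], sd(m[3:7, 3:7]))
  expect_equal(J[4, 6], sd(m[2:6, 4:8]))
  expect_error(compute_texture(matrix(1, 3, 3)), "5x5")
  # J_RGB is the arithmetic mean of the single-channel textures
  arr <- array(rnorm(300, 500, 50), c(10, 10, 3))
  fs <- feature_stack_rgb(arr)
  expect_equal(fs$J_RGB,
               (compute_texture(arr[, , 1]) + compute_texture(arr[, , 2]) +
                  compute_texture(arr[, , 3])) / 3)
})

test_that("init_phi builds an inside-positive signed distance field", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  st <- init_phi(m)
  expect_identical(level_set_mask(st), m)
  disc <- disc_mask(41, 41, 21, 21, 12)
  std <- init_phi(disc)
  expect_equal(std$phi[21, 21], 12, tolerance = 1)
  expect_identical(level_set_mask(std), disc)
  expect_error(init_phi(matrix(FALSE, 5, 5)), "empty")
  expect_error(init_phi(matrix(TRUE, 5, 5)), "empty|full")
})

test_that("region statistics are floored, symmetric, and match hand values", {
  img <- matrix(c(1, 3, 10, 14), 2, 2)
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  st <- region_stats(list(I = img), m)
  expect_equal(st$mu[[1, 1]], 2)
  expect_equal(st$mu[[2, 1]], 12)
  expect_equal(st$sigma[[1, 1]], sd(c(1, 3)))
  sw <- region_stats(list(I = img), !m)
  expect_equal(sw$mu[[1, 1]], st$mu[[2, 1]])
  expect_equal(sw$sigma[[2, 1]], st$sigma[[1, 1]])
  # constant region hits the floor
  cst <- region_stats(list(I = matrix(c(7, 7, 1, 2), 2, 2)), m)
  expect_equal(cst$mu[[1, 1]], 7)
  expect_equal(cst$sigma[[1, 1]], 1.0)
  expect_error(region_stats(list(I = img), matrix(c(TRUE, rep(FALSE, 3)), 2)),
               "degenerate")
})

test_that("homogeneity force matches the closed-form log-Gaussian ratio", {
  f <- matrix(90, 1, 1)
  st <- list(mu = matrix(c(100, 50), 2, 1), sigma = matrix(c(10, 10), 2, 1))
  expect_equal(homogeneity_force(list(I = f), st)[1, 1],
               (-(90 - 100)^2 + (90 - 50)^2) / (2 * 10^2))  # 7.5
  # identical stats in both regions: zero field
  st0 <- list(mu = matrix(c(75, 75), 2, 1), sigma = matrix(c(9, 9), 2, 1))
  expect_equal(homogeneity_force(list(I = f), st0)[1, 1], 0)
  # equidistant feature with equal sigmas: zero by symmetry
  expect_equal(homogeneity_force(list(I = matrix(75, 1, 1)), st)[1, 1], 0)
})

test_that("curvature is zero on planes, -1/r on discs, and rotates with the image", {
  h <- 41; w <- 41
  plane <- matrix(seq_len(w), h, w, byrow = TRUE) - 20.5
  kp <- curvature_force(plane)
  expect_lt(max(abs(kp[5:36, 5:36])), 1e-6)
  # analytic signed-distance disc: curvature -1/r on the contour
  rr <- matrix(seq_len(81), 81, 81)
  phi <- 25 - sqrt((rr - 41)^2 + (t(rr) - 41)^2)
  k <- curvature_force(phi)
  on_contour <- abs(phi) <= 1
  expect_true(all(abs(k[on_contour] * 25 + 1) < 0.1))   # within 10%
  # 90-degree rotation commutes with the operator
  blob <- disc_mask(61, 61, 25, 35, 14)
  phib <- init_phi(blob)$phi
  rot <- function(m) t(m[nrow(m):1, ])
  expect_equal(curvature_force(rot(phib))[10:50, 10:50],
               rot(curvature_force(phib))[10:50, 10:50], tolerance = 1e-9)
})

test_that("a maximum-likelihood labeling is a fixed point of the evolution", {
  fx <- two_gaussian_disc(seed = 4)
  ml <- dnorm(fx$img, 3000, 30, log = TRUE) > dnorm(fx$img, 500, 30, log = TRUE)
  stats_f <- list(mu = matrix(c(3000, 500), 2, 1),
                  sigma = matrix(c(30, 30), 2, 1))
  st <- evolve(init_phi(ml), list(I = fx$img),
               level_set_params(length(fx$img), max_iters = 5, nu = 0,
                                early_stop_delta = 1),
               stats = stats_f)
  expect_true(st$converged)
  expect_identical(level_set_mask(st), ml)
})

test_that("evolution recovers a noisy disc from a half-disc initialization", {
  fx <- two_gaussian_disc(seed = 2)
  half <- fx$disc & col(fx$img) <= 32
  feats <- list(I = fx$img, J = compute_texture(fx$img))
  st <- evolve(init_phi(half), feats,
               level_set_params(length(fx$img), max_iters = 300,
                                early_stop_delta = 1), trace_sdf = TRUE)
  expect_equal(st$status, "ok")
  expect_gt(dice(level_set_mask(st), fx$disc), 0.99)
  # signed-distance maintenance across every reinitialization
  expect_gte(st$sdf_slope_range[1], 0.9)
  expect_lte(st$sdf_slope_range[2], 1.1)
})

test_that("stronger curvature weighting yields shorter contours", {
  h <- 64; w <- 64
  contour_len <- function(m)
    sum(m != rbind(m[-1, ], m[nrow(m), ])) +
    sum(m != cbind(m[, -1], m[, ncol(m)]))
  for (seed in c(8, 15)) {
    set.seed(seed)
    disc <- disc_mask(h, w, 32, 32, 18)
    img <- matrix(rnorm(h * w, 1000, 200), h, w)
    img[disc] <- rnorm(sum(disc), 1450, 200)
    lens <- vapply(c(0, 0.3, 1), function(nu) {
      st <- evolve(init_phi(disc), list(I = img),
                   level_set_params(h * w, max_iters = 80, nu = nu,
                                    early_stop_delta = 1))
      contour_len(level_set_mask(st))
    }, numeric(1))
    expect_true(all(diff(lens) <= 0))
    expect_lt(lens[3], lens[1])
  }
})

test_that("the segmentation supports disconnected regions and holes", {
  set.seed(2)
  h <- 64; w <- 96
  b1 <- disc_mask(h, w, 32, 24, 14)
  b2 <- disc_mask(h, w, 32, 70, 14)
  hole <- disc_mask(h, w, 32, 24, 5)
  img <- matrix(rnorm(h * w, 500, 30), h, w)
  img[b1 | b2] <- rnorm(sum(b1 | b2), 3000, 30)
  img[hole] <- rnorm(sum(hole), 500, 30)
  st <- evolve(init_phi(img > 1750),
               list(I = img, J = compute_texture(img)),
               level_set_params(h * w, max_iters = 300, early_stop_delta = 1))
  m <- level_set_mask(st)
  expect_equal(max(EBImage::bwlabel(m * 1)), 2)            # two components
  expect_equal(max(EBImage::bwlabel((1 - m) * 1)) - 1, 1)  # one hole
})

test_that("degenerate evolutions are signalled, not raised", {
  # statistics that reject every pixel from a region collapse (or fill)
  # the contour; the caller gets a status, not an error
  img <- matrix(100, 48, 48)
  init <- init_phi(disc_mask(48, 48, 24, 24, 10))
  prm <- level_set_params(48 * 48, max_iters = 200, nu = 0,
                          early_stop_delta = 1)
  vanish <- evolve(init, list(I = img), prm,
                   stats = list(mu = matrix(c(1000, 100), 2, 1),
                                sigma = matrix(c(10, 10), 2, 1)))
  expect_equal(vanish$status, "degenerate")
  fill <- evolve(init, list(I = img), prm,
                 stats = list(mu = matrix(c(100, 1000), 2, 1),
                              sigma = matrix(c(10, 10), 2, 1)))
  expect_equal(fill$status, "degenerate")
})
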