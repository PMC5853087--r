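#' Local 5x5 texture image
#'
#' Computes, for every pixel, the sample standard deviation of its 5x5
#' neighbourhood (replicate-padded at the borders). The texture image is
#' used as an additional feature during segmentation so that regions are
#' homogeneous not only in intensity but also in surface structure.
#'
#' @param channel_image numeric matrix, a single image channel.
#' @return numeric matrix of the same dimensions with non-negative values.
#' @export
#' @examples
#' J <- compute_texture(matrix(runif(100), 10, 10))
compute_texture <- function(channel_image) {
  if (!is.matrix(channel_image))
    stop("`channel_image` must be a single-channel matrix")
  if (nrow(channel_image) < 5 || ncol(channel_image) < 5)
    stop("image must be at least 5x5 pixels")
  n <- 25
  s1 <- box5_sum(channel_image)
  s2 <- box5_sum(channel_image^2)
  v <- (s2 - s1^2 / n) / (n - 1)
  sqrt(pmax(v, 0))
}

#' Feature stacks for segmentation
#'
#' For an RGB frame the feature vector is `(I_R, I_G, I_B, J_RGB)` where
#' `J_RGB` is the mean of the per-channel texture images; for an NIR frame
#' it is `(I_N, J_N)`.
#'
#' @param rgb numeric array `h x w x 3` on the 12-bit scale.
#' @return list of feature matrices.
#' @export
feature_stack_rgb <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  jr <- compute_texture(rgb[, , 1])
  jg <- compute_texture(rgb[, , 2])
  jb <- compute_texture(rgb[, , 3])
  list(I_R = rgb[, , 1], I_G = rgb[, , 2], I_B = rgb[, , 3],
       J_RGB = (jr + jg + jb) / 3)
}

#' @rdname feature_stack_rgb
#' @param nir numeric matrix on the 12-bit scale.
#' @export
feature_stack_nir <- function(nir) {
  stopifnot(is.matrix(nir))
  list(I_N = nir, J_N = compute_texture(nir))
}

#' Level-set parameters
#'
#' Bundles the tunables of the two-phase level-set evolution. The
#' curvature weight follows the size-adaptive rule `nu = 0.001 * |Omega|^0.7`
#' with `|Omega|` the number of grid pixels, unless `nu` is given.
#'
#' @param n_pixels number of pixels of the image grid (used for `nu`).
#' @param max_iters iteration budget (300 for RGB detection, 100 for NIR
#'   detection, 50 during tracking).
#' @param early_stop_delta stop when the region size changes by fewer than
#'   this many pixels between iterations (default 50).
#' @param nu optional explicit curvature weight.
#' @param epsilon smoothing width (pixels) of the regularized delta
#'   function.
#' @param sigma_floor lower bound on region standard deviations.
#' @param step_max largest allowed per-pixel update of `Phi` per
#'   iteration, in pixels.
#' @param force_scale scale (in log-likelihood units) of the bounded
#'   force: the total force is passed through `tanh(f / force_scale)`
#'   before the Euler step. Log-Gaussian likelihood ratios span many
#'   orders of magnitude across an image; bounding them keeps the
#'   explicit update well-conditioned so weakly and strongly attracted
#'   pixels both reach their preferred region.
#' @return list of class `levelset_params`.
#' @export
level_set_params <- function(n_pixels, max_iters = 300L,
                             early_stop_delta = 50, nu = NULL,
                             epsilon = 1.5, sigma_floor = 1.0,
                             step_max = 1.2, force_scale = 1.0) {
  stopifnot(is_single_number(n_pixels), n_pixels > 0, max_iters >= 1)
  if (is.null(nu)) nu <- 0.001 * n_pixels^0.7
  structure(list(nu = nu, max_iters = as.integer(max_iters),
                 early_stop_delta = early_stop_delta, epsilon = epsilon,
                 sigma_floor = sigma_floor, step_max = step_max,
                 force_scale = force_scale),
            class = "levelset_params")
}

#' Initialize a level-set state from a binary mask
#'
#' `Phi` is a signed Euclidean distance field: positive inside the mask
#' (region `Omega_1`), negative outside, with the zero level between the
#' two. Pixel centres adjacent to the boundary sit at +/- 0.5 so that the
#' discrete gradient magnitude is ~1 across the contour.
#'
#' @param mask logical or 0/1 matrix; must be neither empty nor full.
#' @return list of class `levelset_state` with elements `phi`,
#'   `iterations`, `converged`, `status` (`"ok"` or `"degenerate"`).
#' @export
init_phi <- function(mask) {
  m <- mask_as_logical(mask)
  a <- sum(m)
  if (a == 0 || a == length(m)) stop("mask must be neither empty nor full")
  structure(list(phi = signed_distance(m), iterations = 0L,
                 converged = FALSE, status = "ok"),
            class = "levelset_state")
}

#' @noRd
mask_as_logical <- function(mask) {
  if (is.logical(mask)) return(mask)
  if (is.numeric(mask)) return(mask > 0)
  stop("mask must be logical or numeric")
}

# Signed Euclidean distance to the region boundary, positive inside.
#' @noRd
signed_distance <- function(mask) {
  storage.mode(mask) <- "double"
  d <- EBImage::distmap(mask) - EBImage::distmap(1 - mask)
  # shift half a pixel so boundary-adjacent centres are at +/-0.5
  d - 0.5 * sign(d)
}

#' Current foreground mask of a level-set state
#' @param state a `levelset_state`.
#' @return logical matrix `Phi > 0`.
#' @export
level_set_mask <- function(state) state$phi > 0

#' Regional feature statistics
#'
#' Mean and standard deviation of every feature inside (`Omega_1`,
#' `Phi > 0`) and outside (`Omega_2`, `Phi <= 0`) the contour. Standard
#' deviations are floored at `sigma_floor` so the Gaussian region model
#' stays well-defined on constant regions.
#'
#' @param features list of feature matrices (see [feature_stack_rgb()]).
#' @param state a `levelset_state` (or a logical mask).
#' @param sigma_floor lower bound for the standard deviations.
#' @return list with `mu` and `sigma`, each a `2 x M` matrix (rows:
#'   region 1, region 2), and `n` the two region sizes.
#' @export
region_stats <- function(features, state, sigma_floor = 1.0) {
  m <- if (inherits(state, "levelset_state")) level_set_mask(state)
       else mask_as_logical(state)
  n1 <- sum(m); n2 <- length(m) - n1
  if (n1 < 2 || n2 < 2)
    stop("degenerate segmentation: a region has fewer than 2 pixels")
  M <- length(features)
  mu <- sig <- matrix(0, 2, M, dimnames = list(NULL, names(features)))
  for (j in seq_len(M)) {
    f <- features[[j]]
    x1 <- f[m]; x2 <- f[!m]
    mu[1, j] <- mean(x1); mu[2, j] <- mean(x2)
    sig[1, j] <- max(stats::sd(x1), sigma_floor)
    sig[2, j] <- max(stats::sd(x2), sigma_floor)
  }
  list(mu = mu, sigma = sig, n = c(n1, n2))
}

#' Homogeneity force field
#'
#' The regional competition term: at every pixel the sum over features of
#' `log(p_1j(F_j) / p_2j(F_j))` where `p_ij` is the Gaussian with the
#' region's mean and standard deviation. Positive values pull a pixel
#' into `Omega_1`.
#'
#' @param features list of feature matrices.
#' @param stats output of [region_stats()].
#' @return numeric matrix.
#' @export
homogeneity_force <- function(features, stats) {
  M <- length(features)
  out <- 0
  for (j in seq_len(M)) {
    f <- features[[j]]
    m1 <- stats$mu[1, j]; m2 <- stats$mu[2, j]
    s1 <- stats$sigma[1, j]; s2 <- stats$sigma[2, j]
    out <- out + (log(s2 / s1) +
                    (f - m2)^2 / (2 * s2^2) - (f - m1)^2 / (2 * s1^2))
  }
  out
}

#' @noRd
shift_rows <- function(m, by) {   # by = +1: value from row above
  h <- nrow(m)
  if (by == 1) m[c(1, 1:(h - 1)), , drop = FALSE]
  else m[c(2:h, h), , drop = FALSE]
}

#' @noRd
shift_cols <- function(m, by) {
  w <- ncol(m)
  if (by == 1) m[, c(1, 1:(w - 1)), drop = FALSE]
  else m[, c(2:w, w), drop = FALSE]
}

#' Curvature force field
#'
#' Mean curvature `div(grad(Phi) / |grad(Phi)|)` computed with central
#' differences and replicate boundaries. With the inside-positive
#' convention a convex `Omega_1` boundary has negative curvature, so the
#' term alone shrinks contours (smoothing).
#'
#' @param state a `levelset_state` or a `Phi` matrix.
#' @param grad_eps small constant regularizing the gradient magnitude.
#' @return numeric matrix.
#' @export
curvature_force <- function(state, grad_eps = 1e-8) {
  phi <- if (inherits(state, "levelset_state")) state$phi else state
  px <- (shift_cols(phi, -1) - shift_cols(phi, 1)) / 2
  py <- (shift_rows(phi, -1) - shift_rows(phi, 1)) / 2
  pxx <- shift_cols(phi, -1) - 2 * phi + shift_cols(phi, 1)
  pyy <- shift_rows(phi, -1) - 2 * phi + shift_rows(phi, 1)
  pxy <- (shift_rows(shift_cols(phi, -1), -1) - shift_rows(shift_cols(phi, -1), 1) -
          shift_rows(shift_cols(phi, 1), -1) + shift_rows(shift_cols(phi, 1), 1)) / 4
  g2 <- px^2 + py^2
  (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) / (g2^1.5 + grad_eps)
}

#' @noRd
smooth_delta <- function(phi, epsilon) epsilon / (pi * (epsilon^2 + phi^2))

#' Discrete unit-slope diagnostic of a signed distance field
#'
#' For every pixel, the largest descent slope of `Phi` over its 5x5
#' neighbourhood (`|Phi(x) - Phi(n)| / |x - n|`). For a field that is a
#' true signed Euclidean distance this directional-derivative magnitude
#' is 1 up to lattice discretization; values far from 1 in a band
#' around the contour indicate a degraded field. (Axis-aligned central
#' differences are not a meaningful check here: a lattice distance
#' field has kinks at pixel scale wherever two boundary points are
#' equidistant. The 5x5 stencil includes enough directions that the
#' steepest-descent direction is approximated within ~13 degrees.)
#'
#' @param phi a `Phi` matrix or `levelset_state`.
#' @return matrix of per-pixel maximum neighbour slopes.
#' @export
sdf_slope <- function(phi) {
  if (inherits(phi, "levelset_state")) phi <- phi$phi
  h <- nrow(phi); w <- ncol(phi)
  best <- matrix(-Inf, h, w)
  for (dr in -2:2) for (dc in -2:2) {
    if (dr == 0 && dc == 0) next
    ri <- clip01(seq_len(h) + dr, 1, h)
    ci <- clip01(seq_len(w) + dc, 1, w)
    best <- pmax(best, abs(phi - phi[ri, ci]) / sqrt(dr^2 + dc^2))
  }
  best
}

#' Evolve a two-phase level set
#'
#' Gradient descent `dPhi/dt = H'(Phi) * [homogeneity + nu * curvature]`
#' solved by forward Euler. After every iteration `Phi` is reinitialized
#' to a signed distance field of the current region, and region
#' statistics are recomputed (unless `stats` is supplied, which freezes
#' them). Evolution stops at `max_iters` or as soon as the region size
#' changes by fewer than `early_stop_delta` pixels between iterations.
#'
#' Two numerical safeguards make the explicit scheme robust. The total
#' force is bounded by `tanh(f / force_scale)` before the update, since
#' log-likelihood ratios vary over orders of magnitude across an image
#' and an unbounded force would stall all but the most attracted pixels
#' once the step is normalized. The time step is then adaptive: the
#' update field is rescaled so its largest magnitude is `step_max`
#' pixels. `step_max` must exceed 1 for the contour to be able to move,
#' because boundary-adjacent pixels of an exactly redistanced field sit
#' at `|Phi| = 0.5 ... 1.5` and change region only when the update
#' crosses zero.
#'
#' @param state a `levelset_state` from [init_phi()].
#' @param features list of feature matrices on the same grid.
#' @param params a `levelset_params` object.
#' @param stats optional frozen [region_stats()]; if `NULL` (default)
#'   statistics are recomputed every iteration.
#' @param trace_sdf if `TRUE`, record the range of the [sdf_slope()]
#'   diagnostic within 3 px of the contour after every
#'   reinitialization (returned as `sdf_slope_range`).
#' @return updated `levelset_state`; `status` is `"degenerate"` if
#'   `Omega_1` vanished or filled the grid (callers should redetect).
#' @export
evolve <- function(state, features, params, stats = NULL,
                   trace_sdf = FALSE) {
  stopifnot(inherits(state, "levelset_state"),
            inherits(params, "levelset_params"))
  phi <- state$phi
  area_prev <- sum(phi > 0)
  converged <- FALSE
  it <- 0L
  slope_rng <- c(Inf, -Inf)
  note_slope <- function(p) {
    band <- abs(p) <= 3
    if (any(band)) {
      s <- sdf_slope(p)[band]
      slope_rng <<- c(min(slope_rng[1], min(s)), max(slope_rng[2], max(s)))
    }
  }
  if (trace_sdf) note_slope(phi)
  for (it in seq_len(params$max_iters)) {
    m <- phi > 0
    n1 <- sum(m)
    if (n1 < 2 || n1 > length(m) - 2) {
      return(structure(list(phi = phi, iterations = it - 1L,
                            converged = FALSE, status = "degenerate"),
                       class = "levelset_state"))
    }
    st <- if (is.null(stats))
      region_stats(features, m, sigma_floor = params$sigma_floor) else stats
    f <- homogeneity_force(features, st)
    if (params$nu != 0) f <- f + params$nu * curvature_force(phi)
    upd <- smooth_delta(phi, params$epsilon) * tanh(f / params$force_scale)
    mx <- max(abs(upd))
    if (mx == 0) { converged <- TRUE; break }
    phi <- phi + (params$step_max / mx) * upd
    mask <- phi > 0
    area <- sum(mask)
    if (area == 0 || area == length(mask)) {
      return(structure(list(phi = phi, iterations = it,
                            converged = FALSE, status = "degenerate"),
                       class = "levelset_state"))
    }
    phi <- signed_distance(mask)
    if (trace_sdf) note_slope(phi)
    if (abs(area - area_prev) < params$early_stop_delta) {
      converged <- TRUE
      area_prev <- area
      break
    }
    area_prev <- area
  }
  out <- structure(list(phi = phi, iterations = it, converged = converged,
                        status = "ok"),
                   class = "levelset_state")
  if (trace_sdf) out$sdf_slope_range <- slope_rng
  out
}
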