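#' Detect ROIs in a synchronized RGB + NIR frame pair
#'
#' One pass of the ROI detector: (1) intensity-adjust the RGB frame and
#' classify skin pixels; (2) refine the skin mask by level-set
#' segmentation on the raw RGB features `(I_R, I_G, I_B, J_RGB)` with an
#' iteration budget of 300; (3) transfer the RGB ROI to the NIR grid by
#' mean-adjusted block matching; (4) refine on the NIR features
#' `(I_N, J_N)` with a budget of 100 iterations. The two streams are
#' otherwise independent: a failed registration only marks the NIR
#' stream as skinless while the RGB result stands.
#'
#' @param frame_pair list with `rgb` (`h x w x 3` array) and `nir`
#'   (`h x w` matrix) on the 12-bit scale.
#' @param skin_model a [build_skin_model()] result.
#' @param config a [ppg_config()]; segmentation, classification and
#'   registration tunables are taken from it.
#' @return list of class `detector_result`: `roi_rgb`, `roi_nir`
#'   (logical masks), `status_rgb`, `status_nir`
#'   (`"ok" | "no_skin" | "degenerate"`), and `diagnostics` (iteration
#'   counts and region sizes). Degenerate segmentations are reported in
#'   the status, never raised.
#' @export
detect <- function(frame_pair, skin_model, config = ppg_config()) {
  rgb <- frame_pair$rgb; nir <- frame_pair$nir
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  empty <- matrix(FALSE, h, w)
  diag <- list(iters_rgb = 0L, iters_nir = 0L,
               n_skin = 0L, n_roi_rgb = 0L, n_reg = 0L, n_roi_nir = 0L)
  res <- list(roi_rgb = empty, roi_nir = empty,
              status_rgb = "no_skin", status_nir = "no_skin",
              diagnostics = diag)
  class(res) <- "detector_result"

  adj <- adjust_intensity(rgb, saturation = config$adjust_saturation)
  skn <- classify_skin(adj, skin_model, theta = config$theta)
  res$diagnostics$n_skin <- sum(skn)
  if (sum(skn) < config$min_roi_px || sum(skn) == length(skn)) return(res)

  feats <- feature_stack_rgb(rgb)
  nu <- config$nu_coef * (h * w)^config$nu_exp
  # detection runs its full budget (or to a standstill); the 50-px early
  # stop is a tracking device where inter-frame changes are minor
  p_rgb <- level_set_params(h * w, max_iters = config$iters_detect_rgb,
                            early_stop_delta = 1, nu = nu,
                            epsilon = config$epsilon,
                            sigma_floor = config$sigma_floor)
  st <- evolve(init_phi(skn), feats, p_rgb)
  res$diagnostics$iters_rgb <- st$iterations
  if (st$status != "ok") { res$status_rgb <- "degenerate"; return(res) }
  roi <- level_set_mask(st)
  res$diagnostics$n_roi_rgb <- sum(roi)
  if (sum(roi) < config$min_roi_px) return(res)
  res$roi_rgb <- roi
  res$status_rgb <- "ok"

  bm <- block_match_params(stride = config$block_stride,
                           dx_range = config$search_dx,
                           dy_range = config$search_dy)
  reg <- register_roi(rgb[, , 2], nir, roi, bm)
  res$diagnostics$n_reg <- sum(reg)
  if (sum(reg) < config$min_roi_px || sum(reg) == length(reg)) return(res)

  nf <- feature_stack_nir(nir)
  p_nir <- level_set_params(h * w, max_iters = config$iters_detect_nir,
                            early_stop_delta = 1, nu = nu,
                            epsilon = config$epsilon,
                            sigma_floor = config$sigma_floor)
  stn <- evolve(init_phi(reg), nf, p_nir)
  res$diagnostics$iters_nir <- stn$iterations
  if (stn$status != "ok") { res$status_nir <- "degenerate"; return(res) }
  roin <- level_set_mask(stn)
  res$diagnostics$n_roi_nir <- sum(roin)
  if (sum(roin) < config$min_roi_px) return(res)
  res$roi_nir <- roin
  res$status_nir <- "ok"
  res
}
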