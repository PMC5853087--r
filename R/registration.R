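#' Block-matching parameters
#'
#' The RGB-to-NIR transfer uses overlapping 5x5 blocks of the green
#' channel and an asymmetric integer search window that encodes the
#' a-priori camera geometry: `d_x` in `[-60, 0]`, `d_y` in `[0, 10]`
#' pixels (both inclusive; `d_x` is a column shift, `d_y` a row shift).
#'
#' @param stride spacing between evaluated block centres (1 = fully
#'   overlapping blocks; larger values trade accuracy for speed).
#' @param dx_range,dy_range inclusive integer displacement bounds.
#' @return list of class `blockmatch_params`.
#' @export
block_match_params <- function(stride = 1L, dx_range = c(-60L, 0L),
                               dy_range = c(0L, 10L)) {
  stopifnot(stride >= 1, dx_range[1] <= dx_range[2],
            dy_range[1] <= dy_range[2])
  structure(list(block = 5L, stride = as.integer(stride),
                 dx_range = as.integer(dx_range),
                 dy_range = as.integer(dy_range)),
            class = "blockmatch_params")
}

#' Mean-adjusted mean squared error between two blocks
#'
#' Both blocks are centred on their own mean before the squared
#' differences are summed, which removes any constant intensity offset
#' between the differently illuminated RGB and NIR views.
#'
#' @param block_g,block_n numeric matrices of identical shape.
#' @return non-negative scalar.
#' @export
#' @examples
#' mean_adjusted_mse(matrix(1:4, 2), matrix(c(1, 2, 3, 8), 2))  # 12
mean_adjusted_mse <- function(block_g, block_n) {
  if (!identical(dim(block_g), dim(block_n)))
    stop("blocks must have identical shapes")
  d <- (block_g - mean(block_g)) - (block_n - mean(block_n))
  sum(d^2)
}

# Displacements in tie-break order: smallest |dx|+|dy| first, then by
# dy, then dx. The search keeps the first strict minimum, so ties
# resolve to the earliest displacement in this order.
#' @noRd
displacement_grid <- function(params) {
  g <- expand.grid(dx = params$dx_range[1]:params$dx_range[2],
                   dy = params$dy_range[1]:params$dy_range[2])
  g[order(abs(g$dx) + abs(g$dy), g$dy, g$dx), , drop = FALSE]
}

#' Transfer an ROI to the NIR grid by block matching
#'
#' Every 5x5 block lying fully inside the ROI of the green channel is
#' matched against the NIR image over the inclusive displacement window;
#' the match minimizes the mean-adjusted MSE. The union of the displaced
#' block footprints forms the registered region, which initializes the
#' NIR segmentation. Blocks are matched independently; candidate
#' displacements that push a block outside the NIR image are skipped for
#' that block.
#'
#' @param green_channel,nir_channel numeric matrices of equal size.
#' @param roi logical ROI mask on the green grid (non-empty).
#' @param params a [block_match_params()].
#' @param details if `TRUE`, also return the per-block displacements.
#' @return logical mask on the NIR grid (empty if no block fits inside
#'   the ROI -- callers treat that as a failed registration); with
#'   `details = TRUE` a list `(mask, displacements)` where
#'   `displacements` is a data frame `(row, col, dx, dy, mse)`.
#' @export
register_roi <- function(green_channel, nir_channel, roi,
                         params = block_match_params(), details = FALSE) {
  stopifnot(identical(dim(green_channel), dim(nir_channel)))
  roi <- mask_as_logical(roi)
  stopifnot(identical(dim(roi), dim(green_channel)))
  if (!any(roi)) stop("roi is empty")
  h <- nrow(green_channel); w <- ncol(green_channel)

  interior <- matrix(FALSE, h, w)
  if (h >= 5 && w >= 5) interior[3:(h - 2), 3:(w - 2)] <- TRUE
  centers <- (box5_sum(roi * 1) >= 25 - 1e-9) & interior
  if (params$stride > 1) {
    keep <- matrix(FALSE, h, w)
    keep[seq(3, h, by = params$stride), seq(3, w, by = params$stride)] <- TRUE
    centers <- centers & keep
  }
  empty <- matrix(FALSE, h, w)
  if (!any(centers)) {
    if (details) return(list(mask = empty,
                             displacements = data.frame(row = integer(),
                                                        col = integer(),
                                                        dx = integer(),
                                                        dy = integer(),
                                                        mse = numeric())))
    return(empty)
  }

  grid <- displacement_grid(params)
  best <- matrix(Inf, h, w)
  bdx <- bdy <- matrix(NA_integer_, h, w)
  for (i in seq_len(nrow(grid))) {
    dx <- grid$dx[i]; dy <- grid$dy[i]
    # centre (r,c) valid if the NIR block at (r+dy, c+dx) fits the image
    rlo <- max(3, 3 - dy); rhi <- min(h - 2, h - 2 - dy)
    clo <- max(3, 3 - dx); chi <- min(w - 2, w - 2 - dx)
    if (rlo > rhi || clo > chi) next
    ns <- shift_fill(nir_channel, -dy, -dx, 0)  # ns[r,c] = nir[r+dy, c+dx]
    D <- green_channel - ns
    cost <- box5_sum(D^2) - box5_sum(D)^2 / 25
    ok <- matrix(FALSE, h, w)
    ok[rlo:rhi, clo:chi] <- TRUE
    ok <- ok & centers & (cost < best)
    if (any(ok)) {
      best[ok] <- cost[ok]
      bdx[ok] <- dx; bdy[ok] <- dy
    }
  }

  found <- is.finite(best) & centers
  mask <- empty
  if (any(found)) {
    combos <- unique(data.frame(dx = bdx[found], dy = bdy[found]))
    for (i in seq_len(nrow(combos))) {
      sel <- found & !is.na(bdx) & bdx == combos$dx[i] & bdy == combos$dy[i]
      moved <- shift_fill(sel, combos$dy[i], combos$dx[i], FALSE)
      mask <- mask | (box5_sum(moved * 1) > 1e-9)
    }
  }
  if (!details) return(mask)
  idx <- which(found, arr.ind = TRUE)
  list(mask = mask,
       displacements = data.frame(row = idx[, 1], col = idx[, 2],
                                  dx = bdx[found], dy = bdy[found],
                                  mse = best[found]))
}
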