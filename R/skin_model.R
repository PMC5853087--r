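#' Build a histogram-based Bayesian skin model
#'
#' Two 3-D RGB histograms (one per class) are filled from labeled pixel
#' corpora and normalized by the total class counts, giving the
#' class-conditional densities `p(c | skin)` and `p(c | non-skin)`.
#' 12-bit values are mapped to `bins^3` color cells by uniform binning
#' (with the default 32 bins this is a right shift to a 7-bit channel
#' resolution).
#'
#' @param skin_pixels,nonskin_pixels numeric `n x 3` matrices of RGB
#'   triples on the `[0, scale_max]` intensity scale.
#' @param bins_per_channel number of histogram bins per channel.
#' @param theta decision threshold of the likelihood-ratio rule.
#' @param scale_max top of the intensity scale (4095 for 12-bit data).
#' @return object of class `skin_model` with the two count histograms,
#'   the normalized densities, and the classification threshold.
#' @export
#' @examples
#' corpus <- generate_skin_corpus(500, 500, seed = 1)
#' model <- build_skin_model(corpus$skin, corpus$nonskin)
build_skin_model <- function(skin_pixels, nonskin_pixels,
                             bins_per_channel = 32L, theta = 5,
                             scale_max = INTENSITY_MAX) {
  skin_pixels <- as_pixel_matrix(skin_pixels)
  nonskin_pixels <- as_pixel_matrix(nonskin_pixels)
  if (nrow(skin_pixels) == 0 || nrow(nonskin_pixels) == 0)
    stop("both class corpora must be non-empty")
  rng <- range(skin_pixels, nonskin_pixels)
  if (rng[1] < 0 || rng[2] > scale_max)
    stop("pixel values outside the [0, ", scale_max, "] intensity scale")
  stopifnot(is_single_number(theta), theta > 0)
  b <- as.integer(bins_per_channel)
  hs <- rgb_histogram(skin_pixels, b, scale_max)
  hn <- rgb_histogram(nonskin_pixels, b, scale_max)
  structure(list(hist_skin = hs, hist_nonskin = hn,
                 pdf_skin = hs / sum(hs), pdf_nonskin = hn / sum(hn),
                 bins_per_channel = b, theta = theta,
                 scale_max = scale_max),
            class = "skin_model")
}

#' @noRd
as_pixel_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("pixels must be an n x 3 RGB matrix")
  storage.mode(x) <- "double"
  x
}

#' @noRd
bin_index <- function(v, bins, scale_max) {
  pmin(bins - 1L, as.integer(floor(v / (scale_max + 1) * bins)))
}

#' @noRd
rgb_histogram <- function(px, bins, scale_max) {
  i <- bin_index(px[, 1], bins, scale_max)
  j <- bin_index(px[, 2], bins, scale_max)
  k <- bin_index(px[, 3], bins, scale_max)
  lin <- 1L + i + bins * (j + bins * k)
  array(tabulate(lin, nbins = bins^3), dim = rep(bins, 3))
}

#' Percentile contrast stretch
#'
#' Per-channel linear intensity adjustment mapping the lower/upper
#' saturation percentiles (default 1% and 99%) to the full scale and
#' clipping outside. Constant channels are returned unchanged. Applied
#' before skin classification to stabilize the classifier under varying
#' illumination; all other stages operate on raw intensities.
#'
#' @param image matrix or `h x w x c` array on the `[0, scale_max]` scale.
#' @param saturation fraction saturated at each end (0 maps min/max).
#' @param scale_max top of the intensity scale.
#' @return adjusted image of the same shape (not rounded).
#' @export
adjust_intensity <- function(image, saturation = 0.01,
                             scale_max = INTENSITY_MAX) {
  stopifnot(saturation >= 0, saturation < 0.5)
  stretch <- function(ch) {
    q <- stats::quantile(ch, c(saturation, 1 - saturation), names = FALSE)
    if (q[2] <= q[1]) return(ch)
    clip01((ch - q[1]) * scale_max / (q[2] - q[1]), 0, scale_max)
  }
  if (is.matrix(image)) return(stretch(image))
  if (length(dim(image)) == 3) {
    for (c in seq_len(dim(image)[3])) image[, , c] <- stretch(image[, , c])
    return(image)
  }
  stop("image must be a matrix or a 3-d array")
}

#' Classify skin pixels
#'
#' Applies the likelihood-ratio rule: a pixel with color `c` is skin if
#' `p(c | skin) / p(c | non-skin) >= theta`. Colors unseen in the
#' non-skin corpus but present in the skin corpus are skin; colors unseen
#' in both corpora are non-skin (conservative; the downstream
#' segmentation can recover under-detection). The image should be
#' intensity-adjusted (see [adjust_intensity()]) before classification.
#'
#' @param rgb_image numeric `h x w x 3` array on the model's scale.
#' @param model a `skin_model`.
#' @param theta optional threshold override (defaults to the model's).
#' @return logical `h x w` mask.
#' @export
classify_skin <- function(rgb_image, model, theta = NULL) {
  stopifnot(inherits(model, "skin_model"),
            length(dim(rgb_image)) == 3, dim(rgb_image)[3] == 3)
  if (max(rgb_image) > model$scale_max || min(rgb_image) < 0)
    stop("image intensities outside the model's scale")
  if (is.null(theta)) theta <- model$theta
  stopifnot(theta > 0)
  b <- model$bins_per_channel
  i <- bin_index(rgb_image[, , 1], b, model$scale_max)
  j <- bin_index(rgb_image[, , 2], b, model$scale_max)
  k <- bin_index(rgb_image[, , 3], b, model$scale_max)
  lin <- 1L + i + b * (j + b * k)
  ps <- model$pdf_skin[lin]
  pn <- model$pdf_nonskin[lin]
  mask <- (pn == 0 & ps > 0) | (pn > 0 & ps >= theta * pn)
  matrix(mask, dim(rgb_image)[1], dim(rgb_image)[2])
}

#' Persist / restore a skin model
#'
#' The model (both histograms plus metadata) is written as a single JSON
#' archive so it can be inspected and versioned as text.
#'
#' @param model a `skin_model`.
#' @param path file path.
#' @export
write_skin_model <- function(model, path) {
  stopifnot(inherits(model, "skin_model"))
  obj <- list(bins_per_channel = model$bins_per_channel,
              theta = model$theta, scale_max = model$scale_max,
              hist_skin = as.integer(model$hist_skin),
              hist_nonskin = as.integer(model$hist_nonskin))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_skin_model
#' @return `read_skin_model()` returns the restored `skin_model`.
#' @export
read_skin_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- as.integer(obj$bins_per_channel)
  hs <- array(obj$hist_skin, dim = rep(b, 3))
  hn <- array(obj$hist_nonskin, dim = rep(b, 3))
  structure(list(hist_skin = hs, hist_nonskin = hn,
                 pdf_skin = hs / sum(hs), pdf_nonskin = hn / sum(hn),
                 bins_per_channel = b, theta = obj$theta,
                 scale_max = obj$scale_max),
            class = "skin_model")
}
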