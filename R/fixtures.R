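# Synthetic data: labeled skin-color corpus and scripted RGB+NIR video
# pairs with ground truth. The generator emulates the statistical
# structure the ROI method relies on -- skin-toned homogeneous regions,
# a small pulsatile intensity component, shared spatial texture between
# the RGB and NIR views (displaced by an integer camera offset), and
# scripted artifacts (occlusions, illumination steps, translations).

# Canonical skin-tone cluster of the synthetic corpus (12-bit RGB).
SKIN_RGB_MEAN <- c(2400, 1600, 1300)
SKIN_RGB_SD <- 160
NONSKIN_DARK_MEAN <- c(500, 500, 500)
NONSKIN_DARK_SD <- 250
NONSKIN_DARK_FRAC <- 0.3

#' Generate a labeled skin / non-skin pixel corpus
#'
#' Skin pixels are drawn from a trivariate Gaussian cluster around a
#' typical skin tone (R > G > B); non-skin pixels from a mixture of a
#' broad uniform color distribution and a dark cluster. The two classes
#' are well separated, which is all the histogram classifier needs to be
#' exercised; no claim of photometric realism is made.
#'
#' @param n_skin,n_nonskin number of pixels per class (>= 1).
#' @param seed integer seed; identical seeds give identical corpora.
#' @return list with `skin` and `nonskin`, each an `n x 3` matrix on the
#'   12-bit scale.
#' @export
#' @examples
#' corpus <- generate_skin_corpus(1000, 1000, seed = 1)
generate_skin_corpus <- function(n_skin, n_nonskin, seed = 1L) {
  if (!is_single_number(n_skin) || !is_single_number(n_nonskin) ||
      n_skin < 1 || n_nonskin < 1)
    stop("both class counts must be positive")
  with_local_seed(seed, {
    skin <- cbind(stats::rnorm(n_skin, SKIN_RGB_MEAN[1], SKIN_RGB_SD),
                  stats::rnorm(n_skin, SKIN_RGB_MEAN[2], SKIN_RGB_SD),
                  stats::rnorm(n_skin, SKIN_RGB_MEAN[3], SKIN_RGB_SD))
    n_dark <- round(n_nonskin * NONSKIN_DARK_FRAC)
    n_unif <- n_nonskin - n_dark
    unif <- matrix(stats::runif(3 * n_unif, 0, INTENSITY_MAX), ncol = 3)
    dark <- cbind(stats::rnorm(n_dark, NONSKIN_DARK_MEAN[1], NONSKIN_DARK_SD),
                  stats::rnorm(n_dark, NONSKIN_DARK_MEAN[2], NONSKIN_DARK_SD),
                  stats::rnorm(n_dark, NONSKIN_DARK_MEAN[3], NONSKIN_DARK_SD))
    list(skin = clip01(skin, 0, INTENSITY_MAX),
         nonskin = clip01(rbind(unif, dark), 0, INTENSITY_MAX))
  })
}

#' Scene script for the synthetic video generator
#'
#' Describes a synthetic recording: scene geometry, photometry, pulse,
#' artifacts, and the NIR viewpoint. Geometry is given in fractional
#' image coordinates so scripts scale with resolution.
#'
#' @param duration recording length in seconds.
#' @param fps frames per second (the reference setup runs at 100 fps).
#' @param resolution `c(height, width)` in pixels (nominal 320 x 420).
#' @param skin_regions list of regions, each a list with `center` and
#'   `axes` (fractions of the image), `color` (RGB triple), `nir` (NIR
#'   base intensity) and `texture_amp` (amplitude of the shared spatial
#'   texture). Later regions are drawn on top of earlier ones.
#' @param pulse list with `hr_bpm`, per-channel `amplitude`
#'   (R, G, B, NIR; intensity units), and `harmonic` (relative amplitude
#'   of the first harmonic of the raised-cosine waveform).
#' @param pulse_max upper bound on the per-channel pulsatile excursion
#'   (default 15 units at 12-bit depth).
#' @param events list of timed events; each is a list with `type`
#'   (`"occlusion"`, `"illumination"`, `"translation"`) and
#'   type-specific fields, see Details.
#' @param nir_offset integer `c(dx, dy)` viewpoint shift of the NIR
#'   stream (column and row displacement of scene content).
#' @param nir_gain_radial radial illumination falloff of the NIR spot
#'   light (0 = flat field).
#' @param noise_sd additive Gaussian sensor noise (intensity units).
#' @param background list with `color`, `nir` and `texture_amp`; the
#'   default background is a wide-range gray mottle so that the 1%/99%
#'   frame percentiles nearly span the intensity scale and the
#'   pre-classification contrast stretch is close to the identity.
#' @param seed integer seed; identical script + seed give bit-identical
#'   frames.
#'
#' @details Event fields: occlusions have `start`, `end` (seconds),
#' `color` (RGB), `nir`, and `extent` (`"full"` or `c(y0, y1, x0, x1)`
#' fractions); the occluder is rendered as an exactly constant, noise-free
#' patch (an opaque matte object near the lens). Illumination steps have
#' `start`, optional `end`, `magnitude` (added to all RGB channels) and
#' optional `nir_magnitude`. Translations have `start` and `shift`
#' (`c(dy, dx)` pixels, applied to the scene from `start` onward).
#'
#' @return object of class `scene_script`.
#' @export
scene_script <- function(duration = 30, fps = 100,
                         resolution = c(320, 420),
                         skin_regions = NULL,
                         pulse = list(hr_bpm = 72,
                                      amplitude = c(3, 10, 2, 8),
                                      harmonic = 0),
                         pulse_max = 15,
                         events = list(),
                         nir_offset = c(-8, 3),
                         nir_gain_radial = 0,
                         noise_sd = 5,
                         background = list(color = c(2000, 2000, 2000),
                                           nir = 900, texture_amp = 1700),
                         seed = 1L) {
  stopifnot(duration > 0, fps > 0, length(resolution) == 2,
            all(resolution >= 16))
  if (is.null(skin_regions))
    skin_regions <- list(list(center = c(0.5, 0.45), axes = c(0.32, 0.30),
                              color = SKIN_RGB_MEAN, nir = 2200,
                              texture_amp = 40))
  if (is.null(pulse$harmonic)) pulse$harmonic <- 0
  amp <- rep_len(pulse$amplitude, 4)
  if (any(amp < 0)) stop("pulsatile amplitudes must be non-negative")
  if (max(amp) * (1 + abs(pulse$harmonic)) > pulse_max)
    stop("pulsatile excursion exceeds the scripted bound of ", pulse_max,
         " units")
  pulse$amplitude <- amp
  for (re in skin_regions)
    if (any(re$color < 0) || any(re$color > INTENSITY_MAX) ||
        re$nir < 0 || re$nir > INTENSITY_MAX)
      stop("base intensities must lie in [0, ", INTENSITY_MAX, "]")
  for (ev in events) {
    if (is.null(ev$type) ||
        !ev$type %in% c("occlusion", "illumination", "translation"))
      stop("unknown event type")
    t0 <- ev$start
    t1 <- if (!is.null(ev$end)) ev$end else t0
    if (t0 < 0 || t1 > duration || (!is.null(ev$end) && ev$end < ev$start))
      stop("event outside [0, duration]")
  }
  structure(list(duration = duration, fps = fps,
                 resolution = as.integer(resolution),
                 skin_regions = skin_regions, pulse = pulse,
                 pulse_max = pulse_max, events = events,
                 nir_offset = as.integer(round(nir_offset)),
                 nir_gain_radial = nir_gain_radial,
                 noise_sd = noise_sd, background = background,
                 seed = as.integer(seed)),
            class = "scene_script")
}

# Smooth pseudo-random spatial field, normalized to [-1, 1].
#' @noRd
smooth_field <- function(h, w, seed) {
  with_local_seed(seed, {
    f <- matrix(stats::rnorm(h * w), h, w)
    f <- box5_sum(box5_sum(f))
    f / max(abs(f))
  })
}

#' @noRd
ellipse_mask <- function(h, w, center, axes) {
  cy <- center[1] * h; cx <- center[2] * w
  ry <- axes[1] * h; rx <- axes[2] * w
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - cy) / ry)^2 + ((c - cx) / rx)^2 <= 1
}

# Shift a matrix by (dy, dx) pixels, filling vacated entries with `fill`.
#' @noRd
shift_fill <- function(m, dy, dx, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  sr <- max(1, 1 + dy):min(h, h + dy)
  sc <- max(1, 1 + dx):min(w, w + dx)
  if (length(sr) > 0 && length(sc) > 0)
    out[sr, sc] <- m[sr - dy, sc - dx]
  out
}

# Compose the static (time-invariant) scene once.
#' @noRd
compose_scene <- function(script) {
  h <- script$resolution[1]; w <- script$resolution[2]
  bg <- script$background
  s_bg <- smooth_field(h, w, script$seed * 13 + 1)
  s_sk <- smooth_field(h, w, script$seed * 13 + 2)
  rgb <- lapply(1:3, function(c) bg$color[c] + bg$texture_amp * s_bg)
  nir <- bg$nir + 0.35 * bg$texture_amp * s_bg
  # deep shadows and specular highlights: small scene fractions at the
  # extremes of the intensity scale, as in natural recordings; they
  # anchor the 1%/99% percentiles so the pre-classification contrast
  # stretch stays close to the identity
  spk <- with_local_seed(script$seed * 13 + 3, {
    u <- matrix(stats::runif(h * w), h, w)
    list(dark = u < 0.03, bright = u > 0.97,
         dv = matrix(stats::runif(h * w, 0, 80), h, w),
         bv = matrix(stats::runif(h * w, INTENSITY_MAX - 80, INTENSITY_MAX),
                     h, w))
  })
  for (c in 1:3) {
    rgb[[c]][spk$dark] <- spk$dv[spk$dark]
    rgb[[c]][spk$bright] <- spk$bv[spk$bright]
  }
  nir[spk$dark] <- spk$dv[spk$dark]
  nir[spk$bright] <- spk$bv[spk$bright]
  skin <- matrix(FALSE, h, w)
  for (re in script$skin_regions) {
    m <- ellipse_mask(h, w, re$center, re$axes)
    for (c in 1:3) rgb[[c]][m] <- re$color[c] + re$texture_amp * s_sk[m]
    nir[m] <- re$nir + re$texture_amp * s_sk[m]
    skin <- skin | m
  }
  if (script$nir_gain_radial > 0) {
    r <- matrix(seq_len(h), h, w); c <- matrix(seq_len(w), h, w, byrow = TRUE)
    d2 <- ((r - h / 2) / (h / 2))^2 + ((c - w / 2) / (w / 2))^2
    nir <- nir * (1 - script$nir_gain_radial * d2)
  }
  list(rgb = rgb, nir = nir, skin = skin)
}

#' @noRd
pulse_wave <- function(pulse, t) {
  f <- pulse$hr_bpm / 60
  cos(2 * pi * f * t) + pulse$harmonic * cos(4 * pi * f * t)
}

#' Render a synthetic RGB + NIR video pair
#'
#' Produces a lazily evaluated, deterministic frame source plus ground
#' truth. Frames are rendered on demand from the cached static scene, so
#' long recordings need no frame storage. The NIR stream shows the same
#' scene displaced by the scripted integer viewpoint offset with its own
#' illumination; both streams share the spatial texture pattern, which is
#' what makes intensity-based block matching between them meaningful.
#'
#' @param script a [scene_script()].
#' @return object of class `cbppg_video` with elements `n_frames`, `fps`,
#'   `resolution`, `nir_offset`, `frame(k)` returning
#'   `list(rgb = h x w x 3 array, nir = h x w matrix)`, and `truth`
#'   (functions `mask_rgb(k)`, `mask_nir(k)`, scalar `f_ref_bpm`, and an
#'   `events` data frame with onset/offset frames).
#' @export
#' @examples
#' v <- render_video_pair(scene_script(duration = 0.1, fps = 20,
#'                                     resolution = c(40, 50)))
#' fr <- v$frame(1)
render_video_pair <- function(script) {
  stopifnot(inherits(script, "scene_script"))
  h <- script$resolution[1]; w <- script$resolution[2]
  n_frames <- round(script$duration * script$fps)
  scene <- compose_scene(script)
  dx <- script$nir_offset[1]; dy <- script$nir_offset[2]
  bg <- script$background

  ev_rows <- lapply(script$events, function(ev) {
    onset <- 1 + floor(ev$start * script$fps)
    offset <- if (!is.null(ev$end)) min(n_frames, ceiling(ev$end * script$fps))
              else n_frames
    data.frame(type = ev$type, onset_frame = onset, offset_frame = offset)
  })
  events_df <- if (length(ev_rows)) do.call(rbind, ev_rows)
    else data.frame(type = character(), onset_frame = integer(),
                    offset_frame = integer())

  active <- function(ev, k) {
    t <- (k - 1) / script$fps
    t1 <- if (!is.null(ev$end)) ev$end else Inf
    t >= ev$start && t < t1
  }

  cumulative_shift <- function(k) {
    s <- c(0L, 0L)
    for (ev in script$events)
      if (ev$type == "translation" && (k - 1) / script$fps >= ev$start)
        s <- s + as.integer(round(ev$shift))
    s
  }

  occlude <- function(m, ev, value) {
    if (identical(ev$extent, "full") || is.null(ev$extent)) {
      m[] <- value
    } else {
      e <- ev$extent
      rr <- max(1, round(e[1] * h)):min(h, round(e[2] * h))
      cc <- max(1, round(e[3] * w)):min(w, round(e[4] * w))
      m[rr, cc] <- value
    }
    m
  }

  skin_mask_at <- function(k) {
    s <- cumulative_shift(k)
    m <- if (any(s != 0)) shift_fill(scene$skin, s[1], s[2], FALSE) else scene$skin
    for (ev in script$events)
      if (ev$type == "occlusion" && active(ev, k))
        m <- occlude(m, ev, FALSE)
    m
  }

  frame <- function(k) {
    stopifnot(k >= 1, k <= n_frames)
    t <- (k - 1) / script$fps
    s <- cumulative_shift(k)
    pw <- pulse_wave(script$pulse, t)
    amp <- script$pulse$amplitude
    sk <- if (any(s != 0)) shift_fill(scene$skin, s[1], s[2], FALSE) else scene$skin

    chan <- vector("list", 4)
    for (c in 1:3) {
      m <- if (any(s != 0))
        shift_fill(scene$rgb[[c]], s[1], s[2], bg$color[c]) else scene$rgb[[c]]
      m[sk] <- m[sk] + amp[c] * pw
      chan[[c]] <- m
    }
    nm <- if (any(s != 0)) shift_fill(scene$nir, s[1], s[2], bg$nir) else scene$nir
    nm[sk] <- nm[sk] + amp[4] * pw

    for (ev in script$events)
      if (ev$type == "illumination" && active(ev, k)) {
        for (c in 1:3) chan[[c]] <- chan[[c]] + ev$magnitude
        nm <- nm + if (!is.null(ev$nir_magnitude)) ev$nir_magnitude else ev$magnitude
      }

    if (script$noise_sd > 0) {
      sd0 <- script$noise_sd
      noise <- with_local_seed((script$seed * 101 + k * 7) %% 2147483600,
                               stats::rnorm(4 * h * w, 0, sd0))
      for (c in 1:3)
        chan[[c]] <- chan[[c]] + matrix(noise[((c - 1) * h * w + 1):(c * h * w)], h, w)
      nm <- nm + matrix(noise[(3 * h * w + 1):(4 * h * w)], h, w)
    }
    for (c in 1:3) chan[[c]] <- clip01(chan[[c]], 0, INTENSITY_MAX)
    nm <- clip01(nm, 0, INTENSITY_MAX)

    # NIR viewpoint displacement, then occluders (opaque, noise-free)
    nm <- shift_fill(nm, dy, dx, bg$nir)
    for (ev in script$events)
      if (ev$type == "occlusion" && active(ev, k)) {
        for (c in 1:3) chan[[c]] <- occlude(chan[[c]], ev, ev$color[c])
        nm <- occlude(nm, ev, ev$nir)
      }
    list(rgb = array(c(chan[[1]], chan[[2]], chan[[3]]), dim = c(h, w, 3)),
         nir = nm)
  }

  truth <- list(
    mask_rgb = skin_mask_at,
    mask_nir = function(k) {
      m <- shift_fill(skin_mask_at(k), dy, dx, FALSE)
      for (ev in script$events)
        if (ev$type == "occlusion" && active(ev, k)) m <- occlude(m, ev, FALSE)
      m
    },
    f_ref_bpm = script$pulse$hr_bpm,
    events = events_df)

  structure(list(n_frames = n_frames, fps = script$fps,
                 resolution = script$resolution,
                 nir_offset = script$nir_offset,
                 frame = frame, truth = truth, script = script),
            class = "cbppg_video")
}

#' Write / read a rendered video pair as frame directories
#'
#' Frames are stored as 16-bit TIFF (intensities scaled from 0..4095;
#' PNG writers available in R are limited to 8 bits, which would
#' truncate the 12-bit data), ground-truth masks as 8-bit PNG, events
#' and the reference heart rate as CSV, and stream metadata as a JSON
#' sidecar.
#'
#' @param video a `cbppg_video`.
#' @param dir output directory (created if needed).
#' @param frames optional subset of frame indices to write.
#' @export
write_video_pair <- function(video, dir, frames = seq_len(video$n_frames)) {
  for (d in file.path(dir, c("rgb", "nir", "mask_rgb", "mask_nir")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (k in frames) {
    fr <- video$frame(k)
    fn <- sprintf("frame_%06d.tif", k)
    fm <- sprintf("frame_%06d.png", k)
    tiff::writeTIFF(fr$rgb / INTENSITY_MAX, file.path(dir, "rgb", fn),
                    bits.per.sample = 16)
    tiff::writeTIFF(fr$nir / INTENSITY_MAX, file.path(dir, "nir", fn),
                    bits.per.sample = 16)
    png::writePNG(video$truth$mask_rgb(k) * 1,
                  file.path(dir, "mask_rgb", fm))
    png::writePNG(video$truth$mask_nir(k) * 1,
                  file.path(dir, "mask_nir", fm))
  }
  jsonlite::write_json(list(fps = video$fps,
                            resolution = video$resolution,
                            n_frames = length(frames),
                            nir_offset = video$nir_offset,
                            seed = video$script$seed),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  utils::write.csv(video$truth$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(f_ref_bpm = video$truth$f_ref_bpm),
                   file.path(dir, "f_ref.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_video_pair
#' @return `read_video_pair()` returns a `cbppg_video`-compatible frame
#'   source backed by the directory.
#' @export
read_video_pair <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(file.path(dir, "rgb"), pattern = "\\.tif$"))
  if (length(files) == 0) stop("no frames found under ", dir)
  frame <- function(k) {
    fn <- files[k]
    list(rgb = tiff::readTIFF(file.path(dir, "rgb", fn)) * INTENSITY_MAX,
         nir = tiff::readTIFF(file.path(dir, "nir", fn)) * INTENSITY_MAX)
  }
  truth <- NULL
  fref_path <- file.path(dir, "f_ref.csv")
  if (file.exists(fref_path)) {
    mask_read <- function(sub) function(k)
      png::readPNG(file.path(dir, sub,
                             sub("\\.tif$", ".png", files[k]))) > 0.5
    truth <- list(mask_rgb = mask_read("mask_rgb"),
                  mask_nir = mask_read("mask_nir"),
                  f_ref_bpm = utils::read.csv(fref_path)$f_ref_bpm[1],
                  events = utils::read.csv(file.path(dir, "events.csv")))
  }
  structure(list(n_frames = length(files), fps = meta$fps,
                 resolution = meta$resolution,
                 nir_offset = meta$nir_offset,
                 frame = frame, truth = truth, script = NULL),
            class = "cbppg_video")
}
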