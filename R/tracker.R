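# Frame-to-frame ROI tracking with artifact monitoring.
#
# Each stream (RGB, NIR) is tracked independently: the level set for
# frame k is initialized from the ROI of frame k-1 and evolved with a
# small iteration budget. Two conditions trigger a redetection: the ROI
# collapsing (empty, degenerate or below the minimum viable size), and
# the standard deviation of the mean ROI intensity over the trailing
# 10 s window exceeding 50 units. A triggered redetection runs the full
# ROI detector on the current frame pair; the logged event is named
# after its outcome -- `redetect_unstable` when skin was found again at
# once (the tracked region was unstable but skin is still visible), and
# `redetect_no_skin` when the detector found no skin, which opens an
# episode of absent ROIs that lasts until the detector succeeds again.
# After every successful (re)selection the monitor is paused for 10 s
# and the intensity buffer is reset so the new region's baseline cannot
# re-trigger it.

#' Initialize a tracking state
#'
#' @param config a [ppg_config()].
#' @param fps frames per second of the streams.
#' @return list of class `track_state`.
#' @export
track_state_init <- function(config = ppg_config(), fps = 100) {
  mk_stream <- function() list(mask = NULL, buffer = numeric(0),
                               paused_until = 0L, fail_count = 0L,
                               had_roi = FALSE)
  structure(list(frame = 0L, fps = fps, config = config,
                 streams = list(rgb = mk_stream(), nir = mk_stream()),
                 events = list()),
            class = "track_state")
}

#' @noRd
log_event <- function(state, frame, stream, event) {
  state$events[[length(state$events) + 1L]] <-
    list(frame = frame, stream = stream, event = event)
  state
}

#' Track one frame pair
#'
#' Advances the tracker by a single frame: evolves each stream's level
#' set from the previous ROI (budget `iters_track`, early stop
#' `early_stop_px`), updates the intensity monitor, and redetects when
#' required. See [track_video()] for the loop over a whole recording.
#'
#' @param state a `track_state`.
#' @param frame_pair list with `rgb` and `nir` frames.
#' @param skin_model a `skin_model`.
#' @return updated `track_state` with per-frame results in
#'   `state$last` (`mask_rgb`, `mask_nir`, `means` = named vector
#'   R, G, B, NIR with `NA` where the ROI was absent).
#' @export
track_step <- function(state, frame_pair, skin_model) {
  stopifnot(inherits(state, "track_state"))
  cfg <- state$config
  k <- state$frame + 1L
  state$frame <- k
  cap <- as.integer(round(cfg$monitor_window_s * state$fps))
  pause_frames <- as.integer(round(cfg$monitor_pause_s * state$fps))

  det_cache <- NULL
  run_detector <- function() {
    if (is.null(det_cache))
      det_cache <<- detect(frame_pair, skin_model, cfg)
    det_cache
  }

  out_masks <- list(rgb = NULL, nir = NULL)
  means <- c(R = NA_real_, G = NA_real_, B = NA_real_, NIR = NA_real_)

  for (sn in c("rgb", "nir")) {
    s <- state$streams[[sn]]
    mon_channel <- if (sn == "rgb") frame_pair$rgb[, , 2] else frame_pair$nir

    accept_mask <- function(m) {
      out_masks[[sn]] <<- m
      if (sn == "rgb") {
        for (c in 1:3)
          means[c] <<- mean(frame_pair$rgb[, , c][m])
      } else means["NIR"] <<- mean(frame_pair$nir[m])
    }

    if (is.null(s$mask)) {
      # redetection pending (or very first frame)
      attempt <- !(s$fail_count >= cfg$redetect_backoff_after &&
                     k %% cfg$redetect_backoff_every != 0L)
      if (attempt) {
        d <- run_detector()
        st <- if (sn == "rgb") d$status_rgb else d$status_nir
        if (st == "ok") {
          s$mask <- if (sn == "rgb") d$roi_rgb else d$roi_nir
          s$fail_count <- 0L
          s$buffer <- numeric(0)
          if (s$had_roi) {          # reselection after a loss: pause monitor
            s$paused_until <- k + pause_frames
            state <- log_event(state, k, sn, "pause_start")
          }
          s$had_roi <- TRUE
          s$buffer <- mean(mon_channel[s$mask])
          accept_mask(s$mask)
        } else {
          s$fail_count <- s$fail_count + 1L
        }
      }
      state$streams[[sn]] <- s
      next
    }

    # ordinary tracking step
    feats <- if (sn == "rgb") feature_stack_rgb(frame_pair$rgb)
             else feature_stack_nir(frame_pair$nir)
    prm <- level_set_params(length(s$mask),
                            max_iters = cfg$iters_track,
                            early_stop_delta = cfg$early_stop_px,
                            nu = cfg$nu_coef * length(s$mask)^cfg$nu_exp,
                            epsilon = cfg$epsilon,
                            sigma_floor = cfg$sigma_floor)
    ev <- evolve(init_phi(s$mask), feats, prm)
    new_mask <- if (ev$status == "ok") level_set_mask(ev) else NULL
    lost <- is.null(new_mask) || sum(new_mask) < cfg$min_roi_px ||
      sum(new_mask) == length(s$mask)

    unstable <- FALSE
    if (!lost) {
      mu <- mean(mon_channel[new_mask])
      buf <- c(s$buffer, mu)
      if (length(buf) > cap) buf <- buf[(length(buf) - cap + 1L):length(buf)]
      monitoring <- k > s$paused_until && length(buf) >= cap
      unstable <- monitoring && stats::sd(buf) > cfg$monitor_sd_max
      if (!unstable) s$buffer <- buf
    }

    if (lost || unstable) {
      d <- run_detector()
      st <- if (sn == "rgb") d$status_rgb else d$status_nir
      if (st == "ok") {
        state <- log_event(state, k, sn, "redetect_unstable")
        s$mask <- if (sn == "rgb") d$roi_rgb else d$roi_nir
        s$paused_until <- k + pause_frames
        s$buffer <- mean(mon_channel[s$mask])
        accept_mask(s$mask)
      } else {
        state <- log_event(state, k, sn, "redetect_no_skin")
        s$mask <- NULL
        s$fail_count <- 1L
        s$buffer <- numeric(0)
      }
    } else {
      s$mask <- new_mask
      accept_mask(new_mask)
    }
    state$streams[[sn]] <- s
  }

  state$last <- list(mask_rgb = out_masks$rgb, mask_nir = out_masks$nir,
                     means = means)
  state
}

#' Detect and track ROIs over a whole recording
#'
#' Runs the detection-and-tracking loop over every frame of a video
#' pair: initial ROI detection, per-frame level-set tracking, artifact
#' monitoring with automatic redetection, and bookkeeping of per-frame
#' channel means for the downstream signal chain.
#'
#' @param video a `cbppg_video` (see [render_video_pair()]) or any list
#'   providing `n_frames`, `fps` and `frame(k)`.
#' @param skin_model a `skin_model`.
#' @param config a [ppg_config()].
#' @param store_masks `"indices"` (default) stores each frame's ROI as a
#'   vector of pixel indices, `"none"` drops masks to save memory.
#' @param verbose print progress every 500 frames.
#' @return list of class `track_result`: `means` (`n_frames x 4` matrix,
#'   columns R, G, B, NIR, `NA` where the ROI was absent), `masks_rgb`,
#'   `masks_nir` (lists of integer index vectors or `NULL`), `events`
#'   (data frame `frame, stream, event`), `fps`, `resolution`.
#' @export
track_video <- function(video, skin_model, config = ppg_config(),
                        store_masks = c("indices", "none"),
                        verbose = FALSE) {
  store_masks <- match.arg(store_masks)
  n <- video$n_frames
  stopifnot(n >= 1)
  state <- track_state_init(config, fps = video$fps)
  means <- matrix(NA_real_, n, 4,
                  dimnames = list(NULL, c("R", "G", "B", "NIR")))
  masks_rgb <- masks_nir <- if (store_masks == "indices") vector("list", n)
    else NULL
  for (k in seq_len(n)) {
    fp <- video$frame(k)
    state <- track_step(state, fp, skin_model)
    means[k, ] <- state$last$means
    if (store_masks == "indices") {
      if (!is.null(state$last$mask_rgb))
        masks_rgb[[k]] <- which(state$last$mask_rgb)
      if (!is.null(state$last$mask_nir))
        masks_nir[[k]] <- which(state$last$mask_nir)
    }
    if (verbose && k %% 500 == 0)
      message("frame ", k, "/", n)
  }
  ev <- if (length(state$events))
    do.call(rbind, lapply(state$events, as.data.frame))
  else data.frame(frame = integer(), stream = character(),
                  event = character())
  structure(list(means = means, masks_rgb = masks_rgb,
                 masks_nir = masks_nir, events = ev, fps = video$fps,
                 resolution = video$resolution),
            class = "track_result")
}
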