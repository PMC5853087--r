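#' Pipeline configuration
#'
#' Collects every tunable of the detection, tracking and signal chain
#' with its default. Defaults follow the reference operating point of
#' the method: classifier threshold `theta = 5` on a 32-bins-per-channel
#' histogram; level-set iteration budgets of 300 (RGB detection), 100
#' (NIR detection) and 50 (tracking) with a 50-pixel early-stop; a
#' curvature weight `0.001 * |Omega|^0.7`; a 5x5 block-matching search
#' over `d_x in [-60, 0]`, `d_y in [0, 10]`; a 10-s intensity monitor
#' with a 50-unit standard-deviation threshold and a 10-s
#' post-redetection pause; 10-s signal segments, an order-250 FIR
#' highpass at 0.5 Hz, zero-padding to 2^13 points, a 30-200 bpm
#' heart-rate band, and +/- 5 bpm SNR signal bands.
#'
#' @param ... overrides of the defaults listed above.
#' @return list of class `ppg_config`.
#' @export
ppg_config <- function(...) {
  cfg <- list(
    theta = 5,
    bins_per_channel = 32L,
    adjust_saturation = 0.01,
    iters_detect_rgb = 300L,
    iters_detect_nir = 100L,
    iters_track = 50L,
    early_stop_px = 50,
    nu_coef = 0.001,
    nu_exp = 0.7,
    epsilon = 1.5,
    sigma_floor = 1.0,
    min_roi_px = 100L,
    block_stride = 1L,
    search_dx = c(-60L, 0L),
    search_dy = c(0L, 10L),
    monitor_window_s = 10,
    monitor_sd_max = 50,
    monitor_pause_s = 10,
    redetect_backoff_after = 100L,
    redetect_backoff_every = 10L,
    segment_s = 10,
    fir_order = 250L,
    fir_cutoff_hz = 0.5,
    fft_pad = 8192L,
    hr_band_bpm = c(30, 200),
    snr_halfwidth_bpm = 5,
    snr_cap_db = 80,
    hdr_tol_bpm = 5)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "ppg_config")
}

#' Write / read a pipeline configuration
#'
#' Round-trips losslessly through a YAML file so runs can be reproduced
#' from a single structured text artifact.
#'
#' @param config a [ppg_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ppg_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(ppg_config, yaml::read_yaml(path))
}

#' Run the full cbPPG pipeline on a video pair
#'
#' Executes detection, tracking, signal extraction, segmentation and
#' per-segment HR/SNR estimation end to end. When the video carries
#' ground truth (synthetic fixtures), the reference heart rate is taken
#' from it and a per-channel detection-rate summary is added.
#'
#' @param video a `cbppg_video` (from [render_video_pair()] or
#'   [read_video_pair()]).
#' @param skin_model a `skin_model`; if `NULL`, one is trained on a
#'   synthetic corpus of `corpus_n` pixels per class.
#' @param config a [ppg_config()].
#' @param f_ref_bpm reference heart rate(s); defaults to the video's
#'   ground truth when present.
#' @param corpus_n corpus size per class for the fallback skin model.
#' @param store_masks passed to [track_video()].
#' @param out_dir optional directory to which signals, segment results
#'   and the event log are written as CSV.
#' @param verbose progress reporting.
#' @return list of class `ppg_run`: `track` (a `track_result`), `signal`
#'   (a `channel_signal`), `segments` (per-segment data frame),
#'   `summary` (named list with frame/event counts, per-channel HDR and
#'   median SNR where a reference was available).
#' @export
run_pipeline <- function(video, skin_model = NULL, config = ppg_config(),
                         f_ref_bpm = NULL, corpus_n = 20000L,
                         store_masks = "indices", out_dir = NULL,
                         verbose = FALSE) {
  if (is.null(skin_model)) {
    corpus <- generate_skin_corpus(corpus_n, corpus_n, seed = 7L)
    skin_model <- build_skin_model(corpus$skin, corpus$nonskin,
                                   bins_per_channel = config$bins_per_channel,
                                   theta = config$theta)
  }
  track <- track_video(video, skin_model, config,
                       store_masks = store_masks, verbose = verbose)
  sig <- signal_from_track(track)
  if (is.null(f_ref_bpm) && !is.null(video$truth))
    f_ref_bpm <- video$truth$f_ref_bpm
  if (is.null(f_ref_bpm)) f_ref_bpm <- NA
  segments <- segment_results(sig, f_ref_bpm, config)

  summary <- list(
    n_frames = video$n_frames,
    n_missing_rgb = sum(is.na(track$means[, "G"])),
    n_missing_nir = sum(is.na(track$means[, "NIR"])),
    n_redetect_no_skin = sum(track$events$event == "redetect_no_skin"),
    n_redetect_unstable = sum(track$events$event == "redetect_unstable"),
    n_segments = max(segments$segment, 0))
  if (!all(is.na(f_ref_bpm)) && nrow(segments) > 0) {
    for (ch in c("R", "G", "B", "NIR")) {
      rc <- segments[segments$channel == ch, ]
      summary[[paste0("hdr_", ch)]] <-
        hdr(rc$hr_bpm, rc$f_ref_bpm, config$hdr_tol_bpm)
      summary[[paste0("snr_", ch)]] <-
        stats::median(rc$snr_db[rc$valid], na.rm = TRUE)
    }
    correct <- lapply(c(G = "G", NIR = "NIR"), function(ch) {
      rc <- segments[segments$channel == ch, ]
      hdr_correct(rc$hr_bpm, rc$f_ref_bpm, config$hdr_tol_bpm)
    })
    summary$hdr_G_NIR <- combine_hdr(correct$G, correct$NIR)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(frame = seq_len(nrow(sig$means)),
                                sig$means),
                     file.path(out_dir, "signals.csv"), row.names = FALSE)
    utils::write.csv(segments, file.path(out_dir, "segments.csv"),
                     row.names = FALSE)
    utils::write.csv(track$events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(track = track, signal = sig, segments = segments,
                 summary = summary, config = config),
            class = "ppg_run")
}
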