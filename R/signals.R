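# cbPPG signal extraction and per-segment heart-rate / SNR estimation.

#' Per-frame channel means under tracked ROIs
#'
#' Builds the four cbPPG channel signals (R, G, B, NIR) by spatially
#' averaging each frame's pixels inside the frame's ROI. Frames without
#' an ROI yield missing entries.
#'
#' @param video a `cbppg_video` (or compatible frame source).
#' @param masks_rgb,masks_nir per-frame masks: a list of logical
#'   matrices, of integer index vectors, or `NULL` entries for absent
#'   ROIs.
#' @return object of class `channel_signal`: list with `means`
#'   (`n x 4` matrix, columns R, G, B, NIR) and `fps`.
#' @export
extract_signals <- function(video, masks_rgb, masks_nir = NULL) {
  n <- video$n_frames
  if (length(masks_rgb) != n ||
      (!is.null(masks_nir) && length(masks_nir) != n))
    stop("video and mask sequences have different lengths")
  means <- matrix(NA_real_, n, 4,
                  dimnames = list(NULL, c("R", "G", "B", "NIR")))
  idx_of <- function(m) {
    if (is.null(m)) return(NULL)
    if (is.matrix(m)) m <- which(mask_as_logical(m))
    if (length(m) == 0) NULL else m
  }
  for (k in seq_len(n)) {
    i_rgb <- idx_of(masks_rgb[[k]])
    i_nir <- if (is.null(masks_nir)) i_rgb else idx_of(masks_nir[[k]])
    if (is.null(i_rgb) && is.null(i_nir)) next
    fr <- video$frame(k)
    if (!is.null(i_rgb))
      for (c in 1:3) means[k, c] <- mean(fr$rgb[, , c][i_rgb])
    if (!is.null(i_nir)) means[k, 4] <- mean(fr$nir[i_nir])
  }
  channel_signal(means, video$fps)
}

#' @rdname extract_signals
#' @param means `n x 4` matrix of channel means (may contain `NA`).
#' @param fps frames per second.
#' @export
channel_signal <- function(means, fps) {
  stopifnot(is.matrix(means), ncol(means) == 4, fps > 0)
  colnames(means) <- c("R", "G", "B", "NIR")
  structure(list(means = means, fps = fps), class = "channel_signal")
}

#' Convert a tracking result to a channel signal
#' @param track a `track_result` from [track_video()].
#' @export
signal_from_track <- function(track) channel_signal(track$means, track$fps)

#' Split a channel signal into consecutive 10-second segments
#'
#' Non-overlapping windows of `segment_s` seconds from the start of the
#' recording; a trailing partial window is discarded. A segment is
#' flagged invalid for a channel if any of its raw entries is missing.
#'
#' @param signal a `channel_signal`.
#' @param segment_s window length in seconds.
#' @return list of segments, each with `index`, `start_frame`, `data`
#'   (`len x 4` matrix) and `valid` (named logical, one flag per
#'   channel).
#' @export
segment_signal <- function(signal, segment_s = 10) {
  stopifnot(inherits(signal, "channel_signal"))
  len <- as.integer(round(segment_s * signal$fps))
  n_seg <- nrow(signal$means) %/% len
  lapply(seq_len(n_seg), function(i) {
    rows <- ((i - 1L) * len + 1L):(i * len)
    d <- signal$means[rows, , drop = FALSE]
    list(index = i, start_frame = rows[1], data = d,
         valid = apply(d, 2, function(x) !anyNA(x)))
  })
}

# cached FIR designs keyed by (order, cutoff, fps)
.fir_cache <- new.env(parent = emptyenv())

#' @noRd
fir_highpass <- function(order, cutoff_hz, fps) {
  key <- paste(order, cutoff_hz, fps, sep = "_")
  if (is.null(.fir_cache[[key]]))
    .fir_cache[[key]] <- as.numeric(
      signal::fir1(order, cutoff_hz / (fps / 2), type = "high"))
  .fir_cache[[key]]
}

#' Detrend and highpass-filter a signal segment
#'
#' Removes the least-squares linear trend, then applies an order-250
#' windowed-sinc (Hamming) FIR highpass with 0.5 Hz cutoff in zero-phase
#' fashion (the filter is run forward and backward by double
#' convolution, so the passband response is squared and the phase is
#' exactly zero).
#'
#' @param x numeric vector without missing values.
#' @param fps sampling rate in Hz.
#' @param order FIR order (the filter has `order + 1` taps).
#' @param cutoff_hz highpass cutoff.
#' @return filtered vector of the same length.
#' @export
preprocess_segment <- function(x, fps, order = 250L, cutoff_hz = 0.5) {
  if (anyNA(x)) stop("segment contains missing entries")
  n <- length(x)
  if (n <= order)
    stop("segment of ", n, " samples is shorter than the FIR warm-up (",
         order + 1, " taps)")
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), x)
  x <- fit$residuals
  b <- fir_highpass(order, cutoff_hz, fps)
  m <- length(b)
  y1 <- stats::convolve(x, rev(b), type = "open")
  y2 <- stats::convolve(y1, b, type = "open")
  y2[m:(m + n - 1)]
}

#' Zero-padded amplitude spectrum
#'
#' The segment is zero-padded to `n_pad` points (2^13 by default) before
#' the FFT, giving a frequency resolution of `fps / n_pad` Hz
#' (0.732 bpm at 100 fps).
#'
#' @param x numeric vector (a preprocessed segment).
#' @param fps sampling rate in Hz.
#' @param n_pad FFT length after zero-padding.
#' @return list of class `amplitude_spectrum` with `freq_bpm`,
#'   `amplitude` (up to the Nyquist bin) and `bin_bpm`.
#' @export
amplitude_spectrum <- function(x, fps, n_pad = 8192L) {
  n <- length(x)
  if (n > n_pad) stop("segment longer than the FFT length")
  X <- abs(stats::fft(c(x, numeric(n_pad - n))))
  half <- seq_len(n_pad %/% 2 + 1L)
  structure(list(freq_bpm = (half - 1) * fps / n_pad * 60,
                 amplitude = X[half],
                 bin_bpm = fps / n_pad * 60),
            class = "amplitude_spectrum")
}

#' Heart rate from an amplitude spectrum
#'
#' Frequency (in bpm) of the largest spectral amplitude within the
#' heart-rate band; ties resolve toward the lower frequency.
#'
#' @param spectrum an `amplitude_spectrum`.
#' @param band_bpm inclusive search band (default 30-200 bpm).
#' @return heart-rate estimate in bpm.
#' @export
estimate_hr <- function(spectrum, band_bpm = c(30, 200)) {
  sel <- spectrum$freq_bpm >= band_bpm[1] & spectrum$freq_bpm <= band_bpm[2]
  f <- spectrum$freq_bpm[sel]
  f[which.max(spectrum$amplitude[sel])]
}

#' Spectral signal-to-noise ratio of a plethysmogram segment
#'
#' Ratio (dB) of the spectral power within +/- 5 bpm of the reference
#' heart rate and of its first harmonic to the remaining power in the
#' 30-200 bpm band. The harmonic band contributes only its part inside
#' the evaluation band. A noise-free spectrum returns `cap_db`.
#'
#' @param spectrum an `amplitude_spectrum`.
#' @param f_ref reference heart rate in bpm (inside `band_bpm`).
#' @param band_bpm evaluation band.
#' @param halfwidth_bpm half-width of the signal bands.
#' @param cap_db value returned when the noise power is zero.
#' @return SNR in dB.
#' @export
snr <- function(spectrum, f_ref, band_bpm = c(30, 200), halfwidth_bpm = 5,
                cap_db = 80) {
  if (f_ref < band_bpm[1] || f_ref > band_bpm[2])
    stop("f_ref outside the evaluation band")
  sel <- spectrum$freq_bpm >= band_bpm[1] & spectrum$freq_bpm <= band_bpm[2]
  f <- spectrum$freq_bpm[sel]
  a2 <- spectrum$amplitude[sel]^2
  pi_mask <- snr_band_mask(f, f_ref, halfwidth_bpm)
  sig <- sum(a2[pi_mask])
  noise <- sum(a2[!pi_mask])
  if (noise == 0) return(cap_db)
  max(10 * log10(sig / noise), -cap_db)
}

#' @rdname snr
#' @param f frequencies in bpm.
#' @return `snr_band_mask()` returns the binary band-selection mask
#'   (fundamental and first harmonic, +/- `halfwidth_bpm`).
#' @export
snr_band_mask <- function(f, f_ref, halfwidth_bpm = 5) {
  abs(f_ref - f) <= halfwidth_bpm | abs(2 * f_ref - f) <= halfwidth_bpm
}

#' Per-segment heart rate and SNR for all channels
#'
#' Runs the full per-segment chain (validity check, detrend, highpass,
#' zero-padded FFT, HR peak picking, SNR) for each channel of a signal.
#'
#' @param signal a `channel_signal`.
#' @param f_ref reference heart rate(s) in bpm: a scalar or one value
#'   per segment; `NA` to skip SNR.
#' @param config a [ppg_config()] supplying the chain's tunables.
#' @return data frame with one row per segment and channel: `segment`,
#'   `channel`, `valid`, `hr_bpm`, `snr_db`, `f_ref_bpm`.
#' @export
segment_results <- function(signal, f_ref = NA, config = ppg_config()) {
  segs <- segment_signal(signal, config$segment_s)
  if (length(segs) == 0)
    return(data.frame(segment = integer(), channel = character(),
                      valid = logical(), hr_bpm = numeric(),
                      snr_db = numeric(), f_ref_bpm = numeric()))
  refs <- rep_len(f_ref, length(segs))
  rows <- list()
  for (s in segs) {
    for (ch in colnames(signal$means)) {
      valid <- s$valid[[ch]]
      hr <- snr_v <- NA_real_
      if (valid) {
        y <- preprocess_segment(s$data[, ch], signal$fps,
                                order = config$fir_order,
                                cutoff_hz = config$fir_cutoff_hz)
        sp <- amplitude_spectrum(y, signal$fps, config$fft_pad)
        hr <- estimate_hr(sp, config$hr_band_bpm)
        if (!is.na(refs[s$index]))
          snr_v <- snr(sp, refs[s$index], config$hr_band_bpm,
                       config$snr_halfwidth_bpm, config$snr_cap_db)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(segment = s$index, channel = ch, valid = valid,
                   hr_bpm = hr, snr_db = snr_v,
                   f_ref_bpm = refs[s$index])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
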