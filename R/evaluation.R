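# Study-level evaluation: heart-rate detection rates, channel
# combinations, and paired one-tailed signed-rank comparisons.

#' Heart-rate detection rate
#'
#' Percentage of segments whose estimated heart rate deviates by less
#' than `tol_bpm` (strictly) from the reference. Missing estimates --
#' segments discarded for absent ROIs -- count as falsely detected.
#'
#' @param estimates per-segment HR estimates in bpm (`NA` = missing).
#' @param references aligned reference HRs in bpm.
#' @param tol_bpm tolerance (strict inequality), default 5 bpm.
#' @return detection rate in percent.
#' @export
#' @examples
#' hdr(c(72, 76, NA), c(70, 70, 70))  # only 72 is within 5 bpm -> 33.3%
hdr <- function(estimates, references, tol_bpm = 5) {
  if (length(estimates) == 0) stop("empty segment list")
  100 * mean(hdr_correct(estimates, references, tol_bpm))
}

#' @rdname hdr
#' @return `hdr_correct()` returns the per-segment correctness vector.
#' @export
hdr_correct <- function(estimates, references, tol_bpm = 5) {
  if (length(references) != length(estimates))
    stop("estimate/reference length mismatch")
  !is.na(estimates) & abs(estimates - references) < tol_bpm
}

#' Combine two channels' per-segment correctness
#'
#' A segment counts as correct for the combination if either channel
#' detected the correct heart rate (the better channel can always be
#' selected per segment).
#'
#' @param correct_a,correct_b aligned logical vectors.
#' @return combined detection rate in percent.
#' @export
combine_hdr <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b)) stop("length mismatch")
  100 * mean(correct_a | correct_b)
}

#' One-tailed paired Wilcoxon signed-rank test
#'
#' Tests whether the paired values in `x` are stochastically larger than
#' those in `y`. For up to 25 pairs the exact null distribution of the
#' signed-rank statistic is computed by dynamic programming (handling
#' tied ranks; zero differences are ranked but excluded from the
#' statistic, following Pratt); larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y paired samples.
#' @param exact_max largest n for which the exact distribution is used.
#' @return one-tailed p-value for `x > y`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  if (length(x) != length(y)) stop("paired samples differ in length")
  d <- x - y
  r <- rank(abs(d))                       # zeros included (Pratt)
  nz <- d != 0
  if (!any(nz)) return(1)                 # no information against H0
  r2 <- round(2 * r[nz])                  # integerized (ties give .5 ranks)
  w_obs <- sum(r2[d[nz] > 0])
  if (sum(nz) <= exact_max) {
    total <- sum(r2)
    p <- numeric(total + 1L); p[1] <- 1   # P(W2 = w), w = 0..total
    for (rk in r2) {
      shifted <- c(numeric(rk), p[seq_len(total + 1L - rk)])
      p <- (p + shifted) / 2
    }
    sum(p[(w_obs + 1L):(total + 1L)])
  } else {
    mu <- sum(r2) / 2
    sg <- sqrt(sum(r2^2) / 4)
    stats::pnorm((w_obs - mu - 0.5) / sg, lower.tail = FALSE)
  }
}

#' Compare a base channel's detection rates with a combination
#'
#' Paired one-tailed signed-rank test of whether the combined
#' detection rates exceed the base channel's across subjects.
#'
#' @param hdr_base,hdr_combined per-subject detection rates (n >= 5).
#' @return one-tailed p-value for `combined > base`.
#' @export
compare_hdr <- function(hdr_base, hdr_combined) {
  if (length(hdr_base) < 5) stop("need at least 5 paired subjects")
  wilcoxon_signed_rank(hdr_combined, hdr_base)
}

#' Study-level evaluation report
#'
#' Aggregates per-segment results of several subjects into per-subject
#' detection rates and median SNRs per channel, channel-combination
#' detection rates (G&B, G&R, G&NIR), and the paired one-tailed
#' signed-rank comparisons of each combination against the green
#' channel. Invalid segments count as false detections in the HDR but do
#' not enter the SNR medians.
#'
#' @param results data frame as returned by [segment_results()], with an
#'   additional `subject` column.
#' @param tol_bpm HDR tolerance in bpm.
#' @return list of class `eval_report`: `per_subject` (data frame with
#'   subject, channel, hdr, median_snr), `combined` (data frame with
#'   subject and the three combination HDRs), `p_values` (named vector),
#'   `medians` (named vector of median HDRs/SNRs per channel).
#' @export
evaluate_study <- function(results, tol_bpm = 5) {
  stopifnot(all(c("subject", "segment", "channel", "hr_bpm",
                  "f_ref_bpm") %in% names(results)))
  subjects <- unique(results$subject)
  chans <- c("R", "G", "B", "NIR")
  per <- list(); comb <- list()
  for (s in subjects) {
    rs <- results[results$subject == s, ]
    correct <- list()
    for (ch in chans) {
      rc <- rs[rs$channel == ch, ]
      rc <- rc[order(rc$segment), ]
      correct[[ch]] <- hdr_correct(rc$hr_bpm, rc$f_ref_bpm, tol_bpm)
      per[[length(per) + 1L]] <- data.frame(
        subject = s, channel = ch,
        hdr = 100 * mean(correct[[ch]]),
        median_snr = stats::median(rc$snr_db[rc$valid], na.rm = TRUE))
    }
    comb[[length(comb) + 1L]] <- data.frame(
      subject = s,
      hdr_g = 100 * mean(correct$G),
      hdr_gb = combine_hdr(correct$G, correct$B),
      hdr_gr = combine_hdr(correct$G, correct$R),
      hdr_gnir = combine_hdr(correct$G, correct$NIR))
  }
  per <- do.call(rbind, per)
  comb <- do.call(rbind, comb)
  p_values <- c(
    G_vs_GB = if (nrow(comb) >= 5) compare_hdr(comb$hdr_g, comb$hdr_gb) else NA,
    G_vs_GR = if (nrow(comb) >= 5) compare_hdr(comb$hdr_g, comb$hdr_gr) else NA,
    G_vs_GNIR = if (nrow(comb) >= 5) compare_hdr(comb$hdr_g, comb$hdr_gnir) else NA)
  med <- c(stats::setNames(sapply(chans, function(ch)
             stats::median(per$hdr[per$channel == ch])),
           paste0("hdr_", chans)),
           stats::setNames(sapply(chans, function(ch)
             stats::median(per$median_snr[per$channel == ch], na.rm = TRUE)),
           paste0("snr_", chans)))
  structure(list(per_subject = per, combined = comb, p_values = p_values,
                 medians = med),
            class = "eval_report")
}
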