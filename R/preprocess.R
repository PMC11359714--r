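# Continuous-signal conditioning and trial segmentation for the
# motor-imagery pipeline: threshold artifact marking, zero-phase band-pass
# filtering, cue-locked epoching, baseline correction, and the round-wise
# 5-fold train/test split.

#' Mark artifact samples by amplitude threshold
#'
#' Flags every sample whose absolute amplitude exceeds the threshold.
#' Marked samples are later excluded from training windows rather than
#' repaired; independent-component-based artifact removal is deliberately
#' not implemented (callers may supply their own mask in its place).
#'
#' @param rec an `eeg_recording`.
#' @param threshold_uV positive amplitude threshold in microvolts. The 100
#'   microvolt default is a common screening convention for scalp EEG.
#' @return logical channels x samples matrix (`TRUE` = artifact).
#' @export
mark_artifacts <- function(rec, threshold_uV = 100) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(threshold_uV) || threshold_uV <= 0)
    stop("threshold_uV must be positive")
  abs(rec$data) > threshold_uV
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass forward and backward (via
#' [signal::filtfilt()]) to each channel, so the pass is zero-phase and
#' cue-locked latencies are not distorted.
#'
#' @param rec an `eeg_recording`.
#' @param lo_hz,hi_hz band edges, 0 < lo < hi < fs/2.
#' @param order Butterworth order per pass (default 4).
#' @return filtered `eeg_recording` of the same shape.
#' @export
bandpass <- function(rec, lo_hz, hi_hz, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_band(lo_hz, hi_hz, rec$fs)
  flt <- signal::butter(order, c(lo_hz, hi_hz) / (rec$fs / 2), type = "pass")
  out <- t(apply(rec$data, 1, function(x) signal::filtfilt(flt, x)))
  new_recording(out, rec$fs, rec$channel_labels)
}

check_band <- function(lo, hi, fs) {
  if (!(lo > 0 && hi > lo && hi < fs / 2))
    stop("band edges must satisfy 0 < lo < hi < fs/2")
  invisible(TRUE)
}

#' Band-pass filter an epoch set
#'
#' Same zero-phase filter as [bandpass()], applied independently per trial
#' and channel.
#'
#' @inheritParams bandpass
#' @param epochs an `eeg_epochs`.
#' @return filtered `eeg_epochs`.
#' @export
bandpass_epochs <- function(epochs, lo_hz, hi_hz, order = 4) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  check_band(lo_hz, hi_hz, epochs$fs)
  flt <- signal::butter(order, c(lo_hz, hi_hz) / (epochs$fs / 2), type = "pass")
  out <- epochs$data
  for (i in seq_len(dim(out)[1]))
    for (j in seq_len(dim(out)[2]))
      out[i, j, ] <- signal::filtfilt(flt, epochs$data[i, j, ])
  new_epochs(out, epochs$labels, epochs$fs, epochs$cue_sample,
             epochs$round_id, epochs$channel_labels)
}

#' Cut cue-aligned trials out of a continuous recording
#'
#' Each epoch spans `[cue - pre_s, cue + post_s)`; with the defaults and a
#' 250 Hz recording this is the standard 2 s rest + 4 s imagery trial of
#' 1500 samples, cue at sample `pre_s * fs + 1`.
#'
#' @param rec an `eeg_recording`.
#' @param cue_samples 1-based sample indices of the cues.
#' @param pre_s,post_s seconds before / after the cue (defaults 2 and 4).
#' @param labels per-trial class labels.
#' @param round_ids per-trial experimental round (1..10).
#' @return an `eeg_epochs`.
#' @export
epoch_trials <- function(rec, cue_samples, pre_s = 2, post_s = 4,
                         labels, round_ids) {
  stopifnot(inherits(rec, "eeg_recording"))
  npre <- round(pre_s * rec$fs); npost <- round(post_s * rec$fs)
  len <- npre + npost
  if (len < 1) stop("epoch window is empty")
  lo <- cue_samples - npre; hi <- cue_samples + npost - 1
  if (any(lo < 1) || any(hi > ncol(rec$data)))
    stop("epoch window exceeds recording bounds")
  arr <- array(NA_real_, c(length(cue_samples), nrow(rec$data), len))
  for (i in seq_along(cue_samples))
    arr[i, , ] <- rec$data[, lo[i]:hi[i]]
  new_epochs(arr, labels, rec$fs, cue_sample = npre + 1,
             round_id = round_ids, channel_labels = rec$channel_labels)
}

#' Baseline-correct epochs against a pre-cue window
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (default the 200 ms immediately preceding the cue). Idempotent.
#'
#' @param epochs an `eeg_epochs`.
#' @param window_ms length-2 numeric, window relative to the cue in
#'   milliseconds; must lie within the epoch.
#' @return baseline-corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, window_ms = c(-200, 0)) {
  stopifnot(inherits(epochs, "eeg_epochs"), length(window_ms) == 2,
            window_ms[1] < window_ms[2])
  idx <- baseline_indices(epochs, window_ms)
  out <- epochs$data
  bl <- apply(out[, , idx, drop = FALSE], c(1, 2), mean)
  out <- out - array(rep(bl, dim(out)[3]), dim(out))
  new_epochs(out, epochs$labels, epochs$fs, epochs$cue_sample,
             epochs$round_id, epochs$channel_labels)
}

baseline_indices <- function(epochs, window_ms) {
  # sample i covers time (i - cue_sample) / fs relative to the cue;
  # the window [a, 0] ms before a cue at sample c covers samples
  # c - a*fs/1000 .. c - 1 (the cue sample itself is post-cue).
  off <- round(window_ms / 1000 * epochs$fs)
  lo <- epochs$cue_sample + off[1]
  hi <- epochs$cue_sample + off[2] - 1
  if (lo < 1 || hi > dim(epochs$data)[3] || hi < lo)
    stop("baseline window lies outside the epoch")
  lo:hi
}

#' Round-wise 5-fold train/test split
#'
#' Trials belong to experimental rounds 1..10; fold `k` holds out rounds
#' `2k - 1` and `2k` for testing and trains on the remaining eight, so the
#' five test sets partition the rounds (8/2 split per fold).
#'
#' @param epochs an `eeg_epochs` with `round_id` in 1..10.
#' @param fold integer in 1..5.
#' @return list with `eeg_epochs` elements `train` and `test`.
#' @export
split_rounds <- function(epochs, fold) {
  stopifnot(inherits(epochs, "eeg_epochs"),
            fold %in% 1:5)
  if (!all(epochs$round_id %in% 1:10))
    stop("round_id values must lie in 1..10")
  test_rounds <- c(2 * fold - 1, 2 * fold)
  te <- epochs$round_id %in% test_rounds
  list(train = subset_epochs(epochs, which(!te)),
       test = subset_epochs(epochs, which(te)))
}
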