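## MEP extraction from TMS-mapping EMG: high-pass filtering, stimulus-locked
## epoching, peak-to-peak amplitude, acceptance rules.

#' Zero-phase high-pass filter for EMG
#'
#' Applies a 4th-order Butterworth high-pass forward and backward
#' (`signal::filtfilt`), giving zero phase distortion and suppressing the DC
#' component and low-frequency motion artefact below the cutoff. EMG for MEP
#' detection is conventionally high-pass filtered at 30 Hz.
#'
#' @param x numeric vector, EMG samples in microvolts.
#' @param sampling_rate sampling rate in Hz.
#' @param cutoff high-pass cutoff in Hz (default 30).
#' @param order Butterworth order of the one-way prototype (default 4).
#' @return filtered signal, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1/2000)
#' x <- 100 + 200 * sin(2 * pi * 100 * t)   # DC offset + 100 Hz component
#' y <- emg_highpass(x, 2000)
#' c(mean(x), mean(y))                       # DC removed
#' @export
emg_highpass <- function(x, sampling_rate, cutoff = 30, order = 4) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("EMG samples must be finite numerics", call. = FALSE)
  }
  check_scalar(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_scalar(cutoff, "cutoff", lower = 0, strict_lower = TRUE)
  if (cutoff >= sampling_rate / 2) {
    stop("cutoff must be below the Nyquist frequency (sampling_rate / 2)",
         call. = FALSE)
  }
  ## demean first: removes the DC step exactly and tames the forward-
  ## backward edge transient; the filter handles the remaining drift
  x <- x - mean(x)
  if (all(x == 0)) return(x)
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

#' Extract a stimulus-locked epoch from a continuous recording
#'
#' Returns the samples in the half-open window
#' `[stim_time, stim_time + duration)`. The default 0.5 s window is the
#' standard MEP analysis epoch following a TMS pulse. An optional blanking
#' interval at the start of the epoch (stimulus artefact suppression) zeroes
#' the first `blank` seconds; the default is no blanking.
#'
#' @param samples numeric vector, continuous EMG in microvolts; sample `i`
#'   is taken at time `(i - 1) / sampling_rate` seconds.
#' @param sampling_rate sampling rate in Hz.
#' @param stim_time stimulus time in seconds.
#' @param duration epoch length in seconds (default 0.5).
#' @param blank post-stimulus blanking length in seconds (default 0).
#' @param stim_id identifier used in error messages.
#' @return list of class `emg_epoch` with elements `samples`,
#'   `sampling_rate`, `t0`, `duration`.
#' @export
extract_epoch <- function(samples, sampling_rate, stim_time,
                          duration = 0.5, blank = 0, stim_id = NA) {
  check_scalar(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_scalar(stim_time, "stim_time", lower = 0)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  n_epoch <- as.integer(round(duration * sampling_rate))
  start <- as.integer(round(stim_time * sampling_rate)) + 1L
  if (start + n_epoch - 1L > length(samples)) {
    stop(sprintf(
      "epoch for stimulation %s (%.3f s + %.3f s) exceeds the recording",
      as.character(stim_id), stim_time, duration), call. = FALSE)
  }
  out <- samples[start:(start + n_epoch - 1L)]
  if (blank > 0) {
    nb <- min(n_epoch, as.integer(round(blank * sampling_rate)))
    out[seq_len(nb)] <- 0
  }
  structure(list(samples = out, sampling_rate = sampling_rate,
                 t0 = stim_time, duration = duration),
            class = "emg_epoch")
}

#' Peak-to-peak amplitude of an epoch
#'
#' @param epoch an `emg_epoch`, or a bare numeric vector of samples (uV).
#' @return peak-to-peak amplitude `max - min` in microvolts.
#' @examples
#' peak_to_peak(c(-30, 40))   # 70
#' @export
peak_to_peak <- function(epoch) {
  x <- if (inherits(epoch, "emg_epoch")) epoch$samples else epoch
  if (length(x) == 0L) stop("empty epoch", call. = FALSE)
  max(x) - min(x)
}

#' Detect MEPs by the peak-to-peak amplitude criterion
#'
#' An epoch counts as a motor evoked potential when its peak-to-peak
#' amplitude is strictly greater than the threshold (50 uV by convention);
#' an epoch at exactly the threshold is rejected.
#'
#' @param epochs list of epochs (as `emg_epoch` or numeric vectors), one per
#'   stimulation, for a single muscle.
#' @param stim_ids stimulation identifiers (default sequential).
#' @param muscle muscle label attached to the records.
#' @param threshold acceptance threshold in microvolts (default 50).
#' @return data.frame of MEP records: `stim_id`, `muscle`, `peak_to_peak`,
#'   `accepted`, `rejection_reason` (one of `"none"`, `"below_50uV"`,
#'   `"below_25pct_peak"`).
#' @export
detect_meps <- function(epochs, stim_ids = seq_along(epochs),
                        muscle = NA_character_, threshold = 50) {
  check_scalar(threshold, "threshold", lower = 0)
  ptp <- vapply(epochs, peak_to_peak, numeric(1))
  accepted <- ptp > threshold
  data.frame(
    stim_id = stim_ids,
    muscle = muscle,
    peak_to_peak = ptp,
    accepted = accepted,
    rejection_reason = ifelse(accepted, "none", "below_50uV"),
    stringsAsFactors = FALSE
  )
}

#' Remove low-amplitude MEPs relative to the peak response
#'
#' Among the accepted MEPs of one muscle's session, records whose
#' peak-to-peak amplitude is strictly less than `fraction` (default 25%) of
#' the maximum accepted amplitude are flagged `below_25pct_peak` and
#' de-accepted; ties at exactly the fraction are retained. The peak response
#' itself always survives, so the retained set is never emptied. Applying
#' the rule twice changes nothing: the maximum retained amplitude is
#' unchanged by the first pass.
#'
#' @param meps MEP record data.frame from [detect_meps()].
#' @param fraction cut fraction of the peak response (default 0.25).
#' @return the record data.frame with `accepted`/`rejection_reason` updated.
#' @export
filter_low_amplitude <- function(meps, fraction = 0.25) {
  if (!is.data.frame(meps) || nrow(meps) == 0L) {
    stop("no MEP records supplied", call. = FALSE)
  }
  check_scalar(fraction, "fraction", lower = 0, upper = 1)
  acc <- meps$accepted
  if (!any(acc)) stop("no accepted MEPs to filter", call. = FALSE)
  peak <- max(meps$peak_to_peak[acc])
  drop <- acc & meps$peak_to_peak < fraction * peak
  meps$accepted[drop] <- FALSE
  meps$rejection_reason[drop] <- "below_25pct_peak"
  meps
}

#' Process one muscle's raw TMS session into MEP records
#'
#' Convenience wrapper chaining [emg_highpass()] on each epoch,
#' [peak_to_peak()] detection and the 25%-of-peak exclusion. Sessions in
#' which no epoch crosses the 50 uV criterion return the record table with
#' zero accepted rows (the map stage reports the muscle outcome missing).
#'
#' @param epochs list of numeric vectors or `emg_epoch`s (raw, unfiltered).
#' @param sampling_rate Hz, used for filtering bare numeric epochs.
#' @param stim_ids,muscle,threshold,fraction passed through.
#' @param filter apply the 30 Hz high-pass first (default TRUE).
#' @return MEP record data.frame.
#' @export
process_epochs <- function(epochs, sampling_rate, stim_ids = seq_along(epochs),
                           muscle = NA_character_, threshold = 50,
                           fraction = 0.25, filter = TRUE) {
  if (filter) {
    epochs <- lapply(epochs, function(e) {
      x <- if (inherits(e, "emg_epoch")) e$samples else e
      emg_highpass(x, sampling_rate)
    })
  }
  recs <- detect_meps(epochs, stim_ids = stim_ids, muscle = muscle,
                      threshold = threshold)
  if (any(recs$accepted)) {
    recs <- filter_low_amplitude(recs, fraction = fraction)
  }
  recs
}
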