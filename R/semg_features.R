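# sEMG feature extraction: band-pass filtering, Willison amplitude (WAMP)
# over a sliding window, and per-channel min-max normalisation.

#' Band-pass filter an sEMG recording
#'
#' Fourth-order Butterworth band-pass (default 15-500 Hz), applied
#' forward-backward (zero phase) so feature frames stay aligned with marker
#' frames; the magnitude response is therefore the squared fourth-order
#' response.
#'
#' @param rec an `emg_recording`.
#' @param lo,hi cut-off frequencies (Hz); `hi` must be below Nyquist.
#' @param order filter order (per pass).
#' @return the filtered `emg_recording`.
#' @export
bandpass <- function(rec, lo = 15, hi = 500, order = 4) {
  stopifnot(inherits(rec, "emg_recording"))
  if (!(lo < hi)) stop_lipmaps("need lo < hi", "lipmaps_config_error")
  if (hi >= rec$fs / 2) {
    stop_lipmaps(sprintf(
      "upper cut-off %g Hz is not below the Nyquist frequency %g Hz",
      hi, rec$fs / 2), "lipmaps_config_error")
  }
  bf <- signal::butter(order, c(lo, hi) / (rec$fs / 2), type = "pass")
  rec$samples <- t(apply(rec$samples, 1, function(x) signal::filtfilt(bf, x)))
  rec
}

# core WAMP counter: sliding-window count of successive-sample absolute
# differences >= s_lim, windows of N samples spaced by `hop`
wamp_counts <- function(x, n_win, s_lim, hop) {
  d <- as.numeric(abs(diff(x)) >= s_lim)
  cs <- c(0, cumsum(d))
  starts <- seq.int(1L, length(x) - n_win + 1L, by = hop)
  # window starting at i covers differences i .. i+n_win-2
  cs[starts + n_win - 1L] - cs[starts]
}

#' Willison amplitude feature traces
#'
#' For every sliding window of `window` seconds (N samples), counts the
#' successive-sample absolute differences that reach the threshold `s_lim`.
#' "Maximum overlap" means a hop of one sample; each frame is stamped with
#' its window-centre time.
#'
#' @param rec an `emg_recording` (typically band-passed first).
#' @param s_lim threshold (mV), default 10.
#' @param window window length (s), default 0.2.
#' @param hop frame spacing (samples), default 1.
#' @return a `feature_series`: `values` (channels x frames), `t` (s),
#'   `window_samples`, `hop`, `s_lim`, `normalised = FALSE`.
#' @export
wamp <- function(rec, s_lim = 10, window = 0.2, hop = 1) {
  stopifnot(inherits(rec, "emg_recording"))
  n_win <- round(window * rec$fs)
  if (n_win < 2) stop_lipmaps("window must span at least 2 samples",
                              "lipmaps_config_error")
  t_s <- ncol(rec$samples)
  if (n_win > t_s) {
    stop_lipmaps(sprintf("window of %d samples exceeds signal length %d",
                         n_win, t_s), "lipmaps_feature_error")
  }
  vals <- t(apply(rec$samples, 1, wamp_counts,
                  n_win = n_win, s_lim = s_lim, hop = hop))
  if (is.null(dim(vals)) || nrow(vals) != nrow(rec$samples)) {
    vals <- matrix(vals, nrow = nrow(rec$samples))
  }
  rownames(vals) <- rownames(rec$samples)
  starts <- seq.int(1L, t_s - n_win + 1L, by = hop)
  structure(list(values = vals,
                 t = (starts - 1 + (n_win - 1) / 2) / rec$fs,
                 fs = rec$fs, window_samples = n_win, hop = hop,
                 s_lim = s_lim, normalised = FALSE,
                 instruction = rec$instruction, repetition = rec$repetition),
            class = "feature_series")
}

#' Min-max normalise feature traces
#'
#' Linearly maps each channel from its own minimum/maximum over the time
#' index to `[0, 1]`.  Channels with a constant raw feature (degenerate
#' denominator) map to all-zeros, so silent channels yield zero activation.
#'
#' @param feat a `feature_series`.
#' @return the normalised `feature_series`.
#' @export
minmax_normalise <- function(feat) {
  stopifnot(inherits(feat, "feature_series"))
  if (ncol(feat$values) == 0) {
    stop_lipmaps("empty feature series", "lipmaps_feature_error")
  }
  v <- feat$values
  lo <- apply(v, 1, min)
  hi <- apply(v, 1, max)
  rng <- hi - lo
  out <- (v - lo) / ifelse(rng > 0, rng, 1)
  out[rng == 0, ] <- 0
  feat$values <- out
  feat$normalised <- TRUE
  feat
}

#' Full feature pipeline for one recording
#'
#' Band-pass filter, WAMP, then min-max normalisation: the standard path from
#' raw bipolar sEMG to normalised per-muscle feature traces.
#'
#' @inheritParams wamp
#' @param lo,hi band-pass cut-offs (Hz).
#' @return a normalised `feature_series`.
#' @export
extract_features <- function(rec, lo = 15, hi = 500, s_lim = 10,
                             window = 0.2, hop = 1) {
  minmax_normalise(wamp(bandpass(rec, lo, hi), s_lim = s_lim,
                        window = window, hop = hop))
}
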