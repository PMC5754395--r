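# Synthetic sEMG and reference-trajectory generator.
#
# Every downstream stage of the pipeline is exercised on data produced here,
# with known ground-truth muscle activation patterns.  An sEMG channel is
# modelled as amplitude-modulated band-limited Gaussian noise: a zero-mean
# carrier filtered to the 15-500 Hz surface-EMG band, multiplied by the
# muscle's activation envelope, mixed across channels by a cross-talk matrix
# and topped with a white measurement-noise floor.

#' Cross-talk mixing model
#'
#' Builds the 14 x 14 nonnegative mixing matrix applied to the per-muscle
#' source signals.  The default couples anatomically adjacent electrode sites
#' (adjacency table in `inst/extdata/crosstalk_adjacency.json`) with a given
#' leakage fraction; rows are normalised to sum to one, so `leak = 0` gives
#' the identity (cross-talk-free) model.
#'
#' @param leak leakage fraction between adjacent sites (default 0.1).
#' @param noise_floor_mv white measurement-noise amplitude (mV RMS).
#' @param adjacency optional path to an alternative adjacency JSON.
#' @return object of class `crosstalk_model` with fields `mixing` (14 x 14)
#'   and `noise_floor_mv`.
#' @export
crosstalk_model <- function(leak = 0.1, noise_floor_mv = 0.5,
                            adjacency = NULL) {
  stopifnot(leak >= 0, leak < 1, noise_floor_mv >= 0)
  ch <- bilateral_channels(measured_muscles())
  n <- length(ch)
  A <- matrix(0, n, n, dimnames = list(ch, ch))
  if (leak > 0) {
    if (is.null(adjacency)) {
      adjacency <- system.file("extdata", "crosstalk_adjacency.json",
                               package = "lipmaps")
    }
    adj <- jsonlite::read_json(adjacency, simplifyVector = TRUE)
    for (p in seq_len(nrow(adj$same_side))) {
      for (side in c("_L", "_R")) {
        i <- paste0(adj$same_side[p, 1], side)
        j <- paste0(adj$same_side[p, 2], side)
        A[i, j] <- A[j, i] <- leak
      }
    }
    for (p in seq_len(nrow(adj$midline))) {
      i <- paste0(adj$midline[p, 1], "_L")
      j <- paste0(adj$midline[p, 2], "_R")
      A[i, j] <- A[j, i] <- leak
    }
  }
  M <- diag(n) + A
  M <- M / rowSums(M)
  dimnames(M) <- list(ch, ch)
  structure(list(mixing = M, noise_floor_mv = noise_floor_mv),
            class = "crosstalk_model")
}

#' Identity (cross-talk-free) mixing model
#' @param noise_floor_mv noise floor (mV RMS), default 0 for clean tests.
#' @return a `crosstalk_model`.
#' @export
identity_crosstalk <- function(noise_floor_mv = 0) {
  crosstalk_model(leak = 0, noise_floor_mv = noise_floor_mv)
}

# raised-cosine ramp-hold-release envelope on time grid t (s), active on
# [t0, t1] with ramp length `ramp` at each end
rc_envelope <- function(t, t0, t1, ramp = 0.3, amp = 1) {
  stopifnot(t1 > t0)
  ramp <- min(ramp, (t1 - t0) / 2)
  e <- numeric(length(t))
  up <- t >= t0 & t < t0 + ramp
  hold <- t >= t0 + ramp & t <= t1 - ramp
  down <- t > t1 - ramp & t <= t1
  e[up] <- 0.5 * (1 - cos(pi * (t[up] - t0) / ramp))
  e[hold] <- 1
  e[down] <- 0.5 * (1 - cos(pi * (t1 - t[down]) / ramp))
  amp * e
}

#' Ground-truth activation patterns for one instruction repetition
#'
#' Generates smooth ramp-hold-release activation envelopes for the measured
#' muscles engaged by the instruction, then maps them through the
#' measured-to-model transfer (see [derive_model_muscles()]) and masks the
#' result to the instruction's relevant model muscles, so that only those
#' muscles carry nonzero truth activation.  Symmetric instructions (A-D) have
#' identical left and right traces; instruction E alternates left/right
#' dominance; instruction F stages purse - smile - purse sub-gestures.
#'
#' @param instruction one of "A".."F".
#' @param duration active-gesture duration in seconds (> 0).
#' @param seed integer seed (amplitudes are drawn per muscle).
#' @param repetition repetition id stored with the truth.
#' @param fps envelope sampling rate (frames/s), default 100.
#' @param rest_s rest padding (s) before and after the gesture (each side),
#'   default 1 so consecutive repetitions are separated by 2 s of rest.
#' @param ramp ramp time (s) of the raised-cosine envelope.
#' @param amp_range range the per-muscle peak amplitude is drawn from.
#' @return object of class `activation_truth`: `model` (20 x T matrix in
#'   `[0,1]`), `measured` (14 x T envelopes), `t` (frame times, s),
#'   `instruction`, `repetition`, `duration`, `fps`, `seed`.
#' @export
gen_activation_truth <- function(instruction, duration = 2, seed = 1,
                                 repetition = 1L, fps = 100, rest_s = 1,
                                 ramp = 0.3, amp_range = c(0.6, 0.9)) {
  if (!is.character(instruction) || length(instruction) != 1 ||
      !instruction %in% names(instructions())) {
    stop_lipmaps(sprintf(
      "unknown instruction %s; valid instructions are %s",
      deparse(substitute(instruction)),
      paste(names(instructions()), collapse = ", ")),
      "lipmaps_config_error")
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop_lipmaps("duration must be positive", "lipmaps_config_error")
  }
  total <- duration + 2 * rest_s
  t <- seq(0, total, by = 1 / fps)
  ch <- bilateral_channels(measured_muscles())
  env <- matrix(0, length(ch), length(t), dimnames = list(ch, NULL))
  src <- instruction_sources()[[instruction]]
  t0 <- rest_s
  t1 <- rest_s + duration

  with_seed(seed, {
    amp <- runif(length(src), amp_range[1], amp_range[2])
    names(amp) <- src
    if (instruction %in% c("A", "B", "C", "D")) {
      # symmetric: identical left and right envelopes
      for (m in src) {
        e <- rc_envelope(t, t0, t1, ramp, amp[m])
        env[paste0(m, "_L"), ] <- e
        env[paste0(m, "_R"), ] <- e
      }
    } else if (instruction == "E") {
      # left-right-left: three sub-gestures with alternating side dominance
      d3 <- duration / 3
      r3 <- min(ramp, d3 / 3)
      for (m in src) {
        b1 <- rc_envelope(t, t0, t0 + d3, r3, amp[m])
        b2 <- rc_envelope(t, t0 + d3, t0 + 2 * d3, r3, amp[m])
        b3 <- rc_envelope(t, t0 + 2 * d3, t1, r3, amp[m])
        env[paste0(m, "_L"), ] <- b1 + 0.2 * b2 + b3
        env[paste0(m, "_R"), ] <- 0.2 * b1 + b2 + 0.2 * b3
      }
    } else { # F: purse - smile - purse
      d3 <- duration / 3
      r3 <- min(ramp, d3 / 3)
      purse <- c("OOS", "OOI")
      smile <- setdiff(src, purse)
      for (m in src) {
        b1 <- rc_envelope(t, t0, t0 + d3, r3, amp[m])
        b2 <- rc_envelope(t, t0 + d3, t0 + 2 * d3, r3, amp[m])
        b3 <- rc_envelope(t, t0 + 2 * d3, t1, r3, amp[m])
        e <- if (m %in% purse) b1 + b3 else b2
        env[paste0(m, "_L"), ] <- e
        env[paste0(m, "_R"), ] <- e
      }
    }
  })

  model <- derive_model_matrix(env)
  keep <- bilateral_channels(relevant_muscles()[[instruction]])
  model[!rownames(model) %in% keep, ] <- 0
  model <- clip01(model)

  structure(list(model = model, measured = env, t = t,
                 instruction = instruction, repetition = as.integer(repetition),
                 duration = duration, rest_s = rest_s, fps = fps, seed = seed),
            class = "activation_truth")
}

#' Synthesise a multi-channel bipolar sEMG recording
#'
#' Each measured channel is the cross-talk mixture of per-muscle sources;
#' a source is band-limited (15-500 Hz) zero-mean Gaussian noise scaled to
#' `rms_full_mv` RMS at full activation, multiplied by the muscle's envelope
#' interpolated to the sampling rate.  A white noise floor is added per the
#' cross-talk model.  Bit-identical for identical seeds.
#'
#' @param truth an `activation_truth`.
#' @param xtalk a `crosstalk_model` (default: identity, no noise).
#' @param fs sampling frequency, Hz (>= 1024 so the 15-500 Hz band fits).
#' @param seed integer seed.
#' @param rms_full_mv carrier RMS (mV) at activation 1.0.  Default 30 mV so
#'   the default Willison-amplitude threshold of 10 mV sits in the sensitive
#'   part of the counting curve.
#' @return object of class `emg_recording`: `samples` (14 x T, mV), `fs`,
#'   `channels`, `instruction`, `repetition`, `active_window` (start/end, s).
#' @export
synth_semg <- function(truth, xtalk = identity_crosstalk(), fs = 2048,
                       seed = 1, rms_full_mv = 30) {
  stopifnot(inherits(truth, "activation_truth"),
            inherits(xtalk, "crosstalk_model"))
  if (fs < 1024) {
    stop_lipmaps("fs must be >= 1024 Hz to contain the 15-500 Hz band",
                 "lipmaps_config_error")
  }
  total <- max(truth$t)
  ts <- seq(0, total, by = 1 / fs)
  env <- resample_matrix(truth$measured, truth$t, ts)
  n_ch <- nrow(env)
  bf <- signal::butter(4, c(15, 500) / (fs / 2), type = "pass")
  src <- with_seed(seed, {
    raw <- matrix(rnorm(n_ch * length(ts)), n_ch)
    nf <- if (xtalk$noise_floor_mv > 0) {
      matrix(rnorm(n_ch * length(ts), sd = xtalk$noise_floor_mv), n_ch)
    } else {
      matrix(0, n_ch, length(ts))
    }
    list(raw = raw, nf = nf)
  })
  carrier <- t(apply(src$raw, 1, function(x) {
    y <- signal::filtfilt(bf, x)
    y / max(sd(y), .Machine$double.eps)
  }))
  samples <- xtalk$mixing %*% (carrier * env * rms_full_mv) + src$nf
  rownames(samples) <- rownames(env)
  structure(list(samples = samples, fs = fs, channels = rownames(env),
                 instruction = truth$instruction, repetition = truth$repetition,
                 active_window = c(truth$rest_s, truth$rest_s + truth$duration),
                 seed = seed),
            class = "emg_recording")
}

#' Kinematic surrogate marker trajectories
#'
#' A cheap, deterministic stand-in for the finite-element model: each marker
#' is displaced by a weighted sum of muscle activations, with weights decaying
#' exponentially with the distance from the marker to the muscle fibre
#' polyline and displacement directed along the muscle's line of action
#' (toward its origin).  Useful for testing the synchronisation and metric
#' stages without running the FEM.
#'
#' @param model a `lip_model` (for marker positions and muscle geometry).
#' @param truth an `activation_truth` (its 20-channel `model` traces drive
#'   the markers).
#' @param fps output frame rate (frames/s).
#' @param amp_mm displacement scale at full activation (mm).
#' @param length_scale_mm decay length of the distance weighting (mm).
#' @return a `trajectory_set` at `fps`.
#' @export
surrogate_trajectories <- function(model, truth, fps = 100, amp_mm = 4,
                                   length_scale_mm = 8) {
  stopifnot(inherits(model, "lip_model"), inherits(truth, "activation_truth"))
  t_out <- seq(0, max(truth$t), by = 1 / fps)
  act <- resample_matrix(truth$model, truth$t, t_out)
  mk <- model$nodes[model$markers, , drop = FALSE]
  n_mk <- nrow(mk)
  pos <- array(rep(t(mk), times = length(t_out)),
               dim = c(3, n_mk, length(t_out)))
  for (mu in model$muscles) {
    a <- act[mu$name, ]
    if (all(a == 0)) next
    for (k in seq_len(n_mk)) {
      np <- nearest_on_polyline(mk[k, ], mu$polyline)
      w <- exp(-np$dist / length_scale_mm)
      dir <- mu$polyline[1, ] - np$point
      nd <- sqrt(sum(dir^2))
      if (nd < 1e-9) next
      dir <- dir / nd
      pos[, k, ] <- pos[, k, ] + (amp_mm * w) * outer(dir, a)
    }
  }
  trajectory_set(aperm(pos, c(2, 3, 1)), fps = fps, source = "measured",
                 instruction = truth$instruction, repetition = truth$repetition,
                 marker_names = names(model$markers))
}

#' Generate a labelled synthetic dataset
#'
#' One record per (instruction, repetition): ground-truth activations, an
#' sEMG recording, and reference marker trajectories produced either by the
#' finite-element lip model itself (self-consistent mode) or by the kinematic
#' surrogate.  Consecutive repetitions are separated by rest (default 2 s
#' total) baked into each record's padding.
#'
#' @param instructions_used character vector of instruction ids.
#' @param repetitions repetitions per instruction (default 4).
#' @param duration gesture duration, s.
#' @param seed master seed; per-record seeds are derived deterministically.
#' @param xtalk a `crosstalk_model`.
#' @param fs sEMG sampling rate (Hz).
#' @param fps trajectory frame rate (frames/s).
#' @param trajectory_source "fem" (self-consistent) or "surrogate".
#' @param model a `lip_model`; required for both trajectory sources.
#' @param sigma_max_kpa maximum muscle stress used for self-consistent
#'   trajectories; if NULL it is adapted from `sigma_start_kpa`.
#' @param sigma_start_kpa starting maximum stress for adaptation (kPa).
#' @param frames FEM time steps per record (self-consistent mode).
#' @param ... further arguments passed to [gen_activation_truth()].
#' @return list of class `lip_dataset`; elements have fields `truth`,
#'   `recording`, `trajectories`; attribute `sigma_max_kpa` records the
#'   stress level used in self-consistent mode.
#' @export
make_dataset <- function(instructions_used = names(instructions()),
                         repetitions = 4, duration = 2, seed = 1,
                         xtalk = crosstalk_model(), fs = 2048, fps = 100,
                         trajectory_source = c("fem", "surrogate"),
                         model = NULL, sigma_max_kpa = NULL,
                         sigma_start_kpa = 300, frames = 160, ...) {
  trajectory_source <- match.arg(trajectory_source)
  if (is.null(model)) {
    stop_lipmaps("a lip_model is required to generate reference trajectories",
                 "lipmaps_config_error")
  }
  if (repetitions < 0) {
    stop_lipmaps("repetitions must be >= 0", "lipmaps_config_error")
  }
  grid <- expand.grid(repetition = seq_len(repetitions),
                      instruction = instructions_used,
                      stringsAsFactors = FALSE)
  records <- vector("list", nrow(grid))
  sigma <- sigma_max_kpa
  if (nrow(grid) > 0) {
    for (idx in seq_len(nrow(grid))) {
      ins <- grid$instruction[idx]
      rep_i <- grid$repetition[idx]
      rec_seed <- (seed * 1009L + idx * 97L) %% 2147483647L
      truth <- gen_activation_truth(ins, duration = duration, seed = rec_seed,
                                    repetition = rep_i, fps = fps, ...)
      rec <- synth_semg(truth, xtalk = xtalk, fs = fs, seed = rec_seed + 1L)
      if (trajectory_source == "fem") {
        act <- resample_matrix(truth$model, truth$t,
                               seq(0, max(truth$t), length.out = frames))
        dt <- max(truth$t) / frames
        if (is.null(sigma)) {
          sigma <- adapt_sigma_max(model, act, dt = dt, steps = frames,
                                   sigma_start_kpa = sigma_start_kpa)
        }
        sim <- simulate_lip(model, act, dt = dt, steps = frames,
                            sigma_max_kpa = sigma)
        tr <- resample_trajectories(
          sim, round(max(truth$t) * fps))
        tr$fps <- fps
        tr$source <- "measured"
        tr$instruction <- ins
        tr$repetition <- rep_i
      } else {
        tr <- surrogate_trajectories(model, truth, fps = fps)
      }
      records[[idx]] <- list(truth = truth, recording = rec, trajectories = tr)
    }
  }
  structure(records, class = "lip_dataset", sigma_max_kpa = sigma,
            seed = seed, trajectory_source = trajectory_source)
}
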