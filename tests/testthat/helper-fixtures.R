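# shared fixtures: tiny meshes and recordings built in code

tiny_mesh_cfg <- function() mesh_config(nx = 4, ny = 1)

tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_lip_mesh(tiny_mesh_cfg())
    cache
  }
})

small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_lip_mesh(mesh_config(nx = 8, ny = 2))
    cache
  }
})

# recording wrapper around an arbitrary channel matrix
fake_recording <- function(samples, fs = 2048, instruction = "A",
                           repetition = 1L) {
  if (is.null(rownames(samples))) {
    rownames(samples) <- bilateral_channels(measured_muscles())[
      seq_len(nrow(samples))]
  }
  structure(list(samples = samples, fs = fs, channels = rownames(samples),
                 instruction = instruction, repetition = repetition,
                 active_window = c(0, ncol(samples) / fs)),
            class = "emg_recording")
}

# feature series wrapper for mapping tests
fake_features <- function(values, normalised = TRUE, instruction = "A") {
  structure(list(values = values, t = seq_len(ncol(values)), fs = 100,
                 window_samples = 2, hop = 1, s_lim = 10,
                 normalised = normalised, instruction = instruction,
                 repetition = 1L),
            class = "feature_series")
}

# 14-channel constant feature matrix from a named list of levels
measured_matrix <- function(levels, frames = 5) {
  ch <- bilateral_channels(measured_muscles())
  v <- matrix(0, length(ch), frames, dimnames = list(ch, NULL))
  for (nm in names(levels)) v[nm, ] <- levels[[nm]]
  v
}

# naive Willison amplitude recount (independent double loop)
wamp_naive <- function(x, n_win, s_lim, hop = 1) {
  starts <- seq.int(1L, length(x) - n_win + 1L, by = hop)
  vapply(starts, function(s) {
    cnt <- 0L
    for (n in 1:(n_win - 1)) {
      if (abs(x[s + n - 1] - x[s + n]) >= s_lim) cnt <- cnt + 1L
    }
    cnt
  }, integer(1))
}

# random smooth gesture-like trajectory set for sync tests: all markers share
# one smooth time course (as in a facial gesture) plus small marker-specific
# smooth components
random_smooth_traj <- function(n_mk = 10, frames = 160, seed = 1,
                               minor_sd = 0.1) {
  set.seed(seed)
  tt <- seq(0, 1, length.out = frames)
  course <- 0
  for (h in 1:4) {
    course <- course +
      rnorm(1) * sin(2 * pi * runif(1, 0.5, 6) * tt + runif(1, 0, 2 * pi))
  }
  pos <- array(0, dim = c(n_mk, frames, 3))
  for (k in seq_len(n_mk)) for (c3 in 1:3) {
    minor <- rnorm(1, 0, minor_sd) *
      sin(2 * pi * runif(1, 0.5, 6) * tt + runif(1, 0, 2 * pi))
    pos[k, , c3] <- rnorm(1) * course + minor
  }
  trajectory_set(pos, fps = frames - 1)
}
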