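test_that("activation truth engages only the instruction's relevant muscles", {
  truth_a <- gen_activation_truth("A", duration = 2, seed = 1)
  nonzero <- rownames(truth_a$model)[rowSums(truth_a$model) > 0]
  expect_setequal(nonzero, bilateral_channels(c("OOP", "OOM", "BUC")))

  truth_b <- gen_activation_truth("B", duration = 2, seed = 42)
  nonzero_b <- rownames(truth_b$model)[rowSums(truth_b$model) > 0]
  expect_setequal(nonzero_b, c("LLSAN_L", "LLSAN_R"))
  expect_length(nonzero_b, 2)

  for (ins in names(instructions())) {
    truth <- gen_activation_truth(ins, seed = 7)
    nonzero <- rownames(truth$model)[rowSums(truth$model) > 0]
    expect_true(all(nonzero %in%
                      bilateral_channels(relevant_muscles()[[ins]])),
                info = ins)
  }
})

test_that("activation truth traces are bounded, smooth and symmetric", {
  for (ins in c("A", "B", "C", "D")) {
    truth <- gen_activation_truth(ins, seed = 11)
    expect_true(all(truth$model >= 0 & truth$model <= 1))
    # symmetric instructions: left equals right
    expect_equal(truth$model[1:10, ], truth$model[11:20, ],
                 ignore_attr = TRUE)
    # slew limit: no frame-to-frame jump beyond what the ramp allows
    expect_lt(max(abs(diff(t(truth$model)))), 0.1)
  }
  # E alternates dominance: left and right traces differ
  truth_e <- gen_activation_truth("E", seed = 11)
  expect_gt(max(abs(truth_e$model[1:10, ] - truth_e$model[11:20, ])), 0.1)
})

test_that("invalid truth requests are rejected with informative errors", {
  expect_error(gen_activation_truth("Z"), "unknown instruction")
  expect_error(gen_activation_truth("A", duration = 0), "positive")
})

test_that("sEMG synthesis is deterministic and respects the mixing model", {
  truth <- gen_activation_truth("A", seed = 5)
  r1 <- synth_semg(truth, identity_crosstalk(0), seed = 9)
  r2 <- synth_semg(truth, identity_crosstalk(0), seed = 9)
  expect_identical(r1$samples, r2$samples)

  # zero activation, identity mixing, zero noise -> all-zero channels
  truth0 <- truth
  truth0$measured[] <- 0
  r0 <- synth_semg(truth0, identity_crosstalk(0), seed = 9)
  expect_equal(max(abs(r0$samples)), 0)

  expect_error(synth_semg(truth, fs = 512), "1024")
})

test_that("windowed RMS grows monotonically with the envelope level", {
  truth <- gen_activation_truth("A", seed = 5)
  active <- truth$t >= 1.5 & truth$t <= 2.5 # plateau of the gesture
  rms_at <- function(level) {
    tr <- truth
    tr$measured[] <- 0
    tr$measured["OOS_L", active] <- level
    rec <- synth_semg(tr, identity_crosstalk(0), fs = 2048, seed = 3)
    mid <- rec$samples["OOS_L", seq(1.7 * 2048, 2.3 * 2048)]
    sqrt(mean(mid^2))
  }
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  rms <- vapply(levels, rms_at, numeric(1))
  expect_true(all(diff(rms) >= 0))
  expect_gt(rms_at(0.8), rms_at(0.2))
})

test_that("generated carrier power is concentrated in the 15-500 Hz band", {
  truth <- gen_activation_truth("A", seed = 5)
  truth$measured[] <- 1
  rec <- synth_semg(truth, identity_crosstalk(0), fs = 2048, seed = 3)
  x <- rec$samples["OOS_L", ]
  sp <- stats::spec.pgram(x, plot = FALSE, taper = 0)
  f_hz <- sp$freq * rec$fs
  in_band <- f_hz >= 15 & f_hz <= 500
  expect_gt(sum(sp$spec[in_band]) / sum(sp$spec), 0.95)
})

test_that("cross-talk model is nonnegative with unit row sums", {
  xt <- crosstalk_model(0.1)
  expect_true(all(xt$mixing >= 0))
  expect_equal(rowSums(xt$mixing), rep(1, 14), ignore_attr = TRUE)
  expect_equal(identity_crosstalk()$mixing, diag(14), ignore_attr = TRUE)
})

test_that("dataset generation yields one record per instruction-repetition", {
  model <- small_model()
  ds <- make_dataset(instructions_used = c("A", "B"), repetitions = 2,
                     seed = 1, model = model,
                     trajectory_source = "surrogate")
  expect_length(ds, 4)
  expect_identical(
    vapply(ds, function(r) r$recording$instruction, character(1)),
    c("A", "A", "B", "B"))
  expect_equal(ds[[1]]$trajectories$fps, 100)

  ds0 <- make_dataset(instructions_used = "A", repetitions = 0,
                      seed = 1, model = model,
                      trajectory_source = "surrogate")
  expect_length(ds0, 0)

  expect_error(make_dataset(instructions_used = "A", repetitions = 1,
                            model = NULL),
               "lip_model")
})

test_that("identical seeds reproduce the dataset bit-exactly", {
  model <- small_model()
  ds1 <- make_dataset(instructions_used = "A", repetitions = 1, seed = 4,
                      model = model, trajectory_source = "surrogate")
  ds2 <- make_dataset(instructions_used = "A", repetitions = 1, seed = 4,
                      model = model, trajectory_source = "surrogate")
  expect_identical(ds1[[1]]$recording$samples, ds2[[1]]$recording$samples)
  expect_identical(ds1[[1]]$trajectories$pos, ds2[[1]]$trajectories$pos)
})
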