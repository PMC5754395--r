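test_that("measured-to-model transfer reproduces the worked arithmetic", {
  v <- measured_matrix(list(OOS_L = 0.4, OOI_L = 0.6, RIS_L = 0.2,
                            ZYG_L = 0.4, LLSAN_L = 0.8, DAO_L = 0.4))
  out <- derive_model_muscles(fake_features(v))$values
  expect_equal(unname(out["OOP_L", 1]), 0.5)
  expect_equal(unname(out["OOM_L", 1]), 0.10 * (0.5 + 0.6))
  expect_equal(unname(out["BUC_L", 1]), 0.3)
  expect_equal(unname(out["LAO_L", 1]), 0.6)
  expect_equal(unname(out["DLI_L", 1]), 0.3)
  # pass-through channels
  expect_equal(unname(out["ZYG_L", 1]), 0.4)
  expect_equal(unname(out["LLSAN_L", 1]), 0.8)
  # untouched right side stays zero; all-zero input maps to all zeros
  expect_equal(sum(out[grepl("_R$", rownames(out)), ]), 0)
  zero <- derive_model_muscles(fake_features(measured_matrix(list())))$values
  expect_equal(sum(abs(zero)), 0)
})

test_that("transfer is degree-1 homogeneous below the clip threshold", {
  set.seed(21)
  v <- measured_matrix(list())
  v[] <- runif(length(v), 0, 0.3)
  one <- derive_model_muscles(fake_features(v))$values
  two <- derive_model_muscles(fake_features(2 * v))$values
  expect_equal(two, 2 * one, tolerance = 1e-12)
  # and outputs stay within [0,1] for arbitrary nonnegative inputs
  v[] <- runif(length(v), 0, 5)
  big <- derive_model_muscles(fake_features(v))$values
  expect_true(all(big >= 0 & big <= 1))
})

test_that("missing measured channels are rejected by name", {
  v <- measured_matrix(list())[-1, ]
  expect_error(derive_model_muscles(fake_features(v)), "OOS_L")
})

test_that("bilateral averaging is the frame-wise mean of the two sides", {
  ch <- bilateral_channels(model_muscles())
  v <- matrix(0, 20, 4, dimnames = list(ch, NULL))
  v["OOP_L", ] <- 0.2
  v["OOP_R", ] <- 0.4
  avg <- bilateral_average(v)
  expect_equal(unname(avg["OOP", ]), rep(0.3, 4))

  set.seed(5)
  v[] <- runif(length(v))
  avg <- bilateral_average(v)
  # brute-force per-frame recount
  for (m in model_muscles()) {
    for (fr in 1:4) {
      expect_equal(unname(avg[m, fr]),
                   mean(unname(c(v[paste0(m, "_L"), fr],
                                 v[paste0(m, "_R"), fr]))))
    }
  }
  # symmetric input: average equals either side
  v[11:20, ] <- v[1:10, ]
  expect_equal(unname(bilateral_average(v)), unname(v[1:10, ]))

  expect_error(bilateral_average(matrix(0, 20, 4)), "metadata")
})

test_that("top-3 selection ranks by variance with canonical tie-break", {
  mk10 <- function() matrix(0, 10, 50, dimnames = list(model_muscles(), NULL))
  v <- mk10()
  v["OOP", ] <- seq(0, 0.9, length.out = 50)   # largest variance
  v["MEN", ] <- seq(0, 0.6, length.out = 50)
  v["ZYG", ] <- seq(0, 0.3, length.out = 50)
  expect_identical(select_top3(v), c("OOP", "MEN", "ZYG"))

  # all-equal variances -> first three muscles in canonical order
  v2 <- mk10()
  v2[] <- rep(seq(0, 1, length.out = 50), each = 10)
  expect_identical(select_top3(v2), model_muscles()[1:3])

  expect_error(select_top3(v[1:2, ]), "3 muscles")
})

test_that("top-3 selection matches a brute-force variance sort", {
  set.seed(99)
  for (trial in 1:200) {
    v <- matrix(runif(10 * 30), 10, dimnames = list(model_muscles(), NULL))
    got <- select_top3(v)
    vars <- apply(v, 1, var)
    ord <- model_muscles()[order(-vars)]
    expect_identical(got, ord[1:3])
  }
})

test_that("strategies gate the expected channel support", {
  set.seed(31)
  ch <- bilateral_channels(model_muscles())
  v <- matrix(runif(20 * 40), 20, dimnames = list(ch, NULL))
  feat <- fake_features(v)

  all_out <- apply_strategy(feat, "act_all")
  expect_equal(all_out$act, v)

  # act_rel for D: support within the relevant-muscle channels
  rel <- apply_strategy(feat, "act_rel", "D")
  nonzero <- rownames(rel$act)[rowSums(rel$act) > 0]
  expect_true(all(nonzero %in% bilateral_channels(
    c("LLSAN", "RIS", "ZYG", "LAO", "DAO", "DLI"))))
  for (ins in names(instructions())) {
    ri <- apply_strategy(feat, "act_rel", ins)
    expect_setequal(
      rownames(ri$act)[rowSums(ri$act) > 0],
      bilateral_channels(relevant_muscles()[[ins]]))
  }

  # act_3 support is the selected muscles on both sides, with each side
  # keeping its own trace
  top <- apply_strategy(feat, "act_3")
  sel <- select_top3(bilateral_average(v))
  expect_setequal(rownames(top$act)[rowSums(top$act) > 0],
                  bilateral_channels(sel))
  expect_equal(top$act[paste0(sel[1], "_L"), ], v[paste0(sel[1], "_L"), ])
  expect_equal(top$act[paste0(sel[1], "_R"), ], v[paste0(sel[1], "_R"), ])
  # act_3 support is a subset of act_all support
  expect_true(all(rowSums(top$act) <= rowSums(all_out$act) + 1e-12))

  # constructed dominant muscle must appear in the selection
  v2 <- matrix(0, 20, 40, dimnames = list(ch, NULL))
  v2["OOP_L", ] <- seq(0, 1, length.out = 40)
  v2["OOP_R", ] <- seq(0, 1, length.out = 40)
  got <- apply_strategy(fake_features(v2), "act_3")
  expect_true("OOP" %in% got$selected)

  expect_error(apply_strategy(feat, "act_5"), "arg")
  expect_error(apply_strategy(feat, "act_rel"), "instruction")
  expect_error(apply_strategy(feat, "act_rel", "Q"), "unknown instruction")
})

test_that("activation sets stay within [0,1] under fuzzing", {
  set.seed(12)
  ch <- bilateral_channels(model_muscles())
  for (trial in 1:20) {
    v <- matrix(runif(20 * 10, 0, 3), 20, dimnames = list(ch, NULL))
    out <- apply_strategy(fake_features(v),
                          sample(c("act_all", "act_3", "act_rel"), 1),
                          instruction = sample(names(instructions()), 1))
    expect_true(all(out$act >= 0 & out$act <= 1))
  }
})
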