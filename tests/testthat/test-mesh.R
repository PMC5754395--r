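test_that("default mesh has the configured element count and fixed set", {
  model <- build_lip_mesh()
  expect_equal(nrow(model$elems), 2 * 16 * 4 * 3)
  expect_equal(sort(unique(model$layer)), c("centre", "inner", "outer"))
  # every node on the inner surface (smallest radius) is fixed
  r <- sqrt(model$nodes[, 1]^2 + model$nodes[, 3]^2)
  inner <- which(abs(r - model$cfg$r_inner_mm) < 1e-9)
  expect_setequal(model$fixed, inner)
  expect_length(model$markers, 10)
  # markers sit on the outer surface
  expect_true(all(abs(r[model$markers] -
                        (model$cfg$r_inner_mm +
                           sum(model$cfg$layer_thicknesses_mm))) < 1e-9))
  # left/right marker pairs mirror in x
  expect_equal(model$nodes[model$markers["UL_corner_L"], 1],
               -model$nodes[model$markers["UL_corner_R"], 1])
  expect_equal(model$nodes[model$markers["UL_corner_L"], 2:3],
               model$nodes[model$markers["UL_corner_R"], 2:3])
})

test_that("mesh volume approximates the analytic arc-slab volume", {
  model <- build_lip_mesh()
  expect_lt(abs(mesh_volume(model) / analytic_slab_volume(model$cfg) - 1),
            0.01)
  # at any resolution the discrete volume equals the chord-corrected
  # closed form exactly (polygonal arc, trilinear elements)
  for (cfg in list(mesh_config(), mesh_config(nx = 8, ny = 2),
                   tiny_mesh_cfg())) {
    m <- build_lip_mesh(cfg)
    dth <- cfg$arc_deg * pi / 180 / cfg$nx
    expect_equal(mesh_volume(m),
                 analytic_slab_volume(cfg) * sin(dth) / dth,
                 tolerance = 1e-10)
  }
})

test_that("reference element Jacobians are positive", {
  model <- tiny_model()
  expect_true(all(lipmaps:::hex_volumes(model$nodes, model$elems) > 0))
  # an element with flipped connectivity has negative volume
  bad <- model$elems
  bad[1, ] <- bad[1, c(4, 3, 2, 1, 8, 7, 6, 5)]
  expect_lt(lipmaps:::hex_volumes(model$nodes, bad)[1], 0)
})

test_that("muscle-element assignment follows the distance rule", {
  # two-unit-cube mesh with known centroids
  nodes <- as.matrix(rbind(
    expand.grid(x = 0:1 * 10, y = 0:1 * 10, z = 0:1 * 10)))[, 1:3]
  nodes <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0),
                 c(0, 0, 10), c(10, 0, 10), c(10, 10, 10), c(0, 10, 10))
  model <- structure(list(nodes = nodes, elems = matrix(1:8, 1, 8)),
                     class = "lip_model")
  # centroid (5,5,5): polyline 4 mm away -> included, 6 mm away -> excluded
  mus4 <- muscle_def("ZYG_L", rbind(c(-20, 5, 9), c(20, 5, 9)))
  got4 <- assign_muscle_elements(model, mus4, radius = 5)
  expect_identical(got4$elements, 1L)
  expect_equal(abs(got4$dirs[1, ]), c(1, 0, 0))
  mus6 <- muscle_def("ZYG_L", rbind(c(-20, 5, 11), c(20, 5, 11)))
  expect_warning(got6 <- assign_muscle_elements(model, mus6, radius = 5),
                 "no elements")
  expect_length(got6$elements, 0)
  # explicit element list overrides the rule
  musov <- muscle_def("ZYG_L", rbind(c(-20, 5, 11), c(20, 5, 11)),
                      elements = 1L)
  expect_identical(assign_muscle_elements(model, musov)$elements, 1L)
})

test_that("assignment matches a brute-force distance scan on random inputs", {
  model <- tiny_model()
  cent <- lipmaps:::element_centroids(model$nodes, model$elems)
  set.seed(71)
  seg_dist <- function(p, a, b) {
    ab <- b - a
    tt <- max(0, min(1, sum((p - a) * ab) / max(sum(ab^2), 1e-300)))
    sqrt(sum((p - a - tt * ab)^2))
  }
  for (trial in 1:50) {
    poly <- matrix(runif(9, -30, 30), 3, 3)
    poly[, 2] <- runif(3, -15, 15)
    mus <- muscle_def("RIS_L", poly)
    got <- suppressWarnings(assign_muscle_elements(model, mus, radius = 5))
    want <- which(vapply(seq_len(nrow(cent)), function(e) {
      d <- min(vapply(seq_len(nrow(poly) - 1), function(s) {
        seg_dist(cent[e, ], poly[s, ], poly[s + 1, ])
      }, numeric(1)))
      d <= 5
    }, logical(1)))
    expect_identical(got$elements, as.integer(want))
  }
})

test_that("mesh round-trips through the VTK writer", {
  model <- tiny_model()
  path <- file.path(tempdir(), "lip.vtk")
  write_lip_mesh(model, path)
  back <- read_lip_mesh(path)
  expect_equal(back$nodes, model$nodes, tolerance = 1e-8)
  expect_identical(back$elems, model$elems)
  expect_identical(back$fixed, model$fixed)
  expect_equal(unname(back$markers), unname(model$markers))
  expect_identical(lapply(back$muscle_elements, `[[`, "elements"),
                   lapply(model$muscle_elements, `[[`, "elements"))
})
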