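# Forward dynamics of the lip model: implicit (backward-Euler) time stepping
# with a lumped mass matrix from the tissue density, stiffness-proportional
# damping anchored at the reference-state stiffness, gravity, exact internal
# forces and a finite-difference-consistent Newton tangent (assembled in
# compiled code, solved sparsely).

# conversions to the internal mm / tonne / s / MPa system
.fem_pars <- function(model, sigma_max_kpa) {
  mat <- model$material
  m1 <- model$muscles[[1]] # fibre-law parameters are common across muscles
  list(c10 = mat$c10_kpa * 1e-3, c20 = mat$c20_kpa * 1e-3,
       kappa = mat$kappa_kpa * 1e-3, bulk = mat$bulk_kpa * 1e-3,
       p1 = m1$p1, p2 = m1$p2, lam_star = m1$lambda_star,
       lam_ofl = m1$lambda_ofl, sigma_max = sigma_max_kpa * 1e-3)
}

# flatten the per-muscle element assignments into parallel vectors
.fem_fibres <- function(model) {
  elem <- integer(0); mus <- character(0); dirs <- NULL
  for (nm in names(model$muscle_elements)) {
    me <- model$muscle_elements[[nm]]
    if (length(me$elements) == 0) next
    elem <- c(elem, me$elements)
    mus <- c(mus, rep(nm, length(me$elements)))
    dirs <- rbind(dirs, me$dirs)
  }
  if (is.null(dirs)) dirs <- matrix(0, 0, 3)
  list(elem = as.integer(elem), muscle = mus, dir = dirs)
}

# sparse-pattern bookkeeping: triplet indices for the per-element 24x24
# stiffness blocks, the map from triplet slots into the full dgCMatrix @x
# slot, and the free-dof submatrix extraction indices.  Cached per model
# geometry since it only depends on connectivity and the fixed set.
.pattern_cache <- new.env(parent = emptyenv())

.fem_pattern <- function(model) {
  key <- paste(nrow(model$nodes), nrow(model$elems),
               sum(as.double(model$elems) * seq_len(length(model$elems))),
               sum(model$fixed), sep = "/")
  hit <- .pattern_cache[[key]]
  if (!is.null(hit)) return(hit)

  ne <- nrow(model$elems)
  ndof <- 3L * nrow(model$nodes)
  dof_of <- function(nodes) as.vector(rbind(3L * (nodes - 1L) + 1L,
                                            3L * (nodes - 1L) + 2L,
                                            3L * (nodes - 1L) + 3L))
  trip_i <- integer(ne * 576L)
  trip_j <- integer(ne * 576L)
  for (e in seq_len(ne)) {
    d <- dof_of(model$elems[e, ])
    blk <- (e - 1L) * 576L
    trip_i[blk + seq_len(576L)] <- rep(d, times = 24L)
    trip_j[blk + seq_len(576L)] <- rep(d, each = 24L)
  }
  K <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = 0,
                            dims = c(ndof, ndof))
  slot_col <- rep(seq_len(ndof), diff(K@p))
  slot_key <- (slot_col - 1) * ndof + (K@i + 1)
  map <- match((trip_j - 1) * ndof + trip_i, slot_key)

  free <- setdiff(seq_len(nrow(model$nodes)), model$fixed)
  free_dof <- dof_of(free)
  Kidx <- K
  Kidx@x <- as.numeric(seq_along(K@x))
  Kff <- Kidx[free_dof, free_dof]
  sel <- as.integer(Kff@x)
  Kff@x <- numeric(length(sel))
  nf <- length(free_dof)
  ff_col <- rep(seq_len(nf), diff(Kff@p))
  dpos <- which(ff_col == Kff@i + 1L) # diagonal slots of the free submatrix

  pat <- list(map = map, nnz = length(K@x), Kff = Kff, sel = sel,
              dpos = dpos, free = free, free_dof = free_dof, ndof = ndof)
  .pattern_cache[[key]] <- pat
  pat
}

# free-submatrix @x values from per-element stiffness values
.fem_kff_x <- function(pat, kvals) {
  fem_aggregate(kvals, pat$map, pat$nnz)[pat$sel]
}

#' Simulate lip motion under an activation set
#'
#' Time-steps the model with backward-Euler dynamics: lumped mass from the
#' tissue density, stiffness-proportional damping `beta * K_ref`, gravity,
#' Mooney-Rivlin passive stresses, soft-incompressibility bulk penalty, and
#' active/passive fibre stresses scaled by `sigma_max_kpa`.  Fixed
#' inner-surface nodes never move.  An element whose deformation-gradient
#' determinant becomes non-positive (or numerically degenerate) raises an
#' inverted-element condition that [adapt_sigma_max()] consumes.
#'
#' @param model a `lip_model`.
#' @param act an `activation_set` or a 20 x `steps` matrix with the canonical
#'   bilateral model channels as row names (values in `[0,1]`).
#' @param dt time-step (s).  Defaults to `duration / steps` where a duration
#'   attribute is available, else 0.0125 s.
#' @param steps number of time steps (default: activation frame count).
#' @param sigma_max_kpa maximum muscle stress (kPa), default 300.
#' @param damping_beta stiffness-proportional damping coefficient (s).
#' @param gravity logical; apply gravity (default TRUE).
#' @param rel_tol Newton convergence tolerance (relative residual).
#' @param max_iter Newton iteration cap per (sub)step.
#' @return a `trajectory_set` (10 markers x steps x 3, source "simulated")
#'   with attribute `detF_range` (steps x 2: min and max det F per step) and
#'   `sigma_max_kpa`.
#' @export
simulate_lip <- function(model, act, dt = NULL, steps = NULL,
                         sigma_max_kpa = 300, damping_beta = 0.05,
                         gravity = TRUE, rel_tol = 1e-9, max_iter = 40) {
  stopifnot(inherits(model, "lip_model"))
  act_m <- if (inherits(act, "activation_set")) act$act else act
  stopifnot(is.matrix(act_m))
  want <- bilateral_channels(model_muscles())
  if (is.null(rownames(act_m)) || !all(want %in% rownames(act_m))) {
    stop_lipmaps("activation matrix must carry the 20 canonical channel names",
                 "lipmaps_channel_error")
  }
  act_m <- clip01(act_m[want, , drop = FALSE])
  if (is.null(steps)) steps <- ncol(act_m)
  if (ncol(act_m) != steps) {
    stop_lipmaps("activation frame count must equal the number of steps",
                 "lipmaps_config_error")
  }
  if (is.null(dt)) dt <- 0.0125

  pars <- .fem_pars(model, sigma_max_kpa)
  fib <- .fem_fibres(model)
  pat <- .fem_pattern(model)
  nn <- nrow(model$nodes)
  free_dof <- pat$free_dof

  density <- model$material$density_kg_m3 * 1e-12 # tonne / mm^3
  m_node <- fem_lumped_mass(model$nodes, model$elems, density)
  m_dof <- rep(m_node, each = 3)
  g_mm <- model$material$gravity_m_s2 * 1e3
  f_ext <- matrix(0, nn, 3)
  if (gravity) f_ext[, 2] <- -m_node * g_mm
  f_ext_dof <- as.vector(t(f_ext))

  zero_act <- rep(0, length(fib$elem))
  ref <- fem_assemble(model$nodes, model$elems, model$nodes, pars,
                      fib$elem, fib$dir, zero_act, TRUE)
  K0ff_x <- .fem_kff_x(pat, ref$kvals)
  K0_free <- pat$Kff
  K0_free@x <- K0ff_x
  M_free <- m_dof[free_dof]

  x <- model$nodes
  v <- matrix(0, nn, 3)
  n_mk <- length(model$markers)
  traj <- array(0, dim = c(n_mk, steps, 3),
                dimnames = list(names(model$markers), NULL, NULL))
  detf <- matrix(NA_real_, steps, 2)

  f_scale <- max(sqrt(sum(f_ext_dof^2)), 1e-6)

  step_once <- function(x, v, dt_s, a_fib, step_id) {
    x_new <- x + dt_s * v
    asm <- fem_assemble(model$nodes, model$elems, x_new, pars,
                        fib$elem, fib$dir, a_fib, TRUE)
    if (asm$inverted > 0) {
      x_new <- x
      asm <- fem_assemble(model$nodes, model$elems, x_new, pars,
                          fib$elem, fib$dir, a_fib, TRUE)
      if (asm$inverted > 0) stop(inverted_element_condition(asm$inverted,
                                                            step_id))
    }
    dx <- as.vector(t(x_new - x))
    for (it in seq_len(max_iter)) {
      f_int <- as.vector(t(asm$force))
      r_free <- M_free * (dx[free_dof] - dt_s * as.vector(t(v))[free_dof]) /
        dt_s^2 +
        as.vector(K0_free %*% (dx[free_dof] / dt_s)) * damping_beta +
        f_int[free_dof] - f_ext_dof[free_dof]
      rn <- sqrt(sum(r_free^2))
      tol <- rel_tol * max(f_scale, sqrt(sum(f_int[free_dof]^2))) + 1e-12
      if (rn <= tol) {
        return(list(x = x_new, asm = asm, converged = TRUE))
      }
      A <- pat$Kff
      A@x <- .fem_kff_x(pat, asm$kvals) + (damping_beta / dt_s) * K0ff_x
      A@x[pat$dpos] <- A@x[pat$dpos] + M_free / dt_s^2
      delta <- as.vector(Matrix::solve(A, r_free))
      scale <- 1
      repeat {
        x_try <- x_new
        x_try_t <- t(x_try)
        x_try_t[free_dof] <- x_try_t[free_dof] - scale * delta
        x_try <- t(x_try_t)
        asm_try <- fem_assemble(model$nodes, model$elems, x_try, pars,
                                fib$elem, fib$dir, a_fib, TRUE)
        if (asm_try$inverted == 0 && asm_try$min_detF > 1e-3) break
        scale <- scale / 2
        if (scale < 1 / 512) {
          bad <- if (asm_try$inverted > 0) asm_try$inverted else 0L
          stop(inverted_element_condition(bad, step_id))
        }
      }
      x_new <- x_try
      dx <- as.vector(t(x_new - x))
      asm <- asm_try
    }
    list(x = x_new, asm = asm, converged = FALSE)
  }

  advance <- function(x, v, dt_s, a_fib, step_id, depth = 0) {
    res <- step_once(x, v, dt_s, a_fib, step_id)
    if (res$converged) {
      v_new <- (res$x - x) / dt_s
      return(list(x = res$x, v = v_new, asm = res$asm))
    }
    if (depth >= 4) {
      stop_lipmaps(sprintf("Newton did not converge at time step %d", step_id),
                   "lipmaps_nonconvergence", step = step_id)
    }
    half <- advance(x, v, dt_s / 2, a_fib, step_id, depth + 1)
    advance(half$x, half$v, dt_s / 2, a_fib, step_id, depth + 1)
  }

  for (s in seq_len(steps)) {
    a_fib <- act_m[fib$muscle, s]
    st <- advance(x, v, dt, if (length(fib$elem)) a_fib else numeric(0), s)
    x <- st$x
    v <- st$v
    detf[s, ] <- c(st$asm$min_detF, st$asm$max_detF)
    traj[, s, ] <- x[model$markers, , drop = FALSE]
  }

  out <- trajectory_set(traj, fps = 1 / dt, source = "simulated",
                        instruction = if (inherits(act, "activation_set"))
                          act$instruction else NA_character_,
                        repetition = if (inherits(act, "activation_set"))
                          act$repetition else NA_integer_,
                        marker_names = names(model$markers))
  attr(out, "detF_range") <- detf
  attr(out, "sigma_max_kpa") <- sigma_max_kpa
  out
}

#' Adapt the maximum muscle stress until the simulation is stable
#'
#' Runs the simulation at the starting maximum stress and, every time an
#' inverted element occurs, multiplies the stress by 0.9 and restarts,
#' returning the first stress level that completes cleanly (a strictly
#' geometric decrement sequence).  A hard floor guards against endless
#' decrements.
#'
#' @param model a `lip_model`.
#' @param act activation input as in [simulate_lip()].
#' @param dt,steps passed to the simulation.
#' @param sigma_start_kpa starting maximum stress (kPa), default 300.
#' @param floor_kpa hard floor (kPa); reaching it raises an error.
#' @param sim_fn simulation function (injectable for testing); must accept
#'   `(model, act, dt, steps, sigma_max_kpa, ...)` and raise a
#'   `lipmaps_inverted_element` condition on failure.
#' @param ... passed through to `sim_fn`.
#' @return the adapted `sigma_max` (kPa) with attributes `trace` (all stress
#'   levels tried) and `runs` (number of simulation attempts).
#' @export
adapt_sigma_max <- function(model, act, dt = NULL, steps = NULL,
                            sigma_start_kpa = 300, floor_kpa = 1,
                            sim_fn = simulate_lip, ...) {
  sigma <- sigma_start_kpa
  trace <- numeric(0)
  repeat {
    trace <- c(trace, sigma)
    ok <- tryCatch({
      sim_fn(model, act, dt = dt, steps = steps, sigma_max_kpa = sigma, ...)
      TRUE
    }, lipmaps_inverted_element = function(e) FALSE)
    if (ok) break
    sigma <- 0.9 * sigma
    if (sigma < floor_kpa) {
      stop_lipmaps(sprintf(
        "cannot stabilise: sigma_max fell below the %g kPa floor", floor_kpa),
        "lipmaps_adapt_error")
    }
  }
  structure(sigma, trace = trace, runs = length(trace))
}
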