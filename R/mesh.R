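# Reduced structured lip mesh: two curved all-hexahedral slabs (upper and
# lower lip) with three element layers through the thickness (inner, centre,
# outer), inner-surface nodes fixed to the underlying bone, ten marker nodes
# on the vermilion border, and schematic muscle fibre polylines.
#
# Geometry: a cylindrical arc with vertical axis; x lateral (left +x),
# y vertical, z anterior.  Local element axes are (arc, vertical, depth
# outward), which yields positive reference Jacobians.

#' Mesh configuration defaults
#'
#' @param nx,ny elements along the lip arc and lip height, per lip.
#' @param layer_thicknesses_mm element-layer thicknesses through the depth
#'   (inner, centre, outer), mm.  The outer (epidermis/dermis) layer is
#'   1.5 mm; the two hypodermis layers make up the rest.
#' @param r_inner_mm inner-surface radius of the lip arc (mm).
#' @param arc_deg angular span of the lip arc (degrees).
#' @param lip_height_mm height of each lip slab (mm).
#' @param gap_mm initial separation between the lips (mm); the lips never
#'   start in contact and interpenetration is not checked.
#' @param muscle_radius_mm assignment radius of the muscle-element rule (mm).
#' @return list of mesh parameters.
#' @export
mesh_config <- function(nx = 16, ny = 4, layer_thicknesses_mm = c(2.5, 2, 1.5),
                        r_inner_mm = 25, arc_deg = 120, lip_height_mm = 10,
                        gap_mm = 2, muscle_radius_mm = 5) {
  stopifnot(nx >= 2, ny >= 1, all(layer_thicknesses_mm > 0),
            r_inner_mm > 0, arc_deg > 0, arc_deg < 180,
            lip_height_mm > 0, gap_mm > 0)
  list(nx = as.integer(nx), ny = as.integer(ny),
       layer_thicknesses_mm = layer_thicknesses_mm,
       r_inner_mm = r_inner_mm, arc_deg = arc_deg,
       lip_height_mm = lip_height_mm, gap_mm = gap_mm,
       muscle_radius_mm = muscle_radius_mm)
}

# closest point on a polyline to p; returns distance, point and unit tangent
# of the nearest segment
nearest_on_polyline <- function(p, poly) {
  best <- list(dist = Inf, point = NULL, tangent = NULL)
  for (s in seq_len(nrow(poly) - 1)) {
    a <- poly[s, ]; b <- poly[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
    q <- a + tt * ab
    d <- sqrt(sum((p - q)^2))
    if (d < best$dist) {
      tangent <- if (len2 == 0) c(1, 0, 0) else ab / sqrt(len2)
      best <- list(dist = d, point = q, tangent = tangent)
    }
  }
  best
}

#' Assign muscle elements by the distance rule
#'
#' Elements whose centroid lies within `radius` of the muscle's fibre
#' polyline become muscle elements; their fibre direction is the unit tangent
#' of the nearest polyline segment.  An explicit `elements` list in the
#' [muscle_def()] overrides the rule (manual assignment hook).
#'
#' @param model a `lip_model`.
#' @param muscle a [muscle_def()].
#' @param radius assignment radius (mm), default 5.
#' @return list: `elements` (integer ids), `dirs` (k x 3 unit fibre
#'   directions).  Empty assignments emit a warning (inactive muscle).
#' @export
assign_muscle_elements <- function(model, muscle, radius = 5) {
  stopifnot(inherits(model, "lip_model"), inherits(muscle, "muscle_def"))
  cent <- element_centroids(model$nodes, model$elems)
  if (!is.null(muscle$elements)) {
    ids <- as.integer(muscle$elements)
    dirs <- t(vapply(ids, function(e) {
      nearest_on_polyline(cent[e, ], muscle$polyline)$tangent
    }, numeric(3)))
    return(list(elements = ids, dirs = dirs))
  }
  hits <- integer(0)
  dirs <- NULL
  for (e in seq_len(nrow(model$elems))) {
    np <- nearest_on_polyline(cent[e, ], muscle$polyline)
    if (np$dist <= radius) {
      hits <- c(hits, e)
      dirs <- rbind(dirs, np$tangent)
    }
  }
  if (length(hits) == 0) {
    warning(sprintf("muscle %s captured no elements (inactive)", muscle$name))
    dirs <- matrix(0, 0, 3)
  }
  list(elements = hits, dirs = dirs)
}

hex_volumes <- function(nodes, elems) {
  storage.mode(elems) <- "integer"
  fem_hex_volumes(nodes, elems)
}

element_centroids <- function(nodes, elems) {
  t(apply(elems, 1, function(e) colMeans(nodes[e, , drop = FALSE])))
}

#' Schematic muscle fibre polylines for the reduced lip mesh
#'
#' Twenty [muscle_def()]s (10 per side, left mirrored to right across the
#' midsagittal plane).  The orbicularis oris rings follow the lip arcs at
#' mid-depth; the radial muscles run from their (extramesh) origins to
#' insertions at the lip corners or vermilion, so the 5 mm distance rule
#' captures the elements along each line of action.  Shipped as code so the
#' polylines remain editable configuration.
#'
#' @param cfg a [mesh_config()].
#' @return named list of 20 `muscle_def`s.
#' @export
default_muscle_set <- function(cfg = mesh_config()) {
  half <- cfg$arc_deg / 2 * pi / 180
  t_tot <- sum(cfg$layer_thicknesses_mm)
  r_mid <- cfg$r_inner_mm + t_tot / 2
  h <- cfg$lip_height_mm
  g2 <- cfg$gap_mm / 2
  xc <- r_mid * sin(half)
  zc <- r_mid * cos(half)
  z_deep <- cfg$r_inner_mm * cos(half)
  arc_pts <- function(th, y, r = r_mid) cbind(r * sin(th), y, r * cos(th))

  y_up <- g2 + h / 2
  y_lo <- -(g2 + h / 2)
  th_seq <- seq(0, half, length.out = 7)

  ring <- function(y_top, y_bot) {
    rbind(arc_pts(th_seq, y_top),
          arc_pts(rev(th_seq), y_bot))
  }

  left <- list(
    OOP = ring(y_up, y_lo),
    OOM = ring(g2 + h / 6, -(g2 + h / 6)),
    BUC = rbind(c(xc + 10, 0, z_deep - 6), c(xc - 4, 0, z_deep + 2)),
    LAO = rbind(c(xc - 2, g2 + h + 8, zc), c(xc - 2, g2 + 1, zc + 1)),
    DLI = {
      th <- 22.5 * pi / 180
      rbind(c(r_mid * sin(th), -(g2 + h + 8), r_mid * cos(th)),
            c(r_mid * sin(th), -(g2 + h / 4), r_mid * cos(th)))
    },
    MEN = {
      th <- 7.5 * pi / 180
      rbind(c(r_mid * sin(th), -(g2 + h + 8), r_mid * cos(th)),
            c(r_mid * sin(th), -(g2 + h / 4), r_mid * cos(th)))
    },
    ZYG = rbind(c(xc + 8, g2 + h + 8, zc - 6), c(xc - 1, g2 + 1, zc + 1)),
    RIS = rbind(c(xc + 12, 0, zc - 8), c(xc - 1, 0, zc + 1)),
    DAO = rbind(c(xc + 3, -(g2 + h + 8), zc - 2), c(xc - 1, -(g2 + 2), zc)),
    LLSAN = {
      th <- 15 * pi / 180
      rbind(c(r_mid * sin(th), g2 + h + 8, r_mid * cos(th)),
            c(r_mid * sin(th), g2 + h / 3, r_mid * cos(th)))
    }
  )
  out <- list()
  for (m in model_muscles()) {
    pl <- left[[m]]
    out[[paste0(m, "_L")]] <- muscle_def(paste0(m, "_L"), pl)
    pr <- pl
    pr[, 1] <- -pr[, 1]
    out[[paste0(m, "_R")]] <- muscle_def(paste0(m, "_R"), pr)
  }
  out
}

#' Build the reduced lip model
#'
#' Structured all-hex mesh of the upper and lower lip (curved slabs), three
#' element layers through the depth labelled inner/centre/outer, inner
#' surface fixed (attachment to mandible/maxilla), ten vermilion marker
#' nodes, default material, and muscle elements assigned by the 5 mm rule.
#'
#' Marker map (fractions are positions along the arc, right to left):
#' upper lip lower-outer edge at 0 (corner R), 0.3125 (cupid R), 0.5
#' (philtrum base), 0.6875 (cupid L), 1 (corner L); lower lip upper-outer
#' edge at 0.125, 0.25, 0.5, 0.75, 0.875.
#'
#' @param cfg a [mesh_config()].
#' @param material material parameters ([material_params()]).
#' @param muscles named list of [muscle_def()]s (default
#'   [default_muscle_set()]).
#' @return object of class `lip_model`: `nodes` (n x 3, mm), `elems`
#'   (ne x 8), `layer`, `fixed`, `markers` (named node ids), `material`,
#'   `muscles`, `muscle_elements`, `cfg`.
#' @export
build_lip_mesh <- function(cfg = mesh_config(), material = material_params(),
                           muscles = NULL) {
  nx <- cfg$nx; ny <- cfg$ny
  nz <- length(cfg$layer_thicknesses_mm)
  radii <- cfg$r_inner_mm + c(0, cumsum(cfg$layer_thicknesses_mm))
  half <- cfg$arc_deg / 2 * pi / 180
  th <- seq(-half, half, length.out = nx + 1)
  g2 <- cfg$gap_mm / 2
  h <- cfg$lip_height_mm

  n_per_lip <- (nx + 1) * (ny + 1) * (nz + 1)
  nodes <- matrix(0, 2 * n_per_lip, 3)
  idx <- function(lip, i, j, k) {
    as.integer((lip - 1) * n_per_lip + i + 1 + (nx + 1) * (j + (ny + 1) * k))
  }
  for (lip in 1:2) {
    ys <- if (lip == 1) seq(g2, g2 + h, length.out = ny + 1) else
      seq(-g2 - h, -g2, length.out = ny + 1)
    for (k in 0:nz) for (j in 0:ny) for (i in 0:nx) {
      nodes[idx(lip, i, j, k), ] <- c(radii[k + 1] * sin(th[i + 1]),
                                      ys[j + 1],
                                      radii[k + 1] * cos(th[i + 1]))
    }
  }

  ne <- 2 * nx * ny * nz
  elems <- matrix(0L, ne, 8)
  layer <- character(ne)
  layer_names <- c("inner", "centre", "outer")
  e <- 0L
  for (lip in 1:2) for (k in 0:(nz - 1)) for (j in 0:(ny - 1)) {
    for (i in 0:(nx - 1)) {
      e <- e + 1L
      elems[e, ] <- c(idx(lip, i, j, k), idx(lip, i + 1, j, k),
                      idx(lip, i + 1, j + 1, k), idx(lip, i, j + 1, k),
                      idx(lip, i, j, k + 1), idx(lip, i + 1, j, k + 1),
                      idx(lip, i + 1, j + 1, k + 1), idx(lip, i, j + 1, k + 1))
      layer[e] <- layer_names[min(k + 1, 3)]
    }
  }

  fixed <- sort(c(vapply(0:ny, function(j) vapply(0:nx, function(i)
    idx(1, i, j, 0), integer(1)), integer(nx + 1)),
    vapply(0:ny, function(j) vapply(0:nx, function(i)
      idx(2, i, j, 0), integer(1)), integer(nx + 1))))

  mk_frac <- function(lip, frac, edge_j) {
    idx(lip, round(frac * nx), edge_j, nz)
  }
  markers <- c(
    UL_corner_R = mk_frac(1, 0, 0), UL_cupid_R = mk_frac(1, 0.3125, 0),
    UL_centre = mk_frac(1, 0.5, 0), UL_cupid_L = mk_frac(1, 0.6875, 0),
    UL_corner_L = mk_frac(1, 1, 0),
    LL_lat_R = mk_frac(2, 0.125, ny), LL_mid_R = mk_frac(2, 0.25, ny),
    LL_centre = mk_frac(2, 0.5, ny), LL_mid_L = mk_frac(2, 0.75, ny),
    LL_lat_L = mk_frac(2, 0.875, ny))

  model <- structure(list(nodes = nodes, elems = elems, layer = layer,
                          fixed = as.integer(fixed), markers = markers,
                          material = material, cfg = cfg),
                     class = "lip_model")

  vols <- hex_volumes(nodes, elems)
  if (any(vols <= 0)) {
    stop_lipmaps(sprintf("degenerate reference element (first: %d)",
                         which(vols <= 0)[1]), "lipmaps_mesh_error")
  }

  if (is.null(muscles)) muscles <- default_muscle_set(cfg)
  model$muscles <- muscles
  model$muscle_elements <- lapply(muscles, function(m) {
    suppressWarnings(assign_muscle_elements(model, m,
                                            radius = cfg$muscle_radius_mm))
  })
  model
}

#' Total mesh volume by Gauss quadrature
#' @param model a `lip_model`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(model) sum(hex_volumes(model$nodes, model$elems))

#' Analytic volume of the configured arc-slab geometry
#' @param cfg a [mesh_config()].
#' @return volume in mm^3 (both lips).
#' @export
analytic_slab_volume <- function(cfg) {
  r_i <- cfg$r_inner_mm
  r_o <- r_i + sum(cfg$layer_thicknesses_mm)
  arc <- cfg$arc_deg * pi / 180
  2 * arc / 2 * (r_o^2 - r_i^2) * cfg$lip_height_mm
}

#' @exportS3Method base::print
print.lip_model <- function(x, ...) {
  cat(sprintf(
    "lip_model: %d nodes, %d hex elements, %d fixed nodes, %d markers\n",
    nrow(x$nodes), nrow(x$elems), length(x$fixed), length(x$markers)))
  n_mus <- sum(vapply(x$muscle_elements, function(m) length(m$elements) > 0,
                      logical(1)))
  cat(sprintf("  %d/%d muscles with assigned elements; volume %.0f mm^3\n",
              n_mus, length(x$muscles), mesh_volume(x)))
  invisible(x)
}
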