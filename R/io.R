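# Plain-text persistence: recordings as CSV (channels x samples) with a JSON
# sidecar (fs, labels), trajectories as wide CSV (frame, marker_id, x, y, z
# in mm), feature series as long CSV plus a JSON parameter sidecar, and the
# mesh as legacy-ASCII VTK with a JSON sidecar for layers, fixed set,
# markers and muscles.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read an sEMG recording
#'
#' CSV rows are channels, columns samples (mV); the JSON sidecar holds fs,
#' channel labels, instruction/repetition and the active window.
#' @param rec an `emg_recording`.
#' @param path CSV path (a .json sidecar is written next to it).
#' @return `path`, invisibly; `read_recording` returns the `emg_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  write.csv(rec$samples, path, row.names = TRUE)
  jsonlite::write_json(
    list(fs = rec$fs, channels = rec$channels, instruction = rec$instruction,
         repetition = rec$repetition, active_window = rec$active_window),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  structure(list(samples = m, fs = meta$fs, channels = meta$channels,
                 instruction = meta$instruction, repetition = meta$repetition,
                 active_window = meta$active_window),
            class = "emg_recording")
}

#' Write / read marker trajectories
#'
#' Long CSV: frame, marker_id, x, y, z (mm); the frame rate and labels go in
#' the JSON sidecar.
#' @param traj a `trajectory_set`.
#' @param path CSV path.
#' @return `path`, invisibly; `read_trajectories` returns the set.
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  n_mk <- dim(traj$pos)[1]; n_fr <- dim(traj$pos)[2]
  mk <- dimnames(traj$pos)[[1]]
  if (is.null(mk)) mk <- paste0("M", seq_len(n_mk))
  df <- data.frame(frame = rep(seq_len(n_fr), each = n_mk),
                   marker_id = rep(mk, times = n_fr),
                   x = as.vector(traj$pos[, , 1]),
                   y = as.vector(traj$pos[, , 2]),
                   z = as.vector(traj$pos[, , 3]))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(fps = traj$fps, source = traj$source, instruction = traj$instruction,
         repetition = traj$repetition, markers = mk),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  df <- read.csv(path)
  mk <- meta$markers
  n_mk <- length(mk); n_fr <- max(df$frame)
  pos <- array(0, dim = c(n_mk, n_fr, 3), dimnames = list(mk, NULL, NULL))
  ord <- order(df$frame, match(df$marker_id, mk))
  df <- df[ord, ]
  pos[, , 1] <- df$x; pos[, , 2] <- df$y; pos[, , 3] <- df$z
  trajectory_set(pos, fps = meta$fps, source = meta$source,
                 instruction = meta$instruction, repetition = meta$repetition)
}

#' Write a feature series
#'
#' Long CSV (frame, channel, value) plus a JSON sidecar with the window
#' parameters.
#' @param feat a `feature_series`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(feat, path) {
  stopifnot(inherits(feat, "feature_series"))
  df <- data.frame(frame = rep(seq_len(ncol(feat$values)),
                               each = nrow(feat$values)),
                   channel = rep(rownames(feat$values),
                                 times = ncol(feat$values)),
                   value = as.vector(feat$values))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = feat$fs, window_samples = feat$window_samples, hop = feat$hop,
         s_lim = feat$s_lim, normalised = feat$normalised,
         instruction = feat$instruction, repetition = feat$repetition),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an activation set
#'
#' Wide CSV (frame x 20 channels) plus a JSON header with the strategy,
#' instruction/repetition and selected-muscle list.
#' @param act an `activation_set`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_activations <- function(act, path) {
  stopifnot(inherits(act, "activation_set"))
  df <- cbind(data.frame(frame = seq_len(ncol(act$act))),
              as.data.frame(t(act$act)))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(strategy = act$strategy, instruction = act$instruction,
         repetition = act$repetition, selected = act$selected),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration from JSON or YAML
#'
#' Parses the file and passes the result through [validate_config()], so
#' defaults are filled and unknown keys rejected.
#' @param path .json, .yaml or .yml file.
#' @return a validated configuration list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop_lipmaps("config file must be .json or .yaml", "lipmaps_config_error")
  }
  if (!is.null(raw$mesh)) raw$mesh <- do.call(mesh_config, raw$mesh)
  validate_config(raw)
}

#' Write / read the lip mesh
#'
#' Legacy-ASCII VTK unstructured grid (hexahedra, cell type 12) plus a JSON
#' sidecar with layer labels, fixed-node set, marker map and muscle
#' polylines.
#' @param model a `lip_model`.
#' @param path .vtk path.
#' @return `path`, invisibly; `read_lip_mesh` rebuilds the model (muscle
#'   elements are re-assigned by the distance rule).
#' @export
write_lip_mesh <- function(model, path) {
  stopifnot(inherits(model, "lip_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 2.0", "lipmaps reduced lip mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(model$nodes))), con)
  write.table(format(model$nodes, digits = 10), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  ne <- nrow(model$elems)
  writeLines(sprintf("CELLS %d %d", ne, 9 * ne), con)
  write.table(cbind(8L, model$elems - 1L), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(12L, ne)), con)
  jsonlite::write_json(
    list(layer = model$layer, fixed = model$fixed,
         markers = as.list(model$markers), material = model$material,
         cfg = model$cfg,
         muscles = lapply(model$muscles, function(m) {
           list(name = m$name, polyline = m$polyline,
                lambda_star = m$lambda_star, p1 = m$p1, p2 = m$p2,
                lambda_ofl = m$lambda_ofl)
         })),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lip_mesh
#' @export
read_lip_mesh <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)
  n <- as.integer(strsplit(lines[ip], " ")[[1]][2])
  nodes <- matrix(scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE),
                  n, 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)
  ne <- as.integer(strsplit(lines[ic], " ")[[1]][2])
  cells <- matrix(scan(text = lines[(ic + 1):(ic + ne)], quiet = TRUE),
                  ne, 9, byrow = TRUE)
  elems <- matrix(as.integer(cells[, -1] + 1L), ne, 8)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  cfg <- do.call(mesh_config, meta$cfg[c("nx", "ny", "layer_thicknesses_mm",
                                         "r_inner_mm", "arc_deg",
                                         "lip_height_mm", "gap_mm",
                                         "muscle_radius_mm")])
  muscles <- lapply(meta$muscles, function(m) {
    muscle_def(m$name, matrix(unlist(m$polyline), ncol = 3),
               lambda_star = m$lambda_star, p1 = m$p1, p2 = m$p2,
               lambda_ofl = m$lambda_ofl)
  })
  names(muscles) <- vapply(muscles, `[[`, character(1), "name")
  model <- structure(list(nodes = nodes, elems = elems, layer = meta$layer,
                          fixed = as.integer(meta$fixed),
                          markers = unlist(meta$markers),
                          material = do.call(material_params, meta$material),
                          cfg = cfg),
                     class = "lip_model")
  model$muscles <- muscles
  model$muscle_elements <- lapply(muscles, function(m) {
    suppressWarnings(assign_muscle_elements(model, m,
                                            radius = cfg$muscle_radius_mm))
  })
  model
}
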