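# Temporal alignment of simulated and measured marker trajectories:
# resample to a common frame grid, reduce the 30-D marker space to 1-D via
# the first principal component (SVD), and shift by cross-correlation
# maximisation.

#' Trajectory-set container
#'
#' @param pos numeric array (markers x frames x 3), mm.
#' @param fps frame rate (frames/s); may be NA for a unit-spaced grid.
#' @param source "simulated" or "measured".
#' @param instruction,repetition labels.
#' @param marker_names optional marker names.
#' @return object of class `trajectory_set`.
#' @export
trajectory_set <- function(pos, fps = NA_real_, source = "simulated",
                           instruction = NA_character_, repetition = NA_integer_,
                           marker_names = NULL) {
  stopifnot(length(dim(pos)) == 3, dim(pos)[3] == 3, dim(pos)[2] >= 2,
            !anyNA(pos))
  if (!is.null(marker_names)) dimnames(pos)[[1]] <- marker_names
  structure(list(pos = pos, fps = fps, source = source,
                 instruction = instruction, repetition = repetition),
            class = "trajectory_set")
}

#' Number of frames in a trajectory set
#' @param traj a `trajectory_set`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$pos)[2]

#' Resample trajectories onto a uniform frame grid
#'
#' Linear interpolation of each marker coordinate onto `frames` uniformly
#' spaced time points spanning the original duration.
#'
#' @param traj a `trajectory_set`.
#' @param frames target frame count (default 160).
#' @return the resampled `trajectory_set` (fps rescaled accordingly).
#' @export
resample_trajectories <- function(traj, frames = 160) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (frames < 2) stop_lipmaps("need at least 2 output frames",
                               "lipmaps_config_error")
  n_in <- n_frames(traj)
  t_in <- seq(0, 1, length.out = n_in)
  t_out <- seq(0, 1, length.out = frames)
  out <- array(0, dim = c(dim(traj$pos)[1], frames, 3),
               dimnames = list(dimnames(traj$pos)[[1]], NULL, NULL))
  for (k in seq_len(dim(traj$pos)[1])) {
    for (c3 in 1:3) {
      out[k, , c3] <- approx(t_in, traj$pos[k, , c3], xout = t_out)$y
    }
  }
  traj$pos <- out
  if (is.finite(traj$fps)) traj$fps <- traj$fps * (frames - 1) / (n_in - 1)
  traj
}

# stack a trajectory set into the 30 x T matrix (x,y,z of the 10 markers)
stack_trajectories <- function(traj) {
  p <- traj$pos
  do.call(rbind, lapply(seq_len(dim(p)[1]),
                        function(k) t(p[k, , , drop = TRUE])))
}

#' First principal component of a stacked marker matrix
#'
#' SVD-based PCA of the 30 x T matrix whose columns hold the x, y, z
#' coordinates of the markers at each frame.  Rows are mean-centred by
#' default (cross-correlation of uncentred coefficients would be dominated by
#' the constant offsets; set `center = FALSE` for the raw variant).  The sign
#' convention makes the largest-magnitude coefficient positive.
#'
#' @param x numeric matrix (rows = coordinates, columns = frames) or a
#'   `trajectory_set`.
#' @param center mean-centre rows before the SVD (default TRUE).
#' @return list of class `pca_coefficients`: `b` (length T), `u1`
#'   (unit norm), `variances` (squared singular values, nonincreasing).
#' @export
pca_first_component <- function(x, center = TRUE) {
  if (inherits(x, "trajectory_set")) x <- stack_trajectories(x)
  stopifnot(is.matrix(x), ncol(x) >= 2)
  xc <- if (center) x - rowMeans(x) else x
  if (all(abs(xc) < 1e-300)) {
    stop_lipmaps("all-constant trajectory matrix: no principal direction",
                 "lipmaps_sync_error")
  }
  sv <- svd(xc)
  u1 <- sv$u[, 1]
  b <- drop(crossprod(u1, xc))
  if (b[which.max(abs(b))] < 0) {
    u1 <- -u1
    b <- -b
  }
  structure(list(b = b, u1 = u1, variances = sv$d^2),
            class = "pca_coefficients")
}

#' Synchronisation shift by cross-correlation maximisation
#'
#' Mean-removes and unit-scales both coefficient vectors, then maximises
#' their normalised cross-correlation over integer lags (zero padding outside
#' the support).  A positive shift means `b_meas` lags `b_est`.  Ties break
#' toward the smallest absolute shift.
#'
#' @param b_est,b_meas equal-length numeric vectors (or `pca_coefficients`).
#' @param max_lag largest |lag| scanned (default full overlap).
#' @return integer shift.
#' @export
align_by_crosscorr <- function(b_est, b_meas, max_lag = NULL) {
  if (inherits(b_est, "pca_coefficients")) b_est <- b_est$b
  if (inherits(b_meas, "pca_coefficients")) b_meas <- b_meas$b
  stopifnot(length(b_est) == length(b_meas))
  n <- length(b_est)
  if (is.null(max_lag)) max_lag <- n - 1L
  a <- b_est - mean(b_est)
  b <- b_meas - mean(b_meas)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-300 || nb < 1e-300) {
    warning("constant coefficient vector; returning shift 0")
    return(0L)
  }
  a <- a / na; b <- b / nb
  sc <- .xcorr_scan(a, b, max_lag)
  best <- which(sc$rho >= max(sc$rho) - 1e-12)
  as.integer(sc$lags[best][which.min(abs(sc$lags[best]))])
}

# normalised cross-correlation over integer lags: Pearson correlation of the
# overlapping segments (normalising by the overlap keeps a constructed delay
# exactly recoverable; a global norm would bias the argmax toward small
# lags).  Lags leaving less than half the signal overlapping are not
# scanned, so short coincidental overlaps cannot dominate.
.xcorr_scan <- function(a, b, max_lag, min_overlap = NULL) {
  n <- length(a)
  if (is.null(min_overlap)) min_overlap <- max(16L, n %/% 2L)
  min_overlap <- min(min_overlap, n - 1L)
  max_lag <- min(max_lag, n - min_overlap)
  lags <- seq.int(-max_lag, max_lag)
  rho <- vapply(lags, function(l) {
    if (l >= 0) {
      sa <- a[seq_len(n - l)]; sb <- b[seq_len(n - l) + l]
    } else {
      sa <- a[seq_len(n + l) - l]; sb <- b[seq_len(n + l)]
    }
    if (sd(sa) == 0 || sd(sb) == 0) return(0)
    stats::cor(sa, sb)
  }, numeric(1))
  list(lags = lags, rho = rho)
}

#' Synchronise a simulated and a measured trajectory set
#'
#' Resamples both sets to `frames` frames, computes the first-principal-
#' component coefficient vectors, estimates the shift by cross-correlation,
#' applies it to the measured set and crops both to the overlapping region.
#'
#' @param sim,meas `trajectory_set`s over the same markers.
#' @param frames common frame count (default 160).
#' @param min_overlap smallest acceptable overlap after shifting.
#' @return list: `sim`, `meas` (aligned, equal length), `shift`, `b_est`,
#'   `b_meas`.
#' @export
synchronise <- function(sim, meas, frames = 160, min_overlap = 16) {
  stopifnot(dim(sim$pos)[1] == dim(meas$pos)[1])
  sim <- resample_trajectories(sim, frames)
  meas <- resample_trajectories(meas, frames)
  b_est <- pca_first_component(sim)
  b_meas <- pca_first_component(meas)
  # the first principal component carries an arbitrary sign; resolve it
  # pairwise so the lag search compares like with like
  a <- b_est$b - mean(b_est$b)
  b <- b_meas$b - mean(b_meas$b)
  a <- a / max(sqrt(sum(a^2)), 1e-300)
  b <- b / max(sqrt(sum(b^2)), 1e-300)
  sc <- .xcorr_scan(a, b, frames - 1L)
  if (max(sc$rho) < max(-sc$rho)) {
    b_meas$b <- -b_meas$b
    b_meas$u1 <- -b_meas$u1
  }
  shift <- align_by_crosscorr(b_est, b_meas)
  if (frames - abs(shift) < min_overlap) {
    stop_lipmaps(sprintf("overlap of %d frames after shift %d is below %d",
                         frames - abs(shift), shift, min_overlap),
                 "lipmaps_sync_error")
  }
  if (shift >= 0) {
    keep_sim <- seq_len(frames - shift)
    keep_meas <- keep_sim + shift
  } else {
    keep_meas <- seq_len(frames + shift)
    keep_sim <- keep_meas - shift
  }
  sim$pos <- sim$pos[, keep_sim, , drop = FALSE]
  meas$pos <- meas$pos[, keep_meas, , drop = FALSE]
  list(sim = sim, meas = meas, shift = shift, b_est = b_est, b_meas = b_meas)
}
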