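# 3D correlation coefficient between marker trajectories and grouped
# report summaries.
#
# The statistic generalises Pearson correlation to 3D trajectories via the
# mean vector dot product:
#   rho = [ (1/n) sum_i v_i . w_i  -  mu_v . mu_w ] / (sigma_v sigma_w)
# As printed, the numerator uses 1/n while sigma uses 1/(n-1); with that
# mixed normalisation rho(v, v) = (n-1)/n < 1.  A "consistent" mode uses
# 1/n in both, making rho(v, v) = 1 exactly.  Both modes are provided and
# neither is silently preferred.

#' 3D correlation coefficient between two trajectories
#'
#' @param v,w numeric matrices (n x 3), equal n >= 2.
#' @param mode "printed" (1/(n-1) in the standard deviations, 1/n in the
#'   numerator, exactly as published) or "consistent" (1/n in both).
#' @return scalar correlation.
#' @export
corr3d <- function(v, w, mode = c("printed", "consistent")) {
  mode <- match.arg(mode)
  v <- as.matrix(v); w <- as.matrix(w)
  stopifnot(ncol(v) == 3, ncol(w) == 3, nrow(v) == nrow(w), nrow(v) >= 2)
  n <- nrow(v)
  mu_v <- colMeans(v)
  mu_w <- colMeans(w)
  num <- mean(rowSums(v * w)) - sum(mu_v * mu_w)
  denom_n <- if (mode == "printed") n - 1 else n
  s_v <- sqrt(sum(rowSums((v - rep(mu_v, each = n))^2)) / denom_n)
  s_w <- sqrt(sum(rowSums((w - rep(mu_w, each = n))^2)) / denom_n)
  if (s_v == 0 || s_w == 0) {
    stop_lipmaps("undefined correlation: constant trajectory (zero sigma)",
                 "lipmaps_metric_error")
  }
  num / (s_v * s_w)
}

#' Per-marker correlation rows for an aligned trajectory pair
#'
#' @param sim,meas aligned `trajectory_set`s (equal frames, same markers).
#' @param mode passed to [corr3d()].
#' @return data.frame with one row per marker: instruction, repetition,
#'   marker, rho.
#' @export
correlation_rows <- function(sim, meas, mode = "printed") {
  n_mk <- dim(sim$pos)[1]
  mk <- dimnames(sim$pos)[[1]]
  if (is.null(mk)) mk <- paste0("M", seq_len(n_mk))
  rho <- vapply(seq_len(n_mk), function(k) {
    corr3d(sim$pos[k, , , drop = TRUE], meas$pos[k, , , drop = TRUE],
           mode = mode)
  }, numeric(1))
  data.frame(instruction = sim$instruction, repetition = sim$repetition,
             marker = mk, rho = rho, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Grouped summaries of a correlation report
#'
#' Mean, sample standard deviation and median of `rho` per group, plus an
#' overall row.  Single-observation groups report a standard deviation of 0
#' with `sd_degenerate = TRUE` rather than NA.
#'
#' @param rows data.frame with a `rho` column (e.g. the `rows` of a
#'   [run_experiment()] report).
#' @param group_by character vector of grouping column names (may be empty
#'   for the overall summary only).
#' @return data.frame of group summaries; the overall row has group value
#'   "(all)".
#' @export
summarise_correlations <- function(rows, group_by = character()) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0, "rho" %in% names(rows))
  bad <- setdiff(group_by, names(rows))
  if (length(bad)) {
    stop_lipmaps(sprintf("unknown grouping key(s): %s",
                         paste(bad, collapse = ", ")),
                 "lipmaps_metric_error")
  }
  one <- function(x) {
    data.frame(n = length(x), mean = mean(x),
               sd = if (length(x) > 1) sd(x) else 0,
               sd_degenerate = length(x) == 1,
               median = median(x))
  }
  if (length(group_by) == 0) {
    out <- cbind(data.frame(group = "(all)"), one(rows$rho))
    return(out)
  }
  key <- interaction(rows[group_by], drop = TRUE, sep = "/")
  parts <- lapply(split(rows$rho, key), one)
  out <- cbind(data.frame(group = names(parts)),
               do.call(rbind, parts))
  rownames(out) <- NULL
  rbind(out, cbind(data.frame(group = "(all)"), one(rows$rho)))
}
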