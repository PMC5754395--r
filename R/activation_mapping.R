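# Mapping the 7 measured bilateral muscles onto the 10 bilateral model
# muscles, and the three activation strategies act_all / act_3 / act_rel.
#
# Per side the transfer is:
#   OOP = 0.50 (OOS + OOI)        OOM = 0.10 (OOP + OOI)
#   BUC = 0.50 (RIS + ZYG)        LAO = 0.75 LLSAN      DLI = 0.75 DAO
#   MEN, ZYG, RIS, DAO, LLSAN pass through; OOS and OOI are dropped.
# (The source text describes OOM in prose as a fifth of the OOP but prints
# the OOM equation above; the printed equation is implemented.)
# Outputs are clipped to [0, 1].

# matrix-level transfer: 14 measured channels -> 20 model channels
derive_model_matrix <- function(v) {
  need <- bilateral_channels(measured_muscles())
  missing <- setdiff(need, rownames(v))
  if (length(missing)) {
    stop_lipmaps(sprintf("missing measured channel(s): %s",
                         paste(missing, collapse = ", ")),
                 "lipmaps_channel_error")
  }
  out <- matrix(0, 20, ncol(v),
                dimnames = list(bilateral_channels(model_muscles()), NULL))
  for (side in c("_L", "_R")) {
    g <- function(m) v[paste0(m, side), , drop = TRUE]
    oop <- 0.50 * (g("OOS") + g("OOI"))
    out[paste0("OOP", side), ] <- oop
    out[paste0("OOM", side), ] <- 0.10 * (oop + g("OOI"))
    out[paste0("BUC", side), ] <- 0.50 * (g("RIS") + g("ZYG"))
    out[paste0("LAO", side), ] <- 0.75 * g("LLSAN")
    out[paste0("DLI", side), ] <- 0.75 * g("DAO")
    for (m in c("MEN", "ZYG", "RIS", "DAO", "LLSAN")) {
      out[paste0(m, side), ] <- g(m)
    }
  }
  clip01(out)
}

#' Derive the 20 model-muscle feature traces
#'
#' Applies the measured-to-model transfer to a 14-channel feature series and
#' returns a 20-channel series (left block then right block, canonical model
#' order), clipped to `[0, 1]`.
#'
#' @param feat a `feature_series` with the 7 measured muscles x 2 sides.
#' @return a 20-channel `feature_series`.
#' @export
derive_model_muscles <- function(feat) {
  stopifnot(inherits(feat, "feature_series"))
  feat$values <- derive_model_matrix(feat$values)
  feat
}

#' Bilateral average of model-muscle traces
#'
#' Frame-wise mean of the left and right trace of each model muscle.
#'
#' @param feat20 a 20-channel `feature_series` (or plain matrix with the
#'   canonical 20 row names).
#' @return matrix (10 muscles x frames) of bilaterally averaged traces.
#' @export
bilateral_average <- function(feat20) {
  v <- if (inherits(feat20, "feature_series")) feat20$values else feat20
  want <- bilateral_channels(model_muscles())
  if (is.null(rownames(v)) || !all(want %in% rownames(v))) {
    stop_lipmaps("channel-order metadata absent: need the 20 canonical model channels",
                 "lipmaps_channel_error")
  }
  v <- v[want, , drop = FALSE]
  out <- 0.5 * (v[1:10, , drop = FALSE] + v[11:20, , drop = FALSE])
  rownames(out) <- model_muscles()
  out
}

#' Select the three most active bilateral muscles
#'
#' Ranks the bilaterally averaged muscle traces by their variance over the
#' time index and returns the three largest, sorted by descending variance.
#' Ties break on the canonical muscle order ([model_muscles()]), via a stable
#' sort.
#'
#' @param feat10 matrix (10 muscles x frames) of bilaterally averaged traces,
#'   e.g. from [bilateral_average()].
#' @return character vector of 3 muscle names (descending variance).
#' @export
select_top3 <- function(feat10) {
  if (nrow(feat10) < 3) {
    stop_lipmaps("need at least 3 muscles to select from",
                 "lipmaps_channel_error")
  }
  v <- apply(feat10, 1, var)
  if (any(!is.finite(v))) {
    stop_lipmaps("non-finite variance in feature traces",
                 "lipmaps_feature_error")
  }
  ord <- order(-v)  # stable: ties keep canonical row order
  rownames(feat10)[ord[1:3]]
}

#' Apply an activation strategy
#'
#' Builds the model activation set from the 20-channel feature traces:
#' `act_all` keeps all channels, `act_3` keeps only the three
#' highest-variance bilaterally averaged muscles (each side keeping its own
#' trace; the bilateral average is used for selection only), `act_rel` keeps
#' the instruction's relevant muscles (see [relevant_muscles()]) bilaterally.
#'
#' @param feat20 a 20-channel normalised `feature_series`.
#' @param strategy one of "act_all", "act_3", "act_rel".
#' @param instruction instruction id (required for `act_rel`).
#' @return an `activation_set`: `act` (20 x frames in `[0,1]`), `t`,
#'   `strategy`, `instruction`, `repetition`, `selected`.
#' @export
apply_strategy <- function(feat20, strategy = c("act_all", "act_3", "act_rel"),
                           instruction = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(feat20, "feature_series"))
  v <- feat20$values
  want <- bilateral_channels(model_muscles())
  if (!all(want %in% rownames(v))) {
    stop_lipmaps("expected the 20 canonical model channels",
                 "lipmaps_channel_error")
  }
  v <- clip01(v[want, , drop = FALSE])
  selected <- model_muscles()
  if (strategy == "act_3") {
    selected <- select_top3(bilateral_average(v))
  } else if (strategy == "act_rel") {
    if (is.null(instruction)) {
      stop_lipmaps("act_rel requires an instruction id", "lipmaps_config_error")
    }
    tab <- relevant_muscles()
    if (!instruction %in% names(tab)) {
      stop_lipmaps(sprintf("unknown instruction %s; valid: %s", instruction,
                           paste(names(tab), collapse = ", ")),
                   "lipmaps_config_error")
    }
    selected <- tab[[instruction]]
  }
  if (strategy != "act_all") {
    v[!rownames(v) %in% bilateral_channels(selected), ] <- 0
  }
  structure(list(act = v, t = feat20$t, strategy = strategy,
                 instruction = if (is.null(instruction)) feat20$instruction
                               else instruction,
                 repetition = feat20$repetition, selected = selected),
            class = "activation_set")
}
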