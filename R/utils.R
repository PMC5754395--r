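# small internal helpers shared by the modules

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Linear resampling of a channels-by-frames matrix
#'
#' @param x numeric matrix (channels x frames).
#' @param t_in input frame times (length `ncol(x)`), strictly increasing.
#' @param t_out output frame times.
#' @return matrix (channels x length(t_out)).
#' @keywords internal
resample_matrix <- function(x, t_in, t_out) {
  stopifnot(is.matrix(x), length(t_in) == ncol(x))
  out <- matrix(0, nrow(x), length(t_out), dimnames = list(rownames(x), NULL))
  for (i in seq_len(nrow(x))) {
    out[i, ] <- approx(t_in, x[i, ], xout = t_out, rule = 2)$y
  }
  out
}

stop_lipmaps <- function(msg, class, ...) {
  stop(structure(class = c(class, "lipmaps_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

# condition signalled by the FEM when an element Jacobian becomes non-positive;
# consumed by adapt_sigma_max()
inverted_element_condition <- function(element, step) {
  structure(class = c("lipmaps_inverted_element", "lipmaps_error",
                      "error", "condition"),
            list(message = sprintf(
                   "inverted element %d at time step %d (det F <= 0)",
                   element, step),
                 call = NULL, element = element, step = step))
}
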