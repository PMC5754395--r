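# Muscle naming conventions.
#
# Measured muscles (7, bipolar sEMG, both sides): OOS, OOI, RIS, ZYG, LLSAN,
# DAO, MEN.  Model muscles (10 per side): OOP, OOM, BUC, LAO, DLI, MEN, ZYG,
# RIS, DAO, LLSAN.  Channel layout is always left side first (channels
# 1..7 / 1..10 suffixed _L), then the right side (_R).

#' Canonical measured-muscle names
#' @return character vector of the 7 bipolar sEMG muscles.
#' @export
measured_muscles <- function() {
  c("OOS", "OOI", "RIS", "ZYG", "LLSAN", "DAO", "MEN")
}

#' Canonical model-muscle names
#'
#' The order doubles as the tie-break order wherever muscles must be ranked.
#' @return character vector of the 10 model muscles.
#' @export
model_muscles <- function() {
  c("OOP", "OOM", "BUC", "LAO", "DLI", "MEN", "ZYG", "RIS", "DAO", "LLSAN")
}

#' Bilateral channel labels
#' @param muscles character vector of muscle names.
#' @return labels, left block first then right block.
#' @export
bilateral_channels <- function(muscles) {
  c(paste0(muscles, "_L"), paste0(muscles, "_R"))
}

#' Instruction set
#'
#' Six facial instructions: A purse lips, B raise upper lip, C depress mouth
#' corners, D voluntary smile, E left-right-left with closed mouth, F purse
#' lips - closed mouth smile - purse lips.
#' @return named character vector of instruction descriptions.
#' @export
instructions <- function() {
  c(A = "purse lips",
    B = "raise upper lip",
    C = "depress mouth corners",
    D = "voluntary smile",
    E = "left-right-left with closed mouth",
    F = "purse lips - closed mouth smile - purse lips")
}

#' Relevant model muscles per instruction
#'
#' The per-instruction relevant-muscle lists used by the `act_rel` activation
#' strategy.  Shipped as editable JSON in `inst/extdata/relevant_muscles.json`;
#' this function loads that file (or a user-supplied one).
#' @param path optional path to an alternative JSON file.
#' @return named list: instruction id -> character vector of model muscles.
#' @export
relevant_muscles <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "relevant_muscles.json", package = "lipmaps")
  }
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(unlist(tab), model_muscles())
  if (length(bad)) {
    stop_lipmaps(sprintf("unknown model muscle(s) in relevant-muscle table: %s",
                         paste(bad, collapse = ", ")), "lipmaps_config_error")
  }
  tab
}

# measured-muscle envelopes that realise each instruction's relevant model
# muscles through the measured->model transfer map (see derive_model_muscles):
# OOS/OOI feed OOP and OOM, RIS+ZYG feed BUC, LLSAN feeds LAO, DAO feeds DLI.
instruction_sources <- function() {
  list(A = c("OOS", "OOI", "RIS", "ZYG"),
       B = c("LLSAN"),
       C = c("DAO", "MEN"),
       D = c("LLSAN", "RIS", "ZYG", "DAO"),
       E = c("OOS", "OOI", "LLSAN", "RIS", "ZYG"),
       F = c("OOS", "OOI", "LLSAN", "RIS", "ZYG"))
}
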