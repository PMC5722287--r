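#' Standard 30-channel 10-20 montage
#'
#' Channel labels for a 32-electrode cap after dropping the two linked-mastoid
#' reference electrodes (A1/A2), i.e. the 30 effective scalp channels used
#' throughout the pipeline. Labels follow the international 10-20 naming
#' scheme.
#'
#' @return Character vector of 30 electrode labels.
#' @export
#' @examples
#' montage_30()
montage_30 <- function() {
  c("FP1", "FP2", "F7", "F3", "Fz", "F4", "F8",
    "FT7", "FC3", "FCz", "FC4", "FT8",
    "T3", "C3", "Cz", "C4", "T4",
    "TP7", "CP3", "CPz", "CP4", "TP8",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "Oz", "O2")
}

#' Default scalp-region map for reduced-montage evaluation
#'
#' Groups the high-weight electrodes into four scalp regions: A (left
#' posterior), B (midline central), C (right central) and D (middle/occipital
#' posterior). Region membership is a configuration choice, not a geometric
#' inference; supply your own named list to override.
#'
#' @return Named list mapping region label to electrode label vector.
#' @export
#' @examples
#' default_region_map()$A
default_region_map <- function() {
  list(
    A = c("TP7", "T5", "P3", "CP3"),
    B = "FCz",
    C = "T4",
    D = c("O1", "Oz", "T6")
  )
}
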