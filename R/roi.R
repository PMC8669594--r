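#' The 24-region Brodmann-subset atlas
#'
#' Region labels used throughout the pipeline: somatosensory (BA1, BA2,
#' BA3a, BA3b), primary motor (BA4a, BA4p), premotor (BA6), Broca (BA44,
#' BA45) and visual (V1, V2, MT) areas of both hemispheres, suffixed `_L` /
#' `_R`.
#'
#' @return character vector of 24 unique ROI labels
#' @export
grasp_rois <- function() {
  base <- c("BA1", "BA2", "BA3a", "BA3b", "BA4a", "BA4p", "BA6",
            "BA44", "BA45", "V1", "V2", "MT")
  c(paste0(base, "_L"), paste0(base, "_R"))
}

# ROI subsets used by the synthetic generator
motor_rois <- function() c("BA4a", "BA4p", "BA6")
sensorimotor_rois <- function() c("BA1", "BA2", "BA3a", "BA3b")
visual_rois <- function() c("V1", "V2", "MT")

#' Task labels of the six-condition paradigm
#'
#' Five natural reach-and-grasp movements plus a no-movement control.
#'
#' @return character vector of length 6
#' @export
grasp_tasks <- function() {
  c("palmar", "pinch", "push", "twist", "plug", "no-movement")
}
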