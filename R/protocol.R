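#' Default dose grid of the binding assay
#'
#' Eleven log-spaced antibody doses spanning 1e-2 to 1e3 nM.
#'
#' @param n number of doses
#' @param lo,hi dose range endpoints, nM
#' @return numeric vector of doses, nM
#' @export
default_doses <- function(n = 11, lo = 1e-2, hi = 1e3) {
  10^seq(log10(lo), log10(hi), length.out = n)
}

#' Assay protocol
#'
#' Describes the timing of a binding assay simulation: an association phase
#' from t = 0, an optional instantaneous washout of free antibody, and the
#' total simulated horizon. The fitting protocol mimics the flow-cytometry
#' experiment (2 h association at 4 C with receptor turnover suppressed,
#' washout, 15 min detection incubation); the analysis protocol runs 24 h
#' with no washout.
#'
#' @param doses antibody doses, nM (all positive)
#' @param association_s association phase duration, seconds
#' @param washout logical; remove free antibody at `washout_time_s`?
#' @param washout_time_s time of washout, seconds
#' @param detection_s post-washout detection incubation, seconds
#' @param horizon_s total simulated time, seconds
#' @param cells_per_well cell count per well (recorded for provenance)
#' @param clamp_washout if `TRUE`, free antibody is held at zero after
#'   washout (released antibody is removed); if `FALSE` (default), antibody
#'   released after washout re-enters the free pool
#' @return an object of class `assay_protocol`
#' @export
assay_protocol <- function(doses = default_doses(), association_s = 7200,
                           washout = TRUE, washout_time_s = association_s,
                           detection_s = 900,
                           horizon_s = if (washout) washout_time_s + detection_s else 86400,
                           cells_per_well = 1e5, clamp_washout = FALSE) {
  if (any(doses <= 0)) stop("doses must be positive")
  if (washout && washout_time_s > horizon_s)
    stop("washout_time_s must not exceed horizon_s")
  structure(list(doses = doses, association_s = association_s,
                 washout = washout, washout_time_s = washout_time_s,
                 detection_s = detection_s, horizon_s = horizon_s,
                 cells_per_well = cells_per_well,
                 clamp_washout = clamp_washout),
            class = "assay_protocol")
}

#' @rdname assay_protocol
#' @export
fitting_protocol <- function(doses = default_doses(), clamp_washout = FALSE) {
  assay_protocol(doses = doses, association_s = 7200, washout = TRUE,
                 washout_time_s = 7200, detection_s = 900, horizon_s = 8100,
                 clamp_washout = clamp_washout)
}

#' @rdname assay_protocol
#' @param horizon_s total simulated time, seconds
#' @export
analysis_protocol <- function(doses = default_doses(), horizon_s = 86400) {
  assay_protocol(doses = doses, washout = FALSE, horizon_s = horizon_s,
                 detection_s = 0)
}
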