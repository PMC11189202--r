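#' Antibody-receptor binding rate constants
#'
#' Container for the six association/dissociation rate constants of the
#' bivalent antibody binding network plus the unit-conversion constant
#' `alpha`. First-step association constants (`kon_6R`, `kon_8R`) are in
#' nM^-1 s^-1; cross-linking (second-step) constants (`kon_6R_star`,
#' `kon_8R_star`) are in (#/cell)^-1 s^-1; dissociation constants are in
#' s^-1. `alpha` (nM per #/cell) couples the free-antibody concentration to
#' per-cell receptor counts. Dissociation from ternary complexes uses the
#' same `koff` as from binary complexes (similarity of binding sites).
#'
#' When `kon_8R_star` is not supplied it is derived from the detailed-balance
#' thermodynamic cycle constraint,
#' `kon_8R_star = kon_8R * kon_6R_star / kon_6R`, which forces the product of
#' the four equilibrium constants around the binding cycle to unity.
#'
#' @param kon_6R first association to IL-6R, nM^-1 s^-1
#' @param kon_8R first association to IL-8R, nM^-1 s^-1
#' @param kon_6R_star cross-linking association to IL-6R, (#/cell)^-1 s^-1
#' @param koff_6R dissociation from IL-6R, s^-1
#' @param koff_8R dissociation from IL-8R, s^-1
#' @param kon_8R_star cross-linking association to IL-8R, (#/cell)^-1 s^-1;
#'   derived from the cycle constraint when `NULL` (the default)
#' @param alpha unit conversion, nM per (#/cell)
#' @return an object of class `rate_constants` (a named list)
#' @examples
#' rc <- best_fit_rates()
#' equilibrium_constants(rc)
#' cross_arm_efficiency(rc)
#' @export
rate_constants <- function(kon_6R, kon_8R, kon_6R_star, koff_6R, koff_8R,
                           kon_8R_star = NULL, alpha = 8.3e-7) {
  kon_6R <- unname(kon_6R); kon_8R <- unname(kon_8R)
  kon_6R_star <- unname(kon_6R_star); koff_6R <- unname(koff_6R)
  koff_8R <- unname(koff_8R); alpha <- unname(alpha)
  if (!is.null(kon_8R_star)) kon_8R_star <- unname(kon_8R_star)
  vals <- c(kon_6R = kon_6R, kon_8R = kon_8R, kon_6R_star = kon_6R_star,
            koff_6R = koff_6R, koff_8R = koff_8R, alpha = alpha)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rate constants and alpha must be finite and strictly positive")
  derived <- is.null(kon_8R_star)
  if (derived) {
    kon_8R_star <- apply_cycle_constraint(kon_6R, kon_8R, kon_6R_star)
  } else if (kon_8R_star < 0 || !is.finite(kon_8R_star)) {
    stop("kon_8R_star must be finite and non-negative")
  }
  structure(list(kon_6R = kon_6R, kon_8R = kon_8R,
                 kon_6R_star = kon_6R_star, kon_8R_star = kon_8R_star,
                 koff_6R = koff_6R, koff_8R = koff_8R, alpha = alpha,
                 cycle_constrained = derived),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Bivalent antibody binding rate constants\n")
  cat(sprintf("  kon_6R      %.4g nM^-1 s^-1\n", x$kon_6R))
  cat(sprintf("  kon_8R      %.4g nM^-1 s^-1\n", x$kon_8R))
  cat(sprintf("  kon_6R*     %.4g (#/cell)^-1 s^-1\n", x$kon_6R_star))
  cat(sprintf("  kon_8R*     %.4g (#/cell)^-1 s^-1%s\n", x$kon_8R_star,
              if (isTRUE(x$cycle_constrained)) "  [cycle-derived]" else ""))
  cat(sprintf("  koff_6R     %.4g s^-1\n", x$koff_6R))
  cat(sprintf("  koff_8R     %.4g s^-1\n", x$koff_8R))
  cat(sprintf("  alpha       %.4g nM/(#/cell)\n", x$alpha))
  invisible(x)
}

#' Thermodynamic cycle constraint for the cross-linking rate constant
#'
#' The four reactions Ab+R1, Ab+R2, Ab.R2+R1, Ab.R1+R2 form a closed cycle;
#' detailed balance requires the product of equilibrium constants around the
#' cycle to be unity. With equal binary/ternary dissociation constants this
#' reduces to `kon_8R_star / kon_8R = kon_6R_star / kon_6R`, fixing the
#' fourth association constant from the other three.
#'
#' @param kon_6R,kon_8R first-step association constants, nM^-1 s^-1
#' @param kon_6R_star cross-linking constant for IL-6R, (#/cell)^-1 s^-1
#' @return `kon_8R_star` in (#/cell)^-1 s^-1
#' @export
apply_cycle_constraint <- function(kon_6R, kon_8R, kon_6R_star) {
  if (any(!is.finite(c(kon_6R, kon_8R, kon_6R_star))) ||
      any(c(kon_6R, kon_8R, kon_6R_star) <= 0))
    stop("cycle constraint requires strictly positive rate constants")
  kon_8R * (kon_6R_star / kon_6R)
}

#' Product of equilibrium constants around the binding cycle
#'
#' Evaluates K1 * K4 / (K2 * K3) with all four dissociation constants
#' expressed in nM; equals 1 exactly for a cycle-constrained set.
#'
#' @param rc a [rate_constants()] object
#' @return dimensionless cycle product
#' @export
cycle_product <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  K <- equilibrium_constants(rc)
  (K[["KD_6R"]] * K[["KD_8R_star"]]) / (K[["KD_8R"]] * K[["KD_6R_star"]])
}

#' Equilibrium dissociation constants
#'
#' Computes the four K_D values (nM) via K_D = koff / kon, with cross-linking
#' constants first converted to nM^-1 s^-1 through `alpha`.
#'
#' @param rc a [rate_constants()] object
#' @return named numeric vector `KD_6R`, `KD_8R`, `KD_6R_star`, `KD_8R_star`
#'   in nM
#' @export
equilibrium_constants <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  c(KD_6R = rc$koff_6R / rc$kon_6R,
    KD_8R = rc$koff_8R / rc$kon_8R,
    KD_6R_star = rc$koff_6R / (rc$kon_6R_star / rc$alpha),
    KD_8R_star = rc$koff_8R / (rc$kon_8R_star / rc$alpha))
}

#' Cross-arm binding efficiency
#'
#' The ratio chi of the second-step (cross-linking) to first-step association
#' rate constant, with both expressed in nM^-1 s^-1. Under the cycle
#' constraint the IL-6R and IL-8R arm ratios are identical; the IL-6R arm is
#' returned. Larger chi means stronger conversion of binary into ternary
#' complexes (avidity).
#'
#' @param rc a [rate_constants()] object
#' @return dimensionless ratio
#' @export
cross_arm_efficiency <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  (rc$kon_6R_star / rc$alpha) / rc$kon_6R
}

#' Best-fit rate constants from the HEK 293T surface-binding assays
#'
#' The lowest-cost parameter set estimated by multi-start least squares
#' against flow-cytometry dose-response data for tocilizumab, 10H2 and BS1
#' binding to IL-6R/IL-8R-transduced HEK 293T cells, with `kon_8R_star`
#' derived from the thermodynamic cycle constraint.
#'
#' @return a [rate_constants()] object
#' @export
best_fit_rates <- function() {
  rate_constants(kon_6R = 5.92e-6, kon_8R = 9.03e-6, kon_6R_star = 8.11e-8,
                 koff_6R = 5.61e-5, koff_8R = 6.38e-5, alpha = 8.3e-7)
}

#' Unit-conversion constant from assay geometry
#'
#' `alpha` converts a per-cell count to the bulk concentration that count
#' represents in the well: `alpha = cells_per_well * 1e9 / (N_A * V)`.
#' The package default `alpha = 8.3e-7` nM/(#/cell) corresponds to 1e5 cells
#' in roughly 200 uL.
#'
#' @param cells_per_well number of cells per well
#' @param well_volume_ul well volume in microliters
#' @return alpha in nM per (#/cell)
#' @export
alpha_from_geometry <- function(cells_per_well = 1e5, well_volume_ul = 200) {
  stopifnot(cells_per_well > 0, well_volume_ul > 0)
  avogadro <- 6.02214076e23
  cells_per_well * 1e9 / (avogadro * well_volume_ul * 1e-6)
}

#' Restrict a rate-constant set to monovalent binding
#'
#' Returns a copy with both cross-linking association constants set to 0 so
#' that no ternary complexes can form; all other rates are unchanged and the
#' cycle-constraint validation is suspended for the variant. Idempotent.
#'
#' @param rc a [rate_constants()] object
#' @return a `rate_constants` object with zero cross-linking rates
#' @export
restrict_monovalent <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  out <- rc
  out$kon_6R_star <- 0
  out$kon_8R_star <- 0
  out$cycle_constrained <- FALSE
  out
}

#' Swap the IL-6R and IL-8R roles of a rate-constant set
#'
#' Utility for symmetry checks: exchanges the 6R and 8R association and
#' dissociation constants (including the cross-linking pair).
#'
#' @param rc a [rate_constants()] object
#' @return a `rate_constants` object with the receptor roles exchanged
#' @export
swap_receptor_roles <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  out <- rc
  out$kon_6R <- rc$kon_8R; out$kon_8R <- rc$kon_6R
  out$kon_6R_star <- rc$kon_8R_star; out$kon_8R_star <- rc$kon_6R_star
  out$koff_6R <- rc$koff_8R; out$koff_8R <- rc$koff_6R
  out
}

#' Serialize / load rate constants as a flat YAML config
#'
#' Rates are written as a flat key-value mapping with explicit unit strings;
#' units are validated on load.
#'
#' @param rc a [rate_constants()] object
#' @param path file path
#' @return `write_rates`: the path, invisibly; `read_rates`: a
#'   `rate_constants` object
#' @export
write_rates <- function(rc, path) {
  stopifnot(inherits(rc, "rate_constants"))
  x <- list(
    kon_6R = rc$kon_6R, kon_6R_units = "nM^-1 s^-1",
    kon_8R = rc$kon_8R, kon_8R_units = "nM^-1 s^-1",
    kon_6R_star = rc$kon_6R_star, kon_6R_star_units = "(#/cell)^-1 s^-1",
    kon_8R_star = rc$kon_8R_star, kon_8R_star_units = "(#/cell)^-1 s^-1",
    koff_6R = rc$koff_6R, koff_6R_units = "s^-1",
    koff_8R = rc$koff_8R, koff_8R_units = "s^-1",
    alpha = rc$alpha, alpha_units = "nM/(#/cell)",
    cycle_constrained = isTRUE(rc$cycle_constrained))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_rates
#' @export
read_rates <- function(path) {
  x <- yaml::read_yaml(path)
  expected <- c(kon_6R = "nM^-1 s^-1", kon_8R = "nM^-1 s^-1",
                kon_6R_star = "(#/cell)^-1 s^-1",
                kon_8R_star = "(#/cell)^-1 s^-1",
                koff_6R = "s^-1", koff_8R = "s^-1",
                alpha = "nM/(#/cell)")
  for (nm in names(expected)) {
    u <- x[[paste0(nm, "_units")]]
    if (is.null(u) || !identical(u, unname(expected[[nm]])))
      stop(sprintf("config field '%s' missing or has unexpected units (want '%s')",
                   nm, expected[[nm]]))
  }
  rate_constants(kon_6R = x$kon_6R, kon_8R = x$kon_8R,
                 kon_6R_star = x$kon_6R_star, koff_6R = x$koff_6R,
                 koff_8R = x$koff_8R,
                 kon_8R_star = if (isTRUE(x$cycle_constrained)) NULL else x$kon_8R_star,
                 alpha = x$alpha)
}
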