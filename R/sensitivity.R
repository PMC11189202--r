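# Trapezoidal AUC over a dense time course.
.auc_trapz <- function(t, y) {
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Perturb one parameter of a rate set; cross-linking constraint handling:
# "propagate" re-derives kon_8R_star from the cycle whenever one of its
# parents (kon_6R, kon_8R, kon_6R_star) moves; "frozen" keeps kon_8R_star at
# its unperturbed value.
.perturb_rates <- function(rc, parameter, factor,
                           constraint = c("propagate", "frozen")) {
  constraint <- match.arg(constraint)
  out <- unclass(rc)
  out[[parameter]] <- out[[parameter]] * factor
  if (constraint == "propagate" && parameter != "kon_8R_star") {
    out$kon_8R_star <- apply_cycle_constraint(out$kon_6R, out$kon_8R,
                                              out$kon_6R_star)
    out$cycle_constrained <- TRUE
  } else {
    out$cycle_constrained <- FALSE
  }
  class(out) <- "rate_constants"
  out
}

# One local-sensitivity baseline simulation: BS1, no washout, dense output.
.local_sim <- function(rc, dose, r6, r8, horizon_s, options) {
  cl <- cell_line("sensitivity", r6, r8)
  prot <- assay_protocol(doses = dose, washout = FALSE, horizon_s = horizon_s,
                         detection_s = 0)
  simulate_assay("BS1", cl, dose, rc, prot, options)
}

.auc_outputs <- function(sim) {
  ternary_receptor <- 2 * sim$states[, "ternary"]
  total_receptor <- sim$states[, "binary_ab_r1"] + sim$states[, "binary_ab_r2"] +
    ternary_receptor
  c(AUC_ternary = .auc_trapz(sim$time, ternary_receptor),
    AUC_total_bound = .auc_trapz(sim$time, total_receptor))
}

#' Local univariate sensitivity analysis
#'
#' Each rate constant and each initial concentration (BS1 dose, IL-6R,
#' IL-8R) is raised 10% above baseline in a separate simulation of BS1
#' binding (10 nM, 5e4 of each receptor per cell, 2 h, no washout). The
#' outputs are the areas under the curve of the ternary-complex-bound and
#' total bound receptor over the simulation, and sensitivity is the percent
#' change in AUC divided by the percent change in the parameter.
#'
#' @param rates baseline [rate_constants()]
#' @param perturbation relative increase (default 0.10)
#' @param dose baseline BS1 concentration, nM
#' @param r6,r8 baseline receptor expressions, #/cell
#' @param horizon_s simulated time, seconds (default 2 h)
#' @param constraint `"propagate"` (re-derive `kon_8R_star` from the cycle
#'   when its parents move) or `"frozen"`
#' @param options a [model_options()] list
#' @return data.frame: `parameter`, `output_metric`, `baseline`,
#'   `perturbed`, `sensitivity`
#' @export
local_sensitivity <- function(rates = best_fit_rates(), perturbation = 0.10,
                              dose = 10, r6 = 5e4, r8 = 5e4,
                              horizon_s = 7200,
                              constraint = c("propagate", "frozen"),
                              options = model_options()) {
  constraint <- match.arg(constraint)
  base_sim <- .local_sim(rates, dose, r6, r8, horizon_s, options)
  base_auc <- .auc_outputs(base_sim)
  rate_pars <- c(fit_param_names(), "kon_8R_star")
  conc_pars <- c("dose_BS1", "conc_IL6R", "conc_IL8R")
  rows <- list()
  for (par in c(rate_pars, conc_pars)) {
    if (perturbation == 0) {
      pert_auc <- base_auc
    } else if (par %in% rate_pars) {
      rc <- .perturb_rates(rates, par, 1 + perturbation, constraint)
      pert_auc <- .auc_outputs(.local_sim(rc, dose, r6, r8, horizon_s, options))
    } else {
      args <- list(dose = dose, r6 = r6, r8 = r8)
      key <- switch(par, dose_BS1 = "dose", conc_IL6R = "r6", conc_IL8R = "r8")
      args[[key]] <- args[[key]] * (1 + perturbation)
      pert_auc <- .auc_outputs(.local_sim(rates, args$dose, args$r6, args$r8,
                                          horizon_s, options))
    }
    for (metric in names(base_auc)) {
      sens <- if (perturbation == 0) 0 else
        ((pert_auc[[metric]] - base_auc[[metric]]) / base_auc[[metric]]) /
        perturbation
      rows[[length(rows) + 1]] <- data.frame(
        parameter = par, output_metric = metric,
        baseline = base_auc[[metric]], perturbed = pert_auc[[metric]],
        sensitivity = sens)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Global univariate sensitivity analysis
#'
#' Each rate constant is varied independently over a log grid spanning two
#' orders of magnitude below and above its baseline value; for each offset
#' and each dose, BS1 binding is simulated for 24 hours (no washout,
#' receptor concentrations as initial values) and the terminal fractional
#' occupancy (ternary and total, over IL-6R + IL-8R) is reported.
#'
#' @param rates baseline [rate_constants()]
#' @param doses BS1 dose panel, nM
#' @param n_offsets points on the log10 offset grid (default 41)
#' @param span half-width of the offset grid in decades (default 2)
#' @param r6,r8 receptor expressions, #/cell
#' @param horizon_s simulated time, seconds (default 24 h)
#' @param constraint cycle-constraint propagation mode, see
#'   [local_sensitivity()]
#' @param options a [model_options()] list
#' @return long data.frame: `parameter`, `offset_log10`, `dose`,
#'   `frac_ternary`, `frac_total`
#' @export
global_sensitivity <- function(rates = best_fit_rates(),
                               doses = c(1, 10, 100), n_offsets = 41,
                               span = 2, r6 = 5e4, r8 = 5e4,
                               horizon_s = 86400,
                               constraint = c("propagate", "frozen"),
                               options = model_options()) {
  constraint <- match.arg(constraint)
  offsets <- seq(-span, span, length.out = n_offsets)
  cl <- cell_line("sensitivity", r6, r8)
  rate_pars <- c(fit_param_names(), "kon_8R_star")
  rows <- list()
  for (par in rate_pars) {
    for (off in offsets) {
      rc <- .perturb_rates(rates, par, 10^off, constraint)
      for (d in doses) {
        prot <- assay_protocol(doses = d, washout = FALSE,
                               horizon_s = horizon_s, detection_s = 0)
        occ <- summarize_occupancy(simulate_assay("BS1", cl, d, rc, prot,
                                                  options))
        rows[[length(rows) + 1]] <- data.frame(
          parameter = par, offset_log10 = off, dose = d,
          frac_ternary = occ$frac_ternary, frac_total = occ$frac_total)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
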