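#' Model options
#'
#' Numerical and structural options for the mass-action simulations.
#'
#' `stat_factor` controls the statistical factors applied to homobivalent
#' (monospecific) antibodies, which carry two identical arms: with the
#' default `2`, the first association proceeds at `2*kon*[Ab][R]` (either arm
#' can bind) and ternary-to-binary dissociation at `2*koff*[R.Ab.R]` (either
#' arm can release); `1` disables the factors for sensitivity analyses of
#' this structural choice. Heterobivalent antibodies are unaffected.
#'
#' @param stat_factor 2 (default) or 1
#' @param rtol relative integration tolerance
#' @param atol_scale absolute tolerance as a fraction of each species'
#'   typical scale
#' @param n_out number of output points per simulation phase for trajectory
#'   output
#' @param max_steps integrator step budget
#' @return a list of class `model_options`
#' @export
model_options <- function(stat_factor = 2, rtol = 1e-8, atol_scale = 1e-12,
                          n_out = 201, max_steps = 2000000L) {
  stopifnot(stat_factor %in% c(1, 2), rtol > 0, atol_scale > 0, n_out >= 2)
  structure(list(stat_factor = stat_factor, rtol = rtol,
                 atol_scale = atol_scale, n_out = as.integer(n_out),
                 max_steps = as.integer(max_steps)),
            class = "model_options")
}

# Canonical species frame columns (r1 = IL-6R, r2 = IL-8R).
.species_cols <- c("free_ab", "free_r1", "free_r2", "binary_ab_r1",
                   "binary_ab_r2", "ternary")

# Network setup for one antibody on one cell line. Returns the C++ network
# type, parameter vector, initial state, typical scales, and the mapping of
# network species into the canonical 6-column frame.
.network_spec <- function(antibody, cell, dose, rc, options) {
  ab <- as_antibody(antibody)
  r1 <- cell$il6r_per_cell
  r2 <- cell$il8r_per_cell
  rmax <- max(r1, r2, 1)
  if (ab$bispecific) {
    list(type = 0L,
         p = c(rc$kon_6R, rc$kon_8R, rc$kon_6R_star, rc$kon_8R_star,
               rc$koff_6R, rc$koff_8R, rc$alpha),
         y0 = c(dose, r1, r2, 0, 0, 0),
         scale = c(max(dose, 1), rep(rmax, 5)),
         map = c(1L, 2L, 3L, 4L, 5L, 6L),  # already canonical
         ternary_comp = c(il6r = 1, il8r = 1))
  } else if (ab$arm_targets[1] == "IL6R") {
    list(type = 1L,
         p = c(rc$kon_6R, rc$kon_6R_star, rc$koff_6R, rc$alpha,
               options$stat_factor),
         y0 = c(dose, r1, 0, 0),
         scale = c(max(dose, 1), rep(max(r1, 1), 3)),
         map = c(1L, 2L, 4L, 6L),  # Ab, R -> free_r1, C -> binary_ab_r1, T
         ternary_comp = c(il6r = 2, il8r = 0))
  } else {
    list(type = 1L,
         p = c(rc$kon_8R, rc$kon_8R_star, rc$koff_8R, rc$alpha,
               options$stat_factor),
         y0 = c(dose, r2, 0, 0),
         scale = c(max(dose, 1), rep(max(r2, 1), 3)),
         map = c(1L, 3L, 5L, 6L),  # Ab, R -> free_r2, C -> binary_ab_r2, T
         ternary_comp = c(il6r = 0, il8r = 2))
  }
}

# Integrate one network through the protocol phases; returns time vector and
# the raw species matrix (network layout, not yet mapped to the frame).
.integrate_phases <- function(spec, protocol, options, terminal_only = FALSE) {
  atol <- options$atol_scale * spec$scale
  npts <- if (terminal_only) 2L else options$n_out
  phase_times <- function(t0, t1) seq(t0, t1, length.out = npts)
  run <- function(y0, times, clamp) {
    tryCatch(
      .ode_solve_cpp(spec$type, spec$p, y0, times, options$rtol, atol,
                     clamp_ab = clamp, max_steps = options$max_steps),
      error = function(e) stop(simpleError(paste0(
        "integrator failure: ", conditionMessage(e)))))
  }
  if (protocol$washout && protocol$washout_time_s < protocol$horizon_s) {
    t1 <- phase_times(0, protocol$washout_time_s)
    m1 <- run(spec$y0, t1, clamp = FALSE)
    y_w <- m1[nrow(m1), ]
    y_w[1] <- 0  # washout: free antibody removed
    t2 <- phase_times(protocol$washout_time_s, protocol$horizon_s)
    m2 <- run(y_w, t2, clamp = protocol$clamp_washout)
    list(time = c(t1, t2[-1]), y = rbind(m1, m2[-1, , drop = FALSE]))
  } else {
    tt <- phase_times(0, protocol$horizon_s)
    list(time = tt, y = run(spec$y0, tt, clamp = FALSE))
  }
}

#' Simulate a binding assay
#'
#' Integrates the mass-action network for one antibody construct on one cell
#' line at a single dose through the phases of an [assay_protocol()]. If the
#' protocol includes a washout, the free antibody concentration is reset to
#' zero at the washout time and the integration continues (released antibody
#' re-enters the free pool unless `clamp_washout` is set).
#'
#' @param antibody an [antibody_construct()] or its name
#' @param cell_line a [cell_line()] or its name
#' @param dose initial antibody concentration, nM
#' @param rates a [rate_constants()] object
#' @param protocol an [assay_protocol()]
#' @param options a [model_options()] list
#' @return an object of class `bsab_sim` with elements `time` (s) and
#'   `states` (matrix, one row per time point, canonical species columns:
#'   `free_ab` in nM, all others in #/cell)
#' @export
simulate_assay <- function(antibody, cell_line, dose, rates = best_fit_rates(),
                           protocol = fitting_protocol(),
                           options = model_options()) {
  ab <- as_antibody(antibody)
  cl <- as_cell_line(cell_line)
  stopifnot(inherits(rates, "rate_constants"), dose > 0)
  spec <- .network_spec(ab, cl, dose, rates, options)
  res <- .integrate_phases(spec, protocol, options)
  states <- matrix(0, nrow = length(res$time), ncol = 6,
                   dimnames = list(NULL, .species_cols))
  states[, spec$map] <- res$y
  # a homobivalent antibody leaves the non-cognate receptor untouched; report
  # it at its constant level rather than zero
  if (!ab$bispecific) {
    if (ab$arm_targets[1] == "IL6R") states[, "free_r2"] <- cl$il8r_per_cell
    else states[, "free_r1"] <- cl$il6r_per_cell
  }
  states[states < 0] <- 0  # clip integrator noise for reporting
  structure(list(time = res$time, states = states, antibody = ab,
                 cell_line = cl, dose = dose, rates = rates,
                 protocol = protocol, options = options,
                 ternary_comp = spec$ternary_comp),
            class = "bsab_sim")
}

#' @export
print.bsab_sim <- function(x, ...) {
  cat(sprintf("Binding simulation: %s on %s, %.3g nM, %d time points\n",
              x$antibody$name, x$cell_line$name, x$dose, length(x$time)))
  tb <- total_bound_antibody(terminal_state(x))
  cat(sprintf("  terminal bound antibody: %.4g /cell\n", tb))
  invisible(x)
}

#' Terminal species state of a simulation
#' @param sim a `bsab_sim` or `bsab_combo_sim`
#' @return named species vector with a `ternary_comp` attribute recording
#'   how many IL-6R/IL-8R each ternary complex contains
#' @export
terminal_state <- function(sim) {
  UseMethod("terminal_state")
}

#' @export
terminal_state.bsab_sim <- function(sim) {
  st <- sim$states[nrow(sim$states), ]
  attr(st, "ternary_comp") <- sim$ternary_comp
  st
}

#' Simulate the combination of the two monospecific antibodies
#'
#' Tocilizumab and 10H2 are dosed jointly on one cell line; because each
#' monoclonal binds only its own receptor, the joint network decouples into
#' two homobivalent systems over the shared receptor pools, which are
#' integrated separately and reported together. `ratio` is the tocilizumab
#' fraction of the total dose (default 1:1, i.e. equal nM of each antibody).
#'
#' @param cell_line a [cell_line()] or its name
#' @param total_dose combined initial antibody concentration, nM
#' @param rates a [rate_constants()] object
#' @param protocol an [assay_protocol()]
#' @param ratio tocilizumab fraction of `total_dose` in (0, 1)
#' @param options a [model_options()] list
#' @return an object of class `bsab_combo_sim` holding both component
#'   simulations
#' @export
simulate_mab_combo <- function(cell_line, total_dose,
                               rates = best_fit_rates(),
                               protocol = analysis_protocol(),
                               ratio = 0.5, options = model_options()) {
  stopifnot(ratio > 0, ratio < 1)
  cl <- as_cell_line(cell_line)
  sims <- list(
    tocilizumab = simulate_assay("tocilizumab", cl, total_dose * ratio,
                                 rates, protocol, options),
    `10H2` = simulate_assay("10H2", cl, total_dose * (1 - ratio),
                            rates, protocol, options))
  structure(list(sims = sims, cell_line = cl, dose = total_dose,
                 ratio = ratio, protocol = protocol),
            class = "bsab_combo_sim")
}

#' @export
terminal_state.bsab_combo_sim <- function(sim) {
  lapply(sim$sims, terminal_state)
}

#' Total receptor-bound antibody in a state
#'
#' Each binary and each ternary complex contains exactly one antibody, so
#' the bound-antibody count per cell is the sum of all complex counts. This
#' is the model quantity compared to the MFI readout of the flow-cytometry
#' assay.
#'
#' @param state a species vector (from [terminal_state()]), a `bsab_sim`, or
#'   a `bsab_combo_sim`
#' @return bound antibody, #/cell
#' @export
total_bound_antibody <- function(state) {
  if (inherits(state, "bsab_sim")) state <- terminal_state(state)
  if (inherits(state, "bsab_combo_sim"))
    return(sum(vapply(state$sims, total_bound_antibody, numeric(1))))
  unname(state[["binary_ab_r1"]] + state[["binary_ab_r2"]] + state[["ternary"]])
}

#' Receptor occupancy summary
#'
#' Splits bound receptor into binary and ternary contributions. Receptor
#' bound in binary complexes equals the binary complex count; each ternary
#' complex occupies two receptors. Fractions divide by the cell line's total
#' receptor count (IL-6R + IL-8R); per-receptor occupancies divide the
#' receptor-specific bound count by that receptor's total.
#'
#' @param state a species vector, `bsab_sim`, or `bsab_combo_sim`
#' @param cell_line a [cell_line()] (optional when `state` is a simulation)
#' @return a one-row data.frame: `bound_binary`, `bound_ternary`,
#'   `bound_total` (#/cell), `frac_binary`, `frac_ternary`, `frac_total`,
#'   `occ_il6r`, `occ_il8r`, and `zero_receptor` flag
#' @export
summarize_occupancy <- function(state, cell_line = NULL) {
  if (inherits(state, "bsab_combo_sim")) {
    parts <- lapply(state$sims, function(s)
      summarize_occupancy(terminal_state(s), s$cell_line))
    return(.combine_occupancy(parts, state$cell_line))
  }
  if (inherits(state, "bsab_sim")) {
    cell_line <- state$cell_line
    state <- terminal_state(state)
  }
  cl <- as_cell_line(cell_line)
  comp <- attr(state, "ternary_comp")
  if (is.null(comp)) comp <- c(il6r = 1, il8r = 1)
  bound_binary <- state[["binary_ab_r1"]] + state[["binary_ab_r2"]]
  bound_ternary <- 2 * state[["ternary"]]
  bound_total <- bound_binary + bound_ternary
  r_tot <- cl$il6r_per_cell + cl$il8r_per_cell
  zero <- r_tot == 0
  frac <- function(x, denom) if (denom > 0) x / denom else 0
  il6r_bound <- state[["binary_ab_r1"]] + comp[["il6r"]] * state[["ternary"]]
  il8r_bound <- state[["binary_ab_r2"]] + comp[["il8r"]] * state[["ternary"]]
  data.frame(bound_binary = unname(bound_binary),
             bound_ternary = unname(bound_ternary),
             bound_total = unname(bound_total),
             frac_binary = frac(bound_binary, r_tot),
             frac_ternary = frac(bound_ternary, r_tot),
             frac_total = frac(bound_total, r_tot),
             occ_il6r = frac(il6r_bound, cl$il6r_per_cell),
             occ_il8r = frac(il8r_bound, cl$il8r_per_cell),
             zero_receptor = zero)
}

.combine_occupancy <- function(parts, cl) {
  counts <- Reduce(`+`, lapply(parts, function(p)
    c(p$bound_binary, p$bound_ternary,
      p$occ_il6r * cl$il6r_per_cell, p$occ_il8r * cl$il8r_per_cell)))
  bound_binary <- counts[1]; bound_ternary <- counts[2]
  r_tot <- cl$il6r_per_cell + cl$il8r_per_cell
  frac <- function(x, denom) if (denom > 0) x / denom else 0
  data.frame(bound_binary = bound_binary, bound_ternary = bound_ternary,
             bound_total = bound_binary + bound_ternary,
             frac_binary = frac(bound_binary, r_tot),
             frac_ternary = frac(bound_ternary, r_tot),
             frac_total = frac(bound_binary + bound_ternary, r_tot),
             occ_il6r = frac(counts[3], cl$il6r_per_cell),
             occ_il8r = frac(counts[4], cl$il8r_per_cell),
             zero_receptor = r_tot == 0)
}

#' Conservation drift of a simulation
#'
#' Maximum relative drift of the receptor conservation sums and (up to the
#' washout) the antibody conservation sum over all reported time points.
#' Mass-action networks conserve these linear combinations exactly; the
#' integrator should hold them to tolerance.
#'
#' @param sim a `bsab_sim`
#' @return largest relative deviation observed
#' @export
conservation_error <- function(sim) {
  stopifnot(inherits(sim, "bsab_sim"))
  st <- sim$states
  comp <- sim$ternary_comp
  cl <- sim$cell_line
  rel_drift <- function(total, ref) {
    if (ref <= 0) return(max(abs(total)))
    max(abs(total - ref) / ref)
  }
  drifts <- c()
  if (cl$il6r_per_cell > 0) {
    tot6 <- st[, "free_r1"] + st[, "binary_ab_r1"] + comp[["il6r"]] * st[, "ternary"]
    drifts <- c(drifts, rel_drift(tot6, cl$il6r_per_cell))
  }
  if (cl$il8r_per_cell > 0) {
    tot8 <- st[, "free_r2"] + st[, "binary_ab_r2"] + comp[["il8r"]] * st[, "ternary"]
    drifts <- c(drifts, rel_drift(tot8, cl$il8r_per_cell))
  }
  pre <- if (sim$protocol$washout)
    sim$time <= sim$protocol$washout_time_s else rep(TRUE, length(sim$time))
  ab_tot <- st[pre, "free_ab"] + sim$rates$alpha *
    (st[pre, "binary_ab_r1"] + st[pre, "binary_ab_r2"] + st[pre, "ternary"])
  drifts <- c(drifts, rel_drift(ab_tot, sim$dose))
  max(drifts)
}
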